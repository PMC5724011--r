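test_that("coverage and redundancy match direct counts on the worked example", {
  rep_ <- coverage_redundancy(tibble::tibble(start = c(1L, 5L), end = c(10L, 15L)), 20)
  # residues 1-4 once, 5-10 twice, 11-15 once: 21 peptide-residues / 15 covered
  expect_equal(rep_$coverage_percent, 75)
  expect_equal(rep_$mean_redundancy, 21 / 15)

  none <- coverage_redundancy(tibble::tibble(start = integer(), end = integer()), 20)
  expect_equal(none$coverage_percent, 0)
  expect_true(is.na(none$mean_redundancy))

  full <- coverage_redundancy(tibble::tibble(start = 1L, end = 20L), 20)
  expect_equal(full$coverage_percent, 100)
  expect_equal(full$mean_redundancy, 1.0)

  expect_error(coverage_redundancy(tibble::tibble(start = 1L, end = 2L), 0),
               "protein_length")
})

test_that("coverage and redundancy equal the per-residue counting oracle", {
  set.seed(404)
  for (i in 1:100) {
    L <- sample(1:300, 1)
    peps <- random_peptide_map(L, sample(0:100, 1))
    got <- coverage_redundancy(peps, L)
    want <- oracle_coverage(peps, L)
    expect_equal(got$coverage_percent, want$coverage_percent)
    expect_equal(got$mean_redundancy, want$mean_redundancy)
  }
})

test_that("normalized uptake increase follows the reference-time definition", {
  base <- toy_table()
  # at time 100: loaded means 3.05, receptive 3.65
  ni <- normalized_increase(base, 2L, 9L, "loaded", "receptive", ref_time = 100)
  expect_equal(ni$mean, (3.65 - 3.05) / 3.05)
  expect_equal(mean(ni$replicates), ni$mean, tolerance = 1e-12)

  # pert == ref -> 0; pert = 2 x ref -> 1; (2.0 -> 2.5) -> 0.25
  same <- base
  same$uptake[same$state == "receptive"] <- same$uptake[same$state == "loaded"]
  expect_equal(normalized_increase(same, 2L, 9L, "loaded", "receptive", 100)$mean, 0)
  dbl <- base
  dbl$uptake[dbl$state == "receptive"] <- 2 * dbl$uptake[dbl$state == "loaded"]
  expect_equal(normalized_increase(dbl, 2L, 9L, "loaded", "receptive", 100)$mean, 1.0)
  q <- base
  q$uptake[q$state == "loaded" & q$time == 100] <- 2.0
  q$uptake[q$state == "receptive" & q$time == 100] <- 2.5
  expect_equal(normalized_increase(q, 2L, 9L, "loaded", "receptive", 100)$mean, 0.25)

  # zero denominator -> excluded with a flag, not a value
  z <- base
  z$uptake[z$state == "loaded" & z$time == 100] <- 0
  ni0 <- normalized_increase(z, 2L, 9L, "loaded", "receptive", 100)
  expect_true(ni0$excluded)
  expect_true(is.na(ni0$mean))

  expect_error(normalized_increase(base, 2L, 9L, "loaded", "receptive", 777),
               "not measured")
})

test_that("the paired t test matches stats::t.test to 1e-10", {
  a <- c(1.1, 2.0, 2.9, 4.2)
  b <- c(1.0, 1.8, 3.1, 3.9)
  got <- paired_t_test(a, b)
  want <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-10)
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
  expect_equal(got$df, unname(want$parameter))

  set.seed(505)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    got <- paired_t_test(x, y)
    want <- stats::t.test(x, y, paired = TRUE)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
  }
})

test_that("the paired t test is antisymmetric and handles degenerate inputs", {
  set.seed(606)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  ab <- paired_t_test(x, y); ba <- paired_t_test(y, x)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)

  ident <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_true(ident$degenerate)

  # constant non-zero difference: zero variance, flagged degenerate
  const <- paired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(const$degenerate)
  expect_equal(const$p, 0)
  expect_equal(const$t, -Inf)

  expect_error(paired_t_test(1, 1), "n >= 2")
  expect_error(paired_t_test(c(1, NA, 3), c(1, 2, 3)), "non-finite|equal length")
})

test_that("per-peptide comparisons match stats::t.test on raw replicates", {
  set.seed(707)
  for (i in 1:50) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1, 1, 0.3); y <- rnorm(n2, 1.4, 0.5)
    ref <- tibble::tibble(time = 1, mean = mean(x), sd = sd(x), n = n1)
    pert <- tibble::tibble(time = 1, mean = mean(y), sd = sd(y), n = n2)
    for (method in c("pooled", "welch")) {
      got <- peptide_state_comparison(ref, pert, method = method)
      want <- stats::t.test(y, x, var.equal = method == "pooled") # pert - ref
      expect_equal(got$per_time$t, unname(want$statistic), tolerance = 1e-10)
      expect_equal(got$per_time$df, unname(want$parameter), tolerance = 1e-10)
      expect_equal(got$per_time$p, want$p.value, tolerance = 1e-10)
    }
  }
})

test_that("state comparisons flag clear separations and not identical stats", {
  ref <- tibble::tibble(time = c(1, 10), mean = c(1, 2), sd = c(0.1, 0.1), n = 3)
  expect_false(peptide_state_comparison(ref, ref)$significant)

  # means differing by 10 pooled SDs
  pert <- dplyr::mutate(ref, mean = mean + 10 * sqrt(2 / 3) * 0.1)
  cmp <- peptide_state_comparison(ref, pert, alpha = 0.05)
  expect_true(cmp$significant)

  # zero-variance equal means: degenerate, not significant
  z <- tibble::tibble(time = 1, mean = 1, sd = 0, n = 3)
  zc <- peptide_state_comparison(z, z)
  expect_false(zc$significant)
  expect_true(zc$per_time$degenerate)

  expect_error(peptide_state_comparison(dplyr::mutate(ref, n = 1), ref),
               ">= 2 replicates")
})

test_that("domain-level paired t tests have power under perturbation and level under the null", {
  # membrane-proximal-domain analog: a mild, domain-wide protection drop
  cfg <- demo_scenario_config(seed = 11)
  cfg$proteins <- cfg$proteins["hc_A"]
  cfg$regions <- tibble::tibble(protein = "hc_A", start = 190L, end = 260L, fold = 3)
  sc <- make_two_state_scenario(cfg)
  stats_tbl <- uptake_stats(sc$tables$hc_A)
  at_ref <- stats_tbl[abs(stats_tbl$time - 4.34 * 60) < 1e-9 &
                        stats_tbl$start >= 190 & stats_tbl$end <= 260, ]
  j <- dplyr::inner_join(
    at_ref[at_ref$state == "loaded", c("start", "end", "mean")],
    at_ref[at_ref$state == "receptive", c("start", "end", "mean")],
    by = c("start", "end"), suffix = c("_ref", "_pert"))
  expect_gte(nrow(j), 3)
  expect_lt(paired_t_test(j$mean_pert, j$mean_ref)$p, 0.01)

  # same domain, null scenario: no rejection at alpha = 0.01
  cfg$regions <- cfg$regions[0, ]
  sc0 <- make_two_state_scenario(cfg)
  stats0 <- uptake_stats(sc0$tables$hc_A)
  at0 <- stats0[abs(stats0$time - 4.34 * 60) < 1e-9 &
                  stats0$start >= 190 & stats0$end <= 260, ]
  j0 <- dplyr::inner_join(
    at0[at0$state == "loaded", c("start", "end", "mean")],
    at0[at0$state == "receptive", c("start", "end", "mean")],
    by = c("start", "end"), suffix = c("_ref", "_pert"))
  expect_gt(paired_t_test(j0$mean_pert, j0$mean_ref)$p, 0.01)
})
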