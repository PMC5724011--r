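test_that("spectrum construction enforces its invariants", {
  expect_error(hdx_spectrum(c(1, 2), c(1, 1, 1)), "lengths differ")
  expect_error(hdx_spectrum(c(2, 1), c(1, 1)), "strictly increasing")
  expect_error(hdx_spectrum(c(1, 2), c(-1, 1)), "negative")
  expect_error(hdx_spectrum(c(1, 2), c(0, 0)), "all intensities")
})

test_that("envelope limits sit at the undeuterated and saturated positions", {
  undeut <- simulate_envelope(7, tibble::tibble(p = 0, weight = 1), 1031, 1)
  expect_equal(centroid_mass(undeut), 1031)
  expect_equal(sum(undeut$intensity > 1e-12), 1L)

  sat <- simulate_envelope(7, tibble::tibble(p = 1, weight = 1), 1031, 1)
  expect_equal(centroid_mass(sat), 1031 + 7 * 1.00628)

  expect_error(simulate_envelope(7, tibble::tibble(p = 1.4, weight = 1), 1031),
               "probabilities")
  expect_error(simulate_envelope(7, tibble::tibble(p = c(0.2, 0.4),
                                                   weight = c(0.7, 0.7)), 1031),
               "sum to 1")
})

test_that("a mixture envelope equals the hand-computed binomial mixture", {
  pops <- tibble::tibble(p = c(0.1, 0.9), weight = c(0.5, 0.5))
  spec <- simulate_envelope(7, pops, 1000, 1)
  k <- 0:7
  want <- 0.5 * choose(7, k) * 0.1^k * 0.9^(7 - k) +
    0.5 * choose(7, k) * 0.9^k * 0.1^(7 - k)
  expect_equal(spec$intensity, want, tolerance = 1e-12)
})

test_that("centroids follow the binomial mean and mixture linearity", {
  # centroid = base_mz + n p dm / z
  for (p in c(0.2, 0.5, 0.73)) {
    spec <- simulate_envelope(10, tibble::tibble(p = p, weight = 1), 500, 2)
    expect_equal(centroid_mass(spec), 500 + 10 * p * 1.00628 / 2,
                 tolerance = 1e-9)
  }
  # two equal peaks at 1031 and 1033 centroid at 1032
  expect_equal(centroid_mass(hdx_spectrum(c(1031, 1033), c(1, 1))), 1032)
  # mixture centroid = weight-average of component centroids
  w <- 0.3
  mix <- simulate_envelope(9, tibble::tibble(p = c(0.2, 0.8), weight = c(w, 1 - w)),
                           800, 1)
  c1 <- centroid_mass(simulate_envelope(9, tibble::tibble(p = 0.2, weight = 1), 800, 1))
  c2 <- centroid_mass(simulate_envelope(9, tibble::tibble(p = 0.8, weight = 1), 800, 1))
  expect_equal(centroid_mass(mix), w * c1 + (1 - w) * c2, tolerance = 1e-9)
})

test_that("modality classification separates single and two-population envelopes", {
  uni <- simulate_envelope(10, tibble::tibble(p = 0.4, weight = 1), 1000, 1)
  expect_equal(classify_modality(uni)$modality, "unimodal")

  bi <- simulate_envelope(10, tibble::tibble(p = c(0.05, 0.9), weight = c(0.5, 0.5)),
                          1000, 1)
  call <- classify_modality(bi)
  expect_equal(call$modality, "bimodal")
  expect_equal(call$components$p, c(0.05, 0.9), tolerance = 0.05)

  # flat two-peak toy: all mass at the extremes
  flat <- hdx_spectrum(1000 + (0:6) * 1.00628,
                       c(1, rep(0, 5), 1))
  expect_equal(classify_modality(flat)$modality, "bimodal")

  expect_error(classify_modality(hdx_spectrum(c(1, 2), c(1, 1))), ">= 3 peaks")
})

test_that("modality classification is invariant to uniform intensity scaling", {
  set.seed(808)
  for (i in 1:10) {
    p1 <- runif(1, 0.05, 0.4)
    spec <- simulate_envelope(12, tibble::tibble(p = c(p1, p1 + 0.45),
                                                 weight = c(0.5, 0.5)), 900, 1)
    a <- classify_modality(spec)
    spec$intensity <- spec$intensity * 1e6
    b <- classify_modality(spec)
    expect_equal(a$modality, b$modality)
    expect_equal(a$delta_bic, b$delta_bic, tolerance = 1e-6)
  }
})

test_that("misclassification is below 5% on well-separated benchmark spectra", {
  set.seed(909)
  n_spectra <- 200
  wrong <- 0
  for (i in seq_len(n_spectra)) {
    n_sites <- sample(8:16, 1)
    bimodal <- i %% 2 == 0
    pops <- if (bimodal) {
      p1 <- runif(1, 0.05, 0.5)
      w <- runif(1, 0.3, 0.7)
      tibble::tibble(p = c(p1, p1 + runif(1, 0.4, 0.45)), weight = c(w, 1 - w))
    } else {
      tibble::tibble(p = runif(1, 0.15, 0.85), weight = 1)
    }
    spec <- simulate_envelope(n_sites, pops, 1000, 1)
    spec$intensity <- spec$intensity * exp(rnorm(length(spec$intensity), 0, 0.02))
    call <- classify_modality(spec)
    if ((call$modality == "bimodal") != bimodal) wrong <- wrong + 1
  }
  expect_lt(wrong / n_spectra, 0.05)
})
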