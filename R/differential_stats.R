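# Dataset-level statistics: coverage/redundancy of the peptide map,
# normalized uptake-increase values, the paired two-tailed t test over
# peptides, and per-peptide Welch comparisons between states.

#' Coverage and redundancy of a peptide map
#'
#' Coverage is the percentage of residues under the union of the peptide
#' intervals; redundancy is the mean, over covered residues only, of the
#' number of peptides containing each residue (full interval membership —
#' this is a map statistic, with no N-terminus exclusion).
#'
#' @param peptides tibble with `start`, `end` (1-based inclusive).
#' @param protein_length protein length in residues (> 0).
#' @return list of class `coverage_report`: `coverage_percent`,
#'   `mean_redundancy` (`NA` when nothing is covered), `n_peptides`.
#' @examples
#' coverage_redundancy(tibble::tibble(start = c(1, 5), end = c(10, 15)), 20)
#' @export
coverage_redundancy <- function(peptides, protein_length) {
  if (protein_length <= 0) stop("protein_length must be > 0", call. = FALSE)
  L <- as.integer(protein_length)
  counts <- integer(L)
  if (nrow(peptides) > 0) {
    if (any(peptides$start < 1L) || any(peptides$end > L) ||
        any(peptides$start > peptides$end)) {
      stop("invalid peptide interval", call. = FALSE)
    }
    for (i in seq_len(nrow(peptides))) {
      idx <- peptides$start[i]:peptides$end[i]
      counts[idx] <- counts[idx] + 1L
    }
  }
  covered <- counts > 0L
  structure(
    list(
      coverage_percent = 100 * sum(covered) / L,
      mean_redundancy = if (any(covered)) mean(counts[covered]) else NA_real_,
      n_peptides = nrow(peptides)
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %.1f%% coverage, redundancy %.2f, %d peptides\n",
              x$coverage_percent, x$mean_redundancy, x$n_peptides))
  invisible(x)
}

#' Normalized uptake increase for one peptide
#'
#' The increase in deuterium uptake caused by the perturbation, normalized
#' to the reference state's uptake at a long labeling time (default
#' 4.34 h): `(mean_pert - mean_ref) / mean_ref`, both at `ref_time`.
#' Per-replicate values pair replicate indices in the numerator while
#' keeping the reference mean as denominator, so their mean equals the
#' summary value. A non-positive denominator excludes the peptide with a
#' flag rather than returning a value.
#'
#' @param table uptake table containing both states.
#' @param start,end peptide interval identifying the peptide.
#' @param ref_state,pert_state state names.
#' @param ref_time labeling time (minutes) used for both numerator and
#'   denominator; default 4.34 h.
#' @return list of class `normalized_increase`: `peptide`, `replicates`,
#'   `mean`, `sd`, `excluded`.
#' @export
normalized_increase <- function(table, start, end, ref_state, pert_state,
                                ref_time = 4.34 * 60) {
  validate_uptake_table(table)
  near <- function(a, b) abs(a - b) < 1e-9
  sub <- table[table$start == start & table$end == end & near(table$time, ref_time), ]
  ref <- sub$uptake[sub$state == ref_state][order(sub$replicate[sub$state == ref_state])]
  pert <- sub$uptake[sub$state == pert_state][order(sub$replicate[sub$state == pert_state])]
  if (length(ref) == 0L || length(pert) == 0L) {
    stop(sprintf("peptide (%d, %d) not measured in both states at ref_time %.4g min",
                 start, end, ref_time), call. = FALSE)
  }
  denom <- mean(ref)
  out <- list(peptide = c(start = start, end = end), replicates = numeric(0),
              mean = NA_real_, sd = NA_real_, excluded = FALSE)
  if (denom <= 0) {
    out$excluded <- TRUE
    class(out) <- "normalized_increase"
    return(out)
  }
  k <- min(length(ref), length(pert))
  reps <- (pert[seq_len(k)] - ref[seq_len(k)]) / denom
  out$replicates <- reps
  out$mean <- (mean(pert) - denom) / denom
  out$sd <- if (k >= 2L) stats::sd(reps) else 0
  class(out) <- "normalized_increase"
  out
}

#' Paired two-tailed t test over peptides
#'
#' Standard paired t statistic on the per-peptide differences `a - b`,
#' with `df = n - 1` and a two-sided p value. A zero-variance difference
#' vector is a degenerate case: it is flagged, with `t = 0, p = 1` when
#' the mean difference is also zero and `|t| = Inf, p = 0` otherwise.
#'
#' @param a,b equal-length numeric vectors, paired by peptide.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("paired t test needs n >= 2", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values", call. = FALSE)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    m <- mean(d)
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0,
                df = n - 1L, mean_diff = m, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1),
       df = n - 1L, mean_diff = mean(d), degenerate = FALSE)
}

# Two-sample t from summary statistics (mean, sd, n per group), t for
# pert - ref. method "pooled": Student t with pooled variance, exact under
# homoscedastic replicate noise; "welch": Welch-Satterthwaite df (robust
# to unequal variances but conservative at triplicate scale).
#' @noRd
two_sample_t_from_stats <- function(m1, s1, n1, m2, s2, n2,
                                    method = c("pooled", "welch")) {
  method <- match.arg(method)
  d <- m2 - m1
  if (method == "welch") {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se2 <- v1 + v2
    if (se2 == 0) {
      return(list(t = if (d == 0) 0 else sign(d) * Inf,
                  p = if (d == 0) 1 else 0, df = NA_real_, degenerate = TRUE))
    }
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    if (se2 == 0) {
      return(list(t = if (d == 0) 0 else sign(d) * Inf,
                  p = if (d == 0) 1 else 0, df = NA_real_, degenerate = TRUE))
    }
    df <- n1 + n2 - 2
  }
  t_stat <- d / sqrt(se2)
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = df), df = df,
       degenerate = FALSE)
}

#' Per-peptide state comparison across timepoints
#'
#' Two-sample t test per timepoint from replicate summary statistics,
#' with Benjamini-Hochberg correction across the peptide's timepoints;
#' the overall call is significant if any adjusted p falls below `alpha`.
#' The default `"pooled"` (Student) test is exact when replicate noise is
#' homoscedastic, which triplicate HDX replicates on one instrument
#' usually are; `"welch"` drops that assumption at the price of a
#' conservative call at n = 3.
#'
#' @param ref,pert tibbles (or data frames) of per-time summary stats with
#'   columns `time`, `mean`, `sd`, `n` (each `n >= 2`) for the reference
#'   and perturbed state of one peptide. Single-row inputs are allowed.
#' @param alpha significance level (default 0.05).
#' @param method `"pooled"` (default) or `"welch"`.
#' @param p_adjust_method passed to [stats::p.adjust()]; default `"BH"`.
#' @return list of class `state_comparison`: `per_time` tibble (`time`,
#'   `t`, `df`, `p`, `p_adj`, `significant`, `degenerate`), `significant`
#'   overall flag, `score` (minimum adjusted p).
#' @export
peptide_state_comparison <- function(ref, pert, alpha = 0.05,
                                     method = c("pooled", "welch"),
                                     p_adjust_method = "BH") {
  method <- match.arg(method)
  ref <- tibble::as_tibble(ref); pert <- tibble::as_tibble(pert)
  stopifnot(all(c("time", "mean", "sd", "n") %in% names(ref)),
            all(c("time", "mean", "sd", "n") %in% names(pert)))
  if (any(ref$n < 2L) || any(pert$n < 2L)) {
    stop("state comparison needs >= 2 replicates per state", call. = FALSE)
  }
  joined <- dplyr::inner_join(ref, pert, by = "time", suffix = c("_ref", "_pert"))
  if (nrow(joined) == 0L) stop("no shared timepoints", call. = FALSE)
  res <- lapply(seq_len(nrow(joined)), function(i) {
    two_sample_t_from_stats(joined$mean_ref[i], joined$sd_ref[i], joined$n_ref[i],
                            joined$mean_pert[i], joined$sd_pert[i], joined$n_pert[i],
                            method = method)
  })
  per_time <- tibble::tibble(
    time = joined$time,
    t = vapply(res, `[[`, numeric(1), "t"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p = vapply(res, `[[`, numeric(1), "p"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate")
  )
  per_time$p_adj <- stats::p.adjust(per_time$p, method = p_adjust_method)
  per_time$significant <- per_time$p_adj < alpha
  structure(
    list(per_time = per_time,
         significant = any(per_time$significant),
         score = min(per_time$p_adj)),
    class = "state_comparison"
  )
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("<state_comparison> %s (min adjusted p = %.3g over %d timepoints)\n",
              if (x$significant) "significant" else "not significant",
              x$score, nrow(x$per_time)))
  invisible(x)
}

#' Significance calls for every (peptide, time) of a table
#'
#' Dataset-level significance calls: two-sample t per (peptide, time)
#' between two states, Benjamini-Hochberg adjusted across all
#' (peptide, time) pairs of the table.
#'
#' @inheritParams differential_table
#' @inheritParams peptide_state_comparison
#' @param alpha significance level.
#' @return tibble with per-(peptide, time) `t`, `df`, `p`, `p_adj`,
#'   `significant`.
#' @export
state_comparison_table <- function(table, ref_state, pert_state, alpha = 0.05,
                                   method = c("pooled", "welch")) {
  method <- match.arg(method)
  diffs <- differential_table(table, ref_state, pert_state)
  res <- lapply(seq_len(nrow(diffs)), function(i) {
    two_sample_t_from_stats(diffs$ref_mean[i], diffs$ref_sd[i], diffs$ref_n[i],
                            diffs$pert_mean[i], diffs$pert_sd[i], diffs$pert_n[i],
                            method = method)
  })
  diffs$t <- vapply(res, `[[`, numeric(1), "t")
  diffs$df <- vapply(res, `[[`, numeric(1), "df")
  diffs$p <- vapply(res, `[[`, numeric(1), "p")
  diffs$p_adj <- stats::p.adjust(diffs$p, method = "BH")
  diffs$significant <- diffs$p_adj < alpha
  diffs
}
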