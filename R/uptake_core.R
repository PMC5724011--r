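# Per-peptide uptake computations: exchangeable-amide counts, replicate
# statistics, relative fractional uptake and between-state differentials.

#' Count exchange-competent backbone amides of a peptide
#'
#' Backbone amide hydrogens exchange with solvent deuterium, with two
#' exceptions: proline has no amide hydrogen, and the first residue(s) of a
#' peptic peptide lose their label too fast to be observed (back-exchange at
#' the free amine). The count returned here is the peptide's maximum
#' theoretical uptake in deuterons (1 Da units), the denominator of relative
#' fractional uptake.
#'
#' @param peptide_sequence single amino-acid string (standard 20 residues).
#' @param first_residue_exclusion number of N-terminal residues excluded
#'   from exchange (1, the default, or 2 — the common field alternative).
#' @return integer count of exchange-competent amides.
#' @examples
#' exchangeable_amides("KRLIGKRY") # 7
#' exchangeable_amides("APGP")     # 1
#' @export
exchangeable_amides <- function(peptide_sequence, first_residue_exclusion = 1L) {
  assert_aa_string(peptide_sequence, "peptide_sequence")
  stopifnot(first_residue_exclusion >= 0)
  chars <- strsplit(toupper(peptide_sequence), "")[[1]]
  n <- length(chars)
  if (n <= first_residue_exclusion) return(0L)
  tail_chars <- chars[(first_residue_exclusion + 1L):n]
  as.integer(sum(tail_chars != "P"))
}

#' Replicate mean and standard deviation for one (peptide, state, time)
#'
#' @param values numeric vector of replicate uptake values (Da).
#' @return a list of class `uptake_stat` with `mean`, `sd` (sample sd,
#'   n - 1 denominator; 0 with `single_replicate = TRUE` when n = 1) and `n`.
#' @examples
#' replicate_stats(c(1.0, 1.2, 1.1))
#' @export
replicate_stats <- function(values) {
  if (length(values) < 1L) stop("at least one replicate value is required", call. = FALSE)
  if (any(!is.finite(values))) stop("replicate values must be finite", call. = FALSE)
  n <- length(values)
  out <- list(
    mean = mean(values),
    sd = if (n >= 2L) stats::sd(values) else 0,
    n = n,
    single_replicate = n < 2L
  )
  class(out) <- "uptake_stat"
  out
}

#' @export
print.uptake_stat <- function(x, ...) {
  cat(sprintf("<uptake_stat> mean %.4g Da, sd %.4g Da, n = %d%s\n",
              x$mean, x$sd, x$n,
              if (isTRUE(x$single_replicate)) " (single replicate)" else ""))
  invisible(x)
}

#' Relative fractional uptake
#'
#' Mean uptake divided by the peptide's maximum theoretical uptake. Values
#' above 1 are possible only if the inputs are (they indicate a convention
#' mismatch) and are flagged, never clamped.
#'
#' @param mean_uptake mean deuterium uptake (Da).
#' @param max_uptake maximum theoretical uptake (Da), must be > 0.
#' @return numeric fraction, with attribute `exceeds_max` when > 1.
#' @export
relative_fractional_uptake <- function(mean_uptake, max_uptake) {
  if (any(max_uptake <= 0)) stop("max_uptake must be > 0", call. = FALSE)
  frac <- mean_uptake / max_uptake
  if (any(frac > 1)) {
    warning("relative fractional uptake exceeds 1; check the amide-count convention",
            call. = FALSE)
    attr(frac, "exceeds_max") <- TRUE
  }
  frac
}

#' Differential uptake between two states of one peptide at one time
#'
#' @param ref `uptake_stat` for the reference state.
#' @param pert `uptake_stat` for the perturbed state.
#' @param max_uptake maximum theoretical uptake (Da), > 0.
#' @param time labeling time (minutes), carried through for bookkeeping.
#' @return list of class `differential_uptake` with `delta` (perturbed minus
#'   reference mean, Da), `rel_frac_delta` (`delta / max_uptake`),
#'   `pooled_sd` (`sqrt(sd_ref^2/n_ref + sd_pert^2/n_pert)`, the standard
#'   error of the difference) and `time`.
#' @export
differential_uptake <- function(ref, pert, max_uptake, time = NA_real_) {
  stopifnot(inherits(ref, "uptake_stat"), inherits(pert, "uptake_stat"))
  if (max_uptake <= 0) stop("max_uptake must be > 0", call. = FALSE)
  delta <- pert$mean - ref$mean
  out <- list(
    delta = delta,
    rel_frac_delta = delta / max_uptake,
    pooled_sd = sqrt(ref$sd^2 / ref$n + pert$sd^2 / pert$n),
    time = time
  )
  class(out) <- "differential_uptake"
  out
}

#' Per-(peptide, state, time) replicate statistics for a whole uptake table
#'
#' @param table an uptake table as returned by [read_state_table()] or
#'   [simulate_uptake()].
#' @return tibble with one row per (protein, state, sequence, start, end,
#'   max_uptake, time): `mean`, `sd`, `n`.
#' @export
uptake_stats <- function(table) {
  validate_uptake_table(table)
  dplyr::summarise(
    dplyr::group_by(table, .data$protein, .data$state, .data$sequence,
                    .data$start, .data$end, .data$max_uptake, .data$time),
    mean = mean(.data$uptake),
    sd = ifelse(dplyr::n() >= 2L, stats::sd(.data$uptake), 0),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Differential uptake table between two states
#'
#' Computes, for every (peptide, time) present in both states,
#' the perturbed-minus-reference uptake difference and its relative
#' fractional form.
#'
#' @param table uptake table containing both states.
#' @param ref_state,pert_state state names.
#' @return tibble with `delta`, `rel_frac_delta`, `pooled_sd` per
#'   (protein, peptide, time).
#' @export
differential_table <- function(table, ref_state, pert_state) {
  stats_tbl <- uptake_stats(table)
  have <- unique(stats_tbl$state)
  if (!all(c(ref_state, pert_state) %in% have)) {
    stop(sprintf("states '%s' and '%s' must both be present in the table",
                 ref_state, pert_state), call. = FALSE)
  }
  keys <- c("protein", "sequence", "start", "end", "max_uptake", "time")
  ref <- dplyr::filter(stats_tbl, .data$state == ref_state)
  pert <- dplyr::filter(stats_tbl, .data$state == pert_state)
  joined <- dplyr::inner_join(
    dplyr::select(ref, dplyr::all_of(keys), ref_mean = "mean", ref_sd = "sd", ref_n = "n"),
    dplyr::select(pert, dplyr::all_of(keys), pert_mean = "mean", pert_sd = "sd", pert_n = "n"),
    by = keys
  )
  dplyr::mutate(
    joined,
    delta = .data$pert_mean - .data$ref_mean,
    rel_frac_delta = .data$delta / .data$max_uptake,
    pooled_sd = sqrt(.data$ref_sd^2 / .data$ref_n + .data$pert_sd^2 / .data$pert_n)
  )
}
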