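# Fluorescence-polarization receptivity analysis: millipolarization from
# filter count rates, and the decay of available peptide-binding sites
# after conditional-ligand hydrolysis.

#' Millipolarization from filter count rates
#'
#' `mP = 1000 * (S - G * P) / (S + G * P)`, where `S` and `P` are
#' background-subtracted count rates with the emission polarizer parallel
#' and perpendicular to the excitation polarizer, and `G` is the
#' instrument grating factor.
#'
#' @param S parallel-filter counts (>= 0).
#' @param P perpendicular-filter counts (>= 0).
#' @param G grating factor (> 0).
#' @return millipolarization (vectorized).
#' @examples
#' compute_mP(2, 1, 1) # 1000/3
#' @export
compute_mP <- function(S, P, G = 1) {
  if (any(S < 0) || any(P < 0)) stop("count rates must be >= 0", call. = FALSE)
  if (any(G <= 0)) stop("grating factor must be > 0", call. = FALSE)
  denom <- S + G * P
  if (any(denom <= 0)) stop("S + G * P must be > 0", call. = FALSE)
  1000 * (S - G * P) / denom
}

#' Fraction of peptide-receptive binding sites remaining
#'
#' Baseline-subtracted polarization fraction:
#' `(mP_t - mP_unbound) / (mP_initial - mP_unbound)`, where unbound
#' fluorescent peptide is assumed to sit at `mP_unbound` (default 50).
#' The complement `1 - fraction` is the fractional loss of binding sites.
#'
#' @param mP_t polarization at time t.
#' @param mP_initial initial polarization (must exceed `mP_unbound`).
#' @param mP_unbound unbound-peptide baseline (default 50).
#' @return receptive fraction (vectorized over `mP_t`).
#' @export
receptive_fraction <- function(mP_t, mP_initial, mP_unbound = 50) {
  if (any(mP_initial <= mP_unbound)) {
    stop("mP_initial must exceed the unbound baseline", call. = FALSE)
  }
  (mP_t - mP_unbound) / (mP_initial - mP_unbound)
}

#' Raw polarization ratio
#'
#' `mP_t / mP_initial` — the form in which late-timecourse polarization is
#' reported relative to its initial level.
#'
#' @param mP_t polarization at time t.
#' @param mP_initial initial polarization (> 0).
#' @return ratio (vectorized over `mP_t`).
#' @export
polarization_ratio <- function(mP_t, mP_initial) {
  if (any(mP_initial <= 0)) stop("mP_initial must be > 0", call. = FALSE)
  mP_t / mP_initial
}

#' Fluorescence-polarization time series
#'
#' @param time hours.
#' @param S,P background-subtracted parallel/perpendicular counts.
#' @param G grating factor.
#' @return tibble of class `fp_series` with derived `mP`.
#' @export
fp_series <- function(time, S, P, G = 1) {
  stopifnot(length(time) == length(S), length(S) == length(P))
  mp <- compute_mP(S, P, G)
  if (any(abs(mp) > 1000)) stop("mP outside [-1000, 1000]", call. = FALSE)
  out <- tibble::tibble(time = time, S = S, P = P, G = G, mP = mp)
  class(out) <- c("fp_series", class(out))
  out
}

#' Receptivity table from an FP time series
#'
#' @param series an [fp_series()].
#' @param mP_unbound unbound baseline (default 50).
#' @return tibble with `receptive_fraction`, `loss`, `polarization_ratio`
#'   per timepoint (relative to the first timepoint).
#' @export
fp_receptivity <- function(series, mP_unbound = 50) {
  mp0 <- series$mP[which.min(series$time)]
  dplyr::mutate(
    tibble::as_tibble(series),
    receptive_fraction = receptive_fraction(.data$mP, mp0, mP_unbound),
    loss = 1 - .data$receptive_fraction,
    polarization_ratio = polarization_ratio(.data$mP, mp0)
  )
}
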