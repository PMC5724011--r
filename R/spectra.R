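# Isotopic envelopes of partially deuterated peptides under a binomial
# incorporation model, centroid masses, and unimodal-versus-bimodal
# classification (the check that distinguishes gradual EX2 shifting from
# the two-population envelopes of EX1 or complex dissociation).

# mass difference between deuterium and hydrogen (Da)
DELTA_M_DEUTERIUM <- 1.00628

#' Construct a mass spectrum
#'
#' @param mz strictly increasing m/z values.
#' @param intensity non-negative intensities, not all zero.
#' @param charge charge state.
#' @param peptide optional peptide annotation.
#' @return an `hdx_spectrum` object.
#' @export
hdx_spectrum <- function(mz, intensity, charge = 1L, peptide = NULL) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ", call. = FALSE)
  if (any(diff(mz) <= 0)) stop("mz must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  if (all(intensity == 0)) stop("all intensities are zero", call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 charge = as.integer(charge), peptide = peptide),
            class = "hdx_spectrum")
}

#' @export
print.hdx_spectrum <- function(x, ...) {
  cat(sprintf("<hdx_spectrum> %d peaks, m/z %.4f-%.4f, charge +%d\n",
              length(x$mz), min(x$mz), max(x$mz), x$charge))
  invisible(x)
}

#' Simulate a deuteration envelope
#'
#' Each of `n_sites` exchange-competent sites carries a deuteron with
#' probability `p`, independently, so the envelope over the number of
#' incorporated deuterons `k` is binomial; a mixture of populations gives
#' a weighted sum of binomials. Peak `k` sits at
#' `base_mz + k * 1.00628 / charge`. Natural isotope structure is omitted
#' (it cancels in centroid differences); `isotope_envelope` optionally
#' convolves one in.
#'
#' @param n_sites number of exchange-competent sites.
#' @param populations data frame (or tibble) with columns `p`
#'   (incorporation probability per site, in `[0, 1]`) and `weight`
#'   (summing to 1), one row per population.
#' @param base_mz m/z of the undeuterated species.
#' @param charge charge state.
#' @param isotope_envelope optional numeric vector of natural-isotope
#'   abundances to convolve with the deuteration envelope.
#' @return an `hdx_spectrum` with `n_sites + 1` peaks (more if convolved).
#' @export
simulate_envelope <- function(n_sites, populations, base_mz, charge = 1L,
                              isotope_envelope = NULL) {
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("p", "weight") %in% names(populations)), n_sites >= 1)
  if (any(populations$p < 0 | populations$p > 1)) {
    stop("incorporation probabilities must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(populations$weight) - 1) > 1e-8 || any(populations$weight < 0)) {
    stop("population weights must be non-negative and sum to 1", call. = FALSE)
  }
  k <- 0:n_sites
  intensity <- rowSums(vapply(seq_len(nrow(populations)), function(i) {
    populations$weight[i] * stats::dbinom(k, n_sites, populations$p[i])
  }, numeric(length(k))))
  if (!is.null(isotope_envelope)) {
    intensity <- stats::convolve(c(intensity, numeric(length(isotope_envelope) - 1L)),
                                 rev(c(isotope_envelope, numeric(length(intensity) - 1L))),
                                 type = "filter")
    k <- seq_along(intensity) - 1L
  }
  hdx_spectrum(base_mz + k * DELTA_M_DEUTERIUM / charge, intensity,
               charge = charge)
}

#' Intensity-weighted centroid of a spectrum
#'
#' @param spectrum an `hdx_spectrum` (or list with `mz`, `intensity`).
#' @return centroid m/z.
#' @export
centroid_mass <- function(spectrum) {
  s <- sum(spectrum$intensity)
  if (s == 0) stop("all intensities are zero", call. = FALSE)
  sum(spectrum$mz * spectrum$intensity) / s
}

# Weighted binomial log-likelihood; counts c_k at k = 0..n.
#' @noRd
binom_mix_loglik <- function(counts, n, p, w) {
  k <- seq_along(counts) - 1L
  lik <- rowSums(vapply(seq_along(p), function(j) {
    w[j] * stats::dbinom(k, n, p[j])
  }, numeric(length(k))))
  sum(counts * log(pmax(lik, 1e-300)))
}

# EM fit of a J-component binomial mixture to pseudo-counts.
#' @noRd
fit_binom_mixture <- function(counts, n, p_init, w_init,
                              max_iter = 300L, tol = 1e-10) {
  k <- seq_along(counts) - 1L
  p <- p_init; w <- w_init
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    comp <- vapply(seq_along(p), function(j) {
      w[j] * stats::dbinom(k, n, p[j])
    }, numeric(length(k)))
    tot <- pmax(rowSums(comp), 1e-300)
    for (j in seq_along(p)) {
      gamma <- counts * comp[, j] / tot
      mass <- sum(gamma)
      if (mass < 1e-12) next
      w[j] <- mass / sum(counts)
      p[j] <- min(max(sum(gamma * k) / (n * mass), 1e-9), 1 - 1e-9)
    }
    w <- w / sum(w)
    ll <- binom_mix_loglik(counts, n, p, w)
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  list(p = p, weight = w, loglik = binom_mix_loglik(counts, n, p, w))
}

#' Classify an envelope as unimodal or bimodal
#'
#' Fits one- and two-component binomial mixtures to the envelope by
#' maximum likelihood (intensities normalized and scaled to a fixed
#' pseudo-count, which makes the call invariant to uniform intensity
#' scaling) and selects by BIC; a BIC improvement greater than
#' `delta_bic` favors two components.
#'
#' @param spectrum an `hdx_spectrum` whose peaks are the consecutive
#'   deuteration states `k = 0..n_sites` (>= 3 peaks).
#' @param delta_bic BIC margin required to call bimodality (default 2).
#' @param pseudo_count effective ion count the normalized envelope is
#'   scaled to for the likelihood (default 1000).
#' @return list of class `modality_call`: `modality` (`"unimodal"` or
#'   `"bimodal"`), `components` tibble (`p`, `weight`), `bic_1`, `bic_2`,
#'   `delta_bic`, `degenerate`.
#' @export
classify_modality <- function(spectrum, delta_bic = 2, pseudo_count = 1000) {
  if (length(spectrum$mz) < 3L) stop("need >= 3 peaks", call. = FALSE)
  n <- length(spectrum$mz) - 1L
  counts <- spectrum$intensity / sum(spectrum$intensity) * pseudo_count
  k <- 0:n
  # single component: ML p is the weighted mean of k / n
  p1 <- min(max(sum(counts * k) / (n * sum(counts)), 1e-9), 1 - 1e-9)
  ll1 <- binom_mix_loglik(counts, n, p1, 1)
  bic1 <- -2 * ll1 + 1 * log(pseudo_count)
  # two components: EM from spread starts
  starts <- list(c(max(p1 / 2, 1e-3), min(p1 * 1.5 + 0.1, 1 - 1e-3)),
                 c(0.05, 0.95),
                 c(max(p1 - 0.2, 1e-3), min(p1 + 0.2, 1 - 1e-3)))
  fits <- lapply(starts, function(s) {
    fit_binom_mixture(counts, n, p_init = s, w_init = c(0.5, 0.5))
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  bic2 <- -2 * best$loglik + 3 * log(pseudo_count)
  degenerate <- min(best$weight) < 1e-3 || abs(diff(best$p)) < 1e-3
  bimodal <- (bic1 - bic2 > delta_bic) && !degenerate
  ord <- order(best$p)
  structure(
    list(modality = if (bimodal) "bimodal" else "unimodal",
         components = if (bimodal) {
           tibble::tibble(p = best$p[ord], weight = best$weight[ord])
         } else {
           tibble::tibble(p = p1, weight = 1)
         },
         bic_1 = bic1, bic_2 = bic2, delta_bic = bic1 - bic2,
         degenerate = degenerate),
    class = "modality_call"
  )
}

#' @export
print.modality_call <- function(x, ...) {
  cat(sprintf("<modality_call> %s (delta BIC = %.2f)\n", x$modality, x$delta_bic))
  print(x$components)
  invisible(x)
}
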