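# Independent brute-force oracles and fixture builders used across tests.
# Oracles deliberately re-derive every rule from scratch, one residue at a
# time, so they share no code path with the implementation.

# For one residue: enumerate all peptides, apply the eligibility rule
# (s < r <= e), pick the shortest, break ties by greatest end then
# greatest start. Returns the peptide row index or NA.
oracle_representative <- function(r, starts, ends) {
  el <- which(starts < r & r <= ends)
  if (length(el) == 0L) return(NA_integer_)
  len <- ends[el] - starts[el] + 1L
  el <- el[len == min(len)]
  el <- el[ends[el] == max(ends[el])]
  el <- el[starts[el] == max(starts[el])]
  el[1L]
}

# Residue x time matrix built cell-by-cell from the per-residue oracle.
oracle_residue_map <- function(diffs, peptides, protein_length) {
  times <- sort(unique(diffs$time))
  val <- matrix(NA_real_, nrow = protein_length, ncol = length(times))
  for (r in seq_len(protein_length)) {
    p <- oracle_representative(r, peptides$start, peptides$end)
    if (is.na(p)) next
    for (ti in seq_along(times)) {
      hit <- diffs$start == peptides$start[p] & diffs$end == peptides$end[p] &
        diffs$time == times[ti]
      val[r, ti] <- diffs$rel_frac_delta[hit][1]
    }
  }
  val
}

# Per-residue counting oracle for coverage/redundancy.
oracle_coverage <- function(peptides, protein_length) {
  counts <- integer(protein_length)
  for (r in seq_len(protein_length)) {
    counts[r] <- sum(peptides$start <= r & r <= peptides$end)
  }
  covered <- counts > 0
  list(coverage_percent = 100 * sum(covered) / protein_length,
       mean_redundancy = if (any(covered)) mean(counts[covered]) else NA_real_)
}

# Random peptide map: n peptides over a protein of length L (may be empty).
random_peptide_map <- function(L, n) {
  if (n == 0L) return(tibble::tibble(start = integer(), end = integer()))
  start <- sample.int(L, n, replace = TRUE)
  len <- pmin(1L + stats::rpois(n, 7), L - start + 1L)
  dplyr::distinct(tibble::tibble(start = start, end = start + len - 1L))
}

# Random per-(peptide, time) differential values.
random_diffs <- function(peptides, times) {
  grid <- tidyr::expand_grid(i = seq_len(nrow(peptides)), time = times)
  tibble::tibble(start = peptides$start[grid$i], end = peptides$end[grid$i],
                 time = grid$time,
                 rel_frac_delta = stats::rnorm(nrow(grid), 0, 0.1))
}

# Deterministic test sequence (proline-free so amide counts are simple).
random_protein_sequence_for_tests <- function(L, seed = 1234) {
  withr::with_seed(seed, {
    paste(sample(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]], L, replace = TRUE),
          collapse = "")
  })
}

# Small two-state exchange model with known ground truth.
toy_model <- function(sequence = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                      k_int = 10,
                      protection_loaded = 500,
                      protection_receptive = NULL,
                      region = NULL, fold = 10) {
  L <- nchar(sequence)
  loaded <- rep(protection_loaded, L)
  receptive <- if (is.null(protection_receptive)) loaded else {
    rep(protection_receptive, L)
  }
  if (!is.null(region)) {
    receptive <- loaded
    receptive[region[1]:region[2]] <- pmax(1, loaded[region[1]:region[2]] / fold)
  }
  exchange_model("toy", sequence, k_int,
                 list(loaded = loaded, receptive = receptive, rescued = loaded))
}

# Minimal well-formed uptake table.
toy_table <- function() {
  tibble::tibble(
    protein = "toy", state = rep(c("loaded", "receptive"), each = 6),
    sequence = "KRLIGKRY", start = 2L, end = 9L, max_uptake = 7,
    time = rep(rep(c(1, 10, 100), each = 2), 2),
    replicate = rep(1:2, 6),
    uptake = c(1.0, 1.1, 2.0, 2.1, 3.0, 3.1, 1.5, 1.6, 2.6, 2.7, 3.6, 3.7)
  )
}
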