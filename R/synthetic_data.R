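# Forward simulator of EX2 exchange kinetics, peptic digestion maps and
# replicate noise. Generates uptake tables with the statistical structure
# the downstream analysis assumes, so the whole pipeline is testable
# without raw instrument data.

#' Exchange model for one protein
#'
#' Describes per-residue intrinsic exchange rates and per-state protection
#' factors under the EX2 (uncorrelated, independent-site) regime. Residue 1
#' of the mature protein and all prolines never contribute observable
#' exchange: proline has no backbone amide hydrogen, and the N-terminal
#' amine back-exchanges instantly.
#'
#' @param protein_id protein identifier.
#' @param sequence amino-acid string, residue 1 = first residue of the
#'   mature protein.
#' @param k_int per-residue intrinsic exchange rates (1/min); either a
#'   single base rate recycled across residues or a full-length vector.
#' @param protection named list, one numeric vector per state, of
#'   per-residue protection factors (>= 1, or `Inf` for non-exchanging).
#' @param d2o_fraction deuterium fraction of the labeling buffer; the
#'   default 0.95 reflects a 20-fold dilution into D2O buffer.
#' @param back_exchange multiplicative recovery factor (0-1) applied to
#'   observable uptake; default 0.7.
#' @return an `exchange_model` object.
#' @export
exchange_model <- function(protein_id, sequence, k_int, protection,
                           d2o_fraction = 0.95, back_exchange = 0.7) {
  assert_aa_string(sequence, "sequence")
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (length(k_int) == 1L) k_int <- rep(as.numeric(k_int), L)
  if (length(k_int) != L) stop("k_int must have one rate per residue", call. = FALSE)
  if (any(!is.finite(k_int)) || any(k_int < 0)) {
    stop("k_int must be finite and >= 0", call. = FALSE)
  }
  if (!is.list(protection) || is.null(names(protection)) ||
      any(names(protection) == "")) {
    stop("protection must be a named list of per-state profiles", call. = FALSE)
  }
  protection <- lapply(protection, function(p) {
    if (length(p) == 1L) p <- rep(as.numeric(p), L)
    if (length(p) != L) stop("each protection profile must cover every residue", call. = FALSE)
    if (any(is.na(p)) || any(p < 1)) {
      stop("protection factors must be >= 1 (or Inf)", call. = FALSE)
    }
    p
  })
  if (d2o_fraction < 0 || d2o_fraction > 1) stop("d2o_fraction must be in [0, 1]", call. = FALSE)
  if (back_exchange < 0 || back_exchange > 1) stop("back_exchange must be in [0, 1]", call. = FALSE)
  structure(
    list(protein_id = protein_id, sequence = sequence, k_int = k_int,
         protection = protection, d2o_fraction = d2o_fraction,
         back_exchange = back_exchange),
    class = "exchange_model"
  )
}

#' @export
print.exchange_model <- function(x, ...) {
  cat(sprintf("<exchange_model> %s: %d residues, states: %s\n",
              x$protein_id, nchar(x$sequence),
              paste(names(x$protection), collapse = ", ")))
  invisible(x)
}

#' Peptic digestion parameters
#'
#' @param mean_length mean peptide length (residues, >= 3).
#' @param length_sd sd of peptide length (residues).
#' @param target_redundancy mean peptides per covered residue (>= 1).
#' @param coverage_target fraction of residues covered (0, 1].
#' @param seed integer seed for map generation.
#' @return a `digestion_params` object.
#' @export
digestion_params <- function(mean_length = 14, length_sd = 4,
                             target_redundancy = 5.95,
                             coverage_target = 0.985, seed = 1L) {
  stopifnot(mean_length >= 3, length_sd >= 0, target_redundancy >= 1,
            coverage_target > 0, coverage_target <= 1)
  structure(list(mean_length = mean_length, length_sd = length_sd,
                 target_redundancy = target_redundancy,
                 coverage_target = coverage_target, seed = as.integer(seed)),
            class = "digestion_params")
}

#' Replicate noise parameters
#'
#' @param uptake_sd Gaussian replicate noise on uptake (Da).
#' @param n_replicates replicates per (state, peptide, time).
#' @return a `noise_model` object.
#' @export
noise_model <- function(uptake_sd = 0.05, n_replicates = 3L) {
  stopifnot(uptake_sd >= 0, n_replicates >= 1)
  structure(list(uptake_sd = uptake_sd, n_replicates = as.integer(n_replicates)),
            class = "noise_model")
}

#' Simulate a peptic peptide map
#'
#' Emulates the overlapping peptide maps of a bottom-up HDX experiment:
#' the covered part of the sequence is tiled with overlapping peptides and
#' further random peptides are added until the target redundancy is met.
#' Achieved coverage is within 5 percentage points of `coverage_target`
#' and achieved redundancy within 20% of `target_redundancy` (both as
#' measured by [coverage_redundancy()]); if the targets cannot be met an
#' infeasibility error is raised.
#'
#' @param sequence amino-acid string.
#' @param params a [digestion_params()] object.
#' @return tibble of 1-based inclusive `(start, end)` intervals, sorted.
#' @export
simulate_digestion <- function(sequence, params) {
  assert_aa_string(sequence)
  stopifnot(inherits(params, "digestion_params"))
  L <- nchar(sequence)
  if (L < params$mean_length) {
    stop("sequence shorter than mean peptide length", call. = FALSE)
  }
  covered_len <- max(as.integer(round(params$coverage_target * L)), 3L)
  n_target <- max(1L, round(params$target_redundancy * covered_len / params$mean_length))
  # Feasibility: covering `covered_len` residues with n_target peptides of
  # ~mean_length requires n_target * mean_length >= covered_len.
  if (n_target * (params$mean_length + 3 * params$length_sd) < covered_len) {
    stop("infeasible digestion targets: too few peptides to reach the coverage target",
         call. = FALSE)
  }
  for (attempt in seq_len(30L)) {
    set.seed(child_seed(params$seed, paste0("digestion", attempt)))
    map <- digestion_attempt(L, covered_len, n_target, params)
    if (is.null(map)) next
    rep_ <- coverage_redundancy(map, L)
    cov_ok <- abs(rep_$coverage_percent / 100 - params$coverage_target) <= 0.05
    red_ok <- abs(rep_$mean_redundancy - params$target_redundancy) <=
      0.2 * params$target_redundancy
    if (cov_ok && red_ok) {
      return(dplyr::arrange(map, .data$start, .data$end))
    }
  }
  stop("infeasible digestion targets: could not achieve coverage/redundancy within tolerance",
       call. = FALSE)
}

# One randomized attempt at a peptide map; NULL if it degenerates.
#' @noRd
digestion_attempt <- function(L, covered_len, n_target, params) {
  draw_len <- function(n) {
    len <- round(stats::rnorm(n, params$mean_length, params$length_sd))
    pmin(pmax(len, 3L), L)
  }
  # Place the uncovered residues as up to two random gap segments.
  gap_total <- L - covered_len
  segments <- list(c(1L, L))
  if (gap_total > 0) {
    n_gaps <- if (gap_total >= 6L) sample(1:2, 1L) else 1L
    gap_lens <- if (n_gaps == 2L) {
      g1 <- sample(seq_len(gap_total - 1L), 1L)
      c(g1, gap_total - g1)
    } else gap_total
    # gaps cannot touch so segments stay non-trivial
    pos <- sort(sample(seq(2L, L - max(gap_lens)), n_gaps))
    segments <- list()
    cursor <- 1L
    for (i in seq_len(n_gaps)) {
      gs <- pos[i]
      ge <- gs + gap_lens[i] - 1L
      if (gs <= cursor || ge >= L) return(NULL)
      if (gs - cursor >= 3L) segments[[length(segments) + 1L]] <- c(cursor, gs - 1L)
      cursor <- ge + 1L
    }
    if (L - cursor + 1L >= 3L) segments[[length(segments) + 1L]] <- c(cursor, L)
  }
  if (length(segments) == 0L) return(NULL)
  starts <- integer(0); ends <- integer(0)
  # Tile each covered segment so its union is fully covered.
  for (seg in segments) {
    s <- seg[1]
    repeat {
      len <- draw_len(1L)
      e <- min(s + len - 1L, seg[2])
      if (e - s + 1L < 3L) s <- max(seg[1], e - 2L)
      e <- min(max(e, s + 2L), seg[2])
      if (e - s + 1L < 3L) { s <- max(seg[1], seg[2] - 2L); e <- seg[2] }
      starts <- c(starts, s); ends <- c(ends, e)
      if (e >= seg[2]) break
      # next start inside the current peptide (overlap) or flush after it
      s <- sample(seq(s + 1L, e + 1L), 1L)
      if (s + 2L > seg[2]) s <- seg[2] - 2L
    }
  }
  # Top up with random peptides inside covered segments until n_target.
  n_extra <- n_target - length(starts)
  if (n_extra < 0) return(NULL)
  seg_len <- vapply(segments, function(x) as.numeric(x[2] - x[1] + 1L), numeric(1))
  seen <- paste(starts, ends)
  added <- 0L
  tries <- 0L
  while (added < n_extra && tries < 50L * n_extra) {
    tries <- tries + 1L
    seg <- segments[[sample.int(length(segments), 1L, prob = seg_len)]]
    len <- min(draw_len(1L), seg[2] - seg[1] + 1L)
    s <- sample(seq(seg[1], seg[2] - len + 1L), 1L)
    key <- paste(s, s + len - 1L)
    if (key %in% seen) next # a peptide map lists each (start, end) once
    seen <- c(seen, key)
    starts <- c(starts, s); ends <- c(ends, s + len - 1L)
    added <- added + 1L
  }
  map <- tibble::tibble(start = as.integer(starts), end = as.integer(ends))
  dplyr::distinct(map)
}

# Noiseless expected uptake (Da) of one peptide interval at time t (min),
# under EX2: D(t) = bx * d2o * sum_i (1 - exp(-(k_int_i / P_i) t)) over the
# peptide's exchange-competent residues.
#' @noRd
expected_uptake <- function(model, state, start, end, time,
                            first_residue_exclusion = 1L) {
  chars <- strsplit(model$sequence, "")[[1]]
  idx <- seq.int(start, end)
  idx <- idx[seq_along(idx) > first_residue_exclusion]
  idx <- idx[chars[idx] != "P" & idx > 1L]
  if (length(idx) == 0L) return(0)
  k <- model$k_int[idx] / model$protection[[state]][idx]
  k[!is.finite(k)] <- 0 # protection = Inf
  model$back_exchange * model$d2o_fraction * sum(1 - exp(-k * time))
}

#' Simulate an uptake table for one state
#'
#' Noiseless expected uptake follows first-order EX2 kinetics summed over
#' each peptide's exchange-competent residues (all residues except the
#' first `first_residue_exclusion` and prolines); replicates add Gaussian
#' noise, floored at zero.
#'
#' @param model an [exchange_model()].
#' @param peptides tibble of `(start, end)` intervals.
#' @param times labeling times (minutes).
#' @param noise a [noise_model()].
#' @param state state name, must exist in `model$protection`.
#' @param seed integer seed.
#' @param first_residue_exclusion N-terminal residues of each peptide with
#'   no observable exchange (default 1).
#' @return uptake table tibble (one row per peptide x time x replicate).
#' @export
simulate_uptake <- function(model, peptides, times, noise, state, seed,
                            first_residue_exclusion = 1L) {
  stopifnot(inherits(model, "exchange_model"), inherits(noise, "noise_model"))
  if (!state %in% names(model$protection)) {
    stop(sprintf("unknown state '%s'", state), call. = FALSE)
  }
  if (any(times < 0)) stop("negative labeling time", call. = FALSE)
  L <- nchar(model$sequence)
  if (any(peptides$start < 1L) || any(peptides$end > L) ||
      any(peptides$start > peptides$end)) {
    stop("peptide interval outside the sequence", call. = FALSE)
  }
  set.seed(child_seed(seed, paste(model$protein_id, state)))
  seqs <- substring(model$sequence, peptides$start, peptides$end)
  max_up <- vapply(seqs, exchangeable_amides, integer(1),
                   first_residue_exclusion = first_residue_exclusion,
                   USE.NAMES = FALSE)
  grid <- tidyr::expand_grid(
    pep = seq_len(nrow(peptides)),
    time = as.numeric(times),
    replicate = seq_len(noise$n_replicates)
  )
  expected <- mapply(function(p, t) {
    expected_uptake(model, state, peptides$start[p], peptides$end[p], t,
                    first_residue_exclusion)
  }, grid$pep, grid$time)
  uptake <- pmax(0, expected + stats::rnorm(nrow(grid), 0, noise$uptake_sd))
  tibble::tibble(
    protein = model$protein_id,
    state = state,
    sequence = seqs[grid$pep],
    start = peptides$start[grid$pep],
    end = peptides$end[grid$pep],
    max_uptake = as.numeric(max_up[grid$pep]),
    time = grid$time,
    replicate = grid$replicate,
    uptake = as.numeric(uptake)
  )
}

#' Default three-state, two-allotype scenario configuration
#'
#' Emulates the study design: two MHC class I heavy-chain allotypes, each
#' with an associated beta-2-microglobulin, measured in a conditional
#' ligand-`loaded` state, a peptide-`receptive` state (post UV hydrolysis)
#' and a `rescued` state (re-supplemented with excess high-affinity
#' peptide), in triplicate over five labeling times from 25 s to 4.34 h.
#' Protection is lowered in the receptive state only inside the configured
#' sub-regions (groove sub-helices of the heavy chain; a beta-strand patch
#' of beta-2-microglobulin), and the rescued profile equals the loaded one.
#'
#' @param seed master seed.
#' @return a configuration list accepted by [make_two_state_scenario()].
#' @export
demo_scenario_config <- function(seed = 1L) {
  hc_a <- random_protein_sequence(275L, child_seed(seed, "hc-seq"))
  # allotype B: groove-domain polymorphisms of allotype A
  poly_pos <- c(22L, 62L, 95L, 111L, 135L, 152L)
  hc_b <- hc_a
  for (p in poly_pos) {
    cur <- substr(hc_a, p, p)
    repl <- setdiff(setdiff(AA_STANDARD, "P"), cur)
    substr(hc_b, p, p) <- repl[child_seed(seed, paste0("poly", p)) %% length(repl) + 1L]
  }
  b2m <- random_protein_sequence(98L, child_seed(seed, "b2m-seq"))
  list(
    seed = as.integer(seed),
    proteins = list(
      hc_A = list(sequence = hc_a, map_group = "hc",
                  digestion = digestion_params(mean_length = 14, length_sd = 4,
                                               target_redundancy = 5.95,
                                               coverage_target = 0.985)),
      hc_B = list(sequence = hc_b, map_group = "hc",
                  digestion = digestion_params(mean_length = 14, length_sd = 4,
                                               target_redundancy = 5.95,
                                               coverage_target = 0.985)),
      b2m_A = list(sequence = b2m, map_group = "b2m",
                   digestion = digestion_params(mean_length = 13, length_sd = 3,
                                                target_redundancy = 5.46,
                                                coverage_target = 1.0)),
      b2m_B = list(sequence = b2m, map_group = "b2m",
                   digestion = digestion_params(mean_length = 13, length_sd = 3,
                                                target_redundancy = 5.46,
                                                coverage_target = 1.0))
    ),
    states = c(loaded = "reference", receptive = "perturbed", rescued = "rescue"),
    times = c(25 / 60, 2.1, 10.4, 52.1, 4.34 * 60),
    noise = noise_model(uptake_sd = 0.05, n_replicates = 3L),
    k_int_base = 50,
    log10_protection_range = c(1.5, 4.5),
    regions = tibble::tibble(
      protein = c("hc_A", "hc_A", "hc_B", "hc_B", "b2m_A", "b2m_B"),
      start   = c(96L, 130L, 96L, 130L, 54L, 54L),
      end     = c(104L, 148L, 104L, 148L, 62L, 62L),
      fold    = c(12, 25, 8, 18, 3, 3)
    )
  )
}

#' @noRd
random_protein_sequence <- function(length, seed) {
  set.seed(seed)
  # proline down-weighted so peptides keep exchange-competent residues
  w <- stats::setNames(rep(1, 20), AA_STANDARD)
  w["P"] <- 0.6
  paste(sample(AA_STANDARD, length, replace = TRUE, prob = w), collapse = "")
}

#' Build the paired multi-state synthetic scenario
#'
#' Generates, for every configured protein, a shared peptide map and uptake
#' tables for all configured states. The receptive state's protection
#' profile is the loaded profile divided by the region fold-changes (only
#' inside the configured sub-regions); the rescued profile is identical to
#' the loaded one. The returned metadata records the ground-truth perturbed
#' regions for recovery tests.
#'
#' @param config configuration list (see [demo_scenario_config()]); fields:
#'   `seed`, `proteins`, `states`, `times`, `noise`, `k_int_base`,
#'   `log10_protection_range`, `regions`.
#' @return list with `tables` (one combined uptake tibble per protein),
#'   `models`, `peptide_maps`, `states`, `times` and `ground_truth`.
#' @export
make_two_state_scenario <- function(config = demo_scenario_config()) {
  stopifnot(is.list(config$proteins), length(config$proteins) > 0)
  regions <- config$regions %||%
    tibble::tibble(protein = character(), start = integer(),
                   end = integer(), fold = numeric())
  # reject contradictory overlapping region specs (same protein, different fold)
  if (nrow(regions) > 1) {
    for (pid in unique(regions$protein)) {
      rr <- regions[regions$protein == pid, ]
      if (nrow(rr) > 1) {
        for (i in seq_len(nrow(rr) - 1)) for (j in seq(i + 1, nrow(rr))) {
          if (rr$start[i] <= rr$end[j] && rr$start[j] <= rr$end[i] &&
              rr$fold[i] != rr$fold[j]) {
            stop("overlapping region specifications with contradictory fold-changes",
                 call. = FALSE)
          }
        }
      }
    }
  }
  state_names <- names(config$states)
  roles <- unname(config$states)
  if (sum(roles == "reference") != 1L) stop("exactly one reference state required", call. = FALSE)
  seed <- config$seed %||% 1L
  noise <- config$noise %||% noise_model()
  times <- config$times %||% c(25 / 60, 2.1, 10.4, 52.1, 4.34 * 60)
  pr_range <- config$log10_protection_range %||% c(1.5, 4.5)
  k_base <- config$k_int_base %||% 50

  models <- list(); maps <- list(); tables <- list()
  for (pid in names(config$proteins)) {
    pr <- config$proteins[[pid]]
    L <- nchar(pr$sequence)
    set.seed(child_seed(seed, paste0("protection-", pid)))
    loaded <- 10^stats::runif(L, pr_range[1], pr_range[2])
    receptive <- loaded
    rr <- regions[regions$protein == pid, ]
    if (nrow(rr) > 0) {
      for (i in seq_len(nrow(rr))) {
        if (rr$end[i] > L) stop("region outside protein", call. = FALSE)
        idx <- rr$start[i]:rr$end[i]
        receptive[idx] <- pmax(1, loaded[idx] / rr$fold[i])
      }
    }
    prot <- stats::setNames(vector("list", length(state_names)), state_names)
    for (k in seq_along(state_names)) {
      prot[[state_names[k]]] <- switch(roles[k],
                                       reference = loaded,
                                       perturbed = receptive,
                                       rescue = loaded)
    }
    model <- exchange_model(pid, pr$sequence, k_base, prot)
    dig <- pr$digestion %||% digestion_params()
    dig$seed <- child_seed(seed, paste0("map-", pr$map_group %||% pid))
    map <- simulate_digestion(pr$sequence, dig)
    tab <- dplyr::bind_rows(lapply(state_names, function(st) {
      simulate_uptake(model, map, times, noise, st, seed)
    }))
    models[[pid]] <- model
    maps[[pid]] <- map
    tables[[pid]] <- tab
  }
  list(
    tables = tables, models = models, peptide_maps = maps,
    states = config$states, times = times,
    ground_truth = list(regions = regions, seed = seed)
  )
}
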