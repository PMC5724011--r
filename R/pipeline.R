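# End-to-end orchestration: from state tables (measured or simulated) to
# coverage reports, differential tables, residue maps, normalized-increase
# statistics, significance calls and serialized outputs.

#' Peptides common to two uptake tables
#'
#' Peptides are matched by their location within the protein sequence
#' (identical `start`, `end`); at matched coordinates, differing sequences
#' (polymorphic positions between allotypes) are reported, not treated as
#' a mismatch.
#'
#' @param table_a,table_b validated uptake tables (typically two
#'   allotypes' tables for homologous proteins).
#' @return tibble with `start`, `end`, `sequence_a`, `sequence_b`,
#'   `polymorphic`.
#' @export
common_peptides <- function(table_a, table_b) {
  pa <- dplyr::distinct(tibble::as_tibble(table_a)[, c("start", "end", "sequence")])
  pb <- dplyr::distinct(tibble::as_tibble(table_b)[, c("start", "end", "sequence")])
  common <- dplyr::inner_join(pa, pb, by = c("start", "end"),
                              suffix = c("_a", "_b"))
  out <- dplyr::transmute(
    common, .data$start, .data$end,
    sequence_a = .data$sequence_a, sequence_b = .data$sequence_b,
    polymorphic = .data$sequence_a != .data$sequence_b
  )
  dplyr::arrange(out, .data$start, .data$end)
}

#' @noRd
stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", label, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full differential HDX analysis
#'
#' For every protein: validates the table, computes coverage/redundancy,
#' replicate statistics and, for each non-reference state, differential
#' uptake tables, consolidated residue maps, per-(peptide, time) Welch
#' significance calls, and normalized uptake increases at the reference
#' labeling time. If `domains` are supplied, a paired two-tailed t test
#' over each domain's peptides (mean uptake at `ref_time`, perturbed vs
#' reference) is added. With a single configured state the differential
#' stages are skipped with a warning.
#'
#' @param config a [run_config()].
#' @param tables named list of uptake tibbles (one per protein), a single
#'   combined tibble, or `NULL` to read CSV paths from
#'   `config$state_tables`.
#' @param sequences optional named sequence vector; read from
#'   `config$proteins` FASTA paths when those are paths.
#' @param domains optional tibble (`protein`, `domain`, `start`, `end`)
#'   defining regions for the paired t tests.
#' @return an `analysis_report` list; files are written when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config, tables = NULL, sequences = NULL,
                         domains = NULL) {
  stopifnot(inherits(config, "run_config"))
  sequences <- stage("load sequences", {
    if (!is.null(sequences)) sequences
    else if (is.character(config$proteins) && all(nzchar(config$proteins)) &&
             all(file.exists(config$proteins))) {
      # one FASTA may hold several records; merge and keep unique ids
      merged <- unlist(unname(lapply(unique(config$proteins), read_fasta)))
      merged[!duplicated(names(merged))]
    } else NULL
  })
  tables <- stage("load tables", {
    if (is.null(tables)) {
      paths <- config$state_tables
      if (is.null(paths)) stop("no uptake tables supplied", call. = FALSE)
      combined <- dplyr::bind_rows(lapply(paths, read_state_table, fasta = sequences))
      split(combined, combined$protein)
    } else if (is.data.frame(tables)) {
      split(tables, tables$protein)
    } else tables
  })
  state_names <- names(config$states)
  ref_state <- state_names[unname(config$states) == "reference"]
  pert_states <- setdiff(state_names, ref_state)
  single_state <- length(state_names) < 2L
  if (single_state) {
    warning("only one state configured: differential stages skipped", call. = FALSE)
  }
  qc <- character(0)

  report <- list()
  for (pid in names(tables)) {
    tab <- stage(paste("validate", pid),
                 validate_uptake_table(tables[[pid]],
                                       fasta = sequences,
                                       first_residue_exclusion = config$first_residue_exclusion))
    over <- tab$uptake > tab$max_uptake
    if (any(over)) {
      qc <- c(qc, sprintf("%s: %d measurement(s) exceed max_uptake (flagged, not clamped)",
                          pid, sum(over)))
    }
    peptides <- dplyr::distinct(tab[, c("start", "end")])
    prot_len <- if (!is.null(sequences) && pid %in% names(sequences)) {
      nchar(sequences[[pid]])
    } else max(tab$end)
    entry <- list(
      coverage = stage(paste("coverage", pid),
                       coverage_redundancy(peptides, prot_len)),
      uptake_stats = stage(paste("replicate stats", pid), uptake_stats(tab)),
      differentials = list(), residue_maps = list(),
      comparisons = list(), normalized = list()
    )
    if (!single_state) {
      for (ps in pert_states) {
        key <- paste0(ps, "_vs_", ref_state)
        diffs <- stage(paste("differential", pid, key),
                       differential_table(tab, ref_state, ps))
        entry$differentials[[key]] <- diffs
        entry$residue_maps[[key]] <- stage(
          paste("residue map", pid, key),
          build_residue_map(diffs, peptides, prot_len, protein_id = pid))
        entry$comparisons[[key]] <- stage(
          paste("state comparison", pid, key),
          state_comparison_table(tab, ref_state, ps, alpha = config$alpha))
        entry$normalized[[key]] <- stage(
          paste("normalized increase", pid, key),
          dplyr::bind_rows(lapply(seq_len(nrow(peptides)), function(i) {
            ni <- normalized_increase(tab, peptides$start[i], peptides$end[i],
                                      ref_state, ps, ref_time = config$ref_time)
            tibble::tibble(start = peptides$start[i], end = peptides$end[i],
                           mean = ni$mean, sd = ni$sd, excluded = ni$excluded)
          })))
      }
    }
    report[[pid]] <- entry
  }

  t_tests <- NULL
  if (!is.null(domains) && !single_state) {
    t_tests <- stage("domain t tests", {
      dplyr::bind_rows(lapply(seq_len(nrow(domains)), function(i) {
        pid <- domains$protein[i]
        stats_tbl <- report[[pid]]$uptake_stats
        in_dom <- stats_tbl$start >= domains$start[i] &
          stats_tbl$end <= domains$end[i] &
          abs(stats_tbl$time - config$ref_time) < 1e-9
        dplyr::bind_rows(lapply(pert_states, function(ps) {
          ref_m <- stats_tbl[in_dom & stats_tbl$state == ref_state, ]
          per_m <- stats_tbl[in_dom & stats_tbl$state == ps, ]
          keys <- c("start", "end")
          j <- dplyr::inner_join(ref_m[, c(keys, "mean")],
                                 per_m[, c(keys, "mean")],
                                 by = keys, suffix = c("_ref", "_pert"))
          if (nrow(j) < 2L) return(NULL)
          tt <- paired_t_test(j$mean_pert, j$mean_ref)
          tibble::tibble(protein = pid, domain = domains$domain[i],
                         comparison = paste0(ps, "_vs_", ref_state),
                         n_peptides = nrow(j), t = tt$t, df = tt$df, p = tt$p,
                         mean_increase = tt$mean_diff)
        }))
      }))
    })
  }

  out <- structure(
    list(proteins = report, t_tests = t_tests, qc = qc, config = config),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) {
    stage("write outputs", write_report(out, config$out_dir))
  }
  out
}

#' @noRd
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(report$proteins)) {
    entry <- report$proteins[[pid]]
    readr::write_csv(entry$uptake_stats,
                     file.path(out_dir, paste0(pid, "_uptake_stats.csv")),
                     progress = FALSE)
    for (key in names(entry$residue_maps)) {
      write_residue_map(entry$residue_maps[[key]],
                        file.path(out_dir, paste0(pid, "_map_", key, ".csv")))
      readr::write_csv(entry$comparisons[[key]],
                       file.path(out_dir, paste0(pid, "_comparison_", key, ".csv")),
                       progress = FALSE)
    }
  }
  if (!is.null(report$t_tests)) {
    readr::write_csv(report$t_tests, file.path(out_dir, "domain_t_tests.csv"),
                     progress = FALSE)
  }
  if (length(report$qc) > 0) {
    writeLines(report$qc, file.path(out_dir, "qc_warnings.txt"))
  }
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (pid in names(x$proteins)) {
    cov <- x$proteins[[pid]]$coverage
    cat(sprintf("  %s: %.1f%% coverage, redundancy %.2f, %d peptides, %d comparison(s)\n",
                pid, cov$coverage_percent, cov$mean_redundancy, cov$n_peptides,
                length(x$proteins[[pid]]$comparisons)))
  }
  if (!is.null(x$t_tests) && nrow(x$t_tests) > 0) {
    cat(sprintf("  domain t tests: %d\n", nrow(x$t_tests)))
  }
  if (length(x$qc) > 0) cat(sprintf("  QC warnings: %d\n", length(x$qc)))
  invisible(x)
}
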