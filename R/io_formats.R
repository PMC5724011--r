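# On-disk formats: uptake state tables (a DynamX-style "state data" CSV
# dialect), FASTA sequences (mature-protein numbering: residue 1 is the
# first FASTA character) and long-format residue maps.
# All coordinates are 1-based inclusive; all times are minutes internally.

STATE_TABLE_COLUMNS <- c("protein", "state", "sequence", "start", "end",
                         "max_uptake", "time", "replicate", "uptake")

# column-name aliases accommodating DynamX-style exports
STATE_COLUMN_ALIASES <- c(
  protein = "protein", Protein = "protein",
  state = "state", State = "state",
  sequence = "sequence", Sequence = "sequence",
  start = "start", Start = "start",
  end = "end", End = "end",
  max_uptake = "max_uptake", MaxUptake = "max_uptake", `Max Uptake` = "max_uptake",
  MHP = "mhp", mhp = "mhp",
  time = "time", Exposure = "time", exposure = "time",
  replicate = "replicate", Replicate = "replicate", File = "replicate",
  uptake = "uptake", Uptake = "uptake", Center = "uptake"
)

#' Validate an uptake table
#'
#' Enforces the table invariants: required columns, 1-based inclusive
#' coordinates with `start <= end`, sequence length matching the interval,
#' non-negative uptake, unique (protein, state, peptide, time, replicate)
#' keys, and — when sequences are supplied — agreement of the peptide
#' sequence with the protein sequence and of `max_uptake` with
#' [exchangeable_amides()].
#'
#' @param table a data frame of peptide-level uptake measurements.
#' @param fasta optional named character vector of protein sequences.
#' @param first_residue_exclusion convention used for the `max_uptake`
#'   consistency check.
#' @return the table, invisibly, as a tibble.
#' @export
validate_uptake_table <- function(table, fasta = NULL,
                                  first_residue_exclusion = 1L) {
  table <- tibble::as_tibble(table)
  missing_cols <- setdiff(STATE_TABLE_COLUMNS, names(table))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  row_err <- function(rows, what) {
    stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                 paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(table$start > table$end | table$start < 1)
  if (length(bad)) row_err(bad, "invalid peptide coordinates (end < start or start < 1)")
  bad <- which(nchar(table$sequence) != table$end - table$start + 1L)
  if (length(bad)) row_err(bad, "peptide sequence length does not match start/end")
  bad <- which(table$uptake < 0)
  if (length(bad)) row_err(bad, "negative uptake")
  key <- paste(table$protein, table$state, table$start, table$end,
               table$sequence, table$time, table$replicate)
  if (anyDuplicated(key)) {
    row_err(which(duplicated(key)), "duplicate (protein, state, peptide, time, replicate) key")
  }
  if (!is.null(fasta)) {
    for (pid in unique(table$protein)) {
      if (!pid %in% names(fasta)) {
        stop(sprintf("protein '%s' not present in FASTA", pid), call. = FALSE)
      }
      idx <- which(table$protein == pid)
      ref <- substring(fasta[[pid]], table$start[idx], table$end[idx])
      bad <- idx[toupper(table$sequence[idx]) != ref]
      if (length(bad)) row_err(bad, sprintf("peptide sequence does not match FASTA for '%s'", pid))
    }
    expected <- vapply(table$sequence, exchangeable_amides, integer(1),
                       first_residue_exclusion = first_residue_exclusion,
                       USE.NAMES = FALSE)
    if (any(abs(table$max_uptake - expected) > 1e-9)) {
      warning("max_uptake inconsistent with the exchangeable-amide count convention",
              call. = FALSE)
    }
  }
  invisible(table)
}

#' Read an uptake state table
#'
#' Reads a comma-separated, UTF-8, headered state-data file. DynamX-style
#' column names (`Protein`, `State`, `Sequence`, `Start`, `End`,
#' `MaxUptake`, `Exposure`, `Replicate`, `Uptake`) are aliased onto the
#' package's lowercase names; `Exposure` values may use `"25s"` /
#' `"4.34h"` suffixes and are normalized to minutes.
#'
#' @param path CSV file path.
#' @param fasta optional named sequence vector for coordinate validation.
#' @return validated uptake tibble with attributes `times`, `states`,
#'   `n_replicates`.
#' @export
read_state_table <- function(path, fasta = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  # read everything as text first: labeling times may carry unit suffixes
  # ("25s", "4.34h") that a numeric guesser would mangle
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  hit <- names(raw) %in% names(STATE_COLUMN_ALIASES)
  names(raw)[hit] <- unname(STATE_COLUMN_ALIASES[names(raw)[hit]])
  if ("time" %in% names(raw)) raw$time <- parse_time_spec(raw$time)
  for (col in intersect(c("start", "end", "replicate"), names(raw))) {
    conv <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(conv) && !all(is.na(raw[[col]]))) {
      stop(sprintf("unparseable value(s) in column '%s' at line(s) %s of %s", col,
                   paste(utils::head(which(is.na(conv) & !is.na(raw[[col]])) + 1L, 5),
                         collapse = ", "), path), call. = FALSE)
    }
    raw[[col]] <- conv
  }
  for (col in intersect(c("max_uptake", "uptake", "mhp"), names(raw))) {
    conv <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(conv) && !all(is.na(raw[[col]]))) {
      stop(sprintf("unparseable value(s) in column '%s' at line(s) %s of %s", col,
                   paste(utils::head(which(is.na(conv) & !is.na(raw[[col]])) + 1L, 5),
                         collapse = ", "), path), call. = FALSE)
    }
    raw[[col]] <- conv
  }
  tab <- validate_uptake_table(raw[, intersect(c(STATE_TABLE_COLUMNS, "mhp"), names(raw))],
                               fasta = fasta)
  attr(tab, "times") <- sort(unique(tab$time))
  attr(tab, "states") <- unique(tab$state)
  attr(tab, "n_replicates") <- max(tab$replicate)
  tab
}

#' Write an uptake state table
#'
#' Writes a validated table as UTF-8 CSV in a stable column order and
#' stable row order, so output is deterministic for a fixed table.
#'
#' @param table uptake table.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(table, path) {
  table <- validate_uptake_table(table)
  out <- dplyr::arrange(table[, STATE_TABLE_COLUMNS],
                        .data$protein, .data$state, .data$start, .data$end,
                        .data$sequence, .data$time, .data$replicate)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Residue 1 is the first FASTA character (mature-protein numbering).
#' Sequences are uppercased and must use the 20 standard residues.
#'
#' @param path FASTA file.
#' @return named character vector, one sequence per record.
#' @export
read_fasta <- function(path) {
  # BStringSet keeps letters verbatim (readAAStringSet silently drops
  # invalid codes), so residue validation below actually sees them
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA contains no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record", call. = FALSE)
  for (i in seq_along(seqs)) assert_aa_string(seqs[i], ids[i])
  stats::setNames(unname(seqs), ids)
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a residue map as a long-format CSV
#'
#' One row per (residue, time): `residue`, `time`, `value`,
#' `source_peptide` (`"start-end"`), `gap_flag`. Gap cells carry an empty
#' value and `gap_flag = TRUE`.
#'
#' @param map a `residue_map`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_residue_map <- function(map, path) {
  stopifnot(inherits(map, "residue_map"))
  long <- tidyr::expand_grid(residue = seq_len(map$length), time = map$times)
  long$value <- map$value[cbind(long$residue, match(long$time, map$times))]
  src <- ifelse(is.na(map$source_start), NA_character_,
                paste0(map$source_start, "-", map$source_end))
  long$source_peptide <- src[long$residue]
  long$gap_flag <- is.na(map$source_start)[long$residue]
  long <- dplyr::arrange(long, .data$residue, .data$time)
  attr(long, "protein_id") <- map$protein_id
  readr::write_csv(dplyr::mutate(long, protein = map$protein_id, .before = 1),
                   path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a residue map written by [write_residue_map()]
#'
#' @param path long-format CSV path.
#' @return a `residue_map`.
#' @export
read_residue_map <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            protein = readr::col_character(),
                            residue = readr::col_integer(),
                            time = readr::col_double(),
                            value = readr::col_double(),
                            source_peptide = readr::col_character(),
                            gap_flag = readr::col_logical()))
  need <- c("protein", "residue", "time", "value", "source_peptide", "gap_flag")
  if (!all(need %in% names(long))) {
    stop("not a residue-map file: missing column(s) ",
         paste(setdiff(need, names(long)), collapse = ", "), call. = FALSE)
  }
  times <- sort(unique(long$time))
  L <- max(long$residue)
  val <- matrix(NA_real_, nrow = L, ncol = length(times),
                dimnames = list(residue = seq_len(L), time = times))
  val[cbind(long$residue, match(long$time, times))] <- long$value
  src <- rep(NA_character_, L)
  src[long$residue] <- long$source_peptide
  ss <- suppressWarnings(as.integer(sub("-.*$", "", src)))
  se <- suppressWarnings(as.integer(sub("^.*-", "", src)))
  structure(
    list(protein_id = long$protein[1], length = L, times = times, value = val,
         source_start = ss, source_end = se),
    class = "residue_map"
  )
}

#' Run configuration for the analysis pipeline
#'
#' @param proteins named character vector: protein id -> FASTA path, or a
#'   named character vector of sequences (detected by content).
#' @param states named character vector mapping state name -> role
#'   (`"reference"`, `"perturbed"`, `"rescue"`); exactly one reference.
#' @param times labeling times, numeric minutes or strings (`"25s"`).
#' @param first_residue_exclusion 1 (default) or 2.
#' @param alpha significance level for state comparisons.
#' @param ref_time normalization labeling time (minutes).
#' @param heatmap_limits symmetric color limits for heat maps.
#' @param state_tables optional character vector of state-data CSV paths
#'   consumed by [run_pipeline()] when no in-memory tables are given.
#' @param out_dir optional output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(proteins, states, times,
                       first_residue_exclusion = 1L, alpha = 0.05,
                       ref_time = 4.34 * 60, heatmap_limits = c(-0.25, 0.25),
                       state_tables = NULL, out_dir = NULL) {
  roles <- unname(states)
  if (sum(roles == "reference") != 1L) {
    stop("exactly one reference state is required", call. = FALSE)
  }
  times <- parse_time_spec(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  stopifnot(first_residue_exclusion %in% c(1L, 2L))
  structure(
    list(proteins = proteins, states = states, times = times,
         first_residue_exclusion = as.integer(first_residue_exclusion),
         alpha = alpha, ref_time = ref_time,
         heatmap_limits = heatmap_limits, state_tables = state_tables,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file with fields matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    proteins = unlist(y$proteins),
    states = unlist(y$states),
    times = unlist(y$times),
    first_residue_exclusion = y$first_residue_exclusion %||% 1L,
    alpha = y$alpha %||% 0.05,
    ref_time = if (is.null(y$ref_time)) 4.34 * 60 else parse_time_spec(y$ref_time),
    heatmap_limits = y$heatmap_limits %||% c(-0.25, 0.25),
    state_tables = unlist(y$state_tables),
    out_dir = y$out_dir
  )
}
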