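# Residue-level consolidation of overlapping peptides into a
# residues x labeling-times map of differential uptake, following the
# heat-map rendering rules: a peptide's own N-terminal residue never
# contributes; each residue takes its value from the shortest covering
# peptide, ties broken by the peptide ending closest to the C terminus.

#' Peptides eligible to report on a residue
#'
#' A peptide `(s, e)` is eligible for residue `r` iff `s < r <= e`: its own
#' first residue carries no observable label and is never used.
#'
#' @param residue 1-based residue index.
#' @param peptides tibble with `start`, `end` columns.
#' @return the eligible subset of `peptides` (possibly empty).
#' @export
eligible_peptides <- function(residue, peptides) {
  peptides[peptides$start < residue & residue <= peptides$end, , drop = FALSE]
}

#' Representative peptide for a residue
#'
#' Among eligible peptides, the shortest; ties broken by greatest
#' C-terminal (end) residue index, then by greatest start. Returns a
#' one-row tibble, or `NULL` when no peptide is eligible (a coverage gap).
#'
#' @inheritParams eligible_peptides
#' @export
select_representative <- function(residue, peptides) {
  el <- eligible_peptides(residue, peptides)
  if (nrow(el) == 0L) return(NULL)
  len <- el$end - el$start + 1L
  el[order(len, -el$end, -el$start)[1L], , drop = FALSE]
}

#' Build a residue-level differential map
#'
#' Collapses per-(peptide, time) differential values onto residues. Every
#' residue takes, at all times, the value of its representative peptide
#' (selection is coverage-based, never time-based); residues with no
#' eligible peptide are gaps (`NA`).
#'
#' @param diffs tibble with `start`, `end`, `time` and a value column
#'   (default `rel_frac_delta`), one row per (peptide, time).
#' @param peptides tibble of `(start, end)` intervals; defaults to the
#'   distinct peptides of `diffs`.
#' @param protein_length protein length in residues.
#' @param protein_id identifier stored on the map.
#' @param value column of `diffs` to consolidate.
#' @return a `residue_map` object: `value` is a `protein_length` x
#'   `length(times)` matrix with `NA` gaps; `source_start`/`source_end`
#'   record the supplying peptide per residue.
#' @export
build_residue_map <- function(diffs, peptides = NULL, protein_length,
                              protein_id = "protein",
                              value = "rel_frac_delta") {
  stopifnot(all(c("start", "end", "time", value) %in% names(diffs)))
  if (is.null(peptides)) {
    peptides <- dplyr::distinct(diffs[, c("start", "end")])
  }
  peptides <- dplyr::distinct(tibble::as_tibble(peptides[, c("start", "end")]))
  times <- sort(unique(diffs$time))
  L <- as.integer(protein_length)

  # rank peptides once: shortest first, then greatest end, then greatest start
  len <- peptides$end - peptides$start + 1L
  ord <- order(len, -peptides$end, -peptides$start)
  assigned <- rep(NA_integer_, L)
  for (p in ord) {
    s <- peptides$start[p]; e <- peptides$end[p]
    if (s + 1L > e) next
    idx <- (s + 1L):min(e, L)
    idx <- idx[is.na(assigned[idx])]
    assigned[idx] <- p
  }

  val <- matrix(NA_real_, nrow = L, ncol = length(times),
                dimnames = list(residue = seq_len(L), time = times))
  sel <- which(!is.na(assigned))
  if (length(sel) > 0L) {
    lookup <- diffs[, c("start", "end", "time", value)]
    for (ti in seq_along(times)) {
      dt <- lookup[lookup$time == times[ti], , drop = FALSE]
      key <- paste(dt$start, dt$end)
      m <- match(paste(peptides$start[assigned[sel]], peptides$end[assigned[sel]]), key)
      if (anyNA(m)) {
        miss <- unique(paste0("(", peptides$start[assigned[sel]][is.na(m)], ",",
                              peptides$end[assigned[sel]][is.na(m)], ")"))
        stop(sprintf("missing differential value at time %g for selected peptide(s) %s",
                     times[ti], paste(miss, collapse = " ")), call. = FALSE)
      }
      val[sel, ti] <- dt[[value]][m]
    }
  }
  structure(
    list(protein_id = protein_id, length = L, times = times, value = val,
         source_start = ifelse(is.na(assigned), NA_integer_, peptides$start[assigned]),
         source_end = ifelse(is.na(assigned), NA_integer_, peptides$end[assigned])),
    class = "residue_map"
  )
}

#' @export
print.residue_map <- function(x, ...) {
  n_gap <- sum(is.na(x$source_start))
  cat(sprintf("<residue_map> %s: %d residues x %d times, %d gap residue(s)\n",
              x$protein_id, x$length, length(x$times), n_gap))
  invisible(x)
}

#' @export
as.matrix.residue_map <- function(x, ...) x$value
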