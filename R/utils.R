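# Internal helpers shared across modules.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
assert_aa_string <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(sprintf("`%s` must be a single non-empty amino-acid string", what),
         call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue character(s) in `%s`: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(toupper(sequence))
}

# Deterministic child seed from a master seed and a text tag; keeps results
# reproducible per (protein, state) without reusing one stream everywhere.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
#' @noRd
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' Parse a labeling-time string into minutes
#'
#' Accepts bare numbers (minutes), or numbers suffixed with `s`/`sec`,
#' `m`/`min`, or `h`/`hr` (e.g. `"25s"`, `"2.1min"`, `"4.34h"`).
#'
#' @param x character or numeric vector of times.
#' @return numeric vector of times in minutes.
#' @examples
#' parse_time_spec(c("25s", "2.1", "4.34h"))
#' @export
parse_time_spec <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    s <- gsub("\\s", "", tolower(s))
    m <- regmatches(s, regexec("^([0-9]*\\.?[0-9]+)(s|sec|m|min|h|hr)?$", s))[[1]]
    if (length(m) == 0L) stop(sprintf("cannot parse time '%s'", s), call. = FALSE)
    val <- as.numeric(m[2])
    unit <- m[3]
    switch(if (unit == "") "m" else substr(unit, 1, 1),
           s = val / 60, m = val, h = val * 60)
  }, numeric(1), USE.NAMES = FALSE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
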