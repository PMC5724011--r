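# Figures: residue-level difference heat maps and per-peptide uptake
# charts with replicate error bars.

#' Heat map of a residue-level differential map
#'
#' Red-blue rendering of relative fractional uptake differences, residues
#' on the x axis, labeling times on the y axis; coverage gaps are blank.
#'
#' @param map a `residue_map`.
#' @param limits symmetric color limits (default `c(-0.25, 0.25)`).
#' @return a ggplot object.
#' @export
plot_residue_map <- function(map, limits = c(-0.25, 0.25)) {
  stopifnot(inherits(map, "residue_map"))
  long <- tidyr::expand_grid(residue = seq_len(map$length), time = map$times)
  long$value <- map$value[cbind(long$residue, match(long$time, map$times))]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue,
                                     y = factor(round(.data$time, 2)),
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = limits, oob = scales_squish,
                                  na.value = "grey85",
                                  name = "rel. fractional\ndifference") +
    ggplot2::labs(x = "residue", y = "labeling time (min)",
                  title = map$protein_id) +
    ggplot2::theme_minimal()
}

# minimal squish so we need not depend on the scales package directly
#' @noRd
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Uptake chart for one peptide
#'
#' Mean deuterium uptake per labeling time and state, replicate standard
#' deviations as vertical error bars, log-scaled time axis.
#'
#' @param table uptake table.
#' @param start,end peptide interval.
#' @return a ggplot object.
#' @export
plot_uptake_chart <- function(table, start, end) {
  stats_tbl <- uptake_stats(table[table$start == start & table$end == end, ])
  if (nrow(stats_tbl) == 0L) stop("peptide not found in table", call. = FALSE)
  ggplot2::ggplot(stats_tbl, ggplot2::aes(x = .data$time, y = .data$mean,
                                          colour = .data$state,
                                          group = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "labeling time (min)", y = "deuterium uptake (Da)",
                  title = sprintf("%s %d-%d (%s)", stats_tbl$protein[1],
                                  start, end, stats_tbl$sequence[1])) +
    ggplot2::theme_minimal()
}
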