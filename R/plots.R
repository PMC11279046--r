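#' Manhattan plot of discovery results
#'
#' @param manhattan a table from [manhattan_table()].
#' @return a [ggplot2::ggplot] object: genomic position on the x-axis
#'   (grouped by chromosome), -log10 p on the y-axis, candidates
#'   highlighted.
#' @export
plot_manhattan <- function(manhattan) {
  chrom_order <- unique(manhattan$chromosome[order(
    suppressWarnings(as.integer(gsub("chr", "", manhattan$chromosome))),
    manhattan$chromosome)])
  df <- manhattan |>
    dplyr::mutate(chromosome = factor(.data$chromosome,
                                      levels = chrom_order)) |>
    dplyr::arrange(.data$chromosome, .data$position) |>
    dplyr::mutate(x = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$neg_log10_p,
                                   colour = .data$candidate)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "forestgreen"),
                                 name = "candidate") +
    ggplot2::facet_grid(~chromosome, scales = "free_x", space = "free_x",
                        switch = "x") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' Kaplan-Meier plot for a fixed methylation threshold
#'
#' @param km a table from [km_plot_table()].
#' @return a [ggplot2::ggplot] step plot, hypomethylated group in green and
#'   hypermethylated in red.
#' @export
plot_km <- function(km) {
  start <- km |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(time = 0, survival = 1, .groups = "drop")
  df <- dplyr::bind_rows(start, km[, c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(hypo = "forestgreen",
                                            hyper = "firebrick")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "survival time (days)", y = "survival rate",
                  colour = "methylation") +
    ggplot2::theme_minimal()
}

#' Scan-trace plot for a threshold result
#'
#' Log-rank p against every candidate threshold, admissible candidates
#' highlighted and the selected threshold marked.
#'
#' @param object a `threshold_result` from [threshold_scan()].
#' @param ... unused.
#' @return a [ggplot2::ggplot] object.
#' @export
#' @method autoplot threshold_result
autoplot.threshold_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$threshold,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$admissible)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "steelblue")) +
    ggplot2::labs(x = "candidate threshold (beta)",
                  y = expression(-log[10] ~ p[logrank])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
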