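#' Quick-look plots for the pipeline's result tables
#'
#' ggplot2 companions to the main tabular outputs.  These are working
#' plots, not publication figures.
#'
#' @name vaxsig-plots
NULL

#' @describeIn vaxsig-plots DE gene counts per condition (up vs down), the
#'   tabular counterpart of a violin overview.
#' @param counts tibble from [count_de()].
#' @export
plot_de_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, c("n_up", "n_down"),
                              names_to = "direction", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$time_h),
    y = ifelse(.data$direction == "n_up", .data$n, -.data$n),
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(
      rows = if ("tissue" %in% names(counts)) ggplot2::vars(.data$tissue)
             else NULL,
      cols = ggplot2::vars(.data$treatment)
    ) +
    ggplot2::labs(x = "hours post-injection", y = "DE genes (down | up)") +
    ggplot2::theme_minimal()
}

#' @describeIn vaxsig-plots module-trait correlation heat tiles.
#' @param trait tibble from [module_trait_correlation()].
#' @export
plot_module_trait <- function(trait) {
  ggplot2::ggplot(trait, ggplot2::aes(.data$treatment, .data$module,
                                      fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn vaxsig-plots serum-protein volcano (log2 fold change vs
#'   Dunnett-adjusted p), significant responses highlighted.
#' @param volcano tibble from [volcano_table()].
#' @export
plot_protein_volcano <- function(volcano) {
  ggplot2::ggplot(volcano, ggplot2::aes(.data$log2fc,
                                        -log10(.data$p.adj))) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$time_h))) +
    ggplot2::geom_text(
      data = filter(volcano, .data$labelled),
      ggplot2::aes(label = .data$analyte), vjust = -0.6, size = 3
    ) +
    ggplot2::labs(x = "log2 fold change vs saline",
                  y = "-log10 adjusted p", colour = "hours") +
    ggplot2::theme_minimal()
}

#' @describeIn vaxsig-plots analyte concentration time courses by
#'   treatment (mean +/- SE over replicates).
#' @param panel long protein tibble.
#' @param analyte analyte to plot.
#' @export
plot_protein_timecourse <- function(panel, analyte) {
  d <- panel |>
    filter(.data$analyte == !!analyte) |>
    group_by(.data$treatment, .data$time_h) |>
    summarise(mean = mean(.data$concentration),
              se = sd(.data$concentration) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$mean,
                                  colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "hours post-injection",
                  y = paste0(analyte, " concentration")) +
    ggplot2::theme_minimal()
}
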