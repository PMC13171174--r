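# ggplot2 displays for spectra and run summaries.

id83_group <- function(channel) {
  p <- str_split(as.character(channel), ":")
  vapply(p, function(x) {
    if (x[3] %in% c("C", "T")) paste0(x[1], "bp ", tolower(x[2]), " (", x[3], ")")
    else if (x[3] == "R") paste0(x[1], "bp+ ", tolower(x[2]), " at repeats")
    else "del. with microhomology"
  }, character(1))
}

#' Plot an 83-channel indel spectrum
#'
#' Bar plot over the canonical channel order, colored by channel family
#' (1-bp deletions/insertions by base, longer indels at repeats, deletions
#' with microhomology).
#'
#' @param object An `indel_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.indel_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  df$group <- id83_group(df$channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "indel count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}

#' @rdname autoplot.indel_spectrum
#' @param spectrum An `indel_spectrum` tibble.
#' @export
plot_spectrum <- function(spectrum, ...) autoplot(spectrum, ...)

#' Plot per-filter removal counts of a run
#'
#' @param run A `duplex_run`.
#' @return A ggplot object.
#' @export
plot_filter_summary <- function(run) {
  df <- run$report |>
    dplyr::filter(str_detect(.data$metric, "^filtered_"), .data$value > 0) |>
    mutate(filter = sub("^filtered_", "", .data$metric))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$filter,
                                                      .data$value),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "candidates removed") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Call counts against the aXsY threshold, mirroring robustness sweeps over
#' rising duplex-consensus stringency.
#'
#' @param sweep Output of [sweep_thresholds()].
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  df <- sweep |>
    mutate(threshold = factor(sprintf("a%ds%d", .data$a, .data$s),
                              levels = sprintf("a%ds%d", .data$a, .data$s)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$n_pass,
                                   group = 1)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pass), color = "firebrick") +
    ggplot2::labs(x = "calling threshold", y = "PASS calls", size = "calls") +
    ggplot2::theme_minimal()
}
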