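# ggplot2 displays for protocol results and rank analyses.

#' @export
autoplot.ab_result <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("test", "recall", "precision", "f3",
                  "classification_error", "rsb_second_pass") |>
    tidyr::pivot_longer(-"test", names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$metric, y = .data$percent,
                               fill = .data$test)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      title = sprintf("A|B protocol: %s features, review %s",
                      object$feature_set[1L], object$review[1L]),
      x = NULL, y = "percent", fill = "independent test") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rank_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature_set, .data$mean_rank),
    y = .data$mean_rank)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = sprintf("Friedman mean ranks (chi2 = %.3f, df = %d, p = %.3f)",
                      object$chi2, object$df, object$p_value),
      subtitle = if (object$direction == "higher_better")
        "higher rank = better" else "lower rank = better",
      x = NULL, y = "mean rank") +
    ggplot2::theme_minimal()
}

#' Heatmap of a metric across reviews and feature sets
#'
#' @param reports Result tibble(s) accepted by [compare_feature_sets()].
#' @param metric One of `"f3"`, `"recall"`, `"precision"`,
#'   `"classification_error"`, `"rsb_second_pass"`.
#' @return A ggplot object.
#' @export
plot_metric_table <- function(reports, metric = "f3") {
  if (is.data.frame(reports)) reports <- list(reports)
  tbl <- dplyr::bind_rows(reports)
  if ("test" %in% names(tbl)) tbl <- tbl[tbl$test %in% "mean", ]
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$feature_set, y = .data$review,
    fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data[[metric]])),
                       color = "white") +
    ggplot2::labs(title = sprintf("mean %s by review and feature set", metric),
                  x = NULL, y = NULL, fill = metric) +
    ggplot2::theme_minimal()
}
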