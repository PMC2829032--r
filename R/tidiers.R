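# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a biomarker pipeline result
#'
#' @param x A `biomarker_result` from [run_biomarker_pipeline()].
#' @param ... Unused.
#' @return Per-animal tibble with scores and calls.
#' @export
tidy.biomarker_result <- function(x, ...) {
  as_tibble(x$scores)
}

#' Summarise a biomarker pipeline result in one row
#'
#' @inheritParams tidy.biomarker_result
#' @return A one-row tibble with tissue, group sizes, threshold, confusion
#'   counts, the four performance metrics and the group-comparison p-values.
#' @export
glance.biomarker_result <- function(x, ...) {
  tibble(
    tissue = x$tissue,
    n_control = sum(x$scores$group == "control"),
    n_stressed = sum(x$scores$group == "stressed"),
    threshold = x$threshold,
    a = x$counts$a, b = x$counts$b, c = x$counts$c, d = x$counts$d,
    sensitivity = x$report$sensitivity,
    specificity = x$report$specificity,
    ppv = x$report$ppv,
    npv = x$report$npv,
    t_statistic = x$ttest$statistic,
    t_p_value = x$ttest$p_value,
    f_statistic = x$anova$statistic,
    anova_p_value = x$anova$p_value
  )
}

#' Tidy a diagnostic report
#'
#' @param x A `diagnostic_report` from [diagnostic_metrics()].
#' @param ... Unused.
#' @return A tibble with one row per metric: `metric`, `value` (exact
#'   percentage, `NA` when undefined), `display` (integer percent).
#' @export
tidy.diagnostic_report <- function(x, ...) {
  metrics <- c("sensitivity", "specificity", "ppv", "npv")
  tibble(
    metric = metrics,
    value = unname(vapply(metrics, function(m) x[[m]], 1)),
    display = unname(vapply(metrics, function(m)
      as.integer(x$display[[m]]), 1L))
  )
}

#' @rdname tidy.diagnostic_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  tibble(
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv, npv = x$npv, threshold = x$threshold,
    a = x$counts$a, b = x$counts$b, c = x$counts$c, d = x$counts$d
  )
}

#' Scatter plot of pro-fraction scores with the positivity threshold
#'
#' Mirrors the scatter-plot view of the two populations: one point per
#' animal by group, the control-derived mean + 1SD threshold as a dashed
#' line, and calls encoded by shape.
#'
#' @param object A `biomarker_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biomarker_result <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$group, y = .data$pro_fraction)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$group,
                                      shape = .data$call),
                         width = 0.12, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::annotate("text", x = 0.55, y = object$threshold,
                      label = sprintf("threshold %.1f%%", object$threshold),
                      vjust = -0.6, hjust = 0, size = 3) +
    ggplot2::labs(
      title = sprintf("proBDNF/totBDNF scores (%s)", object$tissue),
      x = NULL, y = "proBDNF / total BDNF (%)",
      shape = "test call", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of stressed/control expression ratios per transcript variant
#'
#' @param object A `regulation_report`.
#' @param ... Unused.
#' @return A ggplot object with significance stars above the bars.
#' @export
autoplot.regulation_report <- function(object, ...) {
  df <- as_tibble(object)
  df$variant <- factor(df$variant, levels = df$variant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$ratio,
                                   fill = .data$direction)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.4) +
    ggplot2::labs(x = "transcript variant",
                  y = "stressed / control expression ratio",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
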