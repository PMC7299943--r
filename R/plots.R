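#' Plot empirical versus theoretical accuracy
#'
#' Dot plot of empirical accuracy per design with the theoretical accuracy
#' (narrow-sense and family-based heritability) overlaid as open shapes.
#'
#' @param object An `accuracy_report` tibble (one or more rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.accuracy_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("r_empirical", "r_theory_narrow", "r_theory_family"),
    names_to = "kind", values_to = "accuracy"
  )
  long$kind <- factor(long$kind,
                      levels = c("r_empirical", "r_theory_narrow",
                                 "r_theory_family"),
                      labels = c("empirical", "theory (narrow h2)",
                                 "theory (family h2)"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$design, y = .data$accuracy,
                               colour = .data$kind, shape = .data$kind)) +
    ggplot2::geom_point(size = 3, position =
                          ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_shape_manual(values = c(16, 1, 2)) +
    ggplot2::labs(x = NULL, y = "prediction accuracy (r)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a decile prevalence / odds-ratio report
#'
#' Two-panel style plot: prevalence above each decile threshold and the
#' corresponding odds ratio against the population, mirroring the standard
#' clinical presentation of PRS stratification.
#'
#' @param object A `decile_report` tibble.
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @exportS3Method ggplot2::autoplot
autoplot.decile_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("prevalence_above", "odds_ratio"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric,
                        levels = c("prevalence_above", "odds_ratio"),
                        labels = c("prevalence above decile",
                                   "odds ratio vs population"))
  ggplot2::ggplot(long[is.finite(long$value), ],
                  ggplot2::aes(x = .data$decile, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "PRS decile threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fold changes with confidence intervals
#'
#' @param object A `fold_change_summary` (rows may be labelled via a
#'   `comparison` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fold_change_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"comparison" %in% names(df)) {
    df$comparison <- sprintf("comparison %d", seq_len(nrow(df)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison,
                                   y = .data$mean_fold)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, colour = "red") +
    ggplot2::labs(x = NULL, y = "mean fold change (95% CI)") +
    ggplot2::theme_minimal()
}
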