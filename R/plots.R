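#' Plot aggregated feature importances
#'
#' Horizontal bar chart of the top-`n` features by aggregated importance
#' score across the per-class sub-models.
#'
#' @param object A `bp_importance` tibble from [aggregate_importance()].
#' @param n Number of top features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_importance <- function(object, n = 10, ...) {
  d <- head(object, n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$score), y = .data$score)) +
    ggplot2::geom_col(fill = "#3B6E8F") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "aggregated importance score",
                  title = "Top predictive features across sub-models") +
    ggplot2::theme_minimal()
}

#' Plot the repeated-splits comparison table
#'
#' Point-range chart of mean SBP reduction (with one standard deviation
#' across splits) per algorithm and policy mode, with the reference rows
#' (current regimen, standard of care) alongside.
#'
#' @param object A `bp_report` from [repeated_splits()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_report <- function(object, ...) {
  d <- object$table %>%
    mutate(label = if_else(.data$mode == "reference", .data$algorithm,
                           paste(.data$algorithm, .data$mode, sep = " / ")))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$mean_reduction),
    y = .data$mean_reduction,
    ymin = .data$mean_reduction - .data$sd_reduction,
    ymax = .data$mean_reduction + .data$sd_reduction,
    colour = .data$mode)) +
    ggplot2::geom_pointrange() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean SBP reduction (mmHg)",
                  colour = "policy",
                  title = "SBP reduction by algorithm and policy") +
    ggplot2::theme_minimal()
}

#' Plot neighborhood (affinity) profiles against the test-set baseline
#'
#' One panel per profiled feature; bars give the pooled-neighborhood value
#' per recommended drug class and the dashed line the test-set baseline.
#'
#' @param object A `bp_profiles` tibble from [neighborhood_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_profiles <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$drug_class, y = .data$neighborhood)) +
    ggplot2::geom_col(fill = "#88A550") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "neighborhood value (% for binary features)",
                  title = "Affinity profiles per recommended class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot recommended-class shares for the drug-naive initiation subgroup
#'
#' @param shares The `shares` tibble from [naive_initiation_analysis()].
#' @return A ggplot object.
#' @export
plot_initiation_shares <- function(shares) {
  ggplot2::ggplot(shares, ggplot2::aes(
    x = stats::reorder(.data$chosen, -.data$share_pct),
    y = .data$share_pct)) +
    ggplot2::geom_col(fill = "#B46A55") +
    ggplot2::labs(x = NULL, y = "share of recommendations (%)",
                  title = "Treatment initiation for drug-naive visits") +
    ggplot2::theme_minimal()
}
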