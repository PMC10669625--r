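#' Spaghetti plot of breath washout curves
#'
#' One line per subject on a log scale, coloured by group, with the group
#' medians overlaid — the standard view of first-order washout (straight
#' post-peak decay on the log scale).
#'
#' @param washout Long washout table.
#' @return A ggplot object.
#' @export
plot_washout <- function(washout) {
  med <- washout %>%
    group_by(.data$group, .data$timepoint_min) %>%
    summarise(limonene_ng = median(.data$limonene_ng), .groups = "drop")
  ggplot2::ggplot(washout,
                  ggplot2::aes(.data$timepoint_min, .data$limonene_ng,
                               colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.25) +
    ggplot2::geom_line(data = med, linewidth = 1.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time post-dose (min)", y = "Limonene (ng / 400 mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn roc_auroc Plot the ROC curve.
#' @param object A `breath_roc`.
#' @param ... Unused.
#' @method autoplot breath_roc
#' @export
autoplot.breath_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' @describeIn canonical_correlation Bar chart of first-dimension canonical
#'   loadings.
#' @param object A `breath_cca`.
#' @param ... Unused.
#' @method autoplot breath_cca
#' @export
autoplot.breath_cca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$variable, .data$loading,
                                  fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Canonical loading (dimension 1)") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_timepoints Plot split-averaged AUROC, sensitivity and
#'   specificity per feature.
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, ...) {
  d <- as_tibble(object) %>%
    select("feature", auroc = "auroc_mean", sensitivity = "sens_mean",
           specificity = "spec_mean") %>%
    tidyr::pivot_longer(-"feature", names_to = "metric")
  d$feature <- factor(d$feature, levels = unique(as_tibble(object)$feature))
  ggplot2::ggplot(d, ggplot2::aes(.data$feature, .data$value,
                                  group = .data$metric,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Feature (timepoint, min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplot of AUC by a clinical flag
#'
#' @param kinetics Output of [nca()].
#' @param subjects Subject metadata table.
#' @param flag Flag column name (see [compare_auc_by_flag()]).
#' @param group Group to display (default `"cirrhosis"`).
#' @return A ggplot object.
#' @export
plot_auc_by_flag <- function(kinetics, subjects, flag = "portal_htn",
                             group = "cirrhosis") {
  d <- kinetics %>%
    left_join(select(subjects, "subject_id", all_of(flag)), by = "subject_id") %>%
    filter(.data$group == !!group, !is.na(.data$auc_0_90), !is.na(.data[[flag]]))
  ggplot2::ggplot(d, ggplot2::aes(.data[[flag]], .data$auc_0_90)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = flag, y = "AUC 0-90 (ng·min / 400 mL)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
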