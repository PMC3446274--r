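#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_boxplot geom_hline geom_histogram labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An `evorisk_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evorisk_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#2166ac") +
    labs(
      x = "False positive rate", y = "Sensitivity",
      title = sprintf(
        "AUC = %.2f (95%% CI %.2f-%.2f)",
        object$auc, object$ci_low, object$ci_high
      )
    ) +
    theme_minimal()
}

#' Boxplots of held-out AUCs per algorithm
#'
#' @param object An `evorisk_holdout` from [repeated_holdout()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evorisk_holdout <- function(object, ...) {
  ggplot(object$auc, aes(x = .data$algorithm, y = .data$auc)) +
    geom_boxplot(fill = "#d1e5f0") +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    labs(x = NULL, y = "Held-out AUC (C-index)") +
    theme_minimal()
}

#' Variability-versus-mean scatter of the top differentially variable CpGs
#'
#' Plots the log2 case/control variance ratio (b-statistic) against the
#' t-statistic of mean differential methylation for the `top_n`
#' lowest-Bartlett-p CpGs, the standard view of how outlier-driven
#' variance changes decouple from mean shifts.
#'
#' @param dvc A tibble from [rank_dvcs()].
#' @param top_n How many top CpGs to show (default 500).
#' @return A ggplot.
#' @export
plot_dvc <- function(dvc, top_n = 500) {
  top <- utils::head(dvc, top_n)
  ggplot(top, aes(x = .data$t_stat, y = .data$b_stat, colour = .data$direction)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = 0, colour = "grey60") +
    labs(
      x = "t-statistic (differential methylation)",
      y = "log2 variance ratio (case / control)",
      colour = NULL
    ) +
    theme_minimal()
}

#' Histogram of per-sample risk scores by phenotype
#'
#' @param scores An `evorisk_scores` tibble from [score_samples()].
#' @param annotation Sample annotation tibble (for phenotype colours);
#'   optional.
#' @return A ggplot.
#' @export
plot_scores <- function(scores, annotation = NULL) {
  df <- scores
  if (!is.null(annotation)) {
    df <- dplyr::left_join(df, annotation[, c("sample_id", "status")], by = "sample_id")
    return(
      ggplot(df, aes(x = .data$status, y = .data$score)) +
        geom_boxplot(fill = "#fddbc7") +
        labs(x = NULL, y = "Risk score (fraction of risk CpGs hit)") +
        theme_minimal()
    )
  }
  ggplot(df, aes(x = .data$score)) +
    geom_histogram(bins = 30, fill = "#2166ac") +
    labs(x = "Risk score", y = "Samples") +
    theme_minimal()
}
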