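#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained risk model
#'
#' One row per risk CpG with its frozen COPA parameters, in model order.
#'
#' @param x An `evorisk_model`.
#' @param ... Unused.
#' @return A tibble with `cpg_id`, `rank`, `median`, `mad`.
#' @export
tidy.evorisk_model <- function(x, ...) {
  dplyr::mutate(x$copa_params, rank = dplyr::row_number(), .after = "cpg_id")
}

#' @rdname tidy.evorisk_model
#' @return For `glance()`: a one-row tibble with `n_risk_cpgs`,
#'   `threshold`, `scale`, `mean_cv_auc`, `folds`, `seed`.
#' @export
glance.evorisk_model <- function(x, ...) {
  tibble(
    n_risk_cpgs = length(x$risk_cpgs),
    threshold = x$threshold,
    scale = x$scale,
    mean_cv_auc = x$training_meta$mean_cv_auc %||% NA_real_,
    folds = x$training_meta$folds %||% NA_integer_,
    seed = x$training_meta$seed %||% NA_integer_
  )
}

#' Tidy ROC results
#'
#' @param x An `evorisk_roc` from [roc_auc()].
#' @param ... Unused.
#' @return `tidy()`: the ROC curve tibble (`fpr`, `sensitivity`,
#'   `threshold`); `glance()`: one row with `auc`, `ci_low`, `ci_high`,
#'   `n_case`, `n_control`.
#' @export
tidy.evorisk_roc <- function(x, ...) x$curve

#' @rdname tidy.evorisk_roc
#' @export
glance.evorisk_roc <- function(x, ...) {
  tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    n_case = x$n_case, n_control = x$n_control
  )
}

#' Tidy repeated-holdout experiments
#'
#' @param x An `evorisk_holdout` from [repeated_holdout()].
#' @param ... Unused.
#' @return `tidy()`: per-partition AUCs (`partition`, `algorithm`,
#'   `auc`); `glance()`: one row per algorithm with the median AUC and
#'   Wilcoxon p-values.
#' @export
tidy.evorisk_holdout <- function(x, ...) x$auc

#' @rdname tidy.evorisk_holdout
#' @export
glance.evorisk_holdout <- function(x, ...) {
  out <- dplyr::summarise(
    dplyr::group_by(x$auc, .data$algorithm),
    n = dplyr::n(),
    median_auc = median(.data$auc),
    mean_auc = mean(.data$auc),
    .groups = "drop"
  )
  out$p_vs_chance <- unname(x$p_vs_chance[out$algorithm])
  out$p_paired <- x$p_paired
  out$n_failed <- x$n_failed
  out
}
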