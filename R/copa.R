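#' Estimate per-CpG COPA parameters on training samples
#'
#' Cancer Outlier Profile Analysis (COPA) centers each feature at its
#' median and scales by the median absolute deviation (MAD, scaled by the
#' usual 1.4826 consistency factor), so a handful of extreme samples stand
#' out in units that are robust to the bulk of the distribution and
#' invariant to per-feature affine recalibration. CpGs whose MAD is zero
#' (more than half the training samples identical) carry no outlier
#' information and are flagged unusable.
#'
#' @param beta Training methylation matrix (CpGs x samples).
#' @return A tibble of class `evorisk_copa` with `cpg_id`, `median`, `mad`
#'   (already including the 1.4826 factor) and `usable`.
#' @export
copa_fit <- function(beta) {
  rm <- row_median_mad(beta) # 1.4826 * raw MAD, as stats::mad
  med <- rm$median
  madv <- rm$mad
  all_missing <- rowSums(!is.na(beta)) == 0
  out <- tibble(
    cpg_id = rownames(beta),
    median = ifelse(all_missing, NA_real_, med),
    mad = ifelse(all_missing, NA_real_, madv),
    usable = !all_missing & !is.na(madv) & madv > 0
  )
  class(out) <- c("evorisk_copa", class(out))
  out
}

#' Apply the COPA transformation to a methylation matrix
#'
#' Computes `(beta - median) / (1.4826 * MAD)` per CpG. When `params` is
#' `NULL` the median and MAD are estimated from `beta` itself (training
#' use); otherwise the frozen training parameters are applied, which is
#' how an independent test sample is projected into the training outlier
#' basis without leakage. Unusable CpGs (MAD = 0) yield `NA` rows.
#'
#' @param beta Methylation matrix (CpGs x samples).
#' @param params Optional `evorisk_copa` tibble from [copa_fit()]; must
#'   cover every CpG in `beta`.
#' @return Matrix of COPA scores, same shape and dimnames as `beta`.
#' @export
copa_transform <- function(beta, params = NULL) {
  if (is.null(params)) params <- copa_fit(beta)
  idx <- match(rownames(beta), params$cpg_id)
  if (anyNA(idx)) {
    abort(sprintf(
      "COPA parameters missing for CpG(s): %s",
      paste(utils::head(rownames(beta)[is.na(idx)], 5), collapse = ", ")
    ))
  }
  med <- params$median[idx]
  madv <- params$mad[idx]
  madv[!params$usable[idx]] <- NA_real_
  (beta - med) / madv
}
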