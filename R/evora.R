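new_evorisk_model <- function(risk_cpgs, copa_params, threshold, scale,
                              training_meta = list(), cv_auc = NULL) {
  stopifnot(length(risk_cpgs) > 0, threshold > 0)
  structure(
    list(
      risk_cpgs = as.character(risk_cpgs),
      copa_params = copa_params,
      threshold = threshold,
      scale = scale,
      training_meta = training_meta,
      cv_auc = cv_auc
    ),
    class = "evorisk_model"
  )
}

#' @export
print.evorisk_model <- function(x, ...) {
  cat(sprintf(
    "<evorisk_model> %d risk CpGs | threshold %.3g (%s scale) | %s-fold CV\n",
    length(x$risk_cpgs), x$threshold, x$scale,
    x$training_meta$folds %||% "?"
  ))
  if (!is.null(x$training_meta$mean_cv_auc)) {
    cat(sprintf("  mean cross-validated AUC: %.3f\n", x$training_meta$mean_cv_auc))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select candidate risk CpGs
#'
#' A candidate risk CpG must be simultaneously hypervariable in cases
#' (Bartlett q below `fdr_dv` with variance ratio above 1) and
#' significantly hypermethylated with age (age q below `fdr_age` with a
#' positive slope). CpGs unusable in the COPA basis (zero training MAD)
#' are removed. The result is ordered by ascending Bartlett p-value, ties
#' broken by `cpg_id`.
#'
#' @param dvc Differential-variability tibble from [rank_dvcs()].
#' @param age Age-association tibble from [age_association()].
#' @param fdr_dv,fdr_age FDR (q-value) cutoffs for the two axes.
#' @param copa_params Optional [copa_fit()] result used to drop unusable
#'   CpGs.
#' @return Character vector of candidate CpG IDs, best first.
#' @export
select_candidates <- function(dvc, age, fdr_dv = 0.05, fdr_age = 0.05,
                              copa_params = NULL) {
  joined <- dplyr::inner_join(
    dplyr::select(dvc, "cpg_id", "var_ratio", "p_bartlett", "q_bartlett"),
    dplyr::select(age, "cpg_id", "slope", "q_age"),
    by = "cpg_id"
  )
  sel <- dplyr::filter(
    joined,
    !is.na(.data$q_bartlett), !is.na(.data$q_age),
    .data$q_bartlett < fdr_dv, .data$var_ratio > 1,
    .data$q_age < fdr_age, .data$slope > 0
  )
  sel <- dplyr::arrange(sel, .data$p_bartlett, .data$cpg_id)
  ids <- sel$cpg_id
  if (!is.null(copa_params)) {
    usable <- copa_params$cpg_id[copa_params$usable]
    ids <- ids[ids %in% usable]
  }
  if (length(ids) == 0) {
    abort("no candidate risk CpGs at these FDR cutoffs; loosen fdr_dv/fdr_age")
  }
  ids
}

# Tie-corrected Mann-Whitney AUC (ties count 1/2).
auc_mw <- function(scores, labels) {
  pos <- labels == "case" | labels == 1 | labels == TRUE
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fraction of selected CpGs whose transformed value strictly exceeds the
# threshold, per sample; NA values drop out of the denominator.
adaptive_index_scores <- function(values, threshold) {
  hit <- values > threshold
  n_used <- unname(colSums(!is.na(hit)))
  n_hits <- unname(colSums(hit, na.rm = TRUE))
  list(score = ifelse(n_used > 0, n_hits / n_used, NA_real_),
       n_hits = n_hits, n_used = n_used)
}

# Shared adaptive-index trainer. candidate_fun(beta, annotation) must
# return candidate CpG IDs in priority order (it sees training samples
# only; all statistics and COPA parameters are re-estimated within each
# fold, so held-out data never leak into selection).
train_adaptive_index <- function(beta, annotation, candidate_fun,
                                 folds, threshold_grid, size_grid, seed,
                                 meta = list()) {
  annotation <- check_annotation_matches(beta, annotation)
  status <- annotation$status
  tab <- table(factor(status, levels = c("case", "control")))
  if (any(tab == 0)) abort("both classes (case and control) are required for training")
  if (any(tab < folds)) {
    abort(sprintf(
      "smallest class has %d samples; reduce folds below that", min(tab)
    ))
  }
  threshold_grid <- sort(threshold_grid)
  size_grid <- sort(size_grid)
  seeds <- derive_seeds(seed, 1)
  fold <- stratified_folds(status, folds, seeds[1])

  cv_auc <- array(NA_real_,
    dim = c(length(size_grid), length(threshold_grid), folds),
    dimnames = list(size = size_grid, threshold = threshold_grid, fold = NULL)
  )
  for (f in seq_len(folds)) {
    tr <- fold != f
    cand <- tryCatch(
      candidate_fun(beta[, tr, drop = FALSE], annotation[tr, , drop = FALSE]),
      error = function(e) character(0)
    )
    if (length(cand) == 0) next
    params <- copa_fit(beta[cand, tr, drop = FALSE])
    cand <- cand[cand %in% params$cpg_id[params$usable]]
    if (length(cand) == 0) next
    test_copa <- copa_transform(beta[cand, !tr, drop = FALSE], params)
    test_labels <- status[!tr]
    for (si in seq_along(size_grid)) {
      top <- utils::head(cand, min(size_grid[si], length(cand)))
      sub <- test_copa[top, , drop = FALSE]
      for (ti in seq_along(threshold_grid)) {
        sc <- adaptive_index_scores(sub, threshold_grid[ti])$score
        cv_auc[si, ti, f] <- auc_mw(sc, test_labels)
      }
    }
  }

  mean_auc <- apply(cv_auc, c(1, 2), function(a) {
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
  })
  if (all(is.na(mean_auc))) {
    abort("no (threshold, size) combination yielded a computable cross-validated AUC")
  }
  # ties resolved toward the smaller set size, then the smaller threshold
  best <- which(mean_auc == max(mean_auc, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  s_star <- size_grid[best[1]]
  t_star <- threshold_grid[best[2]]

  cand_full <- candidate_fun(beta, annotation)
  params_full <- copa_fit(beta[cand_full, , drop = FALSE])
  cand_full <- cand_full[cand_full %in% params_full$cpg_id[params_full$usable]]
  if (length(cand_full) == 0) abort("no usable candidate CpGs on the full training set")
  risk <- utils::head(cand_full, min(s_star, length(cand_full)))

  meta <- utils::modifyList(meta, list(
    seed = seed, folds = folds,
    threshold_grid = threshold_grid, size_grid = size_grid,
    selected_size = s_star, selected_threshold = t_star,
    mean_cv_auc = max(mean_auc, na.rm = TRUE),
    n_candidates_full = length(cand_full)
  ))
  new_evorisk_model(
    risk_cpgs = risk,
    copa_params = params_full[match(risk, params_full$cpg_id), c("cpg_id", "median", "mad")],
    threshold = t_star,
    scale = "copa",
    training_meta = meta,
    cv_auc = mean_auc
  )
}

#' Train an EVORA risk model
#'
#' Trains the full outlier-based adaptive-index classifier: within each of
#' `folds` stratified cross-validation folds, differential-variability and
#' age-association statistics are re-estimated on the training part only,
#' candidate risk CpGs are the hypervariable/age-hypermethylated overlap
#' ([select_candidates()]), COPA parameters are frozen on the training
#' part, and the held-out AUC of the score "fraction of the top-`s`
#' candidates with COPA value above `t`" is recorded over the grids. The
#' `(t, s)` pair maximizing the mean cross-validated AUC is selected (ties
#' prefer the smaller set, then the smaller threshold) and the final model
#' is refit on the complete training cohort.
#'
#' @param beta Training methylation matrix (CpGs x samples).
#' @param annotation Sample annotation tibble covering the columns of
#'   `beta`.
#' @param folds Number of internal cross-validation folds (default 10).
#' @param threshold_grid COPA outlier thresholds to scan; the default
#'   spans the conventional "> 5" / "> 10" outlier bands.
#' @param size_grid Risk-set sizes to scan; `Inf` means "all candidates".
#' @param fdr_dv,fdr_age FDR cutoffs for candidate selection.
#' @param adjust_hpv Also adjust variances for HPV status.
#' @param seed Integer seed controlling fold assignment.
#' @return An `evorisk_model` with the risk-CpG list, frozen COPA
#'   parameters, optimal threshold, and training metadata.
#' @seealso [score_samples()], [train_mean_comparator()]
#' @export
train_evora <- function(beta, annotation, folds = 10,
                        threshold_grid = c(2, 3, 4, 5, 7, 10),
                        size_grid = c(25, 50, 100, 140, 200, Inf),
                        fdr_dv = 0.05, fdr_age = 0.05,
                        adjust_hpv = FALSE, seed = 1) {
  candidate_fun <- function(b, a) {
    dvc <- rank_dvcs(b, a, adjust_age = TRUE, adjust_hpv = adjust_hpv)
    age <- age_association(b, a, adjust_for_status = TRUE)
    select_candidates(dvc, age, fdr_dv = fdr_dv, fdr_age = fdr_age)
  }
  train_adaptive_index(
    beta, annotation, candidate_fun, folds, threshold_grid, size_grid, seed,
    meta = list(method = "evora", fdr_dv = fdr_dv, fdr_age = fdr_age)
  )
}

#' Train the mean-methylation comparator model
#'
#' Identical machinery to [train_evora()] with a single substitution:
#' candidate CpGs are selected by differential mean methylation (Welch
#' t-test q below `fdr_dm` with a positive case-minus-control mean
#' difference, ranked by t-test p) instead of differential variability.
#' Everything else — COPA basis, cross-validation, scoring — is unchanged,
#' isolating the variability-versus-mean contrast.
#'
#' @inheritParams train_evora
#' @param fdr_dm FDR cutoff on the t-test q-values.
#' @return An `evorisk_model`.
#' @export
train_mean_comparator <- function(beta, annotation, folds = 10,
                                  threshold_grid = c(2, 3, 4, 5, 7, 10),
                                  size_grid = c(25, 50, 100, 140, 200, Inf),
                                  fdr_dm = 0.05, seed = 1) {
  candidate_fun <- function(b, a) {
    dvc <- rank_dvcs(b, a, adjust_age = TRUE)
    sel <- dplyr::filter(
      dvc, !is.na(.data$q_t), .data$q_t < fdr_dm, .data$mean_diff > 0
    )
    sel <- dplyr::arrange(sel, .data$p_t, .data$cpg_id)
    if (nrow(sel) == 0) abort("no differentially methylated candidates at this FDR")
    sel$cpg_id
  }
  train_adaptive_index(
    beta, annotation, candidate_fun, folds, threshold_grid, size_grid, seed,
    meta = list(method = "mean", fdr_dm = fdr_dm)
  )
}

#' Score samples with a trained risk model
#'
#' A sample's risk score is the fraction of the model's risk CpGs that are
#' "methylation hits": CpGs whose COPA value — computed with the frozen
#' training median and MAD — strictly exceeds the trained threshold. On
#' the beta scale ([score_samples_beta()]) a hit is instead a
#' median-normalized beta-value exceeding a beta-unit threshold, which
#' suits cohorts where risk CpGs are hemi-/fully methylated in most cases
#' rather than in rare outliers. Up to 10% of risk CpGs may be absent from
#' `beta` (the denominator shrinks, with a warning); more is an error.
#'
#' @param model An `evorisk_model`.
#' @param beta Methylation matrix of the samples to score.
#' @return A tibble of class `evorisk_scores` with `sample_id`, `score`,
#'   `n_hits`, `n_cpgs_used`, `scale`.
#' @export
score_samples <- function(model, beta) {
  stopifnot(inherits(model, "evorisk_model"))
  if (model$scale == "beta") {
    return(score_samples_beta(model, beta, beta_threshold = model$threshold))
  }
  vals <- model_values(model, beta, what = "copa")
  res <- adaptive_index_scores(vals, model$threshold)
  out <- tibble(
    sample_id = colnames(beta),
    score = res$score,
    n_hits = as.integer(res$n_hits),
    n_cpgs_used = as.integer(res$n_used),
    scale = "copa"
  )
  class(out) <- c("evorisk_scores", class(out))
  out
}

#' @rdname score_samples
#' @param beta_threshold Hit threshold in beta units (default 0.2, i.e. a
#'   20-percentage-point methylation gain over the training median).
#' @export
score_samples_beta <- function(model, beta, beta_threshold = 0.2) {
  stopifnot(inherits(model, "evorisk_model"))
  vals <- model_values(model, beta, what = "beta_centered")
  res <- adaptive_index_scores(vals, beta_threshold)
  out <- tibble(
    sample_id = colnames(beta),
    score = res$score,
    n_hits = as.integer(res$n_hits),
    n_cpgs_used = as.integer(res$n_used),
    scale = "beta"
  )
  class(out) <- c("evorisk_scores", class(out))
  out
}

model_values <- function(model, beta, what) {
  present <- model$risk_cpgs[model$risk_cpgs %in% rownames(beta)]
  frac_missing <- 1 - length(present) / length(model$risk_cpgs)
  if (frac_missing > 0.1) {
    abort(sprintf(
      "%.0f%% of the model's risk CpGs are absent from the matrix (max 10%%)",
      100 * frac_missing
    ))
  }
  if (frac_missing > 0) {
    warn(sprintf(
      "%d of %d risk CpGs absent; scores use the %d present CpGs",
      length(model$risk_cpgs) - length(present), length(model$risk_cpgs),
      length(present)
    ))
  }
  sub <- beta[present, , drop = FALSE]
  idx <- match(present, model$copa_params$cpg_id)
  med <- model$copa_params$median[idx]
  if (what == "copa") {
    (sub - med) / model$copa_params$mad[idx]
  } else {
    sub - med
  }
}

#' Switch a trained model to beta-scale scoring
#'
#' Returns a copy of the model whose [score_samples()] hits are defined on
#' median-normalized beta-values with the given beta-unit threshold.
#'
#' @inheritParams score_samples_beta
#' @return An `evorisk_model` with `scale = "beta"`.
#' @export
as_beta_scale <- function(model, beta_threshold = 0.2) {
  stopifnot(inherits(model, "evorisk_model"))
  model$scale <- "beta"
  model$threshold <- beta_threshold
  model
}
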