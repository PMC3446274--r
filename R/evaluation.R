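#' ROC curve and AUC with bootstrap confidence interval
#'
#' The AUC is the tie-corrected Mann-Whitney estimator (the probability
#' that a random case outscores a random control, ties counting one
#' half); the curve comes from a threshold sweep over the unique scores;
#' the 95% confidence interval is a stratified percentile bootstrap
#' (resampling cases and controls separately), seeded for
#' reproducibility.
#'
#' @param scores Numeric risk scores.
#' @param labels Class labels: `"case"`/`"control"`, or logical/0-1 with
#'   `TRUE`/1 = case.
#' @param n_boot Bootstrap resamples for the CI (default 2000); `0` skips
#'   the CI.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `evorisk_roc`: `auc`, `ci_low`, `ci_high`,
#'   and `curve` (a tibble of `fpr`, `sensitivity`, `threshold`).
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1) {
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) abort("scores must be finite")
  pos <- normalize_labels(labels)
  if (all(pos) || all(!pos)) abort("both classes must be present")

  auc <- auc_mw(scores, pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- tibble(fpr = fpr, sensitivity = tpr, threshold = thr)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ip <- which(pos)
    ic <- which(!pos)
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, replace = TRUE), sample(ic, replace = TRUE))
      auc_mw(scores[idx], pos[idx])
    }, numeric(1)))
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
    ci <- c(min(ci[1], auc), max(ci[2], auc))
  }
  structure(
    list(auc = auc, ci_low = ci[1], ci_high = ci[2], curve = curve,
         n_case = sum(pos), n_control = sum(!pos)),
    class = "evorisk_roc"
  )
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("case", "control")))
    labels == "case"
  } else {
    as.logical(labels)
  }
}

#' @export
print.evorisk_roc <- function(x, ...) {
  cat(sprintf(
    "<evorisk_roc> AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
    x$auc, x$ci_low, x$ci_high, x$n_case, x$n_control
  ))
  invisible(x)
}

#' Wilcoxon tests (rank-sum and signed-rank)
#'
#' Thin, degenerate-safe wrapper around [stats::wilcox.test()]: unpaired
#' rank-sum when `y` is given and `paired = FALSE`; paired signed-rank of
#' `x - y` when `paired = TRUE`; one-sample signed-rank against `mu0`
#' when `y` is `NULL`. Exact for small samples without ties, normal
#' approximation with continuity correction otherwise. All-zero paired
#' differences return p = 1 with a warning instead of an error.
#'
#' @param x,y Numeric vectors (`y` optional).
#' @param paired Paired test (requires `y` of equal length).
#' @param mu0 Null location for the one-sample/paired test.
#' @return The p-value (numeric scalar).
#' @export
wilcoxon_tests <- function(x, y = NULL, paired = FALSE, mu0 = 0) {
  if (paired || is.null(y)) {
    d <- if (is.null(y)) x - mu0 else x - y
    if (all(d == 0)) {
      warn("all differences are zero; p = 1")
      return(1)
    }
    if (is.null(y)) {
      return(quiet_wilcox(stats::wilcox.test(x, mu = mu0))$p.value)
    }
    return(quiet_wilcox(stats::wilcox.test(x, y, paired = TRUE))$p.value)
  }
  quiet_wilcox(stats::wilcox.test(x, y))$p.value
}

# ties/zeros force the documented normal-approximation fallback; the
# warning about it is expected, not actionable
quiet_wilcox <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("cannot compute exact p-value", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Repeated train/test partition experiment
#'
#' Runs `n_partitions` stratified train/test splits; in each, every
#' requested algorithm (EVORA and/or the mean-methylation comparator) is
#' trained on the training part only (internal cross-validation included)
#' and its held-out AUC recorded. Summary tests: Wilcoxon signed-rank of
#' each algorithm's AUCs against the chance value 0.5, and a paired
#' Wilcoxon between the two algorithms. Partitions where training fails
#' (e.g. no candidates survive the FDR cutoffs) are excluded and counted;
#' more than 20% failures is an error. Fully deterministic given `seed`.
#'
#' @param beta Methylation matrix.
#' @param annotation Sample annotation tibble.
#' @param algorithms Subset of `c("evora", "mean")`.
#' @param n_partitions Number of random partitions (default 100).
#' @param train_fraction Fraction of each class used for training
#'   (default 2/3).
#' @param folds Internal cross-validation folds per training run.
#' @param seed Integer seed.
#' @param evora_args,mean_args Named lists of extra arguments for
#'   [train_evora()] and [train_mean_comparator()] respectively (e.g.
#'   `fdr_dv`, `fdr_dm`, `threshold_grid`).
#' @param permute_labels Null-calibration mode: permute the case/control
#'   labels afresh (seeded) before every partition, destroying any
#'   label-phenotype association while keeping the correlation structure
#'   between samples. A fresh permutation per partition is essential: a
#'   single fixed permutation leaves each sample's arbitrary label
#'   constant across partitions, so chance associations found in training
#'   partially generalize to held-out samples of the same cohort and the
#'   mean AUC drifts away from 0.5.
#' @return An object of class `evorisk_holdout`: tibble `auc`
#'   (`partition`, `algorithm`, `auc`), `p_vs_chance` (named), `p_paired`,
#'   `n_failed`, `seed`.
#' @export
repeated_holdout <- function(beta, annotation, algorithms = c("evora", "mean"),
                             n_partitions = 100, train_fraction = 2 / 3,
                             folds = 10, seed = 1,
                             evora_args = list(), mean_args = list(),
                             permute_labels = FALSE) {
  algorithms <- match.arg(algorithms, c("evora", "mean"), several.ok = TRUE)
  annotation <- check_annotation_matches(beta, annotation)
  seeds <- derive_seeds(seed, 3 * n_partitions)
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n_partitions)) {
    part_annot <- annotation
    if (permute_labels) {
      part_annot$status <- with_seed(
        seeds[2 * n_partitions + i],
        sample(part_annot$status)
      )
    }
    tr <- stratified_split(part_annot$status, train_fraction, seeds[i])
    b_tr <- beta[, tr, drop = FALSE]
    a_tr <- part_annot[tr, , drop = FALSE]
    b_te <- beta[, !tr, drop = FALSE]
    lab_te <- part_annot$status[!tr]
    part <- list()
    ok <- TRUE
    for (alg in algorithms) {
      fit <- tryCatch(
        {
          common <- list(b_tr, a_tr, folds = folds, seed = seeds[n_partitions + i])
          if (alg == "evora") {
            do.call(train_evora, c(common, evora_args))
          } else {
            do.call(train_mean_comparator, c(common, mean_args))
          }
        },
        error = function(e) NULL
      )
      if (is.null(fit)) {
        ok <- FALSE
        break
      }
      sc <- score_samples(fit, b_te)
      part[[alg]] <- auc_mw(sc$score, lab_te)
    }
    if (!ok) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      partition = i, algorithm = algorithms,
      auc = unlist(part[algorithms], use.names = FALSE)
    )
  }
  if (n_failed > 0.2 * n_partitions) {
    abort(sprintf("%d of %d partitions failed training (> 20%%)", n_failed, n_partitions))
  }
  auc_tbl <- dplyr::bind_rows(rows)
  p_vs_chance <- vapply(algorithms, function(alg) {
    wilcoxon_tests(auc_tbl$auc[auc_tbl$algorithm == alg], mu0 = 0.5)
  }, numeric(1))
  p_paired <- NA_real_
  if (length(algorithms) == 2) {
    wide <- tidyr::pivot_wider(auc_tbl, names_from = "algorithm", values_from = "auc")
    p_paired <- wilcoxon_tests(wide[[algorithms[1]]], wide[[algorithms[2]]], paired = TRUE)
  }
  structure(
    list(
      auc = auc_tbl, p_vs_chance = p_vs_chance, p_paired = p_paired,
      n_partitions = n_partitions, n_failed = n_failed,
      train_fraction = train_fraction, seed = seed
    ),
    class = "evorisk_holdout"
  )
}

#' @export
print.evorisk_holdout <- function(x, ...) {
  med <- dplyr::summarise(
    dplyr::group_by(x$auc, .data$algorithm),
    median_auc = median(.data$auc)
  )
  cat(sprintf(
    "<evorisk_holdout> %d partitions (%d failed), train fraction %.2f\n",
    x$n_partitions, x$n_failed, x$train_fraction
  ))
  for (i in seq_len(nrow(med))) {
    cat(sprintf(
      "  %s: median AUC %.3f (p vs 0.5 = %.3g)\n",
      med$algorithm[i], med$median_auc[i], x$p_vs_chance[[med$algorithm[i]]]
    ))
  }
  if (!is.na(x$p_paired)) cat(sprintf("  paired Wilcoxon p = %.3g\n", x$p_paired))
  invisible(x)
}
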