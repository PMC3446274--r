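#' Residualize a methylation matrix on a covariate
#'
#' For each CpG, fits ordinary least squares of the methylation value on
#' the covariate — separately within each group when `within` is given —
#' and returns the residuals with the (group) mean added back, so values
#' stay on an interpretable methylation scale. This is how variances are
#' age-adjusted before differential-variability testing: adjusting within
#' each phenotype removes the age trend without touching the between-group
#' mean difference. Missing values pass through untouched.
#'
#' @param beta Methylation matrix (CpGs x samples).
#' @param covariate Numeric covariate per sample (e.g. age in years), or a
#'   sample x term numeric design matrix (no intercept column; one is added).
#' @param within Optional character/factor grouping per sample (e.g.
#'   phenotype); each group is residualized independently and must have at
#'   least 3 samples.
#' @return A matrix of the same shape with residualized values.
#' @export
adjust_covariate <- function(beta, covariate, within = NULL) {
  covariate <- as.matrix(covariate)
  stopifnot(nrow(covariate) == ncol(beta))
  if (any(!is.finite(covariate))) abort("covariate must be finite for all samples")
  groups <- if (is.null(within)) rep("all", ncol(beta)) else as.character(within)
  out <- beta
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) abort(sprintf("group '%s' has %d samples; need at least 3", g, length(idx)))
    X <- cbind(1, covariate[idx, , drop = FALSE])
    out[, idx] <- residualize_rows(beta[, idx, drop = FALSE], X)
  }
  out
}

#' Two-group Bartlett test of equal variances
#'
#' The k = 2 Bartlett statistic
#' `T = ((N-2) log s_p^2 - (n1-1) log s1^2 - (n2-1) log s2^2) / C` with the
#' standard small-sample correction
#' `C = 1 + (1/(n1-1) + 1/(n2-1) - 1/(N-2)) / 3`, referred to a chi-square
#' distribution with 1 degree of freedom. Also reports the case/control
#' variance ratio and its log2 (the b-statistic used to call a CpG
#' hypervariable or hypovariable).
#'
#' @param x Numeric vector of case values (NA dropped).
#' @param y Numeric vector of control values.
#' @return A one-row tibble with `stat`, `p`, `var_ratio`, `b_stat`.
#' @export
bartlett_two_group <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 non-missing values")
  }
  r <- bartlett_rows(matrix(x, nrow = 1), matrix(y, nrow = 1))
  tibble(stat = r$stat, p = r$p, var_ratio = r$var_ratio, b_stat = r$b_stat)
}

#' Welch two-sample t-test for differential methylation
#'
#' @param x Numeric vector of case values.
#' @param y Numeric vector of control values.
#' @return A one-row tibble with `t_stat`, `p`, `mean_diff`
#'   (`mean(x) - mean(y)`).
#' @export
ttest_two_group <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 non-missing values")
  }
  r <- welch_rows(matrix(x, nrow = 1), matrix(y, nrow = 1))
  tibble(t_stat = r$t, p = r$p, mean_diff = r$mean_diff)
}

#' Per-CpG association of methylation with age
#'
#' Fits, for every CpG, an ordinary least-squares regression of beta-value
#' on age — optionally with case/control status as an additive covariate,
#' so the age effect is estimated independently of prospective disease
#' status — and attaches Storey q-values. CpGs with a positive slope are
#' labelled `hyper` (age-hypermethylated), negative `hypo`. Constant CpGs
#' get slope 0 and `NA` p.
#'
#' @param beta Methylation matrix (CpGs x samples).
#' @param annotation Sample annotation tibble (`sample_id`, `status`, `age`).
#' @param adjust_for_status Include status as a covariate (default `TRUE`).
#' @return A tibble with `cpg_id`, `slope` (beta per year), `t_age`,
#'   `p_age`, `q_age`, `direction`.
#' @export
age_association <- function(beta, annotation, adjust_for_status = TRUE) {
  annotation <- check_annotation_matches(beta, annotation)
  age <- annotation$age
  if (length(unique(age)) < 2) abort("age is constant; cannot regress on age")
  if (sum(!is.na(age)) < 10) abort("need at least 10 samples with ages")
  X <- cbind(intercept = 1, age = age)
  if (adjust_for_status) X <- cbind(X, status = as.numeric(annotation$status == "case"))
  fit <- ols_rows(beta, X)
  slope <- fit$coef[, 2]
  t_age <- fit$t[, 2]
  p_age <- fit$p[, 2]
  rv <- row_n_mean_var(beta)$var
  flat <- !is.na(rv) & rv == 0
  slope[flat] <- 0
  t_age[flat] <- NA_real_
  p_age[flat] <- NA_real_
  tibble(
    cpg_id = rownames(beta),
    slope = slope,
    t_age = t_age,
    p_age = p_age,
    q_age = estimate_qvalues(p_age),
    direction = ifelse(slope > 0, "hyper", "hypo")
  )
}

#' Rank CpGs by differential variability between cases and controls
#'
#' The central supervised scan: per CpG, an age-adjusted Bartlett test of
#' equal variances between cases and controls (variances estimated after
#' linear adjustment for age within each phenotype), together with a Welch
#' t-test of mean methylation differences for comparison. Storey q-values
#' are attached to both. The result is sorted by ascending Bartlett p
#' (ties broken by `cpg_id`), and each CpG is labelled `hypervariable`
#' (variance larger in cases) or `hypovariable`.
#'
#' Mean differences and t-statistics are computed on the unadjusted
#' beta-values; the within-phenotype adjustment leaves group means
#' unchanged, so only the variance-based test uses the adjusted matrix.
#'
#' @param beta Methylation matrix (CpGs x samples).
#' @param annotation Sample annotation tibble.
#' @param adjust_age Residualize on age within each phenotype first
#'   (default `TRUE`).
#' @param adjust_hpv Additionally residualize on HPV status (samples with
#'   unknown HPV form their own stratum).
#' @param scale Variance scale: `"beta"` (default) or `"r"`
#'   (R = beta/(1-beta), which mitigates the heteroscedasticity of
#'   beta-values).
#' @return A tibble of class `evorisk_dvc` with columns `cpg_id`,
#'   `var_ratio`, `b_stat`, `bartlett_stat`, `p_bartlett`, `q_bartlett`,
#'   `mean_diff`, `t_stat`, `p_t`, `q_t`, `direction`.
#' @export
rank_dvcs <- function(beta, annotation, adjust_age = TRUE, adjust_hpv = FALSE,
                      scale = c("beta", "r")) {
  scale <- match.arg(scale)
  annotation <- check_annotation_matches(beta, annotation)
  status <- annotation$status
  if (length(unique(status)) < 2) abort("both phenotypes (case and control) must be present")

  work <- if (scale == "r") beta / (1 - beta) else beta
  if (adjust_age) {
    work <- adjust_covariate(work, annotation$age, within = status)
  }
  if (adjust_hpv) {
    hpv <- factor(annotation$hpv)
    if (nlevels(hpv) > 1) {
      H <- stats::model.matrix(~hpv)[, -1, drop = FALSE]
      work <- adjust_covariate(work, H, within = status)
    }
  }

  case <- work[, status == "case", drop = FALSE]
  ctrl <- work[, status == "control", drop = FALSE]
  bt <- bartlett_rows(case, ctrl)
  tt <- welch_rows(
    beta[, status == "case", drop = FALSE],
    beta[, status == "control", drop = FALSE]
  )

  out <- tibble(
    cpg_id = rownames(beta),
    var_ratio = bt$var_ratio,
    b_stat = bt$b_stat,
    bartlett_stat = bt$stat,
    p_bartlett = bt$p,
    q_bartlett = estimate_qvalues(bt$p),
    mean_diff = tt$mean_diff,
    t_stat = tt$t,
    p_t = tt$p,
    q_t = estimate_qvalues(tt$p),
    direction = dplyr::case_when(
      is.na(bt$var_ratio) ~ NA_character_,
      bt$var_ratio > 1 ~ "hypervariable",
      TRUE ~ "hypovariable"
    )
  )
  out <- dplyr::arrange(out, .data$p_bartlett, .data$cpg_id)
  class(out) <- c("evorisk_dvc", class(out))
  out
}

#' Rank CpGs by age-independent variability across all samples
#'
#' Identifies vCpGs: CpGs with the largest variance across the whole
#' cohort after adjusting for age, regardless of phenotype. These capture
#' large phenotype-independent variation (e.g. cell-composition shifts)
#' and are distinct from DVCs.
#'
#' @inheritParams rank_dvcs
#' @return A tibble with `cpg_id`, `variance`, sorted by descending
#'   variance (ties broken by `cpg_id`).
#' @export
rank_vcpgs <- function(beta, annotation, scale = c("beta", "r")) {
  scale <- match.arg(scale)
  annotation <- check_annotation_matches(beta, annotation)
  work <- if (scale == "r") beta / (1 - beta) else beta
  work <- adjust_covariate(work, annotation$age)
  v <- row_n_mean_var(work)$var
  out <- tibble(cpg_id = rownames(beta), variance = v)
  dplyr::arrange(out, dplyr::desc(.data$variance), .data$cpg_id)
}
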