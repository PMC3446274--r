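#' One-tailed Fisher's exact enrichment of a CpG set in a category
#'
#' Tests whether `selected` is enriched for category members within
#' `universe` using the hypergeometric (one-tailed, greater) p-value. The
#' odds ratio is `(a*d)/(b*c)` on the 2x2 table; if any cell is zero the
#' Haldane-Anscombe 0.5 correction is applied (and noted), and the 95%
#' confidence interval uses the Woolf logit method on the (possibly
#' corrected) counts.
#'
#' @param selected Character vector of selected CpG IDs (subset of
#'   `universe`).
#' @param category Named logical vector over `universe` (or a character
#'   vector of member IDs) defining the gene-set/category membership.
#' @param universe Character vector: all CpGs under consideration.
#' @param set_name Label carried into the result.
#' @return A one-row tibble: `set_name`, counts `a` (selected & in
#'   category), `b`, `c`, `d`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_one_tailed`, `corrected` (whether the 0.5 correction was used).
#' @export
fisher_enrichment <- function(selected, category, universe, set_name = "set") {
  if (length(universe) == 0) abort("empty universe")
  if (length(selected) == 0) abort("empty selected set")
  if (!all(selected %in% universe)) abort("selected CpGs must be a subset of the universe")
  member <- category_membership(category, universe)

  in_sel <- universe %in% selected
  a <- sum(in_sel & member)
  b <- sum(in_sel & !member)
  c_ <- sum(!in_sel & member)
  d <- sum(!in_sel & !member)
  # P(X >= a) for X ~ Hypergeom(category size, non-category size, |selected|)
  p <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)

  corrected <- any(c(a, b, c_, d) == 0)
  aa <- a + 0.5 * corrected; bb <- b + 0.5 * corrected
  cc <- c_ + 0.5 * corrected; dd <- d + 0.5 * corrected
  or <- (aa * dd) / (bb * cc)
  se_log <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  tibble(
    set_name = set_name, a = a, b = b, c = c_, d = d,
    odds_ratio = or,
    ci_low = exp(log(or) - 1.959964 * se_log),
    ci_high = exp(log(or) + 1.959964 * se_log),
    p_one_tailed = p,
    corrected = corrected
  )
}

category_membership <- function(category, universe) {
  if (is.logical(category)) {
    if (!is.null(names(category))) {
      member <- unname(category[universe])
      member[is.na(member)] <- FALSE
    } else {
      stopifnot(length(category) == length(universe))
      member <- category
    }
  } else {
    member <- universe %in% as.character(category)
  }
  member
}

#' Relative odds ratio of enrichment in hyper- vs hypovariable CpGs
#'
#' Among the top `top_k` differentially variable CpGs, computes the odds
#' ratio of category enrichment separately for the hypervariable and
#' hypovariable subsets and reports their ratio
#' (ROR = OR_hypervariable / OR_hypovariable). Significance comes from a
#' permutation null: sample labels are permuted, the full
#' differential-variability ranking is recomputed, and the null ROR
#' recorded; the p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param beta Methylation matrix.
#' @param annotation Sample annotation tibble.
#' @param category Category membership (as in [fisher_enrichment()]) over
#'   the CpGs of `beta`.
#' @param top_k Number of top DVCs considered (default 500).
#' @param n_perm Number of label permutations (>= 10; default 50).
#' @param seed Integer seed.
#' @param ... Passed to [rank_dvcs()].
#' @return A list of class `evorisk_ror`: `ror_observed`, `ror_null`
#'   (length `n_perm`, `NA` where undefined), `p_perm`, `n_perm`.
#' @export
relative_odds_ratio <- function(beta, annotation, category, top_k = 500,
                                n_perm = 50, seed = 1, ...) {
  if (n_perm < 10) abort("n_perm must be at least 10")
  if (top_k > nrow(beta)) abort("top_k exceeds the number of CpGs")
  annotation <- check_annotation_matches(beta, annotation)
  universe <- rownames(beta)
  member <- category_membership(category, universe)
  names(member) <- universe

  obs <- ror_from_dvc(rank_dvcs(beta, annotation, ...), member, universe, top_k)
  seeds <- derive_seeds(seed, n_perm)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- annotation
    perm$status <- with_seed(seeds[i], sample(perm$status))
    ror_from_dvc(rank_dvcs(beta, perm, ...), member, universe, top_k)
  }, numeric(1))
  p_perm <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + n_perm)
  structure(
    list(ror_observed = obs, ror_null = null, p_perm = p_perm, n_perm = n_perm),
    class = "evorisk_ror"
  )
}

ror_from_dvc <- function(dvc, member, universe, top_k) {
  top <- utils::head(dvc, top_k)
  hyper <- top$cpg_id[!is.na(top$var_ratio) & top$var_ratio > 1]
  hypo <- top$cpg_id[!is.na(top$var_ratio) & top$var_ratio <= 1]
  if (length(hyper) == 0 || length(hypo) == 0) return(NA_real_)
  or_h <- fisher_enrichment(hyper, member, universe)$odds_ratio
  or_l <- fisher_enrichment(hypo, member, universe)$odds_ratio
  or_h / or_l
}

#' Exact binomial test of directional skew
#'
#' Tests whether `k` events out of `n` deviate from the null proportion
#' `p0` (default a symmetric 1/2, e.g. hyper- vs hypovariable direction
#' among category CpGs). The two-sided p doubles the smaller exact tail,
#' capped at 1.
#'
#' @param k Count in direction A.
#' @param n Total count (>= 1).
#' @param p0 Null success probability.
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`.
#' @return The p-value (numeric scalar).
#' @export
binomial_skew <- function(k, n, p0 = 0.5, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (n < 1) abort("n must be at least 1")
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  switch(tail,
    greater = upper,
    less = lower,
    two_sided = min(1, 2 * min(lower, upper))
  )
}

#' Read a two-column category file (TSV: id, set_name)
#'
#' @param path Path to the TSV (no header required; columns are the
#'   CpG/gene identifier and the set name).
#' @return A tibble with columns `id`, `set_name`.
#' @export
read_category_file <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("id", "set_name"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  df
}
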