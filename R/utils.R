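#' @useDynLib evorisk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad pchisq pt pnorm phyper pbinom dbinom p.adjust
#'   smooth.spline predict quantile rbeta runif rnorm rbinom var sd
NULL

# Deterministic child-seed fan-out: one user-facing seed drives every
# stochastic sub-step, and each sub-step gets its own reproducible stream.
# Seeds stay below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Stratified fold assignment: deterministic given seed, balanced per class.
stratified_folds <- function(status, folds, seed) {
  stopifnot(all(status %in% c("case", "control")))
  fold <- integer(length(status))
  with_seed(seed, {
    for (cls in c("case", "control")) {
      idx <- which(status == cls)
      if (length(idx) < folds) {
        abort(sprintf(
          "class '%s' has %d samples but %d folds requested; use fewer folds",
          cls, length(idx), folds
        ))
      }
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

# Stratified train/test split by class.
stratified_split <- function(status, train_fraction, seed) {
  train <- logical(length(status))
  with_seed(seed, {
    for (cls in unique(status)) {
      idx <- which(status == cls)
      n_train <- max(1L, round(train_fraction * length(idx)))
      train[sample(idx, n_train)] <- TRUE
    }
  })
  train
}

check_annotation_matches <- function(beta, annotation) {
  if (!all(colnames(beta) %in% annotation$sample_id)) {
    missing <- setdiff(colnames(beta), annotation$sample_id)
    abort(sprintf(
      "samples missing from annotation: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  annotation[match(colnames(beta), annotation$sample_id), , drop = FALSE]
}
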