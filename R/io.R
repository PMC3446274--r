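#' Read a beta-value methylation matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample IDs and whose
#' first column (`cpg_id`) holds CpG probe IDs; cells are beta-values in
#' `[0, 1]` or the literal `NA`. Values at the boundaries are clipped to
#' `[clip_epsilon, 1 - clip_epsilon]` so ratio/log scales stay finite.
#' Row and column order is preserved.
#'
#' @param path Path to the TSV file.
#' @param clip_epsilon Boundary clipping margin passed to [clip_beta()].
#' @return A numeric matrix (CpGs x samples) with `cpg_id` rownames and
#'   sample-ID colnames; missing cells are `NA`.
#' @export
read_beta_matrix <- function(path, clip_epsilon = 1e-6) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) abort("beta matrix needs a cpg_id column plus at least one sample")
  cpg_ids <- df[[1]]
  dup <- cpg_ids[duplicated(cpg_ids)]
  if (length(dup)) abort(sprintf("duplicated CpG ID(s): %s", paste(unique(dup), collapse = ", ")))
  sample_ids <- colnames(df)[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) abort(sprintf("duplicated sample ID(s): %s", paste(unique(dup), collapse = ", ")))

  cells <- as.matrix(df[-1])
  suppressWarnings(beta <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(beta) & !(is.na(cells) | cells == "NA"), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-numeric cell at row %d (CpG %s), column %d (sample %s)",
      bad[1, 1], cpg_ids[bad[1, 1]], bad[1, 2], sample_ids[bad[1, 2]]
    ))
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    idx <- which(beta < 0 | beta > 1, arr.ind = TRUE)
    abort(sprintf(
      "beta-value %g outside [0, 1] at CpG %s, sample %s",
      beta[idx[1, 1], idx[1, 2]], cpg_ids[idx[1, 1]], sample_ids[idx[1, 2]]
    ))
  }
  beta <- clip_beta(beta, clip_epsilon)
  dimnames(beta) <- list(cpg_ids, sample_ids)
  beta
}

#' Write a beta-value methylation matrix to TSV
#'
#' Inverse of [read_beta_matrix()]; full `NA` for missing cells.
#'
#' @param beta Numeric matrix with CpG rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- tibble::as_tibble(beta, rownames = "cpg_id")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Read a sample annotation table
#'
#' CSV with header `sample_id,status,age,hpv`. `status` must be `case` or
#' `control`; `hpv` may be `positive`, `negative`, or empty/`unknown`
#' (coded `unknown`).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `sample_id`, `status`, `age`, `hpv`.
#' @export
read_sample_annotation <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    status = readr::col_character(),
    age = readr::col_character(),
    hpv = readr::col_character()
  ), progress = FALSE)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) abort(sprintf("duplicated sample ID(s): %s", paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(df$status), c("case", "control"))
  if (length(bad) || anyNA(df$status)) {
    abort(sprintf(
      "status must be one of {case, control}; found: %s",
      paste(unique(c(bad, if (anyNA(df$status)) NA)), collapse = ", ")
    ))
  }
  suppressWarnings(age <- as.numeric(df$age))
  if (anyNA(age) || any(!is.finite(age)) || any(age < 0)) {
    abort("age must be a finite non-negative number for every sample")
  }
  hpv <- df$hpv
  hpv[is.na(hpv) | hpv == ""] <- "unknown"
  bad <- setdiff(unique(hpv), c("positive", "negative", "unknown"))
  if (length(bad)) abort(sprintf("hpv must be one of {positive, negative, unknown}; found: %s", paste(bad, collapse = ", ")))
  tibble(sample_id = df$sample_id, status = df$status, age = age, hpv = hpv)
}

#' Read a CpG annotation table
#'
#' CSV with header `cpg_id,entrez_id,gene_symbol,pcgt` (`pcgt` in `{0,1}`,
#' missing coded `FALSE`). `pcgt` flags membership of the polycomb-group
#' target gene class; any named gene set can be carried the same way.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `cpg_id`, `entrez_id`, `gene_symbol`, `pcgt`.
#' @export
read_cpg_annotation <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    cpg_id = readr::col_character(),
    entrez_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    pcgt = readr::col_double()
  ), progress = FALSE)
  dup <- df$cpg_id[duplicated(df$cpg_id)]
  if (length(dup)) abort(sprintf("duplicated CpG ID(s): %s", paste(unique(dup), collapse = ", ")))
  pcgt <- df$pcgt
  pcgt[is.na(pcgt)] <- 0
  if (!all(pcgt %in% c(0, 1))) abort("pcgt must be 0 or 1")
  tibble(
    cpg_id = df$cpg_id, entrez_id = df$entrez_id,
    gene_symbol = df$gene_symbol, pcgt = as.logical(pcgt)
  )
}

#' Drop CpGs with too many missing samples
#'
#' Remaining missing values are excluded pairwise from downstream
#' mean/variance estimates rather than imputed.
#'
#' @param beta Methylation matrix (CpGs x samples).
#' @param max_missing Maximum tolerated fraction of missing samples per CpG.
#' @return The filtered matrix.
#' @export
filter_missing_cpgs <- function(beta, max_missing = 0.2) {
  frac <- rowMeans(is.na(beta))
  beta[frac <= max_missing, , drop = FALSE]
}

#' Write a differential-variability table to TSV
#'
#' Column order is fixed: `cpg_id, entrez_id, gene_symbol, var_ratio,
#' b_stat, bartlett_stat, p_bartlett, q_bartlett, mean_diff, t_stat, p_t,
#' q_t, direction`. An empty table yields a header-only file.
#'
#' @param dvc A DVC tibble from [rank_dvcs()].
#' @param path Output path.
#' @param cpg_annotation Optional CpG annotation tibble supplying
#'   `entrez_id`/`gene_symbol`.
#' @return `path`, invisibly.
#' @export
write_dvc_table <- function(dvc, path, cpg_annotation = NULL) {
  cols <- c(
    "cpg_id", "entrez_id", "gene_symbol", "var_ratio", "b_stat",
    "bartlett_stat", "p_bartlett", "q_bartlett", "mean_diff", "t_stat",
    "p_t", "q_t", "direction"
  )
  out <- dvc
  if (!is.null(cpg_annotation)) {
    out <- dplyr::left_join(
      out, dplyr::select(cpg_annotation, "cpg_id", "entrez_id", "gene_symbol"),
      by = "cpg_id"
    )
  }
  for (col in setdiff(cols, names(out))) out[[col]] <- NA_character_
  readr::write_tsv(out[cols], path, na = "NA")
  invisible(path)
}

#' Write per-sample risk scores to TSV
#'
#' Columns: `sample_id, score, n_hits, n_cpgs_used, scale`.
#'
#' @param scores A score tibble from [score_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  cols <- c("sample_id", "score", "n_hits", "n_cpgs_used", "scale")
  readr::write_tsv(scores[cols], path, na = "NA")
  invisible(path)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Save or load a trained risk model as JSON
#'
#' The JSON carries the risk-CpG list, the frozen per-CpG COPA parameters
#' (training median and scaled MAD), the outlier threshold, the scoring
#' scale, and the training metadata (seed, folds, grids, FDR cutoffs).
#' A save/load round trip reproduces scores exactly.
#'
#' @param model An `evorisk_model` from [train_evora()].
#' @param path File path for the model JSON.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the reconstructed `evorisk_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "evorisk_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    risk_cpgs = model$risk_cpgs,
    copa_params = list(
      cpg_id = model$copa_params$cpg_id,
      median = model$copa_params$median,
      mad = model$copa_params$mad
    ),
    threshold = model$threshold,
    scale = model$scale,
    training_meta = model$training_meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema_version, MODEL_SCHEMA_VERSION)) {
    abort(sprintf(
      "model schema version mismatch: file has %s, package expects %s",
      payload$schema_version, MODEL_SCHEMA_VERSION
    ))
  }
  new_evorisk_model(
    risk_cpgs = payload$risk_cpgs,
    copa_params = tibble(
      cpg_id = payload$copa_params$cpg_id,
      median = payload$copa_params$median,
      mad = payload$copa_params$mad
    ),
    threshold = payload$threshold,
    scale = payload$scale,
    training_meta = payload$training_meta
  )
}
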