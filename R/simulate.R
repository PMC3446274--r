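#' Configuration for a synthetic methylation cohort
#'
#' Assembles (and validates) the parameters of the cohort generator. The
#' defaults emulate a prospective nested case-control methylation study:
#' 75 cases and 77 controls over 20,000 CpGs; 500 planted risk CpGs with
#' a low-methylation Beta(2, 18) baseline whose increased case variance
#' comes from 0.2-0.3 methylation gains in a 15% "outlier" subset of
#' cases; risk CpGs also drift upward with age (they are a subset of the
#' planted age CpGs by default, mirroring the observed overlap of
#' hypervariable and age-hypermethylated sites); additional
#' phenotype-independent vCpGs span a > 0.8 beta range. A
#' `cancer_bimodal` regime instead makes risk CpGs hemi- or fully
#' methylated in a majority of cases, the pattern seen in invasive
#' disease.
#'
#' @param n_cases,n_controls Group sizes (defaults 75 / 77).
#' @param n_cpgs Total CpGs (default 20000).
#' @param n_risk Planted risk CpGs (default 500).
#' @param n_age Planted age-hypermethylated CpGs (default 1000). When
#'   `risk_are_age = TRUE` (default) the risk CpGs are counted among
#'   these.
#' @param n_vcpg Planted large-variance phenotype-independent CpGs
#'   (default 200).
#' @param outlier_fraction Probability a given case sample is an outlier
#'   at a given risk CpG (default 0.15).
#' @param outlier_shift_range Uniform range of the beta-shift in outlier
#'   samples (default `c(0.2, 0.3)`).
#' @param age_range Sampled uniformly per subject (default `c(19, 55)`
#'   years).
#' @param age_slope_range Uniform range of the per-year beta slope of age
#'   CpGs (default `c(0.003, 0.007)`).
#' @param risk_shape Beta-distribution shape `c(a, b)` of the risk-CpG
#'   baseline (default `c(2, 18)`, mean 0.1).
#' @param background_precision `a + b` of non-risk baselines; per-CpG
#'   means are drawn uniformly in (0.05, 0.95) (default 20).
#' @param pcgt_fraction_of_risk Fraction of risk CpGs labelled polycomb
#'   targets (default 0.5).
#' @param pcgt_background_rate PCGT rate among non-risk CpGs (default
#'   0.05).
#' @param risk_are_age Risk CpGs are also age CpGs (default `TRUE`).
#' @param cancer_case_fraction In the `cancer_bimodal` regime, fraction
#'   of cases with methylated risk CpGs (default 0.7).
#' @param regime `"prospective"` (outlier contamination; default) or
#'   `"cancer_bimodal"`.
#' @param clip_epsilon Boundary clipping margin.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 75, n_controls = 77, n_cpgs = 20000,
                       n_risk = 500, n_age = 1000, n_vcpg = 200,
                       outlier_fraction = 0.15,
                       outlier_shift_range = c(0.2, 0.3),
                       age_range = c(19, 55),
                       age_slope_range = c(0.003, 0.007),
                       risk_shape = c(2, 18),
                       background_precision = 20,
                       pcgt_fraction_of_risk = 0.5,
                       pcgt_background_rate = 0.05,
                       risk_are_age = TRUE,
                       cancer_case_fraction = 0.7,
                       regime = c("prospective", "cancer_bimodal"),
                       clip_epsilon = 1e-6,
                       seed = 1) {
  regime <- match.arg(regime)
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls, n_cpgs = n_cpgs,
    n_risk = n_risk, n_age = n_age, n_vcpg = n_vcpg,
    outlier_fraction = outlier_fraction,
    outlier_shift_range = outlier_shift_range,
    age_range = age_range, age_slope_range = age_slope_range,
    risk_shape = risk_shape, background_precision = background_precision,
    pcgt_fraction_of_risk = pcgt_fraction_of_risk,
    pcgt_background_rate = pcgt_background_rate,
    risk_are_age = risk_are_age,
    cancer_case_fraction = cancer_case_fraction,
    regime = regime, clip_epsilon = clip_epsilon, seed = seed
  )
  stopifnot(
    n_cases >= 0, n_controls >= 0, n_cpgs > 0,
    n_risk >= 0, n_age >= 0, n_vcpg >= 0
  )
  n_age_extra <- if (risk_are_age) max(0, n_age - n_risk) else n_age
  if (n_risk + n_age_extra + n_vcpg > n_cpgs) {
    abort("planted CpG counts exceed n_cpgs")
  }
  if (outlier_fraction <= 0 || outlier_fraction >= 1) {
    abort("outlier_fraction must lie strictly in (0, 1)")
  }
  # a baseline near the Beta mean plus the maximal age drift and shift must
  # stay below 1 (the generator clips, but a systematically infeasible shift
  # is a configuration error)
  base_mean <- risk_shape[1] / sum(risk_shape)
  drift <- max(age_slope_range) * diff(age_range)
  if (base_mean + drift + max(outlier_shift_range) >= 1.2) {
    abort("outlier_shift_range infeasible: baseline + age drift + shift far exceeds 1")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a methylation cohort with planted ground truth
#'
#' Generates beta-values as per-CpG Beta-distributed baselines, adds an
#' age-hypermethylation trend at age CpGs, plants outlier methylation
#' gains at risk CpGs in a random subset of case samples (prospective
#' regime) or hemi-/full methylation in a majority of cases
#' (cancer-bimodal regime), and gives vCpGs large phenotype-independent
#' spread. Everything the generator decides — which CpGs carry signal,
#' which samples are hit and by how much — is recorded in the returned
#' truth object.
#'
#' @param config A [sim_config()] (or arguments for one via `...`).
#' @param ... Convenience: passed to [sim_config()] when `config` is
#'   missing.
#' @return A list with `beta` (matrix, CpGs x samples), `annotation`
#'   (sample tibble), `cpg_annotation` (CpG tibble with `pcgt`), and
#'   `truth` (class `sim_truth`: per-CpG flags and slopes, per-hit
#'   records, config).
#' @export
simulate_cohort <- function(config = sim_config(...), ...) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_cases + cfg$n_controls
  status <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  sample_ids <- sprintf("s%03d", seq_len(n))
  cpg_ids <- sprintf("cg%06d", seq_len(cfg$n_cpgs))

  seeds <- derive_seeds(cfg$seed, 6)

  # planted CpG identities
  n_age_extra <- if (cfg$risk_are_age) max(0, cfg$n_age - cfg$n_risk) else cfg$n_age
  planted <- with_seed(seeds[1], {
    idx <- sample.int(cfg$n_cpgs, cfg$n_risk + n_age_extra + cfg$n_vcpg)
    risk <- idx[seq_len(cfg$n_risk)]
    age_extra <- idx[cfg$n_risk + seq_len(n_age_extra)]
    vcpg <- idx[cfg$n_risk + n_age_extra + seq_len(cfg$n_vcpg)]
    list(risk = risk, age = if (cfg$risk_are_age) c(risk, age_extra) else age_extra, vcpg = vcpg)
  })
  is_risk <- seq_len(cfg$n_cpgs) %in% planted$risk
  is_age <- seq_len(cfg$n_cpgs) %in% planted$age
  is_vcpg <- seq_len(cfg$n_cpgs) %in% planted$vcpg

  ages <- with_seed(seeds[2], runif(n, cfg$age_range[1], cfg$age_range[2]))

  beta <- with_seed(seeds[3], {
    mu <- runif(cfg$n_cpgs, 0.05, 0.95)
    a <- mu * cfg$background_precision
    b <- (1 - mu) * cfg$background_precision
    a[is_risk] <- cfg$risk_shape[1]
    b[is_risk] <- cfg$risk_shape[2]
    matrix(
      rbeta(cfg$n_cpgs * n, rep(a, n), rep(b, n)),
      nrow = cfg$n_cpgs, ncol = n
    )
  })

  slopes <- rep(0, cfg$n_cpgs)
  slopes[is_age] <- with_seed(
    seeds[4],
    runif(sum(is_age), cfg$age_slope_range[1], cfg$age_slope_range[2])
  )
  if (any(is_age)) {
    beta[is_age, ] <- beta[is_age, , drop = FALSE] +
      outer(slopes[is_age], ages - cfg$age_range[1])
  }

  hits <- tibble(cpg_id = character(0), sample_id = character(0), shift = numeric(0))
  case_idx <- which(status == "case")
  if (cfg$n_risk > 0 && length(case_idx) > 0) {
    if (cfg$regime == "prospective") {
      hit_data <- with_seed(seeds[5], {
        hit <- matrix(
          rbinom(cfg$n_risk * length(case_idx), 1, cfg$outlier_fraction) == 1,
          nrow = cfg$n_risk
        )
        shift <- matrix(
          runif(cfg$n_risk * length(case_idx), cfg$outlier_shift_range[1],
                cfg$outlier_shift_range[2]),
          nrow = cfg$n_risk
        )
        list(hit = hit, shift = shift)
      })
      add <- hit_data$hit * hit_data$shift
      beta[planted$risk, case_idx] <- beta[planted$risk, case_idx, drop = FALSE] + add
      w <- which(hit_data$hit, arr.ind = TRUE)
      hits <- tibble(
        cpg_id = cpg_ids[planted$risk][w[, 1]],
        sample_id = sample_ids[case_idx][w[, 2]],
        shift = hit_data$shift[w]
      )
    } else {
      # cancer-bimodal: most cases hemi- (beta ~ 0.5) or fully (~ 0.9)
      # methylated at risk CpGs
      hit_data <- with_seed(seeds[5], {
        hit <- matrix(
          rbinom(cfg$n_risk * length(case_idx), 1, cfg$cancer_case_fraction) == 1,
          nrow = cfg$n_risk
        )
        level <- matrix(
          ifelse(runif(cfg$n_risk * length(case_idx)) < 0.5, 0.5, 0.9),
          nrow = cfg$n_risk
        )
        noise <- matrix(
          rnorm(cfg$n_risk * length(case_idx), 0, 0.03),
          nrow = cfg$n_risk
        )
        list(hit = hit, level = level + noise)
      })
      block <- beta[planted$risk, case_idx, drop = FALSE]
      block[hit_data$hit] <- hit_data$level[hit_data$hit]
      beta[planted$risk, case_idx] <- block
      w <- which(hit_data$hit, arr.ind = TRUE)
      hits <- tibble(
        cpg_id = cpg_ids[planted$risk][w[, 1]],
        sample_id = sample_ids[case_idx][w[, 2]],
        shift = hit_data$level[w]
      )
    }
  }

  if (cfg$n_vcpg > 0) {
    # phenotype-independent large-spread variation: > 0.8 beta range
    beta[planted$vcpg, ] <- with_seed(
      seeds[6],
      matrix(runif(cfg$n_vcpg * n, 0.05, 0.95), nrow = cfg$n_vcpg)
    )
  }

  # shifts and drifts may overshoot the unit interval; methylation
  # fractions saturate there, then the boundary clip keeps ratios finite
  beta <- pmin(pmax(beta, 0), 1)
  beta <- clip_beta(beta, cfg$clip_epsilon)
  dimnames(beta) <- list(cpg_ids, sample_ids)

  is_pcgt <- with_seed(seeds[1] + 1L, {
    p <- logical(cfg$n_cpgs)
    nr <- round(cfg$pcgt_fraction_of_risk * cfg$n_risk)
    if (nr > 0) p[sample(planted$risk, nr)] <- TRUE
    bg <- which(!is_risk)
    p[sample(bg, round(cfg$pcgt_background_rate * length(bg)))] <- TRUE
    p
  })

  annotation <- tibble(
    sample_id = sample_ids, status = status, age = ages,
    hpv = "unknown"
  )
  cpg_annotation <- tibble(
    cpg_id = cpg_ids,
    entrez_id = NA_character_,
    gene_symbol = NA_character_,
    pcgt = is_pcgt
  )
  truth <- structure(
    list(
      cpg = tibble(
        cpg_id = cpg_ids, is_risk = is_risk, is_age = is_age,
        is_vcpg = is_vcpg, is_pcgt = is_pcgt, age_slope = slopes
      ),
      hits = hits,
      config = cfg
    ),
    class = "sim_truth"
  )
  list(beta = beta, annotation = annotation, cpg_annotation = cpg_annotation, truth = truth)
}

#' Precision and recall of planted risk-CpG recovery
#'
#' @param selected Character vector of selected CpG IDs.
#' @param truth A `sim_truth` from [simulate_cohort()].
#' @return A one-row tibble: `n_selected`, `n_true`, `tp`, `precision`
#'   (`NA` when nothing selected), `recall`.
#' @export
truth_metrics <- function(selected, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!all(selected %in% truth$cpg$cpg_id)) {
    abort("selected CpGs outside the simulated universe")
  }
  true_set <- truth$cpg$cpg_id[truth$cpg$is_risk]
  tp <- sum(selected %in% true_set)
  tibble(
    n_selected = length(selected),
    n_true = length(true_set),
    tp = tp,
    precision = if (length(selected) == 0) NA_real_ else tp / length(selected),
    recall = if (length(true_set) == 0) NA_real_ else tp / length(true_set)
  )
}

#' Write a simulated cohort to the standard input files
#'
#' Writes `beta.tsv`, `samples.csv`, `cpgs.csv` and `truth.json` into
#' `dir`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(sim$beta, file.path(dir, "beta.tsv"))
  readr::write_csv(sim$annotation, file.path(dir, "samples.csv"))
  readr::write_csv(
    dplyr::mutate(sim$cpg_annotation, pcgt = as.integer(.data$pcgt)),
    file.path(dir, "cpgs.csv")
  )
  jsonlite::write_json(
    list(
      cpg = sim$truth$cpg, hits = sim$truth$hits,
      config = unclass(sim$truth$config)
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
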