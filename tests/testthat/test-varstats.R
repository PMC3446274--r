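test_that("two-group Bartlett matches the textbook oracle and base R", {
  r <- bartlett_two_group(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)
  expect_equal(r$var_ratio, 1)
  expect_equal(r$b_stat, 0)

  x <- c(0.10, 0.20, 0.30, 0.40, 0.50)
  y <- c(0.05, 0.05, 0.06, 0.06)
  r <- bartlett_two_group(x, y)
  o <- bartlett_oracle(x, y)
  expect_equal(r$stat, o$stat, tolerance = 1e-10)
  expect_equal(r$p, o$p, tolerance = 1e-10)
  b <- stats::bartlett.test(list(x, y))
  expect_equal(r$stat, unname(b$statistic), tolerance = 1e-10)
  expect_equal(r$p, b$p.value, tolerance = 1e-10)

  # group exchange inverts the ratio and flips the b-statistic only
  rs <- bartlett_two_group(y, x)
  expect_equal(rs$stat, r$stat)
  expect_equal(rs$p, r$p)
  expect_equal(rs$var_ratio, 1 / r$var_ratio)
  expect_equal(rs$b_stat, -r$b_stat)

  expect_error(bartlett_two_group(c(1), c(1, 2)), "at least 2")
})

test_that("Bartlett agrees with base R on many random instances", {
  set.seed(10)
  for (i in 1:200) {
    n1 <- sample(3:40, 1)
    n2 <- sample(3:40, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 3))
    y <- rnorm(n2, sd = runif(1, 0.5, 3))
    r <- bartlett_two_group(x, y)
    b <- stats::bartlett.test(list(x, y))
    expect_equal(r$stat, unname(b$statistic), tolerance = 1e-10)
    expect_equal(r$p, b$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t-test matches base R and is antisymmetric", {
  x <- c(1, 2, 3, 4)
  r <- ttest_two_group(x, x)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p, 1)

  set.seed(11)
  y <- rnorm(20)
  x <- y + 0.5
  r <- ttest_two_group(x, y)
  expect_equal(r$mean_diff, 0.5, tolerance = 1e-12)
  tt <- stats::t.test(x, y)
  expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)

  rs <- ttest_two_group(y, x)
  expect_equal(rs$t_stat, -r$t_stat)
  expect_equal(rs$p, r$p)
})

test_that("covariate adjustment is an OLS residualization with mean restored", {
  set.seed(12)
  n <- 60
  age <- runif(n, 20, 60)
  # orthogonal covariate: residuals = centered values + mean = values
  x <- rnorm(n)
  x_orth <- x - sum(x * (age - mean(age))) / sum((age - mean(age))^2) * (age - mean(age))
  beta <- rbind(cg1 = x_orth, cg2 = 0.2 + 0.004 * age)
  colnames(beta) <- paste0("s", 1:n)
  adj <- adjust_covariate(beta, age)
  expect_equal(unname(adj["cg1", ]), x_orth, tolerance = 1e-10)
  # exactly linear CpG collapses to (numerically) zero residual variance
  expect_lt(var(adj["cg2", ]), 1e-20)

  # residual variance never exceeds raw variance
  Y <- matrix(rnorm(500 * n), ncol = n, dimnames = list(paste0("r", 1:500), colnames(beta)))
  A <- adjust_covariate(Y, age)
  expect_true(all(apply(A, 1, var) <= apply(Y, 1, var) + 1e-12))

  expect_error(adjust_covariate(beta, age, within = c("g1", rep("g2", n - 1))), "g1")
})

test_that("age association recovers a planted slope and is null-calibrated", {
  set.seed(13)
  n <- 150
  ages <- runif(n, 19, 55)
  annot <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    status = rep(c("case", "control"), length.out = n),
    age = ages, hpv = "unknown"
  )
  beta <- matrix(rnorm(400 * n, 0.3, 0.05), nrow = 400)
  rownames(beta) <- paste0("cg", 1:400)
  colnames(beta) <- annot$sample_id
  beta[1, ] <- 0.2 + 0.005 * ages + rnorm(n, 0, 0.01)
  beta[2, ] <- 0.25 # constant CpG

  res <- age_association(beta, annot)
  expect_equal(res$cpg_id, rownames(beta))
  r1 <- res[res$cpg_id == "cg1", ]
  expect_gt(r1$slope, 0.004)
  expect_lt(r1$slope, 0.006)
  expect_lt(r1$p_age, 1e-6)
  expect_equal(r1$direction, "hyper")
  r2 <- res[res$cpg_id == "cg2", ]
  expect_equal(r2$slope, 0)
  expect_true(is.na(r2$p_age))

  # permuted ages: null CpGs reject at ~ the nominal rate
  annot_perm <- annot
  set.seed(14)
  annot_perm$age <- sample(annot$age)
  res_p <- age_association(beta[3:400, ], annot_perm)
  frac <- mean(res_p$p_age < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 398) + 0.01)

  annot$age <- rep(30, n)
  expect_error(age_association(beta, annot), "constant")
})

test_that("age-association slopes match per-CpG lm() fits", {
  cohort <- small_cohort(seed = 21, n_cpgs = 50, n_risk = 5, n_age = 10, n_vcpg = 2)
  res <- age_association(cohort$beta, cohort$annotation, adjust_for_status = TRUE)
  for (i in c(1, 17, 42)) {
    fit <- summary(stats::lm(
      cohort$beta[i, ] ~ cohort$annotation$age + I(cohort$annotation$status == "case")
    ))
    row <- res[res$cpg_id == rownames(cohort$beta)[i], ]
    expect_equal(row$slope, fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(row$p_age, fit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("DVC ranking recovers planted hypervariable CpGs", {
  cohort <- small_cohort(seed = 7, n_cpgs = 3000, n_risk = 100, n_age = 200, n_vcpg = 50)
  dvc <- rank_dvcs(cohort$beta, cohort$annotation)
  risk_ids <- cohort$truth$cpg$cpg_id[cohort$truth$cpg$is_risk]
  top <- head(dvc$cpg_id, 100)
  expect_gt(mean(top %in% risk_ids), 0.8)
  # planted CpGs are labelled hypervariable (case variance exceeds control)
  planted <- dvc[dvc$cpg_id %in% risk_ids, ]
  expect_gt(mean(planted$direction == "hypervariable"), 0.9)
  # sorted ascending by Bartlett p
  expect_true(!is.unsorted(dvc$p_bartlett, na.rm = TRUE))
})

test_that("DVC p-values are uniform once labels are permuted", {
  cohort <- small_cohort(seed = 8, n_cpgs = 2000, n_risk = 50, n_age = 100, n_vcpg = 20)
  annot <- cohort$annotation
  set.seed(15)
  annot$status <- sample(annot$status)
  dvc <- rank_dvcs(cohort$beta, annot)
  ks <- suppressWarnings(stats::ks.test(dvc$p_bartlett, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("HPV adjustment barely moves the ranking when HPV carries no signal", {
  cohort <- small_cohort(seed = 9, n_cpgs = 2000, n_risk = 80, n_age = 160, n_vcpg = 20)
  annot <- cohort$annotation
  set.seed(16)
  annot$hpv <- sample(c("positive", "negative"), nrow(annot), replace = TRUE)
  top_plain <- head(rank_dvcs(cohort$beta, annot)$cpg_id, 500)
  top_hpv <- head(rank_dvcs(cohort$beta, annot, adjust_hpv = TRUE)$cpg_id, 500)
  expect_lt(mean(!top_plain %in% top_hpv), 0.05)
})

test_that("vCpG ranking puts planted high-variance CpGs on top, apart from DVCs", {
  cohort <- small_cohort(seed = 10, n_cpgs = 2000, n_risk = 60, n_age = 120, n_vcpg = 40)
  v <- rank_vcpgs(cohort$beta, cohort$annotation)
  vcpg_ids <- cohort$truth$cpg$cpg_id[cohort$truth$cpg$is_vcpg]
  expect_gt(mean(head(v$cpg_id, 40) %in% vcpg_ids), 0.9)
  # near non-overlap with the DVC ranking
  dvc_top <- head(rank_dvcs(cohort$beta, cohort$annotation)$cpg_id, 60)
  expect_lt(mean(head(v$cpg_id, 60) %in% dvc_top), 0.05)
})

test_that("constant matrix yields zero variances in stable cpg order", {
  beta <- matrix(0.5, nrow = 5, ncol = 12,
    dimnames = list(paste0("cg", 5:1), paste0("s", 1:12))
  )
  annot <- tibble::tibble(
    sample_id = paste0("s", 1:12), status = rep(c("case", "control"), 6),
    age = seq(20, 53, 3), hpv = "unknown"
  )
  v <- rank_vcpgs(beta, annot)
  expect_true(all(v$variance == 0))
  expect_equal(v$cpg_id, sort(paste0("cg", 1:5)))
})
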