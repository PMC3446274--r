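test_that("the generator is deterministic and structurally consistent", {
  cfg <- sim_config(n_cpgs = 500, n_risk = 20, n_age = 40, n_vcpg = 10, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth$cpg, s2$truth$cpg)

  expect_equal(dim(s1$beta), c(500L, 152L))
  expect_true(all(s1$beta > 0 & s1$beta < 1))
  expect_equal(sum(s1$truth$cpg$is_risk), 20)
  expect_equal(sum(s1$truth$cpg$is_age), 40)
  expect_equal(sum(s1$truth$cpg$is_vcpg), 10)
  # risk CpGs are a subset of age CpGs by default (the planted overlap)
  expect_true(all(s1$truth$cpg$is_age[s1$truth$cpg$is_risk]))
  # every recorded hit is a case sample at a risk CpG
  expect_true(all(s1$truth$hits$sample_id %in%
    s1$annotation$sample_id[s1$annotation$status == "case"]))
  expect_true(all(s1$truth$hits$cpg_id %in%
    s1$truth$cpg$cpg_id[s1$truth$cpg$is_risk]))
})

test_that("signal-free cohorts are exchangeable between phenotypes", {
  sim <- simulate_cohort(sim_config(
    n_cpgs = 2000, n_risk = 0, n_age = 0, n_vcpg = 0, seed = 6
  ))
  dvc <- rank_dvcs(sim$beta, sim$annotation)
  expect_gt(suppressWarnings(stats::ks.test(dvc$p_bartlett, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(dvc$p_t, "punif"))$p.value, 0.01)
})

test_that("outlier contamination creates case hypervariability with a small mean shift", {
  sim <- simulate_cohort(sim_config(n_cpgs = 3000, n_risk = 200, n_age = 400, n_vcpg = 0, seed = 8))
  risk <- sim$truth$cpg$is_risk
  case <- sim$annotation$status == "case"
  v_case <- apply(sim$beta[risk, case], 1, var)
  v_ctrl <- apply(sim$beta[risk, !case], 1, var)
  expect_gt(mean(v_case / v_ctrl > 1), 0.95)
  # mean difference ~ outlier_fraction x mean shift = 0.15 x 0.25
  md <- rowMeans(sim$beta[risk, case]) - rowMeans(sim$beta[risk, !case])
  expect_lt(abs(mean(md) - 0.15 * 0.25), 0.01)
  # control-side baseline mean tracks the Beta(2, 18) mean plus age drift
  ctrl_base <- mean(rowMeans(sim$beta[risk, !case]))
  drift <- mean(sim$truth$cpg$age_slope[risk]) *
    mean(sim$annotation$age[!case] - 19)
  expect_equal(ctrl_base, 0.1 + drift, tolerance = 0.02)
})

test_that("planted vCpGs span a large beta range independent of phenotype", {
  sim <- simulate_cohort(sim_config(n_cpgs = 1000, n_risk = 0, n_age = 0, n_vcpg = 50, seed = 9))
  v <- sim$truth$cpg$is_vcpg
  rng <- apply(sim$beta[v, ], 1, function(x) diff(range(x)))
  expect_gt(mean(rng > 0.8), 0.9)
  tt <- welch_p <- apply(sim$beta[v, ], 1, function(x) {
    stats::t.test(x[sim$annotation$status == "case"], x[sim$annotation$status == "control"])$p.value
  })
  expect_gt(mean(welch_p > 0.05), 0.9)
})

test_that("the cancer-bimodal regime methylates risk CpGs in most cases", {
  sim <- simulate_cohort(sim_config(
    n_cpgs = 800, n_risk = 60, n_age = 120, n_vcpg = 0,
    regime = "cancer_bimodal", seed = 10
  ))
  risk <- sim$truth$cpg$is_risk
  case <- sim$annotation$status == "case"
  frac_meth <- mean(sim$beta[risk, case] > 0.35)
  expect_gt(frac_meth, 0.6)
  expect_lt(mean(sim$beta[risk, !case] > 0.35), 0.2)
})

test_that("the bimodal regime compresses the COPA basis, favouring beta-scale scoring", {
  cfg <- list(n_cpgs = 2000, n_risk = 80, n_age = 160, n_vcpg = 20, seed = 55)
  prospective <- simulate_cohort(do.call(sim_config, cfg))
  cancer <- simulate_cohort(do.call(sim_config, c(cfg, regime = "cancer_bimodal")))
  risk <- cancer$truth$cpg$cpg_id[cancer$truth$cpg$is_risk]
  case <- cancer$annotation$status == "case"

  # when most cases are methylated, the MAD inflates and outlier scores
  # shrink relative to an outlier-regime basis at the same CpGs
  s_bimodal <- copa_transform(cancer$beta[risk, case], copa_fit(cancer$beta[risk, ]))
  s_outlier <- copa_transform(cancer$beta[risk, case], copa_fit(prospective$beta[risk, ]))
  expect_lt(
    median(s_bimodal, na.rm = TRUE),
    0.6 * median(s_outlier, na.rm = TRUE)
  )

  # scoring the cancer-like cohort on the beta scale is at least as
  # discriminative as the COPA scale
  model <- train_evora(prospective$beta, prospective$annotation, folds = 5, seed = 3)
  auc_copa <- roc_auc(
    score_samples(model, cancer$beta)$score, cancer$annotation$status,
    n_boot = 0
  )$auc
  auc_beta <- roc_auc(
    score_samples_beta(model, cancer$beta)$score, cancer$annotation$status,
    n_boot = 0
  )$auc
  expect_gte(auc_beta, auc_copa)
  expect_gt(auc_beta, 0.9)
})

test_that("truth metrics are exact set overlaps", {
  sim <- simulate_cohort(sim_config(n_cpgs = 300, n_risk = 30, n_age = 60, n_vcpg = 5, seed = 11))
  risk_ids <- sim$truth$cpg$cpg_id[sim$truth$cpg$is_risk]
  tm <- truth_metrics(risk_ids, sim$truth)
  expect_equal(tm$precision, 1)
  expect_equal(tm$recall, 1)
  tm0 <- truth_metrics(setdiff(sim$truth$cpg$cpg_id, risk_ids), sim$truth)
  expect_equal(tm0$precision, 0)
  tm_empty <- truth_metrics(character(0), sim$truth)
  expect_true(is.na(tm_empty$precision))
  expect_equal(tm_empty$recall, 0)
  # random draws: expected precision = n_risk / n_cpgs
  set.seed(12)
  prec <- replicate(200, {
    truth_metrics(sample(sim$truth$cpg$cpg_id, 50), sim$truth)$precision
  })
  expect_lt(abs(mean(prec) - 30 / 300), 3 * sd(prec) / sqrt(200) + 0.01)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(n_cpgs = 50, n_risk = 40, n_age = 40, n_vcpg = 20), "exceed")
  expect_error(sim_config(outlier_fraction = 0), "outlier_fraction")
  expect_error(
    sim_config(risk_shape = c(18, 2), outlier_shift_range = c(0.5, 0.6)),
    "infeasible"
  )
})
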