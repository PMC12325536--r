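test_that("stratification partitions the cohort on maternal smoking", {
  coh <- generateCohort(simParams(n_pairs = 5000, seed = 61))
  st <- stratifyCohort(coh)
  expect_identical(ncol(st$exposed) + ncol(st$unexposed) + st$n_dropped,
                   ncol(coh))
  expect_equal(ncol(st$exposed) / ncol(coh), 0.306, tolerance = 0.02)
  # missing smoking status is dropped and counted
  coh2 <- coh
  SummarizedExperiment::colData(coh2)$maternal_smoked[1:7] <- NA
  SummarizedExperiment::colData(coh2)$cigs_per_day[1:7] <- NA
  st2 <- stratifyCohort(coh2)
  expect_identical(st2$n_dropped, 7L)
  expect_identical(ncol(st2$exposed) + ncol(st2$unexposed), ncol(coh) - 7L)
  # all mothers smoked -> empty unexposed stratum
  coh3 <- coh[, phenotypes(coh)$maternal_smoked == 1]
  expect_identical(ncol(stratifyCohort(coh3)$unexposed), 0L)
})

test_that("genetic association matches the grid-search MLE on a fixture", {
  y <- c(0, 1, 0, 1, 1, 0, 1, 0)
  g <- c(0, 2, 1, 2, 1, 0, 1, 2)
  coh <- generateCohort(simParams(n_pairs = 8, seed = 62))
  SummarizedExperiment::colData(coh)$left_handed <- y
  a <- geneticAssociation(coh, g, outcome = "left_handed",
                          family = "logistic")
  oracle <- logisticGridMLE(y, matrix(g))
  expect_equal(a@beta, oracle[2], tolerance = 5e-4, ignore_attr = TRUE)
  # permuted outcome: null association at scale
  coh2 <- generateCohort(simParams(n_pairs = 20000, seed = 63))
  set.seed(64)
  SummarizedExperiment::colData(coh2)$left_handed <-
    sample(phenotypes(coh2)$left_handed)
  a2 <- geneticAssociation(coh2, "snp1")
  expect_lt(abs(a2@beta) / a2@se, 4)
})

test_that("the Wald ratio and its delta-method SE follow the formulas", {
  w <- waldRatio(0.02, 0.01, 0.4, 0.05)
  expect_equal(w@beta_iv, 0.05)
  # independently evaluated: sqrt(0.0001/0.16 + 0.0004*0.0025/0.0256)
  expect_equal(w@se_iv, sqrt(0.01^2 / 0.4^2 + 0.02^2 * 0.05^2 / 0.4^4),
               tolerance = 1e-12)
  expect_equal(w@se_iv, 0.02577, tolerance = 1e-3)
  expect_equal(w@ci_low, w@beta_iv - qnorm(0.975) * w@se_iv)
  # beta_gy = 0 limit
  w0 <- waldRatio(0, 0.01, 0.4, 0.05)
  expect_identical(w0@beta_iv, 0)
  expect_equal(w0@se_iv, 0.01 / 0.4)
  # allele recoding flips both betas, leaving the ratio unchanged
  wf <- waldRatio(-0.02, 0.01, -0.4, 0.05)
  expect_equal(wf@beta_iv, w@beta_iv)
  expect_equal(wf@se_iv, w@se_iv)
  # guards
  expect_error(waldRatio(0.1, 0.1, 0, 0.1), "zero")
  expect_warning(waldRatio(0.1, 0.1, 0.2, 0.1), "weak instrument")
})

test_that("pleiotropy correction subtracts the no-relevance stratum", {
  mk <- function(b, se, stratum, inst = "snp") {
    new("WaldEstimate", beta_iv = b, se_iv = se,
        ci_low = b - qnorm(0.975) * se, ci_high = b + qnorm(0.975) * se,
        stratum = stratum, instrument = inst)
  }
  # identical strata cancel exactly
  z <- pleiotropyCorrect(mk(0.3, 0.1, "exposed"), mk(0.3, 0.2, "unexposed"))
  expect_identical(z@beta_corrected, 0)
  expect_equal(z@se, sqrt(0.1^2 + 0.2^2))
  # mismatched instruments are structural errors
  expect_error(pleiotropyCorrect(mk(0.1, 0.1, "exposed", "a"),
                                 mk(0.1, 0.1, "unexposed", "b")),
               "different instruments")
})

test_that("pleiotropy-only worlds bias both strata but not the correction", {
  # nonzero pleiotropy, zero causal effect: the variant associates with
  # handedness in BOTH strata (the no-relevance group reveals the bias)
  p <- simParams(n_pairs = 60000, snp_weights = 3.5, pleiotropy_beta = 0.2,
                 seed = 65)
  coh <- generateCohort(p)
  fit <- suppressWarnings(proxyMR(coh, "snp1"))
  z_exp <- fit$associations$exposed@beta / fit$associations$exposed@se
  z_une <- fit$associations$unexposed@beta / fit$associations$unexposed@se
  expect_gt(z_exp, 3)
  expect_gt(z_une, 3)
  # corrected estimate is consistent with zero
  expect_lt(abs(fit$corrected@beta_corrected) / fit$corrected@se, 3)
})

test_that("the exposed-stratum Wald estimate recovers the causal effect", {
  # strong instrument, causal path only; mean estimate over replicates
  # approaches the true per-cigarette log-odds
  truth <- 0.03
  ests <- vapply(1:60, function(r) {
    p <- simParams(n_pairs = 12000, snp_weights = 3.5, causal_beta = truth,
                   seed = 6500 + r)
    fit <- suppressWarnings(proxyMR(generateCohort(p), "snp1"))
    c(fit$wald$exposed@beta_iv, fit$wald$exposed@se_iv)
  }, numeric(2))
  sem <- sd(ests[1, ]) / sqrt(ncol(ests))
  expect_lt(abs(mean(ests[1, ]) - truth), 3 * sem + 0.002)
  # delta-method SE agrees with the replicate spread
  expect_equal(mean(ests[2, ]), sd(ests[1, ]), tolerance = 0.25)
})

test_that("control checks show the birthweight signature and clean negatives", {
  p <- simParams(n_pairs = 60000, snp_weights = 3.5, bw_theta = -0.03,
                 seed = 67)
  coh <- generateCohort(p)
  ctl <- controlChecks(coh, "snp1")
  bw <- ctl[ctl$control == "birthweight_kg", ]
  # negative dosage-birthweight association only where mothers smoked
  expect_lt(bw$beta[bw$stratum == "exposed"] /
              bw$se[bw$stratum == "exposed"], -3)
  expect_lt(abs(bw$beta[bw$stratum == "unexposed"]) /
              bw$se[bw$stratum == "unexposed"], 3.5)
  # genotype-independent covariates: null in both strata
  neg <- ctl[ctl$control %in% c("sex", "breastfed", "townsend"), ]
  expect_true(all(abs(neg$beta / neg$se) < 4))
})

test_that("proxy attenuation leaves the Wald ratio consistent", {
  # numerator and denominator attenuate by the same transmission factor, so
  # swapping maternal for offspring dosage must not move the ratio (large n)
  p <- simParams(n_pairs = 150000, snp_weights = 3.5, causal_beta = 0.025,
                 seed = 68)
  coh <- generateCohort(p)
  ph <- phenotypes(coh)
  off <- as.numeric(offspringDosage(coh)[1, ])
  mat <- as.numeric(maternalDosage(coh)[1, ])
  sm <- ph$maternal_smoked == 1
  wald_for <- function(g) {
    num <- glm(ph$left_handed[sm] ~ g[sm], family = binomial())
    den <- lm(ph$cigs_per_day[sm] ~ g[sm])
    coef(num)[2] / coef(den)[2]
  }
  w_off <- wald_for(off)
  w_mat <- wald_for(mat)
  expect_lt(abs(w_off - w_mat), 0.04)
  # but the offspring instrument explains ~1/4 the exposure variance
  r_off <- as.numeric(varianceExplained(off[sm], ph$cigs_per_day[sm]))
  r_mat <- as.numeric(varianceExplained(mat[sm], ph$cigs_per_day[sm]))
  expect_lt(abs(r_off / r_mat - 0.25), 0.03)
})
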