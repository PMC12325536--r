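test_that("parental genotypes follow Hardy-Weinberg proportions", {
  n <- 1e5
  g <- drawParentalGenotypes(c(0.5, 0.33), n, seed = 101)
  for (parent in c("maternal", "paternal")) {
    dos <- g[[parent]]$dosage
    # freq 0.5: classes (0.25, 0.50, 0.25), mean dosage 1
    p <- 0.5
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(dos[, 1] + 1L, 3) / n
    mc_se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(obs - expected) < 3 * mc_se))
    expect_equal(mean(dos[, 1]), 1, tolerance = 0.02)
    # freq 0.33: P(dosage = 0) = 0.67^2 = 0.4489
    expect_lt(abs(mean(dos[, 2] == 0) - 0.4489), 0.006)
  }
  expect_error(drawParentalGenotypes(0, 10), "strictly inside")
  expect_error(drawParentalGenotypes(c(0.3, 1), 10), "strictly inside")
})

test_that("Mendelian transmission respects parental pairs", {
  # forced crosses: mother dosage 2 x father dosage 0 -> offspring always 1
  n <- 500
  mat <- list(h1 = matrix(1L, n, 1), h2 = matrix(1L, n, 1))
  pat <- list(h1 = matrix(0L, n, 1), h2 = matrix(0L, n, 1))
  off <- transmitGenotypes(mat, pat, seed = 1)
  expect_true(all(off == 1))
  # het x het -> (1/4, 1/2, 1/4)
  het <- list(h1 = matrix(1L, 4000, 1), h2 = matrix(0L, 4000, 1))
  off2 <- transmitGenotypes(het, het, seed = 2)
  obs <- tabulate(off2 + 1L, 3) / 4000
  expect_true(all(abs(obs - c(0.25, 0.5, 0.25)) <
                    3 * sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 4000)))
  # offspring allele always a member of a parental pair:
  # dosage bounded by (min parental contribution, max parental contribution)
  g <- drawParentalGenotypes(0.4, 2000, seed = 3)
  off3 <- transmitGenotypes(g$maternal, g$paternal, seed = 4)
  lo <- pmin(g$maternal$h1, g$maternal$h2) + pmin(g$paternal$h1, g$paternal$h2)
  hi <- pmax(g$maternal$h1, g$maternal$h2) + pmax(g$paternal$h1, g$paternal$h2)
  expect_true(all(off3 >= lo & off3 <= hi))
  expect_error(transmitGenotypes(g$maternal,
                                 list(h1 = matrix(0, 5, 1),
                                      h2 = matrix(0, 5, 1))),
               "dimensions")
})

test_that("mother-offspring dosage correlation is 0.5 under random mating", {
  g <- drawParentalGenotypes(0.3, 1e5, seed = 11)
  off <- transmitGenotypes(g$maternal, g$paternal, seed = 12)
  expect_lt(abs(cor(g$maternal$dosage[, 1], off[, 1]) - 0.5), 0.01)
  # spousal correlation s gives parental dosage correlation s and
  # mother-offspring correlation (1 + s) / sqrt(2 * (2 + s))
  gs <- drawParentalGenotypes(0.3, 1e5, seed = 13, spousal_cor = 0.4)
  expect_lt(abs(cor(gs$maternal$dosage[, 1], gs$paternal$dosage[, 1]) - 0.4),
            0.01)
  offs <- transmitGenotypes(gs$maternal, gs$paternal, seed = 14)
  expect_lt(abs(cor(gs$maternal$dosage[, 1], offs[, 1]) -
                  1.4 / sqrt(2 * 2.4)), 0.01)
})

test_that("exposure model links genotype, confounder and smoking", {
  p <- simParams(n_pairs = 5e4, seed = 21)
  g <- drawParentalGenotypes(p@allele_freqs, 5e4, seed = 21)
  U <- rnorm(5e4)

  # init_per_allele = 0, conf_on_init = 0: smoking independent of genotype
  e0 <- simulateExposure(g$maternal$dosage, U, p, seed = 22)
  slope <- coef(glm(e0$maternal_smoked ~ g$maternal$dosage[, 1],
                    family = binomial()))[2]
  expect_lt(abs(slope), 0.05)
  expect_lt(abs(mean(e0$maternal_smoked) - 0.306), 0.0075)
  # cigs defined exactly for smokers
  expect_identical(is.na(e0$cigs_per_day), e0$maternal_smoked == 0L)

  # zero weights: no dosage-cigs slope among smokers
  pz <- simParams(n_pairs = 5e4, snp_weights = 0, seed = 23)
  ez <- simulateExposure(g$maternal$dosage, U, pz, seed = 23)
  sm <- ez$maternal_smoked == 1
  fit <- lm(ez$cigs_per_day[sm] ~ g$maternal$dosage[sm, 1])
  expect_lt(abs(coef(fit)[2]), 3 * summary(fit)$coefficients[2, 2] + 0.05)

  # weight tuned so genotype explains ~1% of cigs variance among smokers
  p1 <- simParams(n_pairs = 1e5, allele_freqs = 0.33, snp_weights = 1,
                  exposure_sd = sqrt(2 * 0.33 * 0.67 * 99), seed = 24)
  g1 <- drawParentalGenotypes(0.33, 1e5, seed = 24)
  e1 <- simulateExposure(g1$maternal$dosage, rnorm(1e5), p1, seed = 25)
  sm1 <- e1$maternal_smoked == 1
  r2 <- varianceExplained(g1$maternal$dosage[sm1, 1], e1$cigs_per_day[sm1])
  expect_lt(abs(as.numeric(r2) - 0.01), 0.004)

  expect_error(simParams(exposure_sd = -1), "exposure_sd")
})

test_that("outcome model carries causal, pleiotropic and control paths", {
  # base rate only: left-handed prevalence ~ 9.82%
  coh <- generateCohort(simParams(n_pairs = 1e5, seed = 31))
  ph <- phenotypes(coh)
  expect_lt(abs(mean(ph$left_handed) - 0.0982), 0.003)
  expect_lt(abs(mean(ph$maternal_smoked) - 0.306), 0.006)

  # null genetics: dosage-handedness association null in both strata
  dos <- as.numeric(offspringDosage(coh)[1, ])
  for (s in c(0, 1)) {
    idx <- ph$maternal_smoked == s
    fit <- glm(ph$left_handed[idx] ~ dos[idx], family = binomial())
    expect_lt(abs(coef(fit)[2]) / summary(fit)$coefficients[2, 2], 4)
  }

  # bw_theta < 0: dosage-birthweight slope negative only in exposed stratum
  pb <- simParams(n_pairs = 1e5, snp_weights = 3, bw_theta = -0.04,
                  seed = 32)
  cohb <- generateCohort(pb)
  phb <- phenotypes(cohb)
  dosb <- as.numeric(offspringDosage(cohb)[1, ])
  exp_fit <- lm(phb$birthweight_kg[phb$maternal_smoked == 1] ~
                  dosb[phb$maternal_smoked == 1])
  une_fit <- lm(phb$birthweight_kg[phb$maternal_smoked == 0] ~
                  dosb[phb$maternal_smoked == 0])
  expect_lt(coef(exp_fit)[2] / summary(exp_fit)$coefficients[2, 2], -3)
  expect_lt(abs(coef(une_fit)[2]) / summary(une_fit)$coefficients[2, 2], 4)
})

test_that("cohort generation is deterministic and handles edge cases", {
  p <- simParams(n_pairs = 2000, seed = 41)
  a <- generateCohort(p)
  b <- generateCohort(p)
  expect_identical(offspringDosage(a), offspringDosage(b))
  expect_identical(phenotypes(a), phenotypes(b))
  # different seed changes the draw
  c2 <- generateCohort(simParams(n_pairs = 2000, seed = 42))
  expect_false(identical(phenotypes(a)$left_handed,
                         phenotypes(c2)$left_handed))
  # degenerate input: empty cohort, no error
  empty <- generateCohort(simParams(n_pairs = 0, seed = 1))
  expect_s4_class(empty, "MRCohort")
  expect_identical(ncol(empty), 0L)
  # class validity enforces the exposure invariant
  bad <- a
  SummarizedExperiment::colData(bad)$cigs_per_day <-
    rep(1, ncol(bad))  # defined for non-smokers too
  expect_error(validObject(bad), "cigs_per_day")
})

test_that("proxy attenuation: offspring genotype recovers ~25% of the R2", {
  # strong genetic signal keeps the Monte-Carlo error on the ratio small
  p <- simParams(allele_freqs = 0.33, snp_weights = 3, exposure_sd = 9)
  res <- proxyAttenuation(p, n = 2e5, seed = 51)
  expect_lt(abs(res$ratio - 0.25), 0.035)
  expect_gt(res$r2_maternal, res$r2_offspring)
  # positive spousal correlation raises the ratio to (1+s)^2 / (2(2+s))
  ps <- simParams(allele_freqs = 0.33, snp_weights = 3, exposure_sd = 9,
                  spousal_cor = 0.5)
  ress <- proxyAttenuation(ps, n = 2e5, seed = 52)
  expect_gt(ress$ratio, 0.3)
  expect_lt(abs(ress$ratio - 1.5^2 / (2 * 2.5)), 0.05)
})

test_that("cohort TSV round-trips", {
  coh <- generateCohort(simParams(n_pairs = 300, allele_freqs = c(0.2, 0.5),
                                  snp_weights = c(0.5, 0.3), seed = 61))
  f <- tempfile(fileext = ".tsv")
  writeCohort(coh, f)
  back <- readCohort(f)
  expect_identical(unname(offspringDosage(back)),
                   unname(offspringDosage(coh)))
  ph1 <- phenotypes(coh); ph2 <- phenotypes(back)
  expect_equal(ph1$cigs_per_day, ph2$cigs_per_day)
  expect_identical(ph1$country, ph2$country)
  unlink(f)
})
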