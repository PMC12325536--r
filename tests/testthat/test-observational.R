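test_that("seasonal month encoding peaks in summer and winter", {
  expect_equal(encodeMonth(6), cos(-pi / 6))
  expect_equal(encodeMonth(6), 0.866, tolerance = 1e-3)
  expect_equal(encodeMonth(3), -0.866, tolerance = 1e-3)
  # period 6: s(m) = s(m + 6) for every month
  m <- 1:6
  expect_equal(encodeMonth(m), encodeMonth(m + 6))
  # maxima in {6, 7, 12, 1}, minima in {3, 4, 9, 10}
  s <- encodeMonth(1:12)
  expect_setequal(which(s > 0.8), c(1, 6, 7, 12))
  expect_setequal(which(s < -0.8), c(3, 4, 9, 10))
  expect_error(encodeMonth(13), "1..12")
  expect_error(encodeMonth(0), "1..12")
})

test_that("logistic fits match a brute-force likelihood grid search", {
  # tiny fixtures where the grid oracle is exhaustive
  # overlapping classes in every fixture so the MLE is finite and interior
  fixtures <- list(
    list(y = c(0, 0, 1, 0, 1, 1), x = c(-1.2, -0.4, 0.1, 0.5, 1.0, 2.3)),
    list(y = c(1, 0, 1, 0, 0, 0, 1, 1), x = c(2, -1, 1.5, 0.6, 0.2, -2, 3, -0.5)),
    list(y = c(0, 1, 1, 0, 1, 0), x = c(0, 0, 1, 1, 2, 2)))
  for (f in fixtures) {
    fit <- fitLogistic(f$y, data.frame(x = f$x))
    oracle <- logisticGridMLE(f$y, matrix(f$x))
    expect_equal(fit$estimate, oracle[2], tolerance = 5e-4,
                 ignore_attr = TRUE)
  }
})

test_that("sex-only model reproduces the 2x2 cross-product odds ratio", {
  # counts: males 21,546 left / 175,965 right; females 20,836 / 215,757
  counts <- list(male = c(left = 21546, right = 175965),
                 female = c(left = 20836, right = 215757))
  sex <- rep(c("male", "male", "female", "female"),
             times = c(counts$male, counts$female))
  left <- rep(c(1, 0, 1, 0), times = c(counts$male, counts$female))
  res <- fitLogistic(left, data.frame(sex = factor(sex, c("female", "male"))))
  oracle_or <- (counts$male["left"] * counts$female["right"]) /
    (counts$male["right"] * counts$female["left"])
  expect_equal(res$odds_ratio, unname(oracle_or), tolerance = 1e-6)
  expect_equal(res$odds_ratio, 1.268, tolerance = 1e-3)
})

test_that("logistic regression flags pathologies instead of hiding them", {
  # perfect separation is flagged, not silently reported
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(1, 2, 3, 11, 12, 13)
  res <- fitLogistic(y, data.frame(x = x))
  expect_true(res$flagged)
  expect_match(res$flag_reason, "separation|converge")
  # rank deficiency names the collinear term
  set.seed(5)
  d <- data.frame(a = rnorm(50))
  d$b <- 2 * d$a
  expect_error(fitLogistic(rbinom(50, 1, 0.5), d), "collinear.*b")
})

test_that("results are invariant to row order and track complete cases", {
  set.seed(7)
  d <- data.frame(x = rnorm(300), z = rnorm(300))
  y <- rbinom(300, 1, plogis(-2 + 0.8 * d$x))
  r1 <- fitLogistic(y, d)
  perm <- sample(300)
  r2 <- fitLogistic(y[perm], d[perm, ])
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-10)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-10)
  # one missing predictor value drops exactly one row
  d2 <- d; d2$x[17] <- NA
  r3 <- fitLogistic(y, d2)
  expect_identical(r3$n_used[1], r1$n_used[1] - 1L)
})

test_that("null predictors give unit odds ratios and uniform-ish p", {
  set.seed(9)
  p_vals <- replicate(40, {
    y <- rbinom(150, 1, 0.3)
    fitLogistic(y, data.frame(x = rnorm(150)))$p_value
  })
  expect_gt(mean(p_vals > 0.05), 0.80)  # ~95% expected
  expect_lt(abs(mean(p_vals) - 0.5), 0.15)
})

test_that("McFadden pseudo R2 follows its definition and grows with signal", {
  expect_identical(mcfaddenR2(-100, -100), 0)
  expect_identical(mcfaddenR2(-50, -100), 0.5)
  set.seed(11)
  n <- 2000
  d <- data.frame(x = rnorm(n), junk = rnorm(n))
  y <- rbinom(n, 1, plogis(-2 + d$x))
  d$y <- y
  base <- multivariableFit(d, predictorSpec("junk"), outcome = "y")
  with_x <- multivariableFit(d, rbind(predictorSpec("junk"),
                                      predictorSpec("x")), outcome = "y")
  expect_gte(base$pseudo_r2, 0)
  expect_gt(with_x$pseudo_r2, base$pseudo_r2)
})

test_that("multivariable fit supports encodings, PCs and missing data", {
  coh <- generateCohort(simParams(n_pairs = 4000, seed = 13))
  ph <- phenotypes(coh)
  specs <- defaultPredictorSpecs()
  pcs <- data.frame(PC1 = rnorm(nrow(ph)), PC2 = rnorm(nrow(ph)))
  fit <- multivariableFit(ph, specs, pcs = pcs)
  expect_true(any(grepl("^sex", fit$results$term)))
  expect_true("PC1" %in% fit$results$term)
  expect_gte(fit$pseudo_r2, 0)
  expect_lt(fit$pseudo_r2, 1)
  expect_identical(fit$results$n_used[1], fit$n_used)
  # empty complete-case set is an explicit error
  ph2 <- ph; ph2$townsend <- NA_real_
  expect_error(multivariableFit(ph2, specs), "complete case")
})

test_that("conditioning on a downstream collider shifts the smoking OR", {
  # smoking -> birthweight <- U -> handedness: adding birthweight to the
  # model moves the maternal-smoking coefficient away from its crude value
  params <- colliderParams("birthweight", n_pairs = 40000, seed = 15)
  ph <- phenotypes(generateCohort(params))
  crude <- glm(left_handed ~ maternal_smoked, data = ph,
               family = binomial())
  adj <- glm(left_handed ~ maternal_smoked + birthweight_kg, data = ph,
             family = binomial())
  shift <- coef(adj)["maternal_smoked"] - coef(crude)["maternal_smoked"]
  se <- summary(adj)$coefficients["maternal_smoked", 2]
  expect_gt(abs(shift), 2 * se)
})

test_that("pairwise association dispatches on variable roles", {
  # proportional rows: V = 0
  x <- rep(c("a", "b"), each = 40)
  y <- rep(rep(c("u", "v"), c(10, 30)), 2)
  expect_equal(pairwiseAssociation(x, y)$measure, 0)
  # diagonal table: V = 1
  x2 <- rep(c("a", "b"), each = 10)
  expect_equal(pairwiseAssociation(x2, x2)$measure, 1)
  # ((30,10),(10,30)): chi2 = 20, V = 0.5
  x3 <- rep(c("a", "a", "b", "b"), c(30, 10, 10, 30))
  y3 <- rep(c("u", "v", "u", "v"), c(30, 10, 10, 30))
  r3 <- pairwiseAssociation(x3, y3)
  expect_equal(r3$measure, 0.5)
  expect_identical(r3$measure_type, "cramers_v")
  # continuous pair -> Pearson; mixed -> Spearman
  set.seed(17)
  a <- rnorm(100); b <- a + rnorm(100)
  expect_identical(pairwiseAssociation(a, b)$measure_type, "pearson")
  expect_equal(pairwiseAssociation(a, b)$measure, cor(a, b))
  mix <- pairwiseAssociation(rep(c("x", "y"), 50), a)
  expect_identical(mix$measure_type, "spearman")
  # constant variable: undefined with reason
  const <- pairwiseAssociation(rep(1, length(a)), a)
  expect_true(is.na(const$measure))
  expect_match(const$reason, "constant")
  # matrix helper covers all pairs
  d <- data.frame(a = a, b = b, g = rep(c("x", "y"), 50))
  am <- associationMatrix(d, c("a", "b", "g"))
  expect_identical(nrow(am), 3L)
})
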