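test_that("noiseless synthetic data is interpolated exactly", {
  s <- syntheticStructure(300, seed = 5, noiseSd = 0)
  fit <- suppressWarnings(fitLinear(s$features, s$truth))
  expect_equal(betas(coefficientSet(fit)), betas(s$coefficients),
               tolerance = 1e-8)
  expect_equal(intercept(coefficientSet(fit)), 0, tolerance = 1e-8)
  pred <- predictB(coefficientSet(fit), s$features)
  expect_equal(evaluateCorrelation(pred, s$truth), 1.0)
})

test_that("fitted betas fall in their 99% confidence intervals under noise", {
  nms <- paste0("O", 0:14)
  betaTrue <- stats::setNames(seq(-0.4, 0.4, length.out = 15), nms)
  X <- withr::with_seed(21, matrix(rnorm(5000 * 15), ncol = 15,
                                   dimnames = list(NULL, nms)))
  y <- drop(X %*% betaTrue) +
    withr::with_seed(22, rnorm(5000, sd = 0.3))
  fit <- fitLinear(X, y)
  est <- betas(coefficientSet(fit))
  se <- est / tStatistics(fit)
  halfWidth <- qt(0.995, df = 5000 - 16) * abs(se)
  covered <- abs(est - betaTrue) <= halfWidth
  expect_gte(sum(covered), 14L)
})

test_that("single-column contact design recovers slope -0.64, intercept 0", {
  X <- withr::with_seed(23, matrix(rnorm(4000), ncol = 1,
                                   dimnames = list(NULL, "O0")))
  y <- -0.64 * X[, 1] + withr::with_seed(24, rnorm(4000, sd = 0.3))
  fit <- fitLinear(X, y)
  cs <- coefficientSet(fit)
  expect_equal(modelKind(cs), "contact")
  se <- betas(cs) / tStatistics(fit)
  expect_lt(abs(betas(cs)["O0"] + 0.64), 2.6 * abs(se["O0"]))
  expect_lt(abs(intercept(cs)), 0.02)
})

test_that("prediction is the linear form with no clipping", {
  cs <- presetCoefficients("contact")
  # a zero (column-mean) feature row predicts the intercept
  expect_equal(predictB(cs, matrix(0, 1, 1,
                                   dimnames = list(NULL, "O0"))), 0)
  # standardized contact count of 1.0 predicts -0.64
  expect_equal(predictB(cs, matrix(1, 1, 1,
                                   dimnames = list(NULL, "O0"))), -0.64)
  # extreme values pass through unclipped
  expect_equal(predictB(cs, matrix(-10, 1, 1,
                                   dimnames = list(NULL, "O0"))), 6.4)
  expect_error(predictB(cs, matrix(1, 1, 1,
                                   dimnames = list(NULL, "O3"))),
               "do not match")
})

test_that("training residuals satisfy the OLS normal equations", {
  s <- syntheticStructure(400, seed = 6, noiseSd = 0.5)
  fit <- fitLinear(s$features, s$truth)
  res <- s$truth - predictB(coefficientSet(fit), s$features)
  expect_equal(mean(res), 0, tolerance = 1e-10)
  dots <- abs(crossprod(featureValues(s$features), res))
  expect_true(all(dots < 1e-6))
})

test_that("Pearson correlation matches hand computation and affine invariance", {
  x <- c(1.2, 4.5, 2.2, 8.8, 3.1, 0.4, 7.7, 5.5, 6.1, 2.9)
  y <- c(2.0, 3.9, 2.5, 9.1, 2.8, 1.1, 6.9, 6.2, 5.0, 3.3)
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(evaluateCorrelation(x, y), byHand, tolerance = 1e-12)
  expect_equal(evaluateCorrelation(x, x), 1.0)
  expect_equal(evaluateCorrelation(x, -x), -1.0)
  expect_equal(evaluateCorrelation(3 * x - 2, 0.5 * y + 7),
               byHand, tolerance = 1e-12)
  expect_error(evaluateCorrelation(c(1, 1, 1), y[1:3]), "constant")
  expect_error(evaluateCorrelation(x[1:2], y[1:2]), "at least 3")
})

test_that("cross-validation folds split entries deterministically", {
  entries <- syntheticEntries(10, 120, seed = 40, noiseSd = 0)
  r1 <- perEntry(suppressWarnings(crossValidate(entries, k = 5, seed = 7)))
  r2 <- perEntry(suppressWarnings(crossValidate(entries, k = 5, seed = 7)))
  expect_identical(r1, r2)
  r3 <- perEntry(suppressWarnings(crossValidate(entries, k = 5, seed = 8)))
  expect_false(identical(r1$fold, r3$fold))
  # noiseless data from one generating model: held-out r is 1 everywhere
  expect_equal(r1$pearsonR, rep(1, 10), tolerance = 1e-9)
  expect_error(crossValidate(entries, k = 11), "fewer entries")
})

test_that("variable importance ranks a dominant predictor first at 100", {
  nms <- paste0("O", 0:14)
  X <- withr::with_seed(31, matrix(rnorm(3000 * 15), ncol = 15,
                                   dimnames = list(NULL, nms)))
  beta <- stats::setNames(rep(0, 15), nms)
  beta[c("O4", "O1", "O5")] <- c(0.8, 0.4, 0.4)
  y <- drop(X %*% beta) + withr::with_seed(32, rnorm(3000, sd = 0.5))
  fit <- fitLinear(X, y)
  imp <- variableImportance(fit)
  expect_equal(imp$orbit[1], "O4")
  expect_equal(imp$importance[1], 100)
  expect_setequal(imp$orbit[1:3], c("O4", "O1", "O5"))
})

test_that("duplicated informative columns raise a rank-deficiency error", {
  X <- withr::with_seed(33, matrix(rnorm(200 * 3), ncol = 3,
                                   dimnames = list(NULL,
                                                   c("O0", "O1", "O2"))))
  X[, "O2"] <- X[, "O1"]
  y <- X[, "O1"] + withr::with_seed(34, rnorm(200, sd = 0.1))
  expect_error(fitLinear(X, y), "collinear.*O2")
})

test_that("coefficient files round-trip and presets resolve", {
  cs <- presetCoefficients("contact")
  expect_equal(betas(cs), c(O0 = -0.64))
  expect_equal(intercept(cs), 0)
  expect_equal(cs@cutoff, 7.0)
  tf <- withr::local_tempfile(fileext = ".txt")
  writeCoefficients(cs, tf)
  cs2 <- readCoefficients(tf)
  expect_equal(betas(cs2), betas(cs))
  expect_equal(intercept(cs2), intercept(cs))
  expect_equal(cs2@cutoff, cs@cutoff)

  g <- syntheticGdvCoefficients()
  writeCoefficients(g, tf)
  g2 <- readCoefficients(tf)
  expect_equal(betas(g2), betas(g))
  expect_equal(modelKind(g2), "gdv")
  expect_error(presetCoefficients("gdv"), "unknown preset")
})
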