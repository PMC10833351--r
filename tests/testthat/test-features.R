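test_that("smoothing adds the neighborhood mean, hand-checked on a chain", {
  # 3 atoms at 0, 1.5, 3.0 A; column values (1, 4, 7)
  m <- modelFromCoords(matrix(c(0, 0, 0, 1.5, 0, 0, 3.0, 0, 0),
                              ncol = 3, byrow = TRUE))
  om <- countOrbits(buildContactGraph(m, 5.0))
  fm <- new("FeatureMatrix",
            values = matrix(c(1, 4, 7), ncol = 1,
                            dimnames = list(NULL, "O0")),
            transforms = character(0), cutoff = 5.0)
  sm <- smoothFeatures(fm, m, radius = 2.0)
  expect_equal(unname(featureValues(sm)[, 1]), c(5, 8, 11))
  expect_equal(transformsApplied(sm), c("smoothed"))
  expect_equal(nrow(featureValues(smoothFeatures(om, m))), 3L)
})

test_that("atoms with a neighborhood of constants double; isolated atoms keep their value", {
  xyz <- matrix(c(0, 0, 0, 1.5, 0, 0, 50, 0, 0), ncol = 3, byrow = TRUE)
  m <- modelFromCoords(xyz)
  fm <- new("FeatureMatrix",
            values = matrix(3, nrow = 3, ncol = 2,
                            dimnames = list(NULL, c("O0", "O1"))),
            transforms = character(0), cutoff = 5.0)
  sm <- featureValues(smoothFeatures(fm, m, radius = 2.0))
  expect_equal(unname(sm[1:2, ]), matrix(6, 2, 2))  # value + mean(= value)
  expect_equal(unname(sm[3, ]), c(3, 3))            # no neighbor in 2 A
})

test_that("column z-scoring standardizes, is idempotent, and flags constants", {
  fm <- new("FeatureMatrix",
            values = cbind(O0 = c(1, 2, 3), O1 = c(5, 5, 5)),
            transforms = character(0), cutoff = 5.0)
  expect_warning(z <- zscoreColumns(fm), "constant")
  v <- featureValues(z)
  expect_equal(unname(v[, "O0"]), c(-1, 0, 1))
  expect_equal(unname(v[, "O1"]), c(0, 0, 0))
  expect_equal(abs(mean(v[, "O0"])), 0, tolerance = 1e-12)
  expect_equal(sd(v[, "O0"]), 1, tolerance = 1e-12)

  # idempotence on the non-degenerate column
  fm2 <- new("FeatureMatrix",
             values = v[, "O0", drop = FALSE],
             transforms = character(0), cutoff = 5.0)
  expect_equal(featureValues(zscoreColumns(fm2)), v[, "O0", drop = FALSE],
               tolerance = 1e-12)

  one <- new("FeatureMatrix", values = cbind(O0 = 1),
             transforms = character(0), cutoff = 5.0)
  expect_error(zscoreColumns(one), "2 rows")
})

test_that("B normalization is per-group mean 0 / sd 1 and affine invariant", {
  b <- normalizeB(c(10, 20, 30))
  expect_equal(bValues(b), c(-1, 0, 1))
  expect_equal(bScale(b), "normalized")

  # affine invariance within a group: normalize(a*B + c) == normalize(B)
  raw <- c(12, 55, 31, 20, 44)
  expect_equal(bValues(normalizeB(3.2 * raw + 17)),
               bValues(normalizeB(raw)), tolerance = 1e-12)

  expect_error(normalizeB(c(5, 5, 5)), "zero B-value spread")
  expect_error(normalizeB(c(5)), "fewer than 2")
})

test_that("per-chain vs whole-structure normalization differ for offset chains", {
  # two chains with the same internal B shape, one offset by +50 A^2
  shape <- c(10, 15, 20, 25)
  m <- modelFromCoords(matrix(seq(0, 4.2, length.out = 8), ncol = 3,
                              nrow = 8) + matrix(rnorm(24, sd = 0),
                                                 ncol = 3),
                       b = c(shape, shape + 50))
  m@atoms$chainId <- rep(c("A", "B"), each = 4)

  perChain <- normalizeB(m, groupBy = "chain")
  expect_equal(bValues(perChain)[1:4], bValues(perChain)[5:8],
               tolerance = 1e-12)
  expect_equal(mean(bValues(perChain)[1:4]), 0, tolerance = 1e-12)

  whole <- normalizeB(m, groupBy = "structure")
  # chain means are pushed apart: bimodal normalized values
  expect_gt(mean(bValues(whole)[5:8]) - mean(bValues(whole)[1:4]), 1)
})

test_that("pipeline rows are the non-environment atoms and transforms recorded", {
  s <- syntheticStructure(50, seed = 3, noiseSd = 0)
  model <- markEnvironment(s$model, c(rep(FALSE, 45), rep(TRUE, 5)))
  f <- gdvFeatures(model, cutoff = 5.0)
  expect_equal(nrow(featureValues(f)), 45L)
  expect_equal(transformsApplied(f), c("smoothed", "column_zscored"))
  fc <- gdvFeatures(model, modelKind = "contact", cutoff = 7.0)
  expect_equal(colnames(featureValues(fc)), "O0")

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(f, tf)
  expect_match(readLines(tf, n = 1), "smoothed,column_zscored")
})
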