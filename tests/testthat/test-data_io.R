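test_that("delimited matrices read with NA tokens, both orientations, and write round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2",
               "s1\t1.5\tNA",
               "s2\t2.0\t3.0",
               "s3\t-1.0\t0.5"), tsv)
  em <- readExpressionMatrix(tsv)
  expect_s4_class(em, "ExpressionMatrix")
  expect_identical(sampleIds(em), c("s1", "s2", "s3"))
  expect_identical(geneIds(em), c("g1", "g2"))
  expect_identical(sum(missingMask(em)), 1L)
  expect_true(missingMask(em)["s1", "g2"])
  expect_equal(exprsValues(em)["s2", "g2"], 3.0)

  ## genes-in-rows file with the orientation flag reads identically
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "g1\t1.5\t2.0\t-1.0",
               "g2\tNA\t3.0\t0.5"), tsv2)
  em2 <- readExpressionMatrix(tsv2, orientation = "genes")
  expect_equal(exprsValues(em2), exprsValues(em))
  expect_identical(missingMask(em2), missingMask(em))

  ## write -> read identity on values, mask and ids
  out <- tempfile(fileext = ".csv")
  writeExpressionMatrix(em, out)
  em3 <- readExpressionMatrix(out)
  expect_identical(sampleIds(em3), sampleIds(em))
  expect_identical(geneIds(em3), geneIds(em))
  expect_identical(missingMask(em3), missingMask(em))
  expect_equal(exprsValues(em3)[!missingMask(em)],
               exprsValues(em)[!missingMask(em)])
})

test_that("malformed inputs give descriptive parse errors", {
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(readExpressionMatrix(empty), "parse error")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,g1,g2", "s1,1.0,oops", "s2,2.0,3.0"), bad)
  expect_error(readExpressionMatrix(bad), "oops.*s1.*g2")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,g1,g2", "s1,1,2", "s1,3,4"), dup)
  expect_error(readExpressionMatrix(dup), "duplicate")

  expect_error(readExpressionMatrix(tempfile()), "not found")
})

test_that("missingness filter removes strictly-above-threshold samples only, preserving order", {
  d <- 20L
  mask <- matrix(FALSE, 3, d)
  mask[1, 1:5] <- TRUE # 25% missing -> filtered
  mask[2, 1:4] <- TRUE # exactly 20% -> retained (rule is strictly 'more than')
  v <- matrix(1, 3, d)
  em <- ExpressionMatrix(v, sampleIds = c("a", "b", "c"),
                         geneIds = paste0("g", 1:d), missingMask = mask)
  f <- filterSamplesByMissingness(em, preprocessConfig(missingnessThreshold = 0.20))
  expect_identical(sampleIds(f), c("b", "c"))

  ## no missing values: identity
  em0 <- ExpressionMatrix(matrix(rnorm(40), 2, 20))
  expect_equal(exprsValues(filterSamplesByMissingness(em0)), exprsValues(em0))

  ## everything filtered: unusable dataset
  allMiss <- ExpressionMatrix(matrix(NA_real_, 2, 4))
  expect_error(filterSamplesByMissingness(allMiss), "unusable")
})

test_that("KNN imputation fills with nearest-donor means and leaves observed cells untouched", {
  ## s1 is missing g1; s2 and s3 are its two nearest neighbours on g2/g3
  ## (both at RMS distance ~0.07 vs 7+ for s4) with g1 = 4 and 6 -> mean 5
  v <- rbind(s1 = c(NA, 0.0, 0.0),
             s2 = c(4, 0.1, 0.0),
             s3 = c(6, 0.0, 0.1),
             s4 = c(100, 10, 10))
  colnames(v) <- c("g1", "g2", "g3")
  em <- ExpressionMatrix(v)
  imp <- imputeKNN(em, preprocessConfig(knnK = 2))
  expect_false(any(missingMask(imp)))
  expect_equal(exprsValues(imp)["s1", "g1"], 5)
  ## observed cells bitwise identical
  obs <- !missingMask(em)
  expect_identical(exprsValues(imp)[obs], exprsValues(em)[obs])

  ## k = 1: s2 and s3 tie at the same distance; the stable order() breaks
  ## the tie toward the earlier sample index, so s2 donates
  imp1 <- imputeKNN(em, preprocessConfig(knnK = 1))
  expect_equal(exprsValues(imp1)["s1", "g1"], 4)

  ## k larger than n-1 is clamped to the available donors
  impBig <- imputeKNN(em, preprocessConfig(knnK = 50))
  expect_equal(exprsValues(impBig)["s1", "g1"], mean(c(4, 6, 100)))

  ## no missing values: identity
  em0 <- ExpressionMatrix(matrix(rnorm(12), 3, 4))
  expect_identical(exprsValues(imputeKNN(em0)), exprsValues(em0))

  ## a gene observed nowhere cannot be imputed
  v2 <- matrix(c(NA, NA, 1, 2), 2, 2,
               dimnames = list(c("s1", "s2"), c("gene_dead", "g2")))
  expect_error(imputeKNN(ExpressionMatrix(v2)), "gene_dead")
})

test_that("z-score normalization matches the hand-computed population form", {
  em <- ExpressionMatrix(matrix(c(2, 4, 6), 3, 1,
                                dimnames = list(c("a", "b", "c"), "g1")))
  z <- zscoreNormalize(em)
  expect_equal(as.numeric(exprsValues(z)),
               c(-1.224744871391589, 0, 1.224744871391589), tolerance = 1e-12)

  ## constant gene: set_zero keeps a zero column, drop_gene removes it
  v <- cbind(g1 = c(2, 4, 6), gconst = c(5, 5, 5))
  rownames(v) <- c("a", "b", "c")
  z0 <- zscoreNormalize(ExpressionMatrix(v))
  expect_equal(as.numeric(exprsValues(z0)[, "gconst"]), c(0, 0, 0))
  zd <- zscoreNormalize(ExpressionMatrix(v),
                        preprocessConfig(zeroVariancePolicy = "drop_gene"))
  expect_identical(geneIds(zd), "g1")

  ## idempotence up to tolerance
  z2 <- zscoreNormalize(z)
  expect_equal(exprsValues(z2), exprsValues(z), tolerance = 1e-12)

  ## refuses matrices with remaining missing values
  vm <- matrix(c(NA, 1, 2, 3), 2, 2)
  expect_error(zscoreNormalize(ExpressionMatrix(vm)), "impute")
})

test_that("filter -> impute -> normalize yields exact per-gene moments on synthetic data", {
  sim <- generateClassificationData(nSamples = 40, nGenes = 30, nClasses = 3,
                                    nInformative = 6, missingRate = 0.05,
                                    logNormal = TRUE, seed = 424)
  pre <- preprocessExpression(sim$matrix)
  v <- exprsValues(pre)
  n <- nrow(v)
  mu <- colMeans(v)
  va <- colMeans(sweep(v, 2, mu)^2)
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(va - 1) < 1e-9))
  expect_false(any(missingMask(pre)))
})
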