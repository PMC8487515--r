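test_that("triangular layer weights follow the closed form", {
  expect_equal(layerWeights(4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(layerWeights(1), 1.0)
  for (N in 1:50) {
    w <- layerWeights(N)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    if (N > 1) expect_true(all(diff(w) > 0))
  }
  expect_error(layerWeights(0), "positive")
})

test_that("the confidence gate splits the worked example and collapses at the final layer", {
  fx <- workedExampleFixture()
  g <- gateSamples(fx$outputs, fx$rule)
  expect_identical(fx$outputs[g$Y], c(0.07, 0.95))
  expect_identical(fx$outputs[g$X], c(0.35, 0.52, 0.83))

  ## final layer: threshold 0.5 classifies everything
  gf <- gateSamples(fx$outputs, fx$rule, isFinal = TRUE)
  expect_length(gf$Y, 5L)
  expect_length(gf$X, 0L)

  ## no confidence region: nothing is confident
  g0 <- gateSamples(fx$outputs, confidenceRule(intervals = list()))
  expect_length(g0$Y, 0L)

  ## multi-bit outputs: every bit must sit inside the region
  O <- rbind(c(0.05, 0.95), c(0.05, 0.5), c(0.92, 0.97))
  gm <- gateSamples(O, fx$rule)
  expect_identical(gm$Y, c(1L, 3L))

  ## interval endpoints are inclusive
  ge <- gateSamples(c(0.1, 0.9, 0.11), fx$rule)
  expect_identical(ge$Y, c(1L, 2L))

  expect_error(confidenceRule(list(c(0, 0.5), c(0.4, 1))), "disjoint")
})

test_that("layer outputs average the member forests exactly", {
  fA <- constantForestModel(0.2, inputDim = 4L)
  fB <- constantForestModel(0.6, inputDim = 4L)
  X <- matrix(rnorm(12), 3, 4)
  out <- layerPredict(list(fA, fB), X)
  expect_equal(as.numeric(out), rep(0.4, 3), tolerance = 1e-12)
  ## identical forests: the mean is any single forest's output
  expect_equal(layerPredict(list(fA, fA), X),
               predictDFN(fA, X)$outputs, tolerance = 1e-12)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("dense augmentation stacks base features and all prior layer outputs", {
  X0 <- matrix(rnorm(4 * 100), 4, 100)
  h1 <- matrix(runif(8), 4, 2)
  h2 <- matrix(runif(8), 4, 2)
  h3 <- matrix(runif(8), 4, 2)
  expect_identical(denseAugment(X0, list()), X0)
  A <- denseAugment(X0, list(h1, h2, h3))
  expect_identical(ncol(A), 106L) # d0 + 3 layers x B = 100 + 6
  expect_identical(A[, 1:100], X0)
  expect_identical(A[, 101:102], h1)
  expect_identical(A[, 105:106], h3)
  expect_error(denseAugment(X0, list(h1[1:2, ])), "align")
})

test_that("early-exit combination renormalizes the traversed weight prefix", {
  ## hand-built two-layer model with constant forests: layer 1 emits 0.95
  ## (confident under the default rule) or 0.5 (forwarded to layer 2)
  mkModel <- function(c1, c2) {
    l1 <- new("LaminarLayer", forests = list(constantForestModel(c1, 3L)),
              layerIndex = 1L)
    l2 <- new("LaminarLayer",
              forests = list(constantForestModel(c2, 4L)), # 3 + B = 4 inputs
              layerIndex = 2L)
    new("LaminarModel", layers = list(l1, l2), codebook = buildCodebook(2L),
        baseInputDim = 3L,
        config = unclass(laminarConfig(numLayers = 2L, kBase = 1L)),
        layerWeights = layerWeights(2L), classLevels = c("a", "b"),
        routing = list())
  }
  X <- matrix(rnorm(6), 2, 3)

  ## confident at layer 1: y_f is exactly the layer-1 output
  mExit1 <- mkModel(0.95, 0.3)
  p1 <- predictLaminar(mExit1, X)
  expect_equal(as.numeric(p1$outputs), rep(0.95, 2), tolerance = 1e-12)
  expect_identical(p1$exitLayer, c(1L, 1L))
  expect_identical(as.character(p1$class), c("b", "b"))

  ## uncertain at layer 1 (0.5), classified at the final layer: weights
  ## (1/3, 2/3) give y_f = 0.5/3 + 2*0.9/3
  mExit2 <- mkModel(0.5, 0.9)
  p2 <- predictLaminar(mExit2, X)
  expect_equal(as.numeric(p2$outputs), rep(0.5 / 3 + 2 * 0.9 / 3, 2),
               tolerance = 1e-12)
  expect_identical(p2$exitLayer, c(2L, 2L))
  expect_true(all(p2$outputs >= 0 & p2$outputs <= 1))
})

test_that("the trained first layer matches the published structure and widths widen arithmetically", {
  set.seed(31)
  sim <- generateClassificationData(nSamples = 60, nGenes = 10, nClasses = 4,
                                    nInformative = 5, missingRate = 0, seed = 32)
  X <- exprsValues(zscoreNormalize(sim$matrix))
  ## empty confidence region: every sample stays uncertain, so all four
  ## layers train and the widths are observable
  cfg <- laminarConfig(confidence = confidenceRule(intervals = list()),
                       seed = 33L)
  evo <- evolutionConfig(populationSize = 6L, maxGenerations = 2L,
                         patience = 2L, maxDepth = 2L, maxNodes = 30L)
  pso <- psoConfig(swarmSize = 5L, maxIters = 4L, finalIters = 8L)
  model <- trainLaminar(X, sim$labels, cfg, evo, pso, cascadeMaxLevels = 1L)

  expect_length(model@layers, 4L)
  expect_identical(vapply(model@layers, function(l) length(l@forests),
                          integer(1)),
                   c(3L, 4L, 5L, 6L)) # K + (l-1) for K = 3
  ## each DFNForest level holds log2(4) = 2 FNTs
  for (ly in model@layers)
    for (fo in ly@forests)
      for (lv in fo@levels)
        expect_length(lv@trees, 2L)
  ## dense augmentation: layer l consumes d0 + (l-1)*B columns
  for (l in 1:4)
    expect_identical(model@layers[[l]]@forests[[1]]@baseInputDim,
                     ncol(X) + (l - 1L) * 2L)
  ## grammars rotate F1..F4 across the forests of a layer
  expect_identical(vapply(model@layers[[4]]@forests,
                          function(f) f@functionSet@name, character(1)),
                   c("F1", "F2", "F3", "F4", "F1", "F2"))
})

test_that("routing is exhaustive and uncertain sets shrink monotonically", {
  set.seed(34)
  sim <- generateClassificationData(nSamples = 80, nGenes = 12, nClasses = 3,
                                    nInformative = 6, missingRate = 0, seed = 35)
  X <- exprsValues(zscoreNormalize(sim$matrix))
  model <- trainLaminar(X, sim$labels, laminarConfig(seed = 36L),
                        tinyEvo(), tinyPso(), cascadeMaxLevels = 1L)
  exit <- model@routing$exitLayer
  expect_length(exit, 80L)
  expect_true(all(exit >= 1L & exit <= length(model@layers)))
  ## samples uncertain after layer l are exactly those exiting later
  stillUncertain <- vapply(seq_along(model@layers),
                           function(l) sum(exit > l), integer(1))
  expect_true(all(diff(stillUncertain) <= 0))

  p <- predictLaminar(model, X)
  expect_identical(p$exitLayer, exit) # training routing reproduced
  expect_true(all(p$outputs >= 0 & p$outputs <= 1))
})

test_that("training, prediction and the JSON model file are deterministic round trips", {
  set.seed(37)
  sim <- generateClassificationData(nSamples = 50, nGenes = 8, nClasses = 2,
                                    nInformative = 4, missingRate = 0, seed = 38)
  X <- exprsValues(zscoreNormalize(sim$matrix))
  evo <- tinyEvo(); pso <- tinyPso()
  cfg <- laminarConfig(numLayers = 2L, kBase = 2L, seed = 39L)
  m1 <- trainLaminar(X, sim$labels, cfg, evo, pso, cascadeMaxLevels = 1L)
  m2 <- trainLaminar(X, sim$labels, cfg, evo, pso, cascadeMaxLevels = 1L)
  p1 <- predictLaminar(m1, X); p2 <- predictLaminar(m2, X)
  expect_identical(p1$outputs, p2$outputs)
  expect_identical(p1$exitLayer, p2$exitLayer)

  path <- tempfile(fileext = ".json")
  writeLaminarModel(m1, path)
  m3 <- readLaminarModel(path)
  p3 <- predictLaminar(m3, X)
  expect_equal(p3$outputs, p1$outputs, tolerance = 1e-15)
  expect_identical(p3$classIndex, p1$classIndex)
  expect_identical(p3$exitLayer, p1$exitLayer)
})
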