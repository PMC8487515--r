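fs2 <- functionSet(2, "pair")
fs234 <- functionSet(c(2, 3, 4), "F1")

test_that("random trees are grammar-valid and reproducible", {
  ## depth bound 1 with arities {2}: the grammar forces +2 over two leaves
  set.seed(1)
  for (i in 1:20) {
    t1 <- randomTree(fs2, 5L, maxDepth = 1L)
    expect_identical(t1@root$arity, 2L)
    expect_true(all(vapply(t1@root$children,
                           function(ch) ch$kind == "leaf", logical(1))))
  }

  set.seed(2)
  for (i in 1:200) {
    tr <- randomTree(fs234, 10L, maxDepth = 4L, maxNodes = 50L)
    expect_true(oracleGrammarOk(tr@root, c(2L, 3L, 4L), 10L))
    expect_true(validObject(tr))
    expect_lte(treeSize(tr), 50L)
    expect_lte(treeDepth(tr), 4L)
  }

  set.seed(99); a <- randomTree(fs234, 8L)
  set.seed(99); b <- randomTree(fs234, 8L)
  expect_identical(a@root, b@root)
})

test_that("crossover offspring stay grammar-valid and within bounds", {
  set.seed(3)
  for (i in 1:100) {
    a <- randomTree(fs234, 6L, maxDepth = 4L, maxNodes = 30L)
    b <- randomTree(fs234, 6L, maxDepth = 4L, maxNodes = 30L)
    off <- crossoverTrees(a, b, maxDepth = 4L, maxNodes = 30L)
    for (o in off) {
      expect_true(oracleGrammarOk(o@root, c(2L, 3L, 4L), 6L))
      expect_lte(treeDepth(o), 4L)
      expect_lte(treeSize(o), 30L)
    }
  }
  ## identical single-neuron parents with interchangeable leaves: every
  ## grammar-valid swap reproduces the parents' behaviour
  set.seed(4)
  p <- flexibleNeuralTree(
    fntNeuron(c(0.3, -0.7), 0.1, list(fntLeaf(1L), fntLeaf(1L))), 3L, fs2)
  off <- crossoverTrees(p, p, maxDepth = 1L)
  X <- matrix(rnorm(15), 5, 3)
  for (o in off)
    expect_equal(evaluateTree(o, X), evaluateTree(p, X))
})

test_that("mutation preserves the grammar and is seed-deterministic", {
  set.seed(5)
  for (i in 1:200) {
    tr <- randomTree(fs234, 6L, maxDepth = 4L, maxNodes = 40L)
    mu <- mutateTree(tr, maxDepth = 4L, maxNodes = 40L)
    expect_true(oracleGrammarOk(mu@root, c(2L, 3L, 4L), 6L))
    expect_lte(treeDepth(mu), 4L)
  }
  base <- randomTree(fs234, 6L)
  set.seed(6); m1 <- mutateTree(base)
  set.seed(6); m2 <- mutateTree(base)
  expect_identical(m1@root, m2@root)
})

test_that("particle swarm minimizes a sphere function and respects the velocity clamp", {
  ## classic sanity check: ||x|| over 5 dimensions reaches near zero
  set.seed(7)
  r <- psoMinimize(function(v) sqrt(sum(v^2)), 5L, psoConfig(), iters = 200L)
  expect_lt(r$value, 1e-2)

  ## velocity clamp: successive positions of each particle move by at most
  ## vmax per component (observed through the evaluation stream)
  seen <- list()
  fn <- function(v) { seen[[length(seen) + 1L]] <<- v; sum(v^2) }
  cfg <- psoConfig(swarmSize = 4L, vmax = 2.0)
  set.seed(8)
  invisible(psoMinimize(fn, 3L, cfg, iters = 10L))
  pos <- do.call(rbind, seen)
  for (particle in 1:4) {
    traj <- pos[seq(particle, nrow(pos), by = 4L), , drop = FALSE]
    steps <- abs(diff(traj))
    expect_lte(max(steps), cfg$vmax + 1e-12)
  }
})

test_that("PSO on a tree never worsens the fitness", {
  set.seed(9)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- as.numeric(runif(30) > 0.5)
  for (i in 1:10) {
    tr <- randomTree(fs234, 4L, maxDepth = 3L)
    f0 <- treeFitness(tr, X, y)
    tuned <- psoOptimize(tr, X, y, tinyPso(), iters = 10L)
    expect_lte(tuned@fitness, f0 + 1e-12)
    expect_equal(treeFitness(tuned, X, y), tuned@fitness, tolerance = 1e-12)
  }
})

test_that("structure evolution improves monotonically and learns a separable toy problem", {
  ## linearly separable: class = x1 > x2
  set.seed(10)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- as.numeric(X[, 1] > X[, 2])
  evo <- evolutionConfig(populationSize = 20L, maxGenerations = 10L,
                         patience = 10L, maxDepth = 3L, seed = 11L)
  tree <- evolveStructure(X, y, fs234, evo,
                          psoConfig(swarmSize = 12L, maxIters = 12L,
                                    finalIters = 60L))
  expect_lt(tree@fitness, 0.25)

  trace <- attr(tree, "fitnessTrace")
  expect_true(all(diff(trace) <= 1e-12)) # best-so-far never worsens
  expect_lte(tree@fitness, trace[1]) # returned tree beats the initial best
})

test_that("evolution is fully deterministic under a fixed seed", {
  set.seed(12)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- as.numeric(runif(30) > 0.5)
  evo <- tinyEvo(seed = 77L)
  t1 <- evolveStructure(X, y, fs234, evo, tinyPso())
  t2 <- evolveStructure(X, y, fs234, evo, tinyPso())
  expect_identical(t1@root, t2@root)
  expect_identical(t1@fitness, t2@fitness)
})

test_that("PSO recovers parameters of a known generating tree", {
  set.seed(13)
  tree <- randomTree(fs234, 5L, maxDepth = 2L)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- evaluateTree(tree, X) # targets generated by the true parameters
  shuffled <- setTreeParams(tree, runif(length(flattenParams(tree)), -1, 1))
  tuned <- psoOptimize(shuffled, X, y, psoConfig(), iters = 150L)
  expect_lt(tuned@fitness, 0.05)
})
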