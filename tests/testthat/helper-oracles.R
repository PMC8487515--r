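## Independent oracles and shared tiny training budgets.

## Naive per-sample recursive tree evaluator, written independently of the
## package's vectorized implementation.
oracleEvalNode <- function(node, x) {
  if (node$kind == "leaf") return(x[node$feature])
  acc <- node$bias
  for (j in seq_along(node$children))
    acc <- acc + node$weights[j] * oracleEvalNode(node$children[[j]], x)
  1 / (1 + exp(-acc)) # logistic
}

oracleEvalTree <- function(tree, X) {
  apply(as.matrix(X), 1, function(x) oracleEvalNode(tree@root, x))
}

## Recursive grammar check, independent of the S4 validity method.
oracleGrammarOk <- function(node, arities, d, isRoot = TRUE) {
  if (node$kind == "leaf")
    return(!isRoot && node$feature >= 1 && node$feature <= d)
  node$arity %in% arities &&
    length(node$weights) == node$arity &&
    length(node$children) == node$arity &&
    all(vapply(node$children, oracleGrammarOk, logical(1),
               arities = arities, d = d, isRoot = FALSE))
}

## Small budgets for training-path tests: enough signal to learn an easy
## problem, small enough to keep the suite fast.
tinyEvo <- function(...) {
  do.call(evolutionConfig,
          utils::modifyList(list(populationSize = 8L, maxGenerations = 3L,
                                 patience = 3L, maxDepth = 3L,
                                 maxNodes = 40L),
                            list(...)))
}

tinyPso <- function(...) {
  do.call(psoConfig,
          utils::modifyList(list(swarmSize = 6L, maxIters = 5L,
                                 finalIters = 15L),
                            list(...)))
}

## Hand-built DFNForest whose every tree outputs a constant sigma(bias):
## lets layer arithmetic be checked exactly.
constantForestModel <- function(constants, inputDim, numClasses = 2L) {
  cb <- buildCodebook(numClasses)
  fs <- functionSet(c(2, 3, 4), "F1")
  trees <- lapply(constants, function(k) {
    stopifnot(k > 0, k < 1)
    bias <- log(k / (1 - k)) # logit: sigma(bias) = k
    flexibleNeuralTree(
      fntNeuron(c(0, 0), bias, list(fntLeaf(1L), fntLeaf(min(2L, inputDim)))),
      inputDim, fs)
  })
  new("DFNForestModel",
      levels = list(new("NeuralForest", trees = trees, functionSet = fs)),
      codebook = cb, functionSet = fs, baseInputDim = as.integer(inputDim),
      valAccuracyTrace = 1.0)
}
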