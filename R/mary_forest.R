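## DFNForest: M-ary decomposition into ceiling(log2 M) binary tasks, one
## evolved FNT per bit, cascade levels deepened by feature augmentation with
## automatic depth from a validation split.

#' Build the M-ary codebook
#'
#' Class i (1-based) receives the B-bit binary representation of i-1, most
#' significant bit first, with B = ceiling(log2 M). For M = 4 that is two
#' bits per forest; for M = 3 two bits with the code (1,1) unused.
#'
#' @param M number of classes (>= 2)
#' @return a [BinaryTaskCodebook-class]
#' @export
buildCodebook <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop("need at least 2 classes")
  B <- as.integer(ceiling(log2(M)))
  codes <- matrix(0L, M, B)
  for (b in seq_len(B))
    codes[, b] <- as.integer(((seq_len(M) - 1L) %/% 2L^(B - b)) %% 2L)
  dimnames(codes) <- list(NULL, paste0("bit", seq_len(B)))
  new("BinaryTaskCodebook", numClasses = M, numBits = B, codes = codes)
}

#' Encode a class / decode raw bit outputs
#'
#' \code{encodeLabel} returns the B-bit code of a 1-based class index.
#' \code{decodeOutputs} maps raw outputs in [0,1] to the class whose code is
#' nearest in Euclidean distance among the M valid codes (unused code words
#' of a non-power-of-two M never win); ties break to the lowest class index.
#'
#' @param codebook a [BinaryTaskCodebook-class]
#' @param classIndex 1-based class index
#' @return \code{encodeLabel}: an integer B-vector; \code{decodeOutputs}:
#'   integer class indices (one per row of \code{outputs})
#' @export
encodeLabel <- function(codebook, classIndex) {
  stopifnot(classIndex >= 1L, classIndex <= codebook@numClasses)
  codebook@codes[classIndex, ]
}

#' @rdname encodeLabel
#' @param outputs a B-vector or n x B matrix of raw outputs in [0,1]
#' @export
decodeOutputs <- function(codebook, outputs) {
  O <- if (is.matrix(outputs)) outputs else matrix(outputs, nrow = 1L)
  if (ncol(O) != codebook@numBits)
    stop("outputs must have ", codebook@numBits, " columns")
  d2 <- vapply(seq_len(codebook@numClasses), function(ci) {
    rowSums(sweep(O, 2L, codebook@codes[ci, ])^2)
  }, numeric(nrow(O)))
  d2 <- matrix(d2, nrow = nrow(O))
  cls <- max.col(-d2, ties.method = "first")
  if (is.matrix(outputs)) cls else cls[[1L]]
}

#' Train one cascade level: a forest of B trees
#'
#' Evolves one flexible neural tree per bit column of the code matrix. A
#' degenerate bit column (all 0 or all 1) is trained anyway, with a warning.
#'
#' @param X n x d (possibly augmented) training matrix
#' @param yBits n x B 0/1 matrix of target bits
#' @param functionSet a [FunctionSet-class]
#' @param evoCfg,psoCfg training budgets ([evolutionConfig()], [psoConfig()])
#' @return a [NeuralForest-class]
#' @export
trainLevel <- function(X, yBits, functionSet, evoCfg = evolutionConfig(),
                       psoCfg = psoConfig()) {
  X <- as.matrix(X)
  yBits <- as.matrix(yBits)
  stopifnot(nrow(X) == nrow(yBits))
  trees <- lapply(seq_len(ncol(yBits)), function(b) {
    col <- yBits[, b]
    if (length(unique(col)) < 2L)
      warning("bit ", b, " is constant in this training split")
    evolveStructure(X, col, functionSet, evoCfg, psoCfg)
  })
  new("NeuralForest", trees = trees, functionSet = functionSet)
}

#' Raw outputs of a forest: one column per bit tree
#'
#' @param forest a [NeuralForest-class]
#' @param X n x d matrix matching the forest's input width
#' @return n x B matrix of tree outputs
#' @export
forestOutputs <- function(forest, X) {
  X <- as.matrix(X)
  out <- vapply(forest@trees, evaluateTree, numeric(nrow(X)), x = X)
  matrix(out, nrow = nrow(X))
}

#' Concatenate forest outputs onto a feature matrix
#'
#' @param Xbase n x d matrix
#' @param outputs n x B matrix of raw forest outputs
#' @return n x (d + B) matrix, base columns first
#' @export
augmentFeatures <- function(Xbase, outputs) {
  Xbase <- as.matrix(Xbase); outputs <- as.matrix(outputs)
  if (nrow(Xbase) != nrow(outputs))
    stop("row counts disagree: ", nrow(Xbase), " vs ", nrow(outputs))
  cbind(Xbase, outputs)
}

## stratified holdout: returns validation indices
.stratifiedHoldout <- function(y, fraction) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    nv <- max(1L, round(length(ix) * fraction))
    if (length(ix) <= 1L) return(integer(0)) # keep lone samples in training
    sample(ix, min(nv, length(ix) - 1L))
  }), use.names = FALSE)
  sort(idx)
}

#' Train a DFNForest cascade
#'
#' Splits the data into a training and a validation part (stratified,
#' \code{valFraction} held out), trains cascade levels sequentially - level l
#' consumes the features augmented with the outputs of levels 1..l-1 - and
#' records decoded-class validation accuracy after each level. Training stops
#' when that accuracy fails to strictly increase, or at \code{maxLevels}; the
#' returned model keeps only the levels up to the best validation accuracy.
#'
#' @param X n x d matrix of preprocessed features
#' @param y factor or integer class labels (length n, >= 2 classes present)
#' @param functionSet a [FunctionSet-class]
#' @param evoCfg,psoCfg training budgets
#' @param valFraction held-out fraction for depth selection (default 0.2)
#' @param maxLevels safety cap on cascade depth (default 8)
#' @param codebook optional [BinaryTaskCodebook-class]; default from the
#'   number of classes in \code{y}
#' @return a [DFNForestModel-class]
#' @export
trainCascade <- function(X, y, functionSet, evoCfg = evolutionConfig(),
                         psoCfg = psoConfig(), valFraction = 0.2,
                         maxLevels = 8L, codebook = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("need at least 10 samples")
  y <- as.factor(y)
  idx <- as.integer(y)
  if (is.null(codebook)) codebook <- buildCodebook(nlevels(y))
  B <- codebook@numBits
  valIdx <- .stratifiedHoldout(idx, valFraction)
  if (!length(valIdx)) stop("validation split is empty")
  trIdx <- setdiff(seq_len(nrow(X)), valIdx)
  yBits <- codebook@codes[idx, , drop = FALSE]
  augTr <- X[trIdx, , drop = FALSE]
  augVal <- X[valIdx, , drop = FALSE]
  levels <- list(); trace <- numeric(0)
  repeat {
    forest <- trainLevel(augTr, yBits[trIdx, , drop = FALSE], functionSet,
                         evoCfg, psoCfg)
    oTr <- forestOutputs(forest, augTr)
    oVal <- forestOutputs(forest, augVal)
    acc <- mean(decodeOutputs(codebook, oVal) == idx[valIdx])
    levels <- c(levels, forest)
    trace <- c(trace, acc)
    if (length(trace) >= maxLevels) break
    if (length(trace) >= 2L && acc <= trace[length(trace) - 1L]) break
    augTr <- augmentFeatures(augTr, oTr)
    augVal <- augmentFeatures(augVal, oVal)
  }
  keep <- which.max(trace) # first maximum on ties
  new("DFNForestModel", levels = levels[seq_len(keep)], codebook = codebook,
      functionSet = functionSet, baseInputDim = ncol(X),
      valAccuracyTrace = trace)
}

#' Predict with a DFNForest
#'
#' Runs the cascade with internal augmentation and returns the last level's
#' per-bit raw outputs (retained upstream for gating and augmentation)
#' together with the decoded class indices.
#'
#' @param model a [DFNForestModel-class]
#' @param X n x d matrix, d = the model's base input width
#' @return list with \code{classIndex} (integer n-vector) and \code{outputs}
#'   (n x B matrix)
#' @export
predictDFN <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model@baseInputDim)
    stop("input width ", ncol(X), " does not match model base input width ",
         model@baseInputDim)
  aug <- X
  out <- NULL
  for (l in seq_along(model@levels)) {
    out <- forestOutputs(model@levels[[l]], aug)
    if (l < length(model@levels)) aug <- augmentFeatures(aug, out)
  }
  list(classIndex = decodeOutputs(model@codebook, out), outputs = out)
}

setMethod("show", "BinaryTaskCodebook", function(object) {
  cat(sprintf("BinaryTaskCodebook: %d classes -> %d binary tasks\n",
              object@numClasses, object@numBits))
})

setMethod("show", "NeuralForest", function(object) {
  cat(sprintf("NeuralForest: %d trees (grammar %s, input_dim %d)\n",
              length(object@trees), object@functionSet@name,
              object@trees[[1]]@inputDim))
})

setMethod("show", "DFNForestModel", function(object) {
  cat(sprintf(
    "DFNForestModel: %d classes, %d cascade level(s), base width %d, grammar %s\n",
    object@codebook@numClasses, length(object@levels), object@baseInputDim,
    object@functionSet@name))
  cat("  validation accuracy trace:",
      paste(sprintf("%.3f", object@valAccuracyTrace), collapse = " "), "\n")
})
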