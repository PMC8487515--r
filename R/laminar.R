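## The laminar ensemble: layers of DFNForests that widen with depth, a
## confidence gate routing easy samples out early, densely connected feature
## augmentation, and triangular layer weights combining per-layer outputs.

#' Triangular layer weights
#'
#' w_i = i / (1 + 2 + ... + N) for i = 1..N: later layers, which see only the
#' harder samples, carry more weight. The weights sum to 1 and are strictly
#' increasing.
#'
#' @param N number of layers (>= 1)
#' @return numeric N-vector
#' @export
layerWeights <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  seq_len(N) / (N * (N + 1) / 2)
}

#' Confidence gating rule
#'
#' A sample exits a non-final layer when every bit of its raw output lies in
#' the confidence region (default [0, 0.1] U [0.9, 1]). After the final
#' layer the rule collapses to a plain threshold at \code{finalThreshold} so
#' that every sample is classified.
#'
#' @param intervals list of closed sub-intervals of [0,1], pairwise disjoint
#' @param finalThreshold bit threshold applied at the final layer
#' @return a classed settings list
#' @export
confidenceRule <- function(intervals = list(c(0, 0.1), c(0.9, 1)),
                           finalThreshold = 0.5) {
  for (iv in intervals) {
    stopifnot(length(iv) == 2L, iv[1] <= iv[2], iv[1] >= 0, iv[2] <= 1)
  }
  if (length(intervals) > 1L) {
    b <- do.call(rbind, intervals)
    b <- b[order(b[, 1]), , drop = FALSE]
    if (any(b[-1, 1] < b[-nrow(b), 2])) stop("intervals must be disjoint")
  }
  structure(list(intervals = intervals, finalThreshold = finalThreshold),
            class = "ConfidenceRule")
}

#' Laminar model configuration
#'
#' Defaults follow the published setup: depth N = 4 layers, K = 3 DFNForests
#' in the first layer, the four grammars F1-F4, arithmetic widening (layer l
#' holds K + l - 1 forests; \code{"constant"} keeps width K for ablation),
#' and the [confidenceRule()] gate.
#'
#' @param numLayers ensemble depth N
#' @param kBase first-layer forest count K
#' @param functionSets ordered list of [FunctionSet-class] objects assigned
#'   round-robin to the forests of each layer
#' @param widening \code{"arithmetic"} or \code{"constant"}
#' @param confidence a [confidenceRule()]
#' @param augmentPerForest if TRUE, augmentation contributes each forest's
#'   B columns rather than the layer's B-column mean
#' @param seed optional integer; seeds the RNG at [trainLaminar()] entry
#' @return a classed settings list
#' @export
laminarConfig <- function(numLayers = 4L, kBase = 3L,
                          functionSets = fntFunctionSets(),
                          widening = c("arithmetic", "constant"),
                          confidence = confidenceRule(),
                          augmentPerForest = FALSE, seed = NULL) {
  widening <- match.arg(widening)
  stopifnot(numLayers >= 1, kBase >= 1, length(functionSets) >= 1)
  structure(list(numLayers = as.integer(numLayers), kBase = as.integer(kBase),
                 functionSets = functionSets, widening = widening,
                 confidence = confidence,
                 augmentPerForest = isTRUE(augmentPerForest), seed = seed),
            class = "LaminarConfig")
}

.layerWidth <- function(cfg, l) {
  if (cfg$widening == "arithmetic") cfg$kBase + l - 1L else cfg$kBase
}

#' Split samples into confident (Y) and uncertain (X) sets
#'
#' Non-final layers: a sample is confident iff every bit of its output lies
#' inside the union of the rule's intervals. Final layer: every sample is
#' classified (the gate degenerates to the 0.5 threshold), so the uncertain
#' set is empty.
#'
#' @param outputs n x B matrix (or length-n vector for B = 1) in [0,1]
#' @param rule a [confidenceRule()]
#' @param isFinal TRUE when gating after the final layer
#' @return list with integer index vectors \code{Y} (confident) and \code{X}
#'   (uncertain)
#' @export
gateSamples <- function(outputs, rule = confidenceRule(), isFinal = FALSE) {
  O <- if (is.matrix(outputs)) outputs else matrix(outputs, ncol = 1L)
  n <- nrow(O)
  if (isFinal)
    return(list(Y = seq_len(n), X = integer(0)))
  if (!length(rule$intervals))
    return(list(Y = integer(0), X = seq_len(n)))
  inRegion <- matrix(FALSE, nrow(O), ncol(O))
  for (iv in rule$intervals)
    inRegion <- inRegion | (O >= iv[1] & O <= iv[2])
  conf <- rowSums(inRegion) == ncol(O)
  list(Y = which(conf), X = which(!conf))
}

#' Average a layer's forest outputs
#'
#' The output of one laminar layer is the per-bit arithmetic mean of its
#' DFNForests' raw outputs.
#'
#' @param forests list of [DFNForestModel-class] sharing an input width
#' @param X n x d matrix at that layer's input width
#' @return n x B matrix of averaged outputs
#' @export
layerPredict <- function(forests, X) {
  outs <- lapply(forests, function(f) predictDFN(f, X)$outputs)
  Reduce(`+`, outs) / length(outs)
}

#' Densely connected feature augmentation
#'
#' Concatenates the base features with the outputs of every prior layer
#' (base first, then layers in order), after the dense-block idea: later
#' layers see all earlier augmented sample points, not just the immediately
#' preceding ones.
#'
#' @param X0 n x d0 base matrix
#' @param history list of n x B per-layer output matrices (possibly empty)
#' @return n x (d0 + l*B) matrix
#' @export
denseAugment <- function(X0, history) {
  X0 <- as.matrix(X0)
  if (!length(history)) return(X0)
  for (h in history)
    if (nrow(as.matrix(h)) != nrow(X0))
      stop("history rows do not align with the base matrix")
  do.call(cbind, c(list(X0), history))
}

#' Train a laminar augmented cascading flexible neural forest
#'
#' Trains up to N layers sequentially. Layer l holds K + l - 1 DFNForests
#' (arithmetic widening) whose grammars cycle through
#' \code{cfg$functionSets}; it trains only on the samples still uncertain
#' after the previous layer's gate, on densely augmented inputs
#' [X0 | out_1 | ... | out_(l-1)]. Per-layer outputs, the exit layer of every
#' sample, and the triangular layer weights are recorded in the model. If no
#' uncertain samples remain - or too few (< 10) to train another tier - the
#' remaining layers are skipped and the last trained layer classifies
#' everything at prediction time.
#'
#' @param X n x d0 matrix of preprocessed features
#' @param y factor (or coercible) class labels, >= 2 classes
#' @param cfg a [laminarConfig()]
#' @param evoCfg,psoCfg training budgets per tree
#' @param valFraction cascade validation fraction (depth selection)
#' @param cascadeMaxLevels cap on each DFNForest's cascade depth
#' @return a [LaminarModel-class]
#' @export
trainLaminar <- function(X, y, cfg = laminarConfig(),
                         evoCfg = evolutionConfig(), psoCfg = psoConfig(),
                         valFraction = 0.2, cascadeMaxLevels = 8L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), nlevels(y) >= 2L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  idx <- as.integer(y)
  codebook <- buildCodebook(nlevels(y))
  B <- codebook@numBits
  n <- nrow(X)
  nFS <- length(cfg$functionSets)
  uncertain <- seq_len(n)
  exitLayer <- rep(NA_integer_, n)
  history <- list()
  layers <- list()
  for (l in seq_len(cfg$numLayers)) {
    if (!length(uncertain)) break
    if (l > 1L && length(uncertain) < 10L) {
      ## too few hard samples to train another tier; they exit at the last
      ## trained layer, which acts as final at prediction time
      warning("layer ", l, ": only ", length(uncertain),
              " uncertain sample(s) remain; stopping at ", l - 1L, " layers")
      break
    }
    rows <- uncertain
    if (length(unique(idx[rows])) < 2L)
      warning("layer ", l, ": fewer than 2 classes remain among uncertain ",
              "samples; training without stratification")
    Xrows <- denseAugment(X[rows, , drop = FALSE],
                          lapply(history, function(h)
                            h[rows, , drop = FALSE]))
    width <- .layerWidth(cfg, l)
    forests <- lapply(seq_len(width), function(f) {
      fs <- cfg$functionSets[[((f - 1L) %% nFS) + 1L]]
      trainCascade(Xrows, factor(y[rows], levels = levels(y)), fs,
                   evoCfg, psoCfg, valFraction, cascadeMaxLevels, codebook)
    })
    perForest <- lapply(forests, function(f) predictDFN(f, Xrows)$outputs)
    out <- Reduce(`+`, perForest) / length(perForest)
    h <- matrix(NA_real_, n, if (cfg$augmentPerForest) B * width else B)
    h[rows, ] <- if (cfg$augmentPerForest) do.call(cbind, perForest) else out
    history[[l]] <- h
    layers[[l]] <- new("LaminarLayer", forests = forests,
                       layerIndex = as.integer(l))
    isFinal <- l == cfg$numLayers
    g <- gateSamples(out, cfg$confidence, isFinal = isFinal)
    exitLayer[rows[g$Y]] <- l
    uncertain <- rows[g$X]
  }
  exitLayer[is.na(exitLayer)] <- length(layers)
  new("LaminarModel", layers = layers, codebook = codebook,
      baseInputDim = ncol(X), config = unclass(cfg),
      layerWeights = layerWeights(cfg$numLayers), classLevels = levels(y),
      routing = list(exitLayer = exitLayer, history = history))
}

.combineOutputs <- function(weightsN, history, exitLayer, n, B) {
  yf <- matrix(NA_real_, n, B)
  for (l in sort(unique(exitLayer))) {
    rows <- which(exitLayer == l)
    w <- weightsN[seq_len(l)]
    w <- w / sum(w) # renormalized prefix of the triangular weights
    acc <- matrix(0, length(rows), B)
    for (i in seq_len(l))
      acc <- acc + w[i] * history[[i]][rows, , drop = FALSE]
    yf[rows, ] <- acc
  }
  yf
}

#' Predict with a laminar model
#'
#' Each sample flows through the layers until the confidence gate lets it
#' exit (the model's last layer classifies everything). Its combined output
#' y_f is the weighted sum of the per-layer outputs it traversed, using the
#' triangular weights restricted to those layers and renormalized to sum to
#' 1; the class is the codebook decode of y_f. A sample traversing all N
#' layers is combined with the full weights (0.1, 0.2, 0.3, 0.4 for N = 4).
#'
#' @param model a [LaminarModel-class]
#' @param X n x d0 matrix at the model's base input width
#' @return list with \code{class} (factor, model class levels),
#'   \code{classIndex}, \code{outputs} (n x B combined y_f), and
#'   \code{exitLayer}
#' @export
predictLaminar <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model@baseInputDim)
    stop("input width ", ncol(X), " does not match model base width ",
         model@baseInputDim)
  n <- nrow(X)
  B <- model@codebook@numBits
  cfg <- model@config
  nL <- length(model@layers)
  rule <- cfg$confidence
  uncertain <- seq_len(n)
  exitLayer <- rep(NA_integer_, n)
  history <- vector("list", nL)
  meanHistory <- vector("list", nL)
  for (l in seq_len(nL)) {
    if (!length(uncertain)) {
      history[[l]] <- matrix(NA_real_, n, B)
      meanHistory[[l]] <- matrix(NA_real_, n, B)
      next
    }
    rows <- uncertain
    Xrows <- denseAugment(X[rows, , drop = FALSE],
                          lapply(history[seq_len(l - 1L)], function(h)
                            h[rows, , drop = FALSE]))
    perForest <- lapply(model@layers[[l]]@forests, function(f)
      predictDFN(f, Xrows)$outputs)
    out <- Reduce(`+`, perForest) / length(perForest)
    h <- matrix(NA_real_, n,
                if (isTRUE(cfg$augmentPerForest))
                  B * length(perForest) else B)
    h[rows, ] <- if (isTRUE(cfg$augmentPerForest))
      do.call(cbind, perForest) else out
    history[[l]] <- h
    mh <- matrix(NA_real_, n, B)
    mh[rows, ] <- out
    meanHistory[[l]] <- mh
    g <- gateSamples(out, rule, isFinal = l == nL)
    exitLayer[rows[g$Y]] <- l
    uncertain <- rows[g$X]
  }
  exitLayer[is.na(exitLayer)] <- nL
  yf <- .combineOutputs(model@layerWeights, meanHistory, exitLayer, n, B)
  ci <- decodeOutputs(model@codebook, yf)
  list(class = factor(model@classLevels[ci], levels = model@classLevels),
       classIndex = ci, outputs = yf, exitLayer = exitLayer)
}

setMethod("show", "LaminarLayer", function(object) {
  cat(sprintf("LaminarLayer %d: %d DFNForests\n", object@layerIndex,
              length(object@forests)))
})

setMethod("show", "LaminarModel", function(object) {
  cat(sprintf(
    "LaminarModel: %d classes, %d layer(s), base width %d\n",
    object@codebook@numClasses, length(object@layers), object@baseInputDim))
  for (ly in object@layers)
    cat(sprintf("  layer %d: %d forest(s)\n", ly@layerIndex,
                length(ly@forests)))
  cat("  layer weights:",
      paste(sprintf("%.3f", object@layerWeights), collapse = " "), "\n")
})
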