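#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom stats runif rnorm sd var setNames aggregate
#' @importFrom utils head tail
NULL

#' ExpressionMatrix: a samples-by-genes expression table with a missingness mask
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding two assays:
#' \code{"exprs"} (numeric expression values, genes in rows as usual for
#' Bioconductor containers) and \code{"missing"} (logical mask, \code{TRUE}
#' where a value is absent). The user-facing orientation is samples-in-rows
#' (natural for cross-validation when n << d); accessors transpose on the way
#' out. Missing cells hold \code{NA} in the \code{"exprs"} assay.
#'
#' @seealso [ExpressionMatrix()], [exprsValues()], [missingMask()]
#' @name ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("exprs", "missing") %in% an))
    return("assays 'exprs' and 'missing' are required")
  v <- SummarizedExperiment::assay(object, "exprs")
  m <- SummarizedExperiment::assay(object, "missing")
  if (!is.numeric(v)) return("'exprs' assay must be numeric")
  if (!is.logical(m)) return("'missing' assay must be logical")
  if (!identical(dim(v), dim(m))) return("assay dimensions disagree")
  gid <- rownames(object); sid <- colnames(object)
  if (is.null(gid) || is.null(sid)) return("gene and sample ids are required")
  if (anyDuplicated(gid)) return("duplicate gene ids")
  if (anyDuplicated(sid)) return("duplicate sample ids")
  bad <- !m & (!is.finite(v))
  if (any(bad)) return("non-finite value in a cell not flagged missing")
  TRUE
})

#' FunctionSet: allowed flexible-neuron arities
#'
#' The grammar alphabet for flexible neural trees: the set of neuron arities
#' (e.g. \{+2,+3,+4\}) an internal node may take. Four standard sets (F1-F4)
#' are provided by [fntFunctionSets()] and drive classifier diversity in the
#' laminar ensemble.
#'
#' @slot arities integer vector of allowed arities, all >= 2
#' @slot name short label such as "F1"
#' @name FunctionSet-class
#' @exportClass FunctionSet
setClass("FunctionSet",
  representation(arities = "integer", name = "character"))

setValidity("FunctionSet", function(object) {
  if (length(object@arities) == 0L) return("empty function set")
  if (any(object@arities < 2L)) return("all arities must be >= 2")
  if (anyDuplicated(object@arities)) return("duplicate arities")
  TRUE
})

#' FlexibleNeuralTree: a tree-shaped neural network over input features
#'
#' Internal nodes are flexible neurons +M computing
#' \eqn{\sigma(\sum_j \omega_j I_j + \theta)} over their M children; leaves are
#' input features. Nodes are stored as nested plain lists (fast to recurse
#' over); the S4 wrapper carries the input dimension, grammar, activation and
#' the last fitness (root-mean-square error) assigned during training.
#'
#' @slot root nested node list (see [fntNeuron()], [fntLeaf()])
#' @slot inputDim number of input features d
#' @slot functionSet the [FunctionSet-class] the tree is valid under
#' @slot activation one of "logistic", "gaussian", "relu"
#' @slot fitness numeric(0) or the RMSE fitness of the tree
#' @name FlexibleNeuralTree-class
#' @exportClass FlexibleNeuralTree
setClass("FlexibleNeuralTree",
  representation(root = "list", inputDim = "integer",
                 functionSet = "FunctionSet", activation = "character",
                 fitness = "numeric"))

setValidity("FlexibleNeuralTree", function(object) {
  if (length(object@inputDim) != 1L || object@inputDim < 1L)
    return("inputDim must be a single positive integer")
  if (!object@activation %in% c("logistic", "gaussian", "relu"))
    return("unknown activation")
  if (length(object@fitness) > 1L || (length(object@fitness) == 1L &&
      (is.na(object@fitness) || object@fitness < 0)))
    return("fitness must be empty or a single non-negative number")
  .validateNode(object@root, object@functionSet@arities, object@inputDim,
                topLevel = TRUE)
})

#' BinaryTaskCodebook: M-ary decomposition of an M-class problem
#'
#' Assigns each of M classes a distinct B-bit code with B = ceiling(log2 M);
#' one flexible neural tree predicts each bit. Decoding maps a raw B-vector in
#' (0,1) to the nearest valid code (Euclidean distance, ties to the lowest
#' class index).
#'
#' @slot numClasses M
#' @slot numBits B = ceiling(log2 M)
#' @slot codes M x B 0/1 matrix; row i is the code of class i (binary of i-1)
#' @name BinaryTaskCodebook-class
#' @exportClass BinaryTaskCodebook
setClass("BinaryTaskCodebook",
  representation(numClasses = "integer", numBits = "integer",
                 codes = "matrix"))

setValidity("BinaryTaskCodebook", function(object) {
  M <- object@numClasses; B <- object@numBits
  if (M < 2L) return("need at least two classes")
  if (B != ceiling(log2(M))) return("numBits must equal ceiling(log2(M))")
  if (!identical(dim(object@codes), c(M, B)))
    return("codes must be an M x B matrix")
  if (!all(object@codes %in% c(0, 1))) return("codes must be 0/1")
  if (anyDuplicated(object@codes, MARGIN = 1)) return("codes must be distinct")
  TRUE
})

#' NeuralForest: one cascade level of a DFNForest
#'
#' Holds B flexible neural trees, tree b predicting bit b of the class code.
#'
#' @slot trees list of [FlexibleNeuralTree-class], one per bit
#' @slot functionSet the shared grammar
#' @name NeuralForest-class
#' @exportClass NeuralForest
setClass("NeuralForest",
  representation(trees = "list", functionSet = "FunctionSet"))

setValidity("NeuralForest", function(object) {
  if (length(object@trees) < 1L) return("forest needs at least one tree")
  if (!all(vapply(object@trees, is, logical(1), "FlexibleNeuralTree")))
    return("trees must be FlexibleNeuralTree objects")
  dims <- vapply(object@trees, function(t) t@inputDim, integer(1))
  if (length(unique(dims)) != 1L) return("trees must share input_dim")
  TRUE
})

#' DFNForestModel: a cascade of neural forests for one M-class problem
#'
#' Base classifier of the laminar ensemble: cascade levels of B-tree forests,
#' each level consuming the previous level's outputs concatenated onto the
#' running feature vector, depth chosen automatically from a validation split.
#'
#' @slot levels list of [NeuralForest-class] in cascade order
#' @slot codebook the [BinaryTaskCodebook-class]
#' @slot functionSet grammar shared by every level
#' @slot baseInputDim feature width d fed to level 1
#' @slot valAccuracyTrace validation accuracy after each trained level
#' @name DFNForestModel-class
#' @exportClass DFNForestModel
setClass("DFNForestModel",
  representation(levels = "list", codebook = "BinaryTaskCodebook",
                 functionSet = "FunctionSet", baseInputDim = "integer",
                 valAccuracyTrace = "numeric"))

setValidity("DFNForestModel", function(object) {
  if (length(object@levels) < 1L) return("at least one cascade level required")
  B <- object@codebook@numBits
  d <- object@baseInputDim
  for (l in seq_along(object@levels)) {
    fo <- object@levels[[l]]
    if (!is(fo, "NeuralForest")) return("levels must be NeuralForest objects")
    if (length(fo@trees) != B)
      return(sprintf("level %d has %d trees; expected %d", l,
                     length(fo@trees), B))
    want <- d + (l - 1L) * B
    if (fo@trees[[1]]@inputDim != want)
      return(sprintf("level %d input_dim %d; expected %d (augmentation growth)",
                     l, fo@trees[[1]]@inputDim, want))
  }
  TRUE
})

#' LaminarLayer: one tier of the widening ensemble
#'
#' @slot forests list of [DFNForestModel-class] sharing a base input width
#' @slot layerIndex 1-based tier index
#' @name LaminarLayer-class
#' @exportClass LaminarLayer
setClass("LaminarLayer",
  representation(forests = "list", layerIndex = "integer"))

setValidity("LaminarLayer", function(object) {
  if (length(object@forests) < 1L) return("layer needs at least one forest")
  if (!all(vapply(object@forests, is, logical(1), "DFNForestModel")))
    return("forests must be DFNForestModel objects")
  w <- vapply(object@forests, function(f) f@baseInputDim, integer(1))
  if (length(unique(w)) != 1L)
    return("forests in a layer must share base input width")
  TRUE
})

#' LaminarModel: the full laminar augmented cascading flexible neural forest
#'
#' Layers of DFNForests, widening with depth, with confidence-gated routing
#' and triangular layer weights combining per-layer outputs into the final
#' prediction.
#'
#' @slot layers list of [LaminarLayer-class]
#' @slot codebook shared [BinaryTaskCodebook-class]
#' @slot baseInputDim width d0 of the preprocessed feature vector
#' @slot config the LaminarConfig list used for training
#' @slot layerWeights triangular weights for the configured depth N
#' @slot classLevels class names in codebook order
#' @slot routing training-time routing record (exit layers, per-layer outputs)
#' @name LaminarModel-class
#' @exportClass LaminarModel
setClass("LaminarModel",
  representation(layers = "list", codebook = "BinaryTaskCodebook",
                 baseInputDim = "integer", config = "list",
                 layerWeights = "numeric", classLevels = "character",
                 routing = "list"))

setValidity("LaminarModel", function(object) {
  if (length(object@layers) < 1L) return("at least one layer required")
  if (!all(vapply(object@layers, is, logical(1), "LaminarLayer")))
    return("layers must be LaminarLayer objects")
  w <- object@layerWeights
  if (abs(sum(w) - 1) > 1e-9) return("layer weights must sum to 1")
  if (any(diff(w) <= 0)) return("layer weights must be strictly increasing")
  if (length(object@classLevels) != object@codebook@numClasses)
    return("classLevels must match codebook size")
  TRUE
})
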