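## Flexible neural trees: representation, evaluation, fitness, serialization.
##
## A tree's internal nodes are flexible neurons +M producing
## sigma(sum_j w_j * I_j + theta) over their M children; leaves pass through
## one input feature. Evaluation runs bottom-up and is vectorized over
## samples: each node maps an n x d matrix to an n-vector.

#' Build a FunctionSet
#'
#' @param arities integer vector of allowed neuron arities (each >= 2)
#' @param name short label
#' @return a [FunctionSet-class]
#' @export
functionSet <- function(arities, name = "F") {
  new("FunctionSet", arities = sort(unique(as.integer(arities))),
      name = as.character(name))
}

#' The four standard grammars F1-F4
#'
#' F1 = \{+2,+3,+4\}, F2 = \{+2,+3,+5\}, F3 = \{+2,+4,+5\}, F4 = \{+3,+4,+5\}.
#' Different grammars yield structurally different trees and drive classifier
#' diversity across the laminar ensemble.
#'
#' @return named list of [FunctionSet-class] objects
#' @export
fntFunctionSets <- function() {
  list(F1 = functionSet(c(2, 3, 4), "F1"),
       F2 = functionSet(c(2, 3, 5), "F2"),
       F3 = functionSet(c(2, 4, 5), "F3"),
       F4 = functionSet(c(3, 4, 5), "F4"))
}

#' Node constructors for flexible neural trees
#'
#' Nodes are plain nested lists. A leaf carries a 1-based feature index; a
#' neuron carries weights (one per child), a bias, and its children.
#'
#' @param feature 1-based input feature index
#' @return a node list
#' @export
fntLeaf <- function(feature) {
  list(kind = "leaf", feature = as.integer(feature))
}

#' @rdname fntLeaf
#' @param weights numeric vector, one weight per child
#' @param bias scalar offset theta
#' @param children list of child nodes (length = arity)
#' @export
fntNeuron <- function(weights, bias, children) {
  stopifnot(length(weights) == length(children))
  list(kind = "function", arity = length(children),
       weights = as.numeric(weights), bias = as.numeric(bias),
       children = children)
}

#' Assemble a FlexibleNeuralTree
#'
#' @param root root node (must be a neuron, not a leaf)
#' @param inputDim number of input features
#' @param functionSet a [FunctionSet-class]
#' @param activation "logistic" (default; sigma(x) = 1/(1+exp(-x))),
#'   "gaussian" (exp(-x^2)) or "relu" (max(0,x)). All experiments use
#'   logistic; the others are pluggable alternatives.
#' @param fitness optional RMSE fitness
#' @return a [FlexibleNeuralTree-class]
#' @export
flexibleNeuralTree <- function(root, inputDim, functionSet,
                               activation = "logistic",
                               fitness = numeric(0)) {
  new("FlexibleNeuralTree", root = root, inputDim = as.integer(inputDim),
      functionSet = functionSet, activation = activation,
      fitness = as.numeric(fitness))
}

.validateNode <- function(node, arities, inputDim, topLevel = FALSE) {
  if (!is.list(node) || is.null(node$kind)) return("malformed node")
  if (node$kind == "leaf") {
    if (topLevel) return("root must be a function node")
    if (node$feature < 1L || node$feature > inputDim)
      return(sprintf("leaf feature index %d outside [1,%d]", node$feature,
                     inputDim))
    return(TRUE)
  }
  if (node$kind != "function") return("unknown node kind")
  if (!node$arity %in% arities)
    return(sprintf("arity %d not in function set", node$arity))
  if (length(node$weights) != node$arity || length(node$children) != node$arity)
    return("function node weights/children length must equal arity")
  if (!all(is.finite(node$weights)) || !is.finite(node$bias))
    return("non-finite parameters")
  for (ch in node$children) {
    r <- .validateNode(ch, arities, inputDim)
    if (!isTRUE(r)) return(r)
  }
  TRUE
}

.activation <- function(name) {
  switch(name,
         logistic = function(x) 1 / (1 + exp(-x)),
         gaussian = function(x) exp(-x^2),
         relu = function(x) pmax(0, x),
         stop("unknown activation: ", name))
}

.evalNode <- function(node, X, act) {
  if (node$kind == "leaf") return(X[, node$feature])
  s <- rep.int(node$bias, nrow(X))
  for (j in seq_len(node$arity))
    s <- s + node$weights[j] * .evalNode(node$children[[j]], X, act)
  act(s)
}

#' Evaluate a flexible neural tree
#'
#' Computes outputs bottom-up, leaf to root: a leaf returns its input feature,
#' a neuron returns sigma(sum_j w_j I_j + theta). With the logistic activation
#' the result lies strictly in (0,1).
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @param x a d-vector or an n x d matrix (rows = samples)
#' @return a scalar (vector input) or an n-vector of root outputs
#' @export
evaluateTree <- function(tree, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != tree@inputDim)
    stop(sprintf("input has %d features; tree expects %d", ncol(X),
                 tree@inputDim))
  out <- .evalNode(tree@root, X, .activation(tree@activation))
  if (is.matrix(x)) out else out[[1L]]
}

#' Root-mean-square-error fitness of a tree
#'
#' Fit = sqrt((1/N) * sum_i (y_i - yhat_i)^2) over all N samples; smaller is
#' better. This is the objective minimized by both the structural evolution
#' and the particle swarm parameter tuning.
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @param X n x d matrix
#' @param y n-vector of targets (bit values in \{0,1\} during training)
#' @export
treeFitness <- function(tree, X, y) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("cannot compute fitness on zero samples")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  sqrt(mean((y - evaluateTree(tree, X))^2))
}

.collectFeatures <- function(node) {
  if (node$kind == "leaf") return(node$feature)
  unlist(lapply(node$children, .collectFeatures), use.names = FALSE)
}

#' Input features referenced by a tree's leaves
#'
#' FNTs select features adaptively: only the genes appearing at a leaf enter
#' the computation at all.
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @return sorted unique 1-based feature indices
#' @export
usedFeatures <- function(tree) {
  sort(unique(.collectFeatures(tree@root)))
}

#' Tree shape helpers
#'
#' \code{treeDepth} is the number of neuron levels on the deepest path (a
#' lone-root tree over leaves has depth 1); \code{treeSize} counts all nodes.
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @export
treeDepth <- function(tree) .nodeDepth(tree@root)

.nodeDepth <- function(node) {
  if (node$kind == "leaf") return(0L)
  1L + max(vapply(node$children, .nodeDepth, integer(1)))
}

#' @rdname treeDepth
#' @export
treeSize <- function(tree) .nodeCount(tree@root)

.nodeCount <- function(node) {
  if (node$kind == "leaf") return(1L)
  1L + sum(vapply(node$children, .nodeCount, integer(1)))
}

## --- parameter vector <-> tree (preorder: weights then bias per neuron) ---

.collectParams <- function(node) {
  if (node$kind == "leaf") return(numeric(0))
  c(node$weights, node$bias,
    unlist(lapply(node$children, .collectParams), use.names = FALSE))
}

#' Flatten / restore a tree's parameters
#'
#' Parameters are laid out in preorder, each neuron contributing its weights
#' followed by its bias. The flattened vector is the particle position the
#' swarm optimizer moves through.
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @export
flattenParams <- function(tree) .collectParams(tree@root)

.injectParams <- function(node, params, pos) {
  if (node$kind == "leaf") return(list(node = node, pos = pos))
  m <- node$arity
  node$weights <- params[pos:(pos + m - 1L)]
  node$bias <- params[pos + m]
  pos <- pos + m + 1L
  for (j in seq_len(m)) {
    r <- .injectParams(node$children[[j]], params, pos)
    node$children[[j]] <- r$node
    pos <- r$pos
  }
  list(node = node, pos = pos)
}

#' @rdname flattenParams
#' @param params numeric vector as produced by \code{flattenParams}
#' @export
setTreeParams <- function(tree, params) {
  r <- .injectParams(tree@root, params, 1L)
  if (r$pos != length(params) + 1L)
    stop("parameter vector length does not match tree")
  tree@root <- r$node
  tree@fitness <- numeric(0)
  tree
}

## --- JSON serialization -------------------------------------------------

.nodeToList <- function(node) {
  if (node$kind == "leaf")
    return(list(kind = "leaf", feature = node$feature))
  list(kind = "function", arity = node$arity,
       weights = as.list(node$weights), bias = node$bias,
       children = lapply(node$children, .nodeToList))
}

.nodeFromList <- function(lst) {
  if (is.null(lst$kind)) stop("malformed tree record: node without kind")
  if (lst$kind == "leaf") {
    if (is.null(lst$feature)) stop("malformed tree record: leaf without feature")
    return(fntLeaf(lst$feature))
  }
  if (lst$kind != "function") stop("malformed tree record: unknown kind")
  if (is.null(lst$weights) || is.null(lst$bias) || is.null(lst$children))
    stop("malformed tree record: incomplete function node")
  fntNeuron(unlist(lst$weights), lst$bias,
            lapply(lst$children, .nodeFromList))
}

.treeToList <- function(tree) {
  list(inputDim = tree@inputDim,
       activation = tree@activation,
       functionSet = list(arities = as.list(as.integer(tree@functionSet@arities)),
                          name = tree@functionSet@name),
       fitness = if (length(tree@fitness)) tree@fitness else NULL,
       root = .nodeToList(tree@root))
}

.treeFromList <- function(lst) {
  if (is.null(lst$inputDim) || is.null(lst$root) || is.null(lst$functionSet))
    stop("malformed tree record")
  flexibleNeuralTree(
    .nodeFromList(lst$root), lst$inputDim,
    functionSet(unlist(lst$functionSet$arities), lst$functionSet$name),
    activation = lst$activation,
    fitness = if (is.null(lst$fitness)) numeric(0) else lst$fitness)
}

#' Serialize a tree to JSON / parse it back
#'
#' Round-trips structure and parameters exactly (full double precision).
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @return \code{serializeTree}: a JSON string; \code{deserializeTree}: a tree
#' @export
serializeTree <- function(tree) {
  as.character(jsonlite::toJSON(.treeToList(tree), auto_unbox = TRUE,
                                digits = I(17)))
}

#' @rdname serializeTree
#' @param text JSON produced by \code{serializeTree}
#' @export
deserializeTree <- function(text) {
  lst <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("malformed tree record: ",
                                           conditionMessage(e)))
  tree <- .treeFromList(lst)
  validObject(tree)
  tree
}

setMethod("show", "FlexibleNeuralTree", function(object) {
  cat(sprintf(
    "FlexibleNeuralTree: %d nodes, depth %d, %d/%d features used, grammar %s%s\n",
    treeSize(object), treeDepth(object), length(usedFeatures(object)),
    object@inputDim, object@functionSet@name,
    if (length(object@fitness)) sprintf(", fitness %.4f", object@fitness)
    else ""))
})

setMethod("show", "FunctionSet", function(object) {
  cat(sprintf("FunctionSet %s: {%s}\n", object@name,
              paste0("+", object@arities, collapse = ",")))
})
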