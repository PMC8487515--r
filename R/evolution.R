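## Structure search and parameter tuning for flexible neural trees:
## grammar-guided genetic programming (tournament selection, subtree
## crossover, mutation, elitism) alternating with particle swarm optimization
## of the flattened weight/bias vector.
##
## The grammar is the minimal one generating FNT shapes:
##   Node -> +m(Node, ..., Node)   for m in the function set
##   Node -> x_i                   for i in 1..d
## and every operator below preserves it.

#' Evolution (GGGP) configuration
#'
#' Defaults follow the published setup: population 50, crossover probability
#' 0.4, mutation probability 0.01. Selection is tournament (size 3) with one
#' elite; trees are bounded to depth 5 and 200 nodes; evolution stops at
#' \code{maxGenerations} or after \code{patience} generations without
#' improvement.
#'
#' @param populationSize,crossoverProb,mutationProb core GA settings
#' @param maxGenerations,patience termination controls
#' @param tournamentSize,elitism selection settings
#' @param maxDepth,maxNodes structural bounds on trees
#' @param seed optional integer; when given, [evolveStructure()] seeds the RNG
#' @return a classed settings list
#' @export
evolutionConfig <- function(populationSize = 50L, crossoverProb = 0.4,
                            mutationProb = 0.01, maxGenerations = 30L,
                            tournamentSize = 3L, elitism = 1L,
                            patience = 10L, maxDepth = 5L, maxNodes = 200L,
                            seed = NULL) {
  stopifnot(populationSize >= 1, crossoverProb >= 0, crossoverProb <= 1,
            mutationProb >= 0, mutationProb <= 1, maxGenerations >= 1,
            tournamentSize >= 1, elitism >= 0, maxDepth >= 1, maxNodes >= 3)
  structure(list(populationSize = as.integer(populationSize),
                 crossoverProb = crossoverProb, mutationProb = mutationProb,
                 maxGenerations = as.integer(maxGenerations),
                 tournamentSize = as.integer(tournamentSize),
                 elitism = as.integer(elitism), patience = as.integer(patience),
                 maxDepth = as.integer(maxDepth),
                 maxNodes = as.integer(maxNodes), seed = seed),
            class = "EvolutionConfig")
}

#' Particle swarm (PSO) configuration
#'
#' Learning factors c1 = c2 = 2 and velocity clamp vmax = 2 follow the
#' published setup; inertia 0.7, swarm size 30 and the iteration budgets are
#' package defaults. Positions (tree weights and biases) are clamped to
#' \code{[-paramBound, paramBound]}.
#'
#' @param c1,c2 cognitive/social learning factors
#' @param vmax velocity clamp (componentwise)
#' @param swarmSize number of particles
#' @param inertia velocity inertia weight
#' @param maxIters iterations for the per-generation tuning pass
#' @param finalIters iterations for the final pass on the returned tree
#' @param paramBound box constraint on positions
#' @param seed optional integer
#' @return a classed settings list
#' @export
psoConfig <- function(c1 = 2.0, c2 = 2.0, vmax = 2.0, swarmSize = 30L,
                      inertia = 0.7, maxIters = 50L, finalIters = 200L,
                      paramBound = 5.0, seed = NULL) {
  stopifnot(vmax > 0, swarmSize >= 2, paramBound > 0, maxIters >= 1)
  structure(list(c1 = c1, c2 = c2, vmax = vmax,
                 swarmSize = as.integer(swarmSize), inertia = inertia,
                 maxIters = as.integer(maxIters),
                 finalIters = as.integer(finalIters),
                 paramBound = paramBound, seed = seed),
            class = "PSOConfig")
}

## budget$n counts node slots still unreserved; a neuron reserves its m
## children up front, so the finished tree can never exceed the allowance.
.growNode <- function(arities, d, depth, maxDepth, budget, pLeaf = 0.45,
                      forceFunction = FALSE) {
  feasible <- arities[arities <= budget$n]
  canBranch <- depth <= maxDepth && length(feasible) > 0L
  if (forceFunction && !canBranch)
    stop("cannot grow a function node within the given bounds")
  if (!forceFunction && (!canBranch || stats::runif(1) < pLeaf))
    return(fntLeaf(sample.int(d, 1L)))
  m <- feasible[[sample.int(length(feasible), 1L)]]
  budget$n <- budget$n - m
  children <- vector("list", m)
  for (j in seq_len(m))
    children[[j]] <- .growNode(arities, d, depth + 1L, maxDepth, budget, pLeaf)
  fntNeuron(stats::runif(m, -1, 1), stats::runif(1, -1, 1), children)
}

#' Draw a random grammar-valid tree
#'
#' The root is always a neuron; arities are drawn from the function set,
#' recursion is bounded by \code{maxDepth} (neuron levels) and
#' \code{maxNodes}, and parameters are initialized uniformly in [-1, 1].
#' Uses the current RNG stream (seed at the caller).
#'
#' @param functionSet a [FunctionSet-class]
#' @param inputDim number of input features d
#' @param maxDepth,maxNodes structural bounds
#' @return a [FlexibleNeuralTree-class]
#' @export
randomTree <- function(functionSet, inputDim, maxDepth = 5L,
                       maxNodes = 200L) {
  budget <- new.env(parent = emptyenv())
  budget$n <- as.integer(maxNodes) - 1L # the root takes one slot
  root <- .growNode(functionSet@arities, inputDim, 1L, maxDepth, budget,
                    forceFunction = TRUE)
  flexibleNeuralTree(root, inputDim, functionSet)
}

## enumerate node paths; a path is the integer child-index route from the root
.nodePaths <- function(node, prefix = integer(0)) {
  out <- list(prefix)
  if (node$kind == "function")
    for (j in seq_len(node$arity))
      out <- c(out, .nodePaths(node$children[[j]], c(prefix, j)))
  out
}

.getSubtree <- function(node, path) {
  for (j in path) node <- node$children[[j]]
  node
}

.setSubtree <- function(node, path, sub) {
  if (!length(path)) return(sub)
  node$children[[path[1L]]] <-
    .setSubtree(node$children[[path[1L]]], path[-1L], sub)
  node
}

.treeOk <- function(root, maxDepth, maxNodes) {
  root$kind == "function" && .nodeDepth(root) <= maxDepth &&
    .nodeCount(root) <= maxNodes
}

#' Subtree crossover
#'
#' Swaps two uniformly chosen subtrees between the parents. Offspring that
#' violate the grammar (leaf at the root) or the depth/size bounds trigger a
#' resampled swap point; after \code{retries} failures the parents are
#' returned unchanged.
#'
#' @param a,b parent trees sharing function set and input dimension
#' @param maxDepth,maxNodes structural bounds
#' @param retries swap-point resampling budget
#' @return list of two offspring trees
#' @export
crossoverTrees <- function(a, b, maxDepth = 5L, maxNodes = 200L,
                           retries = 10L) {
  stopifnot(identical(a@functionSet@arities, b@functionSet@arities),
            a@inputDim == b@inputDim)
  pa <- .nodePaths(a@root); pb <- .nodePaths(b@root)
  for (r in seq_len(retries)) {
    i <- sample.int(length(pa), 1L); j <- sample.int(length(pb), 1L)
    sa <- .getSubtree(a@root, pa[[i]]); sb <- .getSubtree(b@root, pb[[j]])
    ra <- .setSubtree(a@root, pa[[i]], sb)
    rb <- .setSubtree(b@root, pb[[j]], sa)
    if (.treeOk(ra, maxDepth, maxNodes) && .treeOk(rb, maxDepth, maxNodes)) {
      ta <- a; ta@root <- ra; ta@fitness <- numeric(0)
      tb <- b; tb@root <- rb; tb@fitness <- numeric(0)
      return(list(ta, tb))
    }
  }
  list(a, b)
}

#' Mutate a tree
#'
#' One of three grammar-preserving edits, chosen uniformly: replace a random
#' subtree by a fresh random subtree; re-draw a random leaf's feature index;
#' change a random neuron's arity within the function set (new children are
#' random leaves, surplus children are dropped).
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @param maxDepth,maxNodes structural bounds
#' @return the mutated tree
#' @export
mutateTree <- function(tree, maxDepth = 5L, maxNodes = 200L) {
  arities <- tree@functionSet@arities
  d <- tree@inputDim
  paths <- .nodePaths(tree@root)
  op <- sample(c("subtree", "leaf", "arity"), 1L)
  root <- tree@root
  if (op == "leaf") {
    leafPaths <- Filter(function(p) .getSubtree(root, p)$kind == "leaf", paths)
    if (length(leafPaths)) {
      p <- leafPaths[[sample.int(length(leafPaths), 1L)]]
      root <- .setSubtree(root, p, fntLeaf(sample.int(d, 1L)))
    }
  } else if (op == "arity") {
    fnPaths <- Filter(function(p) .getSubtree(root, p)$kind == "function",
                      paths)
    p <- fnPaths[[sample.int(length(fnPaths), 1L)]]
    nd <- .getSubtree(root, p)
    m2 <- arities[[sample.int(length(arities), 1L)]]
    if (m2 > nd$arity) {
      extra <- m2 - nd$arity
      nd$children <- c(nd$children,
                       lapply(seq_len(extra),
                              function(i) fntLeaf(sample.int(d, 1L))))
      nd$weights <- c(nd$weights, stats::runif(extra, -1, 1))
    } else if (m2 < nd$arity) {
      nd$children <- nd$children[seq_len(m2)]
      nd$weights <- nd$weights[seq_len(m2)]
    }
    nd$arity <- m2
    cand <- .setSubtree(root, p, nd)
    if (.treeOk(cand, maxDepth, maxNodes)) root <- cand
  } else {
    p <- paths[[sample.int(length(paths), 1L)]]
    depthHere <- length(p) + 1L
    budget <- new.env(parent = emptyenv())
    budget$n <- max(as.integer(maxNodes) - .nodeCount(root), max(arities) + 1L)
    sub <- .growNode(arities, d, depthHere, maxDepth, budget)
    cand <- .setSubtree(root, p, sub)
    if (.treeOk(cand, maxDepth, maxNodes)) root <- cand
  }
  tree@root <- root
  tree@fitness <- numeric(0)
  tree
}

.tournament <- function(fit, k) {
  cand <- sample.int(length(fit), min(k, length(fit)))
  cand[which.min(fit[cand])]
}

#' Global-best particle swarm minimization
#'
#' Standard gbest PSO on a p-dimensional box:
#' v <- inertia*v + c1*r1*(pbest - x) + c2*r2*(gbest - x), with v clamped
#' componentwise to +/- vmax and positions to +/- paramBound. When
#' \code{init} is supplied it seeds one particle, so the returned value never
#' exceeds \code{fn(init)}.
#'
#' @param fn objective function of a numeric p-vector, to minimize
#' @param p number of dimensions
#' @param cfg a [psoConfig()]
#' @param iters iteration count (defaults to \code{cfg$maxIters})
#' @param init optional starting position seeded into the swarm
#' @return list with \code{par} (best position) and \code{value}
#' @export
psoMinimize <- function(fn, p, cfg = psoConfig(), iters = cfg$maxIters,
                        init = NULL) {
  stopifnot(p >= 1L)
  S <- cfg$swarmSize
  pos <- matrix(stats::runif(S * p, -1, 1), S, p)
  if (!is.null(init))
    pos[1L, ] <- pmin(pmax(init, -cfg$paramBound), cfg$paramBound)
  vel <- matrix(stats::runif(S * p, -cfg$vmax, cfg$vmax) * 0.25, S, p)
  pfit <- apply(pos, 1L, fn)
  pbest <- pos
  g <- which.min(pfit)
  gbest <- pbest[g, ]; gfit <- pfit[g]
  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(S * p), S, p)
    r2 <- matrix(stats::runif(S * p), S, p)
    vel <- cfg$inertia * vel + cfg$c1 * r1 * (pbest - pos) +
      cfg$c2 * r2 * (matrix(gbest, S, p, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, -cfg$vmax), cfg$vmax)
    pos <- pmin(pmax(pos + vel, -cfg$paramBound), cfg$paramBound)
    f <- apply(pos, 1L, fn)
    imp <- f < pfit
    pbest[imp, ] <- pos[imp, , drop = FALSE]
    pfit[imp] <- f[imp]
    if (min(pfit) < gfit) {
      g <- which.min(pfit)
      gbest <- pbest[g, ]; gfit <- pfit[g]
    }
  }
  list(par = gbest, value = gfit)
}

#' Particle swarm optimization of a tree's parameters
#'
#' Runs [psoMinimize()] on the flattened weight/bias vector under the RMSE
#' fitness. The current tree parameters seed one particle, so the returned
#' fitness never exceeds the input tree's fitness.
#'
#' @param tree a [FlexibleNeuralTree-class]
#' @param X n x d training matrix
#' @param y n-vector of targets
#' @param cfg a [psoConfig()]
#' @param iters iteration count (defaults to \code{cfg$maxIters})
#' @return the tree carrying the best parameters found, fitness slot set
#' @export
psoOptimize <- function(tree, X, y, cfg = psoConfig(), iters = cfg$maxIters) {
  X <- as.matrix(X)
  p0 <- flattenParams(tree)
  if (length(p0) == 0L) return(tree)
  obj <- function(v) treeFitness(setTreeParams(tree, v), X, y)
  r <- psoMinimize(obj, length(p0), cfg, iters, init = p0)
  out <- setTreeParams(tree, r$par)
  out@fitness <- r$value
  out
}

#' Evolve a flexible neural tree for one binary task
#'
#' Alternates the two search processes: each generation applies tournament
#' selection, subtree crossover, mutation and elitism to the structures, then
#' runs a PSO parameter-tuning pass on the generation's best individual; a
#' longer final PSO pass polishes the best tree seen before it is returned.
#' The best-so-far fitness is non-increasing across generations (elitism plus
#' monotone PSO).
#'
#' @param X n x d training matrix
#' @param y n-vector of binary targets in \{0,1\} (fit as regression under the
#'   RMSE fitness)
#' @param functionSet a [FunctionSet-class]
#' @param evoCfg an [evolutionConfig()]
#' @param psoCfg a [psoConfig()]
#' @return the best [FlexibleNeuralTree-class], fitness slot set; the
#'   attribute \code{"fitnessTrace"} records the (non-increasing) best-so-far
#'   fitness after initialization and after each generation
#' @export
evolveStructure <- function(X, y, functionSet, evoCfg = evolutionConfig(),
                            psoCfg = psoConfig()) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || length(y) != nrow(X))
    stop("empty data or target length mismatch")
  if (!is.null(evoCfg$seed)) set.seed(evoCfg$seed)
  P <- evoCfg$populationSize
  d <- ncol(X)
  pop <- lapply(seq_len(P), function(i)
    randomTree(functionSet, d, evoCfg$maxDepth, evoCfg$maxNodes))
  fit <- vapply(pop, function(t) treeFitness(t, X, y), numeric(1))
  bestIdx <- which.min(fit)
  best <- pop[[bestIdx]]; bestFit <- fit[bestIdx]
  trace <- bestFit # best-so-far after initialization, then per generation
  stale <- 0L
  for (gen in seq_len(evoCfg$maxGenerations)) {
    ord <- order(fit)
    newPop <- pop[ord[seq_len(min(evoCfg$elitism, P))]]
    while (length(newPop) < P) {
      i1 <- .tournament(fit, evoCfg$tournamentSize)
      i2 <- .tournament(fit, evoCfg$tournamentSize)
      off <- if (stats::runif(1) < evoCfg$crossoverProb)
        crossoverTrees(pop[[i1]], pop[[i2]], evoCfg$maxDepth, evoCfg$maxNodes)
      else list(pop[[i1]], pop[[i2]])
      off <- lapply(off, function(t)
        if (stats::runif(1) < evoCfg$mutationProb)
          mutateTree(t, evoCfg$maxDepth, evoCfg$maxNodes) else t)
      newPop <- c(newPop, off)
    }
    pop <- newPop[seq_len(P)]
    fit <- vapply(pop, function(t) treeFitness(t, X, y), numeric(1))
    ## parameter-optimization pass on this generation's elite
    ib <- which.min(fit)
    tuned <- psoOptimize(pop[[ib]], X, y, psoCfg, iters = psoCfg$maxIters)
    if (tuned@fitness <= fit[ib]) {
      pop[[ib]] <- tuned
      fit[ib] <- tuned@fitness
    }
    if (min(fit) < bestFit) {
      bestFit <- min(fit)
      best <- pop[[which.min(fit)]]
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    trace <- c(trace, bestFit)
    if (stale >= evoCfg$patience) break
  }
  final <- psoOptimize(best, X, y, psoCfg, iters = psoCfg$finalIters)
  out <- if (length(final@fitness) && final@fitness <= bestFit) final
  else { best@fitness <- bestFit; best }
  attr(out, "fitnessTrace") <- trace
  out
}
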