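## Synthetic expression-like data with known structure, so that every stage
## of the pipeline is testable without downloads. Class-conditional Gaussian
## model: a minority of informative genes carries per-class mean shifts; all
## other genes are pure noise; optional missingness exercises preprocessing.

## distinct +/-1 shift patterns, one row per class
.classPatterns <- function(M, nInformative) {
  repeat {
    pat <- matrix(sample(c(-1, 1), M * nInformative, replace = TRUE),
                  M, nInformative)
    if (nInformative == 0L || !anyDuplicated(pat, MARGIN = 1)) return(pat)
  }
}

#' Generate class-structured expression-like data
#'
#' Samples are drawn from class-conditional Gaussians: every gene has noise
#' standard deviation \code{noiseSd}; each of \code{nInformative} randomly
#' placed informative genes additionally shifts its mean by
#' \code{effectSize * noiseSd} times a class-specific +/-1 pattern (patterns
#' are pairwise distinct across classes). Missing cells are injected
#' uniformly at rate \code{missingRate}. With \code{logNormal = TRUE} the
#' values are exponentiated onto a positive, skewed scale to exercise the
#' normalization step.
#'
#' @param nSamples,nGenes data dimensions (small n, large d is the regime of
#'   interest)
#' @param nClasses number of classes M
#' @param nInformative number of signal-carrying genes
#' @param effectSize per-class mean shift in noise-SD units (default 2.0)
#' @param noiseSd noise standard deviation (default 1.0)
#' @param missingRate fraction of cells set missing (default 0.02)
#' @param classProportions class mixing proportions (default equal)
#' @param logNormal if TRUE, values are exp-transformed (pre-normalization
#'   scale)
#' @param seed optional integer seed
#' @return list with \code{matrix} (an [ExpressionMatrix-class]),
#'   \code{labels} (named factor) and \code{truth} (informative gene ids,
#'   class shift patterns, generator settings)
#' @export
generateClassificationData <- function(nSamples = 200L, nGenes = 50L,
                                       nClasses = 4L, nInformative = 10L,
                                       effectSize = 2.0, noiseSd = 1.0,
                                       missingRate = 0.02,
                                       classProportions = NULL,
                                       logNormal = FALSE, seed = NULL) {
  nSamples <- as.integer(nSamples); nGenes <- as.integer(nGenes)
  nClasses <- as.integer(nClasses); nInformative <- as.integer(nInformative)
  if (nInformative > nGenes) stop("nInformative cannot exceed nGenes")
  if (nClasses < 2L) stop("need at least 2 classes")
  if (is.null(classProportions))
    classProportions <- rep(1 / nClasses, nClasses)
  if (length(classProportions) != nClasses ||
      abs(sum(classProportions) - 1) > 1e-8)
    stop("classProportions must have one entry per class and sum to 1")
  counts <- floor(classProportions * nSamples)
  rem <- nSamples - sum(counts)
  if (rem > 0L) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  if (any(counts == 0L)) stop("a class received zero samples; spec infeasible")
  if (!is.null(seed)) set.seed(seed)
  classNames <- paste0("class", seq_len(nClasses))
  yIdx <- rep(seq_len(nClasses), counts)
  infGenes <- sort(sample.int(nGenes, nInformative))
  pat <- .classPatterns(nClasses, nInformative)
  v <- matrix(stats::rnorm(nSamples * nGenes, sd = noiseSd), nSamples, nGenes)
  if (nInformative > 0L)
    v[, infGenes] <- v[, infGenes] +
      effectSize * noiseSd * pat[yIdx, , drop = FALSE]
  if (logNormal) v <- exp(2 + v)
  mask <- matrix(stats::runif(nSamples * nGenes) < missingRate,
                 nSamples, nGenes)
  sampleIds <- sprintf("sample_%03d", seq_len(nSamples))
  geneIds <- sprintf("gene_%04d", seq_len(nGenes))
  v[mask] <- NA_real_
  em <- ExpressionMatrix(v, sampleIds = sampleIds, geneIds = geneIds,
                         missingMask = mask)
  labels <- factor(classNames[yIdx], levels = classNames)
  names(labels) <- sampleIds
  list(matrix = em, labels = labels,
       truth = list(informativeGenes = geneIds[infGenes],
                    informativeIndex = infGenes, patterns = pat,
                    effectSize = effectSize, noiseSd = noiseSd,
                    missingRate = missingRate, classLevels = classNames))
}

#' The worked confidence-gating example
#'
#' Five scalar layer outputs \{0.07, 0.35, 0.52, 0.83, 0.95\} with the
#' default confidence region [0, 0.1] U [0.9, 1]: two samples (0.07, 0.95)
#' are confident, three are not; at the final layer the 0.5 threshold
#' classifies all five. Returned as a fixture for reuse in tests and
#' examples.
#'
#' @return list with \code{outputs} (numeric 5-vector) and \code{rule}
#'   (a [confidenceRule()])
#' @export
workedExampleFixture <- function() {
  list(outputs = c(0.07, 0.35, 0.52, 0.83, 0.95),
       rule = confidenceRule())
}
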