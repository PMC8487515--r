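## Expression-matrix IO and preprocessing: missingness filtering, KNN
## imputation, z-score normalization (population variance).

.naTokens <- c("", "na", "nan", "null")

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, samples in rows, genes in columns. \code{NA}
#'   cells are taken as missing unless \code{missingMask} is supplied.
#' @param sampleIds,geneIds unique identifiers; default to the dimnames.
#' @param missingMask logical matrix, same shape as \code{values}, \code{TRUE}
#'   where a measurement is absent.
#' @return an [ExpressionMatrix-class]
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' em <- ExpressionMatrix(m)
#' exprsValues(em)
#' @export
ExpressionMatrix <- function(values, sampleIds = rownames(values),
                             geneIds = colnames(values), missingMask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleIds))
    sampleIds <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(geneIds))
    geneIds <- paste0("gene_", seq_len(ncol(values)))
  if (is.null(missingMask)) missingMask <- is.na(values)
  missingMask <- as.matrix(missingMask)
  if (!identical(dim(values), dim(missingMask)))
    stop("values and missingMask dimensions disagree")
  values[missingMask] <- NA_real_
  ex <- t(values); mm <- t(missingMask)
  dimnames(ex) <- dimnames(mm) <- list(as.character(geneIds),
                                       as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = ex, missing = mm))
  new("ExpressionMatrix", se)
}

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprsValues", "ExpressionMatrix", function(x)
  t(SummarizedExperiment::assay(x, "exprs")))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("missingMask", "ExpressionMatrix", function(x)
  t(SummarizedExperiment::assay(x, "missing")))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

setMethod("show", "ExpressionMatrix", function(object) {
  nm <- sum(SummarizedExperiment::assay(object, "missing"))
  cat(sprintf("ExpressionMatrix: %d samples x %d genes (%d missing cells)\n",
              ncol(object), nrow(object), nm))
})

#' Preprocessing configuration
#'
#' @param missingnessThreshold samples with a missing fraction strictly above
#'   this are removed (default 0.20, the "more than 20% missing" rule).
#' @param knnK number of nearest-neighbour samples for imputation (default 5;
#'   clamped to the number of available donors).
#' @param zeroVariancePolicy what to do with constant genes at normalization:
#'   \code{"set_zero"} keeps the column as all zeros (stable dimensionality
#'   across folds), \code{"drop_gene"} removes it.
#' @return a classed list of settings
#' @export
preprocessConfig <- function(missingnessThreshold = 0.20, knnK = 5L,
                             zeroVariancePolicy = c("set_zero", "drop_gene")) {
  zeroVariancePolicy <- match.arg(zeroVariancePolicy)
  stopifnot(missingnessThreshold >= 0, missingnessThreshold <= 1, knnK >= 1)
  structure(list(missingnessThreshold = missingnessThreshold,
                 knnK = as.integer(knnK),
                 zeroVariancePolicy = zeroVariancePolicy),
            class = "PreprocessConfig")
}

.isMissingToken <- function(x) {
  is.na(x) | tolower(trimws(x)) %in% .naTokens
}

.sepForPath <- function(path) if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","

#' Read a delimited expression matrix
#'
#' Expects one header row and one id column. Canonical orientation is
#' samples-in-rows (header = gene ids, first column = sample id); files with
#' genes in rows are declared via \code{orientation = "genes"} and transposed
#' on read. Empty cells and the tokens \code{NA}, \code{NaN}, \code{null}
#' (case-insensitive) are treated as missing.
#'
#' @param path CSV/TSV file
#' @param orientation \code{"samples"} (rows are samples) or \code{"genes"}
#' @return an [ExpressionMatrix-class] with samples in rows
#' @export
readExpressionMatrix <- function(path, orientation = c("samples", "genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = TRUE, colClasses = "character",
                        data.table = FALSE, na.strings = NULL)),
    error = function(e) stop("parse error reading '", path, "': ",
                             conditionMessage(e)))
  if (NROW(dt) == 0L || NCOL(dt) < 2L)
    stop("parse error: '", path, "' has no data rows or no value columns")
  rowIds <- as.character(dt[[1]])
  colIds <- colnames(dt)[-1]
  if (anyDuplicated(rowIds))
    stop("duplicate row ids: ", paste(rowIds[duplicated(rowIds)], collapse = ", "))
  if (anyDuplicated(colIds))
    stop("duplicate header ids: ", paste(colIds[duplicated(colIds)], collapse = ", "))
  raw <- as.matrix(dt[, -1, drop = FALSE])
  miss <- matrix(.isMissingToken(raw), nrow(raw), ncol(raw))
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(!miss & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 raw[bad[1, 1], bad[1, 2]], rowIds[bad[1, 1]],
                 colIds[bad[1, 2]]))
  num[miss] <- NA_real_
  if (orientation == "genes") {
    ExpressionMatrix(t(num), sampleIds = colIds, geneIds = rowIds,
                     missingMask = t(miss))
  } else {
    ExpressionMatrix(num, sampleIds = rowIds, geneIds = colIds,
                     missingMask = miss)
  }
}

#' Write an ExpressionMatrix to CSV/TSV (samples in rows; missing cells as NA)
#'
#' @param x an [ExpressionMatrix-class]
#' @param path output file; extension picks the delimiter (.tsv/.txt = tab)
#' @export
writeExpressionMatrix <- function(x, path) {
  v <- exprsValues(x)
  v[missingMask(x)] <- NA_real_
  df <- data.frame(sample_id = sampleIds(x), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", geneIds(x))
  data.table::fwrite(df, path, sep = .sepForPath(path), na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write a two-column sample label file (sample_id,label)
#'
#' @param path CSV/TSV with columns sample_id and label
#' @return a named factor: names are sample ids, levels the sorted class names
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("label file needs columns sample_id,label")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in label file")
  y <- factor(as.character(dt[[2]]))
  if (nlevels(y) < 2L) stop("need at least two classes")
  names(y) <- ids
  y
}

#' @rdname readLabels
#' @param y named factor of labels
#' @export
writeLabels <- function(y, path) {
  data.table::fwrite(data.frame(sample_id = names(y),
                                label = as.character(y)),
                     path, sep = .sepForPath(path), quote = FALSE)
  invisible(path)
}

#' Drop samples exceeding the missingness threshold
#'
#' A sample is removed iff its fraction of missing cells is strictly greater
#' than \code{cfg$missingnessThreshold} ("more than 20% missing" by default);
#' a sample at exactly the threshold is retained. Order is preserved.
#'
#' @param x an [ExpressionMatrix-class]
#' @param cfg a [preprocessConfig()]
#' @export
filterSamplesByMissingness <- function(x, cfg = preprocessConfig()) {
  frac <- rowMeans(missingMask(x))
  keep <- frac <= cfg$missingnessThreshold
  if (!any(keep))
    stop("all samples exceed the missingness threshold; dataset unusable")
  ExpressionMatrix(exprsValues(x)[keep, , drop = FALSE],
                   sampleIds = sampleIds(x)[keep], geneIds = geneIds(x),
                   missingMask = missingMask(x)[keep, , drop = FALSE])
}

#' KNN imputation of missing expression values
#'
#' Each missing cell (sample i, gene g) is replaced by the mean of gene g over
#' the k samples nearest to i among those with g observed. Distance between
#' two samples is the root mean square difference over their mutually observed
#' genes (i.e. Euclidean distance scaled by the number of shared genes), so
#' samples with different missingness patterns remain comparable. k is clamped
#' to the number of available donor samples. Observed cells are never altered.
#'
#' @param x an [ExpressionMatrix-class]
#' @param cfg a [preprocessConfig()]; \code{knnK} is the neighbour count
#' @return an [ExpressionMatrix-class] with an all-false missing mask
#' @export
imputeKNN <- function(x, cfg = preprocessConfig()) {
  v <- exprsValues(x); m <- missingMask(x)
  if (!any(m))
    return(x)
  n <- nrow(v)
  allMissing <- colSums(!m) == 0L
  if (any(allMissing))
    stop("gene(s) missing in every sample: ",
         paste(geneIds(x)[allMissing], collapse = ", "))
  obs <- !m
  ## pairwise RMS distance over mutually observed genes
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { D[i, j] <- 0; next }
      sh <- obs[i, ] & obs[j, ]
      ns <- sum(sh)
      if (ns > 0L)
        D[i, j] <- sqrt(sum((v[i, sh] - v[j, sh])^2) / ns)
    }
  }
  out <- v
  for (i in seq_len(n)) {
    missGenes <- which(m[i, ])
    if (!length(missGenes)) next
    ord <- order(D[i, -i]) # stable: ties resolved by sample index
    donors <- seq_len(n)[-i][ord]
    for (g in missGenes) {
      avail <- donors[obs[donors, g]]
      k <- min(cfg$knnK, length(avail))
      if (k == 0L)
        stop("no donor sample observes gene ", geneIds(x)[g])
      out[i, g] <- mean(v[avail[seq_len(k)], g])
    }
  }
  ExpressionMatrix(out, sampleIds = sampleIds(x), geneIds = geneIds(x),
                   missingMask = matrix(FALSE, n, ncol(v)))
}

#' Per-gene z-score normalization
#'
#' Each gene column f is transformed to (f - E(f)) / sqrt(Var(f)) using the
#' population variance (divide by n). Requires a fully observed matrix. Genes
#' with zero variance are set to all zeros (\code{"set_zero"}) or removed
#' (\code{"drop_gene"}).
#'
#' @param x an [ExpressionMatrix-class] with no missing values
#' @param cfg a [preprocessConfig()]
#' @export
zscoreNormalize <- function(x, cfg = preprocessConfig()) {
  if (any(missingMask(x)))
    stop("missing values remain; impute before normalizing")
  v <- exprsValues(x)
  mu <- colMeans(v)
  va <- colMeans(sweep(v, 2, mu)^2) # population variance
  zero <- va < .Machine$double.eps
  sdv <- sqrt(va)
  sdv[zero] <- 1
  z <- sweep(sweep(v, 2, mu), 2, sdv, "/")
  if (any(zero)) {
    if (cfg$zeroVariancePolicy == "set_zero") {
      z[, zero] <- 0
    } else {
      z <- z[, !zero, drop = FALSE]
    }
  }
  ExpressionMatrix(z, sampleIds = sampleIds(x), geneIds = colnames(z),
                   missingMask = matrix(FALSE, nrow(z), ncol(z)))
}

#' Full preprocessing pipeline: filter, impute, normalize
#'
#' @param x an [ExpressionMatrix-class]
#' @param cfg a [preprocessConfig()]
#' @export
preprocessExpression <- function(x, cfg = preprocessConfig()) {
  zscoreNormalize(imputeKNN(filterSamplesByMissingness(x, cfg), cfg), cfg)
}
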