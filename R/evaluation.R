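## Evaluation: macro-averaged metrics, repeated stratified k-fold
## cross-validation of the laminar classifier, and learning curves.

#' Macro-averaged precision, recall and F1
#'
#' Per-class precision and recall are computed from the confusion table and
#' averaged without class weights; per-class F1 is the harmonic mean of the
#' two, averaged the same way. A class that is never predicted contributes
#' precision 0 (with a warning); a class pair with P + R = 0 contributes
#' F1 = 0.
#'
#' @param yTrue,yPred equal-length label vectors (factors or coercible)
#' @param levels optional class levels; default is the union of both vectors
#' @return named numeric vector: precision, recall, f1, accuracy
#' @export
macroMetrics <- function(yTrue, yPred, levels = NULL) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (is.null(levels))
    levels <- sort(unique(c(as.character(yTrue), as.character(yPred))))
  yt <- factor(as.character(yTrue), levels = levels)
  yp <- factor(as.character(yPred), levels = levels)
  tab <- table(yt, yp)
  tp <- diag(tab)
  predTot <- colSums(tab)
  trueTot <- rowSums(tab)
  if (any(predTot == 0))
    warning("class(es) never predicted: ",
            paste(levels[predTot == 0], collapse = ", "))
  prec <- ifelse(predTot > 0, tp / predTot, 0)
  rec <- ifelse(trueTot > 0, tp / trueTot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  c(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    accuracy = mean(yt == yp))
}

#' Repeated stratified k-fold cross-validation of the laminar classifier
#'
#' Each repeat partitions the samples into k stratified folds
#' (\code{caret::createFolds}); each fold in turn is held out, a laminar
#' model is trained on the remainder and evaluated on the fold, so every
#' sample is tested exactly once per repeat. Reports per-fold and aggregate
#' macro precision/recall/F1, training-set accuracy, and standard deviations
#' both across folds and across repeat means.
#'
#' @param X n x d matrix of preprocessed features
#' @param y factor labels
#' @param cfg a [laminarConfig()] (its seed is ignored; see \code{seed})
#' @param evoCfg,psoCfg training budgets per tree
#' @param k folds (default 5)
#' @param repeats independent repetitions (default 1)
#' @param seed master seed for fold assignment and training
#' @param valFraction,cascadeMaxLevels passed to [trainLaminar()]
#' @return a \code{CVReport} list: \code{perFold} data frame, \code{mean},
#'   \code{sdFolds}, \code{sdRepeats}, \code{predictions}, \code{config},
#'   \code{seed}
#' @export
kfoldCV <- function(X, y, cfg = laminarConfig(), evoCfg = evolutionConfig(),
                    psoCfg = psoConfig(), k = 5L, repeats = 1L, seed = NULL,
                    valFraction = 0.2, cascadeMaxLevels = 8L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= k)
  if (!is.null(seed)) set.seed(seed)
  cfg$seed <- NULL # one RNG stream; nested reseeding would clone trees
  perFold <- list()
  predictions <- list()
  for (r in seq_len(repeats)) {
    folds <- caret::createFolds(y, k = k)
    for (fi in seq_along(folds)) {
      test <- folds[[fi]]
      train <- setdiff(seq_along(y), test)
      model <- trainLaminar(X[train, , drop = FALSE], y[train], cfg,
                            evoCfg, psoCfg, valFraction, cascadeMaxLevels)
      predTest <- predictLaminar(model, X[test, , drop = FALSE])
      predTrain <- predictLaminar(model, X[train, , drop = FALSE])
      mm <- macroMetrics(y[test], predTest$class, levels = levels(y))
      perFold[[length(perFold) + 1L]] <- data.frame(
        repeatIndex = r, fold = fi,
        precision = mm[["precision"]], recall = mm[["recall"]],
        f1 = mm[["f1"]], accuracy = mm[["accuracy"]],
        trainAccuracy = mean(predTrain$class == y[train]))
      predictions[[length(predictions) + 1L]] <- data.frame(
        repeatIndex = r, fold = fi,
        sampleIndex = test,
        trueClass = as.character(y[test]),
        predClass = as.character(predTest$class),
        stringsAsFactors = FALSE)
    }
  }
  perFold <- do.call(rbind, perFold)
  predictions <- do.call(rbind, predictions)
  metricCols <- c("precision", "recall", "f1", "accuracy", "trainAccuracy")
  repMeans <- aggregate(perFold[metricCols],
                        by = list(repeatIndex = perFold$repeatIndex), mean)
  structure(list(
    perFold = perFold,
    mean = colMeans(perFold[metricCols]),
    sdFolds = vapply(perFold[metricCols], stats::sd, numeric(1)),
    sdRepeats = if (repeats > 1L)
      vapply(repMeans[metricCols], stats::sd, numeric(1))
    else setNames(rep(NA_real_, length(metricCols)), metricCols),
    repeatMeans = repMeans,
    predictions = predictions,
    k = k, repeats = repeats, seed = seed,
    config = list(laminar = unclass(cfg), evolution = unclass(evoCfg),
                  pso = unclass(psoCfg))),
    class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport: %d-fold CV, %d repeat(s)\n", x$k, x$repeats))
  cat(sprintf("  macro precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f\n",
              x$mean[["precision"]], x$mean[["recall"]], x$mean[["f1"]],
              x$mean[["accuracy"]]))
  cat(sprintf("  sd across folds (F1): %.3f\n", x$sdFolds[["f1"]]))
  invisible(x)
}

#' Write / read a CVReport as JSON
#'
#' All aggregate numbers are recomputable from the stored per-fold
#' predictions.
#'
#' @param report a \code{CVReport}
#' @param path JSON file
#' @export
writeCVReport <- function(report, path) {
  doc <- list(format = "lacfnforest-cvreport/1",
              k = report$k, repeats = report$repeats,
              seed = report$seed,
              mean = as.list(report$mean),
              sdFolds = as.list(report$sdFolds),
              sdRepeats = as.list(report$sdRepeats),
              perFold = report$perFold,
              predictions = report$predictions)
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = I(17), dataframe = "columns",
                                           na = "null")), path)
  invisible(path)
}

#' @rdname writeCVReport
#' @export
readCVReport <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "lacfnforest-cvreport/1"))
    stop("unrecognized report format")
  structure(list(
    perFold = as.data.frame(doc$perFold),
    mean = unlist(doc$mean), sdFolds = unlist(doc$sdFolds),
    sdRepeats = unlist(doc$sdRepeats),
    predictions = as.data.frame(doc$predictions),
    k = doc$k, repeats = doc$repeats, seed = doc$seed,
    config = NULL), class = "CVReport")
}

#' Learning curve on nested subsamples
#'
#' For each fraction, draws a stratified subsample of that size and runs
#' [kfoldCV()] on it, recording the mean training-set and validation
#' (held-out fold) accuracy. An overall increasing validation curve with a
#' shrinking train/validation gap indicates the model is not overfitting.
#'
#' @param X,y data as for [kfoldCV()]
#' @param fractions increasing sample fractions in (0, 1]
#' @param cfg,evoCfg,psoCfg,k,seed as for [kfoldCV()]
#' @return data frame with one row per fraction: fraction, nUsed,
#'   trainScore, valScore
#' @export
learningCurve <- function(X, y, fractions = c(0.4, 0.6, 0.8, 1.0),
                          cfg = laminarConfig(), evoCfg = evolutionConfig(),
                          psoCfg = psoConfig(), k = 5L, seed = NULL) {
  stopifnot(all(diff(fractions) > 0), all(fractions > 0), all(fractions <= 1))
  X <- as.matrix(X)
  y <- as.factor(y)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(fractions, function(fr) {
    idx <- if (fr >= 1) seq_along(y)
    else sort(caret::createDataPartition(y, p = fr, list = TRUE)[[1]])
    if (length(idx) < 2L * k) {
      warning("subsample at fraction ", fr, " too small; skipped")
      return(NULL)
    }
    rep <- kfoldCV(X[idx, , drop = FALSE], y[idx], cfg, evoCfg, psoCfg,
                   k = k, repeats = 1L, seed = NULL)
    data.frame(fraction = fr, nUsed = length(idx),
               trainScore = rep$mean[["trainAccuracy"]],
               valScore = rep$mean[["accuracy"]])
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
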