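## Model persistence: one versioned JSON document holding the whole laminar
## model (layers -> DFNForests -> cascade levels -> trees).

.MODEL_FORMAT <- "lacfnforest-model/1"

.forestToList <- function(forest) {
  list(functionSet = list(arities = as.list(as.integer(forest@functionSet@arities)),
                          name = forest@functionSet@name),
       trees = lapply(forest@trees, .treeToList))
}

.forestFromList <- function(lst) {
  new("NeuralForest",
      trees = lapply(lst$trees, .treeFromList),
      functionSet = functionSet(unlist(lst$functionSet$arities),
                                lst$functionSet$name))
}

.dfnToList <- function(model) {
  list(codebook = list(numClasses = model@codebook@numClasses),
       functionSet = list(arities = as.list(as.integer(model@functionSet@arities)),
                          name = model@functionSet@name),
       baseInputDim = model@baseInputDim,
       valAccuracyTrace = as.list(model@valAccuracyTrace),
       levels = lapply(model@levels, .forestToList))
}

.dfnFromList <- function(lst) {
  new("DFNForestModel",
      levels = lapply(lst$levels, .forestFromList),
      codebook = buildCodebook(lst$codebook$numClasses),
      functionSet = functionSet(unlist(lst$functionSet$arities),
                                lst$functionSet$name),
      baseInputDim = as.integer(lst$baseInputDim),
      valAccuracyTrace = as.numeric(unlist(lst$valAccuracyTrace)))
}

#' Write / read a laminar model as JSON
#'
#' The document carries a format version, the training configuration, the
#' class levels and every tree's structure and parameters at full precision;
#' reading reconstructs a model whose predictions are identical to the
#' original's.
#'
#' @param model a [LaminarModel-class]
#' @param path output/input JSON file
#' @export
writeLaminarModel <- function(model, path) {
  cfg <- model@config
  doc <- list(
    format = .MODEL_FORMAT,
    numClasses = model@codebook@numClasses,
    classLevels = as.list(model@classLevels),
    baseInputDim = model@baseInputDim,
    layerWeights = as.list(model@layerWeights),
    config = list(numLayers = cfg$numLayers, kBase = cfg$kBase,
                  widening = cfg$widening,
                  augmentPerForest = isTRUE(cfg$augmentPerForest),
                  confidence = list(intervals = cfg$confidence$intervals,
                                    finalThreshold = cfg$confidence$finalThreshold),
                  functionSets = lapply(cfg$functionSets, function(fs)
                    list(arities = as.list(as.integer(fs@arities)),
                         name = fs@name))),
    layers = lapply(model@layers, function(ly)
      list(layerIndex = ly@layerIndex,
           forests = lapply(ly@forests, .dfnToList))))
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = I(17))), path)
  invisible(path)
}

#' @rdname writeLaminarModel
#' @export
readLaminarModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, .MODEL_FORMAT))
    stop("unrecognized model format: ", doc$format)
  cfgL <- doc$config
  cfg <- laminarConfig(
    numLayers = cfgL$numLayers, kBase = cfgL$kBase,
    functionSets = lapply(cfgL$functionSets, function(fs)
      functionSet(unlist(fs$arities), fs$name)),
    widening = cfgL$widening,
    confidence = confidenceRule(
      intervals = lapply(cfgL$confidence$intervals, unlist),
      finalThreshold = cfgL$confidence$finalThreshold),
    augmentPerForest = isTRUE(cfgL$augmentPerForest))
  layers <- lapply(doc$layers, function(ly)
    new("LaminarLayer",
        forests = lapply(ly$forests, .dfnFromList),
        layerIndex = as.integer(ly$layerIndex)))
  new("LaminarModel", layers = layers,
      codebook = buildCodebook(doc$numClasses),
      baseInputDim = as.integer(doc$baseInputDim), config = unclass(cfg),
      layerWeights = as.numeric(unlist(doc$layerWeights)),
      classLevels = as.character(unlist(doc$classLevels)),
      routing = list())
}
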