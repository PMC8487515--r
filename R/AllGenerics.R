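#' @rdname ExpressionMatrix-class
#' @param x an ExpressionMatrix
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
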