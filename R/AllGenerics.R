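#' @rdname GenotypeMatrix-class
#' @param x a \code{GenotypeMatrix}.
#' @export
setGeneric("gtCodes", function(x) standardGeneric("gtCodes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname GeneModelSet-class
#' @param x a \code{GeneModelSet}.
#' @export
setGeneric("transcriptInfo", function(x) standardGeneric("transcriptInfo"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("exonsByTx", function(x) standardGeneric("exonsByTx"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("cdsByTx", function(x) standardGeneric("cdsByTx"))

#' @rdname OutlierResult-class
#' @param x an \code{OutlierResult}.
#' @export
setGeneric("flaggedWindows", function(x) standardGeneric("flaggedWindows"))
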