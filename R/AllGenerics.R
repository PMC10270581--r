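#' @name sigcovar-generics
#' @title Accessor generics
#' @description Accessor generics for the core classes.  All slot access in
#'   user code should go through these rather than \code{@}.
#' @param x an object of the appropriate class.
#' @param ... further arguments passed to methods.
#' @return The slot value documented on each method.
NULL

#' @rdname sigcovar-generics
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname sigcovar-generics
#' @export
setGeneric("categoryLabels", function(x, ...) standardGeneric("categoryLabels"))

#' @rdname sigcovar-generics
#' @export
setGeneric("strandCounts", function(x, strand = 1L, ...) standardGeneric("strandCounts"))

#' @rdname sigcovar-generics
#' @export
setGeneric("featureName", function(x, ...) standardGeneric("featureName"))

#' @rdname sigcovar-generics
#' @export
setGeneric("featureValueLabels", function(x, ...) standardGeneric("featureValueLabels"))

#' @rdname sigcovar-generics
#' @export
setGeneric("droppedCount", function(x, ...) standardGeneric("droppedCount"))

#' @rdname sigcovar-generics
#' @export
setGeneric("sampleTotals", function(x, ...) standardGeneric("sampleTotals"))

#' @rdname sigcovar-generics
#' @export
setGeneric("mergeStrands", function(x, ...) standardGeneric("mergeStrands"))

#' @rdname sigcovar-generics
#' @export
setGeneric("signatureIds", function(x, ...) standardGeneric("signatureIds"))

#' @rdname sigcovar-generics
#' @export
setGeneric("gammaMatrix", function(x, ...) standardGeneric("gammaMatrix"))

#' @rdname sigcovar-generics
#' @export
setGeneric("exposureMatrix", function(x, ...) standardGeneric("exposureMatrix"))

#' @rdname sigcovar-generics
#' @export
setGeneric("modelKind", function(x, ...) standardGeneric("modelKind"))

#' @rdname sigcovar-generics
#' @export
setGeneric("aParams", function(x, ...) standardGeneric("aParams"))

#' @rdname sigcovar-generics
#' @export
setGeneric("bParams", function(x, ...) standardGeneric("bParams"))

#' @rdname sigcovar-generics
#' @export
setGeneric("sigmaPrior", function(x, ...) standardGeneric("sigmaPrior"))

#' @rdname sigcovar-generics
#' @export
setGeneric("assignCounts", function(x, strand = 1L, ...) standardGeneric("assignCounts"))

#' @rdname sigcovar-generics
#' @export
setGeneric("exposures", function(x, ...) standardGeneric("exposures"))

#' @rdname sigcovar-generics
#' @export
setGeneric("loglikTrace", function(x, ...) standardGeneric("loglikTrace"))

#' @rdname sigcovar-generics
#' @export
setGeneric("paramsTrace", function(x, ...) standardGeneric("paramsTrace"))

#' @rdname sigcovar-generics
#' @export
setGeneric("elTrace", function(x, ...) standardGeneric("elTrace"))

#' @rdname sigcovar-generics
#' @export
setGeneric("finalParams", function(x, ...) standardGeneric("finalParams"))

#' @rdname sigcovar-generics
#' @export
setGeneric("resultsTable", function(x, ...) standardGeneric("resultsTable"))
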