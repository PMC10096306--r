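#' @name compDTA-accessors
#' @title Accessors for compDTA classes
#' @description Accessor generics for the central data objects; use these
#'   rather than reaching into slots.
#' @param x an object.
#' @param object an object.
#' @return the slot contents documented for each method.
NULL

#' @rdname compDTA-accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' @rdname compDTA-accessors
#' @export
setGeneric("ligandSmiles", function(x) standardGeneric("ligandSmiles"))

#' @rdname compDTA-accessors
#' @export
setGeneric("affinityRecords", function(x) standardGeneric("affinityRecords"))

#' @rdname compDTA-accessors
#' @export
setGeneric("datasetMetadata", function(x) standardGeneric("datasetMetadata"))

#' @rdname compDTA-accessors
#' @export
setGeneric("similarityIds", function(x) standardGeneric("similarityIds"))

#' @rdname compDTA-accessors
#' @export
setGeneric("similarityKind", function(x) standardGeneric("similarityKind"))

#' Count trainable parameters of a model
#'
#' Exact count of trainable scalars in a built [DTAModel-class]. The
#' separable convolution contributes its depthwise part
#' (`filterLength * channels`) plus its pointwise part
#' (`channels * outFilters`) plus biases, which is the parameter economy
#' motivating that layer.
#'
#' @param m a [DTAModel-class].
#' @return positive integer.
#' @export
setGeneric("countTrainableParameters",
           function(m) standardGeneric("countTrainableParameters"))
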