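#' Count trainable parameters
#'
#' Sums trainable parameters over every layer of the built graph using the
#' closed forms `k^2 * C_in * C_out + C_out` for a (transpose) convolution
#' with bias and `2 * C` for a batch-normalisation layer (scale and shift).
#' The result always equals the total length of the network's weight arrays;
#' this agreement is asserted in the test suite.
#'
#' @param object a built [LMBiSNet-class].
#' @return integer parameter count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname metrics
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname metrics
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname metrics
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname metrics
#' @export
setGeneric("f1Score", function(object) standardGeneric("f1Score"))

#' @rdname metrics
#' @export
setGeneric("aucClosedForm", function(object) standardGeneric("aucClosedForm"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("fundusImage", function(object) standardGeneric("fundusImage"))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))

#' @rdname accessors
#' @export
setGeneric("fovMask", function(object) standardGeneric("fovMask"))

#' @rdname accessors
#' @export
setGeneric("sourceResolution", function(object) standardGeneric("sourceResolution"))

#' @rdname accessors
#' @export
setGeneric("variantCount", function(object) standardGeneric("variantCount"))

#' @rdname accessors
#' @export
setGeneric("layerTable", function(object) standardGeneric("layerTable"))

#' @rdname accessors
#' @export
setGeneric("networkVariant", function(object) standardGeneric("networkVariant"))
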