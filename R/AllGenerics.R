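#' @rdname SimulatedGenome-class
#' @param object,x An object.
#' @export
setGeneric("referenceSeq", function(x) standardGeneric("referenceSeq"))

#' @rdname SimulatedGenome-class
#' @export
setGeneric("sampleSeq", function(x) standardGeneric("sampleSeq"))

#' @rdname SimulatedGenome-class
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname SimulatedReads-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname VariantMask-class
#' @export
setGeneric("maskedPositions", function(x) standardGeneric("maskedPositions"))

#' @rdname ErrorRateTable-class
#' @export
setGeneric("errorRate", function(x, ...) standardGeneric("errorRate"))

#' @rdname FitResult-class
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname FitResult-class
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname FitResult-class
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname ModelComparison-class
#' @export
setGeneric("selectedModel", function(x) standardGeneric("selectedModel"))
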