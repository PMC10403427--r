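#' @include AllClasses.R
NULL

#' Number of sections in a stack
#' @param x a SectionStack, LabelStack or SerialResult.
#' @return integer count.
#' @export
setGeneric("nSections", function(x) standardGeneric("nSections"))

#' @rdname nSections
setMethod("nSections", "SectionStack", function(x) dim(x@data)[3])
#' @rdname nSections
setMethod("nSections", "LabelStack", function(x) dim(x@data)[3])
#' @rdname nSections
setMethod("nSections", "SerialResult", function(x) dim(x@warped@data)[3])

#' Section shape (rows, cols)
#' @param x a SectionStack, LabelStack, FlowField or FeatureMap.
#' @return integer(2).
#' @export
setGeneric("stackShape", function(x) standardGeneric("stackShape"))

#' @rdname stackShape
setMethod("stackShape", "SectionStack", function(x) dim(x@data)[1:2])
#' @rdname stackShape
setMethod("stackShape", "LabelStack", function(x) dim(x@data)[1:2])
#' @rdname stackShape
setMethod("stackShape", "FlowField", function(x) dim(x@dy))
#' @rdname stackShape
setMethod("stackShape", "FeatureMap", function(x) dim(x@data)[1:2])

#' Extract one section as a matrix
#' @param x a SectionStack or LabelStack.
#' @param i section index (1-based).
#' @return numeric or integer matrix.
#' @export
setGeneric("section", function(x, i) standardGeneric("section"))

#' @rdname section
setMethod("section", "SectionStack", function(x, i) x@data[, , i])
#' @rdname section
setMethod("section", "LabelStack", function(x, i) x@data[, , i])

#' Raw array accessors
#' @param x an object with array payload.
#' @return the underlying array.
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))
#' @rdname stackData
setMethod("stackData", "SectionStack", function(x) x@data)
#' @rdname stackData
setMethod("stackData", "LabelStack", function(x) x@data)
#' @rdname stackData
setMethod("stackData", "FeatureMap", function(x) x@data)

#' Flow plane accessors
#' @param x a FlowField.
#' @return numeric matrix of displacements (px).
#' @export
setGeneric("flowDy", function(x) standardGeneric("flowDy"))
#' @rdname flowDy
setMethod("flowDy", "FlowField", function(x) x@dy)
#' @rdname flowDy
#' @export
setGeneric("flowDx", function(x) standardGeneric("flowDx"))
#' @rdname flowDy
setMethod("flowDx", "FlowField", function(x) x@dx)

#' Estimate the dense backward flow aligning a moving image to a reference
#'
#' All estimators share the contract: the returned flow F satisfies
#' \code{warpImage(moving, F)} approximately equal to \code{reference}, in
#' the backward-warping convention, with the output shape equal to the input
#' shape.
#'
#' @param estimator a \linkS4class{FlowEstimator}.
#' @param moving numeric matrix, the image to be warped.
#' @param reference numeric matrix, the target of the alignment.
#' @return A \linkS4class{FlowField}.
#' @export
setGeneric("estimateFlow", function(estimator, moving, reference)
  standardGeneric("estimateFlow"))

#' Extract per-pixel descriptor features
#' @param extractor a \linkS4class{DescriptorExtractor}.
#' @param image numeric matrix with intensities in [0, 1].
#' @return A \linkS4class{FeatureMap}.
#' @export
setGeneric("extractFeatures", function(extractor, image)
  standardGeneric("extractFeatures"))
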