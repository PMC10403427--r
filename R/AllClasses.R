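#' @import methods
NULL

## Central data containers. Sections are stored as a rows x cols x n numeric
## array so that section k is the matrix data[, , k]; indexing is 0-based at
## the file/coordinate level and 1-based at the R level, with pixel centres at
## integer coordinates.

#' SectionStack: an ordered stack of co-sized grayscale sections
#'
#' Holds the serial sections \eqn{s_1..s_n} as a rows x cols x n numeric
#' array with intensities normalised to [0, 1] at load time. Optional
#' physical metadata (pixel size, section thickness, in nanometres) travels
#' with the stack but does not affect any computation.
#'
#' @slot data numeric array, rows x cols x n
#' @slot pixelSizeNm numeric(2), (y, x) pixel size in nm, or NA
#' @slot thicknessNm numeric(1), section thickness in nm, or NA
#' @exportClass SectionStack
setClass("SectionStack",
  representation(data = "array", pixelSizeNm = "numeric",
                 thicknessNm = "numeric"),
  prototype(pixelSizeNm = c(NA_real_, NA_real_), thicknessNm = NA_real_))

setValidity("SectionStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a rows x cols x n array")
  if (d[1] < 8L || d[2] < 8L)
    return("sections must be at least 8 x 8 pixels")
  if (d[3] < 1L)
    return("stack must contain at least one section")
  if (!all(is.finite(object@data)))
    return("all intensities must be finite")
  if (length(object@pixelSizeNm) != 2L)
    return("pixelSizeNm must have length 2")
  TRUE
})

#' Construct a SectionStack
#'
#' @param data a rows x cols x n numeric array, or a list of equally sized
#'   numeric matrices.
#' @param pixelSizeNm optional (y, x) pixel size in nm.
#' @param thicknessNm optional section thickness in nm.
#' @return A \linkS4class{SectionStack}.
#' @export
SectionStack <- function(data, pixelSizeNm = c(NA_real_, NA_real_),
                         thicknessNm = NA_real_) {
  if (is.list(data)) {
    shp <- dim(data[[1]])
    if (!all(vapply(data, function(m) identical(dim(m), shp), logical(1))))
      stop("all sections must share one shape")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(shp, length(data)))
  }
  if (length(dim(data)) != 3L)
    stop("data must be a 3-D array (rows x cols x sections)")
  new("SectionStack", data = data * 1.0,
      pixelSizeNm = as.numeric(pixelSizeNm),
      thicknessNm = as.numeric(thicknessNm))
}

#' LabelStack: integer label maps co-registered with a SectionStack
#'
#' Non-negative integer label volumes; 0 is background and a given id denotes
#' the same biological structure (e.g. neurite) on every section.
#'
#' @slot data integer array, rows x cols x n
#' @exportClass LabelStack
setClass("LabelStack", representation(data = "array"))

setValidity("LabelStack", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a rows x cols x n array")
  if (any(object@data < 0L))
    return("labels must be non-negative integers")
  TRUE
})

#' Construct a LabelStack
#' @param data rows x cols x n integer array or list of integer matrices.
#' @return A \linkS4class{LabelStack}.
#' @export
LabelStack <- function(data) {
  if (is.list(data))
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1]]), length(data)))
  storage.mode(data) <- "integer"
  new("LabelStack", data = data)
}

#' FlowField: a dense backward displacement field
#'
#' Per-pixel displacements in pixels, stored as two planes (dy first). The
#' backward-warping convention is used throughout: warping an image by a flow
#' samples the source at p + F(p) for every target pixel p, so a flow
#' estimated from a moving image against a reference aligns the moving image
#' onto the reference grid.
#'
#' @slot dy numeric matrix of vertical (row) displacements, px
#' @slot dx numeric matrix of horizontal (col) displacements, px
#' @exportClass FlowField
setClass("FlowField", representation(dy = "matrix", dx = "matrix"))

setValidity("FlowField", function(object) {
  if (!identical(dim(object@dy), dim(object@dx)))
    return("dy and dx must share one shape")
  if (!all(is.finite(object@dy)) || !all(is.finite(object@dx)))
    return("displacements must be finite")
  TRUE
})

#' Construct a FlowField
#' @param dy,dx numeric matrices of per-pixel row/col displacements (px).
#' @return A \linkS4class{FlowField}.
#' @export
FlowField <- function(dy, dx) new("FlowField", dy = dy, dx = dx)

#' Zero flow of a given shape
#' @param shape integer(2): (rows, cols).
#' @return A zero \linkS4class{FlowField}.
#' @export
zeroFlow <- function(shape)
  FlowField(matrix(0, shape[1], shape[2]), matrix(0, shape[1], shape[2]))

#' RigidTransform: rotation + translation about the image centre
#'
#' The transform maps a moving-image point p to R(theta) (p - c) + c + t in
#' the reference frame, with c the image centre, theta counterclockwise in
#' radians and t = (ty, tx) in pixels.
#'
#' @slot theta numeric(1), rotation in radians, in (-pi, pi]
#' @slot t numeric(2), (ty, tx) translation in px
#' @exportClass RigidTransform
setClass("RigidTransform", representation(theta = "numeric", t = "numeric"),
         prototype(theta = 0, t = c(0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@theta) != 1L || !is.finite(object@theta))
    return("theta must be a finite scalar")
  if (object@theta <= -pi || object@theta > pi)
    return("theta must lie in (-pi, pi]")
  if (length(object@t) != 2L || !all(is.finite(object@t)))
    return("t must be finite (ty, tx)")
  TRUE
})

#' Construct a RigidTransform
#' @param theta rotation angle in radians (counterclockwise, about centre).
#' @param t numeric(2) translation (ty, tx) in pixels.
#' @return A \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(theta = 0, t = c(0, 0)) {
  theta <- ((theta + pi) %% (2 * pi)) - pi
  if (theta == -pi) theta <- pi
  new("RigidTransform", theta = theta, t = as.numeric(t))
}

#' FeatureMap: a per-pixel multi-channel descriptor
#'
#' @slot data numeric array, rows x cols x C
#' @slot extractorId character tag of the producing extractor
#' @exportClass FeatureMap
setClass("FeatureMap",
         representation(data = "array", extractorId = "character"))

setValidity("FeatureMap", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be rows x cols x C")
  if (!all(is.finite(object@data)))
    return("features must be finite")
  TRUE
})

## ---- extractors and estimators -------------------------------------------

#' Virtual parent of per-pixel descriptor extractors
#' @slot id character identifier
#' @exportClass DescriptorExtractor
setClass("DescriptorExtractor", representation("VIRTUAL", id = "character"))

#' Deterministic multi-scale descriptor bank
#'
#' The default stand-in for a learned thickness-insensitive representation:
#' local contrast normalisation followed by Gaussian-smoothed intensity and
#' first-derivative pairs at several scales, each channel standardised per
#' image. Insensitive to positive affine intensity changes by construction.
#'
#' @slot sigmas numeric vector of Gaussian scales (px)
#' @slot lcnSigma numeric(1), scale of the local contrast normalisation
#' @exportClass MultiscaleExtractor
setClass("MultiscaleExtractor", contains = "DescriptorExtractor",
         representation(sigmas = "numeric", lcnSigma = "numeric"))

#' Construct the default multi-scale descriptor extractor
#' @param sigmas Gaussian scales in pixels (default 1, 2, 4).
#' @param lcnSigma local-contrast-normalisation scale in pixels.
#' @return A \linkS4class{MultiscaleExtractor}.
#' @export
multiscaleExtractor <- function(sigmas = c(1, 2, 4), lcnSigma = 4) {
  new("MultiscaleExtractor",
      id = paste0("multiscale-", paste(sigmas, collapse = ",")),
      sigmas = sigmas, lcnSigma = lcnSigma)
}

#' Adapter for an externally supplied descriptor function
#' @slot fun function(matrix) -> rows x cols x C array
#' @exportClass ExternalExtractor
setClass("ExternalExtractor", contains = "DescriptorExtractor",
         representation(fun = "function"))

#' Wrap an external descriptor model as an extractor
#' @param fun function mapping a numeric matrix to a rows x cols x C array.
#' @param id identifier recorded in the produced feature maps.
#' @return An \linkS4class{ExternalExtractor}.
#' @export
externalExtractor <- function(fun, id = "external")
  new("ExternalExtractor", id = id, fun = fun)

#' Virtual parent of dense flow estimators
#' @slot name character label
#' @exportClass FlowEstimator
setClass("FlowEstimator", representation("VIRTUAL", name = "character"))

#' Deterministic coarse-to-fine pyramidal flow estimator
#'
#' Classical block-matching estimator operating on descriptor maps: a
#' five-octave image pyramid is matched coarse to fine; at each level a local
#' cost volume (sum of squared descriptor differences, box-aggregated) is
#' decoded by argmin with parabolic subpixel refinement, the increment is
#' smoothed and composed with the upsampled coarser flow.
#'
#' @slot octaves integer, pyramid depth (clamped so the coarsest level keeps
#'   at least 8 px a side)
#' @slot downscale numeric, scale factor between octaves
#' @slot iterations integer, matching passes per level
#' @slot radius integer, cost-volume search radius per level (px)
#' @slot window integer, half-width of the cost aggregation box (px)
#' @slot smoothSigma numeric, Gaussian smoothing of each increment (px)
#' @slot extractor DescriptorExtractor used to build the matching features
#' @exportClass ClassicalFlowEstimator
setClass("ClassicalFlowEstimator", contains = "FlowEstimator",
  representation(octaves = "integer", downscale = "numeric",
                 iterations = "integer", radius = "integer",
                 window = "integer", smoothSigma = "numeric",
                 extractor = "DescriptorExtractor"))

#' Construct the classical pyramidal estimator
#' @param octaves pyramid depth (default 5).
#' @param downscale factor per octave (default 2).
#' @param iterations matching passes per level (default 2).
#' @param radius search radius per level in px (default 4).
#' @param window aggregation box half-width in px (default 3).
#' @param smoothSigma Gaussian smoothing of flow increments in px.
#' @param extractor descriptor extractor supplying the matching features;
#'   the default is a light two-scale bank (sigma 0.5, 1 px, LCN 1.5 px):
#'   the pyramid itself supplies the coarse scales, so per-level features
#'   keep small support.
#' @return A \linkS4class{ClassicalFlowEstimator}.
#' @export
classicalFlowEstimator <- function(octaves = 5L, downscale = 2, iterations = 4L,
                                   radius = 4L, window = 4L, smoothSigma = 1.5,
                                   extractor = multiscaleExtractor(c(0.5, 1),
                                                                   1.5)) {
  stopifnot(octaves >= 1L, downscale > 1, radius >= 1L)
  new("ClassicalFlowEstimator", name = "classical",
      octaves = as.integer(octaves), downscale = downscale,
      iterations = as.integer(iterations), radius = as.integer(radius),
      window = as.integer(window), smoothSigma = smoothSigma,
      extractor = extractor)
}

#' Learned coarse-to-fine flow estimator
#'
#' A lightweight trainable estimator in the PWC style: a feature pyramid is
#' built over five octaves; at each level base descriptor channels are mixed
#' by a learnable linear map, matched through a local cost volume and decoded
#' by a soft-argmax with learnable temperature; the level increment is
#' smoothed and composed with the upsampled coarser flow. Parameters are
#' trained with \code{\link{trainFlowEstimator}}.
#'
#' @slot params numeric vector of trainable parameters (mixing weights,
#'   biases, log-temperature, log smoothing scale)
#' @slot config list of architecture constants (octaves, radius, channels...)
#' @exportClass LearnedFlowEstimator
setClass("LearnedFlowEstimator", contains = "FlowEstimator",
         representation(params = "numeric", config = "list"))

#' SerialResult: output of sequential registration
#'
#' @slot warped SectionStack of ws_1..ws_n
#' @slot flows list of FlowField, the F_{i -> i-1} for interior sections
#'   (element i - 1 corresponds to section i, i = 2..n-1)
#' @slot endpointRigid RigidTransform placing the last section
#' @slot firstRigid RigidTransform placing the first section (identity for a
#'   standalone short series)
#' @slot manifest list of run metadata (seeds, estimator name, timings)
#' @exportClass SerialResult
setClass("SerialResult",
  representation(warped = "SectionStack", flows = "list",
                 endpointRigid = "RigidTransform",
                 firstRigid = "RigidTransform", manifest = "list"))

#' CumulativeErrorModel: error flow, descriptor distances and weights
#'
#' The residual flow between the last two warped sections approximates the
#' total cumulative registration error; descriptor distances d_i between
#' consecutive warped sections yield compensation weights
#' w_i = sum(d_{j<=i}) / sum(d_{j<=n}).
#'
#' @slot errorFlow FlowField approximating the total cumulative error
#' @slot distances numeric d_1..d_n (d_1 = 0 by convention)
#' @slot weights numeric w_1..w_n (nondecreasing, w_n = 1 when sum(d) > 0)
#' @exportClass CumulativeErrorModel
setClass("CumulativeErrorModel",
  representation(errorFlow = "FlowField", distances = "numeric",
                 weights = "numeric"))

#' SeriesPartition: split of a long series into overlapping short series
#'
#' @slot segments list of integer(2) (start, end) index ranges, 1-based,
#'   consecutive segments sharing exactly one benchmark index
#' @slot benchmarks integer vector of shared benchmark section indices
#'   (including the first and last section of the whole series)
#' @slot rigidChain list of RigidTransform placing each benchmark in the
#'   global frame (identity for the first); empty before estimation
#' @exportClass SeriesPartition
setClass("SeriesPartition",
  representation(segments = "list", benchmarks = "integer",
                 rigidChain = "list"),
  prototype(rigidChain = list()))

## ---- show methods --------------------------------------------------------

setMethod("show", "SectionStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("SectionStack: %d sections of %d x %d px\n", d[3], d[1], d[2]))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(object@data), max(object@data)))
  if (!is.na(object@pixelSizeNm[1]))
    cat(sprintf("  pixel size %g x %g nm, thickness %g nm\n",
                object@pixelSizeNm[1], object@pixelSizeNm[2],
                object@thicknessNm))
})

setMethod("show", "LabelStack", function(object) {
  d <- dim(object@data)
  ids <- setdiff(unique(as.vector(object@data)), 0L)
  cat(sprintf("LabelStack: %d sections of %d x %d px, %d labels\n",
              d[3], d[1], d[2], length(ids)))
})

setMethod("show", "FlowField", function(object) {
  d <- dim(object@dy)
  m <- mean(sqrt(object@dy^2 + object@dx^2))
  cat(sprintf("FlowField: %d x %d px, mean |F| = %.3f px\n", d[1], d[2], m))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: theta = %.3f deg, t = (%.2f, %.2f) px\n",
              object@theta * 180 / pi, object@t[1], object@t[2]))
})

setMethod("show", "FeatureMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("FeatureMap: %d x %d px, %d channels [%s]\n",
              d[1], d[2], d[3], object@extractorId))
})

setMethod("show", "SerialResult", function(object) {
  d <- dim(object@warped@data)
  cat(sprintf("SerialResult: %d registered sections of %d x %d px\n",
              d[3], d[1], d[2]))
  cat(sprintf("  endpoint rigid: theta = %.3f deg, t = (%.2f, %.2f) px\n",
              object@endpointRigid@theta * 180 / pi,
              object@endpointRigid@t[1], object@endpointRigid@t[2]))
})

setMethod("show", "CumulativeErrorModel", function(object) {
  cat(sprintf(
    "CumulativeErrorModel: n = %d, mean |error flow| = %.3f px\n",
    length(object@weights),
    mean(sqrt(object@errorFlow@dy^2 + object@errorFlow@dx^2))))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
})

setMethod("show", "SeriesPartition", function(object) {
  cat(sprintf("SeriesPartition: %d segments, benchmarks at %s\n",
              length(object@segments),
              paste(object@benchmarks, collapse = ", ")))
})
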