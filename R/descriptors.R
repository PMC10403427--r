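#' @include AllClasses.R AllGenerics.R
NULL

## The default per-pixel descriptor stands in for a learned
## thickness-insensitive representation: it favours where structure sits over
## how bright it is. Local contrast normalisation (LCN) removes slow
## illumination and global affine intensity changes; the multi-scale
## smoothed-intensity + first-derivative bank encodes position and edge
## structure at sigma = 1, 2, 4 px by default.

#' @rdname extractFeatures
setMethod("extractFeatures", "MultiscaleExtractor", function(extractor, image) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  # LCN with an epsilon relative to the global sd so that features are
  # exactly invariant under img -> a*img + b (a > 0)
  gsd <- stats::sd(image)
  eps <- if (gsd > 0) 1e-3 * gsd else 1e-8
  mu <- gauss_blur_cpp(image, extractor@lcnSigma)
  v <- gauss_blur_cpp((image - mu)^2, extractor@lcnSigma)
  lcn <- (image - mu) / (sqrt(pmax(v, 0)) + eps)

  chans <- vector("list", 3L * length(extractor@sigmas))
  k <- 1L
  for (s in extractor@sigmas) {
    g <- gauss_blur_cpp(lcn, s)
    chans[[k]] <- g
    chans[[k + 1L]] <- .gradY(g)
    chans[[k + 2L]] <- .gradX(g)
    k <- k + 3L
  }
  # per-image channel standardisation (zero mean, unit variance); flat
  # channels stay identically zero
  arr <- array(0, dim = c(nr, nc, length(chans)))
  for (i in seq_along(chans)) {
    ch <- chans[[i]]
    s <- stats::sd(ch)
    arr[, , i] <- if (s > 1e-12) (ch - mean(ch)) / s else 0 * ch
  }
  new("FeatureMap", data = arr, extractorId = extractor@id)
})

#' @rdname extractFeatures
setMethod("extractFeatures", "ExternalExtractor", function(extractor, image) {
  arr <- extractor@fun(image)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  new("FeatureMap", data = arr, extractorId = extractor@id)
})

# central differences, replicated borders
.gradY <- function(m) {
  nr <- nrow(m)
  (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
}
.gradX <- function(m) {
  nc <- ncol(m)
  (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
}

#' Euclidean distance between two feature maps
#'
#' The descriptor distance d between two sections is the L2 norm of the
#' elementwise difference of their feature maps over all pixels and
#' channels; consecutive-section distances drive the cumulative-error
#' compensation weights.
#'
#' @param a,b \linkS4class{FeatureMap}s from one extractor, one shape.
#' @return Non-negative scalar.
#' @export
featureDistance <- function(a, b) {
  if (!identical(dim(a@data), dim(b@data)))
    stop("feature shapes differ")
  if (!identical(a@extractorId, b@extractorId))
    stop("feature maps come from different extractors")
  sqrt(sum((a@data - b@data)^2))
}

#' Feature-space photometric loss
#'
#' Squared L2 difference between the reference features and the features of
#' the warped moving image, normalised by pixel x channel count so the loss
#' magnitude is resolution independent. The features of the warped image are
#' recomputed from the warped pixels (features of the warp, never the warp of
#' the features).
#'
#' @param refFeat features of the reference section.
#' @param warpedFeat features extracted from the warped moving section.
#' @return Non-negative scalar.
#' @export
featurePhotometricLoss <- function(refFeat, warpedFeat) {
  if (!identical(dim(refFeat@data), dim(warpedFeat@data)))
    stop("feature shapes differ")
  sum((refFeat@data - warpedFeat@data)^2) / length(refFeat@data)
}
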