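#' @include AllClasses.R AllGenerics.R
NULL

#' Warp an image by a dense flow field (backward mapping)
#'
#' Samples the input at p + F(p) for every output pixel p with bilinear
#' interpolation, so the flow returned by \code{\link{estimateFlow}} for a
#' (moving, reference) pair maps the moving image onto the reference grid.
#'
#' @param image numeric matrix.
#' @param flow a \linkS4class{FlowField} with the same shape.
#' @param fill "zeros" (constant fill outside the image) or "edge"
#'   (clamp samples to the border).
#' @param returnMask if TRUE, also return the in-bounds validity mask.
#' @return The warped matrix, or \code{list(image, mask)} when
#'   \code{returnMask} is TRUE; \code{mask} is TRUE where the sample point
#'   fell fully inside the image.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' stopifnot(identical(warpImage(img, zeroFlow(c(8, 8))), img))
#' @export
warpImage <- function(image, flow, fill = c("zeros", "edge"),
                      returnMask = FALSE) {
  fill <- match.arg(fill)
  if (!identical(dim(image), stackShape(flow)))
    stop("image and flow shapes differ")
  if (all(flow@dy == 0) && all(flow@dx == 0)) {
    # identity flow is the identity warp, bit for bit
    if (returnMask)
      return(list(image = image,
                  mask = matrix(TRUE, nrow(image), ncol(image))))
    return(image)
  }
  res <- warp_bilinear_cpp(image, flow@dy, flow@dx, fill == "edge", 0)
  if (returnMask) list(image = res$out, mask = res$mask) else res$out
}

#' Warp an integer label map by a flow field (nearest neighbour)
#'
#' @param labels integer matrix (0 = background).
#' @param flow a \linkS4class{FlowField} of matching shape.
#' @return Integer matrix; out-of-bounds samples become 0.
#' @export
warpLabels <- function(labels, flow) {
  if (!identical(dim(labels), stackShape(flow)))
    stop("labels and flow shapes differ")
  storage.mode(labels) <- "integer"
  warp_nearest_cpp(labels, flow@dy, flow@dx)
}

#' Scale a flow field by a scalar
#' @param flow a \linkS4class{FlowField}.
#' @param alpha finite scalar.
#' @return The elementwise-scaled \linkS4class{FlowField}.
#' @export
scaleFlow <- function(flow, alpha) {
  stopifnot(is.finite(alpha))
  FlowField(flow@dy * alpha, flow@dx * alpha)
}

#' Compose two flow fields
#'
#' Returns the single field equivalent to warping by \code{inner} first and
#' \code{outer} second: F(p) = outer(p) + inner(p + outer(p)), with the inner
#' field sampled bilinearly (edge-clamped).
#'
#' @param outer,inner \linkS4class{FlowField}s of one shape.
#' @return A \linkS4class{FlowField} F with
#'   warp(img, F) == warp(warp(img, inner), outer) up to interpolation error.
#' @export
composeFlows <- function(outer, inner) {
  if (!identical(stackShape(outer), stackShape(inner)))
    stop("flow shapes differ")
  iy <- warp_bilinear_cpp(inner@dy, outer@dy, outer@dx, TRUE, 0)$out
  ix <- warp_bilinear_cpp(inner@dx, outer@dy, outer@dx, TRUE, 0)$out
  FlowField(outer@dy + iy, outer@dx + ix)
}

#' Convert a rigid transform to an equivalent backward flow
#'
#' The returned flow applies the transform through backward warping:
#' \code{warpImage(img, rigidToFlow(T, dim(img)))} rotates img by theta about
#' its centre and translates it by t.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param shape integer(2) (rows, cols).
#' @return A \linkS4class{FlowField}.
#' @export
rigidToFlow <- function(transform, shape) {
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  th <- transform@theta
  ty <- transform@t[1]; tx <- transform@t[2]
  # backward map: source = R^{-1} (p - c - t) + c
  y <- matrix(seq_len(nr) - 1, nr, nc) - cy - ty
  x <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - cx - tx
  sy <- cos(th) * y + sin(th) * x + cy
  sx <- -sin(th) * y + cos(th) * x + cx
  FlowField(sy - (matrix(seq_len(nr) - 1, nr, nc)),
            sx - (matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)))
}

#' Apply a rigid transform to an image
#' @param image numeric matrix.
#' @param transform a \linkS4class{RigidTransform}.
#' @param fill fill policy, see \code{\link{warpImage}}.
#' @return The transformed matrix.
#' @export
applyRigid <- function(image, transform, fill = "zeros")
  warpImage(image, rigidToFlow(transform, dim(image)), fill = fill)

#' Invert a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @return The inverse \linkS4class{RigidTransform} (about the same centre).
#' @export
invertRigid <- function(transform) {
  th <- transform@theta
  t <- transform@t
  # inverse of p -> R(p - c) + c + t is p -> R^{-1}(p - c) + c - R^{-1} t
  RigidTransform(-th, c(-(cos(th) * t[1] + sin(th) * t[2]),
                        -(-sin(th) * t[1] + cos(th) * t[2])))
}

#' Compose two rigid transforms (outer after inner)
#' @param outer,inner \linkS4class{RigidTransform}s.
#' @return The \linkS4class{RigidTransform} equivalent to applying inner then
#'   outer, both about the shared image centre.
#' @export
composeRigid <- function(outer, inner) {
  # outer(inner(p)): R_o (R_i (p-c) + t_i) + c + t_o
  th <- outer@theta + inner@theta
  Ro <- matrix(c(cos(outer@theta), sin(outer@theta),
                 -sin(outer@theta), cos(outer@theta)), 2, 2)
  RigidTransform(th, as.numeric(Ro %*% inner@t) + outer@t)
}

#' Numerically invert a flow field
#'
#' Finds G with warp(warp(img, F), G) approximately the identity by the
#' fixed-point iteration G(p) = -F(p + G(p)) (bilinear, edge-clamped), which
#' converges for smooth fields with sub-unit Jacobian perturbations. Used to
#' express a synthetic deformation field in the convention of the estimator
#' that undoes it.
#'
#' @param flow a \linkS4class{FlowField}.
#' @param iterations fixed-point iterations.
#' @return The approximate inverse \linkS4class{FlowField}.
#' @export
invertFlow <- function(flow, iterations = 25L) {
  gy <- -flow@dy
  gx <- -flow@dx
  for (k in seq_len(iterations)) {
    sy <- warp_bilinear_cpp(flow@dy, gy, gx, TRUE, 0)$out
    sx <- warp_bilinear_cpp(flow@dx, gy, gx, TRUE, 0)$out
    gy <- -sy
    gx <- -sx
  }
  FlowField(gy, gx)
}

#' Resample a flow field to a new shape
#'
#' Each displacement plane is resampled bilinearly and the values are scaled
#' by the resolution change, so the field keeps its meaning in pixels of the
#' new grid.
#'
#' @param flow a \linkS4class{FlowField}.
#' @param shape integer(2) target (rows, cols).
#' @return A \linkS4class{FlowField} of the new shape.
#' @export
resampleFlow <- function(flow, shape) {
  d <- stackShape(flow)
  fy <- if (d[1] > 1) (shape[1] - 1) / (d[1] - 1) else 1
  fx <- if (d[2] > 1) (shape[2] - 1) / (d[2] - 1) else 1
  FlowField(resize_bilinear_cpp(flow@dy, shape[1], shape[2]) * fy,
            resize_bilinear_cpp(flow@dx, shape[1], shape[2]) * fx)
}

#' Write / read a flow field as a pair of 32-bit float TIFFs
#'
#' Channel order is documented: dy first. Because TIFF grayscale storage is
#' [0, 1], each plane is stored affinely rescaled; the offsets/scales travel
#' in a JSON sidecar ("<path>_range.json") and are undone on read.
#'
#' @param flow a \linkS4class{FlowField}.
#' @param path base path; "<path>_dy.tif", "<path>_dx.tif" and
#'   "<path>_range.json" are written.
#' @return \code{writeFlow}: invisibly, the written file paths.
#' @export
writeFlow <- function(flow, path) {
  py <- paste0(path, "_dy.tif"); px <- paste0(path, "_dx.tif")
  pj <- paste0(path, "_range.json")
  rng <- list(dy = range(flow@dy), dx = range(flow@dx))
  sc <- function(m, r) if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  tiff::writeTIFF(sc(flow@dy, rng$dy), py, bits.per.sample = 32L,
                  reduce = FALSE)
  tiff::writeTIFF(sc(flow@dx, rng$dx), px, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(rng, pj, digits = NA)
  invisible(c(py, px, pj))
}

#' @rdname writeFlow
#' @return \code{readFlow}: the \linkS4class{FlowField}.
#' @export
readFlow <- function(path) {
  rng <- jsonlite::read_json(paste0(path, "_range.json"),
                             simplifyVector = TRUE)
  un <- function(m, r) if (r[2] > r[1]) m * (r[2] - r[1]) + r[1] else m
  dy <- un(tiff::readTIFF(paste0(path, "_dy.tif"), as.is = FALSE), rng$dy)
  dx <- un(tiff::readTIFF(paste0(path, "_dx.tif"), as.is = FALSE), rng$dx)
  FlowField(dy, dx)
}
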