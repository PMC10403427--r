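#' @include AllClasses.R AllGenerics.R flow_field.R descriptors.R
NULL

# Gaussian-antialiased image pyramid; level 1 is full resolution. The number
# of levels is clamped so the coarsest level keeps >= 8 px a side.
.buildPyramid <- function(image, octaves, downscale) {
  lv <- list(image)
  for (k in seq_len(octaves - 1L)) {
    prev <- lv[[k]]
    d <- dim(prev)
    nd <- round(d / downscale)
    # levels below ~16 px a side carry only ramp-like structure after the
    # descriptor smoothing and destabilise matching; stop the pyramid there
    if (min(nd) < 16L) break
    sm <- gauss_blur_cpp(prev, 0.5 * downscale)
    lv[[k + 1L]] <- resize_bilinear_cpp(sm, nd[1], nd[2])
  }
  lv
}

# warp every channel of a feature array by (dy, dx), edge-clamped
.warpFeat <- function(feat, dy, dx) {
  out <- feat
  for (ch in seq_len(dim(feat)[3]))
    out[, , ch] <- warp_bilinear_cpp(feat[, , ch], dy, dx, TRUE, 0)$out
  out
}

# Shared coarse-to-fine loop. featFun(levelImage) -> rows x cols x C array.
# method "lk": damped Lucas-Kanade normal equations on the feature channels;
# method "match"/"softargmax": local cost volume decoded by argmin+parabola
# or by soft-argmax(tau).
.coarseToFineFlow <- function(moving, reference, featFun, octaves, downscale,
                              iterations, radius, window, smoothSigma,
                              method = "lk", tau = 1, damping = 0.05,
                              maxStep = 2) {
  pm <- .buildPyramid(moving, octaves, downscale)
  pr <- .buildPyramid(reference, octaves, downscale)
  L <- length(pm)
  flow <- NULL
  for (lev in seq(L, 1L)) {
    d <- dim(pr[[lev]])
    flow <- if (is.null(flow)) zeroFlow(d) else resampleFlow(flow, d)
    fr <- featFun(pr[[lev]])
    fm <- featFun(pm[[lev]])
    if (method == "lk" && lev == L) {
      # one confidence-gated cost-volume pass at the coarsest level captures
      # displacements beyond the differential pull-in range of the
      # Lucas-Kanade refinement (e.g. accumulated inter-section drift)
      inc <- match_level_cpp(fr, fm, radius, window, 0L, tau)
      flow <- composeFlows(FlowField(gauss_blur_cpp(inc$ddy * inc$conf,
                                                    smoothSigma),
                                     gauss_blur_cpp(inc$ddx * inc$conf,
                                                    smoothSigma)), flow)
    }
    for (it in seq_len(iterations)) {
      fw <- .warpFeat(fm, flow@dy, flow@dx)
      if (method == "lk") {
        inc <- lk_step_cpp(fr, fw, window, damping, maxStep)
        ddy <- gauss_blur_cpp(inc$ddy, smoothSigma)
        ddx <- gauss_blur_cpp(inc$ddx, smoothSigma)
      } else {
        inc <- match_level_cpp(fr, fw, radius, window,
                               if (method == "softargmax") 1L else 0L, tau)
        # gate matches by cost contrast so flat (featureless) regions do
        # not inject arbitrary offsets that coarse-to-fine upsampling
        # would amplify
        ddy <- gauss_blur_cpp(inc$ddy * inc$conf, smoothSigma)
        ddx <- gauss_blur_cpp(inc$ddx * inc$conf, smoothSigma)
      }
      flow <- composeFlows(FlowField(ddy, ddx), flow)
    }
  }
  flow
}

#' @rdname estimateFlow
setMethod("estimateFlow", "ClassicalFlowEstimator",
  function(estimator, moving, reference) {
    if (!identical(dim(moving), dim(reference)))
      stop("moving and reference shapes differ")
    ex <- estimator@extractor
    .coarseToFineFlow(moving, reference,
                      featFun = function(img) extractFeatures(ex, img)@data,
                      octaves = estimator@octaves,
                      downscale = estimator@downscale,
                      iterations = estimator@iterations,
                      radius = estimator@radius,
                      window = estimator@window,
                      smoothSigma = estimator@smoothSigma,
                      method = "lk")
  })

#' First-order smoothness loss of a flow field
#'
#' Mean Charbonnier penalty rho(t) = sqrt(t^2 + eps^2) - eps of the forward
#' finite differences of both displacement planes, along rows and columns.
#' Zero for any constant (translational) field.
#'
#' @param flow a \linkS4class{FlowField}.
#' @param eps Charbonnier epsilon (px).
#' @return Non-negative scalar.
#' @export
smoothnessLoss <- function(flow, eps = 1e-3) {
  rho <- function(t) sqrt(t^2 + eps^2) - eps
  diffs <- c(rho(diff(flow@dy)), rho(t(diff(t(flow@dy)))),
             rho(diff(flow@dx)), rho(t(diff(t(flow@dx)))))
  mean(diffs)
}

#' Augmentation-consistency loss
#'
#' Self-supervision in the ARFlow style: the flow predicted on the original
#' pair is held fixed as a pseudo-label; the pair is transformed by a rigid
#' spatial augmentation (plus an appearance gain/bias), the flow is
#' re-predicted, and the loss is the masked Charbonnier distance between the
#' new prediction and the pseudo-label transported through the augmentation.
#'
#' @param estimator a \linkS4class{FlowEstimator}.
#' @param moving,reference the image pair.
#' @param aug list with elements \code{theta} (rad), \code{t} (ty, tx) px,
#'   and optional \code{gain}, \code{bias} applied to intensities.
#' @param pseudo optional precomputed pseudo-label flow (saves one estimate).
#' @param eps Charbonnier epsilon.
#' @return Non-negative scalar; error if the validly transported region is
#'   empty.
#' @export
augmentationLoss <- function(estimator, moving, reference,
                             aug = list(theta = 0, t = c(0, 0)),
                             pseudo = NULL, eps = 1e-3) {
  gain <- if (is.null(aug$gain)) 1 else aug$gain
  bias <- if (is.null(aug$bias)) 0 else aug$bias
  Taug <- RigidTransform(aug$theta, aug$t)
  if (is.null(pseudo))
    pseudo <- estimateFlow(estimator, moving, reference)
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  movA <- clip01(applyRigid(moving, Taug, fill = "edge") * gain + bias)
  refA <- clip01(applyRigid(reference, Taug, fill = "edge") * gain + bias)
  predA <- estimateFlow(estimator, movA, refA)

  # transport the pseudo-label: with g the backward map of the augmentation
  # (both images were warped by g), correspondences become
  # m'(p) = g^{-1}(m(g(p))), m(q) = q + F(q)
  d <- dim(moving)
  gflow <- rigidToFlow(Taug, d)          # g(p) - p
  py <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  px <- matrix(rep(seq_len(d[2]) - 1, each = d[1]), d[1], d[2])
  qy <- py + gflow@dy
  qx <- px + gflow@dx
  valid <- qy >= 0 & qy <= d[1] - 1 & qx >= 0 & qx <= d[2] - 1
  Fy <- warp_bilinear_cpp(pseudo@dy, gflow@dy, gflow@dx, TRUE, 0)$out
  Fx <- warp_bilinear_cpp(pseudo@dx, gflow@dy, gflow@dx, TRUE, 0)$out
  my <- qy + Fy
  mx <- qx + Fx
  # g^{-1}(m) = R(m - c) + c + t
  cy <- (d[1] - 1) / 2; cx <- (d[2] - 1) / 2
  th <- Taug@theta
  mpy <- cos(th) * (my - cy) - sin(th) * (mx - cx) + cy + Taug@t[1]
  mpx <- sin(th) * (my - cy) + cos(th) * (mx - cx) + cx + Taug@t[2]
  ty <- mpy - py
  tx <- mpx - px
  if (!any(valid))
    stop("degenerate augmentation: empty valid region")
  r <- sqrt((predA@dy - ty)^2 + (predA@dx - tx)^2)
  mean(sqrt(r[valid]^2 + eps^2) - eps)
}
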