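#' @include AllClasses.R AllGenerics.R serial_register.R descriptors.R
NULL

#' Estimate the total cumulative registration error flow
#'
#' After sequential registration the last warped section sits on its rigid
#' anchor while the second-to-last carries (nearly) the whole accumulated
#' drift, so the residual flow between them approximates the total
#' cumulative error. The flow is returned in the backward convention:
#' warping ws_{n-1} by it aligns it onto ws_n.
#'
#' @param wsPrevLast,wsLast the last two warped sections (matrices).
#' @param estimator a \linkS4class{FlowEstimator}.
#' @return A \linkS4class{FlowField}.
#' @export
estimateErrorFlow <- function(wsPrevLast, wsLast, estimator)
  estimateFlow(estimator, wsPrevLast, wsLast)

#' Cumulative-error compensation weights from descriptor distances
#'
#' w_i = sum(d_j, j <= i) / sum(d_j, j <= n). With d_1 = 0 by convention the
#' reference section receives no compensation and w_n = 1. When every
#' distance is zero (e.g. an identical-section stack) the weights fall back
#' to the linear ramp (i - 1) / (n - 1).
#'
#' @param distances numeric d_1..d_n, non-negative, d_1 = 0.
#' @return numeric weights w_1..w_n, nondecreasing with w_n = 1.
#' @examples
#' computeWeights(c(0, 1, 1, 1))   # 0, 1/3, 2/3, 1
#' @export
computeWeights <- function(distances) {
  if (any(distances < 0))
    stop("descriptor distances must be non-negative")
  n <- length(distances)
  s <- sum(distances)
  if (s == 0) {
    if (n == 1L) return(1)
    return((seq_len(n) - 1) / (n - 1))
  }
  cumsum(distances) / s
}

#' Apply weighted cumulative-error compensation to a registered stack
#'
#' Each interior section is warped by the error flow scaled by its weight,
#' final_i = warp(ws_i, w_i * errorFlow); the rigidly anchored endpoints are
#' passed through untouched. A zero error flow or all-zero interior weights
#' leave the stack bit-identical.
#'
#' @param result a \linkS4class{SerialResult}.
#' @param model a \linkS4class{CumulativeErrorModel}.
#' @param fill fill policy for the compensation warps.
#' @return A \linkS4class{SectionStack}.
#' @export
compensateStack <- function(result, model, fill = "edge") {
  n <- nSections(result)
  if (length(model@weights) != n)
    stop("model weight count does not match stack")
  if (!identical(stackShape(model@errorFlow), stackShape(result@warped)))
    stop("error-flow shape does not match stack")
  out <- stackData(result@warped)
  for (i in seq(2L, n - 1L)) {
    w <- model@weights[i]
    if (w == 0) next
    ef <- model@errorFlow
    if (all(ef@dy == 0) && all(ef@dx == 0)) next
    out[, , i] <- warpImage(out[, , i], scaleFlow(ef, w), fill = fill)
  }
  SectionStack(out, pixelSizeNm = result@warped@pixelSizeNm,
               thicknessNm = result@warped@thicknessNm)
}

#' Structural regression: estimate and remove the cumulative error
#'
#' Runs the full compensation stage on a sequential-registration result:
#' descriptor distances d_i between consecutive warped sections (d_1 = 0),
#' weights w_i = sum(d_{j<=i}) / sum(d), the error flow between the last two
#' warped sections, and the weighted per-section compensation.
#'
#' @param result a \linkS4class{SerialResult}.
#' @param extractor a \linkS4class{DescriptorExtractor} for the distances.
#' @param estimator a \linkS4class{FlowEstimator} for the error flow.
#' @param fill fill policy for the compensation warps.
#' @return list with \code{stack} (the compensated
#'   \linkS4class{SectionStack}), \code{model} (the
#'   \linkS4class{CumulativeErrorModel}) and \code{manifest} (distances,
#'   weights and error-flow summary statistics).
#' @export
runStructuralRegression <- function(result, extractor = multiscaleExtractor(),
                                    estimator = classicalFlowEstimator(),
                                    fill = "edge") {
  n <- nSections(result)
  feats <- lapply(seq_len(n), function(i)
    extractFeatures(extractor, section(result@warped, i)))
  distances <- c(0, vapply(seq(2L, n), function(i)
    featureDistance(feats[[i]], feats[[i - 1L]]), numeric(1)))
  weights <- computeWeights(distances)
  errorFlow <- estimateErrorFlow(section(result@warped, n - 1L),
                                 section(result@warped, n), estimator)
  model <- new("CumulativeErrorModel", errorFlow = errorFlow,
               distances = distances, weights = weights)
  stack <- compensateStack(result, model, fill = fill)
  mag <- sqrt(errorFlow@dy^2 + errorFlow@dx^2)
  list(stack = stack, model = model,
       manifest = list(distances = distances, weights = weights,
                       errorFlowMeanPx = mean(mag),
                       errorFlowMaxPx = max(mag)))
}
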