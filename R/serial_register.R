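#' @include AllClasses.R AllGenerics.R flow_field.R rigid.R
NULL

#' Sequentially register a short serial stack between rigid endpoints
#'
#' The first and last sections are placed rigidly and are never deformed:
#' ws_1 = s_1 (or its provided rigid placement inside a long series) and
#' ws_n is s_n under the endpoint rigid transform, estimated from
#' (s_n, s_1) keypoint matching when \code{endpointMode = "rigid_pair"}.
#' Every interior section is then registered to the previously warped
#' section: F_{i->i-1} = estimate(s_i, ws_{i-1}), ws_i = warp(s_i, F).
#' The anchored endpoints provide the reference frame that the subsequent
#' cumulative-error compensation (structural regression) relies on.
#'
#' @param stack a \linkS4class{SectionStack} with n >= 3.
#' @param estimator a \linkS4class{FlowEstimator}.
#' @param endpointMode "rigid_pair" (estimate s_n -> s_1 rigidly) or
#'   "provided" (use \code{endpointRigid}/\code{firstRigid} as given).
#' @param endpointRigid rigid placement of s_n (required for "provided").
#' @param firstRigid rigid placement of s_1 (identity by default).
#' @param rigidSeed seed for the endpoint RANSAC.
#' @param fill fill policy for interior warps.
#' @return A \linkS4class{SerialResult}.
#' @export
sequentialRegister <- function(stack, estimator,
                               endpointMode = c("rigid_pair", "provided"),
                               endpointRigid = NULL, firstRigid = NULL,
                               rigidSeed = 42L, fill = "edge") {
  endpointMode <- match.arg(endpointMode)
  n <- nSections(stack)
  if (n < 3L)
    stop("serial registration needs at least 3 sections")
  if (is.null(firstRigid)) firstRigid <- RigidTransform()
  if (endpointMode == "rigid_pair") {
    endpointRigid <- registerRigid(section(stack, n), section(stack, 1L),
                                   seed = rigidSeed)
  } else if (is.null(endpointRigid)) {
    stop("endpointMode = 'provided' requires endpointRigid")
  }
  d <- stackShape(stack)
  warped <- array(0, dim = c(d, n))
  warped[, , 1L] <- if (firstRigid@theta == 0 && all(firstRigid@t == 0))
    section(stack, 1L) else applyRigid(section(stack, 1L), firstRigid,
                                       fill = fill)
  warped[, , n] <- if (endpointRigid@theta == 0 && all(endpointRigid@t == 0))
    section(stack, n) else applyRigid(section(stack, n), endpointRigid,
                                      fill = fill)
  flows <- vector("list", max(0L, n - 2L))
  for (i in seq(2L, n - 1L)) {
    F <- tryCatch(
      estimateFlow(estimator, section(stack, i), warped[, , i - 1L]),
      error = function(e)
        stop("flow estimation failed at section ", i, ": ",
             conditionMessage(e)))
    flows[[i - 1L]] <- F
    warped[, , i] <- warpImage(section(stack, i), F, fill = fill)
  }
  new("SerialResult",
      warped = SectionStack(warped, pixelSizeNm = stack@pixelSizeNm,
                            thicknessNm = stack@thicknessNm),
      flows = flows, endpointRigid = endpointRigid, firstRigid = firstRigid,
      manifest = list(estimator = estimator@name, endpointMode = endpointMode,
                      rigidSeed = rigidSeed, n = n, fill = fill))
}

#' Transport a label stack through a registration result
#'
#' Applies, per section, the same geometric transform that produced the
#' warped sections — the endpoint rigid placements for the first/last
#' section and the recorded interior flows — optionally composed with the
#' weighted cumulative-error compensation, in a single nearest-neighbour
#' resampling step per section.
#'
#' @param result a \linkS4class{SerialResult}.
#' @param labels a \linkS4class{LabelStack} congruent with the input stack.
#' @param model optional \linkS4class{CumulativeErrorModel}; when given, the
#'   compensation flow scaled by w_i is composed on top of each interior
#'   section's flow.
#' @return A \linkS4class{LabelStack}.
#' @export
applyResultToLabels <- function(result, labels, model = NULL) {
  n <- nSections(result)
  stopifnot(nSections(labels) == n)
  d <- stackShape(labels)
  out <- array(0L, dim = c(d, n))
  w <- if (is.null(model)) rep(0, n) else model@weights
  for (i in seq_len(n)) {
    flow <- if (i == 1L) rigidToFlow(result@firstRigid, d)
    else if (i == n) rigidToFlow(result@endpointRigid, d)
    else result@flows[[i - 1L]]
    if (!is.null(model) && i > 1L && i < n && w[i] > 0)
      flow <- composeFlows(scaleFlow(model@errorFlow, w[i]), flow)
    out[, , i] <- warpLabels(section(labels, i), flow)
  }
  LabelStack(out)
}
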