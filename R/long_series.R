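#' @include AllClasses.R AllGenerics.R serial_register.R structural_regression.R
NULL

#' Partition a long series into equal short series sharing benchmarks
#'
#' The last section of each short series doubles as the first section of the
#' next (the benchmark section), so K segments over n sections consume
#' n - 1 inter-section steps split as equally as possible, earlier segments
#' taking any remainder. Every interior index is covered exactly once and
#' every benchmark exactly twice.
#'
#' @param nTotal total section count.
#' @param nSegments number of short series (K >= 1).
#' @return A \linkS4class{SeriesPartition} (indices only; the rigid chain is
#'   filled in by \code{\link{registerBenchmarkChain}}).
#' @examples
#' splitSeries(25, 4)   # segments 1..7, 7..13, 13..19, 19..25
#' @export
splitSeries <- function(nTotal, nSegments) {
  stopifnot(nSegments >= 1L, nTotal >= 3L)
  steps <- nTotal - 1L
  base <- steps %/% nSegments
  rem <- steps %% nSegments
  segSteps <- rep(base, nSegments) + c(rep(1L, rem), rep(0L, nSegments - rem))
  if (any(segSteps < 2L))
    stop("infeasible partition: a segment would have fewer than 3 sections")
  bounds <- cumsum(c(1L, segSteps))
  segments <- lapply(seq_len(nSegments),
                     function(k) c(bounds[k], bounds[k + 1L]))
  new("SeriesPartition", segments = segments, benchmarks = as.integer(bounds))
}

#' Rigidly register a chain of benchmark sections
#'
#' Consecutive benchmarks — a subsampled series with lower axial resolution —
#' are registered pairwise (keypoints + RANSAC) and the pairwise transforms
#' are composed into global-frame placements anchored at the first benchmark
#' (identity).
#'
#' @param benchmarks a \linkS4class{SectionStack} of the benchmark sections.
#' @param seed RANSAC seed.
#' @return list of \linkS4class{RigidTransform}, one per benchmark.
#' @export
registerBenchmarkChain <- function(benchmarks, seed = 42L) {
  nb <- nSections(benchmarks)
  if (nb < 2L) stop("need at least 2 benchmark sections")
  chain <- vector("list", nb)
  chain[[1L]] <- RigidTransform()
  for (k in seq(2L, nb)) {
    pair <- tryCatch(
      registerRigid(section(benchmarks, k), section(benchmarks, k - 1L),
                    seed = seed),
      error = function(e)
        stop("benchmark chain failed between benchmarks ", k - 1L, " and ",
             k, ": ", conditionMessage(e)))
    chain[[k]] <- composeRigid(chain[[k - 1L]], pair)
  }
  chain
}

#' Register a long serial stack by splitting into short series
#'
#' Splits the stack, rigidly chains the shared benchmark sections, then runs
#' sequential registration plus structural regression on every segment with
#' its endpoints placed by the chain, and restacks the results (each shared
#' benchmark emitted once).
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param nSegments number of short series; how finely to split is a
#'   trade-off governed by how quickly error accumulates (more segments for
#'   faster accumulation).
#' @param estimator a \linkS4class{FlowEstimator}.
#' @param extractor a \linkS4class{DescriptorExtractor}.
#' @param chain optional precomputed list of benchmark placements (skips
#'   keypoint-based chaining).
#' @param labels optional \linkS4class{LabelStack} transported through the
#'   same per-section transforms.
#' @param seed RANSAC seed for the chain.
#' @return list with \code{stack} (registered \linkS4class{SectionStack}),
#'   \code{partition} (the \linkS4class{SeriesPartition} with its rigid
#'   chain), \code{labels} (transported \linkS4class{LabelStack} or NULL)
#'   and \code{manifest} (per-segment weights and error-flow summaries).
#' @export
registerLong <- function(stack, nSegments, estimator = classicalFlowEstimator(),
                         extractor = multiscaleExtractor(), chain = NULL,
                         labels = NULL, seed = 42L) {
  n <- nSections(stack)
  part <- splitSeries(n, nSegments)
  bench <- SectionStack(stackData(stack)[, , part@benchmarks, drop = FALSE])
  if (is.null(chain))
    chain <- registerBenchmarkChain(bench, seed = seed)
  if (length(chain) != length(part@benchmarks))
    stop("chain length does not match benchmark count")
  part@rigidChain <- chain
  d <- stackShape(stack)
  out <- array(0, dim = c(d, n))
  outLab <- if (!is.null(labels)) array(0L, dim = c(d, n)) else NULL
  manifests <- vector("list", nSegments)
  for (k in seq_len(nSegments)) {
    rng <- part@segments[[k]]
    idx <- seq(rng[1], rng[2])
    sub <- SectionStack(stackData(stack)[, , idx, drop = FALSE])
    res <- tryCatch(
      sequentialRegister(sub, estimator, endpointMode = "provided",
                         endpointRigid = chain[[k + 1L]],
                         firstRigid = chain[[k]]),
      error = function(e)
        stop("segment ", k, " failed: ", conditionMessage(e)))
    reg <- runStructuralRegression(res, extractor = extractor,
                                   estimator = estimator)
    out[, , idx] <- stackData(reg$stack)
    if (!is.null(labels)) {
      subLab <- LabelStack(stackData(labels)[, , idx, drop = FALSE])
      outLab[, , idx] <- stackData(applyResultToLabels(res, subLab,
                                                       model = reg$model))
    }
    manifests[[k]] <- reg$manifest
  }
  list(stack = SectionStack(out, pixelSizeNm = stack@pixelSizeNm,
                            thicknessNm = stack@thicknessNm),
       partition = part,
       labels = if (!is.null(outLab)) LabelStack(outLab) else NULL,
       manifest = list(segments = manifests,
                       benchmarks = part@benchmarks))
}
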