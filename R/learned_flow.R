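#' @include AllClasses.R AllGenerics.R pairwise_flow.R
NULL

## The trainable estimator keeps the coarse-to-fine, per-level cost-volume
## architecture but concentrates its capacity in a small parameter vector:
## a learnable linear mixing of the base descriptor channels (one shared map
## across the five octaves), a learnable soft-argmax temperature and a
## learnable increment-smoothing scale. With no autodiff dependency the
## parameters are trained by simultaneous-perturbation stochastic
## approximation (SPSA), a stochastic gradient method needing two loss
## evaluations per iteration regardless of parameter count.

#' Construct a learned coarse-to-fine flow estimator
#'
#' @param octaves pyramid depth (default 5, clamped to keep the coarsest
#'   level at least 8 px a side).
#' @param downscale factor per octave.
#' @param radius cost-volume search radius per level (px).
#' @param window aggregation box half-width (px).
#' @param nMixed number of mixed feature channels.
#' @param extractor descriptor extractor providing the base channels.
#' @param iterations matching passes per level.
#' @param seed seed for the parameter initialisation.
#' @return A \linkS4class{LearnedFlowEstimator} with freshly initialised
#'   parameters.
#' @export
learnedFlowEstimator <- function(octaves = 5L, downscale = 2, radius = 3L,
                                 window = 2L, nMixed = 6L,
                                 extractor = multiscaleExtractor(),
                                 iterations = 1L, seed = 1L) {
  nBase <- 3L * length(extractor@sigmas)
  rng <- .substream(seed, 911L)
  W <- matrix(rng$norm(nBase * nMixed, sd = 0.3), nBase, nMixed)
  # nudge toward a channel-selecting initialisation
  for (k in seq_len(min(nBase, nMixed))) W[k, k] <- W[k, k] + 0.5
  params <- c(as.numeric(W), log(0.5), log(1.0))
  cfg <- list(octaves = as.integer(octaves), downscale = downscale,
              radius = as.integer(radius), window = as.integer(window),
              nBase = nBase, nMixed = as.integer(nMixed),
              iterations = as.integer(iterations),
              sigmas = extractor@sigmas, lcnSigma = extractor@lcnSigma)
  new("LearnedFlowEstimator", name = "learned", params = params, config = cfg)
}

.learnedUnpack <- function(estimator) {
  cfg <- estimator@config
  nW <- cfg$nBase * cfg$nMixed
  list(W = matrix(estimator@params[seq_len(nW)], cfg$nBase, cfg$nMixed),
       tau = exp(estimator@params[nW + 1L]),
       smoothSigma = exp(estimator@params[nW + 2L]))
}

#' @rdname estimateFlow
setMethod("estimateFlow", "LearnedFlowEstimator",
  function(estimator, moving, reference) {
    if (!identical(dim(moving), dim(reference)))
      stop("moving and reference shapes differ")
    cfg <- estimator@config
    pr <- .learnedUnpack(estimator)
    ex <- multiscaleExtractor(cfg$sigmas, cfg$lcnSigma)
    featFun <- function(img) {
      base <- extractFeatures(ex, img)@data
      d <- dim(base)
      mixed <- matrix(base, d[1] * d[2], d[3]) %*% pr$W
      array(mixed, dim = c(d[1], d[2], cfg$nMixed))
    }
    .coarseToFineFlow(moving, reference, featFun,
                      octaves = cfg$octaves, downscale = cfg$downscale,
                      iterations = cfg$iterations, radius = cfg$radius,
                      window = cfg$window, smoothSigma = pr$smoothSigma,
                      method = "softargmax", tau = pr$tau)
  })

# total unsupervised loss of one pair under the current parameters;
# returns the individual terms
.pairLoss <- function(estimator, moving, reference, extractor, weights,
                      aug = NULL) {
  flow <- estimateFlow(estimator, moving, reference)
  warped <- warpImage(moving, flow, fill = "edge")
  ph <- featurePhotometricLoss(extractFeatures(extractor, reference),
                               extractFeatures(extractor, warped))
  sm <- if (weights$lambdaSmooth > 0) smoothnessLoss(flow) else 0
  au <- if (weights$lambdaAug > 0 && !is.null(aug))
    augmentationLoss(estimator, moving, reference, aug, pseudo = flow)
  else 0
  c(ph = ph, smooth = sm, aug = au,
    total = ph + weights$lambdaSmooth * sm + weights$lambdaAug * au)
}

.batchLoss <- function(estimator, pairs, idx, extractor, weights, augs) {
  terms <- vapply(idx, function(i)
    .pairLoss(estimator, pairs[[i]]$moving, pairs[[i]]$reference,
              extractor, weights, augs[[i]]),
    numeric(4))
  rowMeans(terms)
}

#' Train the learned flow estimator with the unsupervised loss
#'
#' Minimises L = L_ph + lambda_s L_smooth + lambda_a L_aug over the
#' estimator's parameters by SPSA with decaying gain sequences: each
#' iteration draws a mini-batch and a Rademacher perturbation, evaluates the
#' loss at the two perturbed parameter vectors, and steps along the implied
#' stochastic gradient. Fully deterministic for a fixed seed.
#'
#' @param estimator a \linkS4class{LearnedFlowEstimator} (fresh or resumed).
#' @param pairs list of \code{list(moving=, reference=)} matrix pairs.
#' @param extractor descriptor extractor defining the photometric loss.
#' @param weights list with \code{lambdaSmooth} and \code{lambdaAug}.
#' @param iterations SPSA iterations.
#' @param batchSize pairs per iteration.
#' @param a0,c0 SPSA step and perturbation scales.
#' @param seed RNG seed driving batches, perturbations and augmentations.
#' @param checkpointPath optional RDS path; the estimator and history are
#'   saved there every 25 iterations.
#' @return list(estimator = trained estimator, history = data.frame with one
#'   row per iteration holding the active loss terms).
#' @export
trainFlowEstimator <- function(estimator, pairs,
                               extractor = multiscaleExtractor(),
                               weights = list(lambdaSmooth = 50,
                                              lambdaAug = 0.2),
                               iterations = 100L, batchSize = 4L,
                               a0 = 0.02, c0 = 0.02, seed = 1L,
                               checkpointPath = NULL) {
  stopifnot(length(pairs) >= 1L)
  rng <- .substream(seed, 417L)
  p <- estimator@params
  np <- length(p)
  useAug <- weights$lambdaAug > 0
  cols <- c("ph", if (weights$lambdaSmooth > 0) "smooth",
            if (useAug) "aug", "total")
  hist <- matrix(NA_real_, iterations, length(cols),
                 dimnames = list(NULL, cols))
  for (k in seq_len(iterations)) {
    idx <- rng$sample(length(pairs), min(batchSize, length(pairs)))
    augs <- vector("list", length(pairs))
    if (useAug) {
      for (i in idx)
        augs[[i]] <- list(theta = rng$norm(1, sd = 2 * pi / 180),
                          t = rng$norm(2, sd = 1.5),
                          gain = 1 + rng$norm(1, sd = 0.05),
                          bias = rng$norm(1, sd = 0.02))
    }
    ck <- c0 / k^0.101
    ak <- a0 / (k + 10)^0.602
    delta <- sign(rng$norm(np))
    ep <- estimator; ep@params <- p + ck * delta
    em <- estimator; em@params <- p - ck * delta
    lp <- .batchLoss(ep, pairs, idx, extractor, weights, augs)
    lm <- .batchLoss(em, pairs, idx, extractor, weights, augs)
    ghat <- (lp[["total"]] - lm[["total"]]) / (2 * ck) * delta
    if (!all(is.finite(ghat)))
      stop("non-finite loss during training at iteration ", k)
    p <- p - ak * ghat
    mid <- (lp + lm) / 2
    hist[k, ] <- mid[cols]
    if (!is.null(checkpointPath) && k %% 25L == 0L) {
      est <- estimator; est@params <- p
      saveRDS(list(estimator = est,
                   history = as.data.frame(hist[seq_len(k), , drop = FALSE])),
              checkpointPath)
    }
  }
  estimator@params <- p
  list(estimator = estimator,
       history = as.data.frame(hist))
}

## Deterministic substream RNG: a private L'Ecuyer stream derived from
## (seed, tag) that never touches the global .Random.seed, so components are
## independently reproducible and library code stays side-effect free.
.substream <- function(seed, tag) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer((as.numeric(seed) * 7919 + tag) %% 2147483647),
             kind = "L'Ecuyer-CMRG")
    get(".Random.seed", globalenv())
  })
  withState <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    f()
  }
  list(
    norm = function(n, mean = 0, sd = 1)
      withState(function() stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1)
      withState(function() stats::runif(n, min, max)),
    sample = function(n, size)
      withState(function() sample.int(n, size)),
    pois = function(n, lambda)
      withState(function() stats::rpois(n, lambda))
  )
}
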