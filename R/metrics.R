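#' @include AllClasses.R AllGenerics.R
NULL

#' Zero-normalised cross-correlation between two images
#'
#' sum((a - mean(a)) (b - mean(b))) / sqrt(sum((a - mean(a))^2)
#' sum((b - mean(b))^2)) over the optional mask; in [-1, 1]. NCC is
#' invariant to positive affine intensity changes of either argument.
#'
#' @param a,b numeric matrices of one shape.
#' @param mask optional logical matrix restricting the computation (e.g. the
#'   intersection of warp-validity masks, so border fill does not depress
#'   the score).
#' @return scalar in [-1, 1]; error if either argument has zero variance
#'   over the mask.
#' @export
ncc <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b)))
    stop("image shapes differ")
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
  }
  if (length(a) < 2L)
    stop("need at least 2 valid pixels")
  ac <- a - mean(a)
  bc <- b - mean(b)
  va <- sum(ac^2); vb <- sum(bc^2)
  if (va == 0 || vb == 0)
    stop("NCC undefined: zero variance")
  sum(ac * bc) / sqrt(va * vb)
}

#' Dice overlap of one label id between two label maps or volumes
#'
#' 2 |A intersect B| / (|A| + |B|) for the binary masks of \code{id};
#' defined as 0 when exactly one mask is empty.
#'
#' @param labelA,labelB integer arrays (2-D or 3-D) of one shape.
#' @param id label id present in at least one of the two.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(labelA, labelB, id) {
  if (!identical(dim(labelA), dim(labelB)))
    stop("label shapes differ")
  A <- labelA == id
  B <- labelB == id
  sa <- sum(A); sb <- sum(B)
  if (sa == 0L && sb == 0L)
    stop("label id ", id, " absent from both maps")
  2 * sum(A & B) / (sa + sb)
}

#' Mean Dice of the k largest labels on the first section
#'
#' Selects the k nonzero labels with the largest pixel area on the FIRST
#' ground-truth section (ties broken by ascending id), computes each label's
#' Dice over the full 3-D extent of both volumes, and returns the mean —
#' the headline overlap score for registered neurite volumes, robust to
#' small intercellular-space labels.
#'
#' @param gt ground-truth \linkS4class{LabelStack}.
#' @param result registered \linkS4class{LabelStack}.
#' @param k number of labels (default 50); if fewer exist, all are used and
#'   the count is recorded in the "nLabels" attribute.
#' @return scalar mean Dice with attributes "nLabels" and "ids".
#' @export
topKDice <- function(gt, result, k = 50L) {
  if (!identical(dim(stackData(gt)), dim(stackData(result))))
    stop("label volume shapes differ")
  first <- section(gt, 1L)
  tab <- table(first[first > 0L])
  if (length(tab) == 0L)
    stop("no labels on the first ground-truth section")
  ids <- as.integer(names(tab))
  ord <- order(-as.integer(tab), ids)
  sel <- ids[ord][seq_len(min(k, length(ids)))]
  gtArr <- stackData(gt)
  resArr <- stackData(result)
  scores <- vapply(sel, function(id) diceCoefficient(gtArr, resArr, id),
                   numeric(1))
  structure(mean(scores), nLabels = length(sel), ids = sel)
}

#' Mean endpoint error between two flow fields
#'
#' Mean Euclidean norm of the per-pixel displacement difference (px) over
#' the optional mask.
#'
#' @param est,gt \linkS4class{FlowField}s of one shape.
#' @param mask optional logical matrix.
#' @return non-negative scalar (px).
#' @export
endpointError <- function(est, gt, mask = NULL) {
  if (!identical(stackShape(est), stackShape(gt)))
    stop("flow shapes differ")
  e <- sqrt((est@dy - gt@dy)^2 + (est@dx - gt@dx)^2)
  if (!is.null(mask)) e <- e[mask]
  mean(e)
}

#' Evaluate a registration result against ground truth
#'
#' Convenience wrapper assembling the standard report: per-pair NCC of each
#' result section against its ground-truth section, per-label Dice over the
#' selected top-k labels, and the mean top-k Dice.
#'
#' @param gtStack ground-truth \linkS4class{SectionStack}.
#' @param resultStack registered \linkS4class{SectionStack}.
#' @param gtLabels,resultLabels optional label volumes.
#' @param k top-k label count.
#' @return list(nccPerPair, meanNcc, topKDice, nLabels).
#' @export
evaluateRegistration <- function(gtStack, resultStack, gtLabels = NULL,
                                 resultLabels = NULL, k = 50L) {
  n <- nSections(gtStack)
  nccs <- vapply(seq_len(n), function(i)
    ncc(section(gtStack, i), section(resultStack, i)), numeric(1))
  out <- list(nccPerPair = nccs, meanNcc = mean(nccs))
  if (!is.null(gtLabels) && !is.null(resultLabels)) {
    td <- topKDice(gtLabels, resultLabels, k = k)
    out$topKDice <- as.numeric(td)
    out$nLabels <- attr(td, "nLabels")
  }
  out
}
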