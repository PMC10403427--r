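#' @include AllClasses.R AllGenerics.R flow_field.R
NULL

## Keypoint-based rigid registration: difference-of-Gaussian scale-space
## extrema, dominant-gradient orientation assignment, orientation-normalised
## 4x4x8 gradient-histogram descriptors, ratio-test matching and seeded
## two-point RANSAC with Procrustes refinement on the inliers.

# scale-space keypoints of one image; returns data.frame(y, x, sigma) 0-based
.detectKeypoints <- function(image, nScales = 8L, sigma0 = 1.6,
                             step = 2^(1 / 3), contrastThresh = 0.02,
                             edgeRatio = 10, border = 8L) {
  sig <- sigma0 * step^(0:(nScales - 1))
  G <- lapply(sig, function(s) gauss_blur_cpp(image, s))
  D <- lapply(seq_len(nScales - 1L), function(k) G[[k + 1L]] - G[[k]])
  nr <- nrow(image); nc <- ncol(image)
  kps <- list()
  for (k in 2:(length(D) - 1L)) {
    d0 <- D[[k]]
    a <- abs(d0)
    # strict 3x3x3 extremum test, vectorised over interior pixels
    ii <- (border + 1):(nr - border)
    jj <- (border + 1):(nc - border)
    sub <- d0[ii, jj]
    ok <- abs(sub) > contrastThresh
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      nb <- D[[k + dz]][ii + dy, jj + dx]
      ok <- ok & ((sub > 0 & sub > nb) | (sub < 0 & sub < nb))
      if (!any(ok)) break
    }
    if (!any(ok)) next
    w <- which(ok, arr.ind = TRUE)
    y <- ii[w[, 1]]; x <- jj[w[, 2]]
    # Hessian edge-response filter
    keep <- logical(nrow(w))
    for (q in seq_along(y)) {
      yy <- y[q]; xx <- x[q]
      dyy <- d0[yy + 1, xx] + d0[yy - 1, xx] - 2 * d0[yy, xx]
      dxx <- d0[yy, xx + 1] + d0[yy, xx - 1] - 2 * d0[yy, xx]
      dxy <- (d0[yy + 1, xx + 1] - d0[yy + 1, xx - 1] -
              d0[yy - 1, xx + 1] + d0[yy - 1, xx - 1]) / 4
      tr <- dyy + dxx; det <- dyy * dxx - dxy^2
      keep[q] <- det > 0 && tr^2 / det < (edgeRatio + 1)^2 / edgeRatio
    }
    if (any(keep))
      kps[[length(kps) + 1L]] <- data.frame(y = y[keep] - 1, x = x[keep] - 1,
                                            sigma = sig[k])
  }
  if (length(kps) == 0L)
    return(data.frame(y = numeric(0), x = numeric(0), sigma = numeric(0)))
  do.call(rbind, kps)
}

# orientation + 4x4x8 descriptor for each keypoint; returns list(angles,
# desc matrix) with one row per keypoint (may drop weak keypoints)
.describeKeypoints <- function(image, kps, nBins = 36L) {
  if (nrow(kps) == 0L)
    return(list(kps = kps, desc = matrix(0, 0, 128)))
  nr <- nrow(image); nc <- ncol(image)
  smoothed <- gauss_blur_cpp(image, 1.6)
  gy <- rbind(smoothed[2:nr, ] - smoothed[1:(nr - 1), ], 0)
  gx <- cbind(smoothed[, 2:nc] - smoothed[, 1:(nc - 1)], 0)
  mag <- sqrt(gy^2 + gx^2)
  ang <- atan2(gy, gx)
  descs <- matrix(0, nrow(kps), 128)
  angles <- numeric(nrow(kps))
  ok <- logical(nrow(kps))
  half <- 8L                       # 16x16 sampling grid
  for (q in seq_len(nrow(kps))) {
    y0 <- kps$y[q] + 1; x0 <- kps$x[q] + 1
    rad <- 6L
    ys <- max(1, y0 - rad):min(nr, y0 + rad)
    xs <- max(1, x0 - rad):min(nc, x0 + rad)
    m <- mag[ys, xs]
    a <- ang[ys, xs]
    wy <- exp(-0.5 * ((ys - y0) / (rad / 1.5))^2)
    wx <- exp(-0.5 * ((xs - x0) / (rad / 1.5))^2)
    wgt <- outer(wy, wx) * m
    bins <- floor((a + pi) / (2 * pi) * nBins) %% nBins
    h <- vapply(0:(nBins - 1), function(b) sum(wgt[bins == b]), numeric(1))
    h <- (h + h[c(nBins, 1:(nBins - 1))] + h[c(2:nBins, 1)]) / 3  # smooth
    bmax <- which.max(h)
    # parabolic refinement of the dominant bin
    hl <- h[if (bmax == 1) nBins else bmax - 1]
    hr <- h[if (bmax == nBins) 1 else bmax + 1]
    den <- hl - 2 * h[bmax] + hr
    off <- if (abs(den) > 1e-12) 0.5 * (hl - hr) / den else 0
    theta <- ((bmax - 1 + off) / nBins) * 2 * pi - pi
    angles[q] <- theta
    # rotated 16x16 sampling grid, spacing 1 px, 4x4 cells x 8 bins
    ct <- cos(theta); st <- sin(theta)
    dvec <- numeric(128)
    for (u in seq_len(16)) {
      for (v in seq_len(16)) {
        oy <- u - 8.5; ox <- v - 8.5
        sy <- y0 + ct * oy - st * ox
        sx <- x0 + st * oy + ct * ox
        iy <- round(sy); ix <- round(sx)
        if (iy < 1 || iy > nr || ix < 1 || ix > nc) next
        gmag <- mag[iy, ix]
        gang <- ang[iy, ix] - theta
        gb <- (gang + pi) / (2 * pi) * 8
        b0 <- floor(gb) %% 8
        fb <- gb - floor(gb)
        cell <- (ceiling(u / 4) - 1) * 4 + ceiling(v / 4)
        w <- gmag * exp(-0.5 * ((oy^2 + ox^2) / 36))
        i0 <- (cell - 1) * 8 + b0 + 1
        i1 <- (cell - 1) * 8 + ((b0 + 1) %% 8) + 1
        dvec[i0] <- dvec[i0] + w * (1 - fb)
        dvec[i1] <- dvec[i1] + w * fb
      }
    }
    nn <- sqrt(sum(dvec^2))
    if (nn < 1e-9) next
    dvec <- pmin(dvec / nn, 0.2)
    dvec <- dvec / sqrt(sum(dvec^2))
    descs[q, ] <- dvec
    ok[q] <- TRUE
  }
  list(kps = kps[ok, , drop = FALSE], desc = descs[ok, , drop = FALSE],
       angles = angles[ok])
}

# ratio-test nearest-neighbour matching; returns index pairs into kpsA/kpsB
.matchDescriptors <- function(descA, descB, ratio = 0.8) {
  if (nrow(descA) == 0L || nrow(descB) < 2L)
    return(cbind(integer(0), integer(0)))
  # squared L2 via cross product (descriptors are unit-norm)
  sim <- descA %*% t(descB)
  d2 <- pmax(2 - 2 * sim, 0)
  out <- matrix(0L, 0, 2)
  for (i in seq_len(nrow(descA))) {
    o <- order(d2[i, ])[1:2]
    if (d2[i, o[1]] < ratio^2 * d2[i, o[2]])
      out <- rbind(out, c(i, o[1]))
  }
  out
}

#' Estimate the rigid transform aligning a moving image to a reference
#'
#' Keypoints are detected in both images (difference-of-Gaussian extrema),
#' described by orientation-normalised gradient histograms, matched with a
#' ratio test and fed to a seeded two-point RANSAC; the rotation+translation
#' maximising the inlier count is refined by Procrustes least squares on the
#' inliers. The returned transform satisfies
#' \code{applyRigid(moving, T)} approximately equal to \code{reference}.
#'
#' @param moving,reference numeric matrices of one shape.
#' @param seed RANSAC seed (reproducibility).
#' @param maxIter RANSAC iterations.
#' @param inlierThresh inlier residual threshold (px).
#' @param minInliers minimum inlier count below which estimation fails.
#' @param ratio nearest-neighbour ratio-test threshold.
#' @return A \linkS4class{RigidTransform}.
#' @export
registerRigid <- function(moving, reference, seed = 42L, maxIter = 2000L,
                          inlierThresh = 3, minInliers = 6L, ratio = 0.8) {
  if (!identical(dim(moving), dim(reference)))
    stop("moving and reference shapes differ")
  ka <- .describeKeypoints(moving, .detectKeypoints(moving))
  kb <- .describeKeypoints(reference, .detectKeypoints(reference))
  matches <- .matchDescriptors(ka$desc, kb$desc, ratio = ratio)
  if (nrow(matches) < max(3L, minInliers))
    stop("rigid registration failed: only ", nrow(matches),
         " tentative matches")
  P <- cbind(ka$kps$y[matches[, 1]], ka$kps$x[matches[, 1]])
  Q <- cbind(kb$kps$y[matches[, 2]], kb$kps$x[matches[, 2]])
  d <- dim(moving)
  ctr <- c((d[1] - 1) / 2, (d[2] - 1) / 2)
  Pc <- sweep(P, 2, ctr)
  rng <- .substream(seed, 127L)
  nM <- nrow(P)
  best <- NULL; bestIn <- -1L
  for (it in seq_len(maxIter)) {
    s <- rng$sample(nM, 2L)
    va <- P[s[2], ] - P[s[1], ]
    vb <- Q[s[2], ] - Q[s[1], ]
    if (sum(va^2) < 4 || sum(vb^2) < 4) next
    th <- atan2(vb[2], vb[1]) - atan2(va[2], va[1])
    # model: q = R (p - c) + c + t  with R = [[cos,-sin],[sin,cos]] on (y,x)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t0 <- Q[s[1], ] - (R %*% Pc[s[1], ])[, 1] - ctr
    pred <- t(R %*% t(Pc)) + matrix(ctr + t0, nM, 2, byrow = TRUE)
    res <- sqrt(rowSums((pred - Q)^2))
    nin <- sum(res < inlierThresh)
    if (nin > bestIn) {
      bestIn <- nin
      best <- res < inlierThresh
    }
  }
  if (bestIn < minInliers)
    stop("rigid registration failed: only ", bestIn,
         " RANSAC inliers (need ", minInliers, ")")
  # Procrustes refinement (rotation constrained, no scale)
  Pi <- Pc[best, , drop = FALSE]
  Qi <- sweep(Q[best, , drop = FALSE], 2, ctr)
  mp <- colMeans(Pi); mq <- colMeans(Qi)
  H <- t(sweep(Pi, 2, mp)) %*% sweep(Qi, 2, mq)
  sv <- svd(H)
  S <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  th <- atan2(R[2, 1], R[1, 1])
  t0 <- mq - (R %*% mp)[, 1]
  RigidTransform(th, t0)
}
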