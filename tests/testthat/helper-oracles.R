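# Independent brute-force oracles and small shared fixtures. Everything here
# is written as plain nested loops / direct formulas so it cannot share a bug
# with the vectorised or compiled implementation paths.

# per-pixel bilinear backward warp; strict constant fill outside the domain
oracleWarpBilinear <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      sy <- (i - 1) + dy[i, j]
      sx <- (j - 1) + dx[i, j]
      if (sy < 0 || sy > nr - 1 || sx < 0 || sx > nc - 1) next
      y0 <- min(floor(sy), nr - 2); x0 <- min(floor(sx), nc - 2)
      if (nr == 1) y0 <- 0
      if (nc == 1) x0 <- 0
      fy <- sy - y0; fx <- sx - x0
      y1 <- min(y0 + 1, nr - 1); x1 <- min(x0 + 1, nc - 1)
      out[i, j] <-
        (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * img[y1 + 1, x0 + 1] + fx * img[y1 + 1, x1 + 1])
    }
  }
  out
}

# per-pixel nearest-neighbour label warp; 0 outside
oracleWarpNearest <- function(lab, dy, dx) {
  nr <- nrow(lab); nc <- ncol(lab)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      y <- round((i - 1) + dy[i, j])
      x <- round((j - 1) + dx[i, j])
      if (y >= 0 && y <= nr - 1 && x >= 0 && x <= nc - 1)
        out[i, j] <- lab[y + 1, x + 1]
    }
  }
  out
}

# dense TPS evaluation by explicit system solve + per-pixel loops
oracleTpsField <- function(pts, vec, nr, nc) {
  m <- nrow(pts)
  U <- function(r) if (r > 0) r^2 * log(r) else 0
  K <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m))
    K[a, b] <- U(sqrt(sum((pts[a, ] - pts[b, ])^2)))
  P <- cbind(1, pts)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  evalOne <- function(v) {
    sol <- solve(L, c(v, 0, 0, 0))
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      s <- sol[m + 1] + sol[m + 2] * (i - 1) + sol[m + 3] * (j - 1)
      for (a in seq_len(m))
        s <- s + sol[a] * U(sqrt(((i - 1) - pts[a, 1])^2 +
                                 ((j - 1) - pts[a, 2])^2))
      out[i, j] <- s
    }
    out
  }
  list(fy = evalOne(vec[, 1]), fx = evalOne(vec[, 2]))
}

# mask of pixels whose ground-truth correspondence stays inside the image
gtValidMask <- function(gt) {
  d <- stackShape(gt)
  py <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  px <- matrix(rep(seq_len(d[2]) - 1, each = d[1]), d[1], d[2])
  sy <- py + flowDy(gt)
  sx <- px + flowDx(gt)
  sy >= 0 & sy <= d[1] - 1 & sx >= 0 & sx <= d[2] - 1
}

# per-section centroids (0-based) of the given label ids
labelCentroids <- function(labels, ids) {
  n <- nSections(labels)
  out <- array(NA_real_, c(n, length(ids), 2))
  for (i in seq_len(n)) {
    m <- section(labels, i)
    for (k in seq_along(ids)) {
      w <- which(m == ids[k], arr.ind = TRUE)
      if (nrow(w) > 0) out[i, k, ] <- c(mean(w[, 1]) - 1, mean(w[, 2]) - 1)
    }
  }
  out
}

# shift image content by +(dy, dx) via the backward warp
shiftImage <- function(img, dy, dx, fill = "edge")
  warpImage(img, FlowField(matrix(-dy, nrow(img), ncol(img)),
                           matrix(-dx, nrow(img), ncol(img))), fill = fill)

# drift experiment shared by module and acceptance tests: phantom with known
# tilted-cylinder geometry, constant drift, provided endpoint anchor;
# returns RMS centroid deviation from the true axes with and without
# cumulative-error compensation
runDriftExperiment <- function(seed, nSections = 16L, size = 160L,
                               tiltMaxDeg = 30, driftRange = c(0.5, 2)) {
  dmag <- runif(1, driftRange[1], driftRange[2])
  dang <- runif(1, 0, 2 * pi)
  deltas <- rbind(c(0, 0),
                  matrix(dmag * c(cos(dang), sin(dang)), nSections - 1L, 2,
                         byrow = TRUE))
  margin <- ceiling(max(abs(apply(deltas, 2, cumsum)))) + 2L
  sp <- phantomSpec(nSections = nSections, rows = size, cols = size,
                    nNeurites = 5L, radiusRange = c(5, 8),
                    tiltMax = tan(tiltMaxDeg * pi / 180), marginPx = margin,
                    seed = seed)
  ph <- makePhantom(sp)
  dr <- injectDrift(ph$stack, deltas, labels = ph$labels)
  est <- classicalFlowEstimator()
  res <- sequentialRegister(dr$stack, est, endpointMode = "provided",
                            endpointRigid = RigidTransform(0, -dr$shifts[nSections, ]))
  reg <- runStructuralRegression(res, estimator = est)
  ids <- seq_len(5)
  rms <- function(cc) sqrt(mean((cc - ph$centroids)^2, na.rm = TRUE))
  c(uncompensated = rms(labelCentroids(applyResultToLabels(res, dr$labels),
                                       ids)),
    compensated = rms(labelCentroids(
      applyResultToLabels(res, dr$labels, model = reg$model), ids)))
}
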