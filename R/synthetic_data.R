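#' @include AllClasses.R AllGenerics.R flow_field.R learned_flow.R
NULL

#' Specification of a random thin-plate-spline deformation
#'
#' Emulates section-preparation distortion: displacement vectors drawn from
#' a zero-mean normal distribution at control locations distributed
#' uniformly over the section, interpolated by a thin-plate spline.
#'
#' @param nControl number of control points (>= 3).
#' @param sigmaPx standard deviation of each displacement component (px).
#' @param marginPx exclusion border for control locations (px).
#' @param seed RNG seed.
#' @return list of class "TPSDeformSpec".
#' @export
tpsSpec <- function(nControl = 10L, sigmaPx = 4, marginPx = 16L, seed = 1L) {
  stopifnot(nControl >= 3L, sigmaPx >= 0)
  structure(list(nControl = as.integer(nControl), sigmaPx = sigmaPx,
                 marginPx = as.integer(marginPx), seed = as.integer(seed)),
            class = "TPSDeformSpec")
}

# TPS radial basis; U(0) = 0
.tpsU <- function(r) ifelse(r > 0, r^2 * log(r), 0)

# solve the TPS system for scattered values v at points (y, x); returns the
# weights and affine part. pts: m x 2 (y, x)
.tpsSolve <- function(pts, v) {
  m <- nrow(pts)
  r <- as.matrix(stats::dist(pts))
  K <- .tpsU(r)
  P <- cbind(1, pts)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(L, c(v, 0, 0, 0))
  list(w = sol[seq_len(m)], a = sol[m + 1:3])
}

# evaluate a solved TPS at all pixels of an (nr, nc) grid
.tpsEvalGrid <- function(fit, pts, nr, nc) {
  py <- matrix(seq_len(nr) - 1, nr, nc)
  px <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  out <- fit$a[1] + fit$a[2] * py + fit$a[3] * px
  for (i in seq_len(nrow(pts))) {
    r <- sqrt((py - pts[i, 1])^2 + (px - pts[i, 2])^2)
    out <- out + fit$w[i] * .tpsU(r)
  }
  out
}

#' Deform an image by a random thin-plate-spline field
#'
#' Control locations are sampled uniformly (inside the margin), displacement
#' vectors from N(0, sigmaPx^2) per component; the dense field interpolates
#' those vectors by a thin-plate spline (r^2 log r basis plus affine part)
#' and is returned in the backward convention together with the warped
#' image. sigmaPx = 0 gives the exact identity. Degenerate (collinear)
#' control configurations are resampled from the next substream, as are
#' fields whose map compresses any neighbourhood by more than about 5:1
#' (Jacobian determinant below 0.2): tissue sections distort but do not fold
#' or collapse in plane, and such fields destroy texture instead of
#' displacing it (a folded field also has no inverse).
#'
#' @param image numeric matrix.
#' @param spec a \code{\link{tpsSpec}}.
#' @return list(image = deformed image, flow = ground-truth
#'   \linkS4class{FlowField}, controls = list(points, vectors)).
#' @export
tpsDeform <- function(image, spec) {
  nr <- nrow(image); nc <- ncol(image)
  if (spec$sigmaPx == 0) {
    # exact identity; no control sampling needed
    return(list(image = image, flow = zeroFlow(c(nr, nc)),
                controls = list(points = matrix(numeric(0), 0, 2),
                                vectors = matrix(numeric(0), 0, 2))))
  }
  ctl <- .sampleTpsField(c(nr, nc), spec)
  flow <- FlowField(ctl$fy, ctl$fx)
  list(image = warpImage(image, flow, fill = "edge"), flow = flow,
       controls = ctl[c("points", "vectors")])
}

# smallest Jacobian determinant of the map p -> p + F(p) over the grid
.minJacobian <- function(fy, fx) {
  nr <- nrow(fy); nc <- ncol(fy)
  dydy <- (fy[c(2:nr, nr), ] - fy[c(1, 1:(nr - 1)), ]) / 2
  dydx <- (fy[, c(2:nc, nc)] - fy[, c(1, 1:(nc - 1))]) / 2
  dxdy <- (fx[c(2:nr, nr), ] - fx[c(1, 1:(nr - 1)), ]) / 2
  dxdx <- (fx[, c(2:nc, nc)] - fx[, c(1, 1:(nc - 1))]) / 2
  min((1 + dydy) * (1 + dxdx) - dydx * dxdy)
}

.sampleTpsField <- function(shape, spec) {
  nr <- shape[1]; nc <- shape[2]
  m <- spec$marginPx
  if (2 * m >= min(nr, nc) - 1)
    stop("marginPx too large for the image")
  for (attempt in 0:19) {
    rng <- .substream(spec$seed, 53L + attempt)
    pts <- cbind(rng$unif(spec$nControl, m, nr - 1 - m),
                 rng$unif(spec$nControl, m, nc - 1 - m))
    vec <- cbind(rng$norm(spec$nControl, sd = spec$sigmaPx),
                 rng$norm(spec$nControl, sd = spec$sigmaPx))
    if (spec$sigmaPx == 0)
      return(list(points = pts, vectors = vec))
    # reject (nearly) collinear control configurations
    if (qr(cbind(1, pts))$rank < 3) next
    fitY <- tryCatch(.tpsSolve(pts, vec[, 1]), error = function(e) NULL)
    fitX <- tryCatch(.tpsSolve(pts, vec[, 2]), error = function(e) NULL)
    if (is.null(fitY) || is.null(fitX)) next
    fy <- .tpsEvalGrid(fitY, pts, nr, nc)
    fx <- .tpsEvalGrid(fitX, pts, nr, nc)
    if (.minJacobian(fy, fx) < 0.2) next
    return(list(points = pts, vectors = vec, fitY = fitY, fitX = fitX,
                fy = fy, fx = fx))
  }
  stop("could not sample a non-degenerate control configuration")
}

#' Specification of a tilted-cylinder neurite phantom
#'
#' In a short series a neurite is well approximated by a cylinder: each
#' phantom neurite is a disk whose centre moves linearly with section index
#' (the tilt, in px/section). All sections share one smoothed background
#' texture (mimicking tissue that continues through the block), on which
#' membrane-and-interior disks are rendered and per-section pixel noise is
#' added.
#'
#' @param nSections,rows,cols stack geometry.
#' @param nNeurites number of neurites.
#' @param radiusRange (min, max) disk radius in px.
#' @param tiltMax maximum tilt-vector magnitude (px/section); the tilt
#'   angle against the stack axis is atan(tiltMax) at 1:1 voxel aspect.
#' @param marginPx clear border kept free of neurites on every section;
#'   widen it when the stack will be shifted afterwards (e.g. by
#'   \code{\link{injectDrift}}) so structures stay inside the frame.
#' @param noiseSd additive Gaussian pixel noise sd.
#' @param textureSigma smoothing scale of the background texture (px).
#' @param seed RNG seed.
#' @return list of class "PhantomSpec".
#' @export
phantomSpec <- function(nSections = 16L, rows = 128L, cols = 128L,
                        nNeurites = 6L, radiusRange = c(5, 9), tiltMax = 1,
                        noiseSd = 0.03, textureSigma = 2, marginPx = 2L,
                        seed = 1L) {
  structure(list(nSections = as.integer(nSections), rows = as.integer(rows),
                 cols = as.integer(cols), nNeurites = as.integer(nNeurites),
                 radiusRange = radiusRange, tiltMax = tiltMax,
                 noiseSd = noiseSd, textureSigma = textureSigma,
                 marginPx = as.integer(marginPx), seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a tilted-cylinder neurite phantom with ground truth
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list(stack = \linkS4class{SectionStack},
#'   labels = \linkS4class{LabelStack},
#'   centroids = nSections x nNeurites x 2 array of true (y, x) centres,
#'   tilts = nNeurites x 2 matrix, radii = numeric).
#' @export
makePhantom <- function(spec) {
  rng <- .substream(spec$seed, 211L)
  nr <- spec$rows; nc <- spec$cols; n <- spec$nSections
  radii <- rng$unif(spec$nNeurites, spec$radiusRange[1], spec$radiusRange[2])
  # tilt vectors sampled by magnitude and direction so |tilt| <= tiltMax
  tmag <- rng$unif(spec$nNeurites, 0, spec$tiltMax)
  tang <- rng$unif(spec$nNeurites, 0, 2 * pi)
  tilts <- cbind(tmag * cos(tang), tmag * sin(tang))
  # place centres so every disk stays inside the frame on every section
  centres <- matrix(NA_real_, spec$nNeurites, 2)
  for (k in seq_len(spec$nNeurites)) {
    placed <- FALSE
    for (try in seq_len(400)) {
      span <- tilts[k, ] * (n - 1)
      mg <- spec$marginPx
      loY <- radii[k] + mg + max(0, -span[1])
      hiY <- nr - 1 - radii[k] - mg - max(0, span[1])
      loX <- radii[k] + mg + max(0, -span[2])
      hiX <- nc - 1 - radii[k] - mg - max(0, span[2])
      if (loY >= hiY || loX >= hiX) break
      cand <- c(rng$unif(1, loY, hiY), rng$unif(1, loX, hiX))
      if (k == 1L ||
          all(sqrt(rowSums(sweep(centres[seq_len(k - 1), , drop = FALSE], 2,
                                 cand)^2)) >
              radii[seq_len(k - 1)] + radii[k] + 4)) {
        centres[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible packing: reduce nNeurites, radii or tilt")
  }
  py <- matrix(seq_len(nr) - 1, nr, nc)
  px <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  imgs <- array(0, dim = c(nr, nc, n))
  labs <- array(0L, dim = c(nr, nc, n))
  centroids <- array(NA_real_, dim = c(n, spec$nNeurites, 2))
  # one background texture for the whole short series: tissue around the
  # neurites continues through the block, which is what gives pairwise
  # registration its (correct) anchor and makes straightening of tilted
  # neurites the dominant error mode
  bg0 <- gauss_blur_cpp(matrix(rng$norm(nr * nc), nr, nc),
                        spec$textureSigma)
  bg0 <- 0.45 + 0.12 * bg0 / max(stats::sd(bg0), 1e-9)
  for (i in seq_len(n)) {
    img <- bg0
    lab <- matrix(0L, nr, nc)
    for (k in seq_len(spec$nNeurites)) {
      cy <- centres[k, 1] + tilts[k, 1] * (i - 1)
      cx <- centres[k, 2] + tilts[k, 2] * (i - 1)
      centroids[i, k, ] <- c(cy, cx)
      r <- sqrt((py - cy)^2 + (px - cx)^2)
      # dark membrane ring, bright interior, soft anti-aliased edges
      interior <- pmin(pmax(radii[k] - 1.5 - r, 0), 1)
      membrane <- pmin(pmax(1 - abs(r - radii[k]) / 1.5, 0), 1)
      img <- img * (1 - membrane) + 0.15 * membrane
      img <- img * (1 - interior) + (0.75 - 0.1 * (k %% 3)) * interior
      lab[r < radii[k]] <- k
    }
    img <- img + matrix(rng$norm(nr * nc, sd = spec$noiseSd), nr, nc)
    imgs[, , i] <- pmin(pmax(img, 0), 1)
    labs[, , i] <- lab
  }
  list(stack = SectionStack(imgs), labels = LabelStack(labs),
       centroids = centroids, tilts = tilts, radii = radii)
}

#' Inject cumulative drift into a stack
#'
#' Section i is translated by the prefix sum D_i = sum(delta_j, j <= i) of
#' the per-section drift increments — the constructible analogue of
#' cumulative registration error e_i = e_{i-1} + delta e_i.
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param delta numeric(2) constant per-section increment (dy, dx), or an
#'   n x 2 matrix of per-section increments.
#' @param labels optional \linkS4class{LabelStack} shifted identically.
#' @return list(stack, labels, shifts = n x 2 cumulative shifts,
#'   flows = list of ground-truth backward \linkS4class{FlowField}s).
#' @export
injectDrift <- function(stack, delta, labels = NULL) {
  n <- nSections(stack)
  d <- stackShape(stack)
  if (is.null(dim(delta)))
    delta <- matrix(delta, n, 2, byrow = TRUE)
  stopifnot(nrow(delta) == n, all(is.finite(delta)))
  shifts <- apply(delta, 2, cumsum)
  if (n == 1L) shifts <- matrix(shifts, 1)
  out <- stackData(stack)
  outLab <- if (!is.null(labels)) stackData(labels) else NULL
  flows <- vector("list", n)
  for (i in seq_len(n)) {
    # shifting content by +D is the backward flow F = -D
    fl <- FlowField(matrix(-shifts[i, 1], d[1], d[2]),
                    matrix(-shifts[i, 2], d[1], d[2]))
    flows[[i]] <- fl
    if (any(shifts[i, ] != 0)) {
      out[, , i] <- warpImage(out[, , i], fl, fill = "edge")
      if (!is.null(outLab))
        outLab[, , i] <- warpLabels(section(labels, i), fl)
    }
  }
  list(stack = SectionStack(out),
       labels = if (!is.null(outLab)) LabelStack(outLab) else NULL,
       shifts = shifts, flows = flows)
}

#' Band-limited random texture image
#'
#' Gaussian-smoothed white noise rescaled to [0, 1]; the standard source
#' image for flow-recovery experiments.
#'
#' @param rows,cols image size.
#' @param seed RNG seed.
#' @param smoothSigma smoothing scale (px).
#' @return numeric matrix in [0, 1].
#' @export
textureImage <- function(rows, cols, seed = 1L, smoothSigma = 1.5) {
  rng <- .substream(seed, 389L)
  img <- gauss_blur_cpp(matrix(rng$norm(rows * cols), rows, cols),
                        smoothSigma)
  (img - min(img)) / (max(img) - min(img))
}

#' Generate (moving, reference) training/evaluation pairs with ground truth
#'
#' The reference is a clean section; the moving image is a TPS-deformed copy.
#' The stored ground truth \code{gt} is the backward flow that aligns the
#' moving image onto the reference (the numerical inverse of the deformation
#' field, see \code{\link{invertFlow}}), i.e. the field a perfect estimator
#' would return for the pair. Deterministic per seed.
#'
#' @param nPairs number of pairs.
#' @param spec a \code{\link{tpsSpec}} (its seed field is ignored; per-pair
#'   seeds derive from \code{seed}).
#' @param seed master seed.
#' @param imageSource function(k) returning the k-th (oversized, see
#'   \code{padPx}) source image; defaults to \code{\link{textureImage}}s of
#'   size \code{size + 2 * padPx}.
#' @param size integer(2) final pair size (rows, cols), default 64 x 64.
#' @param padPx border trimmed off after deforming. Deforming an oversized
#'   source and centre-cropping keeps genuine texture at the pair borders
#'   instead of edge-fill smears, mirroring the crop-after-warp protocol
#'   used for real section volumes.
#' @return list of list(moving, reference, gt, deformation); \code{gt} is
#'   the backward flow aligning moving onto reference, \code{deformation}
#'   the field that produced the moving image (both cropped).
#' @export
makeRegistrationPairs <- function(nPairs, spec = tpsSpec(), seed = 1L,
                                  imageSource = NULL, size = c(64L, 64L),
                                  padPx = 16L) {
  size <- as.integer(size)
  padPx <- as.integer(padPx)
  big <- size + 2L * padPx
  if (is.null(imageSource))
    imageSource <- function(k) textureImage(
      big[1], big[2],
      seed = as.integer((as.numeric(seed) * 1000 + k) %% 2147483647))
  crop <- function(m) m[padPx + seq_len(size[1]), padPx + seq_len(size[2]),
                        drop = FALSE]
  lapply(seq_len(nPairs), function(k) {
    ref <- imageSource(k)
    sp <- spec
    sp$seed <- as.integer((as.numeric(seed) * 131 + k) %% 2147483647)
    def <- tpsDeform(ref, sp)
    gt <- if (sp$sigmaPx == 0) def$flow else invertFlow(def$flow)
    list(moving = crop(def$image), reference = crop(ref),
         gt = FlowField(crop(gt@dy), crop(gt@dx)),
         deformation = FlowField(crop(def$flow@dy), crop(def$flow@dx)))
  })
}

#' Keep every k-th section of a stack
#'
#' Axial subsampling utility emulating the reduction of a fine isotropic
#' volume to ssEM-like section spacing.
#'
#' @param stack a \linkS4class{SectionStack} or \linkS4class{LabelStack}.
#' @param k keep sections 1, 1+k, 1+2k, ... (default 8).
#' @return The subsampled stack of the same class.
#' @export
subsampleSections <- function(stack, k = 8L) {
  idx <- seq(1L, nSections(stack), by = k)
  sub <- stackData(stack)[, , idx, drop = FALSE]
  if (is(stack, "LabelStack")) LabelStack(sub) else SectionStack(sub)
}
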