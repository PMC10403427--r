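test_that("zero-amplitude TPS specs give the exact identity", {
  img <- textureImage(32, 32, seed = 1)
  d <- tpsDeform(img, tpsSpec(sigmaPx = 0, seed = 3))
  expect_identical(d$image, img)
  expect_equal(max(abs(flowDy(d$flow))), 0)
})

test_that("dense TPS fields match an independent solve-and-evaluate oracle", {
  for (k in 1:20) {
    spec <- tpsSpec(nControl = sample(4:7, 1), sigmaPx = runif(1, 0.3, 1.2),
                    marginPx = 5L, seed = 100 + k)
    img <- textureImage(24, 24, seed = k)
    d <- tpsDeform(img, spec)
    o <- oracleTpsField(d$controls$points, d$controls$vectors, 24, 24)
    expect_lt(max(abs(flowDy(d$flow) - o$fy)), 1e-6)
    expect_lt(max(abs(flowDx(d$flow) - o$fx)), 1e-6)
  }
})

test_that("the TPS field interpolates its control displacements", {
  spec <- tpsSpec(nControl = 6, sigmaPx = 3, marginPx = 6L, seed = 9)
  d <- tpsDeform(textureImage(48, 48, seed = 2), spec)
  # evaluate the spline analytically at the (continuous) control points
  pts <- d$controls$points
  U <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  m <- nrow(pts)
  K <- outer(seq_len(m), seq_len(m), Vectorize(function(a, b)
    U(sqrt(sum((pts[a, ] - pts[b, ])^2)))))
  P <- cbind(1, pts)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  for (comp in 1:2) {
    sol <- solve(L, c(d$controls$vectors[, comp], 0, 0, 0))
    at <- vapply(seq_len(m), function(a) {
      s <- sol[m + 1] + sol[m + 2] * pts[a, 1] + sol[m + 3] * pts[a, 2]
      s + sum(sol[seq_len(m)] *
              U(sqrt(rowSums(sweep(pts, 2, pts[a, ])^2))))
    }, numeric(1))
    expect_equal(at, d$controls$vectors[, comp], tolerance = 1e-8)
  }
})

test_that("sampled TPS fields never fold the section", {
  for (k in 1:5) {
    d <- tpsDeform(textureImage(64, 64, seed = k),
                   tpsSpec(nControl = 6, sigmaPx = 4, marginPx = 16,
                           seed = 600 + k))
    expect_gte(serialflow:::.minJacobian(flowDy(d$flow), flowDx(d$flow)),
               0.2)
  }
})

test_that("control displacement magnitudes follow the 2-D normal model", {
  # E|v| for a circular 2-D Gaussian is sigma * sqrt(pi / 2)
  sigma <- 3
  mags <- c()
  k <- 0
  while (length(mags) < 1000) {
    k <- k + 1
    # a large domain keeps control points far apart, so the fold-rejection
    # step essentially never engages and the accepted vectors keep the raw
    # sampling distribution
    d <- serialflow:::.sampleTpsField(c(256, 256),
                                      tpsSpec(nControl = 10, sigmaPx = sigma,
                                              marginPx = 16, seed = k))
    mags <- c(mags, sqrt(rowSums(d$vectors^2)))
  }
  expect_equal(mean(mags[1:1000]), sigma * sqrt(pi / 2), tolerance = 0.1)
})

test_that("phantoms are deterministic with linear centroid trajectories", {
  sp <- phantomSpec(nSections = 6L, rows = 96L, cols = 96L, nNeurites = 4L,
                    tiltMax = 0.8, seed = 5)
  a <- makePhantom(sp)
  b <- makePhantom(sp)
  expect_identical(stackData(a$stack), stackData(b$stack))
  expect_identical(stackData(a$labels), stackData(b$labels))
  for (k in 1:4) {
    dy <- diff(a$centroids[, k, 1])
    expect_equal(dy, rep(a$tilts[k, 1], 5), tolerance = 1e-12)
  }
  # zero tilt reproduces identical label maps on every section
  sp0 <- phantomSpec(nSections = 4L, rows = 64L, cols = 64L, nNeurites = 3L,
                     tiltMax = 0, seed = 6)
  ph0 <- makePhantom(sp0)
  for (i in 2:4)
    expect_identical(section(ph0$labels, i), section(ph0$labels, 1L))
})

test_that("label disks cover close to their analytic area", {
  sp <- phantomSpec(nSections = 1L, rows = 96L, cols = 96L, nNeurites = 3L,
                    radiusRange = c(6, 9), tiltMax = 0, seed = 8)
  ph <- makePhantom(sp)
  lab <- section(ph$labels, 1L)
  for (k in 1:3) {
    area <- sum(lab == k)
    expect_lt(abs(area - pi * ph$radii[k]^2) / (pi * ph$radii[k]^2), 0.1)
  }
})

test_that("injected drift is the prefix sum of the per-section deltas", {
  img <- textureImage(48, 48, seed = 3)
  st <- SectionStack(array(rep(img, 5), c(48, 48, 5)))
  same <- injectDrift(st, c(0, 0))
  expect_identical(stackData(same$stack), stackData(st))
  set.seed(10)
  deltas <- matrix(rnorm(10, sd = 0.8), 5, 2)
  dr <- injectDrift(st, deltas)
  expect_equal(dr$shifts, apply(deltas, 2, cumsum))
  # constant delta (1, 0): section 5 content sits 5 rows lower
  dc <- injectDrift(st, c(1, 0))
  expect_equal(dc$shifts[5, ], c(5, 0))
  inner <- 10:38
  expect_lt(max(abs(dc$stack@data[inner + 5, inner, 5] -
                    img[inner, inner])), 1e-9)
  # ground-truth flows are the negated cumulative shifts
  expect_equal(flowDy(dr$flows[[4]])[1, 1], -dr$shifts[4, 1])
})

test_that("registration pairs are seed-reproducible with faithful ground truth", {
  a <- makeRegistrationPairs(2, tpsSpec(nControl = 5, sigmaPx = 2,
                                        marginPx = 8), seed = 12)
  b <- makeRegistrationPairs(2, tpsSpec(nControl = 5, sigmaPx = 2,
                                        marginPx = 8), seed = 12)
  expect_identical(a[[1]]$moving, b[[1]]$moving)
  expect_identical(flowDy(a[[2]]$gt), flowDy(b[[2]]$gt))
  z <- makeRegistrationPairs(1, tpsSpec(sigmaPx = 0), seed = 2)
  expect_identical(z[[1]]$moving, z[[1]]$reference)
  # EPE of the zero flow equals the mean ground-truth magnitude
  p <- a[[1]]
  expect_equal(endpointError(zeroFlow(stackShape(p$gt)), p$gt),
               mean(sqrt(flowDy(p$gt)^2 + flowDx(p$gt)^2)))
  # warping the moving image by gt approximately restores the reference
  und <- warpImage(p$moving, p$gt, fill = "edge")
  expect_gt(ncc(und, p$reference), 0.95)
})

test_that("axial subsampling keeps every k-th section", {
  st <- SectionStack(array(runif(8 * 8 * 17), c(8, 8, 17)))
  sub <- subsampleSections(st, 8L)
  expect_equal(nSections(sub), 3L)
  expect_identical(section(sub, 2L), section(st, 9L))
})
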