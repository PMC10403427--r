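test_that("zero flow is the bit-for-bit identity warp", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(warpImage(img, zeroFlow(c(8, 8))), img)
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  storage.mode(lab) <- "integer"
  expect_identical(warpLabels(lab, zeroFlow(c(8, 8))), lab)
})

test_that("integer-shift warps move content with zero fill in vacated pixels", {
  row <- matrix(c(0, 1, 2, 3), 1, 4)
  f <- FlowField(matrix(0, 1, 4), matrix(1, 1, 4))
  expect_equal(warpImage(row, f), matrix(c(1, 2, 3, 0), 1, 4))
  lab <- matrix(0L, 6, 6); lab[3, 3] <- 7L
  shifted <- warpLabels(lab, FlowField(matrix(-1, 6, 6), matrix(0, 6, 6)))
  expect_equal(shifted[4, 3], 7L)
  expect_equal(sum(shifted), 7L)
})

test_that("bilinear and nearest warps match brute-force oracles", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(5:9, 1); m <- sample(5:9, 1)
    img <- matrix(runif(n * m), n, m)
    dy <- matrix(runif(n * m, -2, 2), n, m)
    dx <- matrix(runif(n * m, -2, 2), n, m)
    expect_lt(max(abs(warpImage(img, FlowField(dy, dx)) -
                      oracleWarpBilinear(img, dy, dx))), 1e-6)
    lab <- matrix(sample(0:5, n * m, TRUE), n, m)
    expect_identical(warpLabels(lab, FlowField(dy, dx)),
                     oracleWarpNearest(lab, dy, dx))
  }
})

test_that("the warp validity mask marks in-bounds samples", {
  img <- matrix(runif(64), 8, 8)
  res <- warpImage(img, FlowField(matrix(3, 8, 8), matrix(0, 8, 8)),
                   returnMask = TRUE)
  expect_true(all(res$mask[1:5, ]))
  expect_false(any(res$mask[6:8, ]))
})

test_that("scaleFlow is elementwise and neutral at 1", {
  f <- FlowField(matrix(2, 5, 5), matrix(4, 5, 5))
  expect_equal(flowDy(scaleFlow(f, 0.5)), matrix(1, 5, 5))
  expect_equal(flowDx(scaleFlow(f, 0.5)), matrix(2, 5, 5))
  expect_equal(scaleFlow(f, 1), f)
  img <- matrix(runif(25), 5, 5)
  expect_identical(warpImage(img, scaleFlow(f, 0)), img)
})

test_that("flow composition is the translation group on constant fields", {
  a <- FlowField(matrix(1, 9, 9), matrix(2, 9, 9))
  b <- FlowField(matrix(0.5, 9, 9), matrix(-1, 9, 9))
  cc <- composeFlows(a, b)
  expect_equal(flowDy(cc), matrix(1.5, 9, 9))
  expect_equal(flowDx(cc), matrix(1, 9, 9))
  g <- FlowField(matrix(rnorm(81, sd = 0.5), 9, 9),
                 matrix(rnorm(81, sd = 0.5), 9, 9))
  expect_equal(composeFlows(zeroFlow(c(9, 9)), g), g)
})

test_that("composed warp equals two-step warping on a smooth image", {
  img <- textureImage(64, 64, seed = 3, smoothSigma = 4)
  f1 <- FlowField(matrix(1.3, 64, 64), matrix(-0.7, 64, 64))
  set.seed(4)
  smoothField <- function() serialflow:::gauss_blur_cpp(
    matrix(rnorm(64 * 64, sd = 2), 64, 64), 5)
  f2 <- FlowField(smoothField(), smoothField())
  two <- warpImage(warpImage(img, f2, fill = "edge"), f1, fill = "edge")
  one <- warpImage(img, composeFlows(f1, f2), fill = "edge")
  inner <- 8:56
  expect_lt(mean(abs(two[inner, inner] - one[inner, inner])), 1e-3)
})

test_that("rigid transforms convert to flows consistently", {
  expect_equal(flowDy(rigidToFlow(RigidTransform(), c(8, 8))),
               matrix(0, 8, 8))
  f <- rigidToFlow(RigidTransform(0, c(2, 3)), c(8, 8))
  expect_equal(flowDy(f), matrix(-2, 8, 8))
  expect_equal(flowDx(f), matrix(-3, 8, 8))
  # 90-degree rotation against a direct coordinate-rotation oracle
  img <- matrix(0, 5, 5); img[2, 4] <- 1
  rot <- applyRigid(img, RigidTransform(pi / 2))
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    # source = R^{-1}(p - c) + c, theta = pi/2 -> R^{-1} = [[0,1],[-1,0]]
    sy <- (j - 3) + 3; sx <- -(i - 3) + 3
    if (sy >= 1 && sy <= 5 && sx >= 1 && sx <= 5) oracle[i, j] <- img[sy, sx]
  }
  expect_equal(rot, oracle)
})

test_that("rigid inverse and composition cancel to sub-0.05 px in the interior", {
  Tc <- RigidTransform(10 * pi / 180, c(5, 3))
  cc <- composeRigid(Tc, invertRigid(Tc))
  expect_lt(abs(cc@theta), 1e-12)
  expect_lt(max(abs(cc@t)), 1e-10)
  f <- composeFlows(rigidToFlow(Tc, c(32, 32)),
                    rigidToFlow(invertRigid(Tc), c(32, 32)))
  inner <- 8:24
  expect_lt(mean(sqrt(flowDy(f)[inner, inner]^2 +
                      flowDx(f)[inner, inner]^2)), 0.05)
})

test_that("flow inversion undoes smooth deformations", {
  ref <- textureImage(64, 64, seed = 12)
  d <- tpsDeform(ref, tpsSpec(nControl = 6, sigmaPx = 3, marginPx = 10,
                              seed = 5))
  gt <- invertFlow(d$flow)
  undone <- warpImage(d$image, gt, fill = "edge")
  inner <- 10:54
  expect_gt(ncc(undone[inner, inner], ref[inner, inner]), 0.98)
})

test_that("flow resampling rescales displacement values with resolution", {
  f <- FlowField(matrix(2, 8, 8), matrix(-1, 8, 8))
  up <- resampleFlow(f, c(15, 15))
  expect_equal(flowDy(up), matrix(4, 15, 15))
  expect_equal(flowDx(up), matrix(-2, 15, 15))
})

test_that("flow fields round-trip through paired TIFF serialisation", {
  td <- withr::local_tempdir()
  f <- FlowField(matrix(rnorm(64, sd = 3), 8, 8),
                 matrix(rnorm(64, sd = 3), 8, 8))
  writeFlow(f, file.path(td, "flow"))
  f2 <- readFlow(file.path(td, "flow"))
  expect_lt(max(abs(flowDy(f2) - flowDy(f))), 1e-6)
  expect_lt(max(abs(flowDx(f2) - flowDx(f))), 1e-6)
})
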