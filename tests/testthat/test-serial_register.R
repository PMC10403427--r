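test_that("an identical-section stack registers to itself", {
  img <- textureImage(64, 64, seed = 3)
  st <- SectionStack(array(rep(img, 5), c(64, 64, 5)))
  res <- sequentialRegister(st, classicalFlowEstimator(),
                            endpointMode = "provided",
                            endpointRigid = RigidTransform())
  expect_lte(mean(abs(stackData(res@warped) - stackData(st))), 1e-3)
  for (f in res@flows)
    expect_lte(mean(sqrt(flowDy(f)^2 + flowDx(f)^2)), 0.1)
})

test_that("endpoints are immutable under their rigid placements", {
  img <- textureImage(64, 64, seed = 4)
  arr <- array(rep(img, 4), c(64, 64, 4))
  arr[, , 2] <- shiftImage(img, 2, 0)
  st <- SectionStack(arr)
  res <- sequentialRegister(st, classicalFlowEstimator(),
                            endpointMode = "provided",
                            endpointRigid = RigidTransform())
  expect_identical(section(res@warped, 1L), section(st, 1L))
  expect_identical(section(res@warped, 4L), section(st, 4L))
})

test_that("a shifted interior section yields the constant aligning flow", {
  img <- textureImage(64, 64, seed = 6)
  arr <- array(rep(img, 3), c(64, 64, 3))
  arr[, , 2] <- shiftImage(img, 4, 0)
  st <- SectionStack(arr)
  res <- sequentialRegister(st, classicalFlowEstimator(),
                            endpointMode = "provided",
                            endpointRigid = RigidTransform())
  f <- res@flows[[1]]
  inner <- matrix(FALSE, 64, 64); inner[13:52, 13:52] <- TRUE
  # s_2(q) = img(q - 4), so the backward flow aligning s_2 onto the
  # reference is +4 rows: s_2(p + 4) = img(p)
  expect_lte(endpointError(f, FlowField(matrix(4, 64, 64),
                                        matrix(0, 64, 64)), inner), 0.5)
})

test_that("rigid_pair endpoint mode estimates the anchor from (s_n, s_1)", {
  img <- textureImage(128, 128, seed = 11, smoothSigma = 2)
  arr <- array(rep(img, 3), c(128, 128, 3))
  arr[, , 3] <- shiftImage(img, -3, 2)
  st <- SectionStack(arr)
  res <- sequentialRegister(st, classicalFlowEstimator(),
                            endpointMode = "rigid_pair")
  expect_lt(max(abs(res@endpointRigid@t - c(3, -2))), 0.5)
  expect_equal(res@manifest$endpointMode, "rigid_pair")
})

test_that("registration on deformed phantoms moves sections toward truth", {
  sp <- phantomSpec(nSections = 6L, rows = 96L, cols = 96L, nNeurites = 4L,
                    radiusRange = c(5, 7), tiltMax = 0.4, marginPx = 4L,
                    seed = 13)
  ph <- makePhantom(sp)
  arr <- stackData(ph$stack)
  for (i in 2:5) {
    d <- tpsDeform(section(ph$stack, i),
                   tpsSpec(nControl = 6, sigmaPx = 3, marginPx = 12,
                           seed = 50 + i))
    arr[, , i] <- d$image
  }
  st <- SectionStack(arr)
  res <- sequentialRegister(st, classicalFlowEstimator(),
                            endpointMode = "provided",
                            endpointRigid = RigidTransform())
  nccTo <- function(s) mean(vapply(1:6, function(i)
    ncc(section(ph$stack, i), section(s, i)), numeric(1)))
  expect_gt(nccTo(res@warped), nccTo(st))
})

test_that("label transport follows the recorded per-section transforms", {
  img <- textureImage(64, 64, seed = 21)
  arr <- array(rep(img, 3), c(64, 64, 3))
  arr[, , 2] <- shiftImage(img, 3, 0)
  lab <- array(0L, c(64, 64, 3)); lab[30:36, 30:36, ] <- 1L
  lab[33:39, 30:36, 2] <- 1L; lab[30:32, , 2] <- 0L
  st <- SectionStack(arr)
  res <- sequentialRegister(st, classicalFlowEstimator(),
                            endpointMode = "provided",
                            endpointRigid = RigidTransform())
  out <- applyResultToLabels(res, LabelStack(lab))
  # the shifted section's labels come back near the reference position
  c2 <- which(section(out, 2L) == 1L, arr.ind = TRUE)
  c1 <- which(section(out, 1L) == 1L, arr.ind = TRUE)
  expect_lt(abs(mean(c2[, 1]) - mean(c1[, 1])), 1.5)
})

test_that("too-short stacks are rejected", {
  st <- SectionStack(array(runif(8 * 8 * 2), c(8, 8, 2)))
  expect_error(sequentialRegister(st, classicalFlowEstimator()),
               "at least 3")
})
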