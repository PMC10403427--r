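test_that("series partitions cover every index with single-section overlap", {
  for (nTotal in 3:200) {
    for (nSeg in 1:10) {
      steps <- nTotal - 1L
      if (nSeg > steps %/% 2) next   # would force a segment under 3 sections
      p <- splitSeries(nTotal, nSeg)
      covered <- unlist(lapply(p@segments, function(s) seq(s[1], s[2])))
      expect_equal(sort(unique(covered)), 1:nTotal)
      counts <- table(covered)
      benchInterior <- p@benchmarks[-c(1, length(p@benchmarks))]
      expect_true(all(counts[as.character(benchInterior)] == 2L))
      expect_true(all(counts[setdiff(names(counts),
                                     as.character(benchInterior))] == 1L))
      lens <- vapply(p@segments, function(s) s[2] - s[1] + 1L, integer(1))
      expect_true(all(lens >= 3L))
      expect_lte(max(lens) - min(lens), 1L)   # equal as possible
      expect_true(all(diff(lens) <= 0))       # earlier segments take extras
    }
  }
})

test_that("the documented partitions match hand-derived boundaries", {
  p <- splitSeries(25, 4)
  expect_equal(p@benchmarks, c(1L, 7L, 13L, 19L, 25L))
  expect_equal(splitSeries(27, 1)@segments[[1]], c(1L, 27L))
  expect_error(splitSeries(5, 3), "infeasible")
})

test_that("benchmark chains compose pairwise translations cumulatively", {
  img <- textureImage(96, 96, seed = 31, smoothSigma = 2)
  b1 <- img
  b2 <- shiftImage(img, 2, 0)
  b3 <- shiftImage(img, 2, 3)
  bench <- SectionStack(array(c(b1, b2, b3), c(96, 96, 3)))
  chain <- registerBenchmarkChain(bench)
  expect_equal(chain[[1]]@t, c(0, 0))
  expect_lt(max(abs(chain[[2]]@t - c(-2, 0))), 0.5)
  expect_lt(max(abs(chain[[3]]@t - c(-2, -3))), 0.5)
  expect_error(registerBenchmarkChain(
    SectionStack(array(img, c(96, 96, 1)))), "at least 2")
})

test_that("long-series registration preserves the section count", {
  img <- textureImage(48, 48, seed = 7)
  for (cfg in list(c(25, 4), c(27, 3))) {
    st <- SectionStack(array(rep(img, cfg[1]), c(48, 48, cfg[1])))
    chain <- replicate(cfg[2] + 1, RigidTransform())
    out <- registerLong(st, cfg[2], chain = chain)
    expect_equal(nSections(out$stack), cfg[1])
    expect_lte(mean(abs(stackData(out$stack) - stackData(st))), 1e-2)
  }
})

test_that("benchmark sections equal their rigid placements exactly", {
  img <- textureImage(48, 48, seed = 8)
  n <- 13L
  arr <- array(NA_real_, c(48, 48, n))
  for (i in 1:n) arr[, , i] <- shiftImage(img, 0.3 * (i - 1), 0)
  st <- SectionStack(arr)
  part <- splitSeries(n, 3L)
  chain <- lapply(part@benchmarks, function(b)
    RigidTransform(0, c(-0.3 * (b - 1), 0)))
  out <- registerLong(st, 3L, chain = chain)
  for (k in seq_along(part@benchmarks)) {
    b <- part@benchmarks[k]
    expect_identical(section(out$stack, b),
                     applyRigid(section(st, b), chain[[k]], fill = "edge"))
  }
})

test_that("splitting a drifting phantom beats naive sequential registration", {
  set.seed(71)
  deltas <- rbind(c(0, 0), matrix(c(1.0, 0.6), 26, 2, byrow = TRUE))
  margin <- ceiling(max(abs(apply(deltas, 2, cumsum)))) + 2L
  sp <- phantomSpec(nSections = 27L, rows = 128L, cols = 128L,
                    nNeurites = 4L, radiusRange = c(5, 7), tiltMax = 0.35,
                    marginPx = margin, seed = 19)
  ph <- makePhantom(sp)
  dr <- injectDrift(ph$stack, deltas, labels = ph$labels)
  est <- classicalFlowEstimator()
  out <- registerLong(dr$stack, 3L, estimator = est, labels = dr$labels)
  expect_equal(nSections(out$stack), 27L)
  rms <- function(cc) sqrt(mean((cc - ph$centroids)^2, na.rm = TRUE))
  long <- rms(labelCentroids(out$labels, 1:4))
  naive <- sequentialRegister(dr$stack, est, endpointMode = "provided",
                              endpointRigid = RigidTransform(0,
                                                             -dr$shifts[27, ]))
  naiveRms <- rms(labelCentroids(applyResultToLabels(naive, dr$labels), 1:4))
  expect_lt(long, naiveRms)
})
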