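test_that("constant images give all-zero features", {
  f <- extractFeatures(multiscaleExtractor(), matrix(0.5, 32, 32))
  expect_equal(max(abs(stackData(f))), 0)
})

test_that("extraction is deterministic and translation-equivariant", {
  ex <- multiscaleExtractor()
  img <- textureImage(48, 48, seed = 2)
  expect_identical(stackData(extractFeatures(ex, img)),
                   stackData(extractFeatures(ex, img)))
  # 3-px shift: deep-interior features must translate correspondingly.
  # The per-image channel standardisation only rescales each channel by
  # constants (boundary pixels shift the statistics slightly), so the
  # translated features agree after a per-channel affine fit.
  big <- textureImage(96, 96, seed = 2)
  sh <- big[c(4:96, 1:3), ]
  fa <- stackData(extractFeatures(ex, big))
  fb <- stackData(extractFeatures(ex, sh))
  inner <- 33:60
  for (ch in seq_len(dim(fa)[3])) {
    a <- as.vector(fa[inner + 3, inner, ch])
    b <- as.vector(fb[inner, inner, ch])
    fit <- stats::lm.fit(cbind(1, b), a)
    expect_lt(max(abs(fit$residuals)), 1e-5)
  }
})

test_that("features are invariant to positive affine intensity changes", {
  ex <- multiscaleExtractor()
  img <- textureImage(32, 32, seed = 7)
  fa <- stackData(extractFeatures(ex, img))
  fb <- stackData(extractFeatures(ex, 0.4 * img + 0.3))
  expect_lt(max(abs(fa - fb)), 1e-5)
})

test_that("feature distance is a metric with the 3-4-5 arithmetic", {
  a <- new("FeatureMap", data = array(0, c(2, 2, 1)), extractorId = "t")
  b <- new("FeatureMap", data = array(c(3, 0, 0, 4), c(2, 2, 1)),
           extractorId = "t")
  expect_equal(featureDistance(a, b), 5)
  expect_equal(featureDistance(a, a), 0)
  expect_equal(featureDistance(a, b), featureDistance(b, a))
  # triangle inequality on random triples from one extractor
  ex <- multiscaleExtractor()
  set.seed(5)
  maps <- lapply(1:3, function(k)
    extractFeatures(ex, textureImage(16, 16, seed = 40 + k)))
  for (p in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)))
    expect_lte(featureDistance(maps[[p[1]]], maps[[p[2]]]),
               featureDistance(maps[[p[1]]], maps[[p[3]]]) +
               featureDistance(maps[[p[3]]], maps[[p[2]]]) + 1e-9)
  wrong <- new("FeatureMap", data = array(0, c(2, 2, 1)), extractorId = "u")
  expect_error(featureDistance(a, wrong), "extractor")
})

test_that("the photometric loss is the normalised squared distance", {
  ex <- multiscaleExtractor()
  fa <- extractFeatures(ex, textureImage(24, 24, seed = 1))
  fb <- extractFeatures(ex, textureImage(24, 24, seed = 2))
  expect_equal(featurePhotometricLoss(fa, fa), 0)
  expect_equal(featurePhotometricLoss(fa, fb),
               featureDistance(fa, fb)^2 / length(stackData(fa)))
})

test_that("warping by the true field lowers the photometric loss", {
  ex <- multiscaleExtractor()
  pairs <- makeRegistrationPairs(1, tpsSpec(nControl = 6, sigmaPx = 3,
                                            marginPx = 10), seed = 9)
  p <- pairs[[1]]
  fr <- extractFeatures(ex, p$reference)
  before <- featurePhotometricLoss(fr, extractFeatures(ex, p$moving))
  warped <- warpImage(p$moving, p$gt, fill = "edge")
  after <- featurePhotometricLoss(fr, extractFeatures(ex, warped))
  expect_lt(after, before)
})

test_that("external extractors plug into the same interface", {
  ex <- externalExtractor(function(img) array(img, c(dim(img), 1L)),
                          id = "raw")
  f <- extractFeatures(ex, matrix(runif(64), 8, 8))
  expect_s4_class(f, "FeatureMap")
  expect_equal(dim(stackData(f))[3], 1L)
})
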