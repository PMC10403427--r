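test_that("NCC matches the direct formula and its fixed points", {
  a <- matrix(c(0, 2, 1, 3), 2, 2)
  b <- matrix(c(1, 3, 0, 2), 2, 2)
  ac <- a - mean(a); bc <- b - mean(b)
  expect_equal(ncc(a, b), sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2)))
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a + 5), -1)
  expect_error(ncc(a, matrix(2, 2, 2)), "zero variance")
  expect_error(ncc(a, matrix(0, 3, 3)), "differ")
})

test_that("NCC is invariant to positive affine rescaling and respects masks", {
  set.seed(2)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(ncc(3 * a + 1, b), ncc(a, b))
  expect_equal(ncc(a, 0.2 * b - 4), ncc(a, b))
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  expect_equal(ncc(a, b, mask), ncc(a[3:6, 3:6], b[3:6, 3:6]))
})

test_that("Dice follows the overlap arithmetic and is symmetric", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[2:3, 1:2] <- 1L
  expect_equal(diceCoefficient(a, b, 1L), 2 * 2 / (4 + 4))
  expect_equal(diceCoefficient(a, a, 1L), 1)
  expect_equal(diceCoefficient(a, b, 1L), diceCoefficient(b, a, 1L))
  d <- matrix(0L, 4, 4); d[4, 4] <- 1L
  expect_equal(diceCoefficient(a, d, 1L), 0)
  expect_error(diceCoefficient(a, b, 9L), "absent")
})

test_that("top-k Dice selects by first-section area and averages volumes", {
  gt <- array(0L, c(8, 8, 2))
  gt[1:4, 1:4, ] <- 1L        # area 16 on first section
  gt[6:8, 1:3, ] <- 2L        # area 9
  gt[6:7, 6:7, ] <- 3L        # area 4
  res <- gt
  res[, , 2][res[, , 2] == 3L] <- 0L
  res[5:6, 5:6, 2] <- 3L      # label 3 half-displaced on section 2
  G <- LabelStack(gt); R <- LabelStack(res)
  expect_equal(as.numeric(topKDice(G, G, k = 50)), 1)
  d3 <- diceCoefficient(gt, res, 3L)
  expect_equal(as.numeric(topKDice(G, R, k = 50)), mean(c(1, 1, d3)))
  # k exceeding the label count uses all and records it
  t2 <- topKDice(G, R, k = 2)
  expect_equal(attr(t2, "nLabels"), 2L)
  expect_equal(attr(topKDice(G, R, k = 50), "nLabels"), 3L)
  expect_equal(as.numeric(t2), 1)   # two largest labels are exact
})

test_that("growing a result mask toward ground truth never lowers top-k Dice", {
  gt <- array(0L, c(10, 10, 1)); gt[3:8, 3:8, 1] <- 1L
  shr <- array(0L, c(10, 10, 1)); shr[5:6, 5:6, 1] <- 1L
  mid <- array(0L, c(10, 10, 1)); mid[4:7, 4:7, 1] <- 1L
  s0 <- as.numeric(topKDice(LabelStack(gt), LabelStack(shr)))
  s1 <- as.numeric(topKDice(LabelStack(gt), LabelStack(mid)))
  s2 <- as.numeric(topKDice(LabelStack(gt), LabelStack(gt)))
  expect_true(s0 <= s1 && s1 <= s2)
})

test_that("endpoint error is the mean displacement-difference norm", {
  z <- zeroFlow(c(4, 4))
  g <- FlowField(matrix(3, 4, 4), matrix(4, 4, 4))
  expect_equal(endpointError(z, g), 5)
  expect_equal(endpointError(g, g), 0)
  set.seed(4)
  e1 <- FlowField(matrix(rnorm(16), 4, 4), matrix(rnorm(16), 4, 4))
  e2 <- FlowField(matrix(rnorm(16), 4, 4), matrix(rnorm(16), 4, 4))
  acc <- 0
  for (i in 1:4) for (j in 1:4)
    acc <- acc + sqrt((flowDy(e1)[i, j] - flowDy(e2)[i, j])^2 +
                      (flowDx(e1)[i, j] - flowDx(e2)[i, j])^2)
  expect_equal(endpointError(e1, e2), acc / 16)
})

test_that("the evaluation report assembles NCC and Dice summaries", {
  img <- textureImage(32, 32, seed = 3)
  st <- SectionStack(array(rep(img, 3), c(32, 32, 3)))
  lab <- LabelStack(array(rep(c(0L, 1L), each = 16 * 32), c(32, 32, 3)))
  rep <- evaluateRegistration(st, st, lab, lab, k = 10)
  expect_equal(rep$meanNcc, 1)
  expect_equal(rep$topKDice, 1)
  expect_equal(length(rep$nccPerPair), 3L)
})
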