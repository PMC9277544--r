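# The seven-statistic metric suite: hand counts, degenerate conventions,
# identities, and loop-oracle agreement.

two_blob_fixture <- function() {
  gt <- matrix(0, 16, 16)
  gt[3:6, 3:6] <- 1
  gt[10:14, 9:13] <- 1
  pred <- matrix(0.05, 16, 16)
  pred[3:6, 4:7] <- 0.9                       # blob 1 shifted one column
  pred[10:13, 9:13] <- 0.8                    # blob 2 slightly clipped
  list(pred = pred, gt = gt)
}

test_that("Dice and IoU reproduce hand counts and degenerate conventions", {
  p <- matrix(c(1, 1, 0, 0), 1)
  g <- matrix(c(1, 0, 1, 0), 1)
  expect_equal(diceCoef(p, g), 0.5)
  expect_equal(iouCoef(p, g), 1 / 3)
  expect_equal(diceCoef(g, g), 1)
  expect_equal(iouCoef(g, g), 1)
  expect_equal(diceCoef(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  expect_equal(iouCoef(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  disj <- matrix(c(0, 0, 1, 1), 1)
  expect_equal(diceCoef(p, 1 - p), 0)
  expect_error(diceCoef(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("MAE reproduces hand means", {
  g <- matrix(rbinom(16, 1, 0.5), 4)
  expect_equal(maeScore(g, g), 0)
  expect_equal(maeScore(1 - g, g), 1)
  p <- g
  p[1:2, ] <- abs(g[1:2, ] - 0.5)             # half the pixels off by 0.5
  expect_equal(maeScore(p, g), 0.25)
})

test_that("weighted F-measure scores perfect, inverted, and shifted masks sensibly", {
  g <- matrix(0, 8, 8)
  g[4, 4] <- 1
  expect_equal(weightedFmeasure(g, g), 1, tolerance = 1e-12)
  expect_lt(weightedFmeasure(1 - g, g), 0.05)
  # a completely missed ground truth zeroes the weighted recall, so both
  # disjoint shifts score ~0; monotonicity in shift distance needs partial
  # overlap. 3x3 object, shifted by one column vs by four.
  g3 <- matrix(0, 8, 8)
  g3[3:5, 3:5] <- 1
  near <- matrix(0, 8, 8); near[3:5, 4:6] <- 1
  far <- matrix(0, 8, 8); far[3:5, 6:8] <- 1
  expect_gt(weightedFmeasure(near, g3), weightedFmeasure(far, g3))
  # empty ground truth conventions
  expect_equal(weightedFmeasure(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_equal(weightedFmeasure(matrix(1, 4, 4), matrix(0, 4, 4)), 0)
})

test_that("S-measure is 1 on perfect predictions and discriminates structure", {
  f <- two_blob_fixture()
  expect_equal(sMeasure(f$gt, f$gt), 1, tolerance = 1e-12)
  flat <- matrix(mean(f$gt), 16, 16)
  expect_gt(sMeasure(f$gt, f$gt), sMeasure(flat, f$gt))
  expect_gt(sMeasure(f$pred, f$gt), sMeasure(flat, f$gt))
  # region component on the fixture against an independent transcription
  s_all <- sMeasure(f$pred, f$gt, alpha = 0)  # pure region term
  ci <- round(mean(row(f$gt)[f$gt == 1]))
  cj <- round(mean(col(f$gt)[f$gt == 1]))
  ssim_ref <- function(p, g) {
    n <- length(p)
    mx <- mean(p); my <- mean(g)
    vx <- sum((p - mx)^2) / (n - 1); vy <- sum((g - my)^2) / (n - 1)
    vxy <- sum((p - mx) * (g - my)) / (n - 1)
    a <- 4 * mx * my * vxy
    b <- (mx^2 + my^2) * (vx + vy)
    if (a != 0) a / (b + .Machine$double.eps) else if (b == 0) 1 else 0
  }
  want <- 0
  for (blk in list(list(1:ci, 1:cj), list(1:ci, (cj + 1):16),
                   list((ci + 1):16, 1:cj), list((ci + 1):16, (cj + 1):16))) {
    pw <- f$pred[blk[[1]], blk[[2]]]
    gw <- f$gt[blk[[1]], blk[[2]]]
    want <- want + length(gw) / 256 * ssim_ref(as.vector(pw), as.vector(gw))
  }
  expect_equal(s_all, max(0, want), tolerance = 1e-12)
})

test_that("E-measure is 1 on perfect binary predictions and max dominates mean", {
  f <- two_blob_fixture()
  e <- eMeasure(f$gt, f$gt)
  expect_equal(e$mean, 1, tolerance = 1e-10)
  expect_equal(e$max, 1, tolerance = 1e-10)
  e2 <- eMeasure(f$pred, f$gt)
  expect_gte(e2$max, e2$mean)
  # the 256-threshold sweep includes 0.5, so the max dominates that cut
  expect_gte(e2$max, eMeasureAt(f$pred, f$gt, 0.5))
})

test_that("E-measure at a single threshold equals the loop oracle", {
  set.seed(5)
  gt <- matrix(0, 8, 8)
  gt[2:4, 3:6] <- 1
  pred <- matrix(runif(64), 8, 8)
  for (thr in c(0.25, 0.5, 0.75))
    expect_equal(eMeasureAt(pred, gt, thr), oracle_emeasure_at(pred, gt, thr),
                 tolerance = 1e-12)
  # degenerate frames
  expect_equal(eMeasureAt(pred, matrix(0, 8, 8), 0.5),
               oracle_emeasure_at(pred, matrix(0, 8, 8), 0.5))
  expect_equal(eMeasureAt(pred, matrix(1, 8, 8), 0.5),
               oracle_emeasure_at(pred, matrix(1, 8, 8), 0.5))
})

test_that("Dice-Jaccard identity holds per image to 1e-12", {
  set.seed(6)
  for (i in 1:10) {
    p <- matrix(rbinom(64, 1, runif(1, 0.2, 0.6)), 8)
    g <- matrix(rbinom(64, 1, 0.4), 8)
    d <- diceCoef(p, g)
    j <- iouCoef(p, g)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("all seven metrics are invariant under image flips", {
  f <- two_blob_fixture()
  cfg <- metricConfig(eThresholds = 64L)
  base <- evaluateSegmentation(list(f$pred), list(f$gt), cfg)
  flip <- function(m) m[nrow(m):1, ncol(m):1]
  rev2 <- evaluateSegmentation(list(flip(f$pred)), list(flip(f$gt)), cfg)
  # pixel-counting metrics are exactly flip-invariant; the weighted
  # F-measure and S-measure involve nearest-pixel tie-breaks and centroid
  # rounding, so they are invariant only up to those discretizations
  for (s in c("mDice", "mIoU", "meanE", "maxE", "mae"))
    expect_equal(slot(base, s), slot(rev2, s), tolerance = 1e-10,
                 label = paste("metric", s))
  for (s in c("wFb", "sAlpha"))
    expect_equal(slot(base, s), slot(rev2, s), tolerance = 0.02,
                 label = paste("metric", s))
})

test_that("evaluate aggregates per-image metrics with the report invariants", {
  f <- two_blob_fixture()
  perfect <- evaluateSegmentation(list(f$gt, f$gt, f$gt),
                                  list(f$gt, f$gt, f$gt),
                                  metricConfig(eThresholds = 32L))
  expect_equal(perfect@mDice, 1)
  expect_equal(perfect@mIoU, 1)
  expect_equal(perfect@wFb, 1)
  expect_equal(perfect@sAlpha, 1)
  expect_equal(perfect@maxE, 1, tolerance = 1e-10)
  expect_equal(perfect@mae, 0)
  r <- evaluateSegmentation(list(f$pred), list(f$gt),
                            metricConfig(eThresholds = 32L))
  expect_gte(r@mDice, r@mIoU)
  expect_equal(nrow(r@perImage), 1L)
  expect_equal(r@mDice, r@perImage$dice[1])
  expect_error(evaluateSegmentation(list(f$pred), list(f$gt, f$gt)), "input error")
})
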