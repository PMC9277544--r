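# The synthetic scene generator: determinism, rendered-contrast and area
# calibration, regime coverage, dataset round-trips, and the augmentation
# pipeline.

test_that("generation is bitwise deterministic in (seed, index)", {
  cfg <- synthConfig(nImages = 4L, seed = 7L)
  a <- generateSample(cfg, 3L)
  b <- generateSample(cfg, 3L)
  expect_identical(a, b)
  c2 <- generateSample(cfg, 4L)
  expect_false(identical(a$image, c2$image))
})

test_that("rendered foreground-background contrast matches the configured gap", {
  cfg <- synthConfig(contrastDelta = c(0.5, 0.5), noiseSigma = 0,
                     polypsPerImage = c(1L, 1L), seed = 12L)
  gaps <- vapply(1:8, function(i) {
    s <- generateSample(cfg, i)
    gray <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    mean(gray[s$mask == 1]) - mean(gray[s$mask == 0])
  }, numeric(1))
  expect_true(all(abs(gaps - 0.5) < 0.05))
})

test_that("mask area tracks the configured disk radius", {
  cfg <- synthConfig(radiusFrac = c(0.05, 0.05), polypsPerImage = c(1L, 1L),
                     boundaryIrregularity = 0.1, seed = 13L)
  areas <- vapply(1:8, function(i) mean(generateSample(cfg, i)$mask), numeric(1))
  disk <- pi * 0.05^2
  expect_true(all(areas > 0.5 * disk & areas < 2.0 * disk))
})

test_that("mask fraction stays within (0, 0.6) across regimes", {
  for (regime in c("low_contrast", "small", "large")) {
    cfg <- synthConfig(regime = regime, seed = 14L)
    for (i in 1:5) {
      fr <- mean(generateSample(cfg, i)$mask)
      expect_gt(fr, 0)
      expect_lt(fr, 0.6)
    }
  }
})

test_that("the low-contrast regime defeats an intensity-threshold baseline", {
  cfg <- synthConfig(regime = "low_contrast", seed = 15L)
  expect_lte(cfg@contrastDelta[2], 0.1)
  dice_thr <- vapply(1:10, function(i) {
    s <- generateSample(cfg, i)
    gray <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    # give the baseline its best fixed threshold per image
    max(vapply(seq(0.05, 0.95, by = 0.03), function(th)
      diceCoef((gray >= th) * 1, s$mask), numeric(1)))
  }, numeric(1))
  expect_lte(mean(dice_thr), 0.5)
})

test_that("mean sampled radius stays within 5% of the configured midpoint", {
  cfg <- synthConfig(radiusFrac = c(0.08, 0.22), polypsPerImage = c(1L, 1L),
                     seed = 16L)
  radii <- vapply(1:200, function(i)
    generateSample(cfg, i)$meta$radii[1] / cfg@size, numeric(1))
  mid <- mean(c(0.08, 0.22))
  expect_lt(abs(mean(radii) - mid) / mid, 0.05)
})

test_that("impossible placements raise a generation error", {
  expect_error(synthConfig(radiusFrac = c(0.5, 0.6)), "radiusFrac")
  cfg <- synthConfig(radiusFrac = c(0.45, 0.49), size = 32L,
                     boundaryIrregularity = 0.4, seed = 1L)
  expect_error(generateSample(cfg, 1L), "generation error")
})

test_that("dataset writing is complete, binary, and reproducible", {
  cfg <- synthConfig(nImages = 10L, size = 32L, seed = 21L)
  d1 <- file.path(tempdir(), "synthA")
  d2 <- file.path(tempdir(), "synthB")
  unlink(c(d1, d2), recursive = TRUE)
  generateDataset(cfg, d1)
  generateDataset(cfg, d2)
  imgs <- list.files(file.path(d1, "images"))
  msks <- list.files(file.path(d1, "masks"))
  expect_length(imgs, 10L)
  expect_length(msks, 10L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # masks decode to {0, 255} only (png values 0/1 after scaling)
  m <- png::readPNG(file.path(d1, "masks", msks[1]))
  expect_true(all(m %in% c(0, 1)))
  # regeneration is byte-identical
  for (f in imgs)
    expect_identical(readBin(file.path(d1, "images", f), "raw", 1e6),
                     readBin(file.path(d2, "images", f), "raw", 1e6))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_length(man$samples, 10L)
  expect_equal(man$config$seed, 21L)
})

test_that("forced double horizontal flip is the identity", {
  cfg <- synthConfig(nImages = 1L, size = 32L, seed = 22L)
  s <- generateSample(cfg, 1L)
  ops <- list(hflip = TRUE, vflip = FALSE, rot = 0L, brightness = 1, contrast = 1)
  once <- augmentPair(s, ops)
  twice <- augmentPair(once, ops)
  expect_equal(twice$image, s$image, tolerance = 1e-12)
  expect_identical(twice$mask, s$mask)
})

test_that("geometric augmentation preserves the mask and moves the centroid correctly", {
  cfg <- synthConfig(nImages = 1L, size = 32L, polypsPerImage = c(1L, 1L),
                     seed = 23L)
  s <- generateSample(cfg, 1L)
  n <- sum(s$mask)
  cen <- c(mean(row(s$mask)[s$mask == 1]), mean(col(s$mask)[s$mask == 1]))
  S <- nrow(s$mask)
  a <- augmentPair(s, list(hflip = TRUE, vflip = FALSE, rot = 0L,
                           brightness = 1.1, contrast = 0.9))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_equal(sum(a$mask), n)
  cen2 <- c(mean(row(a$mask)[a$mask == 1]), mean(col(a$mask)[a$mask == 1]))
  expect_equal(cen2, c(cen[1], S + 1 - cen[2]), tolerance = 1e-9)
  # right-angle rotation also preserves foreground area
  r <- augmentPair(s, list(hflip = FALSE, vflip = FALSE, rot = 1L,
                           brightness = 1, contrast = 1))
  expect_equal(sum(r$mask), n)
})

test_that("seeded augmentation draws reproduce", {
  cfg <- synthConfig(nImages = 1L, size = 32L, seed = 24L)
  s <- generateSample(cfg, 1L)
  set.seed(99)
  a1 <- augmentPair(s)
  set.seed(99)
  a2 <- augmentPair(s)
  expect_identical(a1, a2)
})
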