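# Seeded generator of synthetic colonoscopy-like scenes.
#
# A scene is a smooth reddish low-frequency background (band-limited noise
# upsampled from a coarse grid) with a few bright fold-like ridge
# distractors, plus one or more star-convex polyp blobs rendered as an
# intensity offset over the background. The binary mask is exactly the
# union of the polyp supports; the image-side boundary softens outward over
# a ~2 pixel band so the mask/intensity contrast stays exact inside the
# support. Everything is deterministic given (seed, index).

mix_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 10007) %% 2147483647)
}

# radial perturbation: normalized sum of 1-3 cosine lobes with frequencies
# drawn from 3..7, so |s(theta)| <= 1
star_profile <- function() {
  nk <- sample(1:3, 1L)
  ks <- sample(3:7, nk)
  amps <- runif(nk, 0.3, 1)
  phis <- runif(nk, 0, 2 * pi)
  amps <- amps / sum(amps)
  function(theta) {
    s <- 0
    for (i in seq_len(nk)) s <- s + amps[i] * cos(ks[i] * theta + phis[i])
    s
  }
}

render_background <- function(S) {
  # per-scene illumination: endoscope lighting varies between frames, so a
  # single intensity threshold cannot be calibrated across scenes
  illum <- runif(1, 0.85, 1.15)
  base <- illum * c(0.48, 0.33, 0.29)       # reddish mucosa tone
  gh <- max(4L, S %/% 16L) + 1L
  coarse <- array(rnorm(gh * gh * 3), dim = c(gh, gh, 3, 1))
  tex <- cpp_resize_bilinear(coarse, S, S)
  img <- array(0, dim = c(S, S, 3))
  for (c in 1:3) img[, , c] <- base[c] + 0.05 * tex[, , c, 1]
  # fold-like ridges: bright bands along a sinusoidal curve
  nr <- sample(1:3, 1L)
  hh <- seq_len(S)
  for (k in seq_len(nr)) {
    y0 <- runif(1, 0.1, 0.9) * S
    A <- runif(1, 0.05, 0.15) * S
    om <- 2 * pi * runif(1, 0.5, 1.5) / S
    phi <- runif(1, 0, 2 * pi)
    sig <- runif(1, 0.02, 0.05) * S
    amp <- runif(1, 0.03, 0.08)
    curve <- y0 + A * sin(om * seq_len(S) + phi)
    field <- amp * exp(-outer(hh, curve, `-`)^2 / (2 * sig^2))
    if (runif(1) < 0.5) field <- t(field)
    for (c in 1:3) img[, , c] <- img[, , c] + field
  }
  img
}

render_polyp <- function(S, cfg) {
  R <- runif(1, cfg@radiusFrac[1], cfg@radiusFrac[2]) * S
  irr <- cfg@boundaryIrregularity
  margin <- R * (1 + irr) + 2
  if (2 * margin >= S)
    stop("generation error: polyp radius does not fit the image", call. = FALSE)
  cy <- runif(1, margin, S - margin)
  cx <- runif(1, margin, S - margin)
  prof <- star_profile()
  delta <- runif(1, cfg@contrastDelta[1], cfg@contrastDelta[2])
  if (cfg@polarity == "mixed" && runif(1) < 0.5) delta <- -delta
  hh <- seq_len(S)
  dy <- outer(hh, rep(1, S)) - cy
  dx <- outer(rep(1, S), hh) - cx
  rho <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  rtheta <- R * (1 + irr * prof(theta))
  support <- rho <= rtheta
  soft <- pmin(pmax(1 - (rho - rtheta) / 2, 0), 1)  # decays outward over 2 px
  list(support = support, soft = soft, delta = delta,
       center = c(cy, cx), radius = R)
}

#' Generate one synthetic scene and its mask
#'
#' Deterministic in (`cfg@seed`, `index`): the same pair of arguments always
#' yields a bitwise-identical sample. Polyps whose perturbed outline would
#' leave the frame, or that would push the total mask fraction to 0.6 or
#' more, are rejected and redrawn (up to 100 attempts each).
#'
#' @param cfg a [SynthConfig-class].
#' @param index sample index (any integer).
#' @return list with `image` (H x W x 3 array in [0, 1]), `mask` (H x W
#'   binary matrix), and `meta` (per-polyp centers, base radii, contrast
#'   offsets).
#' @export
generateSample <- function(cfg, index = 1L) {
  stopifnot(is(cfg, "SynthConfig"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(mix_seed(cfg@seed, index))
  if (cfg@regime == "mixed") {
    pick <- sample(c("low_contrast", "small", "large"), 1L)
    cfg <- synthConfig(nImages = cfg@nImages, size = cfg@size,
                       polypsPerImage = cfg@polypsPerImage,
                       radiusFrac = cfg@radiusFrac,
                       contrastDelta = cfg@contrastDelta,
                       boundaryIrregularity = cfg@boundaryIrregularity,
                       noiseSigma = cfg@noiseSigma, polarity = cfg@polarity,
                       seed = cfg@seed, regime = pick)
  }
  S <- cfg@size
  img <- render_background(S)
  npolyp <- if (cfg@polypsPerImage[1] == cfg@polypsPerImage[2])
    cfg@polypsPerImage[1]
  else sample(cfg@polypsPerImage[1]:cfg@polypsPerImage[2], 1L)
  mask <- matrix(0, S, S)
  bump_pos <- matrix(0, S, S)               # max over brighter polyps
  bump_neg <- matrix(0, S, S)               # max over darker polyps
  meta <- list(centers = NULL, radii = numeric(0), contrast = numeric(0))
  for (k in seq_len(npolyp)) {
    ok <- FALSE
    for (attempt in 1:100) {
      p <- tryCatch(render_polyp(S, cfg), error = function(e) NULL)
      if (is.null(p)) next
      newfrac <- mean(mask > 0 | p$support)
      if (newfrac >= 0.6) next
      ok <- TRUE
      break
    }
    if (!ok) stop("generation error: could not place polyp ", k,
                  " in 100 attempts", call. = FALSE)
    mask[p$support] <- 1
    if (p$delta >= 0) bump_pos <- pmax(bump_pos, p$delta * p$soft)
    else bump_neg <- pmax(bump_neg, -p$delta * p$soft)
    meta$centers <- rbind(meta$centers, p$center)
    meta$radii <- c(meta$radii, p$radius)
    meta$contrast <- c(meta$contrast, p$delta)
  }
  for (c in 1:3) img[, , c] <- img[, , c] + bump_pos - bump_neg
  if (cfg@noiseSigma > 0)
    img <- img + rnorm(length(img), sd = cfg@noiseSigma)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, meta = meta)
}

#' Write a synthetic dataset to disk
#'
#' Renders `cfg@nImages` samples and writes `images/NNNN.png` (RGB),
#' `masks/NNNN.png` (8-bit gray, 0/255), and `manifest.json` (configuration
#' echo, file names, per-sample metadata). Re-running with the same
#' configuration reproduces byte-identical files.
#'
#' @param cfg a [SynthConfig-class].
#' @param outDir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
generateDataset <- function(cfg, outDir) {
  stopifnot(is(cfg, "SynthConfig"))
  dir.create(file.path(outDir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("I/O error: cannot create ", outDir, call. = FALSE)
  samples <- vector("list", cfg@nImages)
  for (i in seq_len(cfg@nImages)) {
    s <- generateSample(cfg, i)
    nm <- sprintf("%04d.png", i)
    png::writePNG(s$image, file.path(outDir, "images", nm))
    png::writePNG(s$mask, file.path(outDir, "masks", nm))
    samples[[i]] <- list(file = nm, seed = mix_seed(cfg@seed, i),
                         centers = s$meta$centers, radii = s$meta$radii,
                         contrast = s$meta$contrast)
  }
  manifest <- list(
    config = list(nImages = cfg@nImages, size = cfg@size,
                  polypsPerImage = cfg@polypsPerImage,
                  radiusFrac = cfg@radiusFrac, contrastDelta = cfg@contrastDelta,
                  boundaryIrregularity = cfg@boundaryIrregularity,
                  noiseSigma = cfg@noiseSigma, polarity = cfg@polarity,
                  regime = cfg@regime, seed = cfg@seed),
    samples = samples)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

rot90cw <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  m
}

apply_geom <- function(m, ops) {
  if (ops$hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (ops$vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  rot90cw(m, ops$rot)
}

#' Augment an image/mask pair
#'
#' The training-time augmentation pipeline: horizontal flip and vertical
#' flip each applied with probability 1/2, a rotation by k * 90 degrees
#' with k uniform on \{0, 1, 2, 3\}, and photometric jitter of the image
#' only (brightness scale and contrast scale each uniform in [0.8, 1.2]).
#' Geometric operations are applied identically to image and mask; the mask
#' stays binary.
#'
#' @param pair list with `image` (H x W x 3) and `mask` (H x W) as produced
#'   by [generateSample()].
#' @param ops optional explicit operations, a list with logical `hflip`,
#'   `vflip`, integer `rot` (quarter turns), numeric `brightness`,
#'   `contrast`; when NULL (default) they are drawn from the current RNG.
#' @return augmented pair (same structure; `meta` is passed through).
#' @export
augmentPair <- function(pair, ops = NULL) {
  if (is.null(ops)) {
    ops <- list(hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
                rot = sample(0:3, 1L),
                brightness = runif(1, 0.8, 1.2), contrast = runif(1, 0.8, 1.2))
  }
  img <- pair$image
  out <- NULL
  for (c in 1:3) {
    ch <- apply_geom(img[, , c], ops)
    if (is.null(out)) out <- array(0, dim = c(nrow(ch), ncol(ch), 3))
    out[, , c] <- ch
  }
  out <- out * ops$brightness
  m <- mean(out)
  out <- (out - m) * ops$contrast + m
  out <- pmin(pmax(out, 0), 1)
  list(image = out, mask = apply_geom(pair$mask, ops), meta = pair$meta,
       ops = ops)
}
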