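# Training, inference, and evaluation orchestration.

#' Load an images/masks dataset directory
#'
#' Reads the `images/`, `masks/` layout written by [generateDataset()] (the
#' same reader contract applies to real datasets exported in that layout).
#' Images are resized bilinearly to `inputSize`, masks with nearest
#' neighbour and re-binarized.
#'
#' @param dataDir directory containing `images/` and `masks/`.
#' @param inputSize square side to resize to (multiple of 32), or NULL to
#'   keep native resolution.
#' @return list of pairs (image H x W x 3, mask H x W, name).
#' @export
loadDataset <- function(dataDir, inputSize = NULL) {
  imgDir <- file.path(dataDir, "images")
  mskDir <- file.path(dataDir, "masks")
  imgs <- sort(list.files(imgDir, pattern = "\\.png$"))
  msks <- sort(list.files(mskDir, pattern = "\\.png$"))
  orphans <- c(setdiff(imgs, msks), setdiff(msks, imgs))
  if (length(orphans) > 0)
    stop("data error: unpaired files: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  if (length(imgs) == 0) stop("data error: no images found in ", imgDir,
                              call. = FALSE)
  lapply(imgs, function(nm) {
    img <- read_rgb(file.path(imgDir, nm))
    msk <- read_mask(file.path(mskDir, nm))
    if (!is.null(inputSize)) {
      img <- resize_rgb(img, inputSize, inputSize)
      msk <- (cpp_resize_nearest_mat(msk, inputSize, inputSize) > 0.5) * 1
    }
    list(image = img, mask = msk, name = nm)
  })
}

read_rgb <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x
}

read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x > 0.5) * 1
}

resize_rgb <- function(img, H, W) {
  d <- dim(img)
  if (d[1] == H && d[2] == W) return(img)
  x <- array(img, dim = c(d[1], d[2], 3, 1))
  y <- cpp_resize_bilinear(x, H, W)
  array(y, dim = c(H, W, 3))
}

# stack pairs into internal-layout tensors: x (H,W,3,N), t (H,W,1,N)
stack_batch <- function(pairs) {
  n <- length(pairs)
  d <- dim(pairs[[1]]$image)
  x <- array(0, dim = c(d[1], d[2], 3, n))
  t <- array(0, dim = c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    x[, , , i] <- pairs[[i]]$image
    t[, , 1, i] <- pairs[[i]]$mask
  }
  list(x = x, t = t)
}

adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(model$adam)) model$adam <- list(m = list(), v = list(), t = 0L)
  model$adam$t <- model$adam$t + 1L
  tt <- model$adam$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- model$adam$m[[nm]]
    v <- model$adam$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    model$adam$m[[nm]] <- m
    model$adam$v[[nm]] <- v
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(model)
}

# mean Dice of eval-mode predictions over a list of pairs
validation_mdice <- function(model, pairs, batchSize = 4L, threshold = 0.5) {
  if (length(pairs) == 0) return(NA_real_)
  dices <- numeric(0)
  for (i0 in seq(1, length(pairs), by = batchSize)) {
    chunk <- pairs[i0:min(i0 + batchSize - 1L, length(pairs))]
    b <- stack_batch(chunk)
    p <- forward_ir(model, b$x)
    for (k in seq_along(chunk))
      dices <- c(dices, diceCoef((p[, , 1, k] >= threshold) * 1, b$t[, , 1, k]))
  }
  mean(dices)
}

#' Train the segmentation network
#'
#' Optimizes the compound BCE + Dice loss with Adam over an images/masks
#' dataset. A seeded shuffle holds out `valFrac` of the images for
#' validation; the checkpoint written at the end carries the parameters of
#' the epoch with the highest validation mean Dice (or the final epoch when
#' there is no validation split).
#'
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param dataDir dataset directory with `images/` and `masks/`.
#' @param checkpointPath file for the checkpoint archive (default
#'   `frcnet.ckpt` inside `dataDir`'s parent-level `runs` is avoided:
#'   defaults to tempfile).
#' @param weights a [LossWeights-class].
#' @param quiet suppress per-epoch progress lines on stderr.
#' @return run record: list with `epochLoss` (mean train loss per epoch),
#'   `valDice` (validation mean Dice per epoch), `bestEpoch`, `wallTime`
#'   (seconds), `checkpointPath`, `config` echo, and `seed`.
#' @export
trainFRCNet <- function(modelCfg, trainCfg, dataDir,
                        checkpointPath = tempfile(fileext = ".ckpt"),
                        weights = lossWeights(), quiet = FALSE) {
  stopifnot(is(modelCfg, "ModelConfig"), is(trainCfg, "TrainConfig"))
  t0 <- proc.time()[["elapsed"]]
  pairs <- loadDataset(dataDir, trainCfg@inputSize)
  set.seed(trainCfg@seed)
  n <- length(pairs)
  idx <- sample(n)
  nval <- floor(trainCfg@valFrac * n)
  val <- if (nval > 0) pairs[idx[seq_len(nval)]] else list()
  trn <- pairs[idx[setdiff(seq_len(n), seq_len(nval))]]
  if (length(trn) == 0) stop("data error: no training images left", call. = FALSE)

  model <- buildFRCNet(modelCfg)
  epochLoss <- numeric(0)
  valDice <- numeric(0)
  best <- list(dice = -Inf, epoch = 0L, params = NULL, state = NULL)
  for (ep in seq_len(trainCfg@epochs)) {
    ord <- sample(length(trn))
    losses <- numeric(0)
    for (i0 in seq(1, length(trn), by = trainCfg@batchSize)) {
      take <- ord[i0:min(i0 + trainCfg@batchSize - 1L, length(trn))]
      chunk <- trn[take]
      if (trainCfg@augment) chunk <- lapply(chunk, augmentPair)
      b <- stack_batch(chunk)
      tape <- ad_tape()
      xin <- ad_const(tape, b$x)
      pred <- f_frcnet(tape, model, xin, train = TRUE)
      loss <- f_total_loss(tape, pred, b$t, weights)
      if (!is.finite(loss$v))
        stop("NaN loss at epoch ", ep, ", batch starting at shuffled index ",
             i0, call. = FALSE)
      ad_backward(tape, loss)
      adam_step(model, ad_param_grads(tape), trainCfg@lr)
      losses <- c(losses, loss$v)
    }
    epochLoss <- c(epochLoss, mean(losses))
    vd <- validation_mdice(model, val, trainCfg@batchSize)
    valDice <- c(valDice, vd)
    if (!quiet)
      message(sprintf("epoch %3d | train loss %.4f | val mDice %s", ep,
                      mean(losses), ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    if (is.na(vd) || vd >= best$dice) {
      best <- list(dice = if (is.na(vd)) Inf else vd, epoch = ep,
                   params = model$params, state = as.list(model$state))
    }
  }
  if (!is.null(best$params)) {
    model$params <- best$params
    model$state <- list2env(best$state, new.env(parent = emptyenv()))
  }
  saveCheckpoint(model, checkpointPath)
  list(epochLoss = epochLoss, valDice = valDice, bestEpoch = best$epoch,
       wallTime = proc.time()[["elapsed"]] - t0,
       checkpointPath = checkpointPath,
       config = list(model = modelCfg, train = trainCfg),
       seed = trainCfg@seed, model = model)
}

#' Save a model checkpoint
#'
#' A named-weight archive: the parameter list, batch-norm running
#' statistics, a configuration echo, and the initialization seed, written
#' with `saveRDS` so a load round-trips bitwise.
#'
#' @param model model object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model$params, state = as.list(model$state),
               cfg = model$cfg, seed = model$cfg@seed, kind = model$kind),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [saveCheckpoint()].
#' @return model object equivalent to the saved one.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- new_store()
  model$params <- ck$params
  model$state <- list2env(ck$state, new.env(parent = emptyenv()))
  model$cfg <- ck$cfg
  model$kind <- ck$kind
  model
}

next_mult32 <- function(x) as.integer(ceiling(x / 32) * 32)

#' Predict masks for a directory of images
#'
#' Runs the network at the nearest multiple-of-32 resolution, resizes the
#' probability map back to each image's native resolution, and writes
#' `probs/NAME.png` (8-bit grayscale probability map) and `masks/NAME.png`
#' (0/255 binarization at `threshold`).
#'
#' @param checkpoint checkpoint path or a model object.
#' @param imagesDir directory of input PNG images.
#' @param outDir output directory.
#' @param threshold binarization threshold (default 0.5); probabilities >=
#'   threshold become foreground.
#' @return data.frame listing the written files, invisibly.
#' @export
predictFRCNet <- function(checkpoint, imagesDir, outDir, threshold = 0.5) {
  model <- if (is.character(checkpoint)) loadCheckpoint(checkpoint) else checkpoint
  files <- sort(list.files(imagesDir, pattern = "\\.png$"))
  if (length(files) == 0) stop("input error: no PNG images in ", imagesDir,
                               call. = FALSE)
  dir.create(file.path(outDir, "probs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(files, function(nm) {
    img <- read_rgb(file.path(imagesDir, nm))
    d <- dim(img)
    if (d[1] < 32 || d[2] < 32)
      stop("input error: image ", nm, " is smaller than 32 pixels", call. = FALSE)
    Hr <- next_mult32(d[1]); Wr <- next_mult32(d[2])
    x <- array(resize_rgb(img, Hr, Wr), dim = c(Hr, Wr, 3, 1))
    p <- forward_ir(model, x)
    prob <- cpp_resize_bilinear(p, d[1], d[2])[, , 1, 1]
    png::writePNG(prob, file.path(outDir, "probs", nm))
    png::writePNG((prob >= threshold) * 1, file.path(outDir, "masks", nm))
    data.frame(file = nm, height = d[1], width = d[2])
  })
  invisible(do.call(rbind, rows))
}

#' Evaluate a directory of predictions against ground truth
#'
#' Pairs files by name between `predDir` (grayscale probability or binary
#' mask PNGs) and `gtDir` (0/255 masks), computes the seven-statistic
#' report, and optionally serializes it to JSON.
#'
#' @param predDir directory of prediction PNGs.
#' @param gtDir directory of ground-truth mask PNGs.
#' @param cfg a [MetricConfig-class].
#' @param reportFile optional JSON output path.
#' @return a [MetricReport-class].
#' @export
evaluateDataset <- function(predDir, gtDir, cfg = metricConfig(),
                            reportFile = NULL) {
  pf <- sort(list.files(predDir, pattern = "\\.png$"))
  gf <- sort(list.files(gtDir, pattern = "\\.png$"))
  orphans <- c(setdiff(pf, gf), setdiff(gf, pf))
  if (length(orphans) > 0)
    stop("data error: unpaired files: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  preds <- lapply(pf, function(nm) {
    x <- png::readPNG(file.path(predDir, nm))
    if (length(dim(x)) == 3L) x <- x[, , 1]
    x
  })
  gts <- lapply(gf, function(nm) read_mask(file.path(gtDir, nm)))
  report <- evaluateSegmentation(preds, gts, cfg)
  if (!is.null(reportFile)) writeMetricReport(report, reportFile)
  report
}

#' Audit the parameter budget
#'
#' Builds the configured model, prints total and per-module parameter
#' counts in millions (two decimals), and checks the full variant against
#' the 0.78 M budget.
#'
#' @param modelCfg a [ModelConfig-class].
#' @param budget parameter budget applied to the full variant (default
#'   780000).
#' @param quiet suppress the printed table.
#' @return list with `total`, `byModule`, `budget`, and logical `pass`,
#'   invisibly.
#' @export
auditParams <- function(modelCfg, budget = 780000L, quiet = FALSE) {
  model <- buildFRCNet(modelCfg)
  total <- countParameters(model)
  by <- param_groups(model)
  pass <- !(modelCfg@variant == "full" && total > budget)
  if (!quiet) {
    cat(sprintf("Parameter audit — variant '%s'\n", modelCfg@variant))
    for (nm in names(by)) cat(sprintf("  %-20s %8.2f M\n", nm, by[[nm]] / 1e6))
    cat(sprintf("  %-20s %8.2f M (budget %.2f M) %s\n", "TOTAL", total / 1e6,
                budget / 1e6,
                if (modelCfg@variant == "full") ifelse(pass, "PASS", "FAIL")
                else ""))
  }
  invisible(list(total = total, byModule = as.list(by), budget = budget,
                 pass = pass))
}
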