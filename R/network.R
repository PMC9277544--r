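# Assembly of the full encoder-decoder.
#
# Five encoder levels (stem conv, then 2x2 max-pool between levels); one
# context/conv block per level; PCF at the bottleneck; a mirrored decoder
# with bilinear 2x upsampling and additive skips; MPA (or a plain 1x1 head)
# over the five decoder outputs; final 1x1 conv + sigmoid.
#
# ECC calibration rates per level: the configured rate (default 4) at levels
# 0-3 and 2 at the deepest level, so the pooled calibration map stays at
# least 1x1 for every input with H, W multiples of 32.

ecc_rates <- function(rate) c(rate, rate, rate, rate, 2L)

variant_has <- function(variant, module)
  variant == "full" || variant == module

#' Build the segmentation network
#'
#' Constructs the model described by a [ModelConfig-class]: the `variant`
#' field switches the three context modules on or off ("baseline" uses
#' plain depthwise-separable conv-BN-ReLU units per level, a bare
#' bottleneck, and a 1x1 head on the finest decoder map). Weights are drawn
#' from a generator seeded by `cfg@seed`, so two builds with the same
#' configuration are bitwise identical.
#'
#' @param cfg a [ModelConfig-class].
#' @return a SegModel: an opaque model object (environment) holding the
#'   configuration, the named parameter list, and batch-norm running
#'   statistics. Use with [frcnetForward()], [countParameters()],
#'   [trainFRCNet()].
#' @export
buildFRCNet <- function(cfg) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  w <- cfg@encoderWidths
  v <- cfg@variant
  dw <- cfg@ecc@useDepthwise
  st <- new_store()
  st$cfg <- cfg
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(cfg@seed)

  init_conv(st, "stem", w[1], 3L, 3L)
  init_bn(st, "stem.bn", w[1])
  for (i in 1:5) {
    pre <- paste0("enc", i - 1L)
    if (variant_has(v, "ecc")) init_ecc(st, pre, w[i], cfg@ecc)
    else init_unit3(st, pre, w[i], w[i], dw)
    if (i < 5L) init_unit3(st, paste0("tr", i), w[i], w[i + 1L], dw)
  }
  if (variant_has(v, "pcf")) init_pcf(st, "pcf", w[5], cfg@pcf)
  for (i in 4:1) {
    pre <- paste0("dec", i - 1L)
    init_unit3(st, paste0("dtr", i - 1L), w[i + 1L], w[i], dw)
    if (variant_has(v, "ecc")) init_ecc(st, pre, w[i], cfg@ecc)
    else init_unit3(st, pre, w[i], w[i], dw)
  }
  if (variant_has(v, "mpa")) {
    init_mpa(st, "mpa", w, cfg@mpa@fusedChannels, cfg@mpa@seRatio)
    init_conv(st, "head", 1L, cfg@mpa@fusedChannels, 1L)
  } else {
    init_conv(st, "head", 1L, w[1], 1L)
  }
  st$kind <- "frcnet"
  st
}

# shared by training (tape kept) and inference
f_frcnet <- function(tape, st, x, train) {
  cfg <- st$cfg
  w <- cfg@encoderWidths
  v <- cfg@variant
  rates <- ecc_rates(cfg@ecc@calibrationRate)
  blk <- function(h, pre, lvl) {
    if (variant_has(v, "ecc")) f_ecc(tape, st, h, pre, rates[lvl], train)
    else f_unit3(tape, st, h, pre, train)
  }
  h <- op_relu(tape, f_bn(tape, st, f_conv(tape, st, x, "stem", pad = 1L),
                          "stem.bn", train))
  enc <- vector("list", 5L)
  for (i in 1:5) {
    h <- blk(h, paste0("enc", i - 1L), i)
    enc[[i]] <- h
    if (i < 5L) {
      h <- op_maxpool2(tape, h)
      h <- f_unit3(tape, st, h, paste0("tr", i), train)
    }
  }
  d4 <- if (variant_has(v, "pcf"))
    f_pcf(tape, st, enc[[5]], "pcf", cfg@pcf@dilation, train)
  else enc[[5]]
  dec <- vector("list", 5L)
  dec[[5]] <- d4
  h <- d4
  for (i in 4:1) {
    dd <- dim(enc[[i]]$v)                      # (H, W, C, N)
    h <- op_upsample(tape, h, dd[1], dd[2])
    h <- f_unit3(tape, st, h, paste0("dtr", i - 1L), train)
    h <- blk(op_add(tape, h, enc[[i]]), paste0("dec", i - 1L), i)
    dec[[i]] <- h
  }
  feat <- if (variant_has(v, "mpa")) f_mpa(tape, st, dec, "mpa") else dec[[1]]
  # clamp to the representable open interval: in double arithmetic the raw
  # sigmoid rounds to exactly 0/1 for |logit| > ~37, where its gradient is
  # numerically zero anyway
  op_clamp(tape, op_sigmoid(tape, f_conv(tape, st, feat, "head", pad = 0L)),
           BCE_EPS, 1 - BCE_EPS)
}

#' Run the network on an image batch
#'
#' @param model object from [buildFRCNet()] (or a loaded checkpoint).
#' @param images array (N, 3, H, W) with values in [0, 1]; H and W must be
#'   multiples of 32 (pad or resize first otherwise).
#' @param train use batch statistics in batch normalization (training mode).
#'   Inference (`FALSE`, the default) uses the running estimates and is
#'   deterministic.
#' @return probability maps, array (N, 1, H, W) with entries in (0, 1).
#' @export
frcnetForward <- function(model, images, train = FALSE) {
  d <- check_featuremap(images, "images")
  if (d[2] != 3L) stop("images must have 3 channels", call. = FALSE)
  if (d[3] %% 32L != 0L || d[4] %% 32L != 0L)
    stop("input error: H and W must be multiples of 32 (got ", d[3], "x", d[4],
         "); pad the batch to the next multiple of 32", call. = FALSE)
  run_plain(function(tape, xin) f_frcnet(tape, model, xin, train), images)
}

# inference on an (H, W, 3, N) internal-layout batch, returning (H, W, 1, N)
forward_ir <- function(model, x_ir, train = FALSE) {
  tape <- ad_tape()
  f_frcnet(tape, model, ad_const(tape, x_ir), train)$v
}

#' Count learnable parameters
#' @param model object from [buildFRCNet()], or any block object from
#'   [newEccBlock()], [newPcfBlock()], [newMpaBlock()].
#' @return integer: the exact number of learnable scalar weights (batch-norm
#'   running statistics are buffers, not parameters, and are not counted).
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# per-module breakdown used by auditParams()
param_groups <- function(model) {
  nm <- names(model$params)
  top <- sub("\\..*$", "", nm)
  grp <- ifelse(grepl("^enc", top), "encoder blocks",
         ifelse(grepl("^tr", top), "encoder transitions",
         ifelse(grepl("^dec", top), "decoder blocks",
         ifelse(grepl("^dtr", top), "decoder transitions",
         ifelse(top == "pcf", "PCF bottleneck",
         ifelse(top == "mpa", "MPA head",
         ifelse(top == "stem", "stem", "head")))))))
  tapply(vapply(model$params, length, numeric(1)), grp, sum)
}
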