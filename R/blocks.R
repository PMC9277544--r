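# The three context blocks. Each has an init_* routine that registers
# parameters under a prefix in a store, and an f_* routine that runs the
# forward pass on tape nodes. The exported *Forward() functions wrap these
# for standalone use on plain arrays.

## ---- ECC: enhanced calibration convolution ----

init_ecc <- function(st, prefix, C, cfg) {
  h <- C %/% 2L
  dw <- cfg@useDepthwise
  init_conv(st, paste0(prefix, ".split"), C, C, 1L)
  init_conv(st, paste0(prefix, ".id"), h, h, 1L)
  init_bn(st, paste0(prefix, ".id.bn"), h)
  init_unit3(st, paste0(prefix, ".x2"), h, h, dw)
  init_unit3(st, paste0(prefix, ".cal"), h, h, dw)
  init_unit3(st, paste0(prefix, ".out"), h, h, dw)
  invisible(st)
}

# calibration path: sigma(x2 + Up(F3x3(Down(x2))))
f_calibrate <- function(tape, st, x2, prefix, rate, train) {
  d <- dim(x2$v)
  down <- op_avgpool(tape, x2, rate)
  conv <- f_unit3(tape, st, down, paste0(prefix, ".cal"), train)
  up <- op_upsample(tape, conv, d[1], d[2])
  op_sigmoid(tape, op_add(tape, x2, up))
}

f_ecc <- function(tape, st, x, prefix, rate, train) {
  C <- dim(x$v)[3]
  h <- C %/% 2L
  s <- f_conv(tape, st, x, paste0(prefix, ".split"), pad = 0L)
  x1 <- op_slice_c(tape, s, 1L, h)
  x2 <- op_slice_c(tape, s, h + 1L, C)
  x1p <- op_relu(tape, f_bn(tape, st,
                            f_conv(tape, st, x1, paste0(prefix, ".id"), pad = 0L),
                            paste0(prefix, ".id.bn"), train))
  x2p <- f_unit3(tape, st, x2, paste0(prefix, ".x2"), train)
  att <- f_calibrate(tape, st, x2, prefix, rate, train)
  gated <- op_mul(tape, att, x2p)
  outh <- f_unit3(tape, st, gated, paste0(prefix, ".out"), train)
  op_add(tape, x, op_concat_c(tape, list(x1p, outh)))
}

#' Create a standalone ECC block
#'
#' Instantiates the enhanced calibration convolution block: a 1x1 split into
#' two channel halves, an identity-preserving 1x1 conv-BN-ReLU branch for the
#' first half, a 3x3 feature branch for the second, and a sigmoid attention
#' map from an average-pool / 3x3 conv / bilinear-upsample calibration path
#' that gates the feature branch before re-fusion and the residual add.
#'
#' @param cfg an [ECCConfig-class].
#' @param seed weight initialization seed.
#' @return an opaque block object (environment) holding parameters and
#'   batch-norm state; pass it to [eccForward()] or [contextCalibrate()].
#' @export
newEccBlock <- function(cfg, seed = 0L) {
  stopifnot(is(cfg, "ECCConfig"))
  st <- new_store()
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(seed)
  init_ecc(st, "ecc", cfg@inChannels, cfg)
  st$cfg <- cfg
  st$kind <- "ecc"
  st
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

check_ecc_input <- function(block, x, what = "x", half = FALSE) {
  d <- check_featuremap(x, what)
  want <- block$cfg@inChannels
  if (half) want <- want %/% 2L
  if (d[2] != want)
    stop("configuration error: ", what, " has ", d[2],
         " channels but the block expects ", want, call. = FALSE)
  r <- block$cfg@calibrationRate
  if (d[3] %% r != 0L)
    stop("input error: height ", d[3], " is not divisible by the calibration rate ",
         r, call. = FALSE)
  if (d[4] %% r != 0L)
    stop("input error: width ", d[4], " is not divisible by the calibration rate ",
         r, call. = FALSE)
  d
}

#' Forward pass of a standalone ECC block
#' @param block object from [newEccBlock()].
#' @param x input array with dim (N, C, H, W); H and W must be divisible by
#'   the calibration rate.
#' @param train use batch statistics (TRUE) or running statistics (FALSE)
#'   in batch normalization.
#' @return array of the same shape as `x`.
#' @export
eccForward <- function(block, x, train = FALSE) {
  check_ecc_input(block, x)
  run_plain(function(tape, xin)
    f_ecc(tape, block, xin, "ecc", block$cfg@calibrationRate, train), x)
}

#' Calibration attention map of an ECC block
#'
#' Returns the sigmoid attention map built from the half-width feature map:
#' average-pool by the calibration rate, 3x3 conv-BN-ReLU, bilinear upsample
#' back, add the input, sigmoid. Every entry lies strictly in (0, 1).
#'
#' @param block object from [newEccBlock()].
#' @param x2 array with dim (N, C/2, H, W).
#' @param train batch-norm mode as in [eccForward()].
#' @return array of the same shape as `x2` with entries in (0, 1).
#' @export
contextCalibrate <- function(block, x2, train = FALSE) {
  check_ecc_input(block, x2, "x2", half = TRUE)
  run_plain(function(tape, xin)
    f_calibrate(tape, block, xin, "ecc", block$cfg@calibrationRate, train), x2)
}

## ---- PCF: progressive context-aware fusion ----

init_pcf <- function(st, prefix, C, cfg) {
  h <- C %/% 2L
  hid <- C %/% cfg@bottleneckRatio
  init_conv(st, paste0(prefix, ".comp"), h, C, 1L)
  init_bn(st, paste0(prefix, ".comp.bn"), h)
  init_conv(st, paste0(prefix, ".local"), h, h, 3L)
  init_bn(st, paste0(prefix, ".local.bn"), h)
  init_conv(st, paste0(prefix, ".surr"), h, h, 3L)
  init_bn(st, paste0(prefix, ".surr.bn"), h)
  init_conv(st, paste0(prefix, ".attn"), 1L, C, 1L)
  init_dense(st, paste0(prefix, ".s2"), hid, C)
  init_ln(st, paste0(prefix, ".ln"), hid)
  init_dense(st, paste0(prefix, ".s3"), C, hid)
  invisible(st)
}

f_pcf <- function(tape, st, x, prefix, dil, train, details = FALSE) {
  comp <- op_relu(tape, f_bn(tape, st,
                             f_conv(tape, st, x, paste0(prefix, ".comp"), pad = 0L),
                             paste0(prefix, ".comp.bn"), train))
  xl <- op_relu(tape, f_bn(tape, st,
                           f_conv(tape, st, comp, paste0(prefix, ".local"), pad = 1L),
                           paste0(prefix, ".local.bn"), train))
  xs <- op_relu(tape, f_bn(tape, st,
                           f_conv(tape, st, comp, paste0(prefix, ".surr"),
                                  pad = dil, dil = dil),
                           paste0(prefix, ".surr.bn"), train))
  xp <- op_concat_c(tape, list(xl, xs))
  logits <- f_conv(tape, st, xp, paste0(prefix, ".attn"), pad = 0L)
  beta <- op_softmax_pos(tape, logits)
  ctx <- op_attnpool(tape, xp, beta)
  z <- f_dense(tape, st, ctx, paste0(prefix, ".s2"))
  z <- op_relu(tape, f_ln(tape, st, z, paste0(prefix, ".ln")))
  z <- f_dense(tape, st, z, paste0(prefix, ".s3"))
  out <- op_add(tape, x, op_badd_vec(tape, xp, z))
  if (details) list(out = out, beta = beta, ctx = ctx, xp = xp) else out
}

#' Create a standalone PCF block
#'
#' Instantiates the progressive context-aware fusion block: 1x1 compression
#' to half width, a local 3x3 branch and a surrounding dilated 3x3 branch
#' concatenated back to full width, a softmax global-attention-pooled
#' context vector passed through a layer-normalized channel bottleneck and
#' broadcast onto the features, and a residual skip from the input.
#'
#' The surrounding branch's receptive field spans 2 x dilation + 1 pixels;
#' maps smaller than that still compute (taps fall in the zero padding) but
#' the branch degenerates towards a 1x1.
#'
#' @param cfg a [PCFConfig-class].
#' @param seed weight initialization seed.
#' @return an opaque block object for [pcfForward()].
#' @export
newPcfBlock <- function(cfg, seed = 0L) {
  stopifnot(is(cfg, "PCFConfig"))
  st <- new_store()
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(seed)
  init_pcf(st, "pcf", cfg@inChannels, cfg)
  st$cfg <- cfg
  st$kind <- "pcf"
  st
}

#' Forward pass of a standalone PCF block
#' @param block object from [newPcfBlock()].
#' @param x input array with dim (N, C, H, W), C matching the configuration.
#' @param train batch-norm mode.
#' @param details also return the attention weights and pooled context
#'   vector (as a list) instead of just the output.
#' @return array shaped like `x`, or a list with elements `out`, `beta`
#'   (attention weights, an (N, 1, H, W) array summing to 1 per image), and
#'   `ctx` (the pooled (N, C) context) when `details = TRUE`.
#' @export
pcfForward <- function(block, x, train = FALSE, details = FALSE) {
  d <- check_featuremap(x)
  if (d[2] != block$cfg@inChannels)
    stop("configuration error: x has ", d[2], " channels but the block expects ",
         block$cfg@inChannels, call. = FALSE)
  tape <- ad_tape()
  xin <- ad_const(tape, api_to_ir(x))
  r <- f_pcf(tape, block, xin, "pcf", block$cfg@dilation, train, details = TRUE)
  if (details)
    list(out = ir_to_api(r$out$v), beta = ir_to_api(r$beta$v), ctx = t(r$ctx$v))
  else ir_to_api(r$out$v)
}

## ---- MPA: multi-scale pyramid aggregation ----

init_mpa <- function(st, prefix, levelChannels, fused, seRatio) {
  init_conv(st, paste0(prefix, ".w1"), fused, sum(levelChannels), 1L)
  init_dense(st, paste0(prefix, ".fc1"), fused %/% seRatio, fused)
  init_dense(st, paste0(prefix, ".fc2"), fused, fused %/% seRatio)
  invisible(st)
}

f_se_gate <- function(tape, st, gvec, prefix) {
  z <- op_relu(tape, f_dense(tape, st, gvec, paste0(prefix, ".fc1")))
  op_sigmoid(tape, f_dense(tape, st, z, paste0(prefix, ".fc2")))
}

f_mpa <- function(tape, st, levels, prefix, details = FALSE) {
  # G = W1 Concat(B(l_0), ..., B(l_4)) computed as sum_l B(W1_l l_l): the 1x1
  # projection commutes with bilinear upsampling (both are linear and the
  # interpolation weights sum to 1), so each level is projected at its own
  # resolution first -- identical result, far less arithmetic
  d0 <- dim(levels[[1]]$v)                   # (H, W, C, N)
  w1 <- p_(tape, st, paste0(prefix, ".w1.w"))
  b1 <- p_(tape, st, paste0(prefix, ".w1.b"))
  zerob <- ad_const(tape, numeric(dim(w1$v)[1]))
  at <- 0L
  G <- NULL
  for (k in seq_along(levels)) {
    ck <- dim(levels[[k]]$v)[3]
    wk <- op_slice_w2(tape, w1, at + 1L, at + ck)
    at <- at + ck
    gk <- op_conv(tape, levels[[k]], wk, if (k == 1L) b1 else zerob, pad = 0L)
    gk <- op_upsample(tape, gk, d0[1], d0[2])
    G <- if (is.null(G)) gk else op_add(tape, G, gk)
  }
  gvec <- op_gap(tape, G)
  gate <- f_se_gate(tape, st, gvec, prefix)
  Y <- op_chscale(tape, G, gate)
  if (details) list(out = Y, gvec = gvec, gate = gate, G = G) else Y
}

#' Create a standalone MPA head
#' @param cfg an [MPAConfig-class].
#' @param seed weight initialization seed.
#' @return an opaque block object for [mpaForward()] / [seReweight()].
#' @export
newMpaBlock <- function(cfg, seed = 0L) {
  stopifnot(is(cfg, "MPAConfig"))
  st <- new_store()
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(seed)
  init_mpa(st, "mpa", cfg@levelChannels, cfg@fusedChannels, cfg@seRatio)
  st$cfg <- cfg
  st$kind <- "mpa"
  st
}

#' Forward pass of a standalone MPA head
#'
#' Bilinearly upsamples the five pyramid levels to the finest (first)
#' level's resolution, concatenates, projects with a 1x1 convolution to the
#' fused width, and re-weights the fused channels with a
#' squeeze-and-excitation gate (global average pooling, two-layer
#' bottleneck, sigmoid).
#'
#' @param block object from [newMpaBlock()].
#' @param levels list of 5 arrays (N, C_i, H_i, W_i), finest first, with
#'   channels matching the configuration and non-increasing spatial sizes.
#' @param details also return the pooled channel statistics and the gate.
#' @return array (N, fusedChannels, H_0, W_0), or a list with `out`,
#'   `gvec`, `gate` when `details = TRUE`.
#' @export
mpaForward <- function(block, levels, details = FALSE) {
  cfg <- block$cfg
  if (!is.list(levels) || length(levels) != 5L)
    stop("configuration error: expected a list of 5 feature maps", call. = FALSE)
  ds <- lapply(seq_along(levels), function(i)
    check_featuremap(levels[[i]], paste0("level ", i - 1L)))
  for (i in seq_along(levels)) {
    if (ds[[i]][2] != cfg@levelChannels[i])
      stop("configuration error: level ", i - 1L, " has ", ds[[i]][2],
           " channels, expected ", cfg@levelChannels[i], call. = FALSE)
    if (ds[[i]][3] > ds[[1]][3] || ds[[i]][4] > ds[[1]][4])
      stop("input error: level ", i - 1L,
           " is spatially larger than level 0", call. = FALSE)
  }
  tape <- ad_tape()
  lv <- lapply(levels, function(l) ad_const(tape, api_to_ir(l)))
  r <- f_mpa(tape, block, lv, "mpa", details = TRUE)
  if (details)
    list(out = ir_to_api(r$out$v), gvec = t(r$gvec$v), gate = t(r$gate$v))
  else ir_to_api(r$out$v)
}

#' Squeeze-and-excitation channel gate of an MPA head
#' @param block object from [newMpaBlock()].
#' @param gvec channel statistics: numeric vector of length fusedChannels or
#'   an (N, fusedChannels) matrix.
#' @return gate of the same shape with entries strictly in (0, 1).
#' @export
seReweight <- function(block, gvec) {
  cfg <- block$cfg
  vec <- is.null(dim(gvec))
  if (vec) gvec <- matrix(gvec, 1L)
  if (ncol(gvec) != cfg@fusedChannels)
    stop("configuration error: gvec has length ", ncol(gvec),
         ", expected ", cfg@fusedChannels, call. = FALSE)
  tape <- ad_tape()
  # internal channel statistics are (C, N) columns
  g <- f_se_gate(tape, block, ad_const(tape, t(gvec)), "mpa")
  if (vec) as.vector(g$v) else t(g$v)
}
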