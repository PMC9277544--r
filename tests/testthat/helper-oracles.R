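# Independent straight-loop reference implementations used as oracles.
# Everything here works on the exported (N, C, H, W) convention and plain R
# loops -- deliberately none of the package's compute kernels.

oracle_conv <- function(x, w, b, pad = 0L, dil = 1L, groups = 1L) {
  dx <- dim(x)
  dw <- dim(w)
  N <- dx[1]; C <- dx[2]; H <- dx[3]; W <- dx[4]
  Cout <- dw[1]; Cg <- dw[2]; kh <- dw[3]; kw <- dw[4]
  Cog <- Cout / groups
  Ho <- H + 2 * pad - dil * (kh - 1)
  Wo <- W + 2 * pad - dil * (kw - 1)
  y <- array(0, c(N, Cout, Ho, Wo))
  for (n in 1:N) for (co in 1:Cout) {
    g <- ceiling(co / Cog)
    for (ho in 1:Ho) for (wo in 1:Wo) {
      s <- b[co]
      for (c in 1:Cg) for (ki in 1:kh) for (kj in 1:kw) {
        hh <- ho - pad + dil * (ki - 1)
        ww <- wo - pad + dil * (kj - 1)
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
          s <- s + x[n, (g - 1) * Cg + c, hh, ww] * w[co, c, ki, kj]
      }
      y[n, co, ho, wo] <- s
    }
  }
  y
}

oracle_avgpool <- function(x, r) {
  d <- dim(x)
  Ho <- d[3] / r; Wo <- d[4] / r
  y <- array(0, c(d[1], d[2], Ho, Wo))
  for (n in 1:d[1]) for (c in 1:d[2]) for (h in 1:Ho) for (w in 1:Wo)
    y[n, c, h, w] <- mean(x[n, c, (r * (h - 1) + 1):(r * h),
                            (r * (w - 1) + 1):(r * w)])
  y
}

# bilinear upsampling with half-pixel centers (the package's documented
# convention), computed from the closed-form interpolation weights
oracle_upsample <- function(x, Ho, Wo) {
  d <- dim(x)
  H <- d[3]; W <- d[4]
  y <- array(0, c(d[1], d[2], Ho, Wo))
  co <- function(o, So, Si) {
    s <- min(max((o - 0.5) * Si / So - 0.5, 0), Si - 1)
    i0 <- floor(s)
    list(i0 = i0 + 1, i1 = min(i0 + 1, Si - 1) + 1, f = s - i0)
  }
  for (h in 1:Ho) for (w in 1:Wo) {
    ch <- co(h, Ho, H); cw <- co(w, Wo, W)
    for (n in 1:d[1]) for (c in 1:d[2]) {
      a <- x[n, c, ch$i0, cw$i0] * (1 - ch$f) + x[n, c, ch$i1, cw$i0] * ch$f
      b <- x[n, c, ch$i0, cw$i1] * (1 - ch$f) + x[n, c, ch$i1, cw$i1] * ch$f
      y[n, c, h, w] <- a * (1 - cw$f) + b * cw$f
    }
  }
  y
}

oracle_bn_eval <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in 1:d[2])
    y[, c, , ] <- (x[, c, , ] - mean[c]) / sqrt(var[c] + eps) * gamma[c] + beta[c]
  y
}

oracle_bn_train <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in 1:d[2]) {
    v <- x[, c, , ]
    m <- mean(v)
    va <- mean((v - m)^2)
    y[, c, , ] <- (v - m) / sqrt(va + eps) * gamma[c] + beta[c]
  }
  y
}

oracle_relu <- function(x) pmax(x, 0)
oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# depthwise-separable or dense 3x3 unit (conv -> BN -> ReLU), reading the
# block's parameters by name; `train` selects batch vs running statistics
oracle_unit3 <- function(st, x, name, train, dil = 1L) {
  p <- st$params
  if (!is.null(p[[paste0(name, ".dw.w")]])) {
    C <- dim(x)[2]
    h <- oracle_conv(x, p[[paste0(name, ".dw.w")]], p[[paste0(name, ".dw.b")]],
                     pad = dil, dil = dil, groups = C)
    h <- oracle_conv(h, p[[paste0(name, ".pw.w")]], p[[paste0(name, ".pw.b")]])
  } else {
    h <- oracle_conv(x, p[[paste0(name, ".w")]], p[[paste0(name, ".b")]],
                     pad = dil, dil = dil)
  }
  bn <- paste0(name, ".bn")
  if (train) oracle_relu(oracle_bn_train(h, p[[paste0(bn, ".g")]],
                                         p[[paste0(bn, ".be")]]))
  else oracle_relu(oracle_bn_eval(h, p[[paste0(bn, ".g")]], p[[paste0(bn, ".be")]],
                                  st$state[[bn]]$mean, st$state[[bn]]$var))
}

# full ECC block recomposed step by step from the block's parameters
oracle_ecc <- function(block, x, train = FALSE) {
  p <- block$params
  C <- dim(x)[2]
  hC <- C / 2
  rate <- block$cfg@calibrationRate
  s <- oracle_conv(x, p[["ecc.split.w"]], p[["ecc.split.b"]])
  x1 <- s[, 1:hC, , , drop = FALSE]
  x2 <- s[, (hC + 1):C, , , drop = FALSE]
  idc <- oracle_conv(x1, p[["ecc.id.w"]], p[["ecc.id.b"]])
  x1p <- if (train)
    oracle_relu(oracle_bn_train(idc, p[["ecc.id.bn.g"]], p[["ecc.id.bn.be"]]))
  else
    oracle_relu(oracle_bn_eval(idc, p[["ecc.id.bn.g"]], p[["ecc.id.bn.be"]],
                               block$state[["ecc.id.bn"]]$mean,
                               block$state[["ecc.id.bn"]]$var))
  x2p <- oracle_unit3(block, x2, "ecc.x2", train)
  att <- oracle_ecc_calibrate(block, x2, train)
  gated <- att * x2p
  outh <- oracle_unit3(block, gated, "ecc.out", train)
  d <- dim(x)
  cat2 <- array(0, d)
  cat2[, 1:hC, , ] <- x1p
  cat2[, (hC + 1):C, , ] <- outh
  x + cat2
}

oracle_ecc_calibrate <- function(block, x2, train = FALSE) {
  rate <- block$cfg@calibrationRate
  down <- oracle_avgpool(x2, rate)
  conv <- oracle_unit3(block, down, "ecc.cal", train)
  up <- oracle_upsample(conv, dim(x2)[3], dim(x2)[4])
  oracle_sigmoid(x2 + up)
}

# alignment-based E-measure at one binarization threshold, explicit loops
oracle_emeasure_at <- function(pred, gt, thr) {
  pb <- (pred > thr) * 1
  n <- length(gt)
  if (sum(gt) == 0) enh <- 1 - pb
  else if (sum(gt) == n) enh <- pb
  else {
    mfm <- mean(pb); mgt <- mean(gt)
    enh <- matrix(0, nrow(gt), ncol(gt))
    for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
      a <- pb[i, j] - mfm
      b <- gt[i, j] - mgt
      al <- 2 * a * b / (a * a + b * b + .Machine$double.eps)
      enh[i, j] <- (al + 1)^2 / 4
    }
  }
  min(1, sum(enh) / (n - 1 + .Machine$double.eps))
}

# finite-difference gradient of a scalar-valued function of one parameter
fd_grad <- function(f, eps = 1e-6) (f(eps) - f(-eps)) / (2 * eps)
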