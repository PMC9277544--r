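# Parameter stores and composite layer helpers.
#
# A "store" is an environment with $params (named list of weight arrays) and
# $state (named list of batch-norm running statistics). The network and the
# standalone context blocks all use the same helpers; layer names are
# dot-separated prefixes, e.g. "enc2.x2.pw".

new_store <- function() {
  st <- new.env(parent = emptyenv())
  st$params <- list()
  # running batch-norm statistics live in an environment so that forward
  # passes in training mode can update them in place
  st$state <- new.env(parent = emptyenv())
  st
}

# He-style normal initialization for a (Cout, Cin/groups, k, k) kernel.
init_conv <- function(st, name, Cout, Cin, k, groups = 1L) {
  cg <- Cin %/% groups
  sdv <- sqrt(2 / (cg * k * k))
  st$params[[paste0(name, ".w")]] <-
    array(rnorm(Cout * cg * k * k, sd = sdv), dim = c(Cout, cg, k, k))
  st$params[[paste0(name, ".b")]] <- numeric(Cout)
  invisible(st)
}

init_bn <- function(st, name, C) {
  st$params[[paste0(name, ".g")]] <- rep(1, C)
  st$params[[paste0(name, ".be")]] <- numeric(C)
  st$state[[name]] <- list(mean = numeric(C), var = rep(1, C))
  invisible(st)
}

init_dense <- function(st, name, Cout, Cin) {
  sdv <- sqrt(2 / Cin)
  st$params[[paste0(name, ".w")]] <- matrix(rnorm(Cout * Cin, sd = sdv), Cout, Cin)
  st$params[[paste0(name, ".b")]] <- numeric(Cout)
  invisible(st)
}

init_ln <- function(st, name, C) {
  st$params[[paste0(name, ".g")]] <- rep(1, C)
  st$params[[paste0(name, ".be")]] <- numeric(C)
  invisible(st)
}

# 3x3 unit: depthwise-separable (depthwise 3x3 + pointwise 1x1) or dense.
init_unit3 <- function(st, name, Cin, Cout, depthwise = TRUE) {
  if (depthwise) {
    init_conv(st, paste0(name, ".dw"), Cin, Cin, 3L, groups = Cin)
    init_conv(st, paste0(name, ".pw"), Cout, Cin, 1L)
  } else {
    init_conv(st, name, Cout, Cin, 3L)
  }
  init_bn(st, paste0(name, ".bn"), Cout)
  invisible(st)
}

p_ <- function(tape, st, name) ad_param(tape, st$params[[name]], name)

f_conv <- function(tape, st, x, name, pad, dil = 1L, groups = 1L)
  op_conv(tape, x, p_(tape, st, paste0(name, ".w")),
          p_(tape, st, paste0(name, ".b")), pad, dil, groups)

f_bn <- function(tape, st, x, name, train)
  op_batchnorm(tape, x, p_(tape, st, paste0(name, ".g")),
               p_(tape, st, paste0(name, ".be")), st$state, name, train,
               momentum = st$bn_momentum %||% 0.1)

# conv -> BN -> ReLU
f_cbr <- function(tape, st, x, name, pad, dil = 1L, groups = 1L, train = FALSE)
  op_relu(tape, f_bn(tape, st, f_conv(tape, st, x, name, pad, dil, groups),
                     paste0(name, ".bn"), train))

# 3x3 unit forward matching init_unit3 (conv(s) -> BN -> ReLU)
f_unit3 <- function(tape, st, x, name, train, dil = 1L) {
  if (!is.null(st$params[[paste0(name, ".dw.w")]])) {
    C <- dim(x$v)[3]
    h <- f_conv(tape, st, x, paste0(name, ".dw"), pad = dil, dil = dil, groups = C)
    h <- f_conv(tape, st, h, paste0(name, ".pw"), pad = 0L)
  } else {
    h <- f_conv(tape, st, x, name, pad = dil, dil = dil)
  }
  op_relu(tape, f_bn(tape, st, h, paste0(name, ".bn"), train))
}

f_dense <- function(tape, st, x, name)
  op_dense(tape, x, p_(tape, st, paste0(name, ".w")),
           p_(tape, st, paste0(name, ".b")))

f_ln <- function(tape, st, x, name)
  op_layernorm(tape, x, p_(tape, st, paste0(name, ".g")),
               p_(tape, st, paste0(name, ".be")))

# Conversions between the exported batch convention (N, C, H, W) and the
# internal plane layout (H, W, C, N).
api_to_ir <- function(x) aperm(x, c(3L, 4L, 2L, 1L))
ir_to_api <- function(x) aperm(x, c(4L, 3L, 1L, 2L))

# Run a store-based forward fn on a plain (N, C, H, W) array and return a
# plain array in the same convention.
run_plain <- function(fn, x) {
  tape <- ad_tape()
  xin <- ad_const(tape, api_to_ir(x))
  out <- fn(tape, xin)
  ir_to_api(out$v)
}

check_featuremap <- function(x, what = "x") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(what, " must be a 4-d array with dim (N, C, H, W)", call. = FALSE)
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(dim(x))
}
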