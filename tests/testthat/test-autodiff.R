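# The compute kernels and the reverse-mode tape: forward agreement with
# loop oracles and gradient agreement with finite differences.

ir <- frcnet:::api_to_ir
api <- frcnet:::ir_to_api

test_that("convolution kernels match the loop oracle across configurations", {
  set.seed(1)
  cases <- list(
    list(N = 2L, C = 6L, Cout = 4L, k = 1L, H = 7L, groups = 1L, dil = 1L),
    list(N = 2L, C = 6L, Cout = 6L, k = 1L, H = 5L, groups = 3L, dil = 1L),
    list(N = 2L, C = 5L, Cout = 5L, k = 3L, H = 8L, groups = 5L, dil = 1L),
    list(N = 1L, C = 5L, Cout = 5L, k = 3L, H = 8L, groups = 5L, dil = 2L),
    list(N = 2L, C = 4L, Cout = 6L, k = 3L, H = 8L, groups = 1L, dil = 1L),
    list(N = 1L, C = 4L, Cout = 4L, k = 3L, H = 12L, groups = 1L, dil = 5L))
  for (cs in cases) {
    pad <- as.integer(cs$dil * (cs$k - 1) / 2)
    x <- array(rnorm(cs$N * cs$C * cs$H^2), c(cs$N, cs$C, cs$H, cs$H))
    w <- array(rnorm(cs$Cout * (cs$C / cs$groups) * cs$k^2),
               c(cs$Cout, cs$C / cs$groups, cs$k, cs$k))
    b <- rnorm(cs$Cout)
    got <- api(frcnet:::cpp_conv2d(ir(x), w, b, pad, cs$dil, cs$groups))
    want <- oracle_conv(x, w, b, pad, cs$dil, cs$groups)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("conv backward matches finite differences", {
  set.seed(2)
  x <- array(rnorm(2 * 4 * 6 * 6), c(2, 4, 6, 6))
  w <- array(rnorm(6 * 4 * 9), c(6, 4, 3, 3))
  b <- rnorm(6)
  dy <- array(rnorm(2 * 6 * 6 * 6), c(2, 6, 6, 6))
  r <- frcnet:::cpp_conv2d_bwd(ir(x), w, ir(dy), 1L, 1L, 1L)
  f <- function(xx, ww, bb)
    sum(frcnet:::cpp_conv2d(ir(xx), ww, bb, 1L, 1L, 1L) * ir(dy))
  for (probe in list(list(arr = "x", idx = c(1, 2, 3, 4)),
                     list(arr = "w", idx = c(5, 3, 2, 1)),
                     list(arr = "b", idx = 4))) {
    fd <- fd_grad(function(e) {
      xx <- x; ww <- w; bb <- b
      if (probe$arr == "x") xx[matrix(probe$idx, 1)] <- xx[matrix(probe$idx, 1)] + e
      if (probe$arr == "w") ww[matrix(probe$idx, 1)] <- ww[matrix(probe$idx, 1)] + e
      if (probe$arr == "b") bb[probe$idx] <- bb[probe$idx] + e
      f(xx, ww, bb)
    })
    got <- switch(probe$arr,
                  x = api(r$dx)[matrix(probe$idx, 1)],
                  w = r$dw[matrix(probe$idx, 1)],
                  b = r$db[probe$idx])
    expect_equal(got, fd, tolerance = 1e-5)
  }
})

test_that("average pooling and bilinear resize match their closed forms", {
  set.seed(3)
  x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  expect_equal(api(frcnet:::cpp_avgpool(ir(x), 2L)), oracle_avgpool(x, 2L),
               tolerance = 1e-12)
  small <- array(rnorm(1 * 2 * 4 * 4), c(1, 2, 4, 4))
  expect_equal(api(frcnet:::cpp_resize_bilinear(ir(small), 8L, 8L)),
               oracle_upsample(small, 8L, 8L), tolerance = 1e-12)
  # downscaling path used by the data loader
  expect_equal(api(frcnet:::cpp_resize_bilinear(ir(x), 4L, 4L)),
               oracle_upsample(x, 4L, 4L), tolerance = 1e-12)
})

test_that("max pooling takes blockwise maxima and routes gradients to them", {
  x <- array(0, c(1, 1, 4, 4))
  x[1, 1, , ] <- matrix(1:16, 4)
  r <- frcnet:::cpp_maxpool2(ir(x))
  expect_equal(api(r$y)[1, 1, , ], matrix(c(6, 8, 14, 16), 2))
  dy <- array(1, c(2, 2, 1, 1))
  dx <- frcnet:::cpp_maxpool2_bwd(dy, r$arg, dim(ir(x)))
  expect_equal(sum(api(dx)), 4)
  expect_equal(api(dx)[1, 1, 2, 2], 1)       # position of value 6
})

test_that("tape gradients of the structured ops match finite differences", {
  set.seed(4)
  checks <- list(
    softmax = function(v) {
      tape <- frcnet:::ad_tape()
      xn <- frcnet:::ad_node(tape, array(v, c(3, 3, 1, 1)), param = TRUE, name = "x")
      s <- frcnet:::op_softmax_pos(tape, xn)
      loss <- frcnet:::op_mean_all(tape, frcnet:::op_mul(tape, s, s))
      list(tape = tape, loss = loss, xn = xn)
    },
    gap = function(v) {
      tape <- frcnet:::ad_tape()
      xn <- frcnet:::ad_node(tape, array(v, c(3, 3, 1, 1)), param = TRUE, name = "x")
      g <- frcnet:::op_gap(tape, xn)
      loss <- frcnet:::op_mean_all(tape, frcnet:::op_mul(tape, g, g))
      list(tape = tape, loss = loss, xn = xn)
    },
    layernorm = function(v) {
      tape <- frcnet:::ad_tape()
      xn <- frcnet:::ad_node(tape, matrix(v, 9, 1), param = TRUE, name = "x")
      gam <- frcnet:::ad_const(tape, rep(1.2, 9))
      bet <- frcnet:::ad_const(tape, rep(-0.1, 9))
      y <- frcnet:::op_layernorm(tape, xn, gam, bet)
      loss <- frcnet:::op_mean_all(tape, frcnet:::op_mul(tape, y, y))
      list(tape = tape, loss = loss, xn = xn)
    })
  for (nm in names(checks)) {
    v0 <- rnorm(9)
    r <- checks[[nm]](v0)
    frcnet:::ad_backward(r$tape, r$loss)
    g <- r$xn$grad
    for (idx in c(1, 5, 9)) {
      fd <- fd_grad(function(e) {
        v <- v0
        v[idx] <- v[idx] + e
        checks[[nm]](v)$loss$v
      })
      expect_equal(as.vector(g)[idx], fd, tolerance = 1e-4,
                   label = paste(nm, "grad", idx))
    }
  }
})

test_that("batch normalization in training mode matches the loop oracle", {
  set.seed(5)
  x <- array(rnorm(2 * 3 * 4 * 4, mean = 2, sd = 3), c(2, 3, 4, 4))
  st <- frcnet:::new_store()
  frcnet:::init_bn(st, "bn", 3L)
  st$params[["bn.g"]] <- c(1.5, 0.8, 1.0)
  st$params[["bn.be"]] <- c(0.1, -0.2, 0)
  tape <- frcnet:::ad_tape()
  y <- frcnet:::f_bn(tape, st, frcnet:::ad_const(tape, ir(x)), "bn", TRUE)
  want <- oracle_bn_train(x, st$params[["bn.g"]], st$params[["bn.be"]])
  expect_equal(api(y$v), want, tolerance = 1e-10)
  # running statistics moved toward the batch statistics
  expect_false(all(st$state[["bn"]]$mean == 0))
})
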