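# Reverse-mode autodiff tape.
#
# A tape is an environment collecting nodes in creation order; node ids grow
# monotonically, so walking ids backwards from the loss node is a valid
# topological order. Each node holds its value eagerly and a closure that
# maps the incoming gradient to gradients for its parents. Constants (data,
# targets) are leaf nodes flagged untracked so no gradient is accumulated
# into them.
#
# Internal tensor layout: 4-d activations are (H, W, C, N) — contiguous
# channel planes per image, matching the compiled kernels. Channel
# statistics (pooled vectors, gates) are (C, N) matrices. The exported API
# converts from the conventional (N, C, H, W) at its boundary only.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), bw = NULL,
                    param = FALSE, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$parents <- parents
  nd$bw <- bw
  nd$param <- param
  nd$name <- name
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, value) ad_node(tape, value)
ad_param <- function(tape, value, name) ad_node(tape, value, param = TRUE, name = name)

# Backpropagate from `root` (seed gradient defaults to 1 for scalars).
# Afterwards every parameter node carries its gradient in $grad.
ad_backward <- function(tape, root, seed = NULL) {
  grads <- vector("list", tape$n)
  if (is.null(seed)) {
    seed <- if (is.null(dim(root$v))) rep(1, length(root$v))
            else array(1, dim = dim(root$v))
  }
  grads[[root$id]] <- seed
  for (i in seq(tape$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (nd$param) nd$grad <- g
    if (is.null(nd$bw)) next
    pg <- nd$bw(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (is.null(pg[[k]])) next
      if (is.null(p$bw) && !p$param) next  # untracked constant leaf
      grads[[p$id]] <- if (is.null(grads[[p$id]])) pg[[k]] else grads[[p$id]] + pg[[k]]
    }
    grads[[i]] <- NULL
  }
  invisible(NULL)
}

# Collect {name: grad} over parameter nodes after a backward pass.
ad_param_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (isTRUE(nd$param) && !is.null(nd$grad)) {
      if (is.null(out[[nd$name]])) out[[nd$name]] <- nd$grad
      else out[[nd$name]] <- out[[nd$name]] + nd$grad
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# broadcast a per-column value onto the rows of a matrix view
bc_col <- function(m, v) m * rep(v, each = nrow(m))

## ---- elementwise and scalar ops (layout-agnostic) ----

op_add <- function(tape, a, b)
  ad_node(tape, a$v + b$v, list(a, b), function(g) list(g, g))

op_sub <- function(tape, a, b)
  ad_node(tape, a$v - b$v, list(a, b), function(g) list(g, -g))

op_mul <- function(tape, a, b) {
  av <- a$v; bv <- b$v
  ad_node(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_div <- function(tape, a, b) {
  av <- a$v; bv <- b$v
  ad_node(tape, av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

op_smul <- function(tape, a, k)
  ad_node(tape, a$v * k, list(a), function(g) list(g * k))

op_sadd <- function(tape, a, k)
  ad_node(tape, a$v + k, list(a), function(g) list(g))

op_relu <- function(tape, a) {
  xv <- a$v
  v <- if (length(dim(xv)) == 4L) cpp_relu(xv) else pmax(xv, 0)
  ad_node(tape, v, list(a), function(g) {
    if (length(dim(xv)) == 4L) list(cpp_relu_bwd(g, xv))
    else list(g * (xv > 0))
  })
}

op_sigmoid <- function(tape, a) {
  s <- if (length(dim(a$v)) == 4L) cpp_sigmoid(a$v) else 1 / (1 + exp(-a$v))
  ad_node(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

op_log <- function(tape, a) {
  av <- a$v
  ad_node(tape, log(av), list(a), function(g) list(g / av))
}

op_clamp <- function(tape, a, lo, hi) {
  xv <- a$v
  v <- pmin(pmax(xv, lo), hi)
  dim(v) <- dim(xv)
  ad_node(tape, v, list(a), function(g) list(g * (xv > lo & xv < hi)))
}

## ---- reductions ----

op_mean_all <- function(tape, a) {
  n <- length(a$v)
  ad_node(tape, mean(a$v), list(a), function(g) {
    list(array(g / n, dim = dim(a$v) %||% n))
  })
}

# per-image sum of an (H, W, C, N) array -> numeric vector length N
op_sum_img <- function(tape, a) {
  d <- dim(a$v)
  v <- colSums(matrix(a$v, ncol = d[4]))
  ad_node(tape, v, list(a), function(g) {
    list(array(rep(g, each = d[1] * d[2] * d[3]), dim = d))
  })
}

## ---- structured tensor ops; all 4-d arrays are (H, W, C, N) ----

op_conv <- function(tape, x, w, b, pad, dil = 1L, groups = 1L) {
  xv <- x$v; wv <- w$v
  v <- cpp_conv2d(xv, wv, b$v, pad, dil, groups)
  ad_node(tape, v, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(xv, wv, g, pad, dil, groups)
    list(r$dx, r$dw, r$db)
  })
}

op_maxpool2 <- function(tape, x) {
  d <- dim(x$v)
  r <- cpp_maxpool2(x$v)
  ad_node(tape, r$y, list(x),
          function(g) list(cpp_maxpool2_bwd(g, r$arg, d)))
}

op_avgpool <- function(tape, x, rate) {
  d <- dim(x$v)
  ad_node(tape, cpp_avgpool(x$v, rate), list(x),
          function(g) list(cpp_avgpool_bwd(g, rate, d)))
}

op_upsample <- function(tape, x, Ho, Wo) {
  d <- dim(x$v)
  if (d[1] == Ho && d[2] == Wo)
    return(ad_node(tape, x$v, list(x), function(g) list(g)))
  ad_node(tape, cpp_resize_bilinear(x$v, Ho, Wo), list(x),
          function(g) list(cpp_resize_bilinear_bwd(g, d[1], d[2])))
}

op_concat_c <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(ds, `[`, integer(1), 3L)
  d <- ds[[1]]
  v <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (k in seq_along(xs)) {
    v[, , at + seq_len(cs[k]), ] <- xs[[k]]$v
    at <- at + cs[k]
  }
  ad_node(tape, v, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      out[[k]] <- g[, , at + seq_len(cs[k]), , drop = FALSE]
      at <- at + cs[k]
    }
    out
  })
}

# slice a (Cout, Cin, kh, kw) weight node along the input-channel axis
op_slice_w2 <- function(tape, w, from, to) {
  d <- dim(w$v)
  v <- w$v[, from:to, , , drop = FALSE]
  ad_node(tape, v, list(w), function(g) {
    dw <- array(0, dim = d)
    dw[, from:to, , ] <- g
    list(dw)
  })
}

op_slice_c <- function(tape, x, from, to) {
  d <- dim(x$v)
  v <- x$v[, , from:to, , drop = FALSE]
  ad_node(tape, v, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[, , from:to, ] <- g
    list(dx)
  })
}

# multiply an (H, W, C, N) tensor by an (H, W, 1, N) map, broadcast over C
op_bmul <- function(tape, x, m) {
  xv <- x$v; mv <- m$v
  d <- dim(xv)
  hw <- d[1] * d[2]
  expand <- function(mm) {
    # (HW x N) -> (HW x C*N) with column (c, n) = column n
    matrix(mm, hw)[, rep(seq_len(d[4]), each = d[3]), drop = FALSE]
  }
  me <- expand(mv)
  v <- matrix(xv, hw) * me
  dim(v) <- d
  ad_node(tape, v, list(x, m), function(g) {
    dx <- matrix(g, hw) * me
    dim(dx) <- d
    tmp <- matrix(g, hw) * matrix(xv, hw)
    dim(tmp) <- c(hw, d[3], d[4])
    dm <- array(0, dim = c(d[1], d[2], 1L, d[4]))
    for (n in seq_len(d[4])) dm[, , 1L, n] <- rowSums(tmp[, , n, drop = FALSE])
    list(dx, dm)
  })
}

# scale channels: (H, W, C, N) * gate (C, N)
op_chscale <- function(tape, x, s) {
  xv <- x$v; sv <- s$v
  d <- dim(xv)
  hw <- d[1] * d[2]
  v <- bc_col(matrix(xv, hw), as.vector(sv))
  dim(v) <- d
  ad_node(tape, v, list(x, s), function(g) {
    dx <- bc_col(matrix(g, hw), as.vector(sv))
    dim(dx) <- d
    ds <- matrix(colSums(matrix(g, hw) * matrix(xv, hw)), d[3], d[4])
    list(dx, ds)
  })
}

# broadcast-add a per-(channel, image) matrix (C, N) onto (H, W, C, N)
op_badd_vec <- function(tape, x, b) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  v <- matrix(x$v, hw) + rep(as.vector(b$v), each = hw)
  dim(v) <- d
  ad_node(tape, v, list(x, b), function(g) {
    db <- matrix(colSums(matrix(g, hw)), d[3], d[4])
    list(g, db)
  })
}

# global average pooling (H, W, C, N) -> (C, N)
op_gap <- function(tape, x) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  v <- matrix(colSums(matrix(x$v, hw)) / hw, d[3], d[4])
  ad_node(tape, v, list(x), function(g) {
    list(array(rep(as.vector(g) / hw, each = hw), dim = d))
  })
}

# dense layer on (Cin, N) columns: y = W x + b, W is (Cout, Cin)
op_dense <- function(tape, x, w, b) {
  xv <- x$v; wv <- w$v
  v <- wv %*% xv + b$v
  ad_node(tape, v, list(x, w, b), function(g) {
    list(crossprod(wv, g), tcrossprod(g, xv), rowSums(g))
  })
}

# layer normalization over the channel axis of (C, N), learnable gain/bias
op_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$v
  C <- nrow(xv)
  m <- colMeans(xv)
  xc <- xv - rep(m, each = C)
  va <- colMeans(xc * xc)
  ivar <- rep(1 / sqrt(va + eps), each = C)
  xhat <- xc * ivar
  gv <- gamma$v
  v <- xhat * gv + beta$v
  ad_node(tape, v, list(x, gamma, beta), function(g) {
    dgamma <- rowSums(g * xhat)
    dbeta <- rowSums(g)
    dxhat <- g * gv
    dx <- ivar / C * (C * dxhat - rep(colSums(dxhat), each = C) -
                        xhat * rep(colSums(dxhat * xhat), each = C))
    list(dx, dgamma, dbeta)
  })
}

# softmax over the spatial positions of an (H, W, 1, N) logit map
op_softmax_pos <- function(tape, x) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  m <- matrix(x$v, hw)                         # (HW, N)
  e <- exp(m - rep(apply(m, 2, max), each = hw))
  s <- bc_col(e, 1 / colSums(e))
  v <- array(s, dim = d)
  ad_node(tape, v, list(x), function(g) {
    gm <- matrix(g, hw)
    dx <- s * (gm - rep(colSums(gm * s), each = hw))
    dim(dx) <- d
    list(dx)
  })
}

# attention pooling: sum_j beta_j x_j over positions;
# x (H, W, C, N), beta (H, W, 1, N) -> (C, N)
op_attnpool <- function(tape, x, beta) {
  xv <- x$v; bv <- beta$v
  d <- dim(xv)
  hw <- d[1] * d[2]
  xm <- matrix(xv, hw)                         # cols (c, n)
  bexp <- matrix(bv, hw)[, rep(seq_len(d[4]), each = d[3]), drop = FALSE]
  v <- matrix(colSums(xm * bexp), d[3], d[4])
  ad_node(tape, v, list(x, beta), function(g) {
    dx <- bexp * rep(as.vector(g), each = hw)
    dim(dx) <- d
    tmp <- xm * rep(as.vector(g), each = hw)
    dim(tmp) <- c(hw, d[3], d[4])
    db <- array(0, dim = c(d[1], d[2], 1L, d[4]))
    for (n in seq_len(d[4])) db[, , 1L, n] <- rowSums(tmp[, , n, drop = FALSE])
    list(dx, db)
  })
}

# batch normalization over (H, W, N) per channel; `store` is the model's
# running-statistics environment, `key` its entry name. Heavy lifting is in
# the compiled kernels.
op_batchnorm <- function(tape, x, gamma, beta, store, key, train,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$v
  if (train) {
    st0 <- cpp_bn_stats(xv)
    mu <- st0$mean
    va <- st0$var
    st <- store[[key]]
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va
    store[[key]] <- st
  } else {
    st <- store[[key]]
    mu <- st$mean
    va <- st$var
  }
  ivar <- 1 / sqrt(va + eps)
  gv <- gamma$v
  scale <- gv * ivar
  v <- cpp_bn_apply(xv, scale, beta$v - mu * scale)
  ad_node(tape, v, list(x, gamma, beta), function(g) {
    if (train) {
      r <- cpp_bn_bwd_train(xv, g, gv, mu, ivar)
      list(r$dx, r$dgamma, r$dbeta)
    } else {
      r <- cpp_bn_bwd_eval(xv, g, mu, ivar)
      list(cpp_bn_apply(g, scale, numeric(length(scale))), r$dgamma, r$dbeta)
    }
  })
}
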