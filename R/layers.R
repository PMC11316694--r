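# Differentiable layer primitives for the volumetric segmentation networks.
# All spatial tensors are numeric arrays with dims (X, Y, Z, C). Convolutions
# use im2col (C++) + BLAS matmul; the im2col matrix is recomputed in the
# backward pass instead of cached, trading a little compute for memory.

`%||%` <- function(a, b) if (is.null(a)) b else a

op_input <- function(tape, v) tp_leaf(tape, v)

# 3x3x3 convolution, padding 1, per-axis stride (1 or the pooling factor).
# Forward and backward are fused C++ kernels (im2col in a persistent
# scratch buffer + BLAS dgemm); the column matrix is rebuilt on backward
# rather than cached, trading a little compute for memory.
op_conv3 <- function(tape, x, params, wname, stride = c(1L, 1L, 1L)) {
  xv <- x$v
  dims <- dim(xv)
  W <- params[[paste0(wname, ".W")]]
  b <- params[[paste0(wname, ".b")]]
  cin <- dim(W)[4]; cout <- dim(W)[5]
  stopifnot(dims[4] == cin)
  if (!is.double(xv)) storage.mode(xv) <- "double"
  Wm <- matrix(W, 27L * cin, cout)
  y <- .cpp_conv3_fw(xv, as.integer(dims), as.integer(stride), Wm, b)
  tp_node(tape, y, x$id, function(g) {
    r <- .cpp_conv3_bw(xv, as.integer(dims), as.integer(stride), Wm, g)
    dW <- r$dW
    dim(dW) <- dim(W)
    res <- list(pgrads = list(r$dx), wgrads = list())
    res$wgrads[[paste0(wname, ".W")]] <- dW
    res$wgrads[[paste0(wname, ".b")]] <- r$db
    res
  })
}

# 1x1x1 convolution (pointwise channel mix), used for the output head.
op_conv1 <- function(tape, x, params, wname) {
  xv <- x$v
  dims <- dim(xv)
  W <- params[[paste0(wname, ".W")]]   # (Cin, Cout)
  b <- params[[paste0(wname, ".b")]]
  nvox <- prod(dims[1:3])
  Xm <- matrix(xv, nvox, dims[4])
  y <- Xm %*% W
  y <- y + rep(b, each = nvox)
  dim(y) <- c(dims[1:3], ncol(W))
  tp_node(tape, y, x$id, function(g) {
    gm <- matrix(g, nvox, ncol(W))
    dW <- crossprod(Xm, gm)
    db <- colSums(gm)
    dx <- tcrossprod(gm, W)
    dim(dx) <- dims
    res <- list(pgrads = list(dx), wgrads = list())
    res$wgrads[[paste0(wname, ".W")]] <- dW
    res$wgrads[[paste0(wname, ".b")]] <- db
    res
  })
}

# Transposed convolution with kernel = stride = f (no output overlap):
# exactly inverts the grid coarsening of a pooling step.
op_tconv <- function(tape, x, params, wname, f) {
  xv <- x$v
  dims <- dim(xv)
  W <- params[[paste0(wname, ".W")]]   # (fx, fy, fz, Cin, Cout)
  b <- params[[paste0(wname, ".b")]]
  cin <- dim(W)[4]; cout <- dim(W)[5]
  f3 <- prod(f)
  n <- prod(dims[1:3])
  Wm <- matrix(aperm(array(W, c(f3, cin, cout)), c(2, 1, 3)), cin, f3 * cout)
  Xm <- matrix(xv, n, cin)
  Ym <- Xm %*% Wm                       # (n, f3*cout), col = off + f3*(co-1)
  od <- c(dims[1:3] * f, cout)
  y <- array(0, od)
  sx <- lapply(1:3, function(a) lapply(seq_len(f[a]), function(o) seq.int(o, by = f[a], length.out = dims[a])))
  colk <- 0L
  for (co in seq_len(cout)) {
    for (oz in seq_len(f[3])) for (oy in seq_len(f[2])) for (ox in seq_len(f[1])) {
      # column order must match Wm: offset index = ox + fx*(oy-1) + fx*fy*(oz-1)
      off <- ox + f[1] * (oy - 1L) + f[1] * f[2] * (oz - 1L)
      y[sx[[1]][[ox]], sx[[2]][[oy]], sx[[3]][[oz]], co] <-
        array(Ym[, off + f3 * (co - 1L)], dims[1:3]) + b[co]
    }
  }
  tp_node(tape, y, x$id, function(g) {
    dYm <- matrix(0, n, f3 * cout)
    db <- numeric(cout)
    for (co in seq_len(cout)) {
      for (oz in seq_len(f[3])) for (oy in seq_len(f[2])) for (ox in seq_len(f[1])) {
        off <- ox + f[1] * (oy - 1L) + f[1] * f[2] * (oz - 1L)
        blk <- g[sx[[1]][[ox]], sx[[2]][[oy]], sx[[3]][[oz]], co]
        dYm[, off + f3 * (co - 1L)] <- as.vector(blk)
        db[co] <- db[co] + sum(blk)
      }
    }
    dW <- crossprod(Xm, dYm)            # (cin, f3*cout)
    dW <- aperm(array(dW, c(cin, f3, cout)), c(2, 1, 3))
    dim(dW) <- dim(W)
    dx <- tcrossprod(dYm, Wm)
    dim(dx) <- dims
    res <- list(pgrads = list(dx), wgrads = list())
    res$wgrads[[paste0(wname, ".W")]] <- dW
    res$wgrads[[paste0(wname, ".b")]] <- db
    res
  })
}

op_maxpool <- function(tape, x, f) {
  xv <- x$v
  dims <- dim(xv)
  r <- .cpp_maxpool3(xv, as.integer(dims), as.integer(f))
  tp_node(tape, r$y, x$id, function(g) {
    dx <- numeric(length(xv))
    dx[r$idx] <- g
    dim(dx) <- dims
    list(pgrads = list(dx))
  })
}

# Normalization over all voxels of the sample, per channel. mode "batch"
# keeps running statistics for inference; mode "instance" always normalizes
# with the sample's own statistics. With one volume per forward pass the
# training-time computation is identical; only inference differs.
op_norm <- function(tape, x, params, wname, mode, state, training, eps = 1e-5, momentum = 0.1) {
  xv <- x$v
  dims <- dim(xv)
  nvox <- prod(dims[1:3]); C <- dims[4]
  gam <- params[[paste0(wname, ".g")]]
  bet <- params[[paste0(wname, ".b")]]
  Xm <- matrix(xv, nvox, C)
  use_running <- (mode == "batch") && !training
  if (use_running) {
    mu <- state$running_mean[[wname]] %||% numeric(C)
    va <- state$running_var[[wname]] %||% rep(1, C)
  } else {
    mu <- colMeans(Xm)
    va <- colMeans(Xm * Xm) - mu * mu
    va[va < 0] <- 0
    if (mode == "batch" && training) {
      state$running_mean[[wname]] <- (1 - momentum) * (state$running_mean[[wname]] %||% numeric(C)) + momentum * mu
      state$running_var[[wname]] <- (1 - momentum) * (state$running_var[[wname]] %||% rep(1, C)) + momentum * va
    }
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (Xm - rep(mu, each = nvox)) * rep(istd, each = nvox)
  y <- xhat * rep(gam, each = nvox) + rep(bet, each = nvox)
  dim(y) <- dims
  tp_node(tape, y, x$id, function(g) {
    gm <- matrix(g, nvox, C)
    dgam <- colSums(gm * xhat)
    dbet <- colSums(gm)
    dxhat <- gm * rep(gam, each = nvox)
    if (use_running) {
      dx <- dxhat * rep(istd, each = nvox)
    } else {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- (dxhat - rep(s1 / nvox, each = nvox) - xhat * rep(s2 / nvox, each = nvox)) *
        rep(istd, each = nvox)
    }
    dim(dx) <- dims
    res <- list(pgrads = list(dx), wgrads = list())
    res$wgrads[[paste0(wname, ".g")]] <- dgam
    res$wgrads[[paste0(wname, ".b")]] <- dbet
    res
  })
}

op_act <- function(tape, x, kind = c("relu", "leaky_relu"), alpha = 0.01) {
  kind <- match.arg(kind)
  xv <- x$v
  if (kind == "relu") {
    y <- pmax(xv, 0)
    tp_node(tape, y, x$id, function(g) list(pgrads = list(g * (xv > 0))))
  } else {
    y <- xv
    neg <- xv < 0
    y[neg] <- alpha * xv[neg]
    tp_node(tape, y, x$id, function(g) {
      dg <- g
      dg[neg] <- alpha * g[neg]
      list(pgrads = list(dg))
    })
  }
}

op_concat <- function(tape, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  y <- array(c(a$v, b$v), c(da[1:3], da[4] + db[4]))
  tp_node(tape, y, c(a$id, b$id), function(g) {
    ga <- g[, , , seq_len(da[4]), drop = FALSE]
    gb <- g[, , , da[4] + seq_len(db[4]), drop = FALSE]
    list(pgrads = list(ga, gb))
  })
}

# Element-wise maximum of two equal-shape feature stacks (the competitive
# connection). Ties route the gradient to the first argument.
op_maxout <- function(tape, a, b) {
  y <- pmax(a$v, b$v)
  tp_node(tape, y, c(a$id, b$id), function(g) {
    sel <- a$v >= b$v
    list(pgrads = list(g * sel, g * !sel))
  })
}

op_zeropad <- function(tape, x, lo, hi) {
  dims <- dim(x$v)
  od <- c(dims[1:3] + lo + hi, dims[4])
  if (all(lo == 0L) && all(hi == 0L)) return(x)
  y <- array(0, od)
  ix <- lapply(1:3, function(a) seq.int(lo[a] + 1L, lo[a] + dims[a]))
  y[ix[[1]], ix[[2]], ix[[3]], ] <- x$v
  tp_node(tape, y, x$id, function(g) {
    list(pgrads = list(g[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]))
  })
}

op_crop <- function(tape, x, lo, target) {
  dims <- dim(x$v)
  if (all(dims[1:3] == target)) return(x)
  ix <- lapply(1:3, function(a) seq.int(lo[a] + 1L, lo[a] + target[a]))
  y <- x$v[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  tp_node(tape, y, x$id, function(g) {
    dx <- array(0, dims)
    dx[ix[[1]], ix[[2]], ix[[3]], ] <- g
    list(pgrads = list(dx))
  })
}

# Channel-then-spatial attention gate (bottleneck only). The channel gate is
# a squeeze-excitation MLP over average- and max-pooled channel descriptors;
# the spatial gate is a 3^3 convolution over the channel-mean and
# channel-max maps. Implemented as one composite node with a hand-written
# backward because every piece is small at the bottleneck resolution.
op_attention <- function(tape, x, params, prefix) {
  xv <- x$v
  dims <- dim(xv)
  nvox <- prod(dims[1:3]); C <- dims[4]
  W1 <- params[[paste0(prefix, ".ch1.W")]]; b1 <- params[[paste0(prefix, ".ch1.b")]]
  W2 <- params[[paste0(prefix, ".ch2.W")]]; b2 <- params[[paste0(prefix, ".ch2.b")]]
  Ws <- params[[paste0(prefix, ".sp.W")]]; bs <- params[[paste0(prefix, ".sp.b")]]
  Xm <- matrix(xv, nvox, C)

  # channel gate
  s_avg <- colMeans(Xm)
  amax <- max.col(t(Xm), ties.method = "first")  # argmax voxel per channel
  s_max <- Xm[cbind(amax, seq_len(C))]
  h_avg <- pmax(drop(W1 %*% s_avg) + b1, 0)
  h_max <- pmax(drop(W1 %*% s_max) + b1, 0)
  zc <- drop(W2 %*% h_avg) + drop(W2 %*% h_max) + 2 * b2
  gc <- 1 / (1 + exp(-zc))
  Y1 <- Xm * rep(gc, each = nvox)

  # spatial gate over channel-pooled maps
  m_avg <- rowMeans(Y1)
  smax <- max.col(Y1, ties.method = "first")     # argmax channel per voxel
  m_max <- Y1[cbind(seq_len(nvox), smax)]
  pooled <- array(c(m_avg, m_max), c(dims[1:3], 2L))
  Wsm <- matrix(Ws, 27L * 2L, 1L)
  colp <- .cpp_im2col3(as.double(pooled), as.integer(dim(pooled)), c(1L, 1L, 1L))
  zs <- drop(colp %*% Wsm) + bs
  gs <- 1 / (1 + exp(-zs))
  y <- Y1 * gs
  dim(y) <- dims

  tp_node(tape, y, x$id, function(g) {
    gm <- matrix(g, nvox, C)
    # through spatial product
    dY1 <- gm * gs
    dgs <- rowSums(gm * Y1)
    dzs <- dgs * gs * (1 - gs)
    dWs <- crossprod(colp, dzs)
    dim(dWs) <- dim(Ws)
    dbs <- sum(dzs)
    dpooled <- .cpp_col2im3(tcrossprod(matrix(dzs, ncol = 1), Wsm),
                            as.integer(dim(pooled)), c(1L, 1L, 1L))
    dm <- matrix(dpooled, nvox, 2L)
    dY1 <- dY1 + dm[, 1] / C
    dY1[cbind(seq_len(nvox), smax)] <- dY1[cbind(seq_len(nvox), smax)] + dm[, 2]
    # through channel product
    dXm <- dY1 * rep(gc, each = nvox)
    dgc <- colSums(dY1 * Xm)
    dzc <- dgc * gc * (1 - gc)
    # channel MLP (shared weights on both descriptors)
    dh_avg <- drop(crossprod(W2, dzc)) * (h_avg > 0)
    dh_max <- drop(crossprod(W2, dzc)) * (h_max > 0)
    dW2 <- tcrossprod(dzc, h_avg) + tcrossprod(dzc, h_max)
    db2 <- 2 * dzc
    dW1 <- tcrossprod(dh_avg, s_avg) + tcrossprod(dh_max, s_max)
    db1 <- dh_avg + dh_max
    ds_avg <- drop(crossprod(W1, dh_avg))
    ds_max <- drop(crossprod(W1, dh_max))
    dXm <- dXm + rep(ds_avg / nvox, each = nvox)
    dXm[cbind(amax, seq_len(C))] <- dXm[cbind(amax, seq_len(C))] + ds_max
    dx <- dXm
    dim(dx) <- dims
    res <- list(pgrads = list(dx), wgrads = list())
    res$wgrads[[paste0(prefix, ".ch1.W")]] <- dW1
    res$wgrads[[paste0(prefix, ".ch1.b")]] <- db1
    res$wgrads[[paste0(prefix, ".ch2.W")]] <- dW2
    res$wgrads[[paste0(prefix, ".ch2.b")]] <- db2
    res$wgrads[[paste0(prefix, ".sp.W")]] <- dWs
    res$wgrads[[paste0(prefix, ".sp.b")]] <- dbs
    res
  })
}
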