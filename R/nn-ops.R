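## Reverse-mode tensor operations on a gradient tape.
##
## All activations are dense R arrays in [H, W, C, N] layout.  Convolutions are
## lowered to GEMM through the C++ im2col/col2im kernels; everything else is
## vectorised base R.  Each op appends a node (value + backward closure) to the
## tape; tape_backward() walks the nodes in reverse creation order, which is a
## valid topological order because parents always precede children.

tape_new <- function(params, buffers = NULL, training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$bwds <- list()
  tp$parents <- list()
  tp$nid <- 0L
  tp$params <- params
  tp$buffers <- if (is.null(buffers)) new.env(parent = emptyenv()) else buffers
  tp$pg <- new.env(parent = emptyenv())
  tp$training <- training
  tp
}

tp_push <- function(tp, value, parents = integer(0), bwd = NULL) {
  # force the promises first: nested op calls in `value`/`parents` append
  # their own nodes to the tape and must finish before we claim an id
  force(value)
  parents <- as.integer(parents)
  tp$nid <- tp$nid + 1L
  tp$vals[[tp$nid]] <- value
  tp$parents[[tp$nid]] <- parents
  tp$bwds[[tp$nid]] <- bwd
  tp$nid
}

tp_val <- function(tp, id) {
  # force `id` before touching tp$vals: ops are chained as nested calls whose
  # promises mutate the tape when forced
  id <- as.integer(id)
  tp$vals[[id]]
}

pg_add <- function(tp, name, g) {
  cur <- tp$pg[[name]]
  tp$pg[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

#' @noRd
tape_backward <- function(tp, seeds) {
  grads <- vector("list", tp$nid)
  for (id in names(seeds)) {
    i <- as.integer(id)
    grads[[i]] <- if (is.null(grads[[i]])) seeds[[id]] else grads[[i]] + seeds[[id]]
  }
  for (i in seq(tp$nid, 1L)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(tp$bwds[[i]])) next
    pg <- tp$bwds[[i]](g)
    ps <- tp$parents[[i]]
    for (j in seq_along(ps)) {
      if (is.null(pg[[j]])) next
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

## ---- layout helpers ---------------------------------------------------------

# (H,W,C,N) -> (H*W*N) x C matrix with rows ordered (h, w, n)
chan_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

unchan_mat <- function(m, H, W, C, N) {
  dim(m) <- c(H, W, N, C)
  aperm(m, c(1L, 2L, 4L, 3L))
}

conv_out_size <- function(n, k, pad, stride, dil) {
  (n + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
}

## ---- input ------------------------------------------------------------------

tp_input <- function(tp, x) tp_push(tp, x)

## ---- convolution ------------------------------------------------------------

# w: array c(k, k, Cin, Cout); b: length-Cout vector.  Stride-1 "same"
# convolution; lowered to one BLAS GEMM per kernel tap in C++.
tp_conv <- function(tp, id, wname, bname, dil = 1L) {
  x <- tp_val(tp, id)
  w <- tp$params[[wname]]
  b <- tp$params[[bname]]
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(w)[1]
  stopifnot(dim(w)[3] == C)
  y <- conv2d_fwd(x, w, b, H, W, C, N, k, as.integer(dil))
  bwd <- function(dy) {
    g <- conv2d_bwd(x, w, dy, H, W, C, N, k, as.integer(dil))
    pg_add(tp, wname, g$dw)
    pg_add(tp, bname, g$db)
    list(g$dx)
  }
  tp_push(tp, y, id, bwd)
}

## ---- transpose convolution, kernel 2, stride 2 ------------------------------

# w: array c(2, 2, Cout, Cin).  Doubles H and W; no overlap between output
# blocks, so lowering is a plain GEMM plus an interleave.
tp_tconv2 <- function(tp, id, wname, bname) {
  x <- tp_val(tp, id)
  w <- tp$params[[wname]]
  b <- tp$params[[bname]]
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- dim(w)[3]
  stopifnot(dim(w)[4] == C)
  Wm <- t(matrix(w, nrow = 4L * Cout))   # Cin x (4*Cout), cols ordered (ki,kj,co)
  xm <- chan_mat(x)
  ym <- xm %*% Wm                        # (HWN) x 4Cout
  dim(ym) <- c(H, W, N, 2L, 2L, Cout)
  y <- array(0, c(2L * H, 2L * W, Cout, N))
  for (ki in 1:2) for (kj in 1:2) {
    y[seq(ki, 2L * H, 2L), seq(kj, 2L * W, 2L), , ] <-
      aperm(ym[, , , ki, kj, , drop = FALSE], c(1L, 2L, 6L, 3L, 4L, 5L))
  }
  y <- y + array(rep(rep(b, each = 4L * H * W), times = N), dim(y))
  bwd <- function(dy) {
    db <- colSums(chan_mat(dy))
    dym <- matrix(0, H * W * N, 4L * Cout)
    for (ki in 1:2) for (kj in 1:2) {
      blk <- chan_mat(dy[seq(ki, 2L * H, 2L), seq(kj, 2L * W, 2L), , , drop = FALSE])
      dym[, ki + 2L * (kj - 1L) + 4L * (seq_len(Cout) - 1L)] <- blk
    }
    dWm <- crossprod(xm, dym)            # Cin x 4Cout
    dw <- t(dWm)
    dim(dw) <- dim(w)
    pg_add(tp, wname, dw)
    pg_add(tp, bname, db)
    dxm <- tcrossprod(dym, Wm)
    list(unchan_mat(dxm, H, W, C, N))
  }
  tp_push(tp, y, id, bwd)
}

## ---- batch normalisation ----------------------------------------------------

# Channel statistics are taken over (H, W, N).  Works directly on the native
# [H, W, C, N] layout: with HW rows, columns are (c, n) pairs with c fastest,
# so per-channel reductions are .colSums followed by a C x N row reduction.
tp_bn <- function(tp, id, gname, bname, bufname, momentum = 0.1, eps = 1e-5) {
  x <- tp_val(tp, id)
  g <- tp$params[[gname]]
  be <- tp$params[[bname]]
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  M <- HW * N
  if (tp$training) {
    st <- chan_meanvar_cpp(x, HW, C, N)
    mu <- st$mu
    v <- pmax(st$ex2 - mu * mu, 0)
    rm <- tp$buffers[[paste0(bufname, ".mean")]]
    rv <- tp$buffers[[paste0(bufname, ".var")]]
    if (is.null(rm)) { rm <- rep(0, C); rv <- rep(1, C) }
    tp$buffers[[paste0(bufname, ".mean")]] <- (1 - momentum) * rm + momentum * mu
    tp$buffers[[paste0(bufname, ".var")]] <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- tp$buffers[[paste0(bufname, ".mean")]]
    v <- tp$buffers[[paste0(bufname, ".var")]]
    if (is.null(mu)) { mu <- rep(0, C); v <- rep(1, C) }
  }
  invstd <- 1 / sqrt(v + eps)
  xh <- chan_affine_cpp(x, invstd, -mu * invstd, HW, C, N)
  y <- chan_affine_cpp(xh, g, be, HW, C, N)
  dim(xh) <- d; dim(y) <- d
  training <- tp$training
  bwd <- function(dy) {
    dgamma <- chan_dot_cpp(dy, xh, HW, C, N)
    dbeta <- chan_sum_cpp(dy, HW, C, N)
    pg_add(tp, gname, dgamma)
    pg_add(tp, bname, dbeta)
    if (training) {
      # dx = invstd*g*dy - invstd*g*(dbeta/M) - xh*invstd*g*(dgamma/M)
      a <- invstd * g
      dx <- chan_affine2_cpp(dy, xh, a, -a * dgamma / M, -a * dbeta / M,
                             HW, C, N)
    } else {
      dx <- chan_affine_cpp(dy, invstd * g, rep(0, C), HW, C, N)
    }
    dim(dx) <- d
    list(dx)
  }
  tp_push(tp, y, id, bwd)
}

## ---- pointwise --------------------------------------------------------------

tp_relu <- function(tp, id) {
  x <- tp_val(tp, id)
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  bwd <- function(dy) list(dy * (y > 0))
  tp_push(tp, y, id, bwd)
}

tp_sigmoid <- function(tp, id) {
  x <- tp_val(tp, id)
  y <- 1 / (1 + exp(-x))
  bwd <- function(dy) list(dy * y * (1 - y))
  tp_push(tp, y, id, bwd)
}

tp_dropout <- function(tp, id, p) {
  x <- tp_val(tp, id)
  if (!tp$training || p <= 0) return(tp_push(tp, x, id, function(dy) list(dy)))
  keep <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(keep) <- dim(x)
  bwd <- function(dy) list(dy * keep)
  tp_push(tp, x * keep, id, bwd)
}

tp_scale <- function(tp, id, s) {
  tp_push(tp, tp_val(tp, id) * s, id, function(dy) list(dy * s))
}

tp_add <- function(tp, ida, idb) {
  tp_push(tp, tp_val(tp, ida) + tp_val(tp, idb), c(ida, idb),
          function(dy) list(dy, dy))
}

# Elementwise product; b may have a single channel, broadcast across a's
# channels (used by attention gating).
tp_mul <- function(tp, ida, idb) {
  a <- tp_val(tp, ida)
  b <- tp_val(tp, idb)
  da <- dim(a); db <- dim(b)
  if (db[3] == da[3]) {
    y <- a * b
    bwd <- function(dy) list(dy * b, dy * a)
  } else if (db[3] == 1L) {
    HW <- da[1] * da[2]; C <- da[3]; N <- da[4]
    y <- bcast_mul_cpp(a, b, HW, C, N)
    dim(y) <- da
    bwd <- function(dy) {
      dbs <- bcast_dot_cpp(dy, a, HW, C, N)
      dim(dbs) <- db
      dx <- bcast_mul_cpp(dy, b, HW, C, N)
      dim(dx) <- da
      list(dx, dbs)
    }
  } else stop("incompatible channel dimensions in tp_mul")
  tp_push(tp, y, c(ida, idb), bwd)
}

## ---- pooling ----------------------------------------------------------------

tp_maxpool2 <- function(tp, id) {
  x <- tp_val(tp, id)
  d <- dim(x)
  H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ri <- list(seq(1L, H, 2L), seq(2L, H, 2L))
  ci <- list(seq(1L, W, 2L), seq(2L, W, 2L))
  s <- list()
  for (i in 1:2) for (j in 1:2)
    s[[(i - 1L) * 2L + j]] <- x[ri[[i]], ci[[j]], , , drop = FALSE]
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  dim(y) <- c(H %/% 2L, W %/% 2L, d[3], d[4])
  bwd <- function(dy) {
    dx <- array(0, d)
    taken <- array(FALSE, dim(y))
    for (i in 1:2) for (j in 1:2) {
      m <- (s[[(i - 1L) * 2L + j]] == y) & !taken
      taken <- taken | m
      dx[ri[[i]], ci[[j]], , ] <- dy * m
    }
    list(dx)
  }
  tp_push(tp, y, id, bwd)
}

## ---- channel concatenation --------------------------------------------------

tp_concat <- function(tp, ids) {
  ids <- as.integer(ids)
  xs <- lapply(ids, function(i) tp_val(tp, i))
  d1 <- dim(xs[[1]])
  HW <- d1[1] * d1[2]; N <- d1[4]
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  Ctot <- sum(cs)
  y <- concat_chan_cpp(xs, HW, cs, N)
  dim(y) <- c(d1[1], d1[2], Ctot, N)
  offs <- cumsum(c(0L, cs))
  bwd <- function(dy) {
    lapply(seq_along(ids), function(i) {
      g <- slice_chan_cpp(dy, HW, Ctot, N, offs[i], cs[i])
      dim(g) <- c(d1[1], d1[2], cs[i], N)
      g
    })
  }
  tp_push(tp, y, ids, bwd)
}

## ---- bilinear resize --------------------------------------------------------

# Half-pixel-centre sampling matrix (nout x nin); transpose is the exact
# gradient operator.
bilinear_matrix <- function(nout, nin) {
  A <- matrix(0, nout, nin)
  sc <- nin / nout
  for (i in seq_len(nout)) {
    src <- (i - 0.5) * sc + 0.5
    lo <- floor(src)
    fr <- src - lo
    if (lo < 1) { lo <- 1; fr <- 0 }
    hi <- min(lo + 1, nin)
    if (lo > nin) { lo <- nin; fr <- 0 }
    A[i, lo] <- A[i, lo] + (1 - fr)
    A[i, hi] <- A[i, hi] + fr
  }
  A
}

apply_rows <- function(A, x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  y <- A %*% x
  dim(y) <- c(nrow(A), d[-1])
  y
}

resize_bilinear_arr <- function(x, Hout, Wout, Ah = NULL, Aw = NULL) {
  d <- dim(x)
  if (is.null(Ah)) Ah <- bilinear_matrix(Hout, d[1])
  if (is.null(Aw)) Aw <- bilinear_matrix(Wout, d[2])
  y <- apply_rows(Ah, x)
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  y <- apply_rows(Aw, y)
  aperm(y, c(2L, 1L, 3L, 4L))
}

tp_upsample <- function(tp, id, Hout, Wout) {
  x <- tp_val(tp, id)
  d <- dim(x)
  if (d[1] == Hout && d[2] == Wout)
    return(tp_push(tp, x, id, function(dy) list(dy)))
  Ah <- bilinear_matrix(Hout, d[1])
  Aw <- bilinear_matrix(Wout, d[2])
  y <- resize_bilinear_arr(x, Hout, Wout, Ah, Aw)
  bwd <- function(dy) list(resize_bilinear_arr(dy, d[1], d[2], t(Ah), t(Aw)))
  tp_push(tp, y, id, bwd)
}

## ---- atrous channel attention -----------------------------------------------

# GAP -> two parallel 1-D convolutions over the channel axis (plain and
# dilated, both zero padded), summed, logistic, then channelwise rescale.
tp_chatt <- function(tp, id, w1name, b1name, w2name, b2name, dil) {
  x <- tp_val(tp, id)
  w1 <- tp$params[[w1name]]; b1 <- tp$params[[b1name]]
  w2 <- tp$params[[w2name]]; b2 <- tp$params[[b2name]]
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- length(w1)
  half <- (k - 1L) %/% 2L
  gap <- colMeans(matrix(x, H * W))       # over spatial dims; C*N columns
  dim(gap) <- c(C, N)

  conv1d <- function(g, w, step) {
    out <- matrix(0, C, ncol(g))
    for (u in seq_len(k)) {
      off <- (u - 1L - half) * step
      src <- seq_len(C) + off
      ok <- src >= 1L & src <= C
      out[ok, ] <- out[ok, ] + w[u] * g[src[ok], , drop = FALSE]
    }
    out
  }
  conv1d_T <- function(ds, w, step) {      # transpose (correlation flip)
    out <- matrix(0, C, ncol(ds))
    for (u in seq_len(k)) {
      off <- (u - 1L - half) * step
      dst <- seq_len(C) + off
      ok <- dst >= 1L & dst <= C
      out[dst[ok], ] <- out[dst[ok], ] + w[u] * ds[which(ok), , drop = FALSE]
    }
    out
  }

  s <- conv1d(gap, w1, 1L) + conv1d(gap, w2, dil) + b1 + b2
  wch <- 1 / (1 + exp(-s))                # C x N channel weights
  M <- H * W
  wfull <- array(rep(as.vector(wch), each = M), c(H, W, C, N))
  y <- x * wfull
  bwd <- function(dy) {
    dwch <- colSums(matrix(dy * x, H * W))
    dim(dwch) <- c(C, N)
    ds <- dwch * wch * (1 - wch)
    # tap gradients
    dw1 <- numeric(k); dw2 <- numeric(k)
    for (u in seq_len(k)) {
      off1 <- (u - 1L - half)
      src <- seq_len(C) + off1
      ok <- src >= 1L & src <= C
      dw1[u] <- sum(ds[ok, , drop = FALSE] * gap[src[ok], , drop = FALSE])
      off2 <- (u - 1L - half) * dil
      src2 <- seq_len(C) + off2
      ok2 <- src2 >= 1L & src2 <= C
      dw2[u] <- sum(ds[ok2, , drop = FALSE] * gap[src2[ok2], , drop = FALSE])
    }
    pg_add(tp, w1name, dw1)
    pg_add(tp, w2name, dw2)
    pg_add(tp, b1name, sum(ds))
    pg_add(tp, b2name, sum(ds))
    dgap <- conv1d_T(ds, w1, 1L) + conv1d_T(ds, w2, dil)
    dgfull <- array(rep(as.vector(dgap / M), each = M), c(H, W, C, N))
    list(dy * wfull + dgfull)
  }
  tp_push(tp, y, id, bwd)
}
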