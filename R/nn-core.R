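# Minimal reverse-mode autodiff over channel-first feature tensors.
#
# Tensors are numeric arrays with dim (C, H, W, N) — channel fastest, batch
# last. A "graph" is a tape of nodes; ops called with graph = NULL compute
# plain arrays (inference mode, no tape, no gradients). Ops called with a
# live graph return node environments carrying $val and, after ag_backward(),
# $grad. Parameters live in a flat environment keyed by path strings so the
# optimizer and the parameter counter can enumerate them.

ag_graph <- function(training = TRUE) {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 256L)
  g$n <- 0L
  g$pcache <- new.env(parent = emptyenv())
  g$training <- training
  g
}

is_node <- function(x) is.environment(x) && !is.null(x$ag_node)

vof <- function(x) if (is_node(x)) x$val else x

ag_out <- function(g, val, parents = NULL, backfn = NULL) {
  if (is.null(g)) return(val)
  node <- new.env(parent = emptyenv())
  node$ag_node <- TRUE
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  g$nodes[[g$n]] <- node
  node
}

ag_accum <- function(parent, grad) {
  if (!is_node(parent)) return(invisible(NULL))
  if (is.null(parent$grad)) parent$grad <- grad
  else parent$grad <- parent$grad + grad
  invisible(NULL)
}

#' Run backpropagation over a tape
#'
#' Gradients must have been seeded on one or more output nodes (by assigning
#' their `$grad`) before calling. After the call every parameter node created
#' through [ag_param()] carries its accumulated gradient.
#' @param g tape created by `ag_graph()`.
#' @keywords internal
ag_backward <- function(g) {
  for (i in rev(seq_len(g$n))) {
    node <- g$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node)
  }
  invisible(NULL)
}

ag_param <- function(g, params, path) {
  if (is.null(g)) return(params[[path]])
  cached <- g$pcache[[path]]
  if (!is.null(cached)) return(cached)
  node <- ag_out(g, params[[path]])
  node$is_param <- TRUE
  node$path <- path
  g$pcache[[path]] <- node
  node
}

ag_input <- function(g, x) ag_out(g, x)

# ---- ops ---------------------------------------------------------------------

conv_out_hw <- function(h, w, k, stride, pad) {
  c((h + 2 * pad - k) %/% stride + 1L, (w + 2 * pad - k) %/% stride + 1L)
}

# w: matrix (Cout, Cin*k*k), column order (cin fastest, kh, kw) matching
# cpp_im2col. b: optional length-Cout vector.
ag_conv2d <- function(g, x, w, b = NULL, k, stride = 1L, pad = 0L) {
  xv <- vof(x); d <- dim(xv)
  wm <- vof(w)
  col <- cpp_im2col(as.double(xv), d[1L], d[2L], d[3L], d[4L], k, stride, pad)
  y <- wm %*% col
  if (!is.null(b)) y <- y + as.double(vof(b))
  ohw <- conv_out_hw(d[2L], d[3L], k, stride, pad)
  cout <- nrow(wm)
  dim(y) <- c(cout, ohw[1L], ohw[2L], d[4L])
  if (is.null(g)) return(y)
  force(col); force(d); force(k); force(stride); force(pad)
  ag_out(g, y, list(x = x, w = w, b = b), function(node) {
    dy <- node$grad
    dim(dy) <- c(cout, length(dy) %/% cout)
    p <- node$parents
    if (is_node(p$w)) ag_accum(p$w, tcrossprod(dy, col))
    if (!is.null(p$b) && is_node(p$b)) ag_accum(p$b, rowSums(dy))
    if (is_node(p$x)) {
      dcol <- crossprod(wm, dy)
      dx <- cpp_col2im(dcol, d[1L], d[2L], d[3L], d[4L], k, stride, pad)
      dim(dx) <- d
      ag_accum(p$x, dx)
    }
  })
}

# Batch norm over (H, W, N) per channel. buffers: env with numeric vectors at
# paths <path>.mean / <path>.var maintained when training.
ag_batchnorm <- function(g, x, gamma, beta, buffers, path,
                         eps = 1e-5, momentum = 0.03) {
  xv <- vof(x); d <- dim(xv)
  C <- d[1L]; M <- prod(d) / C
  xm <- xv; dim(xm) <- c(C, M)
  training <- !is.null(g) && g$training
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    rm_path <- paste0(path, ".mean"); rv_path <- paste0(path, ".var")
    old_m <- buffers[[rm_path]]; old_v <- buffers[[rv_path]]
    if (is.null(old_m)) { old_m <- numeric(C); old_v <- rep(1, C) }
    buffers[[rm_path]] <- (1 - momentum) * old_m + momentum * mu
    buffers[[rv_path]] <- (1 - momentum) * old_v + momentum * va
  } else {
    mu <- buffers[[paste0(path, ".mean")]]
    va <- buffers[[paste0(path, ".var")]]
    if (is.null(mu)) { mu <- numeric(C); va <- rep(1, C) }
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * ivar
  gv <- as.double(vof(gamma)); bv <- as.double(vof(beta))
  y <- gv * xhat + bv
  dim(y) <- d
  if (is.null(g)) return(y)
  ag_out(g, y, list(x = x, gamma = gamma, beta = beta), function(node) {
    dy <- node$grad; dim(dy) <- c(C, M)
    p <- node$parents
    if (is_node(p$gamma)) ag_accum(p$gamma, rowSums(dy * xhat))
    if (is_node(p$beta)) ag_accum(p$beta, rowSums(dy))
    if (is_node(p$x)) {
      dxhat <- dy * gv
      if (training) {
        # standard batch-norm backward through batch statistics
        t1 <- rowSums(dxhat)
        t2 <- rowSums(dxhat * xhat)
        dx <- (dxhat - t1 / M - xhat * t2 / M) * ivar
      } else {
        dx <- dxhat * ivar
      }
      dim(dx) <- d
      ag_accum(p$x, dx)
    }
  })
}

ag_silu <- function(g, x) {
  xv <- vof(x)
  s <- 1 / (1 + exp(-xv))
  y <- xv * s
  if (is.null(g)) return(y)
  ag_out(g, y, list(x = x), function(node) {
    ag_accum(node$parents$x, node$grad * (s * (1 + xv * (1 - s))))
  })
}

ag_add <- function(g, a, b) {
  y <- vof(a) + vof(b)
  if (is.null(g)) return(y)
  ag_out(g, y, list(a = a, b = b), function(node) {
    ag_accum(node$parents$a, node$grad)
    ag_accum(node$parents$b, node$grad)
  })
}

# concatenate along channel dim
ag_cat <- function(g, xs) {
  vals <- lapply(xs, vof)
  ds <- lapply(vals, dim)
  C <- vapply(ds, `[`, 0L, 1L)
  d1 <- ds[[1L]]
  y <- array(0, c(sum(C), d1[2L], d1[3L], d1[4L]))
  at <- 0L
  for (i in seq_along(vals)) {
    y[at + seq_len(C[i]), , , ] <- vals[[i]]
    at <- at + C[i]
  }
  if (is.null(g)) return(y)
  ag_out(g, y, xs, function(node) {
    at <- 0L
    for (i in seq_along(node$parents)) {
      ag_accum(node$parents[[i]],
               node$grad[at + seq_len(C[i]), , , , drop = FALSE])
      at <- at + C[i]
    }
  })
}

# take channel range
ag_slice <- function(g, x, channels) {
  xv <- vof(x); d <- dim(xv)
  y <- xv[channels, , , , drop = FALSE]
  if (is.null(g)) return(y)
  ag_out(g, y, list(x = x), function(node) {
    dx <- array(0, d)
    dx[channels, , , ] <- node$grad
    ag_accum(node$parents$x, dx)
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2 <- function(g, x) {
  xv <- vof(x); d <- dim(xv)
  hi <- rep(seq_len(d[2L]), each = 2L)
  wi <- rep(seq_len(d[3L]), each = 2L)
  y <- xv[, hi, wi, , drop = FALSE]
  if (is.null(g)) return(y)
  ag_out(g, y, list(x = x), function(node) {
    dy <- node$grad
    o1 <- seq(1L, 2L * d[2L], by = 2L); o2 <- o1 + 1L
    e1 <- seq(1L, 2L * d[3L], by = 2L); e2 <- e1 + 1L
    dx <- dy[, o1, e1, , drop = FALSE] + dy[, o2, e1, , drop = FALSE] +
      dy[, o1, e2, , drop = FALSE] + dy[, o2, e2, , drop = FALSE]
    ag_accum(node$parents$x, dx)
  })
}

ag_maxpool <- function(g, x, k, stride = 1L, pad = 0L) {
  xv <- vof(x); d <- dim(xv)
  res <- cpp_maxpool_fwd(as.double(xv), d[1L], d[2L], d[3L], d[4L], k, stride, pad)
  y <- res$y
  ohw <- conv_out_hw(d[2L], d[3L], k, stride, pad)
  dim(y) <- c(d[1L], ohw[1L], ohw[2L], d[4L])
  if (is.null(g)) return(y)
  arg <- res$arg
  ag_out(g, y, list(x = x), function(node) {
    dx <- cpp_maxpool_bwd(as.double(node$grad), arg, as.integer(prod(d)))
    dim(dx) <- d
    ag_accum(node$parents$x, dx)
  })
}

# Fast normalized fusion: y = sum_i clamp(w_i, 0) x_i / (sum clamp(w) + beta).
# w is a length-m parameter vector node; xs a list of same-shape tensors.
ag_wfuse <- function(g, xs, w, beta = 1e-4) {
  wv <- as.double(vof(w))
  wc <- pmax(wv, 0)
  S <- sum(wc) + beta
  coef <- wc / S
  vals <- lapply(xs, vof)
  y <- coef[1L] * vals[[1L]]
  if (length(vals) > 1L) {
    for (i in 2L:length(vals)) y <- y + coef[i] * vals[[i]]
  }
  if (is.null(g)) return(y)
  ag_out(g, y, c(xs, list(w = w)), function(node) {
    dy <- node$grad
    m <- length(vals)
    gdot <- numeric(m)
    for (i in seq_len(m)) {
      if (is_node(node$parents[[i]])) ag_accum(node$parents[[i]], coef[i] * dy)
      gdot[i] <- sum(dy * vals[[i]])
    }
    if (is_node(node$parents$w)) {
      dw <- (gdot * S - sum(wc * gdot)) / S^2
      dw[wv < 0] <- 0
      ag_accum(node$parents$w, dw)
    }
  })
}

# Grouped channel attention: per batch element, per-channel spatial mean ->
# softmax across the group's channels -> channel-wise rescale of the group.
ag_channel_attention <- function(g, x) {
  xv <- vof(x); d <- dim(xv)
  C <- d[1L]; HW <- d[2L] * d[3L]; N <- d[4L]
  xm <- xv; dim(xm) <- c(C, HW, N)
  m <- apply(xm, c(1L, 3L), mean)          # (C, N) channel descriptors
  dim(m) <- c(C, N)
  mm <- sweep(m, 2L, apply(m, 2L, max))    # max-shift for stability
  e <- exp(mm)
  a <- sweep(e, 2L, colSums(e), "/")       # (C, N) simplex per column
  a_e <- a[, rep(seq_len(N), each = HW), drop = FALSE]
  ym <- xm; dim(ym) <- c(C, HW * N)
  y <- ym * a_e
  dim(y) <- d
  if (is.null(g)) return(list(out = y, weights = a))
  node <- ag_out(g, y, list(x = x), function(node) {
    dy <- node$grad; dim(dy) <- c(C, HW, N)
    xr <- xv; dim(xr) <- c(C, HW, N)
    # da[c,n] = sum_hw dy * x ; softmax jacobian back to descriptors
    da <- apply(dy * xr, c(1L, 3L), sum); dim(da) <- c(C, N)
    dm <- a * sweep(da, 2L, colSums(da * a))   # a_c (da_c - sum_k da_k a_k)
    # dx = dy * a + (dm / HW) broadcast over spatial positions
    dx <- dy
    dim(dx) <- c(C, HW, N)
    for (n in seq_len(N)) {
      dx[, , n] <- dx[, , n] * a[, n] + dm[, n] / HW
    }
    dim(dx) <- d
    ag_accum(node$parents$x, dx)
  })
  list(out = node, weights = a)
}

ag_sigmoid <- function(g, x) {
  xv <- vof(x)
  s <- 1 / (1 + exp(-xv))
  if (is.null(g)) return(s)
  ag_out(g, s, list(x = x), function(node) {
    ag_accum(node$parents$x, node$grad * s * (1 - s))
  })
}
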