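# Layer constructors register parameters under path keys in a flat
# environment; descriptors are plain lists so a checkpoint is just
# (config, named parameter list, named buffer list). Forward passes dispatch
# on $type through blk_forward().

rand_unif <- function(n, bound) stats::runif(n, -bound, bound)

init_conv2d <- function(params, path, cout, cin, k, bias = FALSE) {
  fan_in <- cin * k * k
  bound <- sqrt(1 / fan_in)
  w <- matrix(rand_unif(cout * fan_in, bound), nrow = cout)
  params[[paste0(path, ".w")]] <- w
  if (bias) params[[paste0(path, ".b")]] <- rand_unif(cout, bound)
  invisible(NULL)
}

new_conv_block <- function(params, path, cin, cout, k = 1L, stride = 1L) {
  init_conv2d(params, path, cout, cin, k)
  params[[paste0(path, ".bn.gamma")]] <- rep(1, cout)
  params[[paste0(path, ".bn.beta")]] <- rep(0, cout)
  list(type = "conv_block", path = path, cin = cin, cout = cout,
       k = as.integer(k), stride = as.integer(stride),
       pad = as.integer((k - 1L) %/% 2L))
}

new_plain_conv <- function(params, path, cin, cout, k = 1L, stride = 1L,
                           bias = TRUE) {
  init_conv2d(params, path, cout, cin, k, bias = bias)
  list(type = "plain_conv", path = path, cin = cin, cout = cout,
       k = as.integer(k), stride = as.integer(stride),
       pad = as.integer((k - 1L) %/% 2L), bias = bias)
}

new_bottleneck <- function(params, path, c, shortcut = TRUE) {
  list(type = "bottleneck", path = path, shortcut = shortcut,
       cv1 = new_conv_block(params, paste0(path, ".cv1"), c, c, 3L),
       cv2 = new_conv_block(params, paste0(path, ".cv2"), c, c, 3L))
}

new_msconv <- function(params, path, c) {
  if (c %% 4L != 0L) {
    stop(sprintf("MSConv requires channels divisible by 4, got %d", c),
         call. = FALSE)
  }
  cg <- c %/% 4L
  list(type = "msconv", path = path, c = c, cg = cg,
       b1 = new_conv_block(params, paste0(path, ".b1"), cg, cg, 1L),
       b3 = new_conv_block(params, paste0(path, ".b3"), cg, cg, 3L),
       b5 = new_conv_block(params, paste0(path, ".b5"), cg, cg, 5L),
       mix = new_conv_block(params, paste0(path, ".mix"), c, c, 1L))
}

new_msbottleneck <- function(params, path, c) {
  list(type = "msbottleneck", path = path,
       cv = new_conv_block(params, paste0(path, ".cv"), c, c, 3L),
       ms = new_msconv(params, paste0(path, ".ms"), c))
}

# C2f-style stage block; `ms` swaps every inner bottleneck for MSBottleneck,
# which is what turns C2f into MSModule.
new_c2f <- function(params, path, cin, cout, n = 1L, shortcut = FALSE,
                    ms = FALSE) {
  c <- cout %/% 2L
  inner <- lapply(seq_len(n), function(i) {
    ipath <- paste0(path, ".m", i)
    if (ms) new_msbottleneck(params, ipath, c)
    else new_bottleneck(params, ipath, c, shortcut = shortcut)
  })
  list(type = "c2f", path = path, c = c, n = as.integer(n), ms = ms,
       cv1 = new_conv_block(params, paste0(path, ".cv1"), cin, 2L * c, 1L),
       cv2 = new_conv_block(params, paste0(path, ".cv2"), (2L + n) * c, cout, 1L),
       m = inner)
}

new_sppf <- function(params, path, cin, cout, k = 5L) {
  ch <- cin %/% 2L
  list(type = "sppf", path = path, k = as.integer(k),
       cv1 = new_conv_block(params, paste0(path, ".cv1"), cin, ch, 1L),
       cv2 = new_conv_block(params, paste0(path, ".cv2"), ch * 4L, cout, 1L))
}

# ---- forward dispatch --------------------------------------------------------

blk_forward <- function(model, g, blk, x) {
  switch(blk$type,
    conv_block = {
      w <- ag_param(g, model$params, paste0(blk$path, ".w"))
      y <- ag_conv2d(g, x, w, NULL, blk$k, blk$stride, blk$pad)
      gamma <- ag_param(g, model$params, paste0(blk$path, ".bn.gamma"))
      beta <- ag_param(g, model$params, paste0(blk$path, ".bn.beta"))
      y <- ag_batchnorm(g, y, gamma, beta, model$buffers, paste0(blk$path, ".bn"))
      ag_silu(g, y)
    },
    plain_conv = {
      w <- ag_param(g, model$params, paste0(blk$path, ".w"))
      b <- if (blk$bias) ag_param(g, model$params, paste0(blk$path, ".b")) else NULL
      ag_conv2d(g, x, w, b, blk$k, blk$stride, blk$pad)
    },
    bottleneck = {
      y <- blk_forward(model, g, blk$cv2, blk_forward(model, g, blk$cv1, x))
      if (blk$shortcut) ag_add(g, x, y) else y
    },
    msconv = {
      cg <- blk$cg
      a <- ag_slice(g, x, seq_len(cg))
      b <- ag_slice(g, x, cg + seq_len(cg))
      cc <- ag_slice(g, x, 2L * cg + seq_len(cg))
      d <- ag_slice(g, x, 3L * cg + seq_len(cg))
      a <- ag_channel_attention(g, blk_forward(model, g, blk$b1, a))$out
      b <- ag_channel_attention(g, blk_forward(model, g, blk$b3, b))$out
      cc <- ag_channel_attention(g, blk_forward(model, g, blk$b5, cc))$out
      blk_forward(model, g, blk$mix, ag_cat(g, list(a, b, cc, d)))
    },
    msbottleneck = {
      y <- blk_forward(model, g, blk$ms, blk_forward(model, g, blk$cv, x))
      ag_add(g, x, y)
    },
    c2f = {
      y <- blk_forward(model, g, blk$cv1, x)
      c <- blk$c
      parts <- list(ag_slice(g, y, seq_len(c)), ag_slice(g, y, c + seq_len(c)))
      for (m in blk$m) {
        parts[[length(parts) + 1L]] <-
          blk_forward(model, g, m, parts[[length(parts)]])
      }
      blk_forward(model, g, blk$cv2, ag_cat(g, parts))
    },
    sppf = {
      y <- blk_forward(model, g, blk$cv1, x)
      p1 <- ag_maxpool(g, y, blk$k, 1L, (blk$k - 1L) %/% 2L)
      p2 <- ag_maxpool(g, p1, blk$k, 1L, (blk$k - 1L) %/% 2L)
      p3 <- ag_maxpool(g, p2, blk$k, 1L, (blk$k - 1L) %/% 2L)
      blk_forward(model, g, blk$cv2, ag_cat(g, list(y, p1, p2, p3)))
    },
    stop(sprintf("unknown block type '%s'", blk$type), call. = FALSE)
  )
}

# ---- public module-level API -------------------------------------------------

#' Numerically stable softmax
#'
#' `softmax(v)_i = exp(v_i) / sum_j exp(v_j)`, computed with the max
#' subtracted before exponentiation. Shift-invariant and order-preserving;
#' the result sums to 1.
#'
#' @param v numeric vector (length >= 1, finite).
#' @return simplex vector of the same length.
#' @examples
#' softmax(c(1, 2, 3))
#' @export
softmax <- function(v) {
  if (length(v) < 1L) stop("softmax of an empty vector is undefined", call. = FALSE)
  if (any(!is.finite(v))) stop("softmax input must be finite", call. = FALSE)
  e <- exp(v - max(v))
  e / sum(e)
}

check_cmap <- function(x) {
  if (length(dim(x)) != 3L) {
    stop("feature map must be a 3-d array with dim (channels, height, width)",
         call. = FALSE)
  }
  x
}

#' Split a feature map into four contiguous channel groups
#'
#' The multi-scale block partitions its input into groups A, B, C, D along the
#' channel axis; concatenating the groups in order reconstructs the input
#' exactly.
#'
#' @param x feature map array with dim `(C, H, W)`, `C` divisible by 4.
#' @return named list of four `(C/4, H, W)` arrays `A, B, C, D`.
#' @export
channel_group_split <- function(x) {
  check_cmap(x)
  C <- dim(x)[1L]
  if (C %% 4L != 0L) {
    stop(sprintf("channel count %d is not divisible by 4", C), call. = FALSE)
  }
  cg <- C %/% 4L
  idx <- function(i) x[(i - 1L) * cg + seq_len(cg), , , drop = FALSE]
  list(A = idx(1L), B = idx(2L), C = idx(3L), D = idx(4L))
}

#' Channel-attention weights of one group
#'
#' Per-channel descriptor = global average pooling (spatial mean of each
#' channel), followed by a softmax across the group's channels. The weights
#' live on the simplex: nonnegative, summing to 1.
#'
#' @param g feature map array with dim `(Cg, H, W)`.
#' @return numeric vector of length `Cg` on the simplex.
#' @export
channel_attention_weights <- function(g) {
  check_cmap(g)
  d <- dim(g)
  m <- rowMeans(matrix(g, d[1L], d[2L] * d[3L]))
  softmax(m)
}

#' Build a standalone MSConv block
#'
#' MSConv splits its input into four channel groups; groups A, B, C pass
#' through 1x1, 3x3 and 5x5 conv cells (each `C/4 -> C/4`, stride 1, same
#' padding) and are rescaled by their own channel-attention simplex; group D
#' is concatenated untouched; a final 1x1 mixing cell (`C -> C`) exchanges
#' channel information. Output shape equals input shape.
#'
#' @param in_channels input channel count (divisible by 4).
#' @return an `msconv_layer` object usable with [msconv_forward()].
#' @export
new_msconv_layer <- function(in_channels) {
  params <- new.env(parent = emptyenv())
  blk <- new_msconv(params, "msconv", as.integer(in_channels))
  structure(list(blk = blk, params = params,
                 buffers = new.env(parent = emptyenv()),
                 in_channels = as.integer(in_channels)),
            class = "msconv_layer")
}

std_layer_forward <- function(layer, x) {
  check_cmap(x)
  d <- dim(x)
  if (d[1L] != layer$in_channels) {
    stop(sprintf("feature map has %d channels, layer expects %d",
                 d[1L], layer$in_channels), call. = FALSE)
  }
  dim(x) <- c(d, 1L)
  model <- list(params = layer$params, buffers = layer$buffers)
  y <- blk_forward(model, NULL, layer$blk, x)
  dim(y) <- dim(y)[1:3]
  y
}

#' Forward pass through a standalone MSConv layer
#' @param layer an object from [new_msconv_layer()].
#' @param x feature map array `(C, H, W)` with `C = in_channels`.
#' @return feature map of the same shape.
#' @export
msconv_forward <- function(layer, x) {
  stopifnot(inherits(layer, "msconv_layer"))
  std_layer_forward(layer, x)
}

#' Build a standalone MSBottleneck block
#'
#' `out = x + MSConv(Conv3x3(x))`: an ordinary 3x3 conv cell followed by
#' MSConv on a residual path. Input and output channel counts are equal.
#'
#' @inheritParams new_msconv_layer
#' @return an `msbottleneck_layer` object usable with [msbottleneck_forward()].
#' @export
new_msbottleneck_layer <- function(in_channels) {
  params <- new.env(parent = emptyenv())
  blk <- new_msbottleneck(params, "msb", as.integer(in_channels))
  structure(list(blk = blk, params = params,
                 buffers = new.env(parent = emptyenv()),
                 in_channels = as.integer(in_channels)),
            class = "msbottleneck_layer")
}

#' Forward pass through a standalone MSBottleneck layer
#' @param layer an object from [new_msbottleneck_layer()].
#' @param x feature map array `(C, H, W)`.
#' @return feature map of the same shape.
#' @export
msbottleneck_forward <- function(layer, x) {
  stopifnot(inherits(layer, "msbottleneck_layer"))
  std_layer_forward(layer, x)
}

#' Build a standalone MSModule stage block
#'
#' Identical topology to the baseline C2f stage block (1x1 expand, split,
#' `n` stacked bottlenecks with all intermediate outputs concatenated, 1x1
#' contract), with every inner bottleneck replaced by MSBottleneck.
#'
#' @param in_channels,out_channels stage channel widths.
#' @param n number of stacked bottlenecks.
#' @param ms if `FALSE`, builds the baseline C2f instead (for comparison).
#' @param shortcut residual shortcut inside baseline bottlenecks.
#' @return an `msmodule_layer` object usable with [msmodule_forward()].
#' @export
new_msmodule_layer <- function(in_channels, out_channels, n = 1L, ms = TRUE,
                               shortcut = TRUE) {
  params <- new.env(parent = emptyenv())
  blk <- new_c2f(params, "stage", as.integer(in_channels),
                 as.integer(out_channels), as.integer(n),
                 shortcut = shortcut, ms = ms)
  structure(list(blk = blk, params = params,
                 buffers = new.env(parent = emptyenv()),
                 in_channels = as.integer(in_channels)),
            class = "msmodule_layer")
}

#' Forward pass through a standalone MSModule (or C2f) stage
#' @param layer an object from [new_msmodule_layer()].
#' @param x feature map array `(C, H, W)`.
#' @return feature map `(out_channels, H, W)`.
#' @export
msmodule_forward <- function(layer, x) {
  stopifnot(inherits(layer, "msmodule_layer"))
  std_layer_forward(layer, x)
}

#' Count the learnable scalars of a standalone layer
#' @param layer any standalone layer object with a `params` environment.
#' @return integer parameter count.
#' @export
layer_parameter_count <- function(layer) {
  sum(vapply(ls(layer$params), function(p) length(layer$params[[p]]), 0))
}
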