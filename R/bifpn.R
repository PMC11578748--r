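# Bidirectional weighted feature-pyramid neck over levels P2-P5.
#
# Every backbone level enters through a 1x1 conv to a common neck width. One
# top-down sweep builds intermediate features (each node fuses the level's
# input with the upsampled level above), then one bottom-up sweep fuses the
# level input, the intermediate, and the downsampled level below. Fusion is
# "fast normalized": nonnegative learned scalars w_i, coefficients
# w_i / (sum w + beta). Heads read the three coarser fused levels; the extra
# fine P2 level participates in fusion only.

#' Nearest-neighbour / strided resampling between adjacent pyramid levels
#'
#' `up2` doubles both spatial dimensions by pixel replication (parameter
#' free). `down2` halves them through a stride-2 convolution cell, which
#' carries parameters: pass a layer built with [new_downsample_layer()].
#'
#' @param x feature map array `(C, H, W)`.
#' @param factor `"up2"` or `"down2"`.
#' @param layer for `down2`, the stride-2 conv layer to apply.
#' @return resampled feature map.
#' @export
resample <- function(x, factor = c("up2", "down2"), layer = NULL) {
  factor <- match.arg(factor)
  check_cmap(x)
  d <- dim(x)
  if (factor == "up2") {
    dim(x) <- c(d, 1L)
    y <- ag_upsample2(NULL, x)
    dim(y) <- dim(y)[1:3]
    return(y)
  }
  if (d[2L] %% 2L != 0L || d[3L] %% 2L != 0L) {
    stop("down2 requires even spatial dimensions", call. = FALSE)
  }
  if (is.null(layer)) {
    stop("down2 is a stride-2 convolution and needs `layer` (see new_downsample_layer())",
         call. = FALSE)
  }
  std_layer_forward(layer, x)
}

#' Build a stride-2 downsampling conv cell for [resample()]
#' @param channels channel count (preserved).
#' @return a layer object.
#' @export
new_downsample_layer <- function(channels) {
  params <- new.env(parent = emptyenv())
  blk <- new_conv_block(params, "down", as.integer(channels),
                        as.integer(channels), 3L, 2L)
  structure(list(blk = blk, params = params,
                 buffers = new.env(parent = emptyenv()),
                 in_channels = as.integer(channels)),
            class = "downsample_layer")
}

#' Fast normalized feature fusion
#'
#' `out = Conv( sum_i w_i x_i / (sum_i w_i + beta) )` with
#' `w_i = max(raw_weights_i, 0)`. The coefficient vector is nonnegative and
#' sums to strictly less than 1. With `conv = NULL` the convolution is the
#' identity (useful for inspecting the fusion itself).
#'
#' @param inputs list of same-shape feature maps `(C, H, W)`.
#' @param raw_weights numeric vector, one learnable scalar per input.
#' @param beta small positive stabilizer (default `1e-4`).
#' @param conv optional conv layer applied to the fused map.
#' @return fused feature map.
#' @export
normalized_fusion <- function(inputs, raw_weights, beta = 1e-4, conv = NULL) {
  if (length(inputs) < 1L) stop("fusion needs at least one input", call. = FALSE)
  if (length(raw_weights) != length(inputs)) {
    stop("one raw weight per input is required", call. = FALSE)
  }
  d1 <- dim(inputs[[1L]])
  for (x in inputs) {
    if (!identical(dim(x), d1)) {
      stop("all fusion inputs must have identical shapes", call. = FALSE)
    }
  }
  wc <- pmax(raw_weights, 0)
  coef <- wc / (sum(wc) + beta)
  y <- coef[1L] * inputs[[1L]]
  if (length(inputs) > 1L) {
    for (i in 2L:length(inputs)) y <- y + coef[i] * inputs[[i]]
  }
  if (!is.null(conv)) y <- std_layer_forward(conv, y)
  y
}

#' Build a standalone BiFPN-P2 neck
#'
#' @param in_channels length-4 integer vector: channels of the P2-P5 inputs.
#' @param width common neck width (channels after the lateral 1x1 convs).
#' @param beta fusion stabilizer.
#' @return a `bifpn_layer` object usable with [bifpn_pass()].
#' @export
new_bifpn_layer <- function(in_channels, width = 60L, beta = 1e-4) {
  stopifnot(length(in_channels) == 4L)
  params <- new.env(parent = emptyenv())
  blk <- new_bifpn_neck(params, "neck", as.integer(in_channels),
                        as.integer(width), beta)
  structure(list(blk = blk, params = params,
                 buffers = new.env(parent = emptyenv()),
                 in_channels = as.integer(in_channels),
                 width = as.integer(width)),
            class = "bifpn_layer")
}

#' One bidirectional pass over a four-level pyramid
#'
#' Top-down sweep producing intermediates, then bottom-up sweep producing the
#' fused outputs; each level keeps its spatial size, all levels leave at the
#' common neck width.
#'
#' @param layer a [new_bifpn_layer()].
#' @param pyramid named list of `(C, H, W)` arrays `p2, p3, p4, p5`, each
#'   level's spatial size exactly double the next.
#' @return named list of fused maps `p2, p3, p4, p5`.
#' @export
bifpn_pass <- function(layer, pyramid) {
  stopifnot(inherits(layer, "bifpn_layer"))
  need <- c("p2", "p3", "p4", "p5")
  if (!all(need %in% names(pyramid))) {
    stop("pyramid must have levels p2, p3, p4, p5", call. = FALSE)
  }
  for (i in 1:3) {
    da <- dim(pyramid[[need[i]]]); db <- dim(pyramid[[need[i + 1L]]])
    if (!(da[2L] == 2L * db[2L] && da[3L] == 2L * db[3L])) {
      stop("each pyramid level must be exactly half the spatial size of the level below",
           call. = FALSE)
    }
  }
  feats <- lapply(pyramid[need], function(x) {
    check_cmap(x); dim(x) <- c(dim(x), 1L); x
  })
  model <- list(params = layer$params, buffers = layer$buffers)
  out <- forward_bifpn(model, NULL, layer$blk, feats)
  lapply(out, function(y) { dim(y) <- dim(y)[1:3]; y })
}

#' Fused maps routed to the detection heads
#'
#' Runs [bifpn_pass()] and returns the three coarser fused levels (strides
#' 8/16/32 relative to the network input); the fine P2 level participates in
#' fusion only.
#'
#' @inheritParams bifpn_pass
#' @return list of three feature maps `p3, p4, p5`.
#' @export
build_neck_outputs <- function(layer, pyramid) {
  out <- bifpn_pass(layer, pyramid)
  out[c("p3", "p4", "p5")]
}

# ---- neck constructors -------------------------------------------------------

new_bifpn_neck <- function(params, path, in_ch, width, beta = 1e-4) {
  p <- function(s) paste0(path, ".", s)
  wpar <- function(name, n) {
    params[[p(name)]] <- rep(1, n)
    p(name)
  }
  list(
    type = "bifpn", path = path, width = as.integer(width), beta = beta,
    lat = lapply(1:4, function(i) {
      new_conv_block(params, p(paste0("lat", i + 1L)), in_ch[i], width, 1L)
    }),
    conv_p4td = new_conv_block(params, p("conv_p4td"), width, width, 3L),
    conv_p3td = new_conv_block(params, p("conv_p3td"), width, width, 3L),
    conv_p2out = new_conv_block(params, p("conv_p2out"), width, width, 3L),
    conv_p3out = new_conv_block(params, p("conv_p3out"), width, width, 3L),
    conv_p4out = new_conv_block(params, p("conv_p4out"), width, width, 3L),
    conv_p5out = new_conv_block(params, p("conv_p5out"), width, width, 3L),
    down_p2 = new_conv_block(params, p("down_p2"), width, width, 3L, 2L),
    down_p3 = new_conv_block(params, p("down_p3"), width, width, 3L, 2L),
    down_p4 = new_conv_block(params, p("down_p4"), width, width, 3L, 2L),
    w_p4td = wpar("w_p4td", 2L), w_p3td = wpar("w_p3td", 2L),
    w_p2out = wpar("w_p2out", 2L), w_p3out = wpar("w_p3out", 3L),
    w_p4out = wpar("w_p4out", 3L), w_p5out = wpar("w_p5out", 2L)
  )
}

fuse_node <- function(model, g, blk, wpath, xs, conv) {
  w <- ag_param(g, model$params, wpath)
  blk_forward(model, g, conv, ag_wfuse(g, xs, w, blk$beta))
}

# feats: list(p2, p3, p4, p5) backbone maps. Returns list(p2, p3, p4, p5)
# fused maps at neck width.
forward_bifpn <- function(model, g, blk, feats) {
  lat <- lapply(1:4, function(i) blk_forward(model, g, blk$lat[[i]], feats[[i]]))
  p2 <- lat[[1L]]; p3 <- lat[[2L]]; p4 <- lat[[3L]]; p5 <- lat[[4L]]
  p4td <- fuse_node(model, g, blk, blk$w_p4td,
                    list(p4, ag_upsample2(g, p5)), blk$conv_p4td)
  p3td <- fuse_node(model, g, blk, blk$w_p3td,
                    list(p3, ag_upsample2(g, p4td)), blk$conv_p3td)
  p2out <- fuse_node(model, g, blk, blk$w_p2out,
                     list(p2, ag_upsample2(g, p3td)), blk$conv_p2out)
  p3out <- fuse_node(model, g, blk, blk$w_p3out,
                     list(p3, p3td, blk_forward(model, g, blk$down_p2, p2out)),
                     blk$conv_p3out)
  p4out <- fuse_node(model, g, blk, blk$w_p4out,
                     list(p4, p4td, blk_forward(model, g, blk$down_p3, p3out)),
                     blk$conv_p4out)
  p5out <- fuse_node(model, g, blk, blk$w_p5out,
                     list(p5, blk_forward(model, g, blk$down_p4, p4out)),
                     blk$conv_p5out)
  list(p2 = p2out, p3 = p3out, p4 = p4out, p5 = p5out)
}

# Baseline path-aggregation neck (top-down + bottom-up with concatenation),
# operating on P3/P4/P5 at the backbone stage widths. `ms` swaps the C2f
# bottlenecks for MSBottlenecks.
new_pan_neck <- function(params, path, ch, ms = FALSE) {
  p <- function(s) paste0(path, ".", s)
  c3 <- ch[1L]; c4 <- ch[2L]; c5 <- ch[3L]
  list(
    type = "pan", path = path, ch = ch,
    td1 = new_c2f(params, p("td1"), c5 + c4, c4, 1L, shortcut = FALSE, ms = ms),
    td2 = new_c2f(params, p("td2"), c4 + c3, c3, 1L, shortcut = FALSE, ms = ms),
    down1 = new_conv_block(params, p("down1"), c3, c3, 3L, 2L),
    bu1 = new_c2f(params, p("bu1"), c3 + c4, c4, 1L, shortcut = FALSE, ms = ms),
    down2 = new_conv_block(params, p("down2"), c4, c4, 3L, 2L),
    bu2 = new_c2f(params, p("bu2"), c4 + c5, c5, 1L, shortcut = FALSE, ms = ms)
  )
}

forward_pan <- function(model, g, blk, feats) {
  p3 <- feats$p3; p4 <- feats$p4; p5 <- feats$p5
  td1 <- blk_forward(model, g, blk$td1, ag_cat(g, list(ag_upsample2(g, p5), p4)))
  td2 <- blk_forward(model, g, blk$td2, ag_cat(g, list(ag_upsample2(g, td1), p3)))
  d1 <- blk_forward(model, g, blk$down1, td2)
  bu1 <- blk_forward(model, g, blk$bu1, ag_cat(g, list(d1, td1)))
  d2 <- blk_forward(model, g, blk$down2, bu1)
  bu2 <- blk_forward(model, g, blk$bu2, ag_cat(g, list(d2, p5)))
  list(p3 = td2, p4 = bu1, p5 = bu2)
}
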