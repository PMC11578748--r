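# Detector assembly: baseline nano one-stage detector and the ablation
# variants that swap in the MSModule backbone blocks, the BiFPN-P2 neck, and
# the MPDIoU box loss. Parameter counts of the assembled variants reproduce
# the printed ablation table after rounding to 0.1 M, which is the fidelity
# oracle for the topology constants used here.

#' Variant configuration for detector assembly
#'
#' The three modifications are independent switches, reproducing the ablation
#' grid: baseline (`model0`), each single modification (`model1`-`model3`),
#' pairs (`model4`-`model6`), and the full model (all three on).
#'
#' @param use_msmodule replace C2f bottlenecks with MSBottleneck.
#' @param use_bifpn_p2 replace the path-aggregation neck with the BiFPN-P2
#'   neck.
#' @param box_loss `"ciou"` (baseline) or `"mpdiou"`.
#' @param num_classes number of object classes (default 2: seedling, weed).
#' @param width_mult multiplier on the nano stage widths 16/32/64/128/256
#'   (values that keep all widths multiples of 4).
#' @param msmodule_stages which C2f positions MSModule replaces when
#'   `use_msmodule` is on: `"all"` (backbone + baseline neck, the default),
#'   `"backbone"`, or `"p4"` (only the stage producing the P4 map).
#' @param neck_width common channel width inside the BiFPN neck. The default
#'   60 is pinned by the printed parameter sizes of the neck-modified
#'   variants.
#' @param reg_max number of bins of the discretized box-side distribution in
#'   the head (baseline convention 16).
#' @return a `variant_config` list.
#' @export
variant_config <- function(use_msmodule = FALSE, use_bifpn_p2 = FALSE,
                           box_loss = c("ciou", "mpdiou"), num_classes = 2L,
                           width_mult = 1, msmodule_stages = c("all", "backbone", "p4"),
                           neck_width = 60L, reg_max = 16L) {
  box_loss <- match.arg(box_loss)
  msmodule_stages <- match.arg(msmodule_stages)
  if (num_classes < 1L) stop("num_classes must be >= 1", call. = FALSE)
  widths <- as.integer(round(c(16L, 32L, 64L, 128L, 256L) * width_mult))
  if (isTRUE(use_msmodule) && any(widths[-1L] %% 4L != 0L)) {
    stop("width_mult must keep stage widths multiples of 4 when MSModule is on",
         call. = FALSE)
  }
  if (any(widths[-1L] %% 2L != 0L)) {
    stop("width_mult must keep stage widths even", call. = FALSE)
  }
  neck_width <- as.integer(round(neck_width * width_mult))
  structure(list(
    use_msmodule = isTRUE(use_msmodule),
    use_bifpn_p2 = isTRUE(use_bifpn_p2),
    box_loss = box_loss,
    num_classes = as.integer(num_classes),
    width_mult = width_mult,
    widths = widths,
    depths = c(1L, 2L, 2L, 1L),
    msmodule_stages = msmodule_stages,
    neck_width = neck_width,
    reg_max = as.integer(reg_max),
    class_names = if (num_classes == 2L) c("Seedling", "Weed")
                  else paste0("class", seq_len(num_classes) - 1L)
  ), class = "variant_config")
}

#' Named ablation variants
#'
#' `model0` = baseline; `model1` = +MSModule; `model2` = +BiFPN-P2;
#' `model3` = +MPDIoU; `model4` = MSModule+BiFPN; `model5` = MSModule+MPDIoU;
#' `model6` = BiFPN+MPDIoU; `ms` = all three.
#'
#' @param name variant name.
#' @param ... passed through to [variant_config()].
#' @return a `variant_config`.
#' @export
named_variant <- function(name = c("model0", "model1", "model2", "model3",
                                   "model4", "model5", "model6", "ms"), ...) {
  name <- match.arg(name)
  flags <- list(
    model0 = c(FALSE, FALSE, FALSE), model1 = c(TRUE, FALSE, FALSE),
    model2 = c(FALSE, TRUE, FALSE),  model3 = c(FALSE, FALSE, TRUE),
    model4 = c(TRUE, TRUE, FALSE),   model5 = c(TRUE, FALSE, TRUE),
    model6 = c(FALSE, TRUE, TRUE),   ms = c(TRUE, TRUE, TRUE)
  )[[name]]
  variant_config(use_msmodule = flags[1L], use_bifpn_p2 = flags[2L],
                 box_loss = if (flags[3L]) "mpdiou" else "ciou", ...)
}

detect_head_widths <- function(ch, nc, reg_max) {
  # both branch widths carry a floor of 16 so very small width multipliers
  # keep a usable head; at nano scale the floors are inactive
  c2 <- max(16L, ch[1L] %/% 4L, 4L * reg_max)
  c3 <- max(16L, ch[1L], min(nc, 100L))
  list(c2 = as.integer(c2), c3 = as.integer(c3))
}

new_detect_head <- function(params, path, ch, nc, reg_max) {
  hw <- detect_head_widths(ch, nc, reg_max)
  levels <- lapply(seq_along(ch), function(i) {
    p <- function(s) paste0(path, ".l", i, ".", s)
    list(
      box1 = new_conv_block(params, p("box1"), ch[i], hw$c2, 3L),
      box2 = new_conv_block(params, p("box2"), hw$c2, hw$c2, 3L),
      box3 = new_plain_conv(params, p("box3"), hw$c2, 4L * reg_max, 1L),
      cls1 = new_conv_block(params, p("cls1"), ch[i], hw$c3, 3L),
      cls2 = new_conv_block(params, p("cls2"), hw$c3, hw$c3, 3L),
      cls3 = new_plain_conv(params, p("cls3"), hw$c3, nc, 1L)
    )
  })
  list(type = "detect", path = path, ch = ch, nc = as.integer(nc),
       reg_max = as.integer(reg_max), levels = levels)
}

# Stable-training bias priors for the head's final 1x1 convs (baseline
# detector convention): box bias 1, class bias log-odds of a sparse prior.
init_head_biases <- function(params, head, strides, img_size = 160) {
  for (i in seq_along(head$levels)) {
    lv <- head$levels[[i]]
    params[[paste0(lv$box3$path, ".b")]] <- rep(1, 4L * head$reg_max)
    prior <- log(5 / head$nc / (img_size / strides[i])^2)
    params[[paste0(lv$cls3$path, ".b")]] <- rep(prior, head$nc)
  }
  invisible(NULL)
}

#' Assemble a detector variant
#'
#' Builds the full convolutional detector described by `cfg`: a stem plus
#' four conv/C2f stages and spatial-pyramid pooling in the backbone, either
#' the baseline path-aggregation neck or the BiFPN-P2 neck, and three
#' decoupled anchor-free heads (box-distribution + class branches) on strides
#' 8/16/32. Parameters are randomly initialized from the current RNG state.
#'
#' @param cfg a [variant_config()].
#' @return a `seedling_detector` object.
#' @export
assemble <- function(cfg) {
  stopifnot(inherits(cfg, "variant_config"))
  params <- new.env(parent = emptyenv())
  buffers <- new.env(parent = emptyenv())
  w <- cfg$widths; dp <- cfg$depths
  ms_on <- function(stage) {
    if (!cfg$use_msmodule) return(FALSE)
    switch(cfg$msmodule_stages,
           all = TRUE, backbone = stage != "neck", p4 = stage == "s3")
  }
  backbone <- list(
    stem = new_conv_block(params, "bb.stem", 3L, w[1L], 3L, 2L),
    d1 = new_conv_block(params, "bb.d1", w[1L], w[2L], 3L, 2L),
    s1 = new_c2f(params, "bb.s1", w[2L], w[2L], dp[1L], TRUE, ms_on("s1")),
    d2 = new_conv_block(params, "bb.d2", w[2L], w[3L], 3L, 2L),
    s2 = new_c2f(params, "bb.s2", w[3L], w[3L], dp[2L], TRUE, ms_on("s2")),
    d3 = new_conv_block(params, "bb.d3", w[3L], w[4L], 3L, 2L),
    s3 = new_c2f(params, "bb.s3", w[4L], w[4L], dp[3L], TRUE, ms_on("s3")),
    d4 = new_conv_block(params, "bb.d4", w[4L], w[5L], 3L, 2L),
    s4 = new_c2f(params, "bb.s4", w[5L], w[5L], dp[4L], TRUE, ms_on("s4")),
    sppf = new_sppf(params, "bb.sppf", w[5L], w[5L], 5L)
  )
  if (cfg$use_bifpn_p2) {
    neck <- new_bifpn_neck(params, "neck", c(w[2L], w[3L], w[4L], w[5L]),
                           cfg$neck_width)
    head_ch <- rep(cfg$neck_width, 3L)
  } else {
    neck <- new_pan_neck(params, "neck", c(w[3L], w[4L], w[5L]),
                         ms = ms_on("neck"))
    head_ch <- c(w[3L], w[4L], w[5L])
  }
  head <- new_detect_head(params, "head", head_ch, cfg$num_classes, cfg$reg_max)
  strides <- c(8, 16, 32)
  init_head_biases(params, head, strides)
  structure(list(cfg = cfg, params = params, buffers = buffers,
                 backbone = backbone, neck = neck, head = head,
                 strides = strides),
            class = "seedling_detector")
}

#' Count the learnable scalars of an assembled detector
#'
#' Exact count over every weight matrix, normalization affine pair, bias and
#' fusion scalar; batch-norm running statistics and the fixed
#' distribution-expectation bins are buffers, not parameters, and are
#' excluded. The count is independent of input resolution (the model is fully
#' convolutional).
#'
#' @param m a `seedling_detector`.
#' @return integer parameter count. Use [params_table()] for the 0.1 M
#'   rounded report across all ablation variants.
#' @export
count_parameters <- function(m) {
  stopifnot(inherits(m, "seedling_detector"))
  sum(vapply(ls(m$params), function(p) length(m$params[[p]]), 0))
}

# ---- forward -----------------------------------------------------------------

forward_backbone <- function(model, g, x) {
  bb <- model$backbone
  x <- blk_forward(model, g, bb$stem, x)
  x <- blk_forward(model, g, bb$d1, x)
  p2 <- blk_forward(model, g, bb$s1, x)
  x <- blk_forward(model, g, bb$d2, p2)
  p3 <- blk_forward(model, g, bb$s2, x)
  x <- blk_forward(model, g, bb$d3, p3)
  p4 <- blk_forward(model, g, bb$s3, x)
  x <- blk_forward(model, g, bb$d4, p4)
  x <- blk_forward(model, g, bb$s4, x)
  p5 <- blk_forward(model, g, bb$sppf, x)
  list(p2 = p2, p3 = p3, p4 = p4, p5 = p5)
}

forward_neck <- function(model, g, feats) {
  if (model$neck$type == "bifpn") {
    out <- forward_bifpn(model, g, model$neck, feats)
    list(p3 = out$p3, p4 = out$p4, p5 = out$p5)
  } else {
    forward_pan(model, g, model$neck, feats)
  }
}

forward_head <- function(model, g, feats3) {
  head <- model$head
  lapply(seq_along(feats3), function(i) {
    lv <- head$levels[[i]]
    x <- feats3[[i]]
    box <- blk_forward(model, g, lv$box3,
                       blk_forward(model, g, lv$box2,
                                   blk_forward(model, g, lv$box1, x)))
    cls <- blk_forward(model, g, lv$cls3,
                       blk_forward(model, g, lv$cls2,
                                   blk_forward(model, g, lv$cls1, x)))
    list(box = box, cls = cls)
  })
}

# x: (3, H, W, N) array in [0, 1]; returns per-level list(box, cls) raw maps
forward_raw <- function(model, x, g = NULL) {
  d <- dim(x)
  if (length(d) != 4L || d[1L] != 3L) {
    stop("input must be a (3, H, W, N) array", call. = FALSE)
  }
  if (d[2L] %% 32L != 0L || d[3L] %% 32L != 0L) {
    stop("input spatial size must be a multiple of 32 (letterbox first)",
         call. = FALSE)
  }
  xin <- ag_input(g, x)
  feats <- forward_backbone(model, g, xin)
  fused <- forward_neck(model, g, feats)
  forward_head(model, g, list(fused$p3, fused$p4, fused$p5))
}

# Decode one level's raw maps into boxes/scores. box map: (4*reg_max, H, W, N)
# sides ordered (left, top, right, bottom), each a reg_max-bin distribution;
# decoded side = softmax expectation in stride units from the cell center.
decode_level <- function(box_map, cls_map, stride, reg_max) {
  d <- dim(box_map)
  H <- d[2L]; W <- d[3L]
  nc <- dim(cls_map)[1L]
  bm <- matrix(box_map[, , , 1L], nrow = 4L * reg_max)
  bins <- seq_len(reg_max) - 1
  sides <- matrix(0, 4L, ncol(bm))
  for (s in 1:4) {
    z <- bm[(s - 1L) * reg_max + seq_len(reg_max), , drop = FALSE]
    z <- exp(sweep(z, 2L, apply(z, 2L, max)))
    p <- sweep(z, 2L, colSums(z), "/")
    sides[s, ] <- colSums(p * bins)
  }
  hh <- rep(seq_len(H) - 0.5, times = W)  # cell centers, column-major (h fastest)
  ww <- rep(seq_len(W) - 0.5, each = H)
  cx <- ww * stride; cy <- hh * stride
  boxes <- cbind(x1 = cx - sides[1L, ] * stride, y1 = cy - sides[2L, ] * stride,
                 x2 = cx + sides[3L, ] * stride, y2 = cy + sides[4L, ] * stride)
  scores <- 1 / (1 + exp(-matrix(cls_map[, , , 1L], nrow = nc)))
  list(boxes = boxes, scores = scores)
}

#' Greedy class-wise non-maximum suppression
#'
#' @param boxes n x 4 corner-form matrix.
#' @param scores numeric vector of confidences.
#' @param classes integer class ids.
#' @param iou_thr suppression IoU threshold.
#' @return integer indices of the surviving detections.
#' @export
nms <- function(boxes, scores, classes, iou_thr = 0.45) {
  keep <- integer(0)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    idx <- idx[order(scores[idx], decreasing = TRUE)]
    while (length(idx) > 0L) {
      i <- idx[1L]
      keep <- c(keep, i)
      idx <- idx[-1L]
      if (length(idx) > 0L) {
        ious <- box_iou(boxes[rep(i, length(idx)), , drop = FALSE],
                        boxes[idx, , drop = FALSE])
        idx <- idx[ious <= iou_thr]
      }
    }
  }
  sort(keep)
}

#' Letterbox an image to a target size
#'
#' Aspect-preserving bilinear resize followed by symmetric gray padding, the
#' preprocessing convention of the detector family.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`.
#' @param size target side length (multiple of 32) or `c(h, w)`.
#' @param fill pad value (default gray 114/255).
#' @return list with the letterboxed `img`, `scale`, and `pad = c(top, left)`.
#' @export
letterbox <- function(img, size = 160L, fill = 114 / 255) {
  d <- dim(img)
  if (length(size) == 1L) size <- c(size, size)
  scale <- min(size[1L] / d[1L], size[2L] / d[2L])
  nh <- round(d[1L] * scale); nw <- round(d[2L] * scale)
  resized <- resize_bilinear(img, nh, nw)
  out <- array(fill, c(size[1L], size[2L], 3L))
  top <- (size[1L] - nh) %/% 2L; left <- (size[2L] - nw) %/% 2L
  out[top + seq_len(nh), left + seq_len(nw), ] <- resized
  list(img = out, scale = scale, pad = c(top = top, left = left))
}

resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (out_h == d[1L] && out_w == d[2L]) return(img)
  ys <- (seq_len(out_h) - 0.5) * d[1L] / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * d[2L] / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), d[1L] - 1); y1 <- pmin(y0 + 1, d[1L] - 1)
  x0 <- pmin(pmax(floor(xs), 0), d[2L] - 1); x1 <- pmin(x0 + 1, d[2L] - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, d[3L]))
  for (ch in seq_len(d[3L])) {
    m <- img[, , ch]
    a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
    cc <- m[y1 + 1, x0 + 1, drop = FALSE]; dd <- m[y1 + 1, x1 + 1, drop = FALSE]
    top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
    bot <- cc * outer(rep(1, out_h), 1 - wx) + dd * outer(rep(1, out_h), wx)
    out[, , ch] <- top * (1 - wy) + bot * wy
  }
  out
}

#' Run detection on a single image
#'
#' Letterboxes the image to `img_size`, runs the detector, decodes the
#' box-distribution outputs at all three scales, applies the confidence
#' filter and class-wise greedy NMS, and maps boxes back to original image
#' coordinates.
#'
#' @param model a `seedling_detector`.
#' @param image `(H, W, 3)` array in `[0, 1]`, or a path to a PNG file.
#' @param conf_thr confidence threshold (default 0.25).
#' @param iou_thr NMS IoU threshold (default 0.45).
#' @param img_size network input side (multiple of 32).
#' @return tibble with columns `x1, y1, x2, y2, score, class_id, class`.
#' @export
forward_detect <- function(model, image, conf_thr = 0.25, iou_thr = 0.45,
                           img_size = 160L) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    stop("image must be an (H, W, 3) array in [0, 1]", call. = FALSE)
  }
  image <- image[, , 1:3, drop = FALSE]
  lb <- letterbox(image, img_size)
  x <- aperm(lb$img, c(3L, 1L, 2L))
  dim(x) <- c(dim(x), 1L)
  raw <- forward_raw(model, x)
  nc <- model$cfg$num_classes
  all_boxes <- NULL; all_scores <- NULL; all_classes <- NULL
  for (i in seq_along(raw)) {
    dec <- decode_level(vof(raw[[i]]$box), vof(raw[[i]]$cls),
                        model$strides[i], model$cfg$reg_max)
    best <- apply(dec$scores, 2L, which.max)
    sc <- dec$scores[cbind(best, seq_len(ncol(dec$scores)))]
    keep <- which(sc >= conf_thr)
    if (length(keep)) {
      all_boxes <- rbind(all_boxes, dec$boxes[keep, , drop = FALSE])
      all_scores <- c(all_scores, sc[keep])
      all_classes <- c(all_classes, best[keep] - 1L)
    }
  }
  if (is.null(all_boxes) || nrow(all_boxes) == 0L) {
    return(tibble::tibble(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                          y2 = numeric(), score = numeric(),
                          class_id = integer(), class = character()))
  }
  # clamp to the padded canvas, then undo the letterbox
  canvas <- c(img_size, img_size)
  all_boxes[, c(1L, 3L)] <- pmin(pmax(all_boxes[, c(1L, 3L)], 0), canvas[2L])
  all_boxes[, c(2L, 4L)] <- pmin(pmax(all_boxes[, c(2L, 4L)], 0), canvas[1L])
  keep <- nms(all_boxes, all_scores, all_classes, iou_thr)
  b <- all_boxes[keep, , drop = FALSE]
  b[, c(1L, 3L)] <- (b[, c(1L, 3L)] - lb$pad["left"]) / lb$scale
  b[, c(2L, 4L)] <- (b[, c(2L, 4L)] - lb$pad["top"]) / lb$scale
  d <- dim(image)
  b[, c(1L, 3L)] <- pmin(pmax(b[, c(1L, 3L)], 0), d[2L])
  b[, c(2L, 4L)] <- pmin(pmax(b[, c(2L, 4L)], 0), d[1L])
  cid <- all_classes[keep]
  tibble::tibble(x1 = b[, 1L], y1 = b[, 2L], x2 = b[, 3L], y2 = b[, 4L],
                 score = all_scores[keep], class_id = as.integer(cid),
                 class = model$cfg$class_names[cid + 1L])
}

# ---- checkpointing -----------------------------------------------------------

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "class_names")]), collapse = "")
  # polynomial rolling hash over the deparsed config (stays in double range)
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Save / load a detector checkpoint
#'
#' A checkpoint is one serialized file holding the variant config, all
#' parameters and normalization buffers, and a config hash that the loader
#' validates before injecting weights into a freshly assembled model.
#'
#' @param model a `seedling_detector`.
#' @param path file path.
#' @return `load_checkpoint()` returns the restored `seedling_detector`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seedling_detector"))
  state <- list(
    cfg = model$cfg,
    hash = config_hash(model$cfg),
    params = as.list(model$params),
    buffers = as.list(model$buffers)
  )
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!identical(state$hash, config_hash(state$cfg))) {
    stop("checkpoint config hash mismatch; file corrupted or incompatible",
         call. = FALSE)
  }
  model <- assemble(state$cfg)
  for (p in names(state$params)) model$params[[p]] <- state$params[[p]]
  for (b in names(state$buffers)) model$buffers[[b]] <- state$buffers[[b]]
  model
}

#' @export
print.seedling_detector <- function(x, ...) {
  n <- count_parameters(x)
  cat(sprintf(
    "<seedling_detector> %s neck, %s backbone blocks, %s box loss, %d classes\n",
    if (x$cfg$use_bifpn_p2) "BiFPN-P2" else "PAN",
    if (x$cfg$use_msmodule) "MSModule" else "C2f",
    x$cfg$box_loss, x$cfg$num_classes))
  cat(sprintf("  parameters: %d (%.1f M)\n", n, round(n / 1e6, 1)))
  invisible(x)
}
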