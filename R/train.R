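# Desk-scale training: task-aligned one-to-one assignment, the detector
# family's composite loss (class BCE + distribution-focal box regression +
# an IoU-family geometric term, CIoU or MPDIoU per variant), and SGD with
# momentum, warmup, and linear decay. Gradients flow through the hand-built
# tape; the geometric box term is differentiated centrally (it is cheap
# scalar arithmetic per assigned anchor) and chained through the
# distribution-expectation decode analytically.

# unvalidated vectorized IoU for hot paths (inputs are known-valid matrices)
iou_fast <- function(a, b) {
  iw <- pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L])
  ih <- pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L]) +
           (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L]) - inter
  ifelse(union > 0, inter / union, 0)
}

mpdiou_loss_fast <- function(p, g, img_size) {
  diag2 <- 2 * img_size^2
  1 - (iou_fast(p, g) -
       ((p[, 1L] - g[, 1L])^2 + (p[, 2L] - g[, 2L])^2) / diag2 -
       ((p[, 3L] - g[, 3L])^2 + (p[, 4L] - g[, 4L])^2) / diag2)
}

ciou_loss_fast <- function(p, g, eps = 1e-9) {
  iou <- iou_fast(p, g)
  rho2 <- ((p[, 1L] + p[, 3L]) / 2 - (g[, 1L] + g[, 3L]) / 2)^2 +
          ((p[, 2L] + p[, 4L]) / 2 - (g[, 2L] + g[, 4L]) / 2)^2
  cw <- pmax(p[, 3L], g[, 3L]) - pmin(p[, 1L], g[, 1L])
  ch <- pmax(p[, 4L], g[, 4L]) - pmin(p[, 2L], g[, 2L])
  v <- (4 / pi^2) * (atan((g[, 3L] - g[, 1L]) / pmax(g[, 4L] - g[, 2L], eps)) -
                     atan((p[, 3L] - p[, 1L]) / pmax(p[, 4L] - p[, 2L], eps)))^2
  alpha <- v / ((1 - iou) + v + eps)
  1 - iou + rho2 / (cw^2 + ch^2 + eps) + alpha * v
}

# anchor grid across the three head levels: centers in input pixels
anchor_grid <- function(img_size, strides) {
  rows <- list()
  for (s in strides) {
    n <- img_size %/% s
    hh <- rep(seq_len(n) - 0.5, times = n)  # h fastest, matching map layout
    ww <- rep(seq_len(n) - 0.5, each = n)
    rows[[length(rows) + 1L]] <- cbind(cx = ww * s, cy = hh * s, stride = s)
  }
  do.call(rbind, rows)
}

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2L, apply(z, 2L, max)))
  sweep(z, 2L, colSums(z), "/")
}

# decode per-image flattened head outputs
# box_z: (4R, A) logits; returns sides (4, A) expectations and probs list
decode_sides <- function(box_z, reg_max) {
  bins <- seq_len(reg_max) - 1
  probs <- vector("list", 4L)
  sides <- matrix(0, 4L, ncol(box_z))
  for (s in 1:4) {
    p <- softmax_cols(box_z[(s - 1L) * reg_max + seq_len(reg_max), , drop = FALSE])
    probs[[s]] <- p
    sides[s, ] <- colSums(p * bins)
  }
  list(sides = sides, probs = probs)
}

# Task-aligned assignment for one image.
# cls_p: (nc, A) probabilities; pred_boxes: (A, 4); gt: tibble x1..y2, class_id
tal_assign <- function(cls_p, pred_boxes, anchors, gt,
                       topk = 10L, alpha = 0.5, beta = 6) {
  A <- nrow(anchors); G <- nrow(gt)
  assign_gt <- rep(NA_integer_, A)
  t_score <- numeric(A)
  if (G == 0L) return(list(gt = assign_gt, score = t_score))
  gtb <- cbind(gt$x1, gt$y1, gt$x2, gt$y2)
  align <- matrix(0, G, A); iou_m <- matrix(0, G, A)
  inside <- matrix(FALSE, G, A)
  for (g in seq_len(G)) {
    inside[g, ] <- anchors[, "cx"] > gtb[g, 1L] & anchors[, "cx"] < gtb[g, 3L] &
                   anchors[, "cy"] > gtb[g, 2L] & anchors[, "cy"] < gtb[g, 4L]
    cand <- which(inside[g, ])
    if (length(cand) == 0L) next
    iou_m[g, cand] <- iou_fast(pred_boxes[cand, , drop = FALSE],
                               gtb[rep(g, length(cand)), , drop = FALSE])
    align[g, cand] <- cls_p[gt$class_id[g] + 1L, cand]^alpha * iou_m[g, cand]^beta
  }
  mask <- matrix(FALSE, G, A)
  for (g in seq_len(G)) {
    cand <- which(inside[g, ] & align[g, ] > 0)
    if (length(cand) == 0L) {
      # degenerate early-training case: keep the best-IoU inside anchor
      cand <- which(inside[g, ])
      if (length(cand) == 0L) next
      best <- cand[which.max(iou_m[g, cand])]
      mask[g, best] <- TRUE
      next
    }
    k <- min(topk, length(cand))
    sel <- cand[order(align[g, cand], decreasing = TRUE)[seq_len(k)]]
    mask[g, sel] <- TRUE
  }
  # resolve anchors claimed by several gts: keep the highest-IoU gt
  for (a in which(colSums(mask) > 1L)) {
    gs <- which(mask[, a])
    keep <- gs[which.max(iou_m[gs, a])]
    mask[, a] <- FALSE; mask[keep, a] <- TRUE
  }
  for (g in seq_len(G)) {
    sel <- which(mask[g, ])
    if (length(sel) == 0L) next
    m_align <- max(align[g, sel]); m_iou <- max(iou_m[g, sel])
    sc <- if (m_align > 0) align[g, sel] / m_align * m_iou else rep(m_iou, length(sel))
    assign_gt[sel] <- g
    t_score[sel] <- sc
  }
  list(gt = assign_gt, score = t_score)
}

box_loss_value <- function(pred, gtb, box_loss, img_size) {
  if (box_loss == "mpdiou") mpdiou_loss_fast(pred, gtb, img_size)
  else ciou_loss_fast(pred, gtb)
}

# central finite differences of the geometric box loss w.r.t. the four
# predicted corners, vectorized over anchor rows (the loss itself is cheap
# closed-form arithmetic)
box_loss_grad <- function(pred, gtb, box_loss, img_size, eps = 1e-3) {
  g <- matrix(0, nrow(pred), 4L)
  for (i in 1:4) {
    hi <- pred; hi[, i] <- hi[, i] + eps
    lo <- pred; lo[, i] <- lo[, i] - eps
    # keep boxes valid under perturbation
    hi[, 1L] <- pmin(hi[, 1L], hi[, 3L]); hi[, 2L] <- pmin(hi[, 2L], hi[, 4L])
    lo[, 1L] <- pmin(lo[, 1L], lo[, 3L]); lo[, 2L] <- pmin(lo[, 2L], lo[, 4L])
    g[, i] <- (box_loss_value(hi, gtb, box_loss, img_size) -
               box_loss_value(lo, gtb, box_loss, img_size)) / (2 * eps)
  }
  g
}

# Compute the composite loss and seed head-output gradients for one batch.
# raw: per-level list(box, cls) tape nodes with (C, H, W, N) values.
# targets: list per image of tibbles (x1, y1, x2, y2, class_id) in input px.
# `assignments`: optional per-image list of precomputed target assignments
# (as returned in $assignments); assignment is a stop-gradient quantity, so
# freezing it makes the loss a smooth function of the head outputs.
detection_loss <- function(model, raw, targets, img_size,
                           w_box = 7.5, w_cls = 0.5, w_dfl = 1.5,
                           class_weights = NULL, seed_grads = TRUE,
                           assignments = NULL) {
  reg_max <- model$cfg$reg_max
  nc <- model$cfg$num_classes
  strides <- model$strides
  anchors <- anchor_grid(img_size, strides)
  A_lv <- (img_size %/% strides)^2
  off <- c(0L, cumsum(A_lv))
  N <- dim(vof(raw[[1L]]$box))[4L]
  A <- sum(A_lv)
  grads <- lapply(seq_along(raw), function(i) {
    list(box = array(0, dim(vof(raw[[i]]$box))),
         cls = array(0, dim(vof(raw[[i]]$cls))))
  })
  loss_box <- 0; loss_cls <- 0; loss_dfl <- 0
  asg_out <- vector("list", N)
  for (n in seq_len(N)) {
    box_z <- matrix(0, 4L * reg_max, A)
    cls_z <- matrix(0, nc, A)
    for (i in seq_along(raw)) {
      bv <- vof(raw[[i]]$box); cv <- vof(raw[[i]]$cls)
      box_z[, off[i] + seq_len(A_lv[i])] <- matrix(bv[, , , n], 4L * reg_max)
      cls_z[, off[i] + seq_len(A_lv[i])] <- matrix(cv[, , , n], nc)
    }
    dec <- decode_sides(box_z, reg_max)
    st <- anchors[, "stride"]
    pred_boxes <- cbind(anchors[, "cx"] - dec$sides[1L, ] * st,
                        anchors[, "cy"] - dec$sides[2L, ] * st,
                        anchors[, "cx"] + dec$sides[3L, ] * st,
                        anchors[, "cy"] + dec$sides[4L, ] * st)
    cls_p <- 1 / (1 + exp(-cls_z))
    gt <- targets[[n]]
    asg <- if (!is.null(assignments)) assignments[[n]]
           else tal_assign(cls_p, pred_boxes, anchors, gt)
    asg_out[[n]] <- asg
    tmat <- matrix(0, nc, A)
    pos <- which(!is.na(asg$gt))
    if (length(pos)) {
      tmat[cbind(gt$class_id[asg$gt[pos]] + 1L, pos)] <- asg$score[pos]
    }
    norm <- max(sum(asg$score), 1)
    # optional inverse-frequency weighting of the positive class targets
    # (rare-class remedy; the negative/background terms keep weight 1)
    wmat <- 1
    if (!is.null(class_weights)) {
      wmat <- 1 + (class_weights - 1) * (tmat > 0)
    }
    loss_cls <- loss_cls - sum(wmat * (tmat * log(pmax(cls_p, 1e-12)) +
                               (1 - tmat) * log(pmax(1 - cls_p, 1e-12)))) / norm
    dcls <- wmat * (cls_p - tmat) / norm
    dbox <- matrix(0, 4L * reg_max, A)
    if (length(pos)) {
      gtb_all <- cbind(gt$x1, gt$y1, gt$x2, gt$y2)
      npos <- length(pos)
      wgt <- asg$score[pos] / norm
      pred_pos <- pred_boxes[pos, , drop = FALSE]
      gtb_pos <- gtb_all[asg$gt[pos], , drop = FALSE]
      bl <- box_loss_value(pred_pos, gtb_pos, model$cfg$box_loss, img_size)
      loss_box <- loss_box + sum(wgt * bl)
      gb <- box_loss_grad(pred_pos, gtb_pos, model$cfg$box_loss, img_size)
      s <- st[pos]
      # chain corners -> side expectations (sides in stride units)
      dside <- cbind(-gb[, 1L], -gb[, 2L], gb[, 3L], gb[, 4L]) * s * wgt
      # dfl targets: gt sides in stride units from the anchor centers
      tside <- cbind(anchors[pos, "cx"] - gtb_pos[, 1L],
                     anchors[pos, "cy"] - gtb_pos[, 2L],
                     gtb_pos[, 3L] - anchors[pos, "cx"],
                     gtb_pos[, 4L] - anchors[pos, "cy"]) / s
      tside <- pmin(pmax(tside, 0), reg_max - 1 - 1e-3)
      fl <- floor(tside); wl <- fl + 1 - tside; wr <- tside - fl
      bins <- seq_len(reg_max) - 1
      cols <- seq_len(npos)
      for (sd in 1:4) {
        rows <- (sd - 1L) * reg_max + seq_len(reg_max)
        p <- dec$probs[[sd]][, pos, drop = FALSE]       # (R, npos)
        mu <- dec$sides[sd, pos]
        p_fl <- p[cbind(fl[, sd] + 1L, cols)]
        p_ce <- p[cbind(fl[, sd] + 2L, cols)]
        loss_dfl <- loss_dfl - sum(wgt * (wl[, sd] * log(pmax(p_fl, 1e-12)) +
                                          wr[, sd] * log(pmax(p_ce, 1e-12))))
        # geometric term through the distribution expectation
        dz_geom <- p * (bins - rep(mu, each = reg_max))
        dz_geom <- sweep(dz_geom, 2L, dside[, sd], "*")
        # distribution-focal cross entropy
        tdist <- matrix(0, reg_max, npos)
        tdist[cbind(fl[, sd] + 1L, cols)] <- wl[, sd]
        tdist[cbind(fl[, sd] + 2L, cols)] <- wr[, sd]
        dz_dfl <- sweep(p - tdist, 2L, wgt, "*")
        dbox[rows, pos] <- dbox[rows, pos, drop = FALSE] +
          w_box * dz_geom + w_dfl * dz_dfl
      }
    }
    if (seed_grads) {
      for (i in seq_along(raw)) {
        idx <- off[i] + seq_len(A_lv[i])
        db <- dbox[, idx, drop = FALSE]
        dc <- w_cls * dcls[, idx, drop = FALSE]
        d <- dim(grads[[i]]$box)
        grads[[i]]$box[, , , n] <- array(db, d[1:3])
        d <- dim(grads[[i]]$cls)
        grads[[i]]$cls[, , , n] <- array(dc, d[1:3])
      }
    }
  }
  list(loss = c(box = w_box * loss_box / N, cls = w_cls * loss_cls / N,
                dfl = w_dfl * loss_dfl / N),
       grads = grads, n = N, assignments = asg_out)
}

#' Train a detector on labeled images
#'
#' Desk-scale training loop: task-aligned assignment, composite loss (class
#' BCE + distribution-focal + the variant's geometric box term), SGD with
#' momentum 0.937, 3-epoch warmup and linear learning-rate decay. All images
#' must share the square size `img_size`. Deterministic for a fixed `seed`
#' (single-threaded; all randomness flows through one seeded generator).
#'
#' @param model a `seedling_detector` (modified in place and returned).
#' @param images list of `(H, W, 3)` arrays in `[0, 1]`.
#' @param labels list of tibbles `class_id, cx, cy, w, h` (normalized YOLO
#'   records) aligned with `images`.
#' @param epochs,batch_size,img_size training profile (desk-scale defaults
#'   30 / 8 / 160; the field-faithful profile of the emulated study is
#'   batch 32, image size 1280, 300 epochs).
#' @param lr0,lrf,momentum,weight_decay optimizer settings.
#' @param schedule learning-rate decay shape after the 3-epoch warmup.
#' @param class_weights optional per-class weights (indexed by `class_id + 1`)
#'   applied to the positive class-BCE terms; the standard inverse-frequency
#'   remedy when one class is much rarer than another.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch losses.
#' @return a `seedling_fit` list: `model`, `history` (tibble with per-epoch
#'   box/cls/dfl/total losses), `epochs`.
#' @export
train_detector <- function(model, images, labels, epochs = 30L,
                           batch_size = 8L, img_size = 160L,
                           lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                           weight_decay = 5e-4, seed = 1L, verbose = FALSE,
                           start_epoch = 1L, schedule = c("cosine", "linear"),
                           class_weights = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(model, "seedling_detector"))
  if (length(images) == 0L) stop("empty dataset", call. = FALSE)
  targets <- lapply(labels, function(lb) {
    tibble::tibble(
      x1 = (lb$cx - lb$w / 2) * img_size, y1 = (lb$cy - lb$h / 2) * img_size,
      x2 = (lb$cx + lb$w / 2) * img_size, y2 = (lb$cy + lb$h / 2) * img_size,
      class_id = lb$class_id)
  })
  vel <- new.env(parent = emptyenv())
  n_img <- length(images)
  steps_per_epoch <- ceiling(n_img / batch_size)
  warmup_steps <- 3L * steps_per_epoch
  history <- list()
  step <- 0L
  total_epochs <- start_epoch + epochs - 1L
  local_seed(seed, {
    for (epoch in start_epoch:total_epochs) {
      perm <- sample.int(n_img)
      ep_loss <- c(box = 0, cls = 0, dfl = 0)
      # warmup (below, per step) into a decay from lr0 to lr0 * lrf
      frac <- (epoch - 1) / max(total_epochs, 1)
      decay <- if (schedule == "cosine") 0.5 * (1 + cos(pi * frac)) else 1 - frac
      lr_epoch <- lr0 * (lrf + (1 - lrf) * decay)
      for (b in seq_len(steps_per_epoch)) {
        idx <- perm[((b - 1L) * batch_size + 1L):min(b * batch_size, n_img)]
        step <- step + 1L
        lr <- if (step <= warmup_steps) lr_epoch * step / warmup_steps else lr_epoch
        x <- array(0, c(3L, img_size, img_size, length(idx)))
        for (k in seq_along(idx)) {
          x[, , , k] <- aperm(images[[idx[k]]], c(3L, 1L, 2L))
        }
        g <- ag_graph(training = TRUE)
        raw <- forward_raw(model, x, g = g)
        dl <- detection_loss(model, raw, targets[idx], img_size,
                             class_weights = class_weights)
        for (i in seq_along(raw)) {
          raw[[i]]$box$grad <- dl$grads[[i]]$box
          raw[[i]]$cls$grad <- dl$grads[[i]]$cls
        }
        ag_backward(g)
        for (p in ls(g$pcache)) {
          node <- g$pcache[[p]]
          if (is.null(node$grad)) next
          grad <- node$grad / dl$n
          if (weight_decay > 0 && grepl("\\.w$", p)) {
            grad <- grad + weight_decay * model$params[[p]]
          }
          v <- vel[[p]]
          if (is.null(v)) v <- 0
          v <- momentum * v - lr * grad
          vel[[p]] <- v
          model$params[[p]] <- model$params[[p]] + v
        }
        ep_loss <- ep_loss + dl$loss
      }
      ep_loss <- ep_loss / steps_per_epoch
      history[[length(history) + 1L]] <- tibble::tibble(
        epoch = epoch, box = ep_loss["box"], cls = ep_loss["cls"],
        dfl = ep_loss["dfl"], total = sum(ep_loss), lr = lr_epoch)
      if (verbose) {
        message(sprintf("epoch %d  box %.4f  cls %.4f  dfl %.4f  total %.4f",
                        epoch, ep_loss["box"], ep_loss["cls"], ep_loss["dfl"],
                        sum(ep_loss)))
      }
    }
  })
  structure(list(model = model, history = dplyr::bind_rows(history),
                 epochs = total_epochs, img_size = img_size, seed = seed),
            class = "seedling_fit")
}

#' @export
print.seedling_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<seedling_fit> %d epochs, final total loss %.4f (from %.4f)\n",
              nrow(h), h$total[nrow(h)], h$total[1L]))
  invisible(x)
}

#' Tidy the loss history of a fit
#' @param x a `seedling_fit`.
#' @param ... unused.
#' @return the per-epoch loss tibble.
#' @export
tidy.seedling_fit <- function(x, ...) x$history

#' One-row fit summary
#' @param x a `seedling_fit`.
#' @param ... unused.
#' @return tibble with initial/final losses and the reduction ratio.
#' @export
glance.seedling_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), initial_loss = h$total[1L],
                 final_loss = h$total[nrow(h)],
                 reduction = 1 - h$total[nrow(h)] / h$total[1L])
}
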