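# Detection evaluation: precision / recall / F1 from match counts, average
# precision as the area under the precision-envelope-vs-recall curve, class
# mean AP (optionally over an IoU sweep), confusion matrix with a background
# row/column, and the frame-rate arithmetic from a timing breakdown.
#
# Detections are tibbles with columns image, x1, y1, x2, y2, score, class_id;
# ground truths the same without score. Zero denominators follow the sparse-
# scene convention: empty precision/recall/AP are 0, never NaN.

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2TP/(2TP+FP+FN)` (algebraically
#' the harmonic mean `2PR/(P+R)`). Zero denominators yield 0.
#'
#' @param tp,fp,fn nonnegative match counts.
#' @return tibble with columns `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(90, 10, 10)
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  tibble::tibble(precision = p, recall = r, f1 = f1)
}

#' Greedy matching of detections to ground truths (single image, single class)
#'
#' Detections are visited in decreasing score order; each claims the
#' unmatched ground truth with the highest IoU, provided that IoU reaches
#' `iou_thr`. A ground truth matches at most one detection. IoU ties are
#' broken by ground-truth index order, so matching is deterministic.
#'
#' @param det_boxes n x 4 matrix (or box input, see [box_iou()]).
#' @param det_scores numeric vector of length n.
#' @param gt_boxes m x 4 matrix.
#' @param iou_thr matching threshold (default 0.5).
#' @return list with `tp` logical flags per detection (in the original
#'   detection order), `match` (gt index or NA per detection), and counts
#'   `tp`, `fp`, `fn` in `counts`.
#' @export
match_detections <- function(det_boxes, det_scores, gt_boxes, iou_thr = 0.5) {
  n <- if (is.null(det_boxes) || length(det_boxes) == 0L) 0L
       else nrow(as_box_matrix(det_boxes, "det_boxes"))
  m <- if (is.null(gt_boxes) || length(gt_boxes) == 0L) 0L
       else nrow(as_box_matrix(gt_boxes, "gt_boxes"))
  tp_flags <- logical(n); match_idx <- rep(NA_integer_, n)
  if (n > 0L && m > 0L) {
    db <- as_box_matrix(det_boxes, "det_boxes")
    gb <- as_box_matrix(gt_boxes, "gt_boxes")
    ord <- order(det_scores, decreasing = TRUE)
    taken <- logical(m)
    for (i in ord) {
      ious <- box_iou(db[rep(i, m), , drop = FALSE], gb)
      ious[taken] <- -1
      j <- which.max(ious)  # ties -> lowest gt index
      if (ious[j] >= iou_thr) {
        taken[j] <- TRUE
        tp_flags[i] <- TRUE
        match_idx[i] <- j
      }
    }
  }
  tp <- sum(tp_flags)
  list(tp = tp_flags, match = match_idx,
       counts = list(tp = tp, fp = n - tp, fn = m - tp))
}

#' Average precision from per-detection flags and scores
#'
#' Sorts detections by decreasing score, accumulates precision/recall, and
#' integrates the monotone precision envelope over recall ("all points"
#' interpolation, approximating the continuous integral of precision over
#' recall). `method = "interp101"` instead averages the envelope at 101
#' equally spaced recall levels, for comparability with toolkits that use
#' that convention.
#'
#' @param tp logical (or 0/1) flags per detection.
#' @param scores detection scores (same length).
#' @param n_gt number of ground truths; `n_gt = 0` gives AP 0.
#' @param method `"all_points"` (default) or `"interp101"`.
#' @return AP in `[0, 1]`.
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), c(.9, .8, .7), n_gt = 2) # 0.8333
#' @export
average_precision <- function(tp, scores, n_gt,
                              method = c("all_points", "interp101")) {
  method <- match.arg(method)
  if (n_gt <= 0L || length(tp) == 0L) return(0)
  ord <- order(scores, decreasing = TRUE)
  tp <- as.logical(tp)[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  # monotone non-increasing precision envelope
  env <- rev(cummax(rev(prec)))
  if (method == "interp101") {
    levels <- seq(0, 1, by = 0.01)
    vals <- vapply(levels, function(r) {
      ok <- rec >= r
      if (any(ok)) max(env[ok]) else 0
    }, 0)
    return(mean(vals))
  }
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * env)
}

#' Unweighted class mean of average precisions
#'
#' @param per_class_ap named numeric vector or list mapping class to AP.
#' @return mean AP.
#' @examples
#' mean_ap(c(seedling = 0.975, weed = 0.755)) # 0.865
#' @export
mean_ap <- function(per_class_ap) {
  v <- unlist(per_class_ap)
  if (length(v) == 0L) stop("mean AP of zero classes is undefined", call. = FALSE)
  mean(v)
}

#' Precision-recall curve per class
#'
#' Sweeps the detection score threshold over all detections of each class and
#' records the cumulative precision/recall pairs; recall is non-decreasing
#' along the sweep.
#'
#' @param detections,ground_truth tibbles (columns `image, x1, y1, x2, y2,
#'   class_id`, detections also `score`).
#' @param iou_thr matching IoU threshold.
#' @return tibble with columns `class_id, score, recall, precision`.
#' @export
pr_curve <- function(detections, ground_truth, iou_thr = 0.5) {
  flags <- flag_detections(detections, ground_truth, iou_thr)
  out <- list()
  for (cl in sort(unique(ground_truth$class_id))) {
    f <- flags[flags$class_id == cl, , drop = FALSE]
    n_gt <- sum(ground_truth$class_id == cl)
    if (nrow(f) == 0L || n_gt == 0L) next
    ord <- order(f$score, decreasing = TRUE)
    ctp <- cumsum(f$tp[ord]); cfp <- cumsum(!f$tp[ord])
    out[[length(out) + 1L]] <- tibble::tibble(
      class_id = cl, score = f$score[ord],
      recall = ctp / n_gt, precision = ctp / (ctp + cfp))
  }
  if (length(out) == 0L) {
    return(tibble::tibble(class_id = integer(), score = numeric(),
                          recall = numeric(), precision = numeric()))
  }
  structure(dplyr::bind_rows(out), class = c("pr_curve", "tbl_df", "tbl", "data.frame"))
}

# per-detection TP/FP flags across a whole dataset (image-wise, class-wise)
flag_detections <- function(detections, ground_truth, iou_thr = 0.5) {
  if (nrow(detections) == 0L) {
    return(tibble::tibble(image = character(), class_id = integer(),
                          score = numeric(), tp = logical()))
  }
  dets <- dplyr::arrange(detections, .data$image, .data$class_id)
  res <- list()
  for (img in unique(dets$image)) {
    d_img <- dets[dets$image == img, , drop = FALSE]
    g_img <- ground_truth[ground_truth$image == img, , drop = FALSE]
    for (cl in unique(d_img$class_id)) {
      d <- d_img[d_img$class_id == cl, , drop = FALSE]
      gm <- g_img[g_img$class_id == cl, , drop = FALSE]
      mt <- match_detections(
        cbind(d$x1, d$y1, d$x2, d$y2), d$score,
        if (nrow(gm)) cbind(gm$x1, gm$y1, gm$x2, gm$y2) else NULL, iou_thr)
      res[[length(res) + 1L]] <- tibble::tibble(
        image = img, class_id = cl, score = d$score, tp = mt$tp)
    }
  }
  dplyr::bind_rows(res)
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP at IoU 0.5 and averaged over the 0.50:0.05:0.95
#' sweep, precision/recall/F1 at `conf_thr`, the class means, and the
#' confusion matrix. This is the evaluation report backing the package's
#' headline metrics.
#'
#' @inheritParams pr_curve
#' @param conf_thr confidence threshold for the P/R/F1 operating point.
#' @param class_names optional names indexed by `class_id + 1`.
#' @return an `eval_report` list with elements `per_class` (tibble), `map50`,
#'   `map50_95`, `confusion`, `pr` (PR curve tibble), `n_images`.
#' @export
evaluate_detections <- function(detections, ground_truth, iou_thr = 0.5,
                                conf_thr = 0.25, class_names = NULL) {
  classes <- sort(unique(ground_truth$class_id))
  sweep_thrs <- seq(0.5, 0.95, by = 0.05)
  per_class <- lapply(classes, function(cl) {
    n_gt <- sum(ground_truth$class_id == cl)
    d_cl <- detections[detections$class_id == cl, , drop = FALSE]
    aps <- vapply(sweep_thrs, function(thr) {
      f <- flag_detections(d_cl, ground_truth, thr)
      average_precision(f$tp, f$score, n_gt)
    }, 0)
    dc <- d_cl[d_cl$score >= conf_thr, , drop = FALSE]
    f <- flag_detections(dc, ground_truth, iou_thr)
    tp <- sum(f$tp); fp <- sum(!f$tp); fn <- n_gt - tp
    prf <- precision_recall_f1(tp, fp, fn)
    tibble::tibble(class_id = cl,
                   class = if (!is.null(class_names)) class_names[cl + 1L]
                           else as.character(cl),
                   n_gt = n_gt, tp = tp, fp = fp, fn = fn,
                   precision = prf$precision, recall = prf$recall, f1 = prf$f1,
                   ap50 = aps[1L], ap50_95 = mean(aps))
  })
  per_class <- dplyr::bind_rows(per_class)
  conf <- confusion_matrix(detections, ground_truth, iou_thr = iou_thr,
                           conf_thr = conf_thr, class_names = class_names)
  structure(list(
    per_class = per_class,
    map50 = mean_ap(per_class$ap50),
    map50_95 = mean_ap(per_class$ap50_95),
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    f1 = mean(per_class$f1),
    confusion = conf,
    pr = pr_curve(detections[detections$score >= 0, , drop = FALSE],
                  ground_truth, iou_thr),
    n_images = length(unique(ground_truth$image)),
    conf_thr = conf_thr, iou_thr = iou_thr
  ), class = "eval_report")
}

#' Class confusion matrix with background row/column
#'
#' Rows are true classes (plus background), columns predicted classes (plus
#' background). A matched pair lands at (true, predicted); an unmatched
#' ground truth at (true, background); an unmatched detection at
#' (background, predicted). Matching is class-agnostic greedy by IoU.
#'
#' @inheritParams evaluate_detections
#' @param normalize return row-normalized proportions instead of counts.
#' @return `(N+1) x (N+1)` matrix.
#' @export
confusion_matrix <- function(detections, ground_truth, iou_thr = 0.5,
                             conf_thr = 0.25, class_names = NULL,
                             normalize = FALSE) {
  classes <- sort(unique(c(detections$class_id, ground_truth$class_id)))
  ncl <- length(classes)
  labs <- c(if (!is.null(class_names)) class_names[classes + 1L]
            else as.character(classes), "background")
  cm <- matrix(0L, ncl + 1L, ncl + 1L, dimnames = list(true = labs, pred = labs))
  dets <- detections[detections$score >= conf_thr, , drop = FALSE]
  images <- unique(c(dets$image, ground_truth$image))
  for (img in images) {
    d <- dets[dets$image == img, , drop = FALSE]
    gm <- ground_truth[ground_truth$image == img, , drop = FALSE]
    mt <- match_detections(
      if (nrow(d)) cbind(d$x1, d$y1, d$x2, d$y2) else NULL, d$score,
      if (nrow(gm)) cbind(gm$x1, gm$y1, gm$x2, gm$y2) else NULL, iou_thr)
    gt_matched <- logical(nrow(gm))
    if (nrow(d)) {
      for (i in seq_len(nrow(d))) {
        ci <- match(d$class_id[i], classes)
        if (!is.na(mt$match[i])) {
          j <- mt$match[i]
          gt_matched[j] <- TRUE
          cj <- match(gm$class_id[j], classes)
          cm[cj, ci] <- cm[cj, ci] + 1L
        } else {
          cm[ncl + 1L, ci] <- cm[ncl + 1L, ci] + 1L
        }
      }
    }
    if (nrow(gm)) {
      for (j in which(!gt_matched)) {
        cj <- match(gm$class_id[j], classes)
        cm[cj, ncl + 1L] <- cm[cj, ncl + 1L] + 1L
      }
    }
  }
  if (normalize) {
    rs <- rowSums(cm)
    cm <- sweep(cm, 1L, pmax(rs, 1L), "/")
  }
  cm
}

#' Frames per second from a timing breakdown
#'
#' `FPS = 1000 / (t_pre + t_inf + t_pos)` with times in milliseconds
#' (preprocessing, inference, post-processing).
#'
#' @param t_pre,t_inf,t_pos nonnegative times in ms.
#' @return frames per second.
#' @examples
#' fps(1, 2, 1) # 250
#' @export
fps <- function(t_pre, t_inf, t_pos) {
  stopifnot(t_pre >= 0, t_inf >= 0, t_pos >= 0)
  total <- t_pre + t_inf + t_pos
  if (total <= 0) stop("total time must be positive", call. = FALSE)
  1000 / total
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d images, IoU %.2f, conf %.2f\n",
              x$n_images, x$iou_thr, x$conf_thr))
  print(x$per_class)
  cat(sprintf("mAP50 %.4f  mAP50-95 %.4f\n", x$map50, x$map50_95))
  invisible(x)
}

#' Tidy an evaluation report into a per-class tibble
#' @param x an `eval_report`.
#' @param ... unused.
#' @return the per-class metrics tibble.
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @return tibble with `map50, map50_95, precision, recall, f1, n_images`.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(map50 = x$map50, map50_95 = x$map50_95,
                 precision = x$precision, recall = x$recall, f1 = x$f1,
                 n_images = x$n_images)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Serialize an evaluation report to JSON
#' @param x an `eval_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_eval_report <- function(x, path) {
  out <- list(per_class = x$per_class, map50 = x$map50, map50_95 = x$map50_95,
              precision = x$precision, recall = x$recall, f1 = x$f1,
              confusion = as.data.frame(as.table(x$confusion)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
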