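#' @useDynLib seedlingdet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import tibble
NULL

# ---- box utilities -----------------------------------------------------------

#' Coerce box input to an n x 4 corner-form matrix
#'
#' Boxes are axis-aligned and corner-form `(x1, y1, x2, y2)`: origin at the
#' top-left of the image, pixel units, continuous coordinates. Accepts a
#' length-4 numeric vector, an n x 4 matrix, or a data frame with columns
#' `x1, y1, x2, y2`.
#'
#' @param x box input.
#' @param arg name used in error messages.
#' @return numeric matrix with columns x1, y1, x2, y2.
#' @keywords internal
as_box_matrix <- function(x, arg = "box") {
  if (is.data.frame(x)) {
    need <- c("x1", "y1", "x2", "y2")
    if (!all(need %in% names(x))) {
      stop(sprintf("`%s` data frame must have columns x1, y1, x2, y2", arg),
           call. = FALSE)
    }
    x <- cbind(x$x1, x$y1, x$x2, x$y2)
  }
  if (is.null(dim(x))) {
    if (length(x) != 4L) {
      stop(sprintf("`%s` must have 4 coordinates (x1, y1, x2, y2)", arg),
           call. = FALSE)
    }
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 4L) {
    stop(sprintf("`%s` must be n x 4 (x1, y1, x2, y2)", arg), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite coordinates", arg), call. = FALSE)
  }
  bad <- x[, 1L] > x[, 3L] | x[, 2L] > x[, 4L]
  if (any(bad)) {
    stop(sprintf(
      "`%s`: invalid box at row %d (requires x1 <= x2 and y1 <= y2)",
      arg, which(bad)[1L]
    ), call. = FALSE)
  }
  x
}

recycle_boxes <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a = a, b = b))
  if (na == 1L) return(list(a = a[rep(1L, nb), , drop = FALSE], b = b))
  if (nb == 1L) return(list(a = a, b = b[rep(1L, na), , drop = FALSE]))
  stop("box arguments must have equal length or length 1", call. = FALSE)
}

#' Intersection over union of axis-aligned boxes
#'
#' @param a,b boxes in corner form; length-4 vectors, n x 4 matrices or data
#'   frames with columns `x1, y1, x2, y2`. Arguments of length 1 are recycled.
#' @return numeric vector of IoU values in `[0, 1]`. Two zero-area boxes have
#'   IoU 0 by convention (avoids 0/0 on degenerate inputs).
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a, "a"); b <- as_box_matrix(b, "b")
  p <- recycle_boxes(a, b); a <- p$a; b <- p$b
  iw <- pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L])
  ih <- pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  union <- area_a + area_b - inter
  out <- ifelse(union > 0, inter / union, 0)
  as.numeric(out)
}

check_image_size <- function(img_w, img_h) {
  if (!is.finite(img_w) || !is.finite(img_h) || img_w <= 0 || img_h <= 0) {
    stop("image dimensions must be positive finite numbers", call. = FALSE)
  }
}

#' Minimum-point-distance IoU (MPDIoU)
#'
#' IoU penalized by the squared distances between the corresponding top-left
#' and bottom-right corners of the two boxes, each normalized by the squared
#' image diagonal `w^2 + h^2`:
#' \deqn{MPDIoU = IoU - d_1^2/(w^2+h^2) - d_2^2/(w^2+h^2)}
#' with \eqn{d_1} the top-left corner distance and \eqn{d_2} the bottom-right
#' corner distance. Values lie in `[-2, 1]` for boxes inside the image;
#' `MPDIoU <= IoU` always, with equality iff both corner pairs coincide.
#'
#' The normalizing `(w, h)` are the dimensions of the image (network input
#' after letterboxing when used as a training loss).
#'
#' @inheritParams box_iou
#' @param img_w,img_h image width and height in pixels (scalars, > 0).
#' @return numeric vector of MPDIoU values.
#' @examples
#' mpdiou(c(0, 0, 2, 2), c(1, 1, 3, 3), 10, 10) # 1/7 - 0.01 - 0.01
#' @export
mpdiou <- function(a, b, img_w, img_h) {
  check_image_size(img_w, img_h)
  am <- as_box_matrix(a, "a"); bm <- as_box_matrix(b, "b")
  p <- recycle_boxes(am, bm); am <- p$a; bm <- p$b
  d1sq <- (am[, 1L] - bm[, 1L])^2 + (am[, 2L] - bm[, 2L])^2
  d2sq <- (am[, 3L] - bm[, 3L])^2 + (am[, 4L] - bm[, 4L])^2
  diag2 <- img_w^2 + img_h^2
  box_iou(am, bm) - d1sq / diag2 - d2sq / diag2
}

#' MPDIoU bounding-box regression loss
#'
#' `1 - mpdiou(pred, gt, img_w, img_h)`; zero iff the boxes coincide, bounded
#' by 3 for boxes inside the image.
#'
#' @param pred,gt predicted and ground-truth boxes (corner form, recycled).
#' @inheritParams mpdiou
#' @return numeric vector of nonnegative loss values.
#' @export
mpdiou_loss <- function(pred, gt, img_w, img_h) {
  1 - mpdiou(pred, gt, img_w, img_h)
}

#' Complete-IoU (CIoU) bounding-box regression loss
#'
#' The baseline detector's box loss: `1 - IoU + rho^2/c^2 + alpha * v`, where
#' `rho` is the center distance, `c` the diagonal of the smallest enclosing
#' box, and `v = (4/pi^2) (atan(w_gt/h_gt) - atan(w_p/h_p))^2` the
#' aspect-ratio penalty with `alpha = v / ((1 - IoU) + v)` (alpha treated as a
#' constant during differentiation, the usual convention).
#'
#' @param pred,gt boxes in corner form (recycled).
#' @param eps numerical guard added to denominators.
#' @return numeric vector of nonnegative loss values.
#' @export
ciou_loss <- function(pred, gt, eps = 1e-9) {
  pm <- as_box_matrix(pred, "pred"); gm <- as_box_matrix(gt, "gt")
  p <- recycle_boxes(pm, gm); pm <- p$a; gm <- p$b
  iou <- box_iou(pm, gm)
  pcx <- (pm[, 1L] + pm[, 3L]) / 2; pcy <- (pm[, 2L] + pm[, 4L]) / 2
  gcx <- (gm[, 1L] + gm[, 3L]) / 2; gcy <- (gm[, 2L] + gm[, 4L]) / 2
  rho2 <- (pcx - gcx)^2 + (pcy - gcy)^2
  cw <- pmax(pm[, 3L], gm[, 3L]) - pmin(pm[, 1L], gm[, 1L])
  ch <- pmax(pm[, 4L], gm[, 4L]) - pmin(pm[, 2L], gm[, 2L])
  c2 <- cw^2 + ch^2 + eps
  pw <- pm[, 3L] - pm[, 1L]; ph <- pm[, 4L] - pm[, 2L]
  gw <- gm[, 3L] - gm[, 1L]; gh <- gm[, 4L] - gm[, 2L]
  v <- (4 / pi^2) * (atan(gw / pmax(gh, eps)) - atan(pw / pmax(ph, eps)))^2
  alpha <- v / ((1 - iou) + v + eps)
  1 - iou + rho2 / c2 + alpha * v
}

#' Convert center-form boxes to corner form
#'
#' @param cx,cy,w,h center coordinates and sizes (vectors).
#' @return n x 4 matrix with columns x1, y1, x2, y2.
#' @export
xywh_to_xyxy <- function(cx, cy, w, h) {
  cbind(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
}

#' Convert corner-form boxes to center form
#'
#' @param boxes corner-form box input (see [box_iou()]).
#' @return n x 4 matrix with columns cx, cy, w, h.
#' @export
xyxy_to_xywh <- function(boxes) {
  m <- as_box_matrix(boxes, "boxes")
  cbind(cx = (m[, 1L] + m[, 3L]) / 2, cy = (m[, 2L] + m[, 4L]) / 2,
        w = m[, 3L] - m[, 1L], h = m[, 4L] - m[, 2L])
}
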