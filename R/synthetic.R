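# Deterministic generator of field-like scenes: noise-textured brown soil,
# clustered green lobed blobs for seedlings (with size jitter emulating
# stunted growth and uneven branching), thin green blades for look-alike
# weeds, and optional translucent pale film strips partially occluding
# plants. Objects are procedural, not photorealistic: enough structure to
# exercise detection, metrics and counting end to end.

local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic scene specification
#'
#' Defaults describe the desk-scale study conditions: a 160 px scene with
#' dense small seedlings and scarce weeds (4:1 class imbalance), seedling
#' blob radii 4-10 px, weed blades 10-22 px, and a 30% chance of a
#' translucent film-glare strip.
#'
#' @param image_size side length in pixels.
#' @param n_seedlings,n_weeds object counts (class ids 0 and 1).
#' @param seedling_radius,weed_length size ranges in pixels.
#' @param film_prob probability that a scene carries a film strip.
#' @param film_opacity strip opacity in `[0, 1]`.
#' @param soil_noise soil texture noise amplitude.
#' @param max_overlap maximum IoU tolerated between placed object boxes.
#' @param seed integer; spec + seed fully determine the scene.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = 160L, n_seedlings = 8L, n_weeds = 2L,
                       seedling_radius = c(4, 10), weed_length = c(10, 22),
                       film_prob = 0.3, film_opacity = 0.45,
                       soil_noise = 0.08, max_overlap = 0.3, seed = 1L) {
  stopifnot(image_size > 0, n_seedlings >= 0, n_weeds >= 0,
            all(seedling_radius > 0), all(weed_length > 0))
  structure(as.list(environment()), class = "scene_spec")
}

soil_background <- function(h, w, noise) {
  base <- c(0.42, 0.30, 0.20)
  coarse_h <- max(2L, h %/% 8L); coarse_w <- max(2L, w %/% 8L)
  coarse <- array(stats::rnorm(coarse_h * coarse_w, 0, noise),
                  c(coarse_h, coarse_w, 1L))
  coarse <- resize_bilinear(coarse, h, w)[, , 1L]
  fine <- matrix(stats::rnorm(h * w, 0, noise / 2), h, w)
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + coarse + fine, 0), 1)
  img
}

# rasterize a lobed blob; returns logical mask over the full image
seedling_mask <- function(h, w, cx, cy, radius) {
  n_lobes <- sample(3:5, 1L)
  mask <- matrix(FALSE, h, w)
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (l in seq_len(n_lobes)) {
    th <- stats::runif(1, 0, 2 * pi)
    off <- radius * stats::runif(1, 0.25, 0.6)
    lx <- cx + off * cos(th); ly <- cy + off * sin(th)
    a <- radius * stats::runif(1, 0.45, 0.8)
    b <- a * stats::runif(1, 0.45, 0.9)
    phi <- stats::runif(1, 0, pi)
    dx <- xs - lx; dy <- ys - ly
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    mask <- mask | (u^2 / a^2 + v^2 / b^2 <= 1)
  }
  # small central disc keeps the lobes connected
  mask | ((xs - cx)^2 + (ys - cy)^2 <= (radius * 0.35)^2)
}

# a weed is a small grass tuft: 2-3 thin blades crossing near one point,
# visually close to a seedling's lobed silhouette
weed_mask <- function(h, w, cx, cy, len) {
  n_blades <- sample(2:3, 1L)
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- matrix(FALSE, h, w)
  th0 <- stats::runif(1, 0, pi)
  for (b in seq_len(n_blades)) {
    th <- th0 + (b - 1) * pi / n_blades + stats::rnorm(1, 0, 0.2)
    half_w <- stats::runif(1, 0.9, 1.6)
    blen <- len * stats::runif(1, 0.7, 1)
    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask <- mask | (abs(u) <= blen / 2 & abs(v) <= half_w)
  }
  mask
}

paint_mask <- function(img, mask, col_mean, col_sd = 0.03) {
  col <- pmin(pmax(stats::rnorm(3, col_mean, col_sd), 0), 1)
  shade <- matrix(stats::runif(sum(mask), 0.85, 1.15), ncol = 1L)
  idx <- which(mask)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- pmin(pmax(col[ch] * shade, 0), 1)
    img[, , ch] <- plane
  }
  img
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x1 = min(idx[, 2L]) - 1, y1 = min(idx[, 1L]) - 1,
    x2 = max(idx[, 2L]), y2 = max(idx[, 1L]))
}

place_objects <- function(spec, h, w, margin_y = c(0, 0)) {
  boxes <- NULL
  objects <- list()
  plan <- c(rep(0L, spec$n_seedlings), rep(1L, spec$n_weeds))
  for (cls in plan) {
    placed <- FALSE
    for (attempt in 1:50) {
      if (cls == 0L) {
        radius <- stats::runif(1, spec$seedling_radius[1L], spec$seedling_radius[2L])
        ext <- radius * 1.6
      } else {
        len <- stats::runif(1, spec$weed_length[1L], spec$weed_length[2L])
        ext <- len / 2 + 2
      }
      cx <- stats::runif(1, ext + 1, w - ext - 1)
      cy <- stats::runif(1, ext + 1 + margin_y[1L], h - ext - 1 - margin_y[2L])
      cand <- c(cx - ext, cy - ext, cx + ext, cy + ext)
      ok <- is.null(boxes) ||
        all(box_iou(matrix(cand, 1L), boxes) <= spec$max_overlap)
      if (ok) {
        boxes <- rbind(boxes, cand)
        objects[[length(objects) + 1L]] <-
          list(class_id = cls, cx = cx, cy = cy,
               size = if (cls == 0L) radius else len)
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  objects
}

render_objects <- function(img, objects, h, w) {
  labels <- list()
  for (ob in objects) {
    if (ob$class_id == 0L) {
      mask <- seedling_mask(h, w, ob$cx, ob$cy, ob$size)
      img <- paint_mask(img, mask, c(0.18, 0.55, 0.16))
    } else {
      mask <- weed_mask(h, w, ob$cx, ob$cy, ob$size)
      img <- paint_mask(img, mask, c(0.30, 0.62, 0.20))
    }
    bb <- mask_bbox(mask)
    labels[[length(labels) + 1L]] <- tibble::tibble(
      class_id = ob$class_id, x1 = bb["x1"], y1 = bb["y1"],
      x2 = bb["x2"], y2 = bb["y2"])
  }
  list(img = img, labels = if (length(labels)) dplyr::bind_rows(labels)
                           else tibble::tibble(class_id = integer(),
                                               x1 = numeric(), y1 = numeric(),
                                               x2 = numeric(), y2 = numeric()))
}

apply_film <- function(img, spec, h, w) {
  if (stats::runif(1) < spec$film_prob) {
    x0 <- stats::runif(1, 0, w * 0.8)
    width <- stats::runif(1, w * 0.06, w * 0.15)
    band <- pmax(1L, round(x0)):pmin(w, round(x0 + width))
    pale <- c(0.88, 0.88, 0.82)
    op <- spec$film_opacity
    for (ch in 1:3) {
      img[, band, ch] <- (1 - op) * img[, band, ch] + op * pale[ch]
    }
  }
  img
}

#' Generate one synthetic field scene with YOLO labels
#'
#' Same spec + seed produce a bit-identical scene. Objects that cannot be
#' placed without exceeding the overlap constraint are skipped (the returned
#' label count is then smaller than requested).
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`(H, W, 3)` array in `[0, 1]`), `labels`
#'   (tibble `class_id, cx, cy, w, h`, normalized center form), and `boxes`
#'   (tibble in pixel corner form).
#' @export
gen_field_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seed(spec$seed, {
    h <- spec$image_size; w <- spec$image_size
    img <- soil_background(h, w, spec$soil_noise)
    objects <- place_objects(spec, h, w)
    ro <- render_objects(img, objects, h, w)
    img <- apply_film(ro$img, spec, h, w)
    boxes <- ro$labels
    labels <- tibble::tibble(
      class_id = boxes$class_id,
      cx = (boxes$x1 + boxes$x2) / 2 / w,
      cy = (boxes$y1 + boxes$y2) / 2 / h,
      w = (boxes$x2 - boxes$x1) / w,
      h = (boxes$y2 - boxes$y1) / h)
    list(image = img, labels = labels, boxes = boxes)
  })
}

#' Generate a fly-over sweep video fixture with ground-truth tracks
#'
#' Simulates a linear sweep over a virtual field strip: the camera window
#' moves down the strip by `sweep_speed` pixels per frame. Objects are placed
#' so their centers pass the frame-center line during the sweep. Returns
#' per-frame ground-truth boxes with persistent ids and the exact per-class
#' number of center-line crossings.
#'
#' @param spec a [scene_spec()] (`image_size` is the frame size).
#' @param n_frames number of frames.
#' @param sweep_speed sweep displacement in pixels per frame (> 0).
#' @param render if `TRUE`, also rasterize the frames (list of arrays).
#' @return list with `tracks` (tibble `frame, id, class_id, x1, y1, x2, y2`),
#'   `expected_counts` (named vector), `n_frames`, and optionally `frames`.
#' @export
gen_field_video <- function(spec, n_frames = 24L, sweep_speed = 6,
                            render = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (sweep_speed <= 0) stop("sweep_speed must be positive", call. = FALSE)
  local_seed(spec$seed + 7L, {
    h <- spec$image_size; w <- spec$image_size
    strip_h <- h + (n_frames - 1L) * sweep_speed
    line_pos <- h / 2
    # centers constrained to strip rows that pass the line mid-sweep
    lo <- line_pos + sweep_speed
    hi <- line_pos + (n_frames - 2L) * sweep_speed
    strip_spec <- spec
    objects <- list()
    plan <- c(rep(0L, spec$n_seedlings), rep(1L, spec$n_weeds))
    boxes <- NULL
    for (cls in plan) {
      for (attempt in 1:80) {
        if (cls == 0L) {
          size <- stats::runif(1, spec$seedling_radius[1L], spec$seedling_radius[2L])
          ext <- size * 1.6
        } else {
          size <- stats::runif(1, spec$weed_length[1L], spec$weed_length[2L])
          ext <- size / 2 + 2
        }
        cx <- stats::runif(1, ext + 1, w - ext - 1)
        cy <- stats::runif(1, max(ext + 1, lo), min(strip_h - ext - 1, hi))
        cand <- c(cx - ext, cy - ext, cx + ext, cy + ext)
        if (is.null(boxes) ||
            all(box_iou(matrix(cand, 1L), boxes) <= spec$max_overlap)) {
          boxes <- rbind(boxes, cand)
          objects[[length(objects) + 1L]] <-
            list(class_id = cls, cx = cx, cy = cy, size = size, ext = ext)
          break
        }
      }
    }
    strip <- NULL
    masks <- NULL
    if (render) {
      strip <- soil_background(strip_h, w, spec$soil_noise)
      for (ob in objects) {
        m <- if (ob$class_id == 0L) seedling_mask(strip_h, w, ob$cx, ob$cy, ob$size)
             else weed_mask(strip_h, w, ob$cx, ob$cy, ob$size)
        strip <- paint_mask(strip, m, if (ob$class_id == 0L)
          c(0.18, 0.55, 0.16) else c(0.30, 0.62, 0.20))
      }
    }
    rows <- list()
    frames <- if (render) vector("list", n_frames) else NULL
    for (f in seq_len(n_frames)) {
      off <- (f - 1L) * sweep_speed
      if (render) frames[[f]] <- strip[off + seq_len(h), , , drop = FALSE]
      for (i in seq_along(objects)) {
        ob <- objects[[i]]
        cy_f <- ob$cy - off
        y1 <- cy_f - ob$ext; y2 <- cy_f + ob$ext
        if (y2 < 0 || y1 > h) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          frame = f, id = i, class_id = ob$class_id,
          x1 = ob$cx - ob$ext, y1 = y1, x2 = ob$cx + ob$ext, y2 = y2)
      }
    }
    tracks <- dplyr::bind_rows(rows)
    # exact expected crossings: consecutive in-frame center positions whose
    # sign around the line flips
    cls_ids <- vapply(objects, function(o) o$class_id, 0L)
    crossed <- vapply(seq_along(objects), function(i) {
      tr <- tracks[tracks$id == i, , drop = FALSE]
      if (nrow(tr) < 2L) return(FALSE)
      cys <- (tr$y1 + tr$y2) / 2
      any(sign(cys[-1L] - line_pos) != sign(cys[-length(cys)] - line_pos))
    }, TRUE)
    expected <- c(
      Seedling = sum(crossed & cls_ids == 0L),
      Weed = sum(crossed & cls_ids == 1L))
    out <- list(tracks = tracks, expected_counts = expected,
                n_frames = n_frames, frame_size = c(w, h),
                line_position = line_pos)
    if (render) out$frames <- frames
    out
  })
}

# ---- YOLO label I/O ----------------------------------------------------------

#' Read YOLO-format label files
#'
#' One row per object: `class cx cy w h`, all box fields normalized to
#' `[0, 1]`. Malformed rows are reported with their line numbers.
#'
#' @param path label text file.
#' @return tibble with columns `class_id, cx, cy, w, h`.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                          w = numeric(), h = numeric()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 5L)
  if (length(bad)) {
    stop(sprintf("malformed label row at line %d of %s (expected 5 fields)",
                 bad[1L], path), call. = FALSE)
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (any(is.na(m))) {
    stop(sprintf("non-numeric label field at line %d of %s",
                 which(rowSums(is.na(m)) > 0)[1L], path), call. = FALSE)
  }
  out_of_range <- which(m[, 2L] < 0 | m[, 2L] > 1 | m[, 3L] < 0 | m[, 3L] > 1 |
                        m[, 4L] <= 0 | m[, 4L] > 1 | m[, 5L] <= 0 | m[, 5L] > 1)
  if (length(out_of_range)) {
    stop(sprintf("label out of normalized range at line %d of %s",
                 out_of_range[1L], path), call. = FALSE)
  }
  tibble::tibble(class_id = as.integer(m[, 1L]), cx = m[, 2L], cy = m[, 3L],
                 w = m[, 4L], h = m[, 5L])
}

#' Write YOLO-format label files
#'
#' @param records tibble with columns `class_id, cx, cy, w, h` (normalized).
#' @param path output text file.
#' @return the path, invisibly. Round trips are exact at 6 decimals.
#' @export
write_yolo_labels <- function(records, path) {
  if (any(records$cx < 0 | records$cx > 1 | records$cy < 0 | records$cy > 1 |
          records$w <= 0 | records$w > 1 | records$h <= 0 | records$h > 1)) {
    stop("label coordinates must be normalized to [0, 1]", call. = FALSE)
  }
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", records$class_id,
                   records$cx, records$cy, records$w, records$h)
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic train/validation/test split
#'
#' Shuffles under `seed`, then takes `round(ratio * n)` items for validation
#' and test and the remainder for training; the three parts are an exact
#' partition.
#'
#' @param items vector (or list) of items to split.
#' @param ratios length-3 numeric summing to 1 (train, val, test).
#' @param seed integer.
#' @return named list `train`, `val`, `test`.
#' @examples
#' lengths(split_dataset(1:2696, c(0.8, 0.1, 0.1), seed = 1)) # 2156 270 270
#' @export
split_dataset <- function(items, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(items)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1", call. = FALSE)
  if (n < length(ratios)) {
    stop("fewer items than splits requested", call. = FALSE)
  }
  local_seed(seed, {
    perm <- sample.int(n)
    n_val <- round(ratios[2L] * n)
    n_test <- round(ratios[3L] * n)
    n_train <- n - n_val - n_test
    list(train = items[perm[seq_len(n_train)]],
         val = items[perm[n_train + seq_len(n_val)]],
         test = items[perm[n_train + n_val + seq_len(n_test)]])
  })
}
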