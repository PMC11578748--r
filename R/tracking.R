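# Reference-line counting over tracked detections. The tracker interface is
# pluggable: anything that yields per-frame (id, class_id, box) records can
# drive the counter; the bundled greedy centroid tracker keeps the package
# free of external tracking dependencies.

#' Reference line for crossing counts
#'
#' @param orientation `"horizontal"` (a row; objects crossing vertically) or
#'   `"vertical"` (a column).
#' @param position line position in pixels. `NULL` places the line at the
#'   frame center.
#' @param frame_size `c(width, height)` of the video frames.
#' @return a `reference_line` object.
#' @export
reference_line <- function(orientation = c("horizontal", "vertical"),
                           position = NULL, frame_size) {
  orientation <- match.arg(orientation)
  limit <- if (orientation == "horizontal") frame_size[2L] else frame_size[1L]
  if (is.null(position)) position <- limit / 2
  if (position < 0 || position > limit) {
    stop("reference line must lie inside the frame", call. = FALSE)
  }
  structure(list(orientation = orientation, position = position,
                 frame_size = frame_size), class = "reference_line")
}

new_count_state <- function(class_names) {
  structure(list(
    counts = stats::setNames(rep(0L, length(class_names)), class_names),
    counted_ids = integer(0),
    crossing_frames = tibble::tibble(id = integer(), class_id = integer(),
                                     frame = integer())
  ), class = "count_state")
}

#' Greedy nearest-centroid tracker update
#'
#' One frame step: every existing track is matched to the nearest detection
#' of the same class within `max_dist` (greedy over increasing distance, so
#' small toy cases coincide with minimum-cost assignment); unmatched
#' detections spawn fresh ids; tracks unseen for more than `patience` frames
#' are dropped.
#'
#' @param tracks tibble of current tracks (columns `id, class_id, cx, cy,
#'   prev_cx, prev_cy, missed`), e.g. from a previous call; `NULL` or empty
#'   to start.
#' @param detections tibble with columns `x1, y1, x2, y2, class_id` (a
#'   `score` column is allowed and ignored).
#' @param max_dist association gate in pixels.
#' @param patience frames a track may go unseen before removal.
#' @return updated track tibble; new tracks have `prev_cx = cx`.
#' @export
centroid_tracker_update <- function(tracks, detections, max_dist = 40,
                                    patience = 3L) {
  if (is.null(tracks) || nrow(tracks) == 0L) {
    tracks <- tibble::tibble(id = integer(), class_id = integer(),
                             cx = numeric(), cy = numeric(),
                             prev_cx = numeric(), prev_cy = numeric(),
                             missed = integer())
  }
  det <- detections
  n_det <- nrow(det)
  dcx <- if (n_det) (det$x1 + det$x2) / 2 else numeric(0)
  dcy <- if (n_det) (det$y1 + det$y2) / 2 else numeric(0)
  assigned_det <- rep(NA_integer_, n_det)   # track row per detection
  if (nrow(tracks) > 0L && n_det > 0L) {
    cand <- expand.grid(t = seq_len(nrow(tracks)), d = seq_len(n_det))
    cand$dist <- sqrt((tracks$cx[cand$t] - dcx[cand$d])^2 +
                      (tracks$cy[cand$t] - dcy[cand$d])^2)
    cand <- cand[tracks$class_id[cand$t] == det$class_id[cand$d] &
                 cand$dist <= max_dist, , drop = FALSE]
    cand <- cand[order(cand$dist), , drop = FALSE]
    used_t <- logical(nrow(tracks)); used_d <- logical(n_det)
    for (k in seq_len(nrow(cand))) {
      t <- cand$t[k]; d <- cand$d[k]
      if (!used_t[t] && !used_d[d]) {
        used_t[t] <- TRUE; used_d[d] <- TRUE
        assigned_det[d] <- t
      }
    }
  }
  next_id <- if (nrow(tracks) > 0L) max(tracks$id) + 1L else 1L
  out <- list()
  # matched + surviving unmatched tracks
  for (t in seq_len(nrow(tracks))) {
    d <- match(t, assigned_det)
    if (!is.na(d)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = tracks$id[t], class_id = tracks$class_id[t],
        cx = dcx[d], cy = dcy[d],
        prev_cx = tracks$cx[t], prev_cy = tracks$cy[t], missed = 0L)
    } else if (tracks$missed[t] + 1L <= patience) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = tracks$id[t], class_id = tracks$class_id[t],
        cx = tracks$cx[t], cy = tracks$cy[t],
        prev_cx = tracks$cx[t], prev_cy = tracks$cy[t],
        missed = tracks$missed[t] + 1L)
    }
  }
  # unmatched detections spawn new ids
  for (d in seq_len(n_det)) {
    if (is.na(assigned_det[d])) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = next_id, class_id = det$class_id[d],
        cx = dcx[d], cy = dcy[d], prev_cx = dcx[d], prev_cy = dcy[d],
        missed = 0L)
      next_id <- next_id + 1L
    }
  }
  if (length(out) == 0L) return(tracks[0, , drop = FALSE])
  dplyr::bind_rows(out)
}

#' Update per-class line-crossing counts
#'
#' A track is counted the first time the sign of (center coordinate − line
#' position) differs between its previous and current center; counted ids
#' are never re-counted, so a track oscillating across the line contributes
#' exactly once. A track that first appears already past the line has no
#' crossing history and is not counted.
#'
#' @param tracks track tibble from [centroid_tracker_update()] (or any
#'   tracker producing `id, class_id, cx, cy, prev_cx, prev_cy`).
#' @param line a [reference_line()].
#' @param state a `count_state` (from a previous call) or `NULL` to start;
#'   when `NULL`, `class_names` must be given.
#' @param class_names class names indexed by `class_id + 1`.
#' @param frame current frame index (recorded with each crossing).
#' @return updated `count_state`; `$counts` is the per-class tally.
#' @export
update_line_counts <- function(tracks, line, state = NULL,
                               class_names = c("Seedling", "Weed"),
                               frame = NA_integer_) {
  stopifnot(inherits(line, "reference_line"))
  if (is.null(state)) state <- new_count_state(class_names)
  if (nrow(tracks) == 0L) return(state)
  coord <- if (line$orientation == "horizontal") tracks$cy else tracks$cx
  prev <- if (line$orientation == "horizontal") tracks$prev_cy else tracks$prev_cx
  s_now <- sign(coord - line$position)
  s_prev <- sign(prev - line$position)
  crossed <- s_now != s_prev & s_prev != 0 & tracks$missed == 0L
  for (i in which(crossed)) {
    id <- tracks$id[i]
    if (id %in% state$counted_ids) next
    state$counted_ids <- c(state$counted_ids, id)
    cname <- class_names[tracks$class_id[i] + 1L]
    state$counts[cname] <- state$counts[cname] + 1L
    state$crossing_frames <- dplyr::bind_rows(
      state$crossing_frames,
      tibble::tibble(id = id, class_id = tracks$class_id[i],
                     frame = as.integer(frame)))
  }
  state
}

#' Count line crossings over a whole frame sequence
#'
#' Drives the tracker and the line counter over per-frame detection records
#' (either ground-truth tracks from the synthetic video generator — in which
#' case the provided `id` column is used directly — or tracker-free
#' detections, which are associated by the centroid tracker).
#'
#' @param frames tibble with columns `frame, x1, y1, x2, y2, class_id` and
#'   optionally `id` (trusted when present).
#' @param line a [reference_line()].
#' @param class_names class names indexed by `class_id + 1`.
#' @param max_dist,patience centroid tracker settings (used when no `id`).
#' @return a `count_report` list: `counts` (named integer vector),
#'   `crossings` tibble (id, class_id, frame), `n_frames`.
#' @export
count_crossings <- function(frames, line, class_names = c("Seedling", "Weed"),
                            max_dist = 40, patience = 3L) {
  state <- new_count_state(class_names)
  tracks <- NULL
  has_ids <- "id" %in% names(frames)
  prev_pos <- list()
  for (f in sort(unique(frames$frame))) {
    fr <- frames[frames$frame == f, , drop = FALSE]
    if (has_ids) {
      cx <- (fr$x1 + fr$x2) / 2; cy <- (fr$y1 + fr$y2) / 2
      prev_cx <- cx; prev_cy <- cy
      for (i in seq_len(nrow(fr))) {
        key <- as.character(fr$id[i])
        if (!is.null(prev_pos[[key]])) {
          prev_cx[i] <- prev_pos[[key]][1L]
          prev_cy[i] <- prev_pos[[key]][2L]
        }
        prev_pos[[key]] <- c(cx[i], cy[i])
      }
      tracks <- tibble::tibble(id = fr$id, class_id = fr$class_id,
                               cx = cx, cy = cy,
                               prev_cx = prev_cx, prev_cy = prev_cy,
                               missed = 0L)
    } else {
      tracks <- centroid_tracker_update(tracks, fr, max_dist, patience)
    }
    state <- update_line_counts(tracks, line, state, class_names, frame = f)
  }
  structure(list(counts = state$counts,
                 crossings = state$crossing_frames,
                 n_frames = length(unique(frames$frame))),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("<count_report>", x$n_frames, "frames\n")
  print(x$counts)
  invisible(x)
}

#' Serialize a count report to JSON
#' @param x a `count_report`.
#' @param path output file.
#' @export
write_count_report <- function(x, path) {
  jsonlite::write_json(list(counts = as.list(x$counts),
                            crossings = x$crossings),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- frame annotation --------------------------------------------------------

# 3x5 bitmap digits for count overlays
digit_glyphs <- local({
  rows <- c(
    "111101101101111", "010110010010111", "111001111100111",
    "111001111001111", "101101111001001", "111100111001111",
    "111100111101111", "111001001001001", "111101111101111",
    "111101111001111")
  lapply(rows, function(r) matrix(as.integer(strsplit(r, "")[[1]]) == 1L,
                                  nrow = 5L, byrow = TRUE))
})

draw_rect <- function(img, x1, y1, x2, y2, col, thickness = 1L) {
  d <- dim(img)
  x1 <- max(1L, round(x1)); y1 <- max(1L, round(y1))
  x2 <- min(d[2L], round(x2)); y2 <- min(d[1L], round(y2))
  if (x2 <= x1 || y2 <= y1) return(img)
  for (t in seq_len(thickness) - 1L) {
    ys <- c(min(y1 + t, d[1L]), max(y2 - t, 1L))
    xs <- c(min(x1 + t, d[2L]), max(x2 - t, 1L))
    for (ch in 1:3) {
      img[ys, x1:x2, ch] <- col[ch]
      img[y1:y2, xs, ch] <- col[ch]
    }
  }
  img
}

draw_number <- function(img, value, x, y, col, scale = 2L) {
  s <- as.character(value)
  for (k in seq_len(nchar(s))) {
    dg <- digit_glyphs[[as.integer(substr(s, k, k)) + 1L]]
    mask <- dg[rep(seq_len(5L), each = scale), rep(seq_len(3L), each = scale)]
    ys <- y + seq_len(nrow(mask)) - 1L
    xs <- x + (k - 1L) * (4L * scale) + seq_len(ncol(mask)) - 1L
    ok_y <- ys <= dim(img)[1L]; ok_x <- xs <= dim(img)[2L]
    for (ch in 1:3) {
      m <- img[ys[ok_y], xs[ok_x], ch]
      m[mask[ok_y, ok_x, drop = FALSE]] <- col[ch]
      img[ys[ok_y], xs[ok_x], ch] <- m
    }
  }
  img
}

#' Annotate a frame with tracks, the reference line and running counts
#'
#' Pure visualization: draws class-colored boxes, a short id tag above each
#' box, the reference line, and the running per-class counts in the top-left
#' corner. The input state is not modified and the frame dimensions are
#' unchanged.
#'
#' @param frame `(H, W, 3)` array in `[0, 1]`.
#' @param tracks track tibble (needs `id, class_id, cx, cy`; boxes drawn when
#'   `x1, y1, x2, y2` present).
#' @param line a [reference_line()].
#' @param counts named per-class counts (e.g. `state$counts`).
#' @return annotated copy of the frame.
#' @export
annotate_frame <- function(frame, tracks, line, counts = NULL) {
  stopifnot(length(dim(frame)) == 3L)
  cols <- list(c(0.1, 0.9, 0.2), c(0.95, 0.3, 0.1), c(0.2, 0.4, 1))
  d <- dim(frame)
  if (line$orientation == "horizontal") {
    y <- max(1L, min(d[1L], round(line$position)))
    frame[y, , 1L] <- 1; frame[y, , 2L] <- 1; frame[y, , 3L] <- 0
  } else {
    x <- max(1L, min(d[2L], round(line$position)))
    frame[, x, 1L] <- 1; frame[, x, 2L] <- 1; frame[, x, 3L] <- 0
  }
  if (!is.null(tracks) && nrow(tracks) > 0L) {
    has_box <- all(c("x1", "y1", "x2", "y2") %in% names(tracks))
    for (i in seq_len(nrow(tracks))) {
      col <- cols[[tracks$class_id[i] %% 3L + 1L]]
      if (has_box) {
        frame <- draw_rect(frame, tracks$x1[i], tracks$y1[i],
                           tracks$x2[i], tracks$y2[i], col)
      }
      frame <- draw_number(frame, tracks$id[i],
                           max(1L, round(tracks$cx[i]) - 3L),
                           max(1L, round(tracks$cy[i]) - 8L), col, scale = 1L)
    }
  }
  if (!is.null(counts)) {
    for (k in seq_along(counts)) {
      frame <- draw_number(frame, unname(counts[k]), 4L, 4L + (k - 1L) * 14L,
                           cols[[(k - 1L) %% 3L + 1L]], scale = 2L)
    }
  }
  frame
}
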