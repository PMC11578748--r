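# Wiring: dataset generation and loading on disk (standard images/ + labels/
# layout with a YAML dataset config), evaluation of a checkpointed or
# in-memory model over a split, video counting, and the ablation parameter
# table. These functions are also the substance behind the command-line
# interface shipped in inst/cli/.

#' Generate a synthetic dataset on disk
#'
#' Writes `images/<split>/*.png`, `labels/<split>/*.txt`, a `data.yaml`
#' listing the class names, and a `summary.json` with per-class object
#' totals. Scenes are split train/val/test by [split_dataset()].
#'
#' @param dir output directory.
#' @param n number of scenes.
#' @param seed integer; scene `i` uses seed `seed + i`.
#' @param spec_args list of overrides passed to [scene_spec()].
#' @param ratios split ratios (default 8:1:1).
#' @param force overwrite a non-empty directory.
#' @return invisibly, the summary list.
#' @export
synth_dataset <- function(dir, n = 30L, seed = 1L, spec_args = list(),
                          ratios = c(0.8, 0.1, 0.1), force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop(sprintf("output dir '%s' is not empty (use force = TRUE)", dir),
         call. = FALSE)
  }
  ids <- seq_len(n)
  splits <- split_dataset(ids, ratios, seed = seed)
  totals <- c(Seedling = 0L, Weed = 0L)
  for (split in names(splits)) {
    img_dir <- file.path(dir, "images", split)
    lbl_dir <- file.path(dir, "labels", split)
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(lbl_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in splits[[split]]) {
      spec <- do.call(scene_spec, c(spec_args, list(seed = seed + i)))
      scene <- gen_field_image(spec)
      stem <- sprintf("img_%04d", i)
      png::writePNG(scene$image, file.path(img_dir, paste0(stem, ".png")))
      write_yolo_labels(scene$labels, file.path(lbl_dir, paste0(stem, ".txt")))
      totals["Seedling"] <- totals["Seedling"] + sum(scene$labels$class_id == 0L)
      totals["Weed"] <- totals["Weed"] + sum(scene$labels$class_id == 1L)
    }
  }
  yaml::write_yaml(list(nc = 2L, names = c("Seedling", "Weed"),
                        train = "images/train", val = "images/val",
                        test = "images/test"),
                   file.path(dir, "data.yaml"))
  summary <- list(n = n, seed = seed,
                  splits = lapply(splits, length),
                  objects = as.list(totals))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Load a dataset split from disk
#'
#' @param dir dataset directory written by [synth_dataset()] (or any dataset
#'   in the same layout).
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list with `images` (list of arrays), `labels` (list of tibbles),
#'   `names` (image stems), `class_names`, `nc`.
#' @export
load_dataset <- function(dir, split = "train") {
  cfg <- yaml::read_yaml(file.path(dir, "data.yaml"))
  img_dir <- file.path(dir, "images", split)
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop(sprintf("no images in %s", img_dir), call. = FALSE)
  stems <- sub("\\.png$", "", files)
  images <- lapply(files, function(f) {
    img <- png::readPNG(file.path(img_dir, f))
    img[, , 1:3, drop = FALSE]
  })
  labels <- lapply(stems, function(s) {
    read_yolo_labels(file.path(dir, "labels", split, paste0(s, ".txt")))
  })
  list(images = images, labels = labels, names = stems,
       class_names = unlist(cfg$names), nc = cfg$nc)
}

labels_to_gt <- function(labels, names, img_sizes) {
  rows <- list()
  for (i in seq_along(labels)) {
    lb <- labels[[i]]
    if (nrow(lb) == 0L) next
    h <- img_sizes[[i]][1L]; w <- img_sizes[[i]][2L]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      image = names[i],
      x1 = (lb$cx - lb$w / 2) * w, y1 = (lb$cy - lb$h / 2) * h,
      x2 = (lb$cx + lb$w / 2) * w, y2 = (lb$cy + lb$h / 2) * h,
      class_id = lb$class_id)
  }
  dplyr::bind_rows(rows)
}

#' Evaluate a detector over a dataset split
#'
#' Runs detection over every image of the split and scores the results. With
#' `oracle = TRUE` the ground-truth labels are replayed as score-1.0
#' detections instead of running the model — the self-consistency check that
#' must give mAP50 = 1.
#'
#' @param model a `seedling_detector`, or `NULL` with `oracle = TRUE`.
#' @param dataset a directory path or the list returned by [load_dataset()].
#' @param split split name when `dataset` is a path.
#' @param conf_thr,iou_thr detection and matching thresholds.
#' @param img_size network input size.
#' @param oracle replay labels as perfect detections.
#' @return an `eval_report` (see [evaluate_detections()]).
#' @export
evaluate_model <- function(model, dataset, split = "val", conf_thr = 0.25,
                           iou_thr = 0.5, img_size = 160L, oracle = FALSE) {
  if (is.character(dataset)) dataset <- load_dataset(dataset, split)
  if (!oracle) {
    stopifnot(inherits(model, "seedling_detector"))
    if (model$cfg$num_classes != dataset$nc) {
      stop(sprintf("model has %d classes but dataset declares %d",
                   model$cfg$num_classes, dataset$nc), call. = FALSE)
    }
  }
  sizes <- lapply(dataset$images, function(im) dim(im)[1:2])
  gt <- labels_to_gt(dataset$labels, dataset$names, sizes)
  if (oracle) {
    dets <- gt
    dets$score <- 1
  } else {
    dets <- dplyr::bind_rows(lapply(seq_along(dataset$images), function(i) {
      d <- forward_detect(model, dataset$images[[i]], conf_thr = conf_thr,
                          img_size = img_size)
      if (nrow(d)) d$image <- dataset$names[i]
      d
    }))
    if (nrow(dets) == 0L) {
      dets <- tibble::tibble(image = character(), x1 = numeric(),
                             y1 = numeric(), x2 = numeric(), y2 = numeric(),
                             score = numeric(), class_id = integer())
    }
  }
  evaluate_detections(dets, gt, iou_thr = iou_thr, conf_thr = conf_thr,
                      class_names = dataset$class_names)
}

#' Count seedlings and weeds crossing a reference line in a video
#'
#' Consumes either ground-truth tracks (tibble with `frame, id, class_id,
#' x1, y1, x2, y2`, e.g. from [gen_field_video()]) or a list of frames, which
#' are run through the detector and the centroid tracker.
#'
#' @param source track tibble or list of frame arrays.
#' @param model detector used when `source` is raw frames.
#' @param frame_size `c(width, height)`; required for raw tracks.
#' @param orientation,position reference-line placement (default horizontal
#'   center).
#' @param class_names class names indexed by `class_id + 1`.
#' @param conf_thr detection threshold for the model path.
#' @param img_size network input size for the model path.
#' @return a `count_report`.
#' @export
count_video <- function(source, model = NULL, frame_size = NULL,
                        orientation = "horizontal", position = NULL,
                        class_names = c("Seedling", "Weed"),
                        conf_thr = 0.25, img_size = 160L) {
  if (is.data.frame(source)) {
    if (is.null(frame_size)) stop("frame_size required for track input", call. = FALSE)
    line <- reference_line(orientation, position, frame_size)
    return(count_crossings(source, line, class_names))
  }
  stopifnot(is.list(source), length(source) > 0L)
  d <- dim(source[[1L]])
  frame_size <- c(d[2L], d[1L])
  line <- reference_line(orientation, position, frame_size)
  rows <- list()
  for (f in seq_along(source)) {
    det <- forward_detect(model, source[[f]], conf_thr = conf_thr,
                          img_size = img_size)
    if (nrow(det)) {
      det$frame <- f
      rows[[length(rows) + 1L]] <- det
    }
  }
  frames <- if (length(rows)) dplyr::bind_rows(rows)
            else tibble::tibble(frame = integer(), x1 = numeric(),
                                y1 = numeric(), x2 = numeric(),
                                y2 = numeric(), class_id = integer())
  count_crossings(frames, line, class_names)
}

#' Parameter-count table over all ablation variants
#'
#' Assembles the eight ablation variants and reports exact learnable-scalar
#' counts plus the 0.1 M rounding used in the ablation literature.
#'
#' @param num_classes classes for all variants (default 2).
#' @return tibble with columns `variant, msmodule, bifpn, mpdiou, params,
#'   params_m`.
#' @export
params_table <- function(num_classes = 2L) {
  variants <- c("model0", "model1", "model2", "model3", "model4", "model5",
                "model6", "ms")
  rows <- lapply(variants, function(v) {
    cfg <- named_variant(v, num_classes = num_classes)
    n <- count_parameters(assemble(cfg))
    tibble::tibble(variant = v, msmodule = cfg$use_msmodule,
                   bifpn = cfg$use_bifpn_p2,
                   mpdiou = identical(cfg$box_loss, "mpdiou"),
                   params = n, params_m = round(n / 1e6, 1))
  })
  dplyr::bind_rows(rows)
}

#' Run configuration profiles
#'
#' `"desk"` is the profile exercised by the package's tests: image 160,
#' batch 8, 30 epochs, 200 synthetic scenes, width multiplier 0.125, and
#' inverse-frequency class weights (1, 4) matching the generator's designed
#' 4:1 seedling:weed imbalance. `"field"` mirrors the emulated study's
#' training setup (batch 32, image size 1280, 300 epochs) and is emitted for
#' documentation; it is not desk-runnable.
#'
#' @param profile `"desk"` or `"field"`.
#' @param variant variant name (see [named_variant()]).
#' @param seed RNG seed.
#' @param ... overrides of individual fields.
#' @return a `run_config` list.
#' @export
run_config <- function(profile = c("desk", "field"), variant = "ms",
                       seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(img_size = 160L, batch_size = 8L, epochs = 30L, n_scenes = 200L,
         width_mult = 0.125, neck_width = 8L, reg_max = 4L, lr0 = 0.02,
         class_weights = c(1, 4))
  } else {
    list(img_size = 1280L, batch_size = 32L, epochs = 300L, n_scenes = 2696L,
         width_mult = 1, neck_width = 60L, reg_max = 16L, lr0 = 0.01)
  }
  over <- list(...)
  for (k in names(over)) base[[k]] <- over[[k]]
  structure(c(list(profile = profile, variant = variant, seed = as.integer(seed)),
              base), class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `read_run_config()` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (k in c("seed", "img_size", "batch_size", "epochs", "n_scenes"))
    if (!is.null(x[[k]])) x[[k]] <- as.integer(x[[k]])
  structure(x, class = "run_config")
}
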