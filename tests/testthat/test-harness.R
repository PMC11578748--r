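test_that("dataset generation writes the standard layout reproducibly", {
  dir1 <- file.path(tempdir(), "ds1")
  unlink(dir1, recursive = TRUE)
  s1 <- synth_dataset(dir1, n = 10, seed = 7)
  expect_equal(unlist(s1$splits), c(train = 8L, val = 1L, test = 1L))
  expect_true(file.exists(file.path(dir1, "data.yaml")))
  expect_length(list.files(file.path(dir1, "images", "train")), 8)
  expect_length(list.files(file.path(dir1, "labels", "train")), 8)
  # refuses to clobber without force
  expect_error(synth_dataset(dir1, n = 10, seed = 7), "force")
  # summary object totals equal the label-file tallies
  lbl_files <- list.files(file.path(dir1, "labels"), recursive = TRUE,
                          full.names = TRUE)
  tallies <- c(Seedling = 0L, Weed = 0L)
  for (f in lbl_files) {
    lb <- read_yolo_labels(f)
    tallies["Seedling"] <- tallies["Seedling"] + sum(lb$class_id == 0L)
    tallies["Weed"] <- tallies["Weed"] + sum(lb$class_id == 1L)
  }
  expect_equal(unlist(s1$objects), tallies)
  # regeneration under force is bit-identical
  dir2 <- file.path(tempdir(), "ds2")
  unlink(dir2, recursive = TRUE)
  synth_dataset(dir2, n = 10, seed = 7)
  f1 <- file.path(dir1, "images", "train", list.files(file.path(dir1, "images", "train"))[1])
  f2 <- file.path(dir2, "images", "train", list.files(file.path(dir2, "images", "train"))[1])
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("loaded datasets carry images, labels and class metadata", {
  dir <- file.path(tempdir(), "ds3")
  unlink(dir, recursive = TRUE)
  synth_dataset(dir, n = 10, seed = 3)
  ds <- load_dataset(dir, "train")
  expect_length(ds$images, 8)
  expect_equal(ds$class_names, c("Seedling", "Weed"))
  expect_equal(dim(ds$images[[1]]), c(160, 160, 3))
  expect_true(all(vapply(ds$labels, nrow, 0L) > 0))
  unlink(dir, recursive = TRUE)
})

test_that("replaying labels as perfect detections scores mAP50 = 1", {
  ds <- make_scene_set(300 + 1:6)
  rep <- evaluate_model(NULL, ds, oracle = TRUE)
  expect_equal(rep$map50, 1)
  expect_equal(rep$map50_95, 1)
  expect_equal(rep$per_class$fp, c(0L, 0L))
  expect_equal(rep$per_class$fn, c(0L, 0L))
  # per-class gt counts equal the label tallies
  expect_equal(rep$per_class$n_gt,
               c(sum(vapply(ds$labels, function(l) sum(l$class_id == 0L), 0L)),
                 sum(vapply(ds$labels, function(l) sum(l$class_id == 1L), 0L))))
})

test_that("a model that emits nothing scores mAP 0", {
  set.seed(8)
  ds <- make_scene_set(400 + 1:3)
  m <- assemble(variant_config(width_mult = 0.125, reg_max = 4))
  rep <- evaluate_model(m, ds, conf_thr = 1.0)
  expect_equal(rep$map50, 0)
  expect_equal(sum(rep$per_class$tp), 0)
})

test_that("class-count mismatches between model and dataset are rejected", {
  set.seed(9)
  ds <- make_scene_set(500 + 1:2)
  m <- assemble(variant_config(num_classes = 3, width_mult = 0.125,
                               reg_max = 4))
  expect_error(evaluate_model(m, ds), "classes")
})

test_that("the ablation table reports eight variants with the printed pattern", {
  set.seed(10)
  tab <- params_table()
  expect_equal(tab$variant[1], "model0")
  expect_equal(tab$params_m,  c(3.0, 2.7, 2.0, 3.0, 1.9, 2.7, 2.0, 1.9))
  expect_equal(tab$msmodule, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("video counting consumes ground-truth tracks and empty videos", {
  vid <- gen_field_video(scene_spec(n_seedlings = 4, n_weeds = 2, seed = 12),
                         n_frames = 20, sweep_speed = 6)
  rep <- count_video(vid$tracks, frame_size = vid$frame_size,
                     position = vid$line_position)
  expect_equal(unname(rep$counts), unname(vid$expected_counts))
  # rerun: identical
  rep2 <- count_video(vid$tracks, frame_size = vid$frame_size,
                      position = vid$line_position)
  expect_identical(rep$counts, rep2$counts)
  empty <- vid$tracks[0, ]
  rep0 <- count_video(empty, frame_size = vid$frame_size)
  expect_equal(unname(rep0$counts), c(0L, 0L))
})

test_that("run configurations round trip through YAML", {
  cfg <- run_config("desk", variant = "ms", seed = 3, epochs = 12L)
  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$epochs, 12L)
  expect_equal(back$variant, "ms")
  expect_equal(back$img_size, cfg$img_size)
  expect_equal(unclass(back)[order(names(back))],
               unclass(cfg)[order(names(cfg))])
})

test_that("count and eval reports serialize to JSON", {
  vid <- gen_field_video(scene_spec(n_seedlings = 3, n_weeds = 1, seed = 14),
                         n_frames = 16, sweep_speed = 8)
  rep <- count_video(vid$tracks, frame_size = vid$frame_size)
  path <- tempfile(fileext = ".json")
  write_count_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$counts$Seedling, unname(rep$counts["Seedling"]))
  ds <- make_scene_set(600 + 1:2)
  er <- evaluate_model(NULL, ds, oracle = TRUE)
  write_eval_report(er, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$map50, 1)
})
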