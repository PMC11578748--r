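test_that("identical spec and seed give bit-identical scenes", {
  s1 <- gen_field_image(scene_spec(seed = 11))
  s2 <- gen_field_image(scene_spec(seed = 11))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  s3 <- gen_field_image(scene_spec(seed = 12))
  expect_false(identical(s1$image, s3$image))
})

test_that("label counts and classes follow the scene plan", {
  s <- gen_field_image(scene_spec(n_seedlings = 5, n_weeds = 0, seed = 2))
  expect_equal(nrow(s$labels), 5)
  expect_true(all(s$labels$class_id == 0L))
  s2 <- gen_field_image(scene_spec(n_seedlings = 0, n_weeds = 3, seed = 2))
  expect_true(all(s2$labels$class_id == 1L))
  # all normalized boxes inside [0, 1]
  s3 <- gen_field_image(scene_spec(seed = 3))
  with(s3$labels, {
    expect_true(all(cx - w / 2 >= 0 & cx + w / 2 <= 1))
    expect_true(all(cy - h / 2 >= 0 & cy + h / 2 <= 1))
  })
})

test_that("label boxes are tight around the drawn plant pixels", {
  s <- gen_field_image(scene_spec(n_seedlings = 4, n_weeds = 2,
                                  film_prob = 0, seed = 5))
  img <- s$image
  green <- img[, , 2] > img[, , 1] & img[, , 2] > img[, , 3] & img[, , 2] > 0.3
  for (i in seq_len(nrow(s$boxes))) {
    b <- s$boxes[i, ]
    sub <- green[max(1, floor(b$y1)):ceiling(b$y2),
                 max(1, floor(b$x1)):ceiling(b$x2)]
    # the box contains plant pixels and its border rows/cols touch them
    expect_gt(sum(sub), 0)
    covered <- sum(sub) / sum(green[max(1, floor(b$y1) - 2):min(nrow(green), ceiling(b$y2) + 2),
                                    max(1, floor(b$x1) - 2):min(ncol(green), ceiling(b$x2) + 2)])
    expect_gte(covered, 0.95)
  }
})

test_that("film strips only appear with positive probability settings", {
  base <- gen_field_image(scene_spec(n_seedlings = 0, n_weeds = 0,
                                     film_prob = 0, seed = 9))
  strip <- gen_field_image(scene_spec(n_seedlings = 0, n_weeds = 0,
                                      film_prob = 1, seed = 9))
  # the film strip brightens a vertical band
  expect_gt(max(colMeans(strip$image[, , 1]) - colMeans(base$image[, , 1])), 0.1)
})

test_that("sweep video tracks move at exactly the sweep speed", {
  vid <- gen_field_video(scene_spec(n_seedlings = 5, n_weeds = 2, seed = 4),
                         n_frames = 15, sweep_speed = 8)
  for (id in unique(vid$tracks$id)) {
    tr <- vid$tracks[vid$tracks$id == id, ]
    if (nrow(tr) < 2) next
    expect_true(all(abs(diff((tr$y1 + tr$y2) / 2) + 8) < 1e-9))
    expect_true(all(diff(tr$frame) == 1))
  }
  expect_error(gen_field_video(scene_spec(seed = 1), sweep_speed = 0),
               "positive")
})

test_that("video ground truth agrees with the line counter", {
  vid <- gen_field_video(scene_spec(n_seedlings = 8, n_weeds = 3, seed = 6),
                         n_frames = 24, sweep_speed = 6)
  line <- reference_line("horizontal", vid$line_position,
                         frame_size = vid$frame_size)
  rep <- count_crossings(vid$tracks, line)
  expect_equal(unname(rep$counts), unname(vid$expected_counts))
})

test_that("rendered video frames match the frame size and are deterministic", {
  vid <- gen_field_video(scene_spec(image_size = 96, n_seedlings = 3,
                                    n_weeds = 1, seed = 8),
                         n_frames = 6, sweep_speed = 10, render = TRUE)
  expect_length(vid$frames, 6)
  expect_equal(dim(vid$frames[[1]]), c(96, 96, 3))
  vid2 <- gen_field_video(scene_spec(image_size = 96, n_seedlings = 3,
                                     n_weeds = 1, seed = 8),
                          n_frames = 6, sweep_speed = 10, render = TRUE)
  expect_identical(vid$frames[[3]], vid2$frames[[3]])
})

test_that("YOLO label files parse, validate, and round trip", {
  path <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.1 0.2", path)
  rec <- read_yolo_labels(path)
  expect_equal(rec$class_id, 0L)
  expect_equal(rec$cx, 0.5)
  expect_equal(rec$h, 0.2)
  # out-of-range and malformed rows are rejected with line numbers
  writeLines(c("0 0.5 0.5 0.1 0.2", "0 1.5 0.5 0.1 0.2"), path)
  expect_error(read_yolo_labels(path), "line 2")
  writeLines("0 0.5 0.5", path)
  expect_error(read_yolo_labels(path), "line 1")
  set.seed(10)
  recs <- tibble::tibble(class_id = sample(0:1, 100, TRUE),
                         cx = runif(100, 0.2, 0.8), cy = runif(100, 0.2, 0.8),
                         w = runif(100, 0.01, 0.3), h = runif(100, 0.01, 0.3))
  write_yolo_labels(recs, path)
  back <- read_yolo_labels(path)
  # exact at the 6-decimal precision of the format
  expect_equal(back$cx, round(recs$cx, 6))
  expect_equal(back$h, round(recs$h, 6))
  expect_identical(back$class_id, recs$class_id)
  expect_error(write_yolo_labels(dplyr::mutate(recs, cx = cx + 1), path),
               "normalized")
})

test_that("the 8:1:1 split applies the rounding rule and partitions exactly", {
  sp <- split_dataset(seq_len(2696), c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(sp), c(train = 2156L, val = 270L, test = 270L))
  sp10 <- split_dataset(1:10, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(sp10), c(train = 8L, val = 1L, test = 1L))
  # exact partition, no overlap
  all_items <- sort(unname(unlist(sp10)))
  expect_equal(all_items, 1:10)
  # determinism
  expect_identical(split_dataset(1:100, seed = 5), split_dataset(1:100, seed = 5))
  expect_false(identical(split_dataset(1:100, seed = 5),
                         split_dataset(1:100, seed = 6)))
  expect_error(split_dataset(1:2, c(0.8, 0.1, 0.1), 1), "fewer items")
  expect_error(split_dataset(1:10, c(0.5, 0.2, 0.2), 1), "sum to 1")
})
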