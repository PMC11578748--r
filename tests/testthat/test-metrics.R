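test_that("precision/recall/F1 follow the count formulas with zero conventions", {
  expect_equal(precision_recall_f1(90, 10, 10),
               tibble::tibble(precision = 0.9, recall = 0.9, f1 = 0.9))
  expect_equal(precision_recall_f1(0, 0, 0),
               tibble::tibble(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(0, 5, 3)$precision, 0)
})

test_that("count-form F1 equals the harmonic mean of P and R", {
  set.seed(1)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp == 0) next
    r <- precision_recall_f1(tp, fp, fn)
    expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall),
                 tolerance = 1e-12)
  }
})

test_that("greedy matching resolves duplicates and ties deterministically", {
  gt <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30))
  # perfect one-to-one
  m <- match_detections(gt, c(0.9, 0.8), gt)
  expect_equal(m$counts, list(tp = 2L, fp = 0L, fn = 0L))
  # duplicate detection of one gt: 1 TP + 1 FP
  d <- rbind(c(0, 0, 10, 10), c(1, 1, 10, 10))
  m <- match_detections(d, c(0.9, 0.8), gt[1, , drop = FALSE])
  expect_equal(m$counts$tp, 1L)
  expect_equal(m$counts$fp, 1L)
  expect_equal(m$tp, c(TRUE, FALSE))
  # exact-tie IoU broken by gt index order
  d <- matrix(c(0, 0, 10, 10), 1)
  g2 <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  m <- match_detections(d, 0.9, g2)
  expect_equal(m$match, 1L)
})

test_that("small-case matching equals the exhaustive-assignment oracle", {
  brute_force_tp <- function(db, scores, gb, thr) {
    n <- nrow(db); m <- nrow(gb)
    iou <- outer(seq_len(n), seq_len(m), function(i, j) {
      box_iou(db[i, , drop = FALSE], gb[j, , drop = FALSE])
    })
    best <- 0L
    # enumerate all one-to-one partial assignments
    assigns <- function(i, used) {
      if (i > n) return(0L)
      best_here <- assigns(i + 1L, used)
      for (j in seq_len(m)) {
        if (!used[j] && iou[i, j] >= thr) {
          u <- used; u[j] <- TRUE
          best_here <- max(best_here, 1L + assigns(i + 1L, u))
        }
      }
      best_here
    }
    assigns(1L, logical(m))
  }
  set.seed(2)
  for (rep in 1:25) {
    n <- sample(1:3, 1); m <- sample(1:3, 1)
    db <- random_boxes(n, 40, 40); gb <- random_boxes(m, 40, 40)
    sc <- runif(n)
    greedy <- match_detections(db, sc, gb, iou_thr = 0.3)
    expect_equal(greedy$counts$tp, brute_force_tp(db, sc, gb, 0.3))
  }
})

test_that("AP integrates the precision envelope over recall", {
  # hand-evaluated worked case: flags TP,FP,TP at scores .9,.8,.7 with 2 gts
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2),
               0.5 * 1.0 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(average_precision(rep(TRUE, 4), seq(0.9, 0.6, by = -0.1), 4), 1)
  expect_equal(average_precision(rep(FALSE, 3), c(0.9, 0.8, 0.7), 3), 0)
  expect_equal(average_precision(logical(0), numeric(0), 0), 0)
  # 101-point interpolation stays close to the envelope integral
  set.seed(3)
  tp <- runif(200) > 0.4; sc <- runif(200)
  a1 <- average_precision(tp, sc, 120)
  a2 <- average_precision(tp, sc, 120, method = "interp101")
  expect_lt(abs(a1 - a2), 0.02)
})

test_that("AP is invariant to monotone score transforms and penalizes added FPs", {
  set.seed(4)
  tp <- runif(50) > 0.5; sc <- runif(50)
  base <- average_precision(tp, sc, sum(tp))
  expect_equal(average_precision(tp, plogis(3 * sc + 1), sum(tp)), base,
               tolerance = 1e-12)
  # an FP below every existing score can never increase AP
  worse <- average_precision(c(tp, FALSE), c(sc, min(sc) - 0.01), sum(tp))
  expect_lte(worse, base + 1e-12)
})

test_that("mean AP averages classes without weighting", {
  expect_equal(mean_ap(c(seedling = 0.975, weed = 0.755)), 0.865)
  expect_equal(mean_ap(c(a = 0.4)), 0.4)
  expect_equal(mean_ap(c(a = 1, b = 1, c = 1)), 1)
  expect_equal(mean_ap(c(a = 0.7, b = 0.7)), 0.7)
  expect_error(mean_ap(numeric(0)), "zero classes")
})

test_that("confusion matrix attributes every gt and detection exactly once", {
  gt <- tibble::tibble(image = "a", x1 = c(0, 20, 40, 60, 80),
                       y1 = 0, x2 = c(10, 30, 50, 70, 90), y2 = 10,
                       class_id = c(0L, 0L, 0L, 1L, 1L))
  # perfect detector: identity block, empty background cells
  det <- gt; det$score <- 0.9
  cm <- confusion_matrix(det, gt)
  expect_equal(unname(diag(cm)[1:2]), c(3, 2))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # no detections: every gt in the background column
  cm0 <- confusion_matrix(det[0, ], gt)
  expect_equal(unname(cm0[1:2, 3]), c(3, 2))
  # hand tally: one misclassified, one missed, one spurious
  det2 <- tibble::tibble(
    image = "a",
    x1 = c(0, 20, 60, 100), y1 = c(0, 0, 0, 100),
    x2 = c(10, 30, 70, 110), y2 = c(10, 10, 10, 110),
    score = 0.9, class_id = c(0L, 1L, 1L, 0L))
  cm2 <- confusion_matrix(det2, gt)
  expect_equal(unname(cm2[1, 1]), 1)  # seedling correctly matched
  expect_equal(unname(cm2[1, 2]), 1)  # seedling predicted as weed
  expect_equal(unname(cm2[2, 2]), 1)  # weed correct
  expect_equal(unname(cm2[1, 3]), 1)  # seedling missed
  expect_equal(unname(cm2[2, 3]), 1)  # weed missed
  expect_equal(unname(cm2[3, 1]), 1)  # spurious detection
  # gt-attributed cells total the number of gts
  expect_equal(sum(cm2[1:2, ]), nrow(gt))
})

test_that("PR curves sweep thresholds with non-decreasing recall", {
  set.seed(5)
  gt <- tibble::tibble(image = rep(c("a", "b"), each = 3),
                       x1 = rep(c(0, 20, 40), 2), y1 = 0,
                       x2 = rep(c(10, 30, 50), 2), y2 = 10,
                       class_id = rep(c(0L, 0L, 1L), 2))
  det <- gt
  det$score <- runif(6)
  det$x1 <- det$x1 + runif(6, -2, 2)
  pr <- pr_curve(det, gt)
  for (cl in unique(pr$class_id)) {
    expect_true(all(diff(pr$recall[pr$class_id == cl]) >= 0))
  }
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
})

test_that("frame-rate arithmetic follows the millisecond formula", {
  expect_equal(fps(1, 2, 1), 250)
  expect_equal(fps(0, 10, 0), 100)
  expect_equal(fps(2, 4, 2), 2 * fps(4, 8, 4))
  expect_error(fps(0, 0, 0), "positive")
})
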