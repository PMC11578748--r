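test_that("up2 replicates pixels and preserves constants", {
  x <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  y <- resample(x, "up2")
  expect_equal(dim(y), c(8, 8, 8))
  expect_equal(y[, 1, 1], x[, 1, 1])
  expect_equal(y[, 2, 2], x[, 1, 1])
  expect_equal(y[, 7, 8], x[, 4, 4])
  cst <- array(2.5, c(3, 4, 4))
  expect_true(all(resample(cst, "up2") == 2.5))
})

test_that("down2 is a learned stride-2 conv and halves spatial dims", {
  set.seed(1)
  layer <- new_downsample_layer(8)
  x <- array(rnorm(8 * 6 * 6), c(8, 6, 6))
  y <- resample(x, "down2", layer)
  expect_equal(dim(y), c(8, 3, 3))
  expect_equal(dim(resample(resample(x, "down2", layer), "up2")), dim(x))
  expect_error(resample(array(0, c(8, 5, 6)), "down2", layer), "even")
})

test_that("normalized fusion forms a sub-convex combination", {
  a <- array(1, c(4, 6, 6)); b <- array(3, c(4, 6, 6))
  # equal weights, vanishing beta -> arithmetic mean
  y <- normalized_fusion(list(a, b), c(1, 1), beta = 1e-12)
  expect_equal(y[1, 1, 1], 2, tolerance = 1e-9)
  # single input, weight 1, beta 1e-4 -> x / (1 + 1e-4)
  y <- normalized_fusion(list(a), 1, beta = 1e-4)
  expect_equal(y[1, 1, 1], 1 / (1 + 1e-4), tolerance = 1e-12)
  # zero raw weight: the second input is ignored entirely
  y1 <- normalized_fusion(list(a, b), c(2, 0))
  y2 <- normalized_fusion(list(a, array(99, dim(b))), c(2, 0))
  expect_equal(y1, y2)
  # clamping: negative raw weights behave as zero
  expect_equal(normalized_fusion(list(a, b), c(2, -5)),
               normalized_fusion(list(a, b), c(2, 0)))
  expect_error(normalized_fusion(list(a, array(0, c(4, 3, 3))), c(1, 1)),
               "identical shapes")
})

test_that("fusion is permutation-equivariant in (input, weight) pairs", {
  set.seed(2)
  xs <- lapply(1:3, function(i) array(rnorm(4 * 5 * 5), c(4, 5, 5)))
  w <- c(0.3, 1.2, 0.8)
  perm <- c(3, 1, 2)
  expect_equal(normalized_fusion(xs, w), normalized_fusion(xs[perm], w[perm]),
               tolerance = 1e-12)
})

test_that("one bidirectional pass preserves every level's shape", {
  set.seed(3)
  layer <- new_bifpn_layer(c(8, 16, 32, 64), width = 8)
  pyr <- list(p2 = array(rnorm(8 * 16 * 16), c(8, 16, 16)),
              p3 = array(rnorm(16 * 8 * 8), c(16, 8, 8)),
              p4 = array(rnorm(32 * 4 * 4), c(32, 4, 4)),
              p5 = array(rnorm(64 * 2 * 2), c(64, 2, 2)))
  out <- bifpn_pass(layer, pyr)
  expect_equal(dim(out$p2), c(8, 16, 16))
  expect_equal(dim(out$p3), c(8, 8, 8))
  expect_equal(dim(out$p4), c(8, 4, 4))
  expect_equal(dim(out$p5), c(8, 2, 2))
  # a second stacked pass at neck width likewise
  layer2 <- new_bifpn_layer(c(8, 8, 8, 8), width = 8)
  out2 <- bifpn_pass(layer2, out)
  expect_equal(lapply(out2, dim), lapply(out, dim))
  expect_error(bifpn_pass(layer, pyr[c("p2", "p3", "p4")]), "levels")
})

test_that("constant pyramids propagate by the closed-form scalar recursion", {
  set.seed(4)
  W <- 4L
  layer <- new_bifpn_layer(c(W, W, W, W), width = W)
  # make every conv cell an exact center-tap identity followed by silu
  for (p in ls(layer$params)) {
    if (grepl("\\.w$", p)) {
      wmat <- layer$params[[p]]
      wmat[] <- 0
      k2 <- ncol(wmat) / W
      center <- if (k2 == 9) 5L else 1L   # center tap of 3x3 / the 1x1 tap
      for (c in seq_len(W)) wmat[c, (center - 1L) * W + c] <- 1
      layer$params[[p]] <- wmat
    }
  }
  for (nm in c("lat2", "lat3", "lat4", "lat5", "conv_p4td", "conv_p3td",
               "conv_p2out", "conv_p3out", "conv_p4out", "conv_p5out",
               "down_p2", "down_p3", "down_p4")) {
    layer$buffers[[paste0("neck.", nm, ".bn.mean")]] <- rep(0, W)
    layer$buffers[[paste0("neck.", nm, ".bn.var")]] <- rep(1 - 1e-5, W)
  }
  vals <- c(p2 = 1, p3 = 2, p4 = 3, p5 = 4)
  pyr <- list(p2 = array(vals[1], c(W, 16, 16)), p3 = array(vals[2], c(W, 8, 8)),
              p4 = array(vals[3], c(W, 4, 4)), p5 = array(vals[4], c(W, 2, 2)))
  out <- bifpn_pass(layer, pyr)
  # independent scalar recursion through the same wiring
  silu <- function(v) v / (1 + exp(-v))
  beta <- 1e-4
  fuse <- function(xs) silu(sum(xs) / (length(xs) + beta))
  lat <- silu(vals)
  p4td <- fuse(c(lat["p4"], lat["p5"]))
  p3td <- fuse(c(lat["p3"], p4td))
  p2out <- fuse(c(lat["p2"], p3td))
  p3out <- fuse(c(lat["p3"], p3td, silu(p2out)))
  p4out <- fuse(c(lat["p4"], p4td, silu(p3out)))
  p5out <- fuse(c(lat["p5"], silu(p4out)))
  expect_equal(max(abs(out$p2 - p2out)), 0, tolerance = 1e-6)
  expect_equal(max(abs(out$p3 - p3out)), 0, tolerance = 1e-6)
  expect_equal(max(abs(out$p4 - p4out)), 0, tolerance = 1e-6)
  expect_equal(max(abs(out$p5 - p5out)), 0, tolerance = 1e-6)
})

test_that("the fine P2 level influences the P3 head input", {
  set.seed(5)
  layer <- new_bifpn_layer(c(8, 16, 32, 64), width = 8)
  pyr <- list(p2 = array(rnorm(8 * 16 * 16), c(8, 16, 16)),
              p3 = array(rnorm(16 * 8 * 8), c(16, 8, 8)),
              p4 = array(rnorm(32 * 4 * 4), c(32, 4, 4)),
              p5 = array(rnorm(64 * 2 * 2), c(64, 2, 2)))
  out1 <- build_neck_outputs(layer, pyr)
  expect_named(out1, c("p3", "p4", "p5"))
  pyr2 <- pyr
  pyr2$p2 <- pyr$p2 + 1
  out2 <- build_neck_outputs(layer, pyr2)
  expect_gt(max(abs(out1$p3 - out2$p3)), 1e-8)
})

test_that("the BiFPN neck is lighter than the baseline neck it replaces", {
  set.seed(6)
  m_pan <- assemble(variant_config())
  m_bifpn <- assemble(variant_config(use_bifpn_p2 = TRUE))
  neck_params <- function(m) {
    ps <- ls(m$params)
    sum(vapply(ps[startsWith(ps, "neck.")],
               function(p) length(m$params[[p]]), 0))
  }
  expect_lt(neck_params(m_bifpn), neck_params(m_pan))
})
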