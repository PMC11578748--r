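test_that("softmax matches direct exponentiation and is shift invariant", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(softmax(c(1, 2, 3)),
               c(0.090031, 0.244728, 0.665241), tolerance = 1e-6)
  v <- rnorm(7)
  expect_equal(softmax(v + 13.7), softmax(v), tolerance = 1e-12)
  expect_equal(sum(softmax(rnorm(100) * 50)), 1, tolerance = 1e-12)
  expect_error(softmax(numeric(0)), "empty")
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("channel grouping partitions contiguous blocks and round trips", {
  x <- array(as.numeric(seq_len(8 * 2 * 2)), c(8, 2, 2))
  g <- channel_group_split(x)
  expect_equal(dim(g$A), c(2, 2, 2))
  expect_equal(g$A, x[1:2, , , drop = FALSE])
  expect_equal(g$D, x[7:8, , , drop = FALSE])
  recon <- array(0, dim(x))
  recon[1:2, , ] <- g$A; recon[3:4, , ] <- g$B
  recon[5:6, , ] <- g$C; recon[7:8, , ] <- g$D
  expect_identical(recon, x)
  expect_error(channel_group_split(array(0, c(6, 2, 2))), "6")
})

test_that("channel attention pools means and lands on the simplex", {
  # identical constant channels -> uniform weights
  x <- array(3.2, c(4, 5, 5))
  expect_equal(channel_attention_weights(x), rep(0.25, 4))
  # one dominant channel saturates toward 1
  x <- array(0, c(3, 4, 4)); x[2, , ] <- 50
  w <- channel_attention_weights(x)
  expect_gt(w[2], 0.999)
  # channel means (1, 2, 3) reproduce the softmax worked example
  x <- array(0, c(3, 6, 6))
  for (c in 1:3) x[c, , ] <- c
  expect_equal(channel_attention_weights(x),
               c(0.090031, 0.244728, 0.665241), tolerance = 1e-6)
  set.seed(1)
  for (i in 1:20) {
    w <- channel_attention_weights(array(rnorm(8 * 3 * 3), c(8, 3, 3)))
    expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_true(all(w >= 0))
  }
})

test_that("MSConv preserves shape and maps zero to zero", {
  set.seed(2)
  layer <- new_msconv_layer(16)
  x <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  y <- msconv_forward(layer, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  # zero input, zero biases (conv cells are bias-free, BN beta = 0) -> zero out
  y0 <- msconv_forward(layer, array(0, c(16, 8, 8)))
  expect_equal(max(abs(y0)), 0, tolerance = 1e-12)
  expect_error(msconv_forward(layer, array(0, c(8, 8, 8))), "channels")
})

test_that("identity mixing leaves the untouched group as its activation", {
  set.seed(3)
  layer <- new_msconv_layer(8)
  # mixing conv = identity matrix; eval-mode BN with unit variance buffers is
  # exactly the identity, so output channels 7:8 are silu(input group D)
  layer$params[["msconv.mix.w"]] <- diag(8)
  layer$buffers[["msconv.mix.bn.mean"]] <- rep(0, 8)
  layer$buffers[["msconv.mix.bn.var"]] <- rep(1 - 1e-5, 8)
  x <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  y <- msconv_forward(layer, x)
  d_in <- x[7:8, , , drop = FALSE]
  expect_equal(y[7:8, , ], (d_in / (1 + exp(-d_in)))[, , ], tolerance = 1e-6)
})

test_that("permuting D-group channels with matching mixing columns is a no-op", {
  set.seed(4)
  layer <- new_msconv_layer(8)
  x <- array(rnorm(8 * 5 * 5), c(8, 5, 5))
  y <- msconv_forward(layer, x)
  # swap the two channels of group D and the corresponding input columns
  # (7, 8) of the 1x1 mixing conv
  xp <- x; xp[7, , ] <- x[8, , ]; xp[8, , ] <- x[7, , ]
  wp <- layer$params[["msconv.mix.w"]]
  wp[, c(7, 8)] <- wp[, c(8, 7)]
  layer$params[["msconv.mix.w"]] <- wp
  yp <- msconv_forward(layer, xp)
  expect_equal(yp, y, tolerance = 1e-10)
})

test_that("MSBottleneck is the identity at zero weights and keeps shape", {
  set.seed(5)
  layer <- new_msbottleneck_layer(8)
  for (p in ls(layer$params)) {
    if (grepl("\\.w$", p)) layer$params[[p]][] <- 0
  }
  x <- array(rnorm(8 * 6 * 6), c(8, 6, 6))
  expect_equal(msbottleneck_forward(layer, x), x, tolerance = 1e-12)
  layer2 <- new_msbottleneck_layer(12)
  y <- msbottleneck_forward(layer2, array(rnorm(12 * 7 * 7), c(12, 7, 7)))
  expect_equal(dim(y), c(12, 7, 7))
})

test_that("random forward passes stay finite", {
  set.seed(6)
  for (i in 1:20) {
    layer <- new_msbottleneck_layer(8)
    x <- array(rnorm(8 * 6 * 6, sd = runif(1, 0.1, 3)), c(8, 6, 6))
    expect_true(all(is.finite(msbottleneck_forward(layer, x))))
  }
})

test_that("MSModule matches C2f topology but carries fewer parameters", {
  set.seed(7)
  ms <- new_msmodule_layer(64, 64, n = 2, ms = TRUE)
  c2f <- new_msmodule_layer(64, 64, n = 2, ms = FALSE)
  expect_lt(layer_parameter_count(ms), layer_parameter_count(c2f))
  x <- array(rnorm(64 * 8 * 8), c(64, 8, 8))
  y <- msmodule_forward(ms, x)
  expect_equal(dim(y), c(64, 8, 8))
})

test_that("gradients reach every parameter of an MSModule", {
  set.seed(8)
  layer <- new_msmodule_layer(8, 8, n = 1, ms = TRUE)
  model <- list(params = layer$params, buffers = layer$buffers)
  g <- seedlingdet:::ag_graph(training = TRUE)
  x <- array(rnorm(8 * 6 * 6 * 2), c(8, 6, 6, 2))
  out <- seedlingdet:::blk_forward(model, g, layer$blk, seedlingdet:::ag_input(g, x))
  out$grad <- array(rnorm(length(out$val)), dim(out$val))
  seedlingdet:::ag_backward(g)
  for (p in ls(layer$params)) {
    node <- g$pcache[[p]]
    expect_false(is.null(node$grad), info = p)
    expect_gt(max(abs(node$grad)), 0)
  }
})

test_that("tape gradients agree with finite differences through MSConv", {
  set.seed(9)
  layer <- new_msconv_layer(8)
  model <- list(params = layer$params, buffers = layer$buffers)
  x <- array(rnorm(8 * 5 * 5), c(8, 5, 5, 1))
  seed <- array(rnorm(8 * 5 * 5), c(8, 5, 5, 1))
  loss <- function() {
    g <- seedlingdet:::ag_graph(training = TRUE)
    out <- seedlingdet:::blk_forward(model, g, layer$blk,
                                     seedlingdet:::ag_input(g, x))
    list(g = g, out = out, val = sum(out$val * seed))
  }
  r <- loss()
  r$out$grad <- seed
  seedlingdet:::ag_backward(r$g)
  eps <- 1e-5
  for (p in c("msconv.b3.w", "msconv.mix.w", "msconv.b5.bn.gamma")) {
    i <- sample(length(layer$params[[p]]), 1)
    orig <- layer$params[[p]][i]
    layer$params[[p]][i] <- orig + eps; up <- loss()$val
    layer$params[[p]][i] <- orig - eps; dn <- loss()$val
    layer$params[[p]][i] <- orig
    fd <- (up - dn) / (2 * eps)
    expect_equal(r$g$pcache[[p]]$grad[i], fd, tolerance = 1e-4, info = p)
  }
})
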