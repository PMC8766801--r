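# Deformable convolution, channel attention, fusion, backbone/head
# geometry and the patch-level prediction interface.

test_that("deformable convolution with zero offsets equals standard convolution", {
  set.seed(21)
  for (i in 1:8) {
    side <- sample(5:8, 1); C <- sample(1:3, 1); co <- sample(1:3, 1)
    x <- rand_image(side, C, -1, 1)
    w <- array(rnorm(co * C * 9), dim = c(co, C, 3, 3))
    Ho <- side - 2
    off <- array(0, dim = c(Ho, Ho, 18))
    got <- deform_conv2d(x, w, off, stride = 1, pad = 0)
    expect_equal(got, naive_conv(x, w), tolerance = 1e-10)
    expect_equal(got, conv2d(x, w), tolerance = 1e-10)
  }
})

test_that("a unit 1x1 kernel with zero offset is the identity per channel", {
  set.seed(3)
  x <- rand_image(6, 2)
  w <- array(0, dim = c(2, 2, 1, 1)); w[1, 1, 1, 1] <- 1; w[2, 2, 1, 1] <- 1
  off <- array(0, dim = c(6, 6, 2))
  expect_equal(deform_conv2d(x, w, off), x, tolerance = 1e-12)
})

test_that("integer offsets reproduce shifted-input convolution in the interior", {
  set.seed(5)
  x <- rand_image(7, 1, -1, 1)
  w <- array(rnorm(9), dim = c(1, 1, 3, 3))
  off <- array(0, dim = c(5, 5, 18))
  off[, , seq(1, 18, by = 2)] <- 1   # +1 row on every tap
  got <- deform_conv2d(x, w, off, stride = 1, pad = 0)
  shifted <- x; shifted[1:6, , ] <- x[2:7, , ]; shifted[7, , ] <- 0
  want <- naive_conv(shifted, w)
  # rows whose taps stay inside the original map
  expect_equal(got[1:4, , , drop = FALSE], want[1:4, , , drop = FALSE],
               tolerance = 1e-10)
})

test_that("fractional offsets match the direct bilinear-resampled sum", {
  set.seed(17)
  for (i in 1:5) {
    x <- rand_image(6, 2, -1, 1)
    w <- array(rnorm(2 * 2 * 9), dim = c(2, 2, 3, 3))
    off <- array(runif(4 * 4 * 18, -3, 3), dim = c(4, 4, 18))
    got <- deform_conv2d(x, w, off, stride = 1, pad = 0, dilation_cap = 2)
    want <- naive_deform_conv(x, w, off, stride = 1, pad = 0, cap = 2)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("offset shape mismatches are rejected", {
  x <- rand_image(6, 1)
  w <- array(1, dim = c(1, 1, 3, 3))
  expect_error(deform_conv2d(x, w, array(0, dim = c(3, 3, 18)), pad = 0),
               "offset")
  expect_error(deform_conv2d(x, array(1, dim = c(1, 2, 3, 3)),
                             array(0, dim = c(4, 4, 18)), pad = 0),
               "channel mismatch")
})

test_that("channel attention implements the squeeze-excitation closed form", {
  set.seed(31)
  # W2 = 0 gives sigmoid(0) = 0.5 exactly
  x <- rand_image(4, 3, -2, 2)
  ca <- channel_attention(x, w1 = matrix(rnorm(3), 1, 3),
                          w2 = matrix(0, 3, 1))
  expect_identical(ca$y, 0.5 * x)
  expect_true(all(ca$weights == 0.5))

  # constant-per-channel input: weights depend only on the channel means
  xc <- array(0, dim = c(5, 5, 2))
  xc[, , 1] <- 1.3; xc[, , 2] <- -0.4
  w1 <- matrix(rnorm(2), 1, 2); w2 <- matrix(rnorm(2), 2, 1)
  ca1 <- channel_attention(xc, w1, w2)
  s_manual <- stats::plogis(w2 %*% pmax(w1 %*% c(1.3, -0.4), 0))
  expect_equal(as.vector(ca1$weights), as.vector(s_manual), tolerance = 1e-12)

  # 2-channel 2x2 input against a step-by-step scalar evaluation
  x2 <- array(c(0.2, -0.5, 1.1, 0.4, -1.2, 0.3, 0.8, -0.1), dim = c(2, 2, 2))
  w1b <- matrix(c(0.5, -0.3), 1, 2)
  w2b <- matrix(c(1.2, -0.7), 2, 1)
  z <- c(mean(x2[, , 1]), mean(x2[, , 2]))
  s <- stats::plogis(w2b %*% pmax(w1b %*% z, 0))
  want <- x2
  want[, , 1] <- x2[, , 1] * s[1]
  want[, , 2] <- x2[, , 2] * s[2]
  got <- channel_attention(x2, w1b, w2b)
  expect_equal(got$y, want, tolerance = 1e-12)
  expect_true(all(got$weights > 0 & got$weights < 1))
})

test_that("channel attention strictly shrinks nonzero channels", {
  set.seed(8)
  x <- rand_image(6, 4, -1, 1)
  ca <- channel_attention(x, matrix(rnorm(4), 1, 4), matrix(rnorm(4), 4, 1))
  for (c in 1:4) {
    nx <- sqrt(sum(x[, , c]^2))
    ny <- sqrt(sum(ca$y[, , c]^2))
    expect_lt(ny, nx)
  }
})

test_that("feature fusion preserves spatial dims and sums channels", {
  set.seed(12)
  f5 <- rand_image(2, 4)
  f4 <- rand_image(4, 3)
  w <- matrix(rnorm(2 * 4), 2, 4)
  fused <- fuse_features(f5, f4, w)
  expect_equal(dim(fused), c(4L, 4L, 2L + 3L))
  expect_error(fuse_features(rand_image(3, 4), f4, w), "half")

  # identity lateral on a constant map: both constants survive the concat
  cmap <- array(2.5, dim = c(2, 2, 1))
  skip <- array(-1, dim = c(4, 4, 1))
  out <- fuse_features(cmap, skip)
  expect_true(all(abs(out[, , 1] - 2.5) < 1e-12))
  expect_true(all(out[, , 2] == -1))

  # upsampled values match first-principles bilinear interpolation
  fn <- rand_image(2, 1)
  fc <- array(0, dim = c(4, 4, 1))
  out2 <- fuse_features(fn, fc)
  expect_equal(out2[, , 1, drop = FALSE], naive_resize_bilinear(fn, 4, 4),
               tolerance = 1e-12)
})

test_that("a zero-initialized residual path reduces the block to its skip", {
  set.seed(2)
  b <- melmap:::make_block(4L, 4L, 1L, stride = 1L, deformable = FALSE,
                           use_ca = FALSE, reduction_ratio = 4L,
                           dilation_cap = 2)
  b$conv2$W[] <- 0
  x <- array(runif(8 * 8 * 4, 0, 1), dim = c(8, 8, 4, 1))
  out <- melmap:::block_forward(b, x)
  # residual branch contributes only bn2's beta (= 0), so out = relu(x)
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("backbone stage outputs follow the stride-4..32 pyramid", {
  set.seed(4)
  m <- build_model(tiny_config(input_size = 64L))
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  f <- backbone_forward(m, x)
  expect_equal(vapply(f, function(a) dim(a)[1], numeric(1)),
               c(C2 = 16, C3 = 8, C4 = 4, C5 = 2))
  # channels double per stage
  expect_equal(vapply(f, function(a) dim(a)[3], numeric(1)),
               c(C2 = 4, C3 = 8, C4 = 16, C5 = 32))
  expect_error(backbone_forward(m, array(0, dim = c(48, 48, 3, 1))),
               "divisible by 32")
  # different inputs produce different deep features
  y <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  f2 <- backbone_forward(m, y)
  expect_gt(max(abs(f$C5 - f2$C5)), 0)
})

test_that("the head concatenates branch vectors into the penultimate layer", {
  set.seed(6)
  cfg <- network_config(depth = 18L, base_width = 8L, dc_stages = "conv5",
                        ca_placement = c("backbone", "shortcut"),
                        fusion_branches = c("F4", "F3", "F2"),
                        input_size = 64L, reduction_ratio = 4L)
  m <- build_model(cfg)
  crops <- replicate(6, rand_image(64), simplify = FALSE)
  pen <- extract_penultimate(m, crops)
  expect_length(pen, 1024L)
  # strict sigmoid range and full determinism
  p1 <- classify_patch(m, crops)
  p2 <- classify_patch(m, crops)
  expect_gt(p1$prob, 0); expect_lt(p1$prob, 1)
  expect_identical(p1$prob, p2$prob)
  expect_identical(pen, extract_penultimate(m, crops))
  # penultimate vectors feed an off-the-shelf 2-D embedding
  mat <- t(vapply(1:4, function(i)
    extract_penultimate(m, replicate(6, rand_image(64), simplify = FALSE)),
    numeric(1024L)))
  emb <- stats::prcomp(mat)$x[, 1:2, drop = FALSE]
  expect_equal(dim(emb), c(4L, 2L))
})

test_that("six identical images predict like a single image", {
  set.seed(9)
  m <- build_model(tiny_config())
  img <- rand_image(32)
  p6 <- classify_patch(m, replicate(6, img, simplify = FALSE))
  p1 <- network_forward(m, array(img, dim = c(32, 32, 3, 1)), group_size = 1L)
  expect_equal(p6$prob, p1$prob, tolerance = 1e-12)
})

test_that("prediction is invariant to the order of the five sub-patches", {
  set.seed(10)
  m <- build_model(tiny_config())
  crops <- replicate(6, rand_image(32), simplify = FALSE)
  p <- classify_patch(m, crops)
  perm <- crops[c(1, 4, 2, 6, 3, 5)]   # whole first, sub-patches permuted
  expect_equal(classify_patch(m, perm)$prob, p$prob, tolerance = 1e-12)
  expect_error(classify_patch(m, crops[1:5]), "6 images")
})

test_that("a probability of exactly 0.5 is labelled malignant", {
  set.seed(11)
  m <- build_model(tiny_config())
  m$fc2$W[] <- 0; m$fc2$b[] <- 0     # logit 0 -> probability exactly 0.5
  p <- classify_patch(m, replicate(6, rand_image(32), simplify = FALSE))
  expect_equal(p$prob, 0.5)
  expect_identical(p$label, 1L)
})

test_that("checkpoints round-trip weights, config and normalization state", {
  set.seed(14)
  m <- build_model(tiny_config())
  # push some batches through so batch-norm running stats are nontrivial
  x <- array(runif(32 * 32 * 3 * 4), dim = c(32, 32, 3, 4))
  invisible(network_forward(m, x, group_size = 1L, training = TRUE))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".yaml")))
  m2 <- load_checkpoint(path)
  crops <- replicate(6, rand_image(32), simplify = FALSE)
  expect_identical(classify_patch(m, crops)$prob,
                   classify_patch(m2, crops)$prob)
})

test_that("freshly built deformable layers start as plain convolutions", {
  set.seed(15)
  cfg_dc <- tiny_config()
  cfg_plain <- network_config(depth = 18L, base_width = 4L,
                              dc_stages = character(),
                              ca_placement = c("backbone", "shortcut"),
                              fusion_branches = c("F4", "F3", "F2"),
                              input_size = 32L, penultimate = 16L,
                              reduction_ratio = 4L, stem_kernel = 3L)
  set.seed(100); m_dc <- build_model(cfg_dc)
  set.seed(100); m_plain <- build_model(cfg_plain)
  # align the 3x3 weights of the dconv layers with their plain twins
  ld <- Filter(function(l) inherits(l, "nn_dconv"), m_dc$layers)
  lp <- Filter(function(l) inherits(l, "nn_conv") && l$k == 3L &&
                 l$c_in == l$c_out && l$c_in == 32L, m_plain$layers)
  for (i in seq_along(ld)) ld[[i]]$W <- lp[[i]]$W
  # remaining weights coincide only by construction of the shared seed; a
  # full-model comparison needs identical layer draw order, so compare the
  # layer outputs directly instead
  xin <- array(runif(4 * 4 * 32 * 1), dim = c(4, 4, 32, 1))
  expect_equal(melmap:::nn_forward.nn_dconv(ld[[1]], xin),
               melmap:::nn_forward.nn_conv(lp[[1]], xin), tolerance = 1e-12)
})
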