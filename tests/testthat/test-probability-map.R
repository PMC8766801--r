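# Probability-map assembly, thresholding, overlay rendering and
# connected lesion regions.

pred <- function(prob, r, c) patch_prediction(as.integer(prob >= 0.5), prob, r, c)

test_that("a single prediction fills its cell; uncovered cells stay 0", {
  spec <- tiling_spec(64, 64)
  pm <- build_probability_map(list(pred(0.9, 0, 0)), c(64, 64), spec)
  expect_equal(pm$grid, matrix(0.9))
  expect_equal(pm$coverage, matrix(1L))

  pm2 <- build_probability_map(list(pred(0.9, 0, 1)), c(64, 128), spec)
  expect_equal(pm2$grid, matrix(c(0, 0.9), 1))
  expect_equal(pm2$coverage, matrix(c(0L, 1L), 1))
})

test_that("multiple predictions on one cell average", {
  spec <- tiling_spec(64, 64)
  pm <- build_probability_map(list(pred(0.2, 0, 0), pred(0.8, 0, 0)),
                              c(64, 64), spec)
  expect_equal(pm$grid[1, 1], 0.5)
  expect_equal(pm$coverage[1, 1], 2L)
})

test_that("out-of-range grid locations are rejected", {
  spec <- tiling_spec(64, 64)
  expect_error(build_probability_map(list(pred(0.5, 2, 0)), c(64, 64), spec),
               "outside")
})

test_that("the map is invariant to prediction ordering", {
  set.seed(51)
  spec <- tiling_spec(32, 32)
  preds <- lapply(1:12, function(i)
    pred(runif(1), sample(0:3, 1), sample(0:3, 1)))
  pm1 <- build_probability_map(preds, c(128, 128), spec)
  pm2 <- build_probability_map(rev(preds), c(128, 128), spec)
  expect_equal(pm1$grid, pm2$grid)
  expect_equal(pm1$coverage, pm2$coverage)
})

test_that("thresholding is inclusive and respects coverage", {
  spec <- tiling_spec(64, 64)
  pm <- build_probability_map(list(pred(0.5, 0, 0)), c(64, 64), spec)
  expect_true(threshold_mask(pm, 0.5)$mask[1, 1])

  # an uncovered cell holding 0 stays negative even at threshold 0
  pm2 <- build_probability_map(list(pred(0.9, 0, 0)), c(64, 128), spec)
  m <- threshold_mask(pm2, 0)
  expect_equal(unname(as.vector(m$mask)), c(TRUE, FALSE))

  expect_error(threshold_mask(pm, 1.5), "threshold")
})

test_that("positive counts match brute-force thresholding on random grids", {
  set.seed(52)
  spec <- tiling_spec(16, 16)
  for (i in 1:10) {
    probs <- matrix(runif(64), 8, 8)
    preds <- list()
    for (r in 0:7) for (c in 0:7)
      preds[[length(preds) + 1]] <- pred(probs[r + 1, c + 1], r, c)
    pm <- build_probability_map(preds, c(128, 128), spec)
    thr <- runif(1)
    m <- threshold_mask(pm, thr)
    expect_equal(sum(m$mask), sum(probs >= thr))
  }
})

test_that("raising the threshold never adds positive cells", {
  set.seed(53)
  spec <- tiling_spec(16, 16)
  preds <- list()
  for (r in 0:5) for (c in 0:5)
    preds[[length(preds) + 1]] <- pred(runif(1), r, c)
  pm <- build_probability_map(preds, c(96, 96), spec)
  prev <- threshold_mask(pm, 0)$mask
  for (thr in seq(0.1, 1, by = 0.1)) {
    cur <- threshold_mask(pm, thr)$mask
    expect_true(all(prev | !cur))   # cur is a subset of prev
    prev <- cur
  }
})

test_that("ground-truth probabilities round-trip through map and mask", {
  spec <- synthetic_slide_spec(dim = c(512L, 512L), seed = 5)
  syn <- generate_slide(spec)
  tl <- tiling_spec(64, 64)
  gl <- patch_labels_from_mask(syn$region_mask, tl, spec$label_threshold,
                               spec$min_tissue)
  preds <- list()
  for (r in seq_len(nrow(gl))) for (c in seq_len(ncol(gl)))
    preds[[length(preds) + 1]] <- pred(as.numeric(gl[r, c]), r - 1L, c - 1L)
  pm <- build_probability_map(preds, dim(syn$image$pixels)[1:2], tl)
  m <- threshold_mask(pm, 0.5)
  expect_identical(dim(m$mask), dim(gl))
  expect_identical(as.vector(m$mask * 1L), as.vector(gl))
})

test_that("lesion regions are 4-connected components sorted by area", {
  spec <- tiling_spec(16, 16)
  empty <- build_probability_map(list(), c(64, 64), spec)
  expect_length(mask_to_regions(threshold_mask(empty, 0.5)), 0)

  # two diagonal-only-adjacent cells form two regions
  preds <- list(pred(0.9, 0, 0), pred(0.9, 1, 1))
  pm <- build_probability_map(preds, c(64, 64), spec)
  regs <- mask_to_regions(threshold_mask(pm, 0.5), pm)
  expect_length(regs, 2)

  # a 3-cell L plus a singleton: sorted by area, bbox in slide pixels
  preds <- list(pred(0.8, 0, 0), pred(0.9, 1, 0), pred(1.0, 1, 1),
                pred(0.7, 3, 3))
  pm <- build_probability_map(preds, c(64, 64), spec)
  regs <- mask_to_regions(threshold_mask(pm, 0.5), pm)
  expect_equal(vapply(regs, `[[`, integer(1), "area_cells"), c(3L, 1L))
  expect_equal(regs[[1]]$bbox, c(0, 0, 32, 32))
  expect_equal(regs[[2]]$bbox, c(48, 48, 64, 64))
  expect_equal(regs[[1]]$mean_prob, mean(c(0.8, 0.9, 1.0)))
})

test_that("component counts match a label-propagation oracle", {
  set.seed(55)
  spec <- tiling_spec(8, 8)
  for (i in 1:8) {
    mask <- matrix(runif(100) < 0.45, 10, 10)
    preds <- list()
    for (r in 0:9) for (c in 0:9)
      preds[[length(preds) + 1]] <- pred(as.numeric(mask[r + 1, c + 1]), r, c)
    pm <- build_probability_map(preds, c(80, 80), spec)
    regs <- mask_to_regions(threshold_mask(pm, 0.5))
    expect_length(regs, relaxation_components(mask))
  }
})

test_that("overlay rendering is deterministic and respects zero probability", {
  set.seed(56)
  px <- array(runif(128 * 128 * 3, 0, 255), dim = c(128, 128, 3))
  slide <- slide_image(px)
  spec <- tiling_spec(32, 32)
  # all-zero probabilities: overlay equals the (downscaled) slide
  preds <- list()
  for (r in 0:3) for (c in 0:3)
    preds[[length(preds) + 1]] <- pred(0, r, c)
  pm0 <- build_probability_map(preds, c(128, 128), spec)
  ov0 <- render_overlay(pm0, slide, alpha = 0.8, scale = 2)
  base <- resize_bilinear(px, 64, 64, antialias = TRUE)
  expect_equal(ov0, base, tolerance = 1e-12)

  # a single positive cell paints exactly window x window pixels
  pm1 <- build_probability_map(list(pred(1, 1, 2)), c(128, 128), spec)
  mask_px <- render_mask(threshold_mask(pm1, 0.5))
  expect_equal(sum(mask_px), 32 * 32)
  expect_true(all(mask_px[33:64, 65:96]))

  ov1 <- render_overlay(pm1, slide)
  expect_identical(ov1, render_overlay(pm1, slide))
  # colour shows up only in the positive cell footprint
  diffmap <- apply(abs(ov1 - px), c(1, 2), max)
  expect_true(all(diffmap[-(33:64), ] < 1e-9))

  expect_error(render_overlay(pm1, slide_image(array(0, c(64, 64, 3)))),
               "dimensions")
})
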