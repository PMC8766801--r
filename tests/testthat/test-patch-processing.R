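# Tiling, tissue filtering, sub-patch cropping, normalization and
# augmentation.

test_that("sliding-window tiling enumerates the expected grid", {
  slide <- slide_image(array(128, dim = c(512, 512, 3)))
  p <- slide_to_patches(slide, tiling_spec(128, 128))
  expect_length(p, 16)
  expect_setequal(vapply(p, `[[`, integer(1), "pixel_row"),
                  rep(c(0L, 128L, 256L, 384L), times = 4))
  expect_equal(vapply(p, function(q) q$pixel_row, integer(1)),
               vapply(p, function(q) q$grid_row * 128L, integer(1)))

  # single-window identity case
  one <- slide_to_patches(slide_image(array(7, dim = c(128, 128, 3))),
                          tiling_spec(128, 128))
  expect_length(one, 1)
  expect_identical(c(one[[1]]$grid_row, one[[1]]$grid_col), c(0L, 0L))
})

test_that("overlapping tiling enumerates all stride positions", {
  slide <- slide_image(array(runif(2048 * 2048 * 3, 0, 255),
                             dim = c(2048, 2048, 3)))
  p <- slide_to_patches(slide, tiling_spec(1024, 512))
  expect_length(p, 9)
  got <- t(vapply(p, function(q) c(q$pixel_row, q$pixel_col), integer(2)))
  want <- expand.grid(r = c(0L, 512L, 1024L), c = c(0L, 512L, 1024L))
  expect_setequal(paste(got[, 1], got[, 2]), paste(want$r, want$c))
  # crop content matches the slide at the recorded offset
  q <- p[[5]]
  expect_equal(q$pixels,
               slide$pixels[q$pixel_row + 1:1024, q$pixel_col + 1:1024, ])
})

test_that("patch counts match brute-force position enumeration", {
  set.seed(41)
  for (i in 1:25) {
    H <- sample(40:160, 1); W <- sample(40:160, 1)
    window <- sample(8:40, 1)
    stride <- sample(seq_len(window), 1)
    if (H < window || W < window) next
    slide <- slide_image(array(1, dim = c(H, W, 3)))
    p <- slide_to_patches(slide, tiling_spec(window, stride))
    rows <- seq(0, H - window, by = stride)
    cols <- seq(0, W - window, by = stride)
    expect_length(p, length(rows) * length(cols))
    expect_setequal(vapply(p, `[[`, integer(1), "pixel_row"),
                    rep(as.integer(rows), times = length(cols)))
  }
})

test_that("non-overlapping patches partition the covered area", {
  H <- 96L; W <- 64L; window <- 32L
  counts <- matrix(0L, H, W)
  slide <- slide_image(array(1, dim = c(H, W, 3)))
  for (p in slide_to_patches(slide, tiling_spec(window, window)))
    counts[p$pixel_row + seq_len(window), p$pixel_col + seq_len(window)] <-
      counts[p$pixel_row + seq_len(window), p$pixel_col + seq_len(window)] + 1L
  expect_true(all(counts == 1L))
})

test_that("undersized slides and malformed input are handled", {
  small <- slide_image(array(0, dim = c(64, 64, 3)))
  expect_warning(p <- slide_to_patches(small, tiling_spec(128, 128)),
                 "smaller than window")
  expect_length(p, 0)
  expect_error(slide_image(matrix(0, 4, 4)), "RGB")
  expect_error(slide_image(array(0, dim = c(4, 4, 4))), "RGB")
})

test_that("tissue filter thresholds the saturated-pixel fraction", {
  white <- array(255, dim = c(32, 32, 3))
  expect_false(tissue_filter(white))
  pink <- array(0, dim = c(32, 32, 3))
  pink[, , 1] <- 200; pink[, , 2] <- 80; pink[, , 3] <- 120
  expect_true(tissue_filter(pink))

  # exactly 30% saturated pixels: accepted at 0.25, rejected at 0.35
  mixed <- array(255, dim = c(10, 10, 3))
  sat_px <- 30
  mixed[, , 2][seq_len(sat_px)] <- 80
  expect_equal(mean(rgb_saturation(mixed) > 0.05), 0.30)
  expect_true(tissue_filter(mixed, tissue_filter_params(0.05, 0.25)))
  expect_false(tissue_filter(mixed, tissue_filter_params(0.05, 0.35)))
})

test_that("raising the tissue-fraction threshold never flips reject to accept", {
  set.seed(7)
  for (i in 1:10) {
    img <- rand_image(16, lo = 0, hi = 255)
    decisions <- vapply(seq(0, 1, by = 0.1), function(fr)
      tissue_filter(img, tissue_filter_params(0.05, fr)), logical(1))
    expect_true(all(diff(as.integer(decisions)) <= 0))
  }
})

test_that("sub-patch crops are the four quadrants plus a centred crop", {
  off <- subpatch_offsets(1024L)
  expect_equal(unname(off),
               rbind(c(0L, 0L), c(0L, 512L), c(512L, 0L), c(512L, 512L),
                     c(256L, 256L)))
  expect_error(subpatch_offsets(1023L), "even")

  # constant patch stays constant through crop + resize
  const <- array(100, dim = c(64, 64, 3))
  crops <- crop_subpatches(const, input_size = 32)
  expect_length(crops, 6)
  for (cr in crops) {
    expect_equal(dim(cr), c(32L, 32L, 3L))
    expect_true(all(abs(cr - 100 / 255) < 1e-12))
  }
})

test_that("a marker pixel lands in exactly the crops covering it", {
  px <- array(0, dim = c(1024, 1024, 3))
  px[301, 701, ] <- 255   # 0-based (300, 700)
  crops <- crop_subpatches(px, resize = FALSE)
  hits <- vapply(crops, function(cr) any(cr > 0), logical(1))
  # (300, 700): rows in [256, 768) and [0, 512); cols in [512, 1024) and [256, 768)
  expect_equal(unname(hits),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("reassembling the four quadrants reproduces the patch bit-exactly", {
  set.seed(13)
  px <- rand_image(64, lo = 0, hi = 255)
  crops <- crop_subpatches(px, resize = FALSE)
  rebuilt <- array(0, dim = dim(px))
  rebuilt[1:32, 1:32, ] <- crops$TL
  rebuilt[1:32, 33:64, ] <- crops$TR
  rebuilt[33:64, 1:32, ] <- crops$BL
  rebuilt[33:64, 33:64, ] <- crops$BR
  expect_identical(rebuilt, px)
  expect_identical(crops$whole, px)
})

test_that("normalize scales to [0,1] and resizes bilinearly", {
  const <- array(255, dim = c(64, 64, 3))
  out <- normalize_image(const, 32)
  expect_equal(dim(out), c(32L, 32L, 3L))
  expect_true(all(abs(out - 1) < 1e-12))

  img <- rand_image(32, lo = 0, hi = 255)
  expect_equal(normalize_image(img, 32), img / 255)

  # 2x2 checkerboard upscaled to 4x4 against first-principles weights
  cb <- array(0, dim = c(2, 2, 1))
  cb[1, 2, 1] <- 1; cb[2, 1, 1] <- 1
  up <- resize_bilinear(cb, 4, 4)
  expect_equal(up, naive_resize_bilinear(cb, 4, 4), tolerance = 1e-12)

  expect_error(normalize_image(numeric(0), 32), "non-empty")
})

test_that("augmentation is the identity at mirror = FALSE, angle = 0", {
  img <- rand_image(32, lo = 0, hi = 255)
  expect_identical(augment_image(img, mirror = FALSE, angle = 0), img)
  twice <- augment_image(augment_image(img, mirror = TRUE, angle = 0),
                         mirror = TRUE, angle = 0)
  expect_identical(twice, img)
})

test_that("rotation angles are uniform on the open interval (-90, 90)", {
  set.seed(99)
  a <- draw_rotation_angle(10000)
  expect_true(all(a > -90 & a < 90))
  expect_lt(abs(mean(a)), 2)        # SE of the mean is ~0.52 degrees
  expect_gt(stats::sd(a), 45)       # uniform sd is 90/sqrt(3) ~ 52
  # deterministic given the seed
  set.seed(99)
  expect_identical(draw_rotation_angle(10000), a)
})

test_that("rotation preserves shape and fills corners by reflection", {
  img <- rand_image(32, lo = 50, hi = 255)
  rot <- augment_image(img, mirror = FALSE, angle = 37)
  expect_equal(dim(rot), dim(img))
  # reflect padding never introduces out-of-range (dark) corners
  expect_gte(min(rot), 50 - 1e-9)
})
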