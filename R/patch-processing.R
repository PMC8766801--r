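#' @useDynLib melmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Slide image container
#'
#' Wraps an RGB raster as used throughout the package: a numeric array of
#' dimension `height x width x 3` holding 8-bit values (0--255), with a
#' 0-based, row-major, top-left pixel origin.
#'
#' @param pixels numeric array `H x W x 3`, values in 0--255.
#' @param source_path optional path the pixels were read from.
#' @return an object of class `slide_image`.
#' @export
slide_image <- function(pixels, source_path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("slide pixels must be an RGB array (H x W x 3)", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("slide must have height >= 1 and width >= 1", call. = FALSE)
  structure(list(pixels = pixels, source_path = source_path),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %d x %d px, source: %s\n", d[1], d[2],
              x$source_path))
  invisible(x)
}

#' Read a slide from PNG or TIFF
#'
#' Reads level-0 pixels of a PNG or (possibly multi-page) TIFF file; the
#' first page/directory is used. Pixels are returned on the 0--255 scale.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return a [slide_image()].
#' @export
read_slide <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      x <- tiff::readTIFF(path, all = FALSE)
      x
    },
    stop("unsupported slide format: ", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  slide_image(img * 255, source_path = path)
}

#' Write a slide or RGB image to PNG
#' @param image a [slide_image()] or `H x W x 3` array on the 0--255 scale.
#' @param path output path.
#' @export
write_slide <- function(image, path) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  png::writePNG(pmin(pmax(px / 255, 0), 1), path)
  invisible(path)
}

#' Sliding-window tiling specification
#'
#' @param window square window side in pixels (default 1024).
#' @param stride sliding stride in pixels; `stride < window` gives
#'   overlapping sampling (default 1024, i.e. non-overlapping).
#' @param drop_partial drop windows that would extend past the slide
#'   border (default `TRUE`); when `FALSE`, border windows are zero-padded.
#' @return an object of class `tiling_spec`.
#' @export
tiling_spec <- function(window = 1024L, stride = 1024L, drop_partial = TRUE) {
  window <- as.integer(window); stride <- as.integer(stride)
  stopifnot(window >= 1L, stride >= 1L, stride <= window)
  structure(list(window = window, stride = stride, drop_partial = drop_partial),
            class = "tiling_spec")
}

#' Number of tile positions along one axis
#' @keywords internal
n_tiles <- function(extent, window, stride) {
  if (extent < window) return(0L)
  as.integer((extent - window) %/% stride + 1L)
}

#' Break a slide into patches by sliding cropping
#'
#' Enumerates all window positions `(r * stride, c * stride)` whose window
#' lies fully inside the slide (with `drop_partial = TRUE`); the patch count
#' is `floor((H - window)/stride + 1) * floor((W - window)/stride + 1)`.
#' Each patch carries its grid indices and top-left pixel offset.
#'
#' @param slide a [slide_image()].
#' @param spec a [tiling_spec()].
#' @return list of `patch_record` objects, each with fields `pixels`,
#'   `grid_row`, `grid_col`, `pixel_row`, `pixel_col`, `label`
#'   (0-based grid and pixel coordinates; `label` is `NA` until assigned).
#' @export
slide_to_patches <- function(slide, spec) {
  if (!inherits(slide, "slide_image")) slide <- slide_image(slide)
  d <- dim(slide$pixels)
  H <- d[1]; W <- d[2]
  w <- spec$window; s <- spec$stride
  if (spec$drop_partial && (H < w || W < w)) {
    warning("slide smaller than window; no patches produced")
    return(list())
  }
  nr <- n_tiles(H, w, s); nc <- n_tiles(W, w, s)
  if (!spec$drop_partial) {
    nr <- max(nr, as.integer(ceiling(max(H - w, 0) / s)) + 1L)
    nc <- max(nc, as.integer(ceiling(max(W - w, 0) / s)) + 1L)
  }
  out <- vector("list", nr * nc)
  i <- 1L
  for (gc in seq_len(nc) - 1L) {
    for (gr in seq_len(nr) - 1L) {
      pr <- gr * s; pc <- gc * s
      h2 <- min(pr + w, H); w2 <- min(pc + w, W)
      px <- array(0, dim = c(w, w, 3L))
      px[seq_len(h2 - pr), seq_len(w2 - pc), ] <-
        slide$pixels[(pr + 1L):h2, (pc + 1L):w2, , drop = FALSE]
      out[[i]] <- patch_record(px, gr, gc, pixel_row = pr, pixel_col = pc)
      i <- i + 1L
    }
  }
  out
}

#' Patch record constructor
#' @param pixels RGB array (`window x window x 3`, 0--255 scale).
#' @param grid_row,grid_col 0-based tile indices.
#' @param pixel_row,pixel_col top-left offset in the slide.
#' @param label 0 (benign), 1 (malignant) or `NA` (unset).
#' @export
patch_record <- function(pixels, grid_row, grid_col,
                         pixel_row = NA_integer_, pixel_col = NA_integer_,
                         label = NA_integer_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("patch pixels must be RGB (H x W x 3)", call. = FALSE)
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop("label must be 0 (benign), 1 (malignant) or NA", call. = FALSE)
  structure(list(pixels = pixels,
                 grid_row = as.integer(grid_row),
                 grid_col = as.integer(grid_col),
                 pixel_row = as.integer(pixel_row),
                 pixel_col = as.integer(pixel_col),
                 label = as.integer(label)),
            class = "patch_record")
}

#' Tissue filter parameters
#'
#' Colour-analysis rule used to pick tissue-containing patches: a pixel
#' counts as tissue when its HSV saturation exceeds `saturation_threshold`,
#' and the patch passes when the tissue-pixel fraction reaches
#' `tissue_fraction_min`. Glass background is near-white (saturation ~ 0),
#' H&E-stained tissue is pink/purple (saturation well above 0.05).
#'
#' @param saturation_threshold saturation cut-off in \[0,1\] (default 0.05).
#' @param tissue_fraction_min minimum tissue-pixel fraction in \[0,1\]
#'   (default 0.10).
#' @export
tissue_filter_params <- function(saturation_threshold = 0.05,
                                 tissue_fraction_min = 0.10) {
  stopifnot(saturation_threshold >= 0, saturation_threshold <= 1,
            tissue_fraction_min >= 0, tissue_fraction_min <= 1)
  structure(list(saturation_threshold = saturation_threshold,
                 tissue_fraction_min = tissue_fraction_min),
            class = "tissue_filter_params")
}

#' Per-pixel HSV saturation of an RGB image
#' @param pixels RGB array on any common scale.
#' @return matrix `H x W` of saturations in \[0,1\] (0 where max channel is 0).
#' @export
rgb_saturation <- function(pixels) {
  mx <- pmax(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  mn <- pmin(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

#' Decide whether a patch contains tissue
#'
#' @param patch a [patch_record()] or RGB array.
#' @param params a [tissue_filter_params()].
#' @return `TRUE` iff the fraction of pixels with saturation above the
#'   threshold is at least `tissue_fraction_min`.
#' @export
tissue_filter <- function(patch, params = tissue_filter_params()) {
  px <- if (inherits(patch, "patch_record")) patch$pixels else patch
  s <- rgb_saturation(px)
  mean(s > params$saturation_threshold) >= params$tissue_fraction_min
}

#' Sub-patch crop offsets
#'
#' For a square patch of even side `s`, the five sub-patches are the four
#' half-side corner quadrants and one centred half-side crop. Offsets are
#' 0-based top-left corners of half-open intervals `[r, r + s/2)`.
#'
#' @param side patch side in pixels (even).
#' @return 5 x 2 integer matrix of (row, col) offsets, rows named
#'   `TL`, `TR`, `BL`, `BR`, `center`.
#' @export
subpatch_offsets <- function(side) {
  if (side %% 2L != 0L) stop("patch side must be even", call. = FALSE)
  h <- side %/% 2L
  m <- rbind(TL = c(0L, 0L), TR = c(0L, h), BL = c(h, 0L), BR = c(h, h),
             center = c(h %/% 2L, h %/% 2L))
  storage.mode(m) <- "integer"
  m
}

#' Crop the multi-scale sub-patch set from a patch
#'
#' Returns the whole patch plus five half-side sub-patches (four corner
#' quadrants and one centred crop), in the fixed order
#' `[whole, TL, TR, BL, BR, center]`. With `resize = TRUE` all six images
#' are bilinearly resized (antialiased on downscale) to
#' `input_size x input_size` and scaled to \[0,1\]; with `resize = FALSE`
#' the raw crops are returned unchanged.
#'
#' @param patch a [patch_record()] or square RGB array with even side.
#' @param input_size network input side (default 512).
#' @param resize resize + normalize the six images (default `TRUE`).
#' @return list of 6 arrays; attribute `offsets` records the crop layout.
#' @export
crop_subpatches <- function(patch, input_size = 512L, resize = TRUE) {
  px <- if (inherits(patch, "patch_record")) patch$pixels else patch
  d <- dim(px)
  if (d[1] != d[2]) stop("patch must be square", call. = FALSE)
  side <- d[1]
  off <- subpatch_offsets(side)
  h <- side %/% 2L
  crops <- vector("list", 6L)
  crops[[1]] <- px
  for (i in 1:5) {
    r <- off[i, 1]; c <- off[i, 2]
    crops[[i + 1]] <- px[(r + 1L):(r + h), (c + 1L):(c + h), , drop = FALSE]
  }
  names(crops) <- c("whole", rownames(off))
  if (resize) crops <- lapply(crops, normalize_image, input_size = input_size)
  attr(crops, "offsets") <- off
  crops
}

#' Resize and scale an RGB image for network input
#'
#' Scales 8-bit values to \[0,1\] and resizes to
#' `input_size x input_size` with half-pixel-centre bilinear interpolation;
#' downscales are antialiased by an integer-factor box prefilter.
#'
#' @param image RGB array `H x W x 3` (0--255 scale).
#' @param input_size output side in pixels.
#' @return numeric array `input_size x input_size x 3` with values in \[0,1\].
#' @export
normalize_image <- function(image, input_size = 512L) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("expected a non-empty RGB image", call. = FALSE)
  x <- image / 255
  out <- resize_bilinear(x, input_size, input_size, antialias = TRUE)
  out
}

#' Bilinear resize of an image or feature map
#'
#' @param x array `H x W x C` or `H x W x C x N`.
#' @param height,width output spatial dims.
#' @param antialias apply an integer-factor box prefilter before
#'   downscaling (default `FALSE`).
#' @return resized array with the same trailing dims.
#' @export
resize_bilinear <- function(x, height, width, antialias = FALSE) {
  d <- dim(x)
  drop3 <- length(d) == 3L
  if (drop3) dim(x) <- c(d, 1L)
  xd <- dim(x)
  if (antialias) {
    f <- min(xd[1] %/% height, xd[2] %/% width)
    if (f >= 2L) {
      x <- cpp_box_reduce(x, dim(x), as.integer(f))
      xd <- dim(x)
    }
  }
  if (xd[1] == height && xd[2] == width) {
    y <- x
  } else {
    y <- cpp_resize_bilinear(x, xd, as.integer(height), as.integer(width))
  }
  if (drop3) dim(y) <- dim(y)[1:3]
  y
}

#' Training-time augmentation: mirror + random rotation
#'
#' Applies an independent horizontal-mirror coin flip and a rotation with
#' angle drawn uniformly from the open interval (-90, +90) degrees.
#' Rotation uses bilinear sampling with reflect padding so the output keeps
#' the input size without introducing dark corners. Uses the R RNG: seed
#' with [set.seed()] for reproducibility.
#'
#' @param image square image array `H x W x C` (any value scale).
#' @param mirror,angle optional overrides; when `NULL` they are drawn from
#'   the RNG.
#' @return augmented array, same shape.
#' @export
augment_image <- function(image, mirror = NULL, angle = NULL) {
  d <- dim(image)
  stopifnot(d[1] == d[2])
  if (is.null(mirror)) mirror <- stats::runif(1) < 0.5
  if (is.null(angle)) angle <- draw_rotation_angle(1L)
  out <- image
  if (mirror) out <- out[, d[2]:1, , drop = FALSE]
  if (angle != 0) out <- cpp_rotate_reflect(out, dim(out), angle)
  out
}

#' Draw a rotation angle for augmentation
#'
#' Uniform on the open interval (-90, +90) degrees.
#' @param n number of draws.
#' @export
draw_rotation_angle <- function(n = 1L) {
  a <- stats::runif(n, -90, 90)
  # runif can in principle return an endpoint; resample those draws
  bad <- a <= -90 | a >= 90
  while (any(bad)) {
    a[bad] <- stats::runif(sum(bad), -90, 90)
    bad <- a <= -90 | a >= 90
  }
  a
}

#' Write a patch manifest CSV
#'
#' @param patches list of [patch_record()]s.
#' @param path output CSV path.
#' @param slide_id identifier recorded in the first column.
#' @param tissue optional logical vector of tissue-filter decisions.
#' @param paths optional vector of per-patch image paths.
#' @export
write_patch_manifest <- function(patches, path, slide_id = "slide",
                                 tissue = NA, paths = NA_character_) {
  df <- data.frame(
    slide_id = slide_id,
    grid_row = vapply(patches, `[[`, integer(1), "grid_row"),
    grid_col = vapply(patches, `[[`, integer(1), "grid_col"),
    pixel_row = vapply(patches, `[[`, integer(1), "pixel_row"),
    pixel_col = vapply(patches, `[[`, integer(1), "pixel_col"),
    tissue = tissue,
    label = vapply(patches, `[[`, integer(1), "label"),
    path = paths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
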