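# Slide-level aggregation: probability map over the tile grid, mosaic
# mask by thresholding, overlay rendering and 4-connected lesion regions.

#' Build a slide-level probability map from patch predictions
#'
#' Each covered grid cell holds the mean malignancy probability of all
#' predictions mapped to it (the mean only matters for overlapping
#' tilings); cells without predictions (background filtered out) hold 0
#' with coverage 0. The map is invariant to prediction order.
#'
#' @param preds list of [patch_prediction()]s with grid locations set.
#' @param slide_dim integer `c(height, width)` of the slide in pixels.
#' @param spec the [tiling_spec()] used to cut the patches.
#' @return object of class `probability_map` with fields `grid`
#'   (probabilities in \[0,1\]), `coverage` (prediction counts), `window`,
#'   `stride`, `slide_dim`.
#' @export
build_probability_map <- function(preds, slide_dim, spec) {
  nr <- n_tiles(slide_dim[1], spec$window, spec$stride)
  nc <- n_tiles(slide_dim[2], spec$window, spec$stride)
  acc <- matrix(0, nr, nc)
  cov <- matrix(0L, nr, nc)
  for (p in preds) {
    r <- p$grid_row + 1L; c <- p$grid_col + 1L
    if (r < 1L || r > nr || c < 1L || c > nc)
      stop(sprintf("prediction grid location (%d, %d) outside the %d x %d tiling",
                   p$grid_row, p$grid_col, nr, nc), call. = FALSE)
    acc[r, c] <- acc[r, c] + p$prob
    cov[r, c] <- cov[r, c] + 1L
  }
  grid <- matrix(0, nr, nc)
  grid[cov > 0L] <- acc[cov > 0L] / cov[cov > 0L]
  structure(list(grid = grid, coverage = cov, window = spec$window,
                 stride = spec$stride, slide_dim = as.integer(slide_dim)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d cells (window %d, stride %d), %d covered\n",
              nrow(x$grid), ncol(x$grid), x$window, x$stride,
              sum(x$coverage > 0)))
  invisible(x)
}

#' Threshold a probability map into a mosaic mask
#'
#' Covered cells with probability >= `threshold` (inclusive, matching the
#' patch labeling rule) become positive; uncovered cells stay negative.
#'
#' @param pmap a [build_probability_map()] result.
#' @param threshold malignancy cut-off in \[0,1\] (default 0.5).
#' @return object of class `mask_image`: logical `mask` at grid
#'   resolution, the `threshold` used, and the tiling metadata.
#' @export
threshold_mask <- function(pmap, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  mask <- pmap$grid >= threshold & pmap$coverage > 0L
  structure(list(mask = mask, threshold = threshold, window = pmap$window,
                 stride = pmap$stride, slide_dim = pmap$slide_dim),
            class = "mask_image")
}

#' Render a mask at full slide resolution
#'
#' Paints each positive cell's window footprint; with overlapping tilings
#' a pixel is positive when any positive cell covers it.
#'
#' @param mask a [threshold_mask()] result.
#' @param scale integer downscale factor of the rendering (default 1).
#' @return logical matrix `slide_dim / scale`.
#' @export
render_mask <- function(mask, scale = 1L) {
  H <- mask$slide_dim[1] %/% scale; W <- mask$slide_dim[2] %/% scale
  out <- matrix(FALSE, H, W)
  w <- mask$window %/% scale; s <- mask$stride %/% scale
  pos <- which(mask$mask, arr.ind = TRUE)
  for (i in seq_len(nrow(pos))) {
    r0 <- (pos[i, 1] - 1L) * s; c0 <- (pos[i, 2] - 1L) * s
    out[(r0 + 1L):min(r0 + w, H), (c0 + 1L):min(c0 + w, W)] <- TRUE
  }
  out
}

#' Render a probability heatmap over the slide
#'
#' Upsamples the grid probabilities to slide resolution (each cell paints
#' its window footprint; overlapping cells average) and alpha-blends a
#' colour ramp over the (downscaled) slide. The blend weight is
#' `alpha * probability`, so a probability of 0 leaves the slide pixel
#' unchanged. Deterministic.
#'
#' @param pmap a [build_probability_map()] result.
#' @param slide a [slide_image()] (or `NULL` for the bare heatmap on white).
#' @param alpha maximum blend weight in \[0,1\] (default 0.5).
#' @param scale integer downscale factor of the rendering.
#' @param colormap function mapping probabilities in \[0,1\] to an `n x 3`
#'   0--255 colour matrix; default a blue-to-red ramp.
#' @return RGB array (`H/scale x W/scale x 3`, 0--255 scale).
#' @export
render_overlay <- function(pmap, slide = NULL, alpha = 0.5, scale = 1L,
                           colormap = NULL) {
  H <- pmap$slide_dim[1] %/% scale; W <- pmap$slide_dim[2] %/% scale
  if (!is.null(slide)) {
    d <- dim(slide$pixels)
    if (!all(d[1:2] == pmap$slide_dim))
      stop("slide dimensions do not match the probability map", call. = FALSE)
    base <- resize_bilinear(slide$pixels, H, W, antialias = TRUE)
  } else {
    base <- array(255, dim = c(H, W, 3))
  }
  if (is.null(colormap)) {
    ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
    colormap <- function(p) ramp(p)
  }
  acc <- matrix(0, H, W); cnt <- matrix(0L, H, W)
  w <- pmap$window %/% scale; s <- pmap$stride %/% scale
  cov <- which(pmap$coverage > 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(cov))) {
    r0 <- (cov[i, 1] - 1L) * s; c0 <- (cov[i, 2] - 1L) * s
    rows <- (r0 + 1L):min(r0 + w, H); cols <- (c0 + 1L):min(c0 + w, W)
    acc[rows, cols] <- acc[rows, cols] + pmap$grid[cov[i, 1], cov[i, 2]]
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  p <- matrix(0, H, W)
  p[cnt > 0L] <- acc[cnt > 0L] / cnt[cnt > 0L]
  cols <- colormap(as.vector(p))
  out <- base
  wgt <- alpha * as.vector(p)
  for (ch in 1:3) {
    b <- as.vector(base[, , ch])
    out[, , ch] <- matrix((1 - wgt) * b + wgt * cols[, ch], H, W)
  }
  out
}

#' Extract 4-connected lesion regions from a mask
#'
#' Labels the 4-connected components of positive cells and reports, for
#' each, its member cells, pixel bounding box
#' (`grid index * stride .. + window`) and mean probability, sorted by
#' area (cell count) descending.
#'
#' @param mask a [threshold_mask()] result.
#' @param pmap the matching [build_probability_map()] (for mean
#'   probabilities); optional.
#' @return list of `lesion_region` lists with fields `id`, `cells`
#'   (two-column matrix of 0-based grid rows/cols), `area_cells`,
#'   `bbox` (`c(row_min, col_min, row_max, col_max)` in slide pixels,
#'   half-open), `mean_prob`.
#' @export
mask_to_regions <- function(mask, pmap = NULL) {
  m <- mask$mask
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  regions <- list()
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!m[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(rr, cc), ncol = 2L)
    lab[rr, cc] <- cur
    cells <- matrix(integer(), ncol = 2L)
    while (nrow(queue) > 0L) {
      cell <- queue[1L, , drop = FALSE]
      queue <- queue[-1L, , drop = FALSE]
      cells <- rbind(cells, cell)
      r <- cell[1]; c <- cell[2]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            m[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue <- rbind(queue, c(r2, c2))
        }
      }
    }
    cells0 <- cells - 1L
    bbox <- c(min(cells0[, 1]) * mask$stride, min(cells0[, 2]) * mask$stride,
              max(cells0[, 1]) * mask$stride + mask$window,
              max(cells0[, 2]) * mask$stride + mask$window)
    mp <- if (!is.null(pmap)) mean(pmap$grid[cells]) else NA_real_
    regions[[cur]] <- structure(
      list(id = cur, cells = cells0, area_cells = nrow(cells0),
           bbox = bbox, mean_prob = mp),
      class = "lesion_region")
  }
  ord <- order(vapply(regions, `[[`, integer(1), "area_cells"),
               decreasing = TRUE)
  regions[ord]
}

#' Write probability map, mask and regions to disk
#'
#' The map is serialized as CSV (`grid` and `coverage` long format), the
#' mask as a grid-resolution PNG, and the regions as a BED-like TSV.
#'
#' @param pmap a [build_probability_map()] result.
#' @param mask a [threshold_mask()] result.
#' @param regions a [mask_to_regions()] result.
#' @param dir output directory (created if missing).
#' @param slide_id identifier used in file contents.
#' @return invisibly, the vector of files written.
#' @export
write_map_artifacts <- function(pmap, mask, regions, dir, slide_id = "slide") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  grid_df <- data.frame(
    grid_row = rep(seq_len(nrow(pmap$grid)) - 1L, ncol(pmap$grid)),
    grid_col = rep(seq_len(ncol(pmap$grid)) - 1L, each = nrow(pmap$grid)),
    prob = as.vector(pmap$grid), coverage = as.vector(pmap$coverage))
  f <- file.path(dir, "probability_map.csv")
  utils::write.csv(grid_df, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "mask_grid.png")
  png::writePNG(mask$mask * 1, f); files <- c(files, f)
  reg_df <- if (length(regions)) data.frame(
    slide_id = slide_id,
    x_min = vapply(regions, function(r) r$bbox[2], numeric(1)),
    y_min = vapply(regions, function(r) r$bbox[1], numeric(1)),
    x_max = vapply(regions, function(r) r$bbox[4], numeric(1)),
    y_max = vapply(regions, function(r) r$bbox[3], numeric(1)),
    area_cells = vapply(regions, `[[`, integer(1), "area_cells"),
    mean_prob = vapply(regions, `[[`, numeric(1), "mean_prob"))
  else data.frame(slide_id = character(), x_min = numeric(),
                  y_min = numeric(), x_max = numeric(), y_max = numeric(),
                  area_cells = integer(), mean_prob = numeric())
  f <- file.path(dir, "regions.tsv")
  utils::write.table(reg_df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  invisible(files)
}
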