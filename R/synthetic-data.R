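# Seeded generator of H&E-like synthetic slides: near-white glass
# background, elliptical tissue blobs filled with eosin-pink stroma, and
# per-class nucleus textures. Malignant regions carry larger, darker,
# more eccentric and more irregular nuclei than benign regions -- the
# visual contrast the classifier must learn -- plus a per-pixel
# ground-truth region mask from which patch labels are derived.

#' Per-class nucleus parameters
#'
#' @param radius_mean,radius_sd nucleus radius distribution in pixels
#'   (normal, clamped at 2 px).
#' @param darkness stain intensity in \[0,1\]: blend weight of the nucleus
#'   colour over the stroma.
#' @param eccentricity axis elongation in \[0,1).
#' @param irregularity relative amplitude of the radial boundary
#'   perturbation.
#' @param density expected nuclei per pixel of region area.
#' @export
nucleus_params <- function(radius_mean, radius_sd, darkness, eccentricity,
                           irregularity, density) {
  stopifnot(radius_mean > 0, darkness >= 0, darkness <= 1,
            eccentricity >= 0, eccentricity < 1, density >= 0)
  list(radius_mean = radius_mean, radius_sd = radius_sd,
       darkness = darkness, eccentricity = eccentricity,
       irregularity = irregularity, density = density)
}

#' Synthetic slide specification
#'
#' Defaults give a clearly separable benign/malignant contrast: malignant
#' nuclei are larger, darker, denser, more eccentric and more irregular
#' than benign ones (enlarged, darkly stained nuclei with varying shapes).
#'
#' @param dim slide `c(height, width)` in pixels.
#' @param background near-white glass RGB.
#' @param tissue_color eosin-pink stroma RGB.
#' @param nucleus_color hematoxylin-purple nucleus RGB.
#' @param tissue_fraction target fraction of the slide covered by tissue.
#' @param n_tissue_blobs number of elliptical tissue blobs.
#' @param lesion_fraction target fraction of the tissue that is malignant.
#' @param n_lesion_blobs number of lesion ellipses (each concentric with a
#'   tissue blob, so lesions never touch background).
#' @param benign,malignant [nucleus_params()] per class; the malignant
#'   radius mean and darkness must exceed the benign ones.
#' @param noise_sd Gaussian pixel noise, 8-bit scale.
#' @param label_threshold a patch is malignant iff at least this fraction
#'   of its tissue pixels is malignant (generator convention).
#' @param min_tissue minimum tissue fraction for a patch to carry a
#'   malignant label at all (aligned with the tissue filter default).
#' @param seed RNG seed.
#' @export
synthetic_slide_spec <- function(dim = c(2048L, 2048L),
                                 background = c(246, 245, 247),
                                 tissue_color = c(233, 199, 211),
                                 nucleus_color = c(72, 48, 118),
                                 tissue_fraction = 0.5,
                                 n_tissue_blobs = 3L,
                                 lesion_fraction = 0.4,
                                 n_lesion_blobs = 1L,
                                 benign = nucleus_params(7, 1.5, 0.55, 0.25, 0.05, 6e-4),
                                 malignant = nucleus_params(10, 2.5, 0.80, 0.55, 0.25, 8e-4),
                                 noise_sd = 2.5,
                                 label_threshold = 0.5,
                                 min_tissue = 0.10,
                                 seed = 1L) {
  dim <- as.integer(unlist(dim))
  if (length(dim) != 2L || any(is.na(dim)) || any(dim < 32L))
    stop("degenerate slide dimensions", call. = FALSE)
  if (malignant$radius_mean <= benign$radius_mean)
    stop("malignant nuclei must be larger than benign on average", call. = FALSE)
  if (malignant$darkness <= benign$darkness)
    stop("malignant nuclei must be darker than benign", call. = FALSE)
  stopifnot(tissue_fraction >= 0, tissue_fraction <= 1,
            lesion_fraction >= 0, lesion_fraction <= 1,
            n_lesion_blobs <= n_tissue_blobs)
  structure(list(dim = as.integer(dim), background = background,
                 tissue_color = tissue_color, nucleus_color = nucleus_color,
                 tissue_fraction = tissue_fraction,
                 n_tissue_blobs = as.integer(n_tissue_blobs),
                 lesion_fraction = lesion_fraction,
                 n_lesion_blobs = as.integer(n_lesion_blobs),
                 benign = benign, malignant = malignant,
                 noise_sd = noise_sd, label_threshold = label_threshold,
                 min_tissue = min_tissue, seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# mark the inside of a rotated ellipse on a logical matrix (bbox-local)
mark_ellipse <- function(mask, cy, cx, a, b, theta) {
  H <- nrow(mask); W <- ncol(mask)
  rmax <- max(a, b)
  rows <- max(1L, floor(cy - rmax)):min(H, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(W, ceiling(cx + rmax))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (y * ct + x * st) / a)
  v <- outer(dy, dx, function(y, x) (-y * st + x * ct) / b)
  mask[rows, cols] <- mask[rows, cols] | (u^2 + v^2 <= 1)
  mask
}

# nucleus radii: normal, clamped at 2 px
sample_nucleus_radius <- function(n, params) {
  pmax(2, stats::rnorm(n, params$radius_mean, params$radius_sd))
}

draw_nucleus_field <- function(img, region_ok, centers, params,
                               nucleus_color) {
  # img: H x W x 3 numeric; region_ok: logical H x W restricting the stain
  H <- dim(img)[1]; W <- dim(img)[2]
  n <- nrow(centers)
  if (n == 0L) return(img)
  radius <- sample_nucleus_radius(n, params)
  theta <- stats::runif(n, 0, pi)
  ph1 <- stats::runif(n, 0, 2 * pi)
  ph2 <- stats::runif(n, 0, 2 * pi)
  for (i in seq_len(n)) {
    r <- radius[i]
    a <- r * (1 + params$eccentricity)
    b <- r * (1 - params$eccentricity)
    cy <- centers[i, 1]; cx <- centers[i, 2]
    rmax <- ceiling(a * (1 + params$irregularity) + 1)
    rows <- max(1L, floor(cy - rmax)):min(H, ceiling(cy + rmax))
    cols <- max(1L, floor(cx - rmax)):min(W, ceiling(cx + rmax))
    dy <- rows - cy
    dx <- cols - cx
    ct <- cos(theta[i]); st <- sin(theta[i])
    u <- outer(dy, dx, function(y, x) (y * ct + x * st) / a)
    v <- outer(dy, dx, function(y, x) (-y * st + x * ct) / b)
    phi <- atan2(outer(dy, dx, function(y, x) y),
                 outer(dy, dx, function(y, x) x))
    rad_scale <- 1 + params$irregularity *
      (sin(3 * phi + ph1[i]) + 0.5 * sin(5 * phi + ph2[i]))
    rad_scale[rad_scale < 0.3] <- 0.3
    d <- sqrt(u^2 + v^2) / rad_scale
    alpha <- pmin(pmax((1 - d) * b + 0.5, 0), 1)   # ~1 px anti-alias band
    alpha <- alpha * region_ok[rows, cols]
    if (all(alpha == 0)) next
    wgt <- alpha * params$darkness
    for (ch in 1:3)
      img[rows, cols, ch] <- img[rows, cols, ch] * (1 - wgt) +
        nucleus_color[ch] * wgt
  }
  img
}

#' Generate a synthetic H&E-like slide with ground truth
#'
#' Fully seeded and reproducible: the same spec (including seed) yields a
#' byte-identical image and mask.
#'
#' @param spec a [synthetic_slide_spec()].
#' @return object of class `synthetic_slide`: `image` (a [slide_image()]),
#'   `region_mask` (integer matrix, 0 background / 1 benign / 2 malignant)
#'   and the `spec`.
#' @export
generate_slide <- function(spec = synthetic_slide_spec()) {
  set.seed(spec$seed)
  H <- spec$dim[1]; W <- spec$dim[2]
  tissue <- matrix(FALSE, H, W)
  lesion <- matrix(FALSE, H, W)
  nb <- spec$n_tissue_blobs
  area_per_blob <- spec$tissue_fraction * H * W / nb
  centers <- cbind(stats::runif(nb, 0.25 * H, 0.75 * H),
                   stats::runif(nb, 0.25 * W, 0.75 * W))
  stretch <- stats::runif(nb, 0, 0.5)
  angles <- stats::runif(nb, 0, pi)
  lesion_scale <- if (spec$n_lesion_blobs > 0)
    min(0.85, sqrt(spec$lesion_fraction * nb / spec$n_lesion_blobs)) else 0
  for (i in seq_len(nb)) {
    a <- sqrt(area_per_blob / pi) * (1 + stretch[i])
    b <- area_per_blob / (pi * a)
    tissue <- mark_ellipse(tissue, centers[i, 1], centers[i, 2], a, b,
                           angles[i])
    if (i <= spec$n_lesion_blobs && spec$lesion_fraction > 0)
      lesion <- mark_ellipse(lesion, centers[i, 1], centers[i, 2],
                             a * lesion_scale, b * lesion_scale, angles[i])
  }
  lesion <- lesion & tissue
  region <- matrix(0L, H, W)
  region[tissue] <- 1L
  region[lesion] <- 2L
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$background[ch], H, W)
    plane[tissue] <- spec$tissue_color[ch]
    img[, , ch] <- plane
  }
  for (cls in 1:2) {
    params <- if (cls == 1L) spec$benign else spec$malignant
    ok <- region == cls
    npx <- sum(ok)
    nn <- stats::rpois(1, params$density * npx)
    if (nn > 0L && npx > 0L) {
      pick <- sample.int(npx, nn, replace = TRUE)
      idx <- which(ok)[pick]
      centers_n <- cbind((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L)
      img <- draw_nucleus_field(img, ok, centers_n, params,
                                spec$nucleus_color)
    }
  }
  img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 255)
  structure(list(image = slide_image(img, source_path = "<synthetic>"),
                 region_mask = region, spec = spec),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %d x %d px, tissue %.1f%%, malignant %.1f%% of tissue\n",
              nrow(x$region_mask), ncol(x$region_mask),
              100 * mean(x$region_mask > 0),
              100 * sum(x$region_mask == 2L) / max(1, sum(x$region_mask > 0))))
  invisible(x)
}

#' Derive ground-truth patch labels from a region mask
#'
#' A patch is malignant iff its tissue fraction is at least `min_tissue`
#' and at least `label_threshold` of its tissue pixels are malignant.
#'
#' @param region_mask integer matrix (0 background / 1 benign /
#'   2 malignant).
#' @param spec a [tiling_spec()].
#' @param label_threshold,min_tissue generator label convention (defaults
#'   from [synthetic_slide_spec()]).
#' @return integer matrix of 0/1 labels over the tile grid, with
#'   attributes `tissue_fraction` and `malignant_fraction` (matrices of
#'   the underlying per-patch fractions).
#' @export
patch_labels_from_mask <- function(region_mask, spec, label_threshold = 0.5,
                                   min_tissue = 0.10) {
  H <- nrow(region_mask); W <- ncol(region_mask)
  nr <- n_tiles(H, spec$window, spec$stride)
  nc <- n_tiles(W, spec$window, spec$stride)
  tf <- matrix(0, nr, nc); mf <- matrix(0, nr, nc)
  for (gc in seq_len(nc)) for (gr in seq_len(nr)) {
    r0 <- (gr - 1L) * spec$stride; c0 <- (gc - 1L) * spec$stride
    sub <- region_mask[(r0 + 1L):(r0 + spec$window),
                       (c0 + 1L):(c0 + spec$window)]
    tpx <- sum(sub > 0L)
    tf[gr, gc] <- tpx / length(sub)
    mf[gr, gc] <- if (tpx > 0L) sum(sub == 2L) / tpx else 0
  }
  labels <- matrix(as.integer(tf >= min_tissue & mf >= label_threshold),
                   nr, nc)
  attr(labels, "tissue_fraction") <- tf
  attr(labels, "malignant_fraction") <- mf
  labels
}

render_texture_patch <- function(patch_size, params, spec) {
  # single-class tissue texture (uses the current RNG state)
  img <- array(0, dim = c(patch_size, patch_size, 3))
  for (ch in 1:3) img[, , ch] <- spec$tissue_color[ch]
  ok <- matrix(TRUE, patch_size, patch_size)
  nn <- stats::rpois(1, params$density * patch_size^2)
  if (nn > 0L) {
    centers <- cbind(stats::runif(nn, 1, patch_size),
                     stats::runif(nn, 1, patch_size))
    img <- draw_nucleus_field(img, ok, centers, params, spec$nucleus_color)
  }
  img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  pmin(pmax(img, 0), 255)
}

#' Generate a labeled single-class patch dataset
#'
#' Renders `n_patches` pure benign or pure malignant tissue textures at
#' the requested class balance, crops the standard six-image sub-patch set
#' from each and normalizes to `input_size`. The result feeds
#' [train_model()] directly.
#'
#' @param n_patches number of patches (>= 2).
#' @param class_balance malignant fraction in (0,1).
#' @param patch_size rendered patch side in pixels (even).
#' @param spec a [synthetic_slide_spec()] supplying colours and nucleus
#'   statistics.
#' @param seed RNG seed.
#' @param input_size network input side the six images are resized to.
#' @return list of `n_patches` entries `list(images, label)`, `images`
#'   an `input_size x input_size x 3 x 6` array in \[0,1\]; shuffled order.
#' @export
generate_patch_dataset <- function(n_patches, class_balance = 0.5,
                                   patch_size = 256L,
                                   spec = synthetic_slide_spec(),
                                   seed = 1L, input_size = 64L) {
  if (n_patches < 2L) stop("need at least 2 patches", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must be in (0,1)", call. = FALSE)
  n_mal <- round(n_patches * class_balance)
  if (n_mal == 0L || n_mal == n_patches)
    stop("class balance unreachable at this dataset size", call. = FALSE)
  set.seed(seed)
  labels <- sample(c(rep(1, n_mal), rep(0, n_patches - n_mal)))
  out <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    params <- if (labels[i] == 1) spec$malignant else spec$benign
    px <- render_texture_patch(patch_size, params, spec)
    crops <- crop_subpatches(px, input_size = input_size)
    images <- array(0, dim = c(input_size, input_size, 3L, 6L))
    for (j in 1:6) images[, , , j] <- crops[[j]]
    out[[i]] <- list(images = images, label = labels[i])
  }
  out
}
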