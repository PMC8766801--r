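# The patch-classification network: residual backbone with optional
# deformable convolution and channel attention, multi-scale fusion
# branches, and a shortcut-connected fully connected head ending in a
# single sigmoid malignancy output.

#' Network configuration
#'
#' @param depth backbone depth: 18 (basic blocks) or 50/101 (bottleneck).
#' @param base_width channels of the first stage before expansion
#'   (64 for the full-scale network; small values give desk-scale models).
#' @param dc_stages backbone stages whose 3x3 convolution is deformable,
#'   subset of `c("conv2","conv3","conv4","conv5")`.
#' @param ca_placement where channel attention is applied, subset of
#'   `c("backbone","shortcut")`: inside every residual block, and/or on each
#'   branch feeding the fully connected head.
#' @param fusion_branches enabled fusion maps, a contiguous suffix of
#'   `c("F4","F3","F2")` (F5 always exists).
#' @param input_size network input side; must be divisible by 32.
#' @param penultimate width of the second-to-last fully connected layer.
#' @param reduction_ratio channel-attention squeeze ratio.
#' @param dilation_cap elementwise clamp on learned offsets (kernel-grid
#'   units).
#' @param aggregation how the six per-image penultimate vectors of a patch
#'   are combined before the final layer: `"mean"` (default) or `"concat"`.
#' @param stem_kernel stem convolution size (7 standard; 3 is a common
#'   small-image variant).
#' @return a `network_config` list.
#' @export
network_config <- function(depth = 50L,
                           base_width = 64L,
                           dc_stages = c("conv2", "conv3", "conv4", "conv5"),
                           ca_placement = c("backbone", "shortcut"),
                           fusion_branches = c("F4", "F3", "F2"),
                           input_size = 512L,
                           penultimate = 1024L,
                           reduction_ratio = 16L,
                           dilation_cap = 2,
                           aggregation = c("mean", "concat"),
                           stem_kernel = 7L) {
  depth <- as.integer(depth)
  if (!depth %in% c(18L, 50L, 101L))
    stop("depth must be one of 18, 50, 101", call. = FALSE)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32", call. = FALSE)
  if (length(dc_stages))
    dc_stages <- match.arg(dc_stages, c("conv2", "conv3", "conv4", "conv5"),
                           several.ok = TRUE)
  if (length(ca_placement))
    ca_placement <- match.arg(ca_placement, c("backbone", "shortcut"),
                              several.ok = TRUE)
  allowed <- list(character(), "F4", c("F4", "F3"), c("F4", "F3", "F2"))
  fb <- sort(fusion_branches, decreasing = TRUE)
  if (!any(vapply(allowed, identical, logical(1), y = fb)))
    stop("fusion_branches must be a contiguous suffix of F4, F3, F2",
         call. = FALSE)
  structure(list(depth = depth, base_width = as.integer(base_width),
                 dc_stages = dc_stages, ca_placement = ca_placement,
                 fusion_branches = fb, input_size = as.integer(input_size),
                 penultimate = as.integer(penultimate),
                 reduction_ratio = as.integer(reduction_ratio),
                 dilation_cap = dilation_cap,
                 aggregation = match.arg(aggregation),
                 stem_kernel = as.integer(stem_kernel)),
            class = "network_config")
}

stage_plan <- function(config) {
  blocks <- switch(as.character(config$depth),
                   "18" = c(2L, 2L, 2L, 2L),
                   "50" = c(3L, 4L, 6L, 3L),
                   "101" = c(3L, 4L, 23L, 3L))
  expansion <- if (config$depth == 18L) 1L else 4L
  widths <- config$base_width * c(1L, 2L, 4L, 8L)
  list(blocks = blocks, expansion = expansion, widths = widths,
       out_channels = widths * expansion)
}

# ---- residual blocks ------------------------------------------------------

make_block <- function(c_in, width, expansion, stride, deformable, use_ca,
                       reduction_ratio, dilation_cap) {
  b <- new.env(parent = emptyenv())
  b$bottleneck <- expansion > 1L
  c_out <- width * expansion
  mk3 <- function(ci, co, s) {
    if (deformable) layer_dconv(ci, co, 3L, stride = s, pad = 1L,
                                dilation_cap = dilation_cap)
    else layer_conv(ci, co, 3L, stride = s, pad = 1L)
  }
  if (b$bottleneck) {
    b$conv1 <- layer_conv(c_in, width, 1L, pad = 0L)
    b$bn1 <- layer_bn(width)
    b$relu1 <- layer_relu()
    b$conv2 <- mk3(width, width, stride)
    b$bn2 <- layer_bn(width)
    b$relu2 <- layer_relu()
    b$conv3 <- layer_conv(width, c_out, 1L, pad = 0L)
    b$bn3 <- layer_bn(c_out)
  } else {
    b$conv1 <- layer_conv(c_in, width, 3L, stride = stride, pad = 1L)
    b$bn1 <- layer_bn(width)
    b$relu1 <- layer_relu()
    b$conv2 <- mk3(width, c_out, 1L)
    b$bn2 <- layer_bn(c_out)
  }
  b$ca <- if (use_ca) layer_ca(c_out, reduction_ratio) else NULL
  if (stride != 1L || c_in != c_out) {
    b$down_conv <- layer_conv(c_in, c_out, 1L, stride = stride, pad = 0L)
    b$down_bn <- layer_bn(c_out)
  }
  b$relu_out <- layer_relu()
  b$c_out <- c_out
  b
}

block_layers <- function(b) {
  nms <- c("conv1", "bn1", "relu1", "conv2", "bn2", "relu2", "conv3", "bn3",
           "ca", "down_conv", "down_bn", "relu_out")
  Filter(Negate(is.null), lapply(nms, function(n) b[[n]]))
}

block_forward <- function(b, x, training = FALSE) {
  h <- nn_forward(b$conv1, x, training)
  h <- nn_forward(b$bn1, h, training)
  h <- nn_forward(b$relu1, h, training)
  h <- nn_forward(b$conv2, h, training)
  h <- nn_forward(b$bn2, h, training)
  if (b$bottleneck) {
    h <- nn_forward(b$relu2, h, training)
    h <- nn_forward(b$conv3, h, training)
    h <- nn_forward(b$bn3, h, training)
  }
  if (!is.null(b$ca)) h <- nn_forward(b$ca, h, training)
  skip <- if (!is.null(b$down_conv)) {
    s <- nn_forward(b$down_conv, x, training)
    nn_forward(b$down_bn, s, training)
  } else x
  nn_forward(b$relu_out, h + skip, training)
}

block_backward <- function(b, dy) {
  d <- nn_backward(b$relu_out, dy)
  dskip <- d
  dh <- d
  if (!is.null(b$ca)) dh <- nn_backward(b$ca, dh)
  if (b$bottleneck) {
    dh <- nn_backward(b$bn3, dh)
    dh <- nn_backward(b$conv3, dh)
    dh <- nn_backward(b$relu2, dh)
  }
  dh <- nn_backward(b$bn2, dh)
  dh <- nn_backward(b$conv2, dh)
  dh <- nn_backward(b$relu1, dh)
  dh <- nn_backward(b$bn1, dh)
  dx <- nn_backward(b$conv1, dh)
  if (!is.null(b$down_conv)) {
    ds <- nn_backward(b$down_bn, dskip)
    dx <- dx + nn_backward(b$down_conv, ds)
  } else {
    dx <- dx + dskip
  }
  dx
}

# ---- model builder --------------------------------------------------------

#' Build the patch-classification model
#'
#' Constructs the residual backbone (stem + stages Conv2..Conv5), the
#' enabled multi-scale fusion branches and the fully connected head with
#' randomly initialized weights drawn from the current R RNG state
#' (call [set.seed()] first for reproducibility). Offset-predicting
#' convolutions of deformable layers start at zero, so a freshly built
#' model behaves exactly like its non-deformable counterpart.
#'
#' @param config a [network_config()].
#' @return an object of class `melmap_model`.
#' @export
build_model <- function(config) {
  sp <- stage_plan(config)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$stem_conv <- layer_conv(3L, config$base_width, config$stem_kernel,
                            stride = 2L,
                            pad = (config$stem_kernel - 1L) %/% 2L)
  m$stem_bn <- layer_bn(config$base_width)
  m$stem_relu <- layer_relu()
  m$pool <- layer_maxpool(3L, 2L, 1L)
  ca_backbone <- "backbone" %in% config$ca_placement
  m$stages <- vector("list", 4L)
  c_in <- config$base_width
  for (s in 1:4) {
    stage_name <- paste0("conv", s + 1L)
    deform <- stage_name %in% config$dc_stages
    stride1 <- if (s == 1L) 1L else 2L
    nb <- sp$blocks[s]
    blocks <- vector("list", nb)
    for (j in seq_len(nb)) {
      blocks[[j]] <- make_block(c_in, sp$widths[s], sp$expansion,
                                stride = if (j == 1L) stride1 else 1L,
                                deformable = deform, use_ca = ca_backbone,
                                reduction_ratio = config$reduction_ratio,
                                dilation_cap = config$dilation_cap)
      c_in <- blocks[[j]]$c_out
    }
    m$stages[[s]] <- blocks
  }
  ch <- sp$out_channels  # channels of C2..C5
  # fusion branches: F5 = C5; F_i = concat(BN(up2(1x1(F_{i+1}))), BN(C_i))
  m$fusion <- list()
  f_ch <- c(C2 = ch[1], C3 = ch[2], C4 = ch[3], C5 = ch[4])
  prev_ch <- ch[4]
  branch_ch <- c(F5 = ch[4])
  for (nm in c("F4", "F3", "F2")) {
    if (!nm %in% config$fusion_branches) break
    i <- as.integer(substring(nm, 2)) - 1L  # stage index 1..3 for C_i
    lat_out <- ch[i]
    fz <- new.env(parent = emptyenv())
    fz$lat <- layer_conv(prev_ch, lat_out, 1L, pad = 0L)
    fz$up <- layer_upsample2()
    fz$bn_lat <- layer_bn(lat_out)
    fz$bn_skip <- layer_bn(ch[i])
    fz$c_lat <- lat_out
    fz$c_skip <- ch[i]
    m$fusion[[nm]] <- fz
    prev_ch <- lat_out + ch[i]
    branch_ch[nm] <- prev_ch
  }
  m$branch_names <- names(branch_ch)
  m$branch_ch <- branch_ch
  # head: per-branch shortcut channel attention + GAP, concat, FC layers
  ca_short <- "shortcut" %in% config$ca_placement
  m$head_ca <- stats::setNames(
    lapply(branch_ch, function(cc)
      if (ca_short) layer_ca(cc, config$reduction_ratio) else NULL),
    names(branch_ch))
  m$head_gap <- stats::setNames(
    lapply(branch_ch, function(cc) layer_gap()), names(branch_ch))
  d_in <- sum(branch_ch)
  m$fc1 <- layer_fc(d_in, config$penultimate)
  m$fc1_relu <- layer_relu()
  n_images <- 6L
  fc2_in <- if (config$aggregation == "concat")
    config$penultimate * n_images else config$penultimate
  m$fc2 <- layer_fc(fc2_in, 1L)
  m$layers <- model_layers(m)
  class(m) <- "melmap_model"
  m
}

model_layers <- function(m) {
  ls <- list(m$stem_conv, m$stem_bn, m$stem_relu, m$pool)
  for (st in m$stages)
    for (b in st) ls <- c(ls, block_layers(b))
  for (fz in m$fusion)
    ls <- c(ls, list(fz$lat, fz$up, fz$bn_lat, fz$bn_skip))
  for (nm in names(m$head_ca))
    if (!is.null(m$head_ca[[nm]])) ls <- c(ls, list(m$head_ca[[nm]]))
  ls <- c(ls, unname(m$head_gap), list(m$fc1, m$fc1_relu, m$fc2))
  ls
}

#' @export
print.melmap_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$layers, function(l)
    sum(vapply(l$params, function(p) length(l[[p]]), numeric(1))), numeric(1)))
  cat(sprintf(
    "<melmap_model> depth %d, base width %d, input %d, %s fusion, %d params\n",
    cfg$depth, cfg$base_width, cfg$input_size,
    paste(c("F5", cfg$fusion_branches), collapse = "/"), np))
  invisible(x)
}

#' Backbone forward pass
#'
#' Runs the stem and the four residual stages, returning the stage outputs
#' `F_Conv2 .. F_Conv5` at spatial strides 4, 8, 16 and 32 relative to the
#' input.
#'
#' @param model a [build_model()] result.
#' @param x input tensor `H x W x 3 x N` with `H = W` divisible by 32,
#'   or a single `H x W x 3` image.
#' @param training keep caches for a backward pass and use batch statistics
#'   in normalization layers.
#' @return named list of four feature maps `C2`, `C3`, `C4`, `C5`.
#' @export
backbone_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] %% 32L != 0L || dim(x)[2] %% 32L != 0L)
    stop("input side must be divisible by 32", call. = FALSE)
  h <- nn_forward(model$stem_conv, x, training)
  h <- nn_forward(model$stem_bn, h, training)
  h <- nn_forward(model$stem_relu, h, training)
  h <- nn_forward(model$pool, h, training)
  feats <- vector("list", 4L)
  for (s in 1:4) {
    for (b in model$stages[[s]]) h <- block_forward(b, h, training)
    feats[[s]] <- h
  }
  names(feats) <- c("C2", "C3", "C4", "C5")
  feats
}

backbone_backward <- function(model, dfeats) {
  # dfeats: named list C2..C5 of gradients (any may be contributed to by
  # both the next stage and a fusion skip connection)
  d <- dfeats$C5
  for (s in 4:1) {
    for (b in rev(model$stages[[s]])) d <- block_backward(b, d)
    if (s > 1L) d <- d + dfeats[[paste0("C", s)]]
  }
  d <- nn_backward(model$pool, d)
  d <- nn_backward(model$stem_relu, d)
  d <- nn_backward(model$stem_bn, d)
  nn_backward(model$stem_conv, d)
}

fusion_forward <- function(model, feats, training = FALSE) {
  maps <- list(F5 = feats$C5)
  prev <- feats$C5
  for (nm in names(model$fusion)) {
    fz <- model$fusion[[nm]]
    i <- as.integer(substring(nm, 2)) - 1L
    ci <- feats[[paste0("C", i + 1L)]]
    lat <- nn_forward(fz$lat, prev, training)
    up <- nn_forward(fz$up, lat, training)
    a <- nn_forward(fz$bn_lat, up, training)
    b <- nn_forward(fz$bn_skip, ci, training)
    d <- dim(a)
    out <- array(0, dim = c(d[1], d[2], fz$c_lat + fz$c_skip, d[4]))
    out[, , seq_len(fz$c_lat), ] <- a
    out[, , fz$c_lat + seq_len(fz$c_skip), ] <- b
    maps[[nm]] <- out
    prev <- out
  }
  maps
}

fusion_backward <- function(model, dmaps) {
  # dmaps: gradients w.r.t. each branch map from the head; returns
  # gradients w.r.t. the backbone stage outputs C2..C5.
  dC <- list(C2 = NULL, C3 = NULL, C4 = NULL, C5 = NULL)
  fnames <- rev(names(model$fusion))  # shallowest first, e.g. F2, F3, F4
  carry <- NULL
  for (nm in fnames) {
    fz <- model$fusion[[nm]]
    i <- as.integer(substring(nm, 2)) - 1L
    dmap <- dmaps[[nm]]
    if (!is.null(carry)) dmap <- dmap + carry
    da <- dmap[, , seq_len(fz$c_lat), , drop = FALSE]
    db <- dmap[, , fz$c_lat + seq_len(fz$c_skip), , drop = FALSE]
    dC[[paste0("C", i + 1L)]] <- nn_backward(fz$bn_skip, db)
    dup <- nn_backward(fz$bn_lat, da)
    dlat <- nn_backward(fz$up, dup)
    carry <- nn_backward(fz$lat, dlat)  # gradient w.r.t. previous branch map
  }
  dC5 <- dmaps$F5
  if (!is.null(carry)) dC5 <- dC5 + carry
  dC$C5 <- dC5
  for (nm in c("C2", "C3", "C4"))
    if (is.null(dC[[nm]])) dC[[nm]] <- 0
  dC
}

#' Full network forward pass
#'
#' @param model a [build_model()] result.
#' @param x image tensor `H x W x 3 x N`; images belonging to one patch
#'   must be contiguous.
#' @param group_size images per patch (6 for the standard sub-patch set;
#'   1 treats each image as its own patch).
#' @param training training mode (caches + batch statistics).
#' @return list with `logits` (length `N / group_size`), `prob`,
#'   `penultimate` (matrix `penultimate x n_patches`, the aggregated
#'   second-to-last-layer features), and `branch_maps` (training = FALSE
#'   only on request).
#' @export
network_forward <- function(model, x, group_size = 1L, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[4]
  stopifnot(N %% group_size == 0L)
  G <- N %/% group_size
  feats <- backbone_forward(model, x, training)
  maps <- fusion_forward(model, feats, training)
  vecs <- vector("list", length(maps))
  for (j in seq_along(model$branch_names)) {
    nm <- model$branch_names[j]
    h <- maps[[nm]]
    if (!is.null(model$head_ca[[nm]]))
      h <- nn_forward(model$head_ca[[nm]], h, training)
    vecs[[j]] <- nn_forward(model$head_gap[[nm]], h, training)
  }
  z <- do.call(rbind, vecs)                       # D x N
  p <- nn_forward(model$fc1, z, training)
  p <- nn_forward(model$fc1_relu, p, training)    # penultimate per image
  if (model$config$aggregation == "concat" && group_size > 1L) {
    pm <- p
    dim(pm) <- c(nrow(p) * group_size, G)
  } else if (group_size > 1L) {
    pm <- p %*% group_mean_matrix(group_size, G)
  } else {
    pm <- p
  }
  logits <- nn_forward(model$fc2, pm, training)
  if (training) {
    model$cache <- list(group_size = group_size, G = G, N = N,
                        pen_width = nrow(p))
  }
  list(logits = as.numeric(logits),
       prob = as.numeric(stats::plogis(logits)),
       penultimate = pm)
}

network_backward <- function(model, dlogits) {
  cc <- model$cache
  dlog <- matrix(dlogits, nrow = 1L)
  dpm <- nn_backward(model$fc2, dlog)
  g <- cc$group_size
  if (model$config$aggregation == "concat" && g > 1L) {
    dp <- dpm
    dim(dp) <- c(cc$pen_width, cc$N)
  } else if (g > 1L) {
    dp <- dpm[, rep(seq_len(cc$G), each = g), drop = FALSE] / g
  } else {
    dp <- dpm
  }
  dp <- nn_backward(model$fc1_relu, dp)
  dz <- nn_backward(model$fc1, dp)
  # split the concatenated branch vectors
  dmaps <- list()
  r0 <- 0L
  for (j in seq_along(model$branch_names)) {
    nm <- model$branch_names[j]
    cb <- model$branch_ch[[nm]]
    dv <- dz[r0 + seq_len(cb), , drop = FALSE]
    r0 <- r0 + cb
    dh <- nn_backward(model$head_gap[[nm]], dv)
    if (!is.null(model$head_ca[[nm]]))
      dh <- nn_backward(model$head_ca[[nm]], dh)
    dmaps[[nm]] <- dh
  }
  dC <- fusion_backward(model, dmaps)
  backbone_backward(model, dC)
}

#' Head forward on precomputed branch maps
#'
#' Applies per-branch shortcut attention and pooling, concatenates the
#' branch vectors and runs the fully connected layers. Mostly useful for
#' inspecting the head in isolation; [network_forward()] is the standard
#' entry point.
#'
#' @param model a [build_model()] result.
#' @param maps named list of branch maps (`F5`, and `F4`/`F3`/`F2` when
#'   enabled), each `H x W x C x N`.
#' @param group_size images per patch.
#' @return list with `prob` and `penultimate` as in [network_forward()].
#' @export
head_forward <- function(model, maps, group_size = 1L) {
  vecs <- lapply(model$branch_names, function(nm) {
    h <- maps[[nm]]
    if (length(dim(h)) == 3L) dim(h) <- c(dim(h), 1L)
    if (!is.null(model$head_ca[[nm]]))
      h <- nn_forward(model$head_ca[[nm]], h)
    nn_forward(model$head_gap[[nm]], h)
  })
  z <- do.call(rbind, vecs)
  p <- nn_forward(model$fc1, z)
  p <- nn_forward(model$fc1_relu, p)
  N <- ncol(p); G <- N %/% group_size
  if (model$config$aggregation == "concat" && group_size > 1L) {
    dim(p) <- c(nrow(p) * group_size, G)
    pm <- p
  } else if (group_size > 1L) {
    pm <- p %*% group_mean_matrix(group_size, G)
  } else pm <- p
  logits <- nn_forward(model$fc2, pm)
  list(prob = as.numeric(stats::plogis(logits)), penultimate = pm)
}

#' Patch prediction record
#' @param label predicted class, 0 benign / 1 malignant.
#' @param prob malignancy confidence in \[0,1\].
#' @param grid_row,grid_col tile indices of the patch.
#' @export
patch_prediction <- function(label, prob, grid_row = NA_integer_,
                             grid_col = NA_integer_) {
  structure(list(label = as.integer(label), prob = as.numeric(prob),
                 grid_row = as.integer(grid_row),
                 grid_col = as.integer(grid_col)),
            class = "patch_prediction")
}

group_mean_matrix <- function(g, G) {
  kronecker(diag(G), matrix(1 / g, g, 1L))
}

stack_images <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, dim = c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

#' Classify one patch from its sub-patch set
#'
#' Runs the six normalized images (whole patch + five sub-patches) through
#' the shared-weight network, averages the per-image penultimate vectors
#' and applies the final layer. The predicted label is malignant when the
#' probability is >= 0.5 (inclusive).
#'
#' @param model a [build_model()] result.
#' @param subpatches list of 6 normalized images (from [crop_subpatches()]).
#' @param grid_row,grid_col tile indices recorded in the prediction.
#' @return a [patch_prediction()].
#' @export
classify_patch <- function(model, subpatches, grid_row = NA_integer_,
                           grid_col = NA_integer_) {
  if (length(subpatches) != 6L)
    stop("expected 6 images (whole patch + 5 sub-patches)", call. = FALSE)
  x <- stack_images(subpatches)
  out <- network_forward(model, x, group_size = 6L)
  patch_prediction(label = as.integer(out$prob >= 0.5), prob = out$prob,
                   grid_row = grid_row, grid_col = grid_col)
}

#' Extract the aggregated penultimate feature vector of a patch
#'
#' Same computation as [classify_patch()] but returns the averaged
#' second-to-last-layer vector, the representation used for downstream
#' embedding diagnostics.
#'
#' @inheritParams classify_patch
#' @return numeric vector of length `config$penultimate`.
#' @export
extract_penultimate <- function(model, subpatches) {
  if (length(subpatches) != 6L)
    stop("expected 6 images (whole patch + 5 sub-patches)", call. = FALSE)
  x <- stack_images(subpatches)
  out <- network_forward(model, x, group_size = 6L)
  as.numeric(out$penultimate)
}

# ---- functional forms of the core operations ------------------------------

as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

weights_to_matrix <- function(w) {
  # w: c_out x c_in x k x k (kernel taps row-major over the k x k grid)
  d <- dim(w)
  co <- d[1]; ci <- d[2]; k <- d[3]
  W <- matrix(0, k * k * ci, co)
  for (o in seq_len(co))
    for (c in seq_len(ci))
      for (kh in seq_len(k))
        for (kw in seq_len(k))
          W[(c - 1L) * k * k + (kh - 1L) * k + kw, o] <- w[o, c, kh, kw]
  W
}

#' Standard 2-D convolution (functional)
#'
#' @param x feature map `H x W x C` or `H x W x C x N`.
#' @param w kernel array `c_out x c_in x k x k`.
#' @param bias optional length-`c_out` vector.
#' @param stride,pad convolution geometry (pad 0 = valid).
#' @return output feature map (batch dim dropped if the input had none).
#' @export
conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L) {
  had3 <- length(dim(x)) == 3L
  x <- as_batch(x)
  d <- dim(w)
  if (d[2] != dim(x)[3]) stop("kernel/input channel mismatch", call. = FALSE)
  W <- weights_to_matrix(w)
  cols <- cpp_im2col(x, dim(x), d[3], as.integer(stride), as.integer(pad))
  out <- crossprod(W, cols)
  if (!is.null(bias)) out <- out + bias
  Ho <- conv_out_side(dim(x)[1], d[3], stride, pad)
  Wo <- conv_out_side(dim(x)[2], d[3], stride, pad)
  dim(out) <- c(d[1], Ho, Wo, dim(x)[4])
  y <- aperm(out, c(2, 3, 1, 4))
  if (had3) dim(y) <- dim(y)[1:3]
  y
}

#' Deformable 2-D convolution (functional)
#'
#' Computes `y(p) = sum_k w(p_k) x(p + p_k + dp_k)`: each kernel tap is
#' displaced by a learned offset, fractional sample positions are resolved
#' by bilinear interpolation and out-of-bounds samples read zero. Offsets
#' are clamped elementwise to `[-dilation_cap, dilation_cap]`. With all
#' offsets zero this is exactly [conv2d()].
#'
#' @inheritParams conv2d
#' @param offsets array `Ho x Wo x 2*k*k` (or with a batch dim); channel
#'   `2t-1` is the row offset and `2t` the column offset of kernel tap `t`
#'   (taps row-major over the kernel grid).
#' @param dilation_cap maximum resampling distance (default 2).
#' @return output feature map.
#' @export
deform_conv2d <- function(x, w, offsets, bias = NULL, stride = 1L, pad = 0L,
                          dilation_cap = 2) {
  had3 <- length(dim(x)) == 3L
  x <- as_batch(x)
  d <- dim(w)
  k <- d[3]
  if (d[2] != dim(x)[3]) stop("kernel/input channel mismatch", call. = FALSE)
  if (length(dim(offsets)) == 3L) dim(offsets) <- c(dim(offsets), 1L)
  Ho <- conv_out_side(dim(x)[1], k, stride, pad)
  Wo <- conv_out_side(dim(x)[2], k, stride, pad)
  od <- dim(offsets)
  if (od[1] != Ho || od[2] != Wo || od[3] != 2L * k * k || od[4] != dim(x)[4])
    stop("offset field shape does not match the output grid", call. = FALSE)
  W <- weights_to_matrix(w)
  cols <- cpp_deform_im2col(x, dim(x), offsets, k, as.integer(stride),
                            as.integer(pad), dilation_cap)
  out <- crossprod(W, cols)
  if (!is.null(bias)) out <- out + bias
  dim(out) <- c(d[1], Ho, Wo, dim(x)[4])
  y <- aperm(out, c(2, 3, 1, 4))
  if (had3) dim(y) <- dim(y)[1:3]
  y
}

#' Channel attention (functional)
#'
#' Squeeze-excitation gating: per-channel weights
#' `s = sigmoid(W2 relu(W1 mean_{i,j} X(i,j)))` scale each channel of the
#' input. All weights lie strictly inside (0, 1).
#'
#' @param x feature map `H x W x C` (or with a batch dim).
#' @param w1 matrix `c_reduced x C`.
#' @param w2 matrix `C x c_reduced`.
#' @param b1,b2 optional bias vectors (default 0).
#' @return list with `y` (the gated map) and `weights` (the per-channel
#'   gains, one column per batch element).
#' @export
channel_attention <- function(x, w1, w2, b1 = 0, b2 = 0) {
  had3 <- length(dim(x)) == 3L
  x <- as_batch(x)
  xd <- dim(x)
  m2 <- x
  dim(m2) <- c(xd[1] * xd[2], xd[3] * xd[4])
  z <- colMeans(m2)
  dim(z) <- c(xd[3], xd[4])
  a <- w1 %*% z + b1
  a[a < 0] <- 0
  s <- stats::plogis(w2 %*% a + b2)
  y <- sweep(m2, 2, as.vector(s), "*")
  dim(y) <- xd
  if (had3) dim(y) <- xd[1:3]
  list(y = y, weights = s)
}

#' Multi-scale feature fusion (functional)
#'
#' Applies a 1x1 lateral convolution to the deeper map, doubles its spatial
#' size by bilinear up-sampling and concatenates it with the shallower map
#' along channels. The deeper map's spatial dims must be exactly half of
#' the shallower map's.
#'
#' @param f_next deeper feature map `h x w x C_next`.
#' @param f_conv shallower stage output `2h x 2w x C_i`.
#' @param w_lateral matrix `c_out x C_next` of 1x1 convolution weights, or
#'   `NULL` for the identity.
#' @param normalize standardize each group per channel before
#'   concatenation (default `FALSE`; the trained network uses batch
#'   normalization here).
#' @return fused map `2h x 2w x (c_out + C_i)`.
#' @export
fuse_features <- function(f_next, f_conv, w_lateral = NULL, normalize = FALSE) {
  dn <- dim(f_next); dc <- dim(f_conv)
  if (2L * dn[1] != dc[1] || 2L * dn[2] != dc[2])
    stop("deeper map must have exactly half the spatial dims", call. = FALSE)
  lat <- if (is.null(w_lateral)) f_next else {
    if (ncol(w_lateral) != dn[3])
      stop("lateral weights do not match channel count", call. = FALSE)
    m <- matrix(f_next, ncol = dn[3])
    out <- m %*% t(w_lateral)
    array(out, dim = c(dn[1], dn[2], nrow(w_lateral)))
  }
  up <- resize_bilinear(lat, dc[1], dc[2])
  if (normalize) {
    std <- function(a) {
      for (c in seq_len(dim(a)[3])) {
        v <- a[, , c]
        a[, , c] <- (v - mean(v)) / sqrt(stats::var(as.vector(v)) + 1e-5)
      }
      a
    }
    up <- std(up); f_conv <- std(f_conv)
  }
  out <- array(0, dim = c(dc[1], dc[2], dim(up)[3] + dc[3]))
  out[, , seq_len(dim(up)[3])] <- up
  out[, , dim(up)[3] + seq_len(dc[3])] <- f_conv
  out
}

# ---- checkpointing --------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes a single-file checkpoint (RDS with a versioned header) and the
#' network configuration as a YAML sidecar (`<path>.yaml`).
#'
#' @param model a [build_model()] result.
#' @param path output file path.
#' @export
save_checkpoint <- function(model, path) {
  params <- lapply(model$layers, function(l) {
    stats::setNames(lapply(l$params, function(p) l[[p]]), l$params)
  })
  bn_state <- lapply(model$layers, function(l)
    if (inherits(l, "nn_bn")) list(rmean = l$rmean, rvar = l$rvar) else NULL)
  obj <- list(format = "melmap-checkpoint", version = 1L,
              config = unclass(model$config), params = params,
              bn_state = bn_state)
  saveRDS(obj, path)
  yaml::write_yaml(unclass(model$config), paste0(path, ".yaml"))
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a rebuilt [build_model()] with restored weights.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "melmap-checkpoint"))
    stop("not a melmap checkpoint", call. = FALSE)
  cfg <- do.call(network_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- build_model(cfg)
  stopifnot(length(model$layers) == length(obj$params))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    for (p in l$params) l[[p]] <- obj$params[[i]][[p]]
    if (inherits(l, "nn_bn") && !is.null(obj$bn_state[[i]])) {
      l$rmean <- obj$bn_state[[i]]$rmean
      l$rvar <- obj$bn_state[[i]]$rvar
    }
  }
  model
}
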