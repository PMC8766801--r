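# End-to-end orchestration: resolved run configuration (YAML), slide
# prediction, and the tile -> filter -> train/load -> predict -> map ->
# mask -> regions pipeline with reproducibility metadata.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "melmap-run",
    slide_path = NULL,           # when NULL, a synthetic slide is generated
    synth = list(),              # synthetic_slide_spec() overrides
    tiling = list(window = 1024L, stride = 1024L),
    filter = list(saturation_threshold = 0.05, tissue_fraction_min = 0.10),
    network = list(depth = 50L, base_width = 64L,
                   dc_stages = c("conv2", "conv3", "conv4", "conv5"),
                   ca_placement = c("backbone", "shortcut"),
                   fusion_branches = c("F4", "F3", "F2"),
                   input_size = 512L),
    checkpoint = NULL,           # when set, training is skipped
    train = list(epochs = 30L, batch_size = 32L, learning_rate = 0.001,
                 momentum = 0.9, lr_decay = 0.99,
                 n_patches = 600L, class_balance = 0.5, patch_size = 256L),
    map = list(threshold = 0.5)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and resolve a run configuration
#'
#' Reads a YAML file (or takes a list of overrides), merges it over the
#' defaults and validates the schema. Defaults are the full-scale
#' settings: window 1024, stride 1024, input 512, depth 50, 30 epochs,
#' batch 32, lr 0.001, momentum 0.9, decay 0.99, 6:2:2 split, map
#' threshold 0.5.
#'
#' @param config path to a YAML file, or a named list of overrides, or
#'   `NULL` for pure defaults.
#' @return resolved `run_config` list.
#' @export
run_config <- function(config = NULL) {
  cfg <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg <- merge_config(cfg, config)
  }
  stopifnot(cfg$map$threshold >= 0, cfg$map$threshold <= 1)
  cfg$tiling <- cfg$tiling[c("window", "stride")]
  structure(cfg, class = "run_config")
}

#' Classify every tissue patch of a slide
#'
#' Tiles the slide, applies the tissue filter, crops and normalizes the
#' six-image sub-patch set of each tissue patch and classifies it.
#'
#' @param model a trained [build_model()].
#' @param slide a [slide_image()].
#' @param tiling a [tiling_spec()].
#' @param filter_params a [tissue_filter_params()].
#' @param batch_patches patches per forward pass.
#' @return list with `predictions` (list of [patch_prediction()] for
#'   tissue patches), `tissue` (logical per patch), `patches` (all patch
#'   records, pixel payloads dropped).
#' @export
predict_slide <- function(model, slide, tiling = tiling_spec(),
                          filter_params = tissue_filter_params(),
                          batch_patches = 16L) {
  input_size <- model$config$input_size
  patches <- slide_to_patches(slide, tiling)
  tissue <- vapply(patches, tissue_filter, logical(1), params = filter_params)
  keep <- which(tissue)
  preds <- list()
  for (start in seq(1, length(keep), by = batch_patches)) {
    idx <- keep[start:min(start + batch_patches - 1L, length(keep))]
    imgs <- vector("list", 6L * length(idx))
    for (j in seq_along(idx)) {
      crops <- crop_subpatches(patches[[idx[j]]], input_size = input_size)
      for (q in 1:6) imgs[[(j - 1L) * 6L + q]] <- crops[[q]]
    }
    out <- network_forward(model, stack_images(imgs), group_size = 6L)
    for (j in seq_along(idx)) {
      p <- patches[[idx[j]]]
      preds[[length(preds) + 1L]] <- patch_prediction(
        label = as.integer(out$prob[j] >= 0.5), prob = out$prob[j],
        grid_row = p$grid_row, grid_col = p$grid_col)
    }
  }
  meta <- lapply(patches, function(p) p[c("grid_row", "grid_col",
                                          "pixel_row", "pixel_col")])
  list(predictions = preds, tissue = tissue, patches = meta)
}

write_predictions_csv <- function(preds, path) {
  df <- data.frame(
    grid_row = vapply(preds, `[[`, integer(1), "grid_row"),
    grid_col = vapply(preds, `[[`, integer(1), "grid_col"),
    prob = vapply(preds, `[[`, numeric(1), "prob"),
    label = vapply(preds, `[[`, integer(1), "label"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full recognition pipeline
#'
#' Executes tile -> tissue filter -> (train | load checkpoint) ->
#' patch prediction -> probability map -> mosaic mask -> lesion regions,
#' writing all artifacts plus the resolved configuration and seed to
#' `config$out_dir`. With no `slide_path`, a synthetic slide with ground
#' truth is generated and patch-level metrics against the ground-truth
#' mask are reported.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @return list with the trained `model`, `pmap`, `mask`, `regions`,
#'   `predictions`, `metrics` (synthetic slides only) and `files`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  set.seed(cfg$seed)

  synth_spec <- NULL
  gt <- NULL
  slide <- pipeline_stage("slide", {
    if (!is.null(cfg$slide_path)) read_slide(cfg$slide_path)
    else {
      synth_spec <- do.call(synthetic_slide_spec,
                            merge_config(list(seed = cfg$seed), cfg$synth))
      syn <- generate_slide(synth_spec)
      gt <- syn$region_mask
      syn$image
    }
  })

  tiling <- pipeline_stage("tile",
    tiling_spec(cfg$tiling$window, cfg$tiling$stride))
  fparams <- pipeline_stage("filter",
    do.call(tissue_filter_params, cfg$filter))

  model <- pipeline_stage("train", {
    if (!is.null(cfg$checkpoint)) load_checkpoint(cfg$checkpoint)
    else {
      ncfg <- do.call(network_config, cfg$network)
      set.seed(cfg$seed)
      m <- build_model(ncfg)
      dspec <- if (is.null(synth_spec)) do.call(
        synthetic_slide_spec, merge_config(list(seed = cfg$seed), cfg$synth))
        else synth_spec
      ds <- generate_patch_dataset(cfg$train$n_patches,
                                   cfg$train$class_balance,
                                   patch_size = cfg$train$patch_size,
                                   spec = dspec, seed = cfg$seed,
                                   input_size = ncfg$input_size)
      labels <- vapply(ds, `[[`, numeric(1), "label")
      sp <- split_dataset(labels, seed = cfg$seed)
      tcfg <- train_config(epochs = cfg$train$epochs,
                           batch_size = cfg$train$batch_size,
                           learning_rate = cfg$train$learning_rate,
                           momentum = cfg$train$momentum,
                           lr_decay = cfg$train$lr_decay,
                           rng_seed = cfg$seed)
      m <- train_model(m, ds[sp$train], ds[sp$val], tcfg)
      log <- attr(m, "log")
      f <- file.path(cfg$out_dir, "training_log.csv")
      utils::write.csv(log, f, row.names = FALSE)
      files <- c(files, f)
      m
    }
  })
  f <- file.path(cfg$out_dir, "checkpoint.rds")
  save_checkpoint(model, f)
  files <- c(files, f, paste0(f, ".yaml"))

  pred <- pipeline_stage("predict",
    predict_slide(model, slide, tiling, fparams))
  f <- file.path(cfg$out_dir, "predictions.csv")
  write_predictions_csv(pred$predictions, f)
  files <- c(files, f)

  pmap <- pipeline_stage("map",
    build_probability_map(pred$predictions, dim(slide$pixels)[1:2], tiling))
  mask <- pipeline_stage("mask", threshold_mask(pmap, cfg$map$threshold))
  regions <- pipeline_stage("regions", mask_to_regions(mask, pmap))
  files <- c(files, write_map_artifacts(pmap, mask, regions, cfg$out_dir))

  metrics <- NULL
  if (!is.null(gt)) {
    glab <- patch_labels_from_mask(gt, tiling,
                                   label_threshold = synth_spec$label_threshold,
                                   min_tissue = synth_spec$min_tissue)
    metrics <- evaluate_metrics(as.integer(mask$mask), as.vector(glab))
    f <- file.path(cfg$out_dir, "metrics.json")
    jsonlite::write_json(metrics[c("precision", "recall", "accuracy", "f1")],
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  f <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), f)
  files <- c(files, f)
  f <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(list(seed = cfg$seed, files = basename(files)),
                       f, auto_unbox = TRUE)
  files <- c(files, f)

  list(model = model, pmap = pmap, mask = mask, regions = regions,
       predictions = pred$predictions, tissue = pred$tissue,
       metrics = metrics, ground_truth_labels = if (!is.null(gt))
         patch_labels_from_mask(gt, tiling) else NULL,
       files = files, config = cfg)
}
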