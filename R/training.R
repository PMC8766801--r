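# Training: sigmoid binary cross-entropy, stratified splitting,
# SGD with momentum and per-epoch learning-rate decay, and the
# precision/recall/accuracy/F1 metrics used throughout.

#' Training configuration
#'
#' Defaults are the full-scale settings: 30 epochs, batch size 32,
#' learning rate 0.001 with multiplicative per-epoch decay 0.99, momentum
#' 0.9, 6:2:2 train/validation/test split.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size patches per gradient step.
#' @param learning_rate initial SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param lr_decay multiplicative learning-rate decay applied after each
#'   epoch.
#' @param split_ratio train/validation/test fractions (must sum to 1).
#' @param rng_seed seed recorded and applied by [train_model()].
#' @param augment apply mirror/rotation augmentation to training images.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L,
                         learning_rate = 0.001, momentum = 0.9,
                         lr_decay = 0.99, split_ratio = c(0.6, 0.2, 0.2),
                         rng_seed = 1L, augment = TRUE) {
  stopifnot(epochs >= 0L, batch_size >= 1L, learning_rate > 0,
            momentum >= 0, lr_decay > 0,
            abs(sum(split_ratio) - 1) < 1e-8)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 lr_decay = lr_decay, split_ratio = split_ratio,
                 rng_seed = as.integer(rng_seed), augment = augment),
            class = "train_config")
}

#' Sigmoid binary cross-entropy loss
#'
#' `-(y log p + (1 - y) log(1 - p))`, averaged over the batch. When
#' `logits` is supplied the loss is evaluated in a numerically safe form
#' directly from the logits and `prob` is ignored.
#'
#' @param prob predicted probabilities strictly inside (0,1).
#' @param label binary labels (0/1).
#' @param logits optional logits (pre-sigmoid scores).
#' @return mean loss (nonnegative scalar).
#' @export
bce_loss <- function(prob, label, logits = NULL) {
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  if (!is.null(logits)) {
    z <- logits
    l <- pmax(z, 0) - z * label + log1p(exp(-abs(z)))
    return(mean(l))
  }
  if (any(prob <= 0 | prob >= 1))
    stop("probabilities must be strictly inside (0,1); pass logits for the boundary",
         call. = FALSE)
  if (length(label) != length(prob)) stop("length mismatch", call. = FALSE)
  mean(-(label * log(prob) + (1 - label) * log(1 - prob)))
}

#' Stratified train/validation/test split
#'
#' Splits indices into disjoint, exhaustive sets, stratified by label and
#' reproducible by seed; split sizes are within one of the exact
#' fractions.
#'
#' @param labels binary label vector (one per record).
#' @param ratio length-3 fractions summing to 1 (default 6:2:2).
#' @param seed RNG seed for the shuffle.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, ratio = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- length(labels)
  if (n < 5L) stop("need at least 5 records to split", call. = FALSE)
  stopifnot(abs(sum(ratio) - 1) < 1e-8)
  out <- list(train = integer(), val = integer(), test = integer())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    m <- length(idx)
    # largest-remainder apportionment of m into the three splits
    raw <- ratio * m
    base <- floor(raw)
    rem <- m - sum(base)
    if (rem > 0) {
      add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[add] <- base[add] + 1
    }
    cuts <- cumsum(base)
    out$train <- c(out$train, idx[seq_len(base[1])])
    out$val <- c(out$val, idx[seq(base[1] + 1, length.out = base[2])])
    out$test <- c(out$test, idx[seq(cuts[2] + 1, length.out = base[3])])
  }
  lapply(out, sort)
}

#' Classification metrics with malignant as the positive class
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy `(TP+TN)/n` and
#' `F1 = 2 P R / (P + R)`. A zero denominator is reported as 0 and flagged
#' in `degenerate`.
#'
#' @param predictions predicted labels (0/1) or a list of
#'   [patch_prediction()]s.
#' @param labels true labels (0/1).
#' @return list with `tp`, `fp`, `tn`, `fn`, `precision`, `recall`,
#'   `accuracy`, `f1`, `degenerate`.
#' @export
evaluate_metrics <- function(predictions, labels) {
  if (is.list(predictions) && length(predictions) &&
      inherits(predictions[[1]], "patch_prediction"))
    predictions <- vapply(predictions, `[[`, integer(1), "label")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  tn <- sum(predictions == 0 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  degenerate <- character()
  p <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- c(degenerate, "precision"); 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- c(degenerate, "recall"); 0 }
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else { degenerate <- c(degenerate, "f1"); 0 }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = p, recall = r,
       accuracy = (tp + tn) / length(labels), f1 = f1,
       degenerate = degenerate)
}

dataset_tensor <- function(dataset, idx) {
  # dataset: list of entries list(images = H x W x 3 x 6 array, label)
  d <- dim(dataset[[1]]$images)
  g <- d[4]
  x <- array(0, dim = c(d[1], d[2], d[3], g * length(idx)))
  for (j in seq_along(idx))
    x[, , , (j - 1L) * g + seq_len(g)] <- dataset[[idx[j]]]$images
  x
}

augment_tensor <- function(x) {
  d <- dim(x)
  for (i in seq_len(d[4])) {
    img <- x[, , , i]
    dim(img) <- d[1:3]
    x[, , , i] <- augment_image(img)
  }
  x
}

#' Train the network with SGD and momentum
#'
#' Runs `epochs` passes of mini-batch gradient descent with momentum on
#' sigmoid binary cross-entropy; the learning rate is multiplied by
#' `lr_decay` after each epoch. Mirror/rotation augmentation is applied to
#' training images only. Everything is driven by `config$rng_seed`, so a
#' rerun with the same seed reproduces the epoch-loss trace.
#'
#' @param model a [build_model()] result (updated in place and returned).
#' @param train_set,val_set lists of entries `list(images, label)` where
#'   `images` is an `H x W x 3 x 6` array of the normalized patch +
#'   sub-patch images (see [generate_patch_dataset()]).
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return the model, with attribute `"log"` holding a data frame of
#'   per-epoch learning rate, training loss and validation metrics.
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        config = train_config(), verbose = FALSE) {
  labels <- vapply(train_set, `[[`, numeric(1), "label")
  if (length(train_set) == 0L) stop("empty training set", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; both benign and malignant patches are required",
         call. = FALSE)
  set.seed(config$rng_seed)
  lr <- config$learning_rate
  g <- dim(train_set[[1]]$images)[4]
  log <- data.frame()
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(train_set))
    losses <- numeric()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      x <- dataset_tensor(train_set, idx)
      if (config$augment) x <- augment_tensor(x)
      y <- labels[idx]
      zero_grads(model$layers)
      out <- network_forward(model, x, group_size = g, training = TRUE)
      losses <- c(losses, bce_loss(NULL, y, logits = out$logits))
      dlogits <- (stats::plogis(out$logits) - y) / length(y)
      network_backward(model, dlogits)
      sgd_step(model$layers, lr, config$momentum)
    }
    val <- if (!is.null(val_set)) predict_dataset(model, val_set) else NULL
    row <- data.frame(epoch = epoch, lr = lr, train_loss = mean(losses),
                      val_precision = if (is.null(val)) NA else val$metrics$precision,
                      val_recall = if (is.null(val)) NA else val$metrics$recall,
                      val_accuracy = if (is.null(val)) NA else val$metrics$accuracy,
                      val_f1 = if (is.null(val)) NA else val$metrics$f1)
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %d  lr %.5f  loss %.4f  val F1 %s", epoch, lr,
                      mean(losses),
                      if (is.null(val)) "-" else sprintf("%.4f", val$metrics$f1)))
    lr <- lr * config$lr_decay
  }
  attr(model, "log") <- log
  model
}

#' Predict a labeled patch dataset and compute metrics
#'
#' @param model a trained [build_model()].
#' @param dataset list of `list(images, label)` entries.
#' @param batch_size patches per forward pass.
#' @return list with `prob`, `pred`, `labels`, `metrics`.
#' @export
predict_dataset <- function(model, dataset, batch_size = 32L) {
  g <- dim(dataset[[1]]$images)[4]
  probs <- numeric(length(dataset))
  for (start in seq(1, length(dataset), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(dataset))
    x <- dataset_tensor(dataset, idx)
    out <- network_forward(model, x, group_size = g)
    probs[idx] <- out$prob
  }
  pred <- as.integer(probs >= 0.5)
  labels <- vapply(dataset, `[[`, numeric(1), "label")
  list(prob = probs, pred = pred, labels = labels,
       metrics = evaluate_metrics(pred, labels))
}
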