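# Minimal neural-network layer framework.
#
# Each layer is an environment carrying parameters (`l$params` names them),
# accumulated gradients (prefix "g_") and forward caches used by the
# backward pass. Tensors are column-major arrays dim = c(H, W, C, N);
# vector features are matrices (features x N).

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  l$params <- character()
  class(l) <- c(paste0("nn_", type), "nn_layer")
  l
}

add_param <- function(l, name, value) {
  l[[name]] <- value
  l[[paste0("g_", name)]] <- value * 0  # same shape and class as the param
  l$params <- c(l$params, name)
  invisible(l)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

zero_grads <- function(layers) {
  for (l in layers)
    for (p in l$params) l[[paste0("g_", p)]][] <- 0
  invisible(NULL)
}

nn_forward <- function(l, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(l, dy) UseMethod("nn_backward")

conv_out_side <- function(side, k, stride, pad) {
  as.integer((side + 2L * pad - k) %/% stride + 1L)
}

# ---- standard convolution -------------------------------------------------

layer_conv <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = FALSE, zero_init = FALSE) {
  l <- new_layer("conv", c_in = c_in, c_out = c_out, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad))
  W <- if (zero_init) matrix(0, k * k * c_in, c_out)
       else he_init(k * k * c_in, c_out, k * k * c_in)
  add_param(l, "W", W)
  if (bias) add_param(l, "b", numeric(c_out))
  l
}

nn_forward.nn_conv <- function(l, x, training = FALSE) {
  xd <- dim(x)
  cols <- cpp_im2col(x, xd, l$k, l$stride, l$pad)
  out <- crossprod(l$W, cols)
  if (!is.null(l$b)) out <- out + l$b
  Ho <- conv_out_side(xd[1], l$k, l$stride, l$pad)
  Wo <- conv_out_side(xd[2], l$k, l$stride, l$pad)
  dim(out) <- c(l$c_out, Ho, Wo, xd[4])
  y <- aperm(out, c(2, 3, 1, 4))
  if (training) { l$cols <- cols; l$xd <- xd }
  y
}

nn_backward.nn_conv <- function(l, dy) {
  dyd <- dim(dy)
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(l$c_out, prod(dyd[c(1, 2, 4)]))
  l$g_W <- l$g_W + tcrossprod(l$cols, dym)
  if (!is.null(l$b)) l$g_b <- l$g_b + rowSums(dym)
  dcols <- l$W %*% dym
  dx <- cpp_col2im(dcols, l$xd, l$k, l$stride, l$pad)
  l$cols <- NULL
  dx
}

# ---- deformable convolution ----------------------------------------------
# A parallel zero-initialized convolution predicts 2*k*k offset channels
# (dy, dx per kernel tap per output position); offsets are clamped to
# [-dilation_cap, dilation_cap] and resolved by bilinear sampling.

layer_dconv <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                        bias = FALSE, dilation_cap = 2) {
  l <- new_layer("dconv", c_in = c_in, c_out = c_out, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad),
                 cap = dilation_cap, K = as.integer(k * k))
  add_param(l, "W", he_init(k * k * c_in, c_out, k * k * c_in))
  if (bias) add_param(l, "b", numeric(c_out))
  add_param(l, "Woff", matrix(0, k * k * c_in, 2L * k * k))
  add_param(l, "boff", numeric(2L * k * k))
  l
}

nn_forward.nn_dconv <- function(l, x, training = FALSE) {
  xd <- dim(x)
  Ho <- conv_out_side(xd[1], l$k, l$stride, l$pad)
  Wo <- conv_out_side(xd[2], l$k, l$stride, l$pad)
  cols_std <- cpp_im2col(x, xd, l$k, l$stride, l$pad)
  offm <- crossprod(l$Woff, cols_std) + l$boff        # (2K) x M
  dim(offm) <- c(2L * l$K, Ho, Wo, xd[4])
  off <- aperm(offm, c(2, 3, 1, 4))
  cols_def <- cpp_deform_im2col(x, xd, off, l$k, l$stride, l$pad, l$cap)
  out <- crossprod(l$W, cols_def)
  if (!is.null(l$b)) out <- out + l$b
  dim(out) <- c(l$c_out, Ho, Wo, xd[4])
  y <- aperm(out, c(2, 3, 1, 4))
  if (training) {
    l$cols_std <- cols_std; l$cols_def <- cols_def
    l$off <- off; l$x <- x; l$xd <- xd
  }
  y
}

nn_backward.nn_dconv <- function(l, dy) {
  dyd <- dim(dy)
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(l$c_out, prod(dyd[c(1, 2, 4)]))
  l$g_W <- l$g_W + tcrossprod(l$cols_def, dym)
  if (!is.null(l$b)) l$g_b <- l$g_b + rowSums(dym)
  dcols_def <- l$W %*% dym
  bk <- cpp_deform_backward(dcols_def, l$x, l$xd, l$off,
                            l$k, l$stride, l$pad, l$cap)
  dx <- bk$dx
  doff <- aperm(bk$doff, c(3, 1, 2, 4))
  dim(doff) <- c(2L * l$K, prod(dyd[c(1, 2, 4)]))
  l$g_Woff <- l$g_Woff + tcrossprod(l$cols_std, doff)
  l$g_boff <- l$g_boff + rowSums(doff)
  dcols_std <- l$Woff %*% doff
  dx <- dx + cpp_col2im(dcols_std, l$xd, l$k, l$stride, l$pad)
  l$cols_std <- NULL; l$cols_def <- NULL; l$off <- NULL; l$x <- NULL
  dx
}

# ---- batch normalization --------------------------------------------------

layer_bn <- function(c_ch, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("bn", C = as.integer(c_ch), momentum = momentum, eps = eps,
                 rmean = numeric(c_ch), rvar = rep(1, c_ch))
  add_param(l, "gamma", rep(1, c_ch))
  add_param(l, "beta", numeric(c_ch))
  l
}

channel_stat <- function(m2, C, N) {
  # m2: (H*W) x (C*N) with channel fastest in the column index
  cm <- colMeans(m2)
  dim(cm) <- c(C, N)
  rowMeans(cm)
}

nn_forward.nn_bn <- function(l, x, training = FALSE) {
  xd <- dim(x)
  HW <- xd[1] * xd[2]; C <- xd[3]; N <- xd[4]
  m2 <- x
  dim(m2) <- c(HW, C * N)
  if (training) {
    mu <- channel_stat(m2, C, N)
    v <- channel_stat(m2 * m2, C, N) - mu^2
    v[v < 0] <- 0
    l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * mu
    l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * v
  } else {
    mu <- l$rmean; v <- l$rvar
  }
  invstd <- 1 / sqrt(v + l$eps)
  xh <- sweep(m2, 2, rep(mu, N), "-")
  xh <- sweep(xh, 2, rep(invstd, N), "*")
  y <- sweep(xh, 2, rep(l$gamma, N), "*")
  y <- sweep(y, 2, rep(l$beta, N), "+")
  dim(y) <- xd
  if (training) { l$xh <- xh; l$invstd <- invstd; l$xd <- xd }
  y
}

nn_backward.nn_bn <- function(l, dy) {
  xd <- l$xd
  HW <- xd[1] * xd[2]; C <- xd[3]; N <- xd[4]
  M <- HW * N
  dym <- dy
  dim(dym) <- c(HW, C * N)
  sum_dy <- channel_stat(dym, C, N) * M
  sum_dyxh <- channel_stat(dym * l$xh, C, N) * M
  l$g_gamma <- l$g_gamma + sum_dyxh
  l$g_beta <- l$g_beta + sum_dy
  # dx = gamma*invstd/M * (M*dy - sum_dy - xh*sum_dyxh)
  dx <- sweep(dym, 2, rep(l$gamma, N), "*") * M
  dx <- sweep(dx, 2, rep(l$gamma * sum_dy, N), "-")
  dx <- dx - sweep(l$xh, 2, rep(l$gamma * sum_dyxh, N), "*")
  dx <- sweep(dx, 2, rep(l$invstd / M, N), "*")
  dim(dx) <- xd
  l$xh <- NULL
  dx
}

# ---- activations, pooling -------------------------------------------------

layer_relu <- function() new_layer("relu")

nn_forward.nn_relu <- function(l, x, training = FALSE) {
  y <- x
  y[y < 0] <- 0
  if (training) l$mask <- x > 0
  y
}

nn_backward.nn_relu <- function(l, dy) {
  dx <- dy * l$mask
  l$mask <- NULL
  dx
}

layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

nn_forward.nn_maxpool <- function(l, x, training = FALSE) {
  r <- cpp_maxpool(x, dim(x), l$k, l$stride, l$pad)
  if (training) { l$argmax <- r$argmax; l$xd <- dim(x) }
  r$y
}

nn_backward.nn_maxpool <- function(l, dy) {
  dx <- cpp_maxpool_backward(dy, l$argmax, l$xd)
  l$argmax <- NULL
  dx
}

layer_upsample2 <- function() new_layer("upsample2")

nn_forward.nn_upsample2 <- function(l, x, training = FALSE) {
  xd <- dim(x)
  if (training) l$xd <- xd
  cpp_resize_bilinear(x, xd, 2L * xd[1], 2L * xd[2])
}

nn_backward.nn_upsample2 <- function(l, dy) {
  cpp_resize_bilinear_backward(dy, dim(dy), l$xd[1], l$xd[2])
}

layer_gap <- function() new_layer("gap")

nn_forward.nn_gap <- function(l, x, training = FALSE) {
  xd <- dim(x)
  m2 <- x
  dim(m2) <- c(xd[1] * xd[2], xd[3] * xd[4])
  z <- colMeans(m2)
  dim(z) <- c(xd[3], xd[4])
  if (training) l$xd <- xd
  z
}

nn_backward.nn_gap <- function(l, dz) {
  xd <- l$xd
  HW <- xd[1] * xd[2]
  dx <- matrix(rep(as.vector(dz) / HW, each = HW), nrow = HW)
  dim(dx) <- xd
  dx
}

# ---- squeeze-excitation channel attention --------------------------------
# s = sigmoid(W2 relu(W1 * globalmean(X))), Y = s (*) X channel-wise.

layer_ca <- function(c_ch, reduction_ratio = 16L) {
  cr <- max(1L, as.integer(c_ch %/% reduction_ratio))
  l <- new_layer("ca", C = as.integer(c_ch), Cr = cr)
  add_param(l, "W1", he_init(cr, c_ch, c_ch))
  add_param(l, "b1", numeric(cr))
  add_param(l, "W2", he_init(c_ch, cr, cr))
  add_param(l, "b2", numeric(c_ch))
  l
}

nn_forward.nn_ca <- function(l, x, training = FALSE) {
  xd <- dim(x)
  HW <- xd[1] * xd[2]; C <- xd[3]; N <- xd[4]
  m2 <- x
  dim(m2) <- c(HW, C * N)
  z <- colMeans(m2)
  dim(z) <- c(C, N)
  a <- l$W1 %*% z + l$b1
  r <- a; r[r < 0] <- 0
  s <- stats::plogis(l$W2 %*% r + l$b2)
  y <- sweep(m2, 2, as.vector(s), "*")
  dim(y) <- xd
  if (training) {
    l$m2 <- m2; l$z <- z; l$a <- a; l$r <- r; l$s <- s; l$xd <- xd
  }
  y
}

nn_backward.nn_ca <- function(l, dy) {
  xd <- l$xd
  HW <- xd[1] * xd[2]
  dym <- dy
  dim(dym) <- c(HW, prod(xd[3:4]))
  ds <- colSums(dym * l$m2)
  dim(ds) <- dim(l$s)
  dx <- sweep(dym, 2, as.vector(l$s), "*")
  dsz <- ds * l$s * (1 - l$s)
  l$g_W2 <- l$g_W2 + tcrossprod(dsz, l$r)
  l$g_b2 <- l$g_b2 + rowSums(dsz)
  dr <- crossprod(l$W2, dsz)
  da <- dr * (l$a > 0)
  l$g_W1 <- l$g_W1 + tcrossprod(da, l$z)
  l$g_b1 <- l$g_b1 + rowSums(da)
  dz <- crossprod(l$W1, da)
  dx <- sweep(dx, 2, as.vector(dz) / HW, "+")
  dim(dx) <- xd
  l$m2 <- NULL; l$z <- NULL; l$a <- NULL; l$r <- NULL; l$s <- NULL
  dx
}

# ---- fully connected ------------------------------------------------------

layer_fc <- function(n_in, n_out, bias = TRUE) {
  l <- new_layer("fc", n_in = as.integer(n_in), n_out = as.integer(n_out))
  add_param(l, "W", he_init(n_out, n_in, n_in))
  if (bias) add_param(l, "b", numeric(n_out))
  l
}

nn_forward.nn_fc <- function(l, x, training = FALSE) {
  y <- l$W %*% x
  if (!is.null(l$b)) y <- y + l$b
  if (training) l$x <- x
  y
}

nn_backward.nn_fc <- function(l, dy) {
  l$g_W <- l$g_W + tcrossprod(dy, l$x)
  if (!is.null(l$b)) l$g_b <- l$g_b + rowSums(dy)
  dx <- crossprod(l$W, dy)
  l$x <- NULL
  dx
}

# ---- SGD with momentum ----------------------------------------------------

sgd_step <- function(layers, lr, momentum = 0.9) {
  for (l in layers) {
    for (p in l$params) {
      g <- l[[paste0("g_", p)]]
      vn <- paste0("v_", p)
      v <- if (is.null(l[[vn]])) 0 * g else l[[vn]]
      v <- momentum * v + g
      l[[vn]] <- v
      l[[p]] <- l[[p]] - lr * v
    }
  }
  invisible(NULL)
}
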