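# Shared fixtures and independent oracles for the test suite.

# Direct nested-loop convolution (the independent oracle for conv paths).
# x: H x W x C, w: c_out x c_in x k x k, zero padding.
naive_conv <- function(x, w, stride = 1L, pad = 0L) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  co <- dim(w)[1]; k <- dim(w)[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  xp <- array(0, dim = c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(0, dim = c(Ho, Wo, co))
  for (o in seq_len(co)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    s <- 0
    for (c in seq_len(C)) for (kh in seq_len(k)) for (kw in seq_len(k))
      s <- s + w[o, c, kh, kw] *
        xp[(ho - 1L) * stride + kh, (wo - 1L) * stride + kw, c]
    y[ho, wo, o] <- s
  }
  y
}

# Direct evaluation of the deformable sum: y(p) = sum_k w(p_k) x(p+p_k+dp_k)
# with bilinear resolution of fractional positions and zero out of bounds.
naive_deform_conv <- function(x, w, offsets, stride = 1L, pad = 0L, cap = 2) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  co <- dim(w)[1]; k <- dim(w)[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  sample_bilinear <- function(hh, ww, c) {
    h0 <- floor(hh); w0 <- floor(ww)
    a <- hh - h0; b <- ww - w0
    v <- 0
    for (dh in 0:1) for (dw in 0:1) {
      h <- h0 + dh; w2 <- w0 + dw
      if (h >= 1 && h <= H && w2 >= 1 && w2 <= W)
        v <- v + (if (dh) a else 1 - a) * (if (dw) b else 1 - b) * x[h, w2, c]
    }
    v
  }
  y <- array(0, dim = c(Ho, Wo, co))
  for (o in seq_len(co)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    s <- 0
    for (c in seq_len(C)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
      t <- (kh - 1L) * k + kw
      dy <- min(max(offsets[ho, wo, 2L * t - 1L], -cap), cap)
      dx <- min(max(offsets[ho, wo, 2L * t], -cap), cap)
      hh <- (ho - 1L) * stride - pad + kh + dy
      ww <- (wo - 1L) * stride - pad + kw + dx
      s <- s + w[o, c, kh, kw] * sample_bilinear(hh, ww, c)
    }
    y[ho, wo, o] <- s
  }
  y
}

# Half-pixel-centre bilinear resize computed from first principles.
naive_resize_bilinear <- function(x, Ho, Wo) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, dim = c(Ho, Wo, C))
  for (c in seq_len(C)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    hs <- min(max((ho - 0.5) * H / Ho - 0.5, 0), H - 1)
    ws <- min(max((wo - 0.5) * W / Wo - 0.5, 0), W - 1)
    h0 <- floor(hs); w0 <- floor(ws)
    a <- hs - h0; b <- ws - w0
    h1 <- min(h0 + 1, H - 1); w1 <- min(w0 + 1, W - 1)
    y[ho, wo, c] <- (1 - a) * (1 - b) * x[h0 + 1, w0 + 1, c] +
      (1 - a) * b * x[h0 + 1, w1 + 1, c] +
      a * (1 - b) * x[h1 + 1, w0 + 1, c] +
      a * b * x[h1 + 1, w1 + 1, c]
  }
  y
}

# Label-propagation connected components (independent of the package's
# BFS flood fill): iterate minimum-label relaxation until fixed point.
relaxation_components <- function(mask, diagonal = FALSE) {
  lab <- matrix(seq_along(mask), nrow(mask), ncol(mask))
  lab[!mask] <- 0L
  repeat {
    old <- lab
    nr <- nrow(mask); nc <- ncol(mask)
    shift <- function(m, dr, dc) {
      out <- matrix(Inf, nr, nc)
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
      out
    }
    cand <- pmin(shift(ifelse(lab == 0L, Inf, lab), 1, 0),
                 shift(ifelse(lab == 0L, Inf, lab), -1, 0),
                 shift(ifelse(lab == 0L, Inf, lab), 0, 1),
                 shift(ifelse(lab == 0L, Inf, lab), 0, -1))
    upd <- mask & is.finite(cand) & (cand < lab)
    lab[upd] <- cand[upd]
    if (identical(old, lab)) break
  }
  length(unique(lab[lab > 0L]))
}

# Small network config used across network tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(depth = 18L, base_width = 4L, dc_stages = "conv5",
         ca_placement = c("backbone", "shortcut"),
         fusion_branches = c("F4", "F3", "F2"),
         input_size = 32L, penultimate = 16L,
         reduction_ratio = 4L, stem_kernel = 3L),
    list(...))
  do.call(network_config, args)
}

rand_image <- function(side, channels = 3L, lo = 0, hi = 1) {
  array(stats::runif(side * side * channels, lo, hi),
        dim = c(side, side, channels))
}
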