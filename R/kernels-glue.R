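# R-side wrappers for the compiled kernels (registered in src/init.cpp).

cpp_im2col <- function(x, xdim, k, stride, pad) {
  .Call("melmap_im2col", x, as.integer(xdim), as.integer(k),
        as.integer(stride), as.integer(pad))
}

cpp_col2im <- function(cols, xdim, k, stride, pad) {
  .Call("melmap_col2im", cols, as.integer(xdim), as.integer(k),
        as.integer(stride), as.integer(pad))
}

cpp_deform_im2col <- function(x, xdim, off, k, stride, pad, cap) {
  .Call("melmap_deform_im2col", x, as.integer(xdim), off, as.integer(k),
        as.integer(stride), as.integer(pad), as.numeric(cap))
}

cpp_deform_backward <- function(dcols, x, xdim, off, k, stride, pad, cap) {
  .Call("melmap_deform_backward", dcols, x, as.integer(xdim), off,
        as.integer(k), as.integer(stride), as.integer(pad), as.numeric(cap))
}

cpp_resize_bilinear <- function(x, xdim, Ho, Wo) {
  .Call("melmap_resize_bilinear", x, as.integer(xdim), as.integer(Ho),
        as.integer(Wo))
}

cpp_resize_bilinear_backward <- function(dy, ydim, H, W) {
  .Call("melmap_resize_bilinear_backward", dy, as.integer(ydim),
        as.integer(H), as.integer(W))
}

cpp_box_reduce <- function(x, xdim, f) {
  .Call("melmap_box_reduce", x, as.integer(xdim), as.integer(f))
}

cpp_maxpool <- function(x, xdim, k, stride, pad) {
  .Call("melmap_maxpool", x, as.integer(xdim), as.integer(k),
        as.integer(stride), as.integer(pad))
}

cpp_maxpool_backward <- function(dy, argmax, xdim) {
  .Call("melmap_maxpool_backward", dy, argmax, as.integer(xdim))
}

cpp_rotate_reflect <- function(img, dim, angle) {
  .Call("melmap_rotate_reflect", img, as.integer(dim), as.numeric(angle))
}
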