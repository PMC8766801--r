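// Call registration for the compiled kernels in kernels.cpp.

#include <Rcpp.h>
#include <R_ext/Rdynload.h>
using namespace Rcpp;

NumericMatrix cpp_im2col(NumericVector x, IntegerVector xdim, int k, int stride, int pad);
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector xdim, int k, int stride, int pad);
NumericMatrix cpp_deform_im2col(NumericVector x, IntegerVector xdim, NumericVector off, int k, int stride, int pad, double cap);
List cpp_deform_backward(NumericMatrix dcols, NumericVector x, IntegerVector xdim, NumericVector off, int k, int stride, int pad, double cap);
NumericVector cpp_resize_bilinear(NumericVector x, IntegerVector xdim, int Ho, int Wo);
NumericVector cpp_resize_bilinear_backward(NumericVector dy, IntegerVector ydim, int H, int W);
NumericVector cpp_box_reduce(NumericVector x, IntegerVector xdim, int f);
List cpp_maxpool(NumericVector x, IntegerVector xdim, int k, int stride, int pad);
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector argmax, IntegerVector xdim);
NumericVector cpp_rotate_reflect(NumericVector img, IntegerVector dim, double angle);

extern "C" {

SEXP melmap_im2col(SEXP x, SEXP xdim, SEXP k, SEXP stride, SEXP pad) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_im2col(x, xdim, as<int>(k), as<int>(stride), as<int>(pad)));
END_RCPP
}

SEXP melmap_col2im(SEXP cols, SEXP xdim, SEXP k, SEXP stride, SEXP pad) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_col2im(cols, xdim, as<int>(k), as<int>(stride), as<int>(pad)));
END_RCPP
}

SEXP melmap_deform_im2col(SEXP x, SEXP xdim, SEXP off, SEXP k, SEXP stride, SEXP pad, SEXP cap) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_deform_im2col(x, xdim, off, as<int>(k), as<int>(stride),
                                      as<int>(pad), as<double>(cap)));
END_RCPP
}

SEXP melmap_deform_backward(SEXP dcols, SEXP x, SEXP xdim, SEXP off, SEXP k, SEXP stride, SEXP pad, SEXP cap) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_deform_backward(dcols, x, xdim, off, as<int>(k),
                                        as<int>(stride), as<int>(pad), as<double>(cap)));
END_RCPP
}

SEXP melmap_resize_bilinear(SEXP x, SEXP xdim, SEXP Ho, SEXP Wo) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_resize_bilinear(x, xdim, as<int>(Ho), as<int>(Wo)));
END_RCPP
}

SEXP melmap_resize_bilinear_backward(SEXP dy, SEXP ydim, SEXP H, SEXP W) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_resize_bilinear_backward(dy, ydim, as<int>(H), as<int>(W)));
END_RCPP
}

SEXP melmap_box_reduce(SEXP x, SEXP xdim, SEXP f) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_box_reduce(x, xdim, as<int>(f)));
END_RCPP
}

SEXP melmap_maxpool(SEXP x, SEXP xdim, SEXP k, SEXP stride, SEXP pad) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_maxpool(x, xdim, as<int>(k), as<int>(stride), as<int>(pad)));
END_RCPP
}

SEXP melmap_maxpool_backward(SEXP dy, SEXP argmax, SEXP xdim) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_maxpool_backward(dy, argmax, xdim));
END_RCPP
}

SEXP melmap_rotate_reflect(SEXP img, SEXP dim, SEXP angle) {
BEGIN_RCPP
  return Rcpp::wrap(cpp_rotate_reflect(img, dim, as<double>(angle)));
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
  {"melmap_im2col", (DL_FUNC) &melmap_im2col, 5},
  {"melmap_col2im", (DL_FUNC) &melmap_col2im, 5},
  {"melmap_deform_im2col", (DL_FUNC) &melmap_deform_im2col, 7},
  {"melmap_deform_backward", (DL_FUNC) &melmap_deform_backward, 8},
  {"melmap_resize_bilinear", (DL_FUNC) &melmap_resize_bilinear, 4},
  {"melmap_resize_bilinear_backward", (DL_FUNC) &melmap_resize_bilinear_backward, 4},
  {"melmap_box_reduce", (DL_FUNC) &melmap_box_reduce, 3},
  {"melmap_maxpool", (DL_FUNC) &melmap_maxpool, 5},
  {"melmap_maxpool_backward", (DL_FUNC) &melmap_maxpool_backward, 3},
  {"melmap_rotate_reflect", (DL_FUNC) &melmap_rotate_reflect, 3},
  {NULL, NULL, 0}
};

void R_init_melmap(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}

} // extern "C"
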