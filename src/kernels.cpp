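#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window raw cross-correlation: for every valid placement (one per
// output cell) the sum over the kernel footprint of ker * window. Output is
// (H - h + 1) x (W - w + 1); out(y, x) corresponds to the window whose
// top-left pixel is image row y, column x (0-based). Direct evaluation, no
// padding, exact double arithmetic.
// [[Rcpp::export]]
NumericMatrix cpp_xcorr(NumericMatrix image, NumericMatrix kernel) {
  const int H = image.nrow(), W = image.ncol();
  const int h = kernel.nrow(), w = kernel.ncol();
  const int oh = H - h + 1, ow = W - w + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than image");
  NumericMatrix out(oh, ow);
  for (int x = 0; x < ow; ++x) {
    for (int y = 0; y < oh; ++y) {
      double acc = 0.0;
      for (int tx = 0; tx < w; ++tx) {
        const double* icol = &image(0, x + tx);
        const double* kcol = &kernel(0, tx);
        for (int ty = 0; ty < h; ++ty) {
          acc += kcol[ty] * icol[y + ty];
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}
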