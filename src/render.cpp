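#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Render one transmitted-light frame: uniform bright background, one
// subtracted Gaussian blob per bacterium (motion-blurred by averaging
// sub-exposure positions interpolated between consecutive frame positions),
// a dark fiber occluder rectangle, additive Gaussian noise, clipped to
// [0, 255] and quantized half-away-from-zero to 8-bit.
//
// Positions are lab micrometres with the origin at the center of pixel
// (1,1); fiber_rect is {col0, col1, row0, row1}, 0-based inclusive, or
// col0 = -1 for no occluder.
// [[Rcpp::export]]
IntegerMatrix render_frame_cpp(int width, int height,
                               NumericVector x0, NumericVector y0,
                               NumericVector x1, NumericVector y1,
                               LogicalVector blur,
                               double pixel_size, double background,
                               double contrast, double sigma_um,
                               int n_samples, double exposure_fraction,
                               double noise_sigma, double contrast_flicker,
                               IntegerVector fiber_rect, double fiber_level) {
  const int n = x0.size();
  const double sig = sigma_um / pixel_size;  // blob scale in px
  const double inv2s2 = 1.0 / (2.0 * sig * sig);
  const int rad = (int)std::ceil(3.5 * sig);
  NumericMatrix img(height, width);
  std::fill(img.begin(), img.end(), background);

  for (int i = 0; i < n; ++i) {
    const int ns = blur[i] ? n_samples : 1;
    // a rod-shaped cell tumbles between frames; its projected contrast
    // varies with orientation
    const double ori = (contrast_flicker > 0)
      ? 1.0 + contrast_flicker * (2.0 * unif_rand() - 1.0) : 1.0;
    const double amp = ori * contrast / ns;
    for (int s = 0; s < ns; ++s) {
      // sub-exposure midpoint fraction within the open-shutter interval
      const double f = blur[i]
        ? exposure_fraction * ((s + 0.5) / ns) : 0.0;
      const double cx = (x0[i] + f * (x1[i] - x0[i])) / pixel_size; // 0-based col
      const double cy = (y0[i] + f * (y1[i] - y0[i])) / pixel_size; // 0-based row
      const int c0 = std::max(0, (int)std::floor(cx) - rad);
      const int c1 = std::min(width - 1, (int)std::ceil(cx) + rad);
      const int r0 = std::max(0, (int)std::floor(cy) - rad);
      const int r1 = std::min(height - 1, (int)std::ceil(cy) + rad);
      for (int c = c0; c <= c1; ++c) {
        const double dx = c - cx;
        for (int r = r0; r <= r1; ++r) {
          const double dy = r - cy;
          img(r, c) -= amp * std::exp(-(dx * dx + dy * dy) * inv2s2);
        }
      }
    }
  }

  if (fiber_rect[0] >= 0) {
    const int fc0 = std::max(0, (int)fiber_rect[0]);
    const int fc1 = std::min(width - 1, (int)fiber_rect[1]);
    const int fr0 = std::max(0, (int)fiber_rect[2]);
    const int fr1 = std::min(height - 1, (int)fiber_rect[3]);
    for (int c = fc0; c <= fc1; ++c)
      for (int r = fr0; r <= fr1; ++r)
        img(r, c) = fiber_level;
  }

  IntegerMatrix out(height, width);
  for (int j = 0; j < width * height; ++j) {
    double v = img[j];
    if (noise_sigma > 0) v += norm_rand() * noise_sigma;
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    out[j] = (int)std::floor(v + 0.5);
  }
  return out;
}
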