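#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scalar-field interference renderer.
//
// For each camera frame the complex field at a pixel is
//   E = sqrt(R_ref) + sum_j w_j(x, y) * a_j * exp(i * (2 k z_j + phi_j))
// with w_j the lateral point-spread weight of scatterer j integrated over the
// pixel area (separable Gaussian, sd = sigma_psf). Detected intensity is
// |E|^2, averaged over the exposure substeps (the detector integrates
// intensity, not field). Positions arrive as flat arrays for one frame chunk:
// n_sub substeps x n scatterers.
//
// Pixel p covers [p*px, (p+1)*px) in micrometres; the weight on pixel p is
//   0.5 * (erf((hi - x)/(sqrt2 sigma)) - erf((lo - x)/(sqrt2 sigma)))
// so a scatterer's total lateral weight sums to ~1 across pixels.

static inline double pix_weight(double lo, double hi, double x, double inv_s) {
  return 0.5 * (std::erf((hi - x) * inv_s) - std::erf((lo - x) * inv_s));
}

// [[Rcpp::export(name = ".render_frame_chunk")]]
NumericMatrix render_frame_chunk(NumericVector xs, NumericVector ys,
                                 NumericVector zs,
                                 NumericVector amp, NumericVector phase,
                                 int n_sub, int n_exp_sub,
                                 double k, double sigma_psf, double pixel_um,
                                 double x0, double y0,
                                 int ny, int nx, double r_ref) {
  const int n = amp.size();
  if ((int)xs.size() != n_sub * n)
    stop("position chunk does not match n_sub * n scatterers");
  if (n_exp_sub < 1 || n_exp_sub > n_sub) stop("invalid n_exp_sub");
  const double sqrt_r = std::sqrt(r_ref);
  const double inv_s = 1.0 / (M_SQRT2 * sigma_psf);
  // stamp half-width in pixels: 4 sigma plus one pixel of slack
  const int hw = (int)std::ceil(4.0 * sigma_psf / pixel_um) + 1;
  NumericMatrix frame(ny, nx);
  std::vector<double> re(ny * nx), im(ny * nx);
  std::vector<double> wx(2 * hw + 1), wy(2 * hw + 1);

  for (int s = 0; s < n_exp_sub; ++s) {
    std::fill(re.begin(), re.end(), 0.0);
    std::fill(im.begin(), im.end(), 0.0);
    // positions arrive as column-major (n_sub x n) slices: substep fastest
    for (int j = 0; j < n; ++j) {
      const size_t pj = (size_t)j * n_sub + s;
      const double x = xs[pj] - x0, y = ys[pj] - y0;
      const int cx = (int)std::floor(x / pixel_um);
      const int cy = (int)std::floor(y / pixel_um);
      if (cx < -hw || cx >= nx + hw || cy < -hw || cy >= ny + hw) continue;
      const double th = 2.0 * k * zs[pj] + phase[j];
      const double ar = amp[j] * std::cos(th);
      const double ai = amp[j] * std::sin(th);
      int nwin = 0;
      for (int d = -hw; d <= hw; ++d, ++nwin) {
        const int ix = cx + d, iy = cy + d;
        wx[nwin] = (ix >= 0 && ix < nx)
          ? pix_weight(ix * pixel_um, (ix + 1) * pixel_um, x, inv_s) : 0.0;
        wy[nwin] = (iy >= 0 && iy < ny)
          ? pix_weight(iy * pixel_um, (iy + 1) * pixel_um, y, inv_s) : 0.0;
      }
      for (int dy = -hw; dy <= hw; ++dy) {
        const int iy = cy + dy;
        if (iy < 0 || iy >= ny) continue;
        const double wyv = wy[dy + hw];
        if (wyv == 0.0) continue;
        for (int dx = -hw; dx <= hw; ++dx) {
          const int ix = cx + dx;
          if (ix < 0 || ix >= nx) continue;
          const double w = wx[dx + hw] * wyv;
          if (w == 0.0) continue;
          const size_t idx = (size_t)ix * ny + iy;
          re[idx] += w * ar;
          im[idx] += w * ai;
        }
      }
    }
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) {
        const size_t idx = (size_t)ix * ny + iy;
        const double er = sqrt_r + re[idx];
        frame(iy, ix) += er * er + im[idx] * im[idx];
      }
    }
  }
  const double inv_m = 1.0 / n_exp_sub;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      frame(iy, ix) *= inv_m;
  return frame;
}
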