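// Parallel-beam Radon transform and backprojection.
//
// Conventions (shared by cpp_radon and cpp_backproject):
//  - image is H x W, pixel (i, j) sits at coordinates x = j - cx, y = i - cy
//    with cx = (W-1)/2, cy = (H-1)/2 (pixel units)
//  - a projection at angle theta integrates along the direction
//    (-sin theta, cos theta); the detector axis is (cos theta, sin theta)
//  - detector u for column d: u = d - (n_det-1)/2
//  - line integrals use unit (1 pixel) steps with bilinear sampling,
//    zero outside the grid
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double bilinear(const arma::mat& img, double y, double x) {
  // y: row coordinate, x: column coordinate (0-based, fractional)
  const int H = img.n_rows, W = img.n_cols;
  if (y < -1.0 || y > H || x < -1.0 || x > W) return 0.0;
  int i0 = (int)std::floor(y), j0 = (int)std::floor(x);
  double fy = y - i0, fx = x - j0;
  double v = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int i = i0 + di;
    if (i < 0 || i >= H) continue;
    double wy = di ? fy : 1.0 - fy;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= W) continue;
      double wx = dj ? fx : 1.0 - fx;
      v += wy * wx * img(i, j);
    }
  }
  return v;
}

// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& image, const arma::vec& angles, int n_det) {
  const int H = image.n_rows, W = image.n_cols;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double cd = (n_det - 1) / 2.0;
  // ray length: cover the full grid diagonal
  const int ns = (int)std::ceil(std::sqrt((double)H * H + (double)W * W)) + 2;
  const double cs = (ns - 1) / 2.0;
  arma::mat sino(angles.n_elem, n_det, arma::fill::zeros);
  for (arma::uword a = 0; a < angles.n_elem; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int d = 0; d < n_det; ++d) {
      const double u = d - cd;
      double acc = 0.0;
      for (int s = 0; s < ns; ++s) {
        const double t = s - cs;
        const double x = cx + u * ct - t * st;
        const double y = cy + u * st + t * ct;
        acc += bilinear(image, y, x);
      }
      sino(a, d) = acc;
    }
  }
  return sino;
}

// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& fsino, const arma::vec& angles,
                          int H, int W) {
  const int n_det = fsino.n_cols;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double cd = (n_det - 1) / 2.0;
  arma::mat img(H, W, arma::fill::zeros);
  for (arma::uword a = 0; a < angles.n_elem; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const arma::rowvec row = fsino.row(a);
    for (int i = 0; i < H; ++i) {
      const double y = i - cy;
      for (int j = 0; j < W; ++j) {
        const double x = j - cx;
        const double u = x * ct + y * st + cd;  // detector coordinate
        const int d0 = (int)std::floor(u);
        if (d0 < -1 || d0 >= n_det) continue;
        const double f = u - d0;
        double v = 0.0;
        if (d0 >= 0) v += (1.0 - f) * row[d0];
        if (d0 + 1 < n_det) v += f * row[d0 + 1];
        img(i, j) += v;
      }
    }
  }
  // standard FBP scaling for angles uniform over [0, pi)
  img *= M_PI / (2.0 * angles.n_elem);
  return img;
}
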