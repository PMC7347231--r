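// Level-set curvature-flow denoising of magnitude spectrograms (min/max
// flow variant).  The image evolves under u_t = F * |grad u| where
// F * |grad u| is the second derivative of u along the tangent of the local
// level line (equal to curvature times gradient magnitude).  Where the
// central-difference gradient degenerates (ridge crests, isolated spikes)
// the limit is taken as the Hessian eigenvalue of smaller magnitude: an
// isolated spike is curved in every direction and erodes, while a straight
// spectral ridge is flat along its length and survives.  The min/max switch
// restricts motion so pixels brighter than their surroundings may only
// erode and darker ones only fill, which removes speckle of both signs
// without blurring the call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using arma::mat;

// [[Rcpp::export]]
arma::mat curvature_flow_cpp(arma::mat u, int iterations, double dt,
                             bool minmax) {
  const int nr = u.n_rows, nc = u.n_cols;
  if (nr < 3 || nc < 3 || iterations <= 0) return u;
  mat unew = u;
  for (int it = 0; it < iterations; ++it) {
    const double scale = u.max() - u.min();
    if (scale <= 0) break;
    const double g2min = 1e-9 * scale * scale;
    for (int j = 1; j < nc - 1; ++j) {
      for (int i = 1; i < nr - 1; ++i) {
        const double ux = (u(i, j + 1) - u(i, j - 1)) / 2.0;
        const double uy = (u(i + 1, j) - u(i - 1, j)) / 2.0;
        const double uxx = u(i, j + 1) - 2 * u(i, j) + u(i, j - 1);
        const double uyy = u(i + 1, j) - 2 * u(i, j) + u(i - 1, j);
        const double uxy = (u(i + 1, j + 1) - u(i + 1, j - 1) -
                            u(i - 1, j + 1) + u(i - 1, j - 1)) / 4.0;
        const double g2 = ux * ux + uy * uy;
        double F;
        if (g2 > g2min) {
          F = (uxx * uy * uy - 2 * ux * uy * uxy + uyy * ux * ux) / g2;
        } else {
          // Hessian eigenvalue of smaller magnitude
          const double tr = uxx + uyy;
          const double disc = std::sqrt(std::max(
              0.0, (uxx - uyy) * (uxx - uyy) / 4.0 + uxy * uxy));
          const double l1 = tr / 2.0 + disc, l2 = tr / 2.0 - disc;
          F = std::abs(l1) < std::abs(l2) ? l1 : l2;
        }
        if (minmax) {
          double s = 0; int n = 0;
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0) continue;
              s += u(i + di, j + dj); ++n;
            }
          const double avg = s / n;
          F = (u(i, j) > avg) ? std::min(F, 0.0) : std::max(F, 0.0);
        }
        unew(i, j) = u(i, j) + dt * F;
      }
    }
    u = unew;
  }
  // magnitudes stay non-negative
  u.transform([](double v) { return v < 0 ? 0.0 : v; });
  return u;
}
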