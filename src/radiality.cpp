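#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Catmull-Rom cubic interpolation (a = -1/2 cubic convolution kernel)
static inline double cubic1d(double p0, double p1, double p2, double p3, double t) {
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// bicubic sample of M (rows = y) at continuous (y, x), clamped borders
static double interp_bicubic(const arma::mat& M, double y, double x) {
  int H = M.n_rows, W = M.n_cols;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double tx = x - x0, ty = y - y0;
  double col[4];
  for (int j = -1; j <= 2; ++j) {
    int xj = clampi(x0 + j, 0, W - 1);
    double p0 = M(clampi(y0 - 1, 0, H - 1), xj);
    double p1 = M(clampi(y0,     0, H - 1), xj);
    double p2 = M(clampi(y0 + 1, 0, H - 1), xj);
    double p3 = M(clampi(y0 + 2, 0, H - 1), xj);
    col[j + 1] = cubic1d(p0, p1, p2, p3, ty);
  }
  return cubic1d(col[0], col[1], col[2], col[3], tx);
}

// Radiality map of one frame: gradient-line convergence scoring.
// For each magnified sub-pixel centre c, gradients are sampled (bicubic)
// at 2*axes points on a ring of radius ring_radius (source pixels); each
// sample scores by how close the line through it along its gradient passes
// to c, signed by whether the gradient points toward c.
// [[Rcpp::export]]
arma::mat radiality_cpp(const arma::mat& frame, double ring_radius,
                        int mag, int axes, int score_power) {
  int H = frame.n_rows, W = frame.n_cols;
  arma::mat gx(H, W), gy(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      gx(y, x) = 0.5 * (frame(y, clampi(x + 1, 0, W - 1)) -
                        frame(y, clampi(x - 1, 0, W - 1)));
      gy(y, x) = 0.5 * (frame(clampi(y + 1, 0, H - 1), x) -
                        frame(clampi(y - 1, 0, H - 1), x));
    }
  }
  int ns = 2 * axes;
  std::vector<double> cth(ns), sth(ns);
  for (int q = 0; q < ns; ++q) {
    double th = 2.0 * M_PI * q / ns;
    cth[q] = std::cos(th);
    sth[q] = std::sin(th);
  }
  arma::mat out(H * mag, W * mag);
  const double eps = 1e-12;
  for (int X = 0; X < W * mag; ++X) {
    double cx = (X + 0.5) / mag - 0.5;
    for (int Y = 0; Y < H * mag; ++Y) {
      double cy = (Y + 0.5) / mag - 0.5;
      double acc = 0.0;
      for (int q = 0; q < ns; ++q) {
        double px = cx + ring_radius * cth[q];
        double py = cy + ring_radius * sth[q];
        double gxi = interp_bicubic(gx, py, px);
        double gyi = interp_bicubic(gy, py, px);
        double gn = std::sqrt(gxi * gxi + gyi * gyi);
        if (gn < eps) continue;
        double ux = cx - px, uy = cy - py;
        double d = std::fabs(gxi * uy - gyi * ux) / gn;     // centre-to-line distance
        double conv = 1.0 - std::min(d, ring_radius) / ring_radius;
        double s = (gxi * ux + gyi * uy >= 0.0) ? 1.0 : -1.0;
        acc += s * std::pow(conv, (double)score_power);
      }
      out(Y, X) = acc / ns;
    }
  }
  return out;
}

// Bicubic rotation about the image centre; destination pixels whose source
// falls outside the image are set to NA so callers can detect clipped ROIs.
// [[Rcpp::export]]
arma::mat rotate_bicubic_cpp(const arma::mat& img, double angle_deg) {
  int H = img.n_rows, W = img.n_cols;
  double th = angle_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  arma::mat out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      // inverse map: rotate destination coords by -angle around the centre
      double dx = x - cx, dy = y - cy;
      double sx = cx + ct * dx + st * dy;
      double sy = cy - st * dx + ct * dy;
      if (sx < 0 || sx > W - 1 || sy < 0 || sy > H - 1) {
        out(y, x) = NA_REAL;
      } else {
        out(y, x) = interp_bicubic(img, sy, sx);
      }
    }
  }
  return out;
}
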