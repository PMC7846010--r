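#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

#ifndef RESTRICT
# define RESTRICT __restrict__
#endif

// ---------------------------------------------------------------------------
// Exact disc / rectangle overlap geometry (continuous, pixel-centre hull).
// Radii are constrained upstream to at most half the shorter window side,
// so a disc can clip at most one vertical and one horizontal edge.
// ---------------------------------------------------------------------------

// area of the circular segment beyond a chord at distance d from the centre
static double seg_area(double d, double r) {
  if (d >= r) return 0.0;
  return r * r * std::acos(d / r) - d * std::sqrt(r * r - d * d);
}

static double G_int(double u, double r) {
  // antiderivative of sqrt(r^2 - u^2)
  double s = std::max(0.0, r * r - u * u);
  double q = std::min(1.0, std::max(-1.0, u / r));
  return 0.5 * (u * std::sqrt(s) + r * r * std::asin(q));
}

// area of the disc with u >= a and v >= b (a, b >= 0, a^2 + b^2 < r^2)
static double corner_area(double a, double b, double r) {
  double xm = std::sqrt(r * r - b * b);
  return G_int(xm, r) - G_int(a, r) - b * (xm - a);
}

// overlap of a disc of radius r whose centre lies at distances (ax, ay)
// from the nearest vertical and horizontal window edges
static double disc_window_overlap(double ax, double ay, double r) {
  double area = M_PI * r * r - seg_area(ax, r) - seg_area(ay, r);
  if (ax * ax + ay * ay < r * r) area += corner_area(ax, ay, r);
  return area;
}

// Besag edge-correction weights for a full W x H rectangular window.
// Returns an H x W matrix (rows = y) of pi r^2 / overlap, >= 1.
// [[Rcpp::export]]
arma::mat besag_weights_rect_cpp(int W, int H, double r) {
  arma::mat e(H, W);
  double full = M_PI * r * r;
  for (int x = 0; x < W; ++x) {
    double ax = std::min((double)x, (double)(W - 1 - x));
    for (int y = 0; y < H; ++y) {
      double ay = std::min((double)y, (double)(H - 1 - y));
      e(y, x) = full / disc_window_overlap(ax, ay, r);
    }
  }
  return e;
}

// ---------------------------------------------------------------------------
// Intensity-weighted Ripley K with Besag correction on a full rectangle.
//
//   K(r) = A * sum_{i != j} w_i w_j e_i(r) 1(d_ij <= r) / (sum w)^2
//
// split as  sum_i w_i (N_i - w_i)                 [FFT autocorrelation]
//         + sum_i w_i (e_i - 1) (N_i - w_i)       [edge band, prefix sums]
// where N_i = sum_{|delta| <= r} w_{i+delta} (self included).
// The permutation null packs two permuted fields per complex FFT.
// ---------------------------------------------------------------------------

static int next_pow2(int n) {
  int p = 1;
  while (p < n) p <<= 1;
  return p;
}

struct KWorkspace {
  int W, H, P1, P2, nrad, M;      // M = floor(rmax)
  arma::vec radii;                 // px units, increasing
  std::vector<int> off_dy, off_dx; // offsets grouped by ring bin
  std::vector<int> bin_start;      // size nrad + 1
  std::vector<std::vector<int>> hline; // hline[k][dx] = floor(sqrt(r_k^2-dx^2))
  arma::cube em1;                  // (M+1) x (M+1) x nrad, e(ax,ay;r_k) - 1
};

static void build_workspace(KWorkspace& ws, int W, int H, const arma::vec& radii) {
  ws.W = W; ws.H = H; ws.radii = radii;
  ws.nrad = radii.n_elem;
  double rmax = radii(ws.nrad - 1);
  ws.M = (int)std::floor(rmax);
  ws.P1 = next_pow2(H + ws.M + 1);
  ws.P2 = next_pow2(W + ws.M + 1);

  // ring-binned offsets (delta != 0, |delta| <= rmax)
  std::vector<std::vector<std::pair<int,int>>> bins(ws.nrad);
  for (int dx = -ws.M; dx <= ws.M; ++dx) {
    for (int dy = -ws.M; dy <= ws.M; ++dy) {
      if (dx == 0 && dy == 0) continue;
      double d = std::sqrt((double)(dx * dx + dy * dy));
      if (d > rmax) continue;
      int k = (int)(std::lower_bound(radii.begin(), radii.end(), d - 1e-9) - radii.begin());
      if (k >= ws.nrad) continue;
      bins[k].push_back(std::make_pair(dy, dx));
    }
  }
  ws.off_dy.clear(); ws.off_dx.clear();
  ws.bin_start.assign(ws.nrad + 1, 0);
  for (int k = 0; k < ws.nrad; ++k) {
    ws.bin_start[k] = (int)ws.off_dy.size();
    for (size_t j = 0; j < bins[k].size(); ++j) {
      ws.off_dy.push_back(bins[k][j].first);
      ws.off_dx.push_back(bins[k][j].second);
    }
  }
  ws.bin_start[ws.nrad] = (int)ws.off_dy.size();

  // half-chord table per radius
  ws.hline.assign(ws.nrad, std::vector<int>());
  for (int k = 0; k < ws.nrad; ++k) {
    double r = radii(k);
    int I = (int)std::floor(r);
    ws.hline[k].assign(I + 1, 0);
    for (int dx = 0; dx <= I; ++dx)
      ws.hline[k][dx] = (int)std::floor(std::sqrt(std::max(0.0, r * r - dx * dx)) + 1e-9);
  }

  // edge factor table by (capped ax, capped ay, radius)
  ws.em1.set_size(ws.M + 1, ws.M + 1, ws.nrad);
  for (int k = 0; k < ws.nrad; ++k) {
    double r = radii(k);
    double full = M_PI * r * r;
    for (int a = 0; a <= ws.M; ++a) {
      for (int b = 0; b <= ws.M; ++b) {
        ws.em1(a, b, k) = full / disc_window_overlap((double)a, (double)b, r) - 1.0;
      }
    }
  }
}

// ring-cumulated autocorrelation sums S1(k) = sum_{0<|d|<=r_k} X(d)
static void ring_sums(const KWorkspace& ws, const arma::mat& X, arma::vec& S1) {
  S1.zeros(ws.nrad);
  double acc = 0.0;
  for (int k = 0; k < ws.nrad; ++k) {
    for (int j = ws.bin_start[k]; j < ws.bin_start[k + 1]; ++j) {
      int iy = ws.off_dy[j]; if (iy < 0) iy += ws.P1;
      int ix = ws.off_dx[j]; if (ix < 0) ix += ws.P2;
      acc += X(iy, ix);
    }
    S1(k) = acc;
  }
}

// disc column-segment accumulation over one y range, split into clamp-free
// zones so the hot loop auto-vectorises:
//   y in [0, h-1]       : pc[y+h+1]           (window clipped below)
//   y in [h, H-1-h]     : pc[y+h+1] - pc[y-h]
//   y in [H-h, H-1]     : pc[H]    - pc[y-h]  (window clipped above)
static inline void add_colseg(double* RESTRICT N, const double* RESTRICT pc,
                              int h, int H, int y0, int y1) {
  int a = std::min(y1, h - 1);
  for (int y = y0; y <= a; ++y) N[y] += pc[y + h + 1];
  int b = std::max(y0, h), c = std::min(y1, H - 1 - h);
  for (int y = b; y <= c; ++y) N[y] += pc[y + h + 1] - pc[y - h];
  int d = std::max(y0, H - h);
  double top = pc[H];
  for (int y = d; y <= y1; ++y) N[y] += top - pc[y - h];
}

// edge band correction: sum_i w_i (e_i(r_k) - 1) (N_i(r_k) - w_i)
static void band_terms(const KWorkspace& ws, const arma::mat& w, arma::vec& S2) {
  const int W = ws.W, H = ws.H, M = ws.M;
  // column prefix sums: P(y+1, x) = sum_{y' <= y} w(y', x)
  arma::mat P(H + 1, W);
  for (int x = 0; x < W; ++x) {
    P(0, x) = 0.0;
    const double* wc = w.colptr(x);
    double* pc = P.colptr(x);
    for (int y = 0; y < H; ++y) pc[y + 1] = pc[y] + wc[y];
  }
  std::vector<int> ayc(H);
  for (int y = 0; y < H; ++y) ayc[y] = std::min(std::min(y, H - 1 - y), M);
  S2.zeros(ws.nrad);
  std::vector<double> Nbuf(H);
  for (int k = 0; k < ws.nrad; ++k) {
    double r = ws.radii(k);
    int I = (int)ws.hline[k].size() - 1;
    int yb = (int)std::ceil(r - 1e-9) - 1;       // largest integer strictly < r
    const double* em1k = &ws.em1(0, 0, k);
    const int* hl = ws.hline[k].data();
    double acc = 0.0;
    for (int x = 0; x < W; ++x) {
      int ax = std::min(x, W - 1 - x);
      bool colfull = (ax < r);                    // whole column is in the band
      int axc = std::min(ax, M);
      int n_rng, lo[2], hi[2];
      if (colfull) { n_rng = 1; lo[0] = 0; hi[0] = H - 1; }
      else {
        n_rng = 0;
        int h1 = std::min(yb, H - 1);
        if (h1 >= 0) { lo[n_rng] = 0; hi[n_rng] = h1; ++n_rng; }
        int l2 = std::max(H - 1 - yb, h1 + 1);
        if (l2 <= H - 1) { lo[n_rng] = l2; hi[n_rng] = H - 1; ++n_rng; }
        if (n_rng == 0) continue;
      }
      int dlo = std::max(-I, -x), dhi = std::min(I, W - 1 - x);
      for (int q = 0; q < n_rng; ++q)
        std::fill(Nbuf.begin() + lo[q], Nbuf.begin() + hi[q] + 1, 0.0);
      for (int dx = dlo; dx <= dhi; ++dx) {
        int h = hl[dx < 0 ? -dx : dx];
        const double* pc = P.colptr(x + dx);
        for (int q = 0; q < n_rng; ++q)
          add_colseg(Nbuf.data(), pc, h, H, lo[q], hi[q]);
      }
      const double* wc = w.colptr(x);
      const double* em1x = em1k + (size_t)axc * (M + 1);
      for (int q = 0; q < n_rng; ++q) {
        for (int y = lo[q]; y <= hi[q]; ++y) {
          double wv = wc[y];
          if (wv == 0.0) continue;
          double em1 = em1x[ayc[y]];
          if (em1 != 0.0) acc += em1 * wv * (Nbuf[y] - wv);
        }
      }
    }
    S2(k) = acc;
  }
}

static arma::vec k_from_field(const KWorkspace& ws, const arma::mat& w,
                              const arma::mat& X, bool edge_correct) {
  arma::vec S1, S2(ws.nrad, arma::fill::zeros);
  ring_sums(ws, X, S1);
  if (edge_correct) band_terms(ws, w, S2);
  double SW = arma::accu(w);
  double A = (double)(ws.W * ws.H);
  return A * (S1 + S2) / (SW * SW);
}

// autocorrelation of a zero-padded field via FFT (linear, no wrap)
static arma::mat autocorr_fft(const KWorkspace& ws, const arma::mat& w) {
  arma::cx_mat z(ws.P1, ws.P2, arma::fill::zeros);
  z.submat(0, 0, ws.H - 1, ws.W - 1) = arma::cx_mat(w, arma::mat(ws.H, ws.W, arma::fill::zeros));
  arma::cx_mat F = arma::fft2(z);
  arma::cx_mat X = arma::ifft2(F % arma::conj(F));
  return arma::real(X);
}

// Observed K curve plus nsim permutation-null K curves.
// w: H x W nonnegative weights; radii in pixel units.
// Returns (nsim + 1) x nrad; row 0 = observed. Uses R's RNG for permutations.
// [[Rcpp::export]]
arma::mat k_perm_engine(const arma::mat& w, const arma::vec& radii_px,
                        int nsim, bool edge_correct = true) {
  KWorkspace ws;
  build_workspace(ws, w.n_cols, w.n_rows, radii_px);
  arma::mat out(nsim + 1, ws.nrad);
  out.row(0) = k_from_field(ws, w, autocorr_fft(ws, w), edge_correct).t();

  if (nsim <= 0) return out;
  int N = ws.W * ws.H;
  arma::vec wflat = arma::vectorise(w);

  // two permutations per complex FFT
  for (int s = 1; s <= nsim; s += 2) {
    bool pair = (s + 1 <= nsim);
    arma::mat wA(ws.H, ws.W), wB;
    {
      IntegerVector p = Rcpp::sample(N, N); // 1-based permutation
      for (int i = 0; i < N; ++i) wA(i) = wflat(p[i] - 1);
    }
    if (pair) {
      wB.set_size(ws.H, ws.W);
      IntegerVector p = Rcpp::sample(N, N);
      for (int i = 0; i < N; ++i) wB(i) = wflat(p[i] - 1);
    }
    if (!pair) {
      out.row(s) = k_from_field(ws, wA, autocorr_fft(ws, wA), edge_correct).t();
      break;
    }
    // packed FFT: F = fft(wA + i wB); unpack spectra, ifft packed power spectra
    arma::cx_mat z(ws.P1, ws.P2, arma::fill::zeros);
    z.submat(0, 0, ws.H - 1, ws.W - 1) = arma::cx_mat(wA, wB);
    arma::cx_mat F = arma::fft2(z);
    arma::mat GA(ws.P1, ws.P2), GB(ws.P1, ws.P2);
    for (int j = 0; j < ws.P2; ++j) {
      int jr = (ws.P2 - j) % ws.P2;
      for (int i = 0; i < ws.P1; ++i) {
        int ir = (ws.P1 - i) % ws.P1;
        std::complex<double> f = F(i, j), fr = std::conj(F(ir, jr));
        std::complex<double> fa = 0.5 * (f + fr);
        std::complex<double> fb = std::complex<double>(0, -0.5) * (f - fr);
        GA(i, j) = std::norm(fa);
        GB(i, j) = std::norm(fb);
      }
    }
    arma::cx_mat Xp = arma::ifft2(arma::cx_mat(GA, GB));
    out.row(s)     = k_from_field(ws, wA, arma::real(Xp), edge_correct).t();
    out.row(s + 1) = k_from_field(ws, wB, arma::imag(Xp), edge_correct).t();
  }
  return out;
}
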