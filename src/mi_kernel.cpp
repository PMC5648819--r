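#include <Rcpp.h>
using namespace Rcpp;

// Gaussian kernel on [0,1] with boundary reflection at 0 and 1.
// Rank-transformed data live strictly inside the unit interval; reflection
// stops the density estimate from leaking mass outside it.
static inline double kernel_refl(double u, double v, double inv2h2) {
  double d1 = u - v, d2 = u + v, d3 = u + v - 2.0;
  return std::exp(-d1 * d1 * inv2h2) + std::exp(-d2 * d2 * inv2h2) +
         std::exp(-d3 * d3 * inv2h2);
}

// Plug-in kernel MI from precomputed per-feature kernel matrices.
// kx, ky: n*n column-major kernel matrices; rsx, rsy: their row sums.
// w_loo blends the leave-one-out log-density estimate (weight w_loo) with the
// full-sample one (weight 1 - w_loo); the two bracket the truth (the self term
// inflates densities, dropping it deflates them), so the blend cancels most of
// the small-sample bias in both the null and the strongly dependent regime.
static double mi_from_kernels(const double* kx, const double* ky,
                              const double* rsx, const double* rsy,
                              int n, double w_loo) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* kxi = kx + (size_t)i * n;
    const double* kyi = ky + (size_t)i * n;
    double fj = 0.0;
    for (int j = 0; j < n; ++j) fj += kxi[j] * kyi[j];
    double fx = rsx[i], fy = rsy[i];
    double si = kxi[i] * kyi[i];
    double lfull = std::log(n * fj / (fx * fy));
    double lloo  = std::log((n - 1.0) * (fj - si) / ((fx - kxi[i]) * (fy - kyi[i])));
    acc += (1.0 - w_loo) * lfull + w_loo * lloo;
  }
  return acc / n;
}

static void fill_kernel(const double* x, int n, double inv2h2,
                        double* k, double* rs) {
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double v = kernel_refl(x[i], x[j], inv2h2);
      k[(size_t)i * n + j] = v;
      s += v;
    }
    rs[i] = s;
  }
}

// [[Rcpp::export(name = ".mi_pair_cpp")]]
double mi_pair_cpp(NumericVector x, NumericVector y, double h, double w_loo) {
  int n = x.size();
  double inv2h2 = 1.0 / (2.0 * h * h);
  std::vector<double> kx((size_t)n * n), ky((size_t)n * n), rsx(n), rsy(n);
  fill_kernel(REAL(x), n, inv2h2, kx.data(), rsx.data());
  fill_kernel(REAL(y), n, inv2h2, ky.data(), rsy.data());
  double mi = mi_from_kernels(kx.data(), ky.data(), rsx.data(), rsy.data(), n, w_loo);
  return mi > 0.0 ? mi : 0.0;
}

// All unordered pairs (i < j) restricted to pair_mask (p*p logical, column
// major, symmetric). rank_mat: n x p matrix of rank-transformed features.
// Returns a p x p symmetric matrix with NA on the diagonal and for skipped
// pairs. Kernel matrices are precomputed per feature so each pair costs one
// n^2 multiply-accumulate pass.
// [[Rcpp::export(name = ".mi_allpairs_cpp")]]
NumericMatrix mi_allpairs_cpp(NumericMatrix rank_mat, double h, double w_loo,
                              LogicalMatrix pair_mask) {
  int n = rank_mat.nrow(), p = rank_mat.ncol();
  double inv2h2 = 1.0 / (2.0 * h * h);
  std::vector<double> kern((size_t)p * n * n), rs((size_t)p * n);
  for (int f = 0; f < p; ++f) {
    fill_kernel(&rank_mat(0, f), n, inv2h2,
                kern.data() + (size_t)f * n * n, rs.data() + (size_t)f * n);
  }
  NumericMatrix out(p, p);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int a = 0; a < p; ++a) {
    for (int b = a + 1; b < p; ++b) {
      if (!pair_mask(a, b)) continue;
      double mi = mi_from_kernels(kern.data() + (size_t)a * n * n,
                                  kern.data() + (size_t)b * n * n,
                                  rs.data() + (size_t)a * n,
                                  rs.data() + (size_t)b * n, n, w_loo);
      if (mi < 0.0) mi = 0.0;
      out(a, b) = mi;
      out(b, a) = mi;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Null MI draws: MI between independently permuted columns of rank_mat.
// pair_a / pair_b are 0-based feature indices; perm is an n x m matrix of
// 0-based permutations applied to the second feature of each draw.
// [[Rcpp::export(name = ".mi_null_cpp")]]
NumericVector mi_null_cpp(NumericMatrix rank_mat, double h, double w_loo,
                          IntegerVector pair_a, IntegerVector pair_b,
                          IntegerMatrix perm) {
  int n = rank_mat.nrow();
  int m = pair_a.size();
  double inv2h2 = 1.0 / (2.0 * h * h);
  NumericVector out(m);
  std::vector<double> kx((size_t)n * n), ky((size_t)n * n), rsx(n), rsy(n), yp(n);
  for (int t = 0; t < m; ++t) {
    const double* x = &rank_mat(0, pair_a[t]);
    const double* y = &rank_mat(0, pair_b[t]);
    for (int i = 0; i < n; ++i) yp[i] = y[perm(i, t % perm.ncol())];
    fill_kernel(x, n, inv2h2, kx.data(), rsx.data());
    fill_kernel(yp.data(), n, inv2h2, ky.data(), rsy.data());
    double mi = mi_from_kernels(kx.data(), ky.data(), rsx.data(), rsy.data(), n, w_loo);
    out[t] = mi > 0.0 ? mi : 0.0;
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
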