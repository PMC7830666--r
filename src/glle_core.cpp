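#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// |x|^p specialised for the common grid orders: integer p and p = 0.5 avoid
// std::pow in the O(M^2) loops, which dominates the neighbour search cost.
struct PowOp {
  double p;
  int ip;        // p rounded, valid when is_int
  bool is_int;
  bool is_half;
  explicit PowOp(double p_) : p(p_) {
    ip = (int) std::lround(p_);
    is_int = std::fabs(p_ - ip) < 1e-12 && ip >= 1;
    is_half = std::fabs(p_ - 0.5) < 1e-12;
  }
  inline double operator()(double x) const {
    x = std::fabs(x);
    if (is_int) {
      double r = x;
      for (int k = 1; k < ip; ++k) r *= x;
      return r;
    }
    if (is_half) return std::sqrt(x);
    return std::pow(x, p);
  }
};

// Sum_k |u_k - v_k|^p between rows a and b of traj (column-major access).
// Stops early once the partial sum exceeds `cap` (monotone in k).
static inline double row_ppow_dist(const double* x, int M, int m,
                                   int a, int b, const PowOp& op,
                                   double cap = R_PosInf) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    s += op(x[a + (size_t)k * M] - x[b + (size_t)k * M]);
    if (s >= cap) return s;
  }
  return s;
}

// [[Rcpp::export]]
List nn_search_cpp(NumericMatrix traj, double p, int min_sep) {
  const int M = traj.nrow(), m = traj.ncol();
  const double* x = REAL(traj);
  PowOp op(p);
  IntegerVector idx(M);
  NumericVector dist(M);
  for (int j = 0; j < M; ++j) {
    double best = R_PosInf;
    int bestk = NA_INTEGER;
    for (int k = 0; k < M; ++k) {
      if (std::abs(k - j) <= min_sep) continue;
      double d = row_ppow_dist(x, M, m, j, k, op, best);
      if (d < best) { best = d; bestk = k; }
    }
    if (bestk == NA_INTEGER) {
      idx[j] = NA_INTEGER;
      dist[j] = NA_REAL;
    } else {
      idx[j] = bestk + 1;                      // 1-based
      dist[j] = std::pow(best, 1.0 / p);
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Average log p-norm separation of neighbour pairs after i steps,
// i = 0..k_max.  Pairs leave the average once either trajectory index runs
// off the end of the matrix; zero separations are excluded from that step.
// [[Rcpp::export]]
List div_curve_cpp(NumericMatrix traj, IntegerVector nn, double p, int k_max) {
  const int M = traj.nrow(), m = traj.ncol();
  const double* x = REAL(traj);
  PowOp op(p);
  const double inv_p = 1.0 / p;
  NumericVector mean_log(k_max + 1);
  IntegerVector n_valid(k_max + 1);
  for (int i = 0; i <= k_max; ++i) {
    double acc = 0.0;
    int n = 0;
    for (int j = 0; j < M; ++j) {
      int jm = nn[j];
      if (jm == NA_INTEGER) continue;
      --jm;                                    // 0-based
      if (j + i >= M || jm + i >= M) continue;
      double d = row_ppow_dist(x, M, m, j + i, jm + i, op);
      if (d <= 0.0) continue;
      acc += inv_p * std::log(d);              // log(d^(1/p))
      ++n;
    }
    mean_log[i] = n > 0 ? acc / n : NA_REAL;
    n_valid[i] = n;
  }
  return List::create(_["mean_log"] = mean_log, _["n_valid"] = n_valid);
}

// Cao (1997) quantities for dimensions d = 1..max_d: E(d) from the mean
// ratio of (d+1)- to d-dimensional maximum-norm neighbour distances and
// E*(d) from the mean extra-coordinate gap.  Neighbours are recomputed per
// d over the N - d*J vectors that still extend to dimension d + 1.
// [[Rcpp::export]]
NumericMatrix cao_e_cpp(NumericVector x, int J, int max_d) {
  const int N = x.size();
  NumericMatrix out(max_d, 2);
  for (int d = 1; d <= max_d; ++d) {
    const int M = N - d * J;                   // rows embeddable at d+1
    if (M < 2) { out(d - 1, 0) = NA_REAL; out(d - 1, 1) = NA_REAL; continue; }
    double acc_a = 0.0, acc_s = 0.0;
    int n_a = 0;
    for (int i = 0; i < M; ++i) {
      double best = R_PosInf;
      int bestk = -1;
      for (int k = 0; k < M; ++k) {
        if (k == i) continue;
        double dm = 0.0;
        for (int c = 0; c < d; ++c) {
          double diff = std::fabs(x[i + c * J] - x[k + c * J]);
          if (diff > dm) dm = diff;
          if (dm >= best) break;
        }
        if (dm < best) { best = dm; bestk = k; }
      }
      if (bestk < 0) continue;
      double dm1 = best;
      double extra = std::fabs(x[i + d * J] - x[bestk + d * J]);
      if (extra > dm1) dm1 = extra;            // max norm in d+1 dims
      if (best > 0.0) { acc_a += dm1 / best; ++n_a; }
      acc_s += extra;
    }
    out(d - 1, 0) = n_a > 0 ? acc_a / n_a : NA_REAL;  // E(d)
    out(d - 1, 1) = acc_s / M;                        // E*(d)
  }
  return out;
}

// Grassberger-Procaccia correlation sum: fraction of pairs with temporal
// separation > theiler whose Euclidean distance is below each radius.
// [[Rcpp::export]]
List corr_sum_cpp(NumericMatrix traj, NumericVector radii, int theiler) {
  const int M = traj.nrow(), m = traj.ncol();
  const int nr = radii.size();
  const double* x = REAL(traj);
  std::vector<double> r2(nr);
  for (int q = 0; q < nr; ++q) r2[q] = radii[q] * radii[q];
  std::vector<double> counts(nr, 0.0);
  double n_pairs = 0.0;
  for (int j = 0; j < M; ++j) {
    for (int k = j + theiler + 1; k < M; ++k) {
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = x[j + (size_t)c * M] - x[k + (size_t)c * M];
        s += diff * diff;
      }
      n_pairs += 1.0;
      // radii sorted ascending: record the smallest covering radius,
      // accumulate into C(r) afterwards
      int lo = 0, hi = nr;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (s < r2[mid]) hi = mid; else lo = mid + 1;
      }
      if (lo < nr) counts[lo] += 1.0;
    }
  }
  NumericVector cr(nr);
  double run = 0.0;
  for (int q = 0; q < nr; ++q) {
    run += counts[q];
    cr[q] = n_pairs > 0 ? run / n_pairs : NA_REAL;
  }
  return List::create(_["c_r"] = cr, _["n_pairs"] = n_pairs);
}
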