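#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// `order` below holds one column of 0-based row indices per pass (a
// single column is reused for every epoch; with per-epoch shuffling one
// column per epoch is supplied).
//
// Candidate TADs are half-open bin intervals [start, end); the response
// row t corresponds to the lower-triangle bin pair (i, j), i >= j, in
// row-major order (i = 0..m-1, j = 0..i). A pair belongs to a candidate
// iff start <= j and i < end, and its design value depends only on the
// bin distance d = i - j: x_d as supplied (log(m/(d+1)) by default).

static inline double weight_of(double z, double nn, double alpha,
                               double beta, double l1, bool nonneg) {
  if (std::fabs(z) <= l1) return 0.0;
  double w = -(z - (z > 0 ? l1 : -l1)) * alpha / (beta + std::sqrt(nn));
  if (nonneg && w < 0.0) w = 0.0;
  return w;
}

// predicted response for every lower-triangle pair given coefficients w
static void predict_all(const std::vector<double>& w,
                        const IntegerVector& starts,
                        const IntegerVector& ends, int m,
                        const NumericVector& xd,
                        std::vector<double>& yhat) {
  int n = starts.size();
  std::fill(yhat.begin(), yhat.end(), 0.0);
  for (int c = 0; c < n; c++) {
    if (w[c] == 0.0) continue;
    int s = starts[c], e = ends[c];
    for (int i = s; i < e; i++) {
      int base = i * (i + 1) / 2;
      for (int j = s; j <= i; j++) {
        yhat[base + j] += w[c] * xd[i - j];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector ftrl_predict_cpp(NumericVector w, IntegerVector starts,
                               IntegerVector ends, int m, NumericVector xd) {
  int npairs = m * (m + 1) / 2;
  std::vector<double> wv(w.begin(), w.end());
  std::vector<double> yhat(npairs, 0.0);
  predict_all(wv, starts, ends, m, xd, yhat);
  return NumericVector(yhat.begin(), yhat.end());
}

// FTRL-Proximal with quadratic loss, L1 soft-thresholding and
// nonnegativity clamping. Y: npairs x k response matrix; `order` is the
// 0-based row stream of one pass (possibly bootstrap-resampled).
// Candidates must be sorted by start ascending (allows early exit).
// [[Rcpp::export]]
List ftrl_fit_cpp(NumericMatrix Y, IntegerVector starts, IntegerVector ends,
                  int m, NumericVector xd, double alpha, double beta,
                  double l1, int epochs, IntegerMatrix order,
                  bool nonneg = true) {
  int n = starts.size();
  int k = Y.ncol();
  int npairs = m * (m + 1) / 2;
  if (Y.nrow() != npairs) stop("response length must be m(m+1)/2");
  std::vector<double> z(n, 0.0), nn(n, 0.0);
  std::vector<int> ri(npairs), rj(npairs);
  {
    int t = 0;
    for (int i = 0; i < m; i++)
      for (int j = 0; j <= i; j++) { ri[t] = i; rj[t] = j; t++; }
  }
  NumericMatrix r2hist(epochs, k);
  std::vector<int> active;
  active.reserve(256);
  std::vector<double> wact(256);
  std::vector<double> yhat(npairs);
  for (int e = 0; e < epochs; e++) {
    int ocol = (order.ncol() > 1) ? (e % order.ncol()) : 0;
    for (int r = 0; r < k; r++) {
      for (int oi = 0; oi < order.nrow(); oi++) {
        int t = order(oi, ocol);
        int i = ri[t], j = rj[t];
        double x = xd[i - j];
        if (x == 0.0) continue;
        active.clear();
        double p = 0.0;
        for (int c = 0; c < n; c++) {
          if (starts[c] > j) break;
          if (i < ends[c]) active.push_back(c);
        }
        if (active.empty()) continue;
        if (wact.size() < active.size()) wact.resize(active.size());
        for (size_t a = 0; a < active.size(); a++) {
          double w = weight_of(z[active[a]], nn[active[a]], alpha, beta,
                               l1, nonneg);
          wact[a] = w;
          p += x * w;
        }
        double y = Y(t, r);
        if (!R_finite(y)) stop("non-finite response at row %d", t + 1);
        double g0 = (p - y) * x;
        for (size_t a = 0; a < active.size(); a++) {
          int c = active[a];
          double sigma = (std::sqrt(nn[c] + g0 * g0) - std::sqrt(nn[c])) / alpha;
          z[c] += g0 - sigma * wact[a];
          nn[c] += g0 * g0;
        }
      }
    }
    // end-of-epoch diagnostics: R^2 per replicate on current coefficients
    std::vector<double> w(n);
    for (int c = 0; c < n; c++)
      w[c] = weight_of(z[c], nn[c], alpha, beta, l1, nonneg);
    predict_all(w, starts, ends, m, xd, yhat);
    for (int r = 0; r < k; r++) {
      double ybar = 0.0;
      for (int t = 0; t < npairs; t++) ybar += Y(t, r);
      ybar /= npairs;
      double sstot = 0.0, ssres = 0.0;
      for (int t = 0; t < npairs; t++) {
        double dy = Y(t, r) - ybar;
        double dr = Y(t, r) - yhat[t];
        sstot += dy * dy;
        ssres += dr * dr;
      }
      r2hist(e, r) = (sstot > 0.0) ? 1.0 - ssres / sstot : NA_REAL;
    }
  }
  std::vector<double> w(n);
  for (int c = 0; c < n; c++)
    w[c] = weight_of(z[c], nn[c], alpha, beta, l1, nonneg);
  return List::create(_["coefficients"] = NumericVector(w.begin(), w.end()),
                      _["r2_history"] = r2hist);
}
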