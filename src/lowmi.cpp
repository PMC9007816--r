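#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Quantized log-ratio: [ln(i/j)/q]_R * q with round-half-away-from-zero,
// clamped to the representable fixed-point range [-vmax, vmax] where
// vmax = 2^bi - q. std::round rounds halves away from zero, matching the
// R-side LUT builder bit for bit.
static inline double quant_log_ratio(double i, double j, double q, double vmax) {
  double v = std::round(std::log(i / j) / q) * q;
  if (v > vmax) return vmax;
  if (v < -vmax) return -vmax;
  return v;
}

// Stream (x, y) pairs into a joint counter table with saturation halving:
// whenever the population counter C would exceed M, every joint counter is
// halved (floor) and C recomputed as their sum before the increment.
// M = R_PosInf disables halving (full-precision tally).
static bool accumulate_joint(const int* x, const int* y, int n,
                             NumericMatrix joint, double M, double& C) {
  bool saturated = false;
  int cells = joint.nrow() * joint.ncol();
  C = 0.0;
  for (int t = 0; t < n; ++t) {
    if (C + 1.0 > M) {
      saturated = true;
      C = 0.0;
      for (int idx = 0; idx < cells; ++idx) {
        joint[idx] = std::floor(joint[idx] / 2.0);
        C += joint[idx];
      }
    }
    joint(x[t], y[t]) += 1.0;
    C += 1.0;
  }
  return saturated;
}

// Plug-in MI (nats) from a joint counter table; lowprec = true replaces each
// of the three log terms with its quantized LUT value. Marginals are derived
// from the (possibly halved) joint table. Zero joint cells contribute 0.
static double mi_from_joint(const NumericMatrix& joint, double C,
                            bool lowprec, double q, double vmax) {
  int nr = joint.nrow(), nc = joint.ncol();
  std::vector<double> rs(nr, 0.0), cs(nc, 0.0);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) { rs[i] += joint(i, j); cs[j] += joint(i, j); }
  double mi = 0.0;
  for (int i = 0; i < nr; ++i) {
    if (rs[i] == 0.0) continue;
    for (int j = 0; j < nc; ++j) {
      double c = joint(i, j);
      if (c == 0.0) continue;
      double w = c / C;
      if (lowprec) {
        mi += w * (quant_log_ratio(c, C, q, vmax)
                   - quant_log_ratio(rs[i], C, q, vmax)
                   - quant_log_ratio(cs[j], C, q, vmax));
      } else {
        mi += w * std::log((c * C) / (rs[i] * cs[j]));
      }
    }
  }
  return mi;
}

// [[Rcpp::export]]
List cpp_accumulate(IntegerVector xs, IntegerVector ys, int ax, int ay,
                    double M) {
  NumericMatrix joint(ax, ay);
  double C = 0.0;
  bool sat = accumulate_joint(xs.begin(), ys.begin(), xs.size(), joint, M, C);
  return List::create(_["joint"] = joint, _["C"] = C, _["saturated"] = sat);
}

// [[Rcpp::export]]
double cpp_mi_from_joint(NumericMatrix joint, double C, bool lowprec,
                         double q, double vmax) {
  return mi_from_joint(joint, C, lowprec, q, vmax);
}

// [[Rcpp::export]]
NumericVector cpp_quant_log_ratio(NumericVector i, NumericVector j,
                                  double q, double vmax) {
  int n = i.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) out[t] = quant_log_ratio(i[t], j[t], q, vmax);
  return out;
}

// MI between each listed column of X (0-based bin indices) and the target
// vector y, at the requested precision. One streaming accumulation per
// column, observations in row order.
// [[Rcpp::export]]
NumericVector cpp_mi_columns(IntegerMatrix X, IntegerVector cols,
                             IntegerVector y, int nbins, int ny,
                             double M, bool lowprec, double q, double vmax) {
  int n = X.nrow(), m = cols.size();
  NumericVector out(m);
  std::vector<int> xv(n);
  NumericMatrix joint(nbins, ny);
  for (int c = 0; c < m; ++c) {
    int col = cols[c];
    for (int t = 0; t < n; ++t) xv[t] = X(t, col);
    std::fill(joint.begin(), joint.end(), 0.0);
    double C = 0.0;
    accumulate_joint(xv.data(), y.begin(), n, joint, M, C);
    out[c] = mi_from_joint(joint, C, lowprec, q, vmax);
  }
  return out;
}

// Pairwise MI between each listed column and one fixed column (mRMR
// redundancy terms).
// [[Rcpp::export]]
NumericVector cpp_mi_with_column(IntegerMatrix X, IntegerVector cols,
                                 int scol, int nbins,
                                 double M, bool lowprec, double q,
                                 double vmax) {
  int n = X.nrow(), m = cols.size();
  NumericVector out(m);
  std::vector<int> sv(n), xv(n);
  for (int t = 0; t < n; ++t) sv[t] = X(t, scol);
  NumericMatrix joint(nbins, nbins);
  for (int c = 0; c < m; ++c) {
    int col = cols[c];
    for (int t = 0; t < n; ++t) xv[t] = X(t, col);
    std::fill(joint.begin(), joint.end(), 0.0);
    double C = 0.0;
    accumulate_joint(xv.data(), sv.data(), n, joint, M, C);
    out[c] = mi_from_joint(joint, C, lowprec, q, vmax);
  }
  return out;
}

// Joint MI I((X_col, X_scol); Y) for each listed column: the candidate/
// selected pair is encoded over the product alphabet (code = x1*nbins + x2)
// and streamed against y (JMI criterion terms).
// [[Rcpp::export]]
NumericVector cpp_joint_mi_columns(IntegerMatrix X, IntegerVector cols,
                                   int scol, IntegerVector y, int nbins,
                                   int ny, double M, bool lowprec, double q,
                                   double vmax) {
  int n = X.nrow(), m = cols.size();
  NumericVector out(m);
  std::vector<int> pv(n);
  NumericMatrix joint(nbins * nbins, ny);
  for (int c = 0; c < m; ++c) {
    int col = cols[c];
    for (int t = 0; t < n; ++t) pv[t] = X(t, col) * nbins + X(t, scol);
    std::fill(joint.begin(), joint.end(), 0.0);
    double C = 0.0;
    accumulate_joint(pv.data(), y.begin(), n, joint, M, C);
    out[c] = mi_from_joint(joint, C, lowprec, q, vmax);
  }
  return out;
}
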