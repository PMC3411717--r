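// Compiled inner loops of the two summarizers. Both operate on a log2
// probe matrix whose rows are pre-grouped into features (probe sets or
// transcript clusters) by a 0-based feature index per row.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static double med(std::vector<double> v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
    m = 0.5 * (m + v[h - 1]);
  }
  return m;
}

// Tukey median polish on a dense r x c block held row-major in `y`.
// Sweep order: rows first, then columns (plus the median re-centering
// steps of the classic algorithm). Returns overall + column effects.
static void medpolish_block(std::vector<double>& y, int r, int c,
                            int maxiter, double tol, double* out) {
  if (r == 1) {            // single-probe feature: its own values
    for (int j = 0; j < c; ++j) out[j] = y[j];
    return;
  }
  std::vector<double> re(r, 0.0), ce(c, 0.0), buf;
  double t = 0.0, oldsum = 0.0;
  for (int it = 0; it < maxiter; ++it) {
    for (int i = 0; i < r; ++i) {
      buf.assign(y.begin() + (size_t)i * c, y.begin() + (size_t)(i + 1) * c);
      double m = med(buf);
      re[i] += m;
      for (int j = 0; j < c; ++j) y[(size_t)i * c + j] -= m;
    }
    { buf.assign(ce.begin(), ce.end());
      double d = med(buf); t += d;
      for (int j = 0; j < c; ++j) ce[j] -= d; }
    for (int j = 0; j < c; ++j) {
      buf.clear();
      for (int i = 0; i < r; ++i) buf.push_back(y[(size_t)i * c + j]);
      double m = med(buf);
      ce[j] += m;
      for (int i = 0; i < r; ++i) y[(size_t)i * c + j] -= m;
    }
    { buf.assign(re.begin(), re.end());
      double d = med(buf); t += d;
      for (int i = 0; i < r; ++i) re[i] -= d; }
    double newsum = 0.0;
    for (size_t k = 0; k < y.size(); ++k) newsum += std::fabs(y[k]);
    if (newsum == 0.0 || std::fabs(newsum - oldsum) < tol * newsum) break;
    oldsum = newsum;
  }
  for (int j = 0; j < c; ++j) out[j] = t + ce[j];
}

// [[Rcpp::export]]
NumericMatrix cpp_medpolish_groups(NumericMatrix logmat, IntegerVector grp,
                                   int nfeat, int maxiter, double tol) {
  const int nr = logmat.nrow(), nc = logmat.ncol();
  std::vector<std::vector<int> > rows(nfeat);
  for (int i = 0; i < nr; ++i) rows[grp[i]].push_back(i);
  NumericMatrix out(nfeat, nc);
  std::vector<double> y;
  for (int f = 0; f < nfeat; ++f) {
    const int r = rows[f].size();
    if (r == 0) { for (int j = 0; j < nc; ++j) out(f, j) = NA_REAL; continue; }
    y.resize((size_t)r * nc);
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < nc; ++j)
        y[(size_t)i * nc + j] = logmat(rows[f][i], j);
    std::vector<double> res(nc);
    medpolish_block(y, r, nc, maxiter, tol, res.data());
    for (int j = 0; j < nc; ++j) out(f, j) = res[j];
  }
  return out;
}

// Robust alternating fit of log2 y_ij ~ alpha_i + c_j with Tukey biweight
// weights; gauge: mean(alpha) = 0 (geometric mean affinity 1). Returns c.
static bool plier_block(const std::vector<double>& y, int r, int c,
                        int maxiter, double tol, double k,
                        std::vector<double>& conc) {
  conc.assign(c, 0.0);
  if (r == 1) { for (int j = 0; j < c; ++j) conc[j] = y[j]; return true; }
  std::vector<double> alpha(r, 0.0), w((size_t)r * c, 1.0), e((size_t)r * c);
  // init: column means / centered row means
  for (int j = 0; j < c; ++j) {
    double s = 0.0; for (int i = 0; i < r; ++i) s += y[(size_t)i * c + j];
    conc[j] = s / r;
  }
  for (int i = 0; i < r; ++i) {
    double s = 0.0; for (int j = 0; j < c; ++j) s += y[(size_t)i * c + j] - conc[j];
    alpha[i] = s / c;
  }
  bool converged = false;
  for (int it = 0; it < maxiter; ++it) {
    // residuals and biweights
    std::vector<double> abse;
    abse.reserve((size_t)r * c);
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < c; ++j) {
        double res = y[(size_t)i * c + j] - alpha[i] - conc[j];
        e[(size_t)i * c + j] = res;
        abse.push_back(std::fabs(res));
      }
    double s = 1.4826 * med(abse);
    if (s < 1e-12) { converged = true; break; }
    for (size_t q = 0; q < e.size(); ++q) {
      double u = e[q] / (k * s);
      double wq = (std::fabs(u) < 1.0) ? (1.0 - u * u) * (1.0 - u * u) : 0.0;
      w[q] = wq < 1e-6 ? 1e-6 : wq;
    }
    // alpha update
    for (int i = 0; i < r; ++i) {
      double num = 0.0, den = 0.0;
      for (int j = 0; j < c; ++j) {
        double wq = w[(size_t)i * c + j];
        num += wq * (y[(size_t)i * c + j] - conc[j]);
        den += wq;
      }
      alpha[i] = num / den;
    }
    double abar = 0.0;
    for (int i = 0; i < r; ++i) abar += alpha[i];
    abar /= r;
    for (int i = 0; i < r; ++i) alpha[i] -= abar;
    // c update
    double maxdel = 0.0;
    for (int j = 0; j < c; ++j) {
      double num = 0.0, den = 0.0;
      for (int i = 0; i < r; ++i) {
        double wq = w[(size_t)i * c + j];
        num += wq * (y[(size_t)i * c + j] - alpha[i]);
        den += wq;
      }
      double nc_ = num / den;
      double d = std::fabs(nc_ - conc[j]);
      if (d > maxdel) maxdel = d;
      conc[j] = nc_;
    }
    if (maxdel < tol) { converged = true; break; }
  }
  return converged;
}

static double pearson(const double* x, const double* y, int n) {
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return 0.0;
  return sxy / std::sqrt(sxx * syy);
}

// Iter-PLIER: fit all probes, then (iter_rounds - 1 times) keep the
// probes_kept probes best correlated with the fitted concentration and
// refit. Features with <= probes_kept probes skip selection.
// [[Rcpp::export]]
List cpp_plier_groups(NumericMatrix logmat, IntegerVector grp, int nfeat,
                      int maxiter, double tol, double biweight_k,
                      int iter_rounds, int probes_kept) {
  const int nr = logmat.nrow(), nc = logmat.ncol();
  std::vector<std::vector<int> > rows(nfeat);
  for (int i = 0; i < nr; ++i) rows[grp[i]].push_back(i);
  NumericMatrix out(nfeat, nc);
  LogicalVector conv(nfeat);
  std::vector<double> y, conc;
  for (int f = 0; f < nfeat; ++f) {
    std::vector<int> keep = rows[f];
    if (keep.empty()) {
      for (int j = 0; j < nc; ++j) out(f, j) = NA_REAL;
      conv[f] = true;
      continue;
    }
    bool ok = true;
    for (int round = 0; round < std::max(1, iter_rounds); ++round) {
      const int r = keep.size();
      y.resize((size_t)r * nc);
      for (int i = 0; i < r; ++i)
        for (int j = 0; j < nc; ++j)
          y[(size_t)i * nc + j] = logmat(keep[i], j);
      ok = plier_block(y, r, nc, maxiter, tol, biweight_k, conc);
      if (round == iter_rounds - 1 || r <= probes_kept) break;
      // rank probes by correlation with the fitted concentration
      std::vector<std::pair<double, int> > cr(r);
      for (int i = 0; i < r; ++i)
        cr[i] = std::make_pair(-pearson(&y[(size_t)i * nc], conc.data(), nc),
                               keep[i]);
      std::stable_sort(cr.begin(), cr.end());
      std::vector<int> nk;
      for (int i = 0; i < probes_kept; ++i) nk.push_back(cr[i].second);
      std::sort(nk.begin(), nk.end());
      keep = nk;
    }
    for (int j = 0; j < nc; ++j) out(f, j) = conc[j];
    conv[f] = ok;
  }
  return List::create(_["conc"] = out, _["converged"] = conv);
}
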