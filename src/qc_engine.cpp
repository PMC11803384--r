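#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// status codes shared with R (see R/status.R)
const int ST_PENDING = 0, ST_FLAGGED = 2, ST_MISSING = 5;

enum Stat { STAT_MEAN = 0, STAT_MEDIAN = 1, STAT_TRI_MEAN = 2 };

struct WinStats {
  double center;
  double spread;
  int n;
};

// Statistics over the valid members of the centred window at i.
// Valid = not flagged, not missing, finite. Window truncates at the
// series boundary; remaining points are used as-is.
WinStats window_stats(const NumericVector& x, const IntegerVector& status,
                      int i, int h, int stat, bool include_center) {
  int n = x.size();
  int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
  std::vector<double> v;
  v.reserve(hi - lo + 1);
  std::vector<double> w;
  for (int j = lo; j <= hi; ++j) {
    if (!include_center && j == i) continue;
    int sj = status[j];
    if (sj == ST_FLAGGED || sj == ST_MISSING) continue;
    double xj = x[j];
    if (!R_finite(xj)) continue;
    v.push_back(xj);
    if (stat == STAT_TRI_MEAN) w.push_back((double)(h + 1 - std::abs(j - i)));
  }
  WinStats out;
  out.n = (int)v.size();
  out.center = NA_REAL;
  out.spread = NA_REAL;
  if (out.n == 0) return out;

  if (stat == STAT_TRI_MEAN) {
    double sw = 0.0, swx = 0.0;
    for (size_t k = 0; k < v.size(); ++k) {
      sw += w[k];
      swx += w[k] * v[k];
    }
    double m = swx / sw, ss = 0.0;
    for (size_t k = 0; k < v.size(); ++k) {
      double d = v[k] - m;
      ss += w[k] * d * d;
    }
    out.center = m;
    out.spread = std::sqrt(ss / sw);  // frequency-weight convention
  } else {
    double s = 0.0;
    for (double xv : v) s += xv;
    double m = s / out.n;
    if (stat == STAT_MEDIAN) {
      std::vector<double> tmp(v);
      std::sort(tmp.begin(), tmp.end());
      int nn = out.n;
      out.center = (nn % 2 == 1) ? tmp[nn / 2]
                                 : 0.5 * (tmp[nn / 2 - 1] + tmp[nn / 2]);
    } else {
      out.center = m;
    }
    if (out.n >= 2) {
      double ss = 0.0;
      for (double xv : v) {
        double d = xv - m;
        ss += d * d;
      }
      out.spread = std::sqrt(ss / (out.n - 1));  // sample sd
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List rolling_stats_cpp(NumericVector x, LogicalVector valid, int width,
                       int stat, int min_valid, bool include_center) {
  int n = x.size(), h = (width - 1) / 2;
  IntegerVector status(n);
  for (int i = 0; i < n; ++i)
    status[i] = (valid[i] == TRUE && R_finite(x[i])) ? ST_PENDING : ST_MISSING;
  NumericVector center(n, NA_REAL), spread(n, NA_REAL);
  IntegerVector nv(n);
  for (int i = 0; i < n; ++i) {
    WinStats s = window_stats(x, status, i, h, stat, include_center);
    nv[i] = s.n;
    if (s.n >= min_valid) {
      center[i] = s.center;
      spread[i] = s.spread;
    }
  }
  return List::create(_["center_stat"] = center, _["spread"] = spread,
                      _["n_valid"] = nv);
}

// One flagging pass: left-to-right scan; a point flagged at position i is
// excluded from every later window evaluation in the same pass.
// [[Rcpp::export]]
List qc_pass_cpp(NumericVector x, IntegerVector status,
                 IntegerVector flag_window, int width, int stat,
                 double topadd, double bottomsub, double std_factor,
                 bool use_uncertainty, double unc_pct, double unc_con,
                 int min_valid, bool include_center, int window_id) {
  int n = x.size(), h = (width - 1) / 2, nnew = 0;
  IntegerVector st = clone(status), fw = clone(flag_window);
  for (int i = 0; i < n; ++i) {
    if (st[i] != ST_PENDING) continue;
    WinStats s = window_stats(x, st, i, h, stat, include_center);
    if (s.n < min_valid || !R_finite(s.center) || !R_finite(s.spread))
      continue;
    double top = s.center + topadd + std_factor * s.spread;
    double bot = s.center - bottomsub - std_factor * s.spread;
    double m = 0.0;
    if (use_uncertainty)
      m = std::max(unc_pct * std::fabs(x[i]) / 100.0, unc_con);
    // strict inequalities: a value on the boundary survives
    if (x[i] - m > top || x[i] + m < bot) {
      st[i] = ST_FLAGGED;
      fw[i] = window_id;
      ++nnew;
    }
  }
  return List::create(_["status"] = st, _["flag_window"] = fw,
                      _["n_flagged"] = nnew);
}
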