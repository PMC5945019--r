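// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Count local maxima on v[lo..hi] whose topographic prominence is at least
// prom_frac * (max - min). Prominence of a peak is its height minus the
// higher of the two minima separating it from the nearest taller point (or
// the series edge) on each side. Plateaus count once.
static int peak_count_range(const double* v, int lo, int hi, double prom_frac) {
  int n = hi - lo + 1;
  if (n < 3) return 0;
  double gmax = v[lo], gmin = v[lo];
  for (int i = lo + 1; i <= hi; ++i) {
    if (v[i] > gmax) gmax = v[i];
    if (v[i] < gmin) gmin = v[i];
  }
  double rng = gmax - gmin;
  if (rng <= 0.0) return 0;
  double thr = prom_frac * rng;
  int count = 0;
  int i = lo + 1;
  while (i <= hi - 1) {
    if (v[i] > v[i - 1]) {
      int j = i;
      while (j < hi && v[j + 1] == v[i]) ++j;
      if (j < hi && v[j + 1] < v[i]) {
        double h = v[i];
        // left base
        double minl = h;
        for (int t = i - 1; t >= lo; --t) {
          if (v[t] > h) break;
          if (v[t] < minl) minl = v[t];
        }
        // right base
        double minr = h;
        for (int t = j + 1; t <= hi; ++t) {
          if (v[t] > h) break;
          if (v[t] < minr) minr = v[t];
        }
        double prom = h - std::max(minl, minr);
        if (prom >= thr) ++count;
        i = j + 1;
      } else {
        i = j + 1;
      }
    } else {
      ++i;
    }
  }
  return count;
}

// Pulse-shape features for a batch of particles.
//
// mats: list of 6 numeric matrices (n x mmax), one per channel, row i holding
//       the pulse of particle i padded beyond plen[i].
// plen: recorded pulse length (samples) per particle, shared across channels.
// step: spatial sampling interval (um per sample).
// trigger: trigger threshold (mV) applied to channel trig_ch; samples outside
//       the first..last index where that channel >= trigger are truncated.
//       Pass a negative value to disable cropping.
// red1_ch / red2_ch: 0-based channel indices for the Red1/Red2 area ratio.
//
// Returns an n x (6*11 + 1) matrix; column order is the 11 features
// (Maximum, Minimum, First, Last, Total, Average, Range, Length, Fill.factor,
// Gradient, Number.of.cells) per channel, then the Red1Red2 ratio.
// [[Rcpp::export]]
NumericMatrix cpp_pulse_features(List mats, IntegerVector plen, double step,
                                 double trigger, int trig_ch,
                                 int red1_ch, int red2_ch,
                                 double prom_frac, double ratio_cap) {
  const int nch = mats.size();
  std::vector<NumericMatrix> ch(nch);
  for (int c = 0; c < nch; ++c) ch[c] = as<NumericMatrix>(mats[c]);
  const int n = plen.size();
  NumericMatrix out(n, nch * 11 + 1);

  std::vector<double> buf;
  for (int i = 0; i < n; ++i) {
    int m = plen[i];
    int lo = 0, hi = m - 1;
    if (trigger >= 0.0) {
      const NumericMatrix& T = ch[trig_ch];
      int first = -1, last = -1;
      double best = R_NegInf; int ibest = 0;
      for (int j = 0; j < m; ++j) {
        double v = T(i, j);
        if (v >= trigger) { if (first < 0) first = j; last = j; }
        if (v > best) { best = v; ibest = j; }
      }
      if (first < 0) { first = ibest; last = ibest; }
      lo = first; hi = last;
    }
    int nwin = hi - lo + 1;
    double totals[8]; // per-channel totals for the ratio (only 2 used)
    for (int c = 0; c < nch; ++c) {
      const NumericMatrix& M = ch[c];
      buf.resize(nwin);
      double vmax = M(i, lo), vmin = M(i, lo), sum = 0.0, gsum = 0.0;
      for (int j = lo; j <= hi; ++j) {
        double v = M(i, j);
        buf[j - lo] = v;
        if (v > vmax) vmax = v;
        if (v < vmin) vmin = v;
        sum += v;
        if (j > lo) gsum += std::fabs(v - M(i, j - 1));
      }
      double total = sum * step;
      double len = nwin * step;
      double fill = (vmax > 0.0) ? total / (vmax * len) : 0.0;
      double grad = (nwin > 1) ? (gsum / (nwin - 1)) / step : 0.0;
      int np = peak_count_range(buf.data(), 0, nwin - 1, prom_frac);
      int b = c * 11;
      out(i, b + 0) = vmax;
      out(i, b + 1) = vmin;
      out(i, b + 2) = buf[0];
      out(i, b + 3) = buf[nwin - 1];
      out(i, b + 4) = total;
      out(i, b + 5) = sum / nwin;
      out(i, b + 6) = vmax - vmin;
      out(i, b + 7) = len;
      out(i, b + 8) = fill;
      out(i, b + 9) = grad;
      out(i, b + 10) = (double)np;
      if (c < 8) totals[c] = total;
    }
    double t1 = totals[red1_ch], t2 = totals[red2_ch];
    out(i, nch * 11) = (t2 > 0.0) ? t1 / t2 : ratio_cap;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_peak_count(NumericVector v, double prom_frac) {
  if (v.size() == 0) return 0;
  return peak_count_range(REAL(v), 0, v.size() - 1, prom_frac);
}

// log density of a Gaussian mixture at the rows of X.
// M: k x d component means; logw: log weights; IC: d x d x k inverse
// covariances; logdet: log |Sigma_k|.
// [[Rcpp::export]]
arma::vec cpp_gmm_logdens(const arma::mat& X, const arma::mat& M,
                          const arma::vec& logw, const arma::cube& IC,
                          const arma::vec& logdet) {
  const int q = X.n_rows, k = M.n_rows, d = X.n_cols;
  arma::vec out(q);
  const double c0 = -0.5 * d * std::log(2.0 * M_PI);
  std::vector<double> dif(d), l(k);
  for (int i = 0; i < q; ++i) {
    double mx = -arma::datum::inf;
    for (int j = 0; j < k; ++j) {
      const double* ic = IC.slice(j).memptr();
      for (int a = 0; a < d; ++a) dif[a] = X(i, a) - M(j, a);
      double quad = 0.0;
      for (int b = 0; b < d; ++b) {
        double acc = 0.0;
        const double* col = ic + (size_t)b * d;
        for (int a = 0; a < d; ++a) acc += dif[a] * col[a];
        quad += acc * dif[b];
      }
      l[j] = logw(j) + c0 - 0.5 * logdet(j) - 0.5 * quad;
      if (l[j] > mx) mx = l[j];
    }
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::exp(l[j] - mx);
    out(i) = mx + std::log(s);
  }
  return out;
}

// log f and the gradient of log f for a Gaussian mixture at a single point.
// [[Rcpp::export]]
List cpp_gmm_logdens_grad(const arma::rowvec& x, const arma::mat& M,
                          const arma::vec& logw, const arma::cube& IC,
                          const arma::vec& logdet) {
  const int k = M.n_rows, d = M.n_cols;
  const double c0 = -0.5 * d * std::log(2.0 * M_PI);
  arma::vec l(k);
  arma::mat dirs(k, d);
  double mx = -arma::datum::inf;
  for (int j = 0; j < k; ++j) {
    arma::rowvec dif = M.row(j) - x;
    arma::vec icd = IC.slice(j) * dif.t();
    l(j) = logw(j) + c0 - 0.5 * logdet(j) - 0.5 * arma::dot(dif, icd.t());
    dirs.row(j) = icd.t();
    if (l(j) > mx) mx = l(j);
  }
  double s = 0.0;
  arma::rowvec g(d, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    double r = std::exp(l(j) - mx);
    s += r;
    g += r * dirs.row(j);
  }
  g /= s;
  return List::create(_["logf"] = mx + std::log(s), _["grad"] = g);
}
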