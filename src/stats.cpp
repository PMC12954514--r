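#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// The nine intra-subvolume descriptive statistics, in the fixed order
// MIN, MAX, MEDIAN, MEAN, COV, P25, P75, SKEWNESS, MODE_OVER_MEDIAN.
// COV = population sd / median; MODE = midpoint of the highest-count of 64
// equal-width bins over [min, max] (single bin when min == max, count ties
// to the lowest bin). COV and MODE/MEDIAN are NA when the median is zero.
// Long-double accumulation keeps sums stable on large subvolumes.
namespace {

inline double quantile_sorted(const std::vector<double>& s, double p) {
  const size_t n = s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  double lo = std::floor(h);
  size_t il = static_cast<size_t>(lo);
  if (il >= n - 1) return s[n - 1];
  return s[il] + (h - lo) * (s[il + 1] - s[il]);
}

void stats9(const double* x, size_t n, double* out) {
  std::vector<double> s(x, x + n);
  std::sort(s.begin(), s.end());
  double mn = s.front(), mx = s.back();
  double med = quantile_sorted(s, 0.5);
  long double acc = 0.0L;
  for (size_t i = 0; i < n; ++i) acc += x[i];
  double mean = static_cast<double>(acc / n);
  long double m2a = 0.0L, m3a = 0.0L;
  for (size_t i = 0; i < n; ++i) {
    double d = x[i] - mean;
    m2a += d * d;
    m3a += d * d * d;
  }
  double m2 = static_cast<double>(m2a / n);
  double m3 = static_cast<double>(m3a / n);
  double skew = (m2 == 0.0) ? 0.0 : m3 / std::pow(m2, 1.5);
  double cov = NA_REAL, modeOverMed = NA_REAL;
  if (med != 0.0) {
    cov = std::sqrt(m2) / med;
    double mode;
    if (mn == mx) {
      mode = mn;
    } else {
      const int nbins = 64;
      double w = (mx - mn) / nbins;
      std::vector<int> counts(nbins, 0);
      for (size_t i = 0; i < n; ++i) {
        int b = static_cast<int>(std::floor((x[i] - mn) / w));
        if (b >= nbins) b = nbins - 1;
        ++counts[b];
      }
      int best = 0;
      for (int b = 1; b < nbins; ++b)
        if (counts[b] > counts[best]) best = b;
      mode = mn + (best + 0.5) * w;
    }
    modeOverMed = mode / med;
  }
  out[0] = mn; out[1] = mx; out[2] = med; out[3] = mean; out[4] = cov;
  out[5] = quantile_sorted(s, 0.25); out[6] = quantile_sorted(s, 0.75);
  out[7] = skew; out[8] = modeOverMed;
}

} // namespace

// [[Rcpp::export(name = ".intraAllCpp")]]
NumericVector intra_all_cpp(NumericVector x) {
  if (x.size() == 0) stop("empty input");
  NumericVector out(9);
  stats9(x.begin(), x.size(), out.begin());
  return out;
}

// Batch version: per-subvolume statistics for one lung. `labels` holds the
// 1..K subvolume id of each value (same order as `values`); rows of the
// returned 9 x K matrix follow the fixed metric order above, and values are
// grouped in first-appearance scan order, matching split().
// [[Rcpp::export(name = ".intraGroupsCpp")]]
NumericMatrix intra_groups_cpp(NumericVector values, IntegerVector labels,
                               int K) {
  std::vector<std::vector<double>> groups(K);
  const R_xlen_t n = values.size();
  for (int g = 0; g < K; ++g) groups[g].reserve(n / K + 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    int g = labels[i] - 1;
    if (g < 0 || g >= K) stop("label outside 1..K");
    groups[g].push_back(values[i]);
  }
  NumericMatrix out(9, K);
  for (int g = 0; g < K; ++g) {
    if (groups[g].empty()) stop("empty subvolume %d", g + 1);
    stats9(groups[g].data(), groups[g].size(), &out(0, g));
  }
  return out;
}

// All inter-subvolume statistics: the P_N defect-volume curve over the N
// grid followed by COV, MODE_OVER_MEDIAN, MEDIAN, P25, P75, SKEWNESS of the
// subvolume values (unweighted). P_N = 100 * sum(w_i [v_i <= (N/100) max v])
// / sum(w_i). Integer-valued weights keep the sums exact.
// [[Rcpp::export(name = ".interAllCpp")]]
NumericVector inter_all_cpp(NumericVector subvalues, NumericVector weights,
                            NumericVector nGrid) {
  const R_xlen_t n = subvalues.size(), m = nGrid.size();
  if (n == 0) stop("empty input");
  NumericVector out(m + 6);
  double mx = subvalues[0];
  for (R_xlen_t i = 1; i < n; ++i) if (subvalues[i] > mx) mx = subvalues[i];
  double wTot = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) wTot += weights[i];
  for (R_xlen_t j = 0; j < m; ++j) {
    double cutoff = (nGrid[j] / 100.0) * mx;
    double w = 0.0;
    for (R_xlen_t i = 0; i < n; ++i)
      if (subvalues[i] <= cutoff) w += weights[i];
    out[j] = 100.0 * w / wTot;
  }
  double s9[9];
  stats9(subvalues.begin(), n, s9);
  out[m + 0] = s9[4]; // COV
  out[m + 1] = s9[8]; // MODE_OVER_MEDIAN
  out[m + 2] = s9[2]; // MEDIAN
  out[m + 3] = s9[5]; // P25
  out[m + 4] = s9[6]; // P75
  out[m + 5] = s9[7]; // SKEWNESS
  return out;
}
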