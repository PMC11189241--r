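#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Add Gaussian bumps (one per pulse component) onto a regularly sampled
// waveform. Support truncated at 4 sigma.
// [[Rcpp::export]]
NumericVector cpp_add_pulses(NumericVector wave, double fs,
                             NumericVector centers, NumericVector amps,
                             NumericVector sigmas) {
  int n = wave.size();
  NumericVector out = clone(wave);
  for (int k = 0; k < centers.size(); ++k) {
    double c = centers[k], a = amps[k], s = sigmas[k];
    int lo = (int)std::floor((c - 4.0 * s) * fs);
    int hi = (int)std::ceil((c + 4.0 * s) * fs);
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    for (int i = lo; i <= hi; ++i) {
      double d = i / fs - c;
      out[i] += a * std::exp(-0.5 * d * d / (s * s));
    }
  }
  return out;
}

// Zero-phase IIR filtering (forward-backward) with odd edge reflection,
// as used for the PPG band-pass.
static std::vector<double> iir1(const std::vector<double> &x,
                                const NumericVector &b,
                                const NumericVector &a) {
  int n = x.size(), nb = b.size(), na = a.size();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb; ++j)
      if (i - j >= 0) acc += b[j] * x[i - j];
    for (int j = 1; j < na; ++j)
      if (i - j >= 0) acc -= a[j] * y[i - j];
    y[i] = acc / a[0];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector x, NumericVector b, NumericVector a) {
  int n = x.size();
  int np = std::min(n - 1, 3 * (int)std::max(b.size(), a.size()) * 10);
  std::vector<double> xp(n + 2 * np);
  for (int i = 0; i < np; ++i) xp[i] = 2 * x[0] - x[np - i];
  for (int i = 0; i < n; ++i) xp[np + i] = x[i];
  for (int i = 0; i < np; ++i) xp[np + n + i] = 2 * x[n - 1] - x[n - 2 - i];
  std::vector<double> y = iir1(xp, b, a);
  std::reverse(y.begin(), y.end());
  y = iir1(y, b, a);
  std::reverse(y.begin(), y.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = y[np + i];
  return out;
}

// Peak candidate selection on a band-passed signal: strict local maxima
// above frac * (block-wise 75th percentile of local-max amplitudes,
// linearly interpolated between block centres), greedy 300 ms refractory
// keeping the larger of colliding peaks, parabolic sub-sample refinement.
// Returns refined peak times in seconds.
// [[Rcpp::export]]
NumericVector cpp_detect_peaks(NumericVector bp, double fs, double block_s,
                               double frac, double refractory_s) {
  int n = bp.size();
  std::vector<int> cand;
  for (int i = 1; i + 1 < n; ++i)
    if (bp[i] > 1e-8 && bp[i] > bp[i - 1] && bp[i] >= bp[i + 1] &&
        !(i >= 2 && bp[i] == bp[i - 1]))
      cand.push_back(i);
  if (cand.empty()) return NumericVector(0);
  int block = std::max(1, (int)std::lround(block_s * fs));
  int nb = (n + block - 1) / block;
  std::vector<double> q75(nb, NA_REAL);
  std::vector<double> buf;
  size_t c0 = 0;
  for (int b = 0; b < nb; ++b) {
    buf.clear();
    while (c0 < cand.size() && cand[c0] / block == b) buf.push_back(bp[cand[c0++]]);
    if (buf.empty()) continue;
    std::sort(buf.begin(), buf.end());
    double h = 0.75 * (buf.size() - 1);
    int lo = (int)std::floor(h);
    int hi = std::min((int)buf.size() - 1, lo + 1);
    q75[b] = buf[lo] + (h - lo) * (buf[hi] - buf[lo]);
  }
  // fill empty blocks by nearest non-empty, then threshold by interpolation
  std::vector<double> centers(nb), qv(nb);
  int m = 0;
  for (int b = 0; b < nb; ++b)
    if (!ISNA(q75[b])) { centers[m] = (b + 0.5) * block; qv[m] = q75[b]; ++m; }
  if (m == 0) return NumericVector(0);
  std::vector<int> keep;
  double ref_n = refractory_s * fs;
  double last = -1e18;
  for (size_t c = 0; c < cand.size(); ++c) {
    int i = cand[c];
    double thr;
    if (m == 1) thr = qv[0];
    else if (i <= centers[0]) thr = qv[0];
    else if (i >= centers[m - 1]) thr = qv[m - 1];
    else {
      int j = 0;
      while (j + 1 < m && centers[j + 1] < i) ++j;
      double fr = (i - centers[j]) / (centers[j + 1] - centers[j]);
      thr = qv[j] + fr * (qv[j + 1] - qv[j]);
    }
    if (bp[i] <= frac * thr) continue;
    if (i - last >= ref_n) {
      keep.push_back(i);
      last = i;
    } else if (!keep.empty() && bp[i] > bp[keep.back()]) {
      keep.back() = i;
      last = i;
    }
  }
  NumericVector out(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) {
    int i = keep[k];
    double delta = 0.0;
    if (i > 0 && i + 1 < n) {
      double den = bp[i - 1] - 2 * bp[i] + bp[i + 1];
      if (std::fabs(den) > 1e-12) delta = 0.5 * (bp[i - 1] - bp[i + 1]) / den;
      if (delta > 0.5) delta = 0.5;
      if (delta < -0.5) delta = -0.5;
    }
    out[k] = (i + delta) / fs;
  }
  return out;
}

// Resample heart cycles (given by 0-based start index and length in
// samples) to a common length by linear interpolation. Rows = cycles.
// [[Rcpp::export]]
NumericMatrix cpp_cycle_matrix(NumericVector x, IntegerVector starts,
                               IntegerVector lens, int out_len) {
  int nc = starts.size();
  NumericMatrix out(nc, out_len);
  for (int c = 0; c < nc; ++c) {
    int s = starts[c], L = lens[c];
    for (int j = 0; j < out_len; ++j) {
      double pos = s + (double)j * L / (out_len - 1);
      int i0 = (int)std::floor(pos);
      double fr = pos - i0;
      if (i0 + 1 > s + L) { i0 = s + L; fr = 0.0; }
      out(c, j) = (1 - fr) * x[i0] + fr * x[i0 + 1 > (int)x.size() - 1 ? i0 : i0 + 1];
    }
  }
  return out;
}

// ---- tree ensemble helpers -------------------------------------------------
// Trees are given as parallel arrays; leaf nodes have left == -1.
// Numeric splits: x <= threshold goes left.

// Per-node cover: weighted count of training rows passing through each node.
// [[Rcpp::export]]
NumericVector cpp_tree_covers(NumericMatrix X, NumericVector w,
                              IntegerVector left, IntegerVector right,
                              IntegerVector feature, NumericVector threshold) {
  int nnode = left.size();
  NumericVector cover(nnode);
  int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0) continue;
    int node = 0;
    cover[node] += w[i];
    while (left[node] != -1) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      cover[node] += w[i];
    }
  }
  return cover;
}

// Leaf value reached by each row of X in one tree.
// [[Rcpp::export]]
NumericVector cpp_tree_predict(NumericMatrix X, IntegerVector left,
                               IntegerVector right, IntegerVector feature,
                               NumericVector threshold, NumericVector value) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (left[node] != -1)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}

// ---- path-dependent TreeSHAP ----------------------------------------------
// Shapley attributions for a single tree under the cover-weighted
// conditional-expectation game, following the polynomial-time path algorithm
// for tree ensembles (extend/unwind over the unique decision path).

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight +=
        one_fraction * path[i].pweight * (i + 1) / (double)(unique_depth + 1);
    path[i].pweight =
        zero_fraction * path[i].pweight * (unique_depth - i) /
        (double)(unique_depth + 1);
  }
}

static void unwind_path(std::vector<PathElement> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1) /
                        (double)((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                                   (unique_depth - i) /
                                   (double)(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         (double)((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight -
                         tmp * zero_fraction * (unique_depth - i) /
                             (double)(unique_depth + 1);
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((unique_depth - i) / (double)(unique_depth + 1));
    }
  }
  return total;
}

static void tree_shap_recursive(
    const IntegerVector &left, const IntegerVector &right,
    const IntegerVector &feature, const NumericVector &threshold,
    const NumericVector &value, const NumericVector &cover,
    const NumericMatrix &X, int row, std::vector<double> &phi, int node,
    int unique_depth, std::vector<PathElement> path, double parent_zero_fraction,
    double parent_one_fraction, int parent_feature_index) {
  // path is received by value: each branch owns its own copy
  if ((int)path.size() < unique_depth + 1) path.resize(unique_depth + 1);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);
  if (left[node] == -1) {
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      phi[path[i].feature_index] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * value[node];
    }
    return;
  }
  const int split = feature[node];
  int hot, cold;
  if (X(row, split) <= threshold[node]) {
    hot = left[node];
    cold = right[node];
  } else {
    hot = right[node];
    cold = left[node];
  }
  const double w = cover[node];
  const double hot_zero_fraction = cover[hot] / w;
  const double cold_zero_fraction = cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (path[path_index].feature_index == split) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  tree_shap_recursive(left, right, feature, threshold, value, cover, X, row,
                      phi, hot, unique_depth + 1, path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split);
  tree_shap_recursive(left, right, feature, threshold, value, cover, X, row,
                      phi, cold, unique_depth + 1, path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0, split);
}

// Forest-level SHAP: attributions averaged over trees (the ensemble output is
// the tree mean), plus the cover-weighted base value and the ensemble
// prediction for each row (for local-accuracy checking).
// [[Rcpp::export]]
List cpp_forest_shap(NumericMatrix X, List forest) {
  const int n = X.nrow(), m = X.ncol(), ntree = forest.size();
  NumericMatrix phi(n, m);
  NumericVector pred(n);
  double base = 0.0;
  for (int t = 0; t < ntree; ++t) {
    List tr = forest[t];
    IntegerVector left = tr["left"], right = tr["right"],
                  feature = tr["feature"];
    NumericVector threshold = tr["threshold"], value = tr["value"],
                  cover = tr["cover"];
    // base value: cover-weighted mean of leaf values
    double b = 0.0;
    for (int k = 0; k < left.size(); ++k)
      if (left[k] == -1) b += cover[k] * value[k];
    b /= cover[0];
    base += b / ntree;
    for (int i = 0; i < n; ++i) {
      std::vector<double> phi_i(m, 0.0);
      std::vector<PathElement> path(1);
      tree_shap_recursive(left, right, feature, threshold, value, cover, X, i,
                          phi_i, 0, 0, path, 1.0, 1.0, -1);
      for (int j = 0; j < m; ++j) phi(i, j) += phi_i[j] / ntree;
      int node = 0;
      while (left[node] != -1)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      pred[i] += value[node] / ntree;
    }
  }
  return List::create(_["phi"] = phi, _["base"] = base, _["pred"] = pred);
}
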