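#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Alternating decision tree trainer (Freund & Mason).
//
// Boosting with the Z-criterion
//   Z(c1, c2) = 2( sqrt(W+(c1&c2) W-(c1&c2)) + sqrt(W+(c1&!c2) W-(c1&!c2)) )
//               + W(!c1)
// over preconditions c1 (paths already in the tree) and base conditions
// c2 of the form x_j < t, with t the midpoints between consecutive
// distinct values.  Prediction values use +1 smoothing,
//   a = 0.5 * log((W+ + 1) / (W- + 1)),
// and instance weights are updated multiplicatively by exp(-y * a).
//
// Ties in Z are broken toward the heavier path, then the earlier
// attribute, then the smaller threshold, so training is deterministic.

// [[Rcpp::export]]
List adtree_train_cpp(NumericMatrix X, IntegerVector y, int rounds) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(n, 1.0);

  double wp = 0.0, wm = 0.0;
  for (int i = 0; i < n; ++i) (y[i] > 0 ? wp : wm) += w[i];
  const double root = 0.5 * std::log((wp + 1.0) / (wm + 1.0));
  for (int i = 0; i < n; ++i) w[i] *= std::exp(-(double)y[i] * root);

  // per-attribute sort order, computed once
  std::vector<std::vector<int> > ord(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& o = ord[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  // paths: membership masks; path 0 = root (all instances)
  std::vector<std::vector<char> > paths;
  paths.push_back(std::vector<char>(n, 1));

  std::vector<int> r_path, r_attr;
  std::vector<double> r_thr, r_a, r_b;

  for (int t = 0; t < rounds; ++t) {
    double wtot = 0.0;
    for (int i = 0; i < n; ++i) wtot += w[i];

    double bestZ = R_PosInf, bestThr = 0.0;
    int bestPath = -1, bestAttr = -1;

    // per-path weights; scanning heavy paths first lets the Z >= W(!c1)
    // lower bound prune the light ones exactly
    const size_t np = paths.size();
    std::vector<double> wp_in_v(np, 0.0), wm_in_v(np, 0.0);
    std::vector<size_t> order(np);
    for (size_t pi = 0; pi < np; ++pi) {
      order[pi] = pi;
      const std::vector<char>& mem = paths[pi];
      for (int i = 0; i < n; ++i)
        if (mem[i]) (y[i] > 0 ? wp_in_v[pi] : wm_in_v[pi]) += w[i];
    }
    std::stable_sort(order.begin(), order.end(), [&](size_t a, size_t b) {
      return wp_in_v[a] + wm_in_v[a] > wp_in_v[b] + wm_in_v[b];
    });

    for (size_t oi = 0; oi < np; ++oi) {
      const size_t pi = order[oi];
      const std::vector<char>& mem = paths[pi];
      const double wp_in = wp_in_v[pi], wm_in = wm_in_v[pi];
      if (wp_in + wm_in <= 0.0) continue;
      const double w_not = wtot - wp_in - wm_in;
      if (w_not >= bestZ) break;   // no later (lighter) path can win

      for (int j = 0; j < p; ++j) {
        const std::vector<int>& o = ord[j];
        const double* col = &X(0, j);
        double wpl = 0.0, wml = 0.0;
        double prev = 0.0;
        bool have_prev = false;
        for (int q = 0; q < n; ++q) {
          const int i = o[q];
          if (!mem[i]) continue;
          const double v = col[i];
          if (have_prev && v > prev) {
            const double z = 2.0 * (std::sqrt(wpl * wml) +
                                    std::sqrt((wp_in - wpl) * (wm_in - wml)))
                             + w_not;
            if (z < bestZ - 1e-12) {
              bestZ = z;
              bestPath = (int)pi;
              bestAttr = j;
              bestThr = (prev + v) / 2.0;
            }
          }
          (y[i] > 0 ? wpl : wml) += w[i];
          prev = v;
          have_prev = true;
        }
      }
    }

    if (bestPath < 0) break;   // no admissible split left

    // prediction values for the winning rule
    const std::vector<char>& mem = paths[bestPath];
    double wpl = 0.0, wml = 0.0, wpr = 0.0, wmr = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!mem[i]) continue;
      const bool left = X(i, bestAttr) < bestThr;
      if (y[i] > 0) (left ? wpl : wpr) += w[i];
      else          (left ? wml : wmr) += w[i];
    }
    const double a = 0.5 * std::log((wpl + 1.0) / (wml + 1.0));
    const double b = 0.5 * std::log((wpr + 1.0) / (wmr + 1.0));

    std::vector<char> left_mem(n, 0), right_mem(n, 0);
    for (int i = 0; i < n; ++i) {
      if (!mem[i]) continue;
      const bool left = X(i, bestAttr) < bestThr;
      (left ? left_mem : right_mem)[i] = 1;
      w[i] *= std::exp(-(double)y[i] * (left ? a : b));
    }
    paths.push_back(left_mem);
    paths.push_back(right_mem);
    r_path.push_back(bestPath);
    r_attr.push_back(bestAttr + 1);   // 1-based for R
    r_thr.push_back(bestThr);
    r_a.push_back(a);
    r_b.push_back(b);
  }

  return List::create(
    _["root"] = root,
    _["rule_path"] = IntegerVector(r_path.begin(), r_path.end()),
    _["rule_attr"] = IntegerVector(r_attr.begin(), r_attr.end()),
    _["rule_threshold"] = NumericVector(r_thr.begin(), r_thr.end()),
    _["rule_left"] = NumericVector(r_a.begin(), r_a.end()),
    _["rule_right"] = NumericVector(r_b.begin(), r_b.end()));
}

// Score instances: root plus the prediction values on satisfied paths.
// Rule r has precondition path rule_path[r] (0 = root; rule r created
// paths 2r+1 and 2r+2).
// [[Rcpp::export]]
NumericVector adtree_score_cpp(NumericMatrix X, double root,
                               IntegerVector rule_path,
                               IntegerVector rule_attr,
                               NumericVector rule_threshold,
                               NumericVector rule_left,
                               NumericVector rule_right) {
  const int n = X.nrow(), m = rule_path.size();
  NumericVector out(n);
  std::vector<char> sat(2 * m + 1);
  for (int i = 0; i < n; ++i) {
    std::fill(sat.begin(), sat.end(), 0);
    sat[0] = 1;
    double s = root;
    for (int r = 0; r < m; ++r) {
      if (!sat[rule_path[r]]) continue;
      const bool left = X(i, rule_attr[r] - 1) < rule_threshold[r];
      s += left ? rule_left[r] : rule_right[r];
      sat[2 * r + 1] = left;
      sat[2 * r + 2] = !left;
    }
    out[i] = s;
  }
  return out;
}

// ---- wrapper-evaluation core -------------------------------------------
//
// Fitness evaluator for the wrapper feature-selection search.  The
// caller precomputes, once per outer fold and inner fold, the contiguous
// training matrix `Xtr`, the held-out matrix `Xte`, and the per-column
// sort order `ord` of the training rows (1-based), so each of the
// thousands of fitness evaluations does no sorting and no row
// indirection.  Each path keeps its members pre-sorted per selected
// attribute and the Z >= W(!c1) bound prunes light paths exactly.
struct AdtPath {
  std::vector<std::vector<int> > ord;  // per selected attribute
};

// [[Rcpp::export]]
int adtree_fit_eval_cpp(NumericMatrix Xtr, IntegerVector ytr,
                        IntegerMatrix ord, IntegerVector sel_cols,
                        NumericMatrix Xte, IntegerVector yte, int rounds) {
  const int n = Xtr.nrow();
  const int p = sel_cols.size();
  std::vector<int> cols(p);
  for (int j = 0; j < p; ++j) cols[j] = sel_cols[j] - 1;
  std::vector<double> w(n, 1.0);

  double wp = 0.0, wm = 0.0;
  for (int i = 0; i < n; ++i) (ytr[i] > 0 ? wp : wm) += w[i];
  const double root = 0.5 * std::log((wp + 1.0) / (wm + 1.0));
  for (int i = 0; i < n; ++i) w[i] *= std::exp(-(double)ytr[i] * root);

  std::vector<AdtPath> paths(1);
  paths[0].ord.resize(p, std::vector<int>(n));
  for (int jj = 0; jj < p; ++jj) {
    const int* oc = &ord(0, cols[jj]);
    std::vector<int>& o = paths[0].ord[jj];
    for (int i = 0; i < n; ++i) o[i] = oc[i] - 1;
  }

  std::vector<int> r_path, r_attr;
  std::vector<double> r_thr, r_a, r_b;
  std::vector<double> wpa(n), wma(n);   // branchless per-class weights

  for (int t = 0; t < rounds; ++t) {
    for (int i = 0; i < n; ++i) {
      wpa[i] = ytr[i] > 0 ? w[i] : 0.0;
      wma[i] = ytr[i] > 0 ? 0.0 : w[i];
    }
    const size_t np = paths.size();
    std::vector<double> wp_in_v(np, 0.0), wm_in_v(np, 0.0);
    std::vector<size_t> order(np);
    for (size_t pi = 0; pi < np; ++pi) {
      order[pi] = pi;
      const std::vector<int>& mem = paths[pi].ord[0];
      for (size_t q = 0; q < mem.size(); ++q) {
        wp_in_v[pi] += wpa[mem[q]];
        wm_in_v[pi] += wma[mem[q]];
      }
    }
    const double wtot = wp_in_v[0] + wm_in_v[0];  // root holds everyone
    std::stable_sort(order.begin(), order.end(), [&](size_t a, size_t b) {
      return wp_in_v[a] + wm_in_v[a] > wp_in_v[b] + wm_in_v[b];
    });

    double bestZ = R_PosInf, bestThr = 0.0;
    int bestPath = -1, bestAttr = -1;
    for (size_t oi = 0; oi < np; ++oi) {
      const size_t pi = order[oi];
      const double wp_in = wp_in_v[pi], wm_in = wm_in_v[pi];
      if (wp_in + wm_in <= 0.0) continue;
      const double w_not = wtot - wp_in - wm_in;
      if (w_not >= bestZ) break;
      for (int jj = 0; jj < p; ++jj) {
        const std::vector<int>& o = paths[pi].ord[jj];
        const double* col = &Xtr(0, cols[jj]);
        double wpl = 0.0, wml = 0.0, prev = 0.0;
        bool have_prev = false;
        for (size_t q = 0; q < o.size(); ++q) {
          const int i = o[q];
          const double v = col[i];
          if (have_prev && v > prev) {
            const double z = 2.0 * (std::sqrt(wpl * wml) +
                                    std::sqrt((wp_in - wpl) * (wm_in - wml)))
                             + w_not;
            if (z < bestZ - 1e-12) {
              bestZ = z; bestPath = (int)pi; bestAttr = jj;
              bestThr = (prev + v) / 2.0;
            }
          }
          wpl += wpa[i]; wml += wma[i];
          prev = v; have_prev = true;
        }
      }
    }
    if (bestPath < 0) break;

    const std::vector<int>& mem = paths[bestPath].ord[0];
    const double* bcol = &Xtr(0, cols[bestAttr]);
    double wpl = 0.0, wml = 0.0, wpr = 0.0, wmr = 0.0;
    for (size_t q = 0; q < mem.size(); ++q) {
      const bool left = bcol[mem[q]] < bestThr;
      if (ytr[mem[q]] > 0) (left ? wpl : wpr) += w[mem[q]];
      else                 (left ? wml : wmr) += w[mem[q]];
    }
    const double a = 0.5 * std::log((wpl + 1.0) / (wml + 1.0));
    const double b = 0.5 * std::log((wpr + 1.0) / (wmr + 1.0));

    std::vector<char> side(n, 0);
    for (size_t q = 0; q < mem.size(); ++q) {
      const int i = mem[q];
      const bool left = bcol[i] < bestThr;
      side[i] = left ? 1 : 2;
      w[i] *= std::exp(-(double)ytr[i] * (left ? a : b));
    }
    paths.push_back(AdtPath());
    paths.push_back(AdtPath());
    AdtPath& lp = paths[paths.size() - 2];
    AdtPath& rp = paths[paths.size() - 1];
    lp.ord.resize(p); rp.ord.resize(p);
    for (int jj = 0; jj < p; ++jj) {
      const std::vector<int>& o = paths[bestPath].ord[jj];
      for (size_t q = 0; q < o.size(); ++q)
        (side[o[q]] == 1 ? lp.ord[jj] : rp.ord[jj]).push_back(o[q]);
    }
    r_path.push_back(bestPath); r_attr.push_back(bestAttr);
    r_thr.push_back(bestThr); r_a.push_back(a); r_b.push_back(b);
  }

  // held-out correctness at the zero-score threshold
  const int m = (int)r_path.size();
  std::vector<char> sat(2 * m + 1);
  int correct = 0;
  for (int i = 0; i < Xte.nrow(); ++i) {
    std::fill(sat.begin(), sat.end(), 0);
    sat[0] = 1;
    double s = root;
    for (int r = 0; r < m; ++r) {
      if (!sat[r_path[r]]) continue;
      const bool left = Xte(i, cols[r_attr[r]]) < r_thr[r];
      s += left ? r_a[r] : r_b[r];
      sat[2 * r + 1] = left;
      sat[2 * r + 2] = !left;
    }
    if ((s > 0 ? 1 : -1) == yte[i]) ++correct;
  }
  return correct;
}

// Batch fitness evaluation: one call scores many attribute subsets
// against the same precomputed inner folds, so the genetic search pays
// interface overhead once per generation instead of once per subset.
// [[Rcpp::export]]
NumericVector adtree_wse_batch_cpp(List fold_xtr, List fold_ytr,
                                   List fold_ord, List fold_xte,
                                   List fold_yte, List sel_list,
                                   int rounds) {
  const int nf = fold_xtr.size();
  const int nm = sel_list.size();
  NumericVector out(nm);
  int n_total = 0;
  for (int f = 0; f < nf; ++f)
    n_total += as<IntegerVector>(fold_yte[f]).size();
  for (int m = 0; m < nm; ++m) {
    IntegerVector sel = sel_list[m];
    int correct = 0;
    for (int f = 0; f < nf; ++f) {
      correct += adtree_fit_eval_cpp(fold_xtr[f], fold_ytr[f], fold_ord[f],
                                     sel, fold_xte[f], fold_yte[f], rounds);
    }
    out[m] = (double)correct / (double)n_total;
  }
  return out;
}
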