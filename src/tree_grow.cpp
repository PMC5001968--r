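// Survival tree growth with log-rank split search.
//
// Greedy recursive partitioning: at each node every feature and every
// midpoint between consecutive distinct observed values is scored by the
// two-sample log-rank chi-square statistic; the best (feature, threshold)
// wins, ties broken by lowest feature index then smallest threshold (the
// sweep visits candidates in exactly that order and only a strictly larger
// statistic replaces the incumbent). Stopping: child would fall below
// min_node_size, node events below min_events_to_split, max_depth reached,
// or best statistic zero.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct NodeWork {
  std::vector<int> rows; // indices into the training sample (0-based)
  int depth;
  int node_id; // position in the output node table
};

// Log-rank chi-square for the split defined by left-group risk counts.
// y1/d1: at-risk and event counts in the left group at each distinct event
// time; y/d: the node totals. Returns 0 when the variance sum is 0.
double logrank_from_counts(const std::vector<double>& y1,
                           const std::vector<double>& d1,
                           const std::vector<double>& y,
                           const std::vector<double>& d) {
  double oe = 0.0, v = 0.0;
  const int ntimes = static_cast<int>(y.size());
  for (int j = 0; j < ntimes; ++j) {
    if (y[j] <= 0) continue;
    oe += d1[j] - y1[j] * d[j] / y[j];
    if (y[j] > 1) {
      const double frac = y1[j] / y[j];
      v += d[j] * frac * (1.0 - frac) * (y[j] - d[j]) / (y[j] - 1.0);
    }
  }
  if (v <= 0) return 0.0;
  return oe * oe / v;
}

} // namespace

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericVector time, IntegerVector event, NumericMatrix Z,
                   int min_node_size, int min_events_to_split, int max_depth) {
  const int n = time.size();
  const int nfeat = Z.ncol();
  if (Z.nrow() != n || event.size() != n)
    stop("time, event and Z must agree in length");

  std::vector<int> feature;    // 1-based split feature, NA_INTEGER for leaves
  std::vector<double> threshold;
  std::vector<int> left, right; // 1-based child node ids, NA for leaves
  std::vector<int> n_node, n_events, depth_out;
  IntegerVector leaf_of_row(n, NA_INTEGER);

  std::vector<NodeWork> stack;
  {
    NodeWork root;
    root.rows.resize(n);
    for (int i = 0; i < n; ++i) root.rows[i] = i;
    root.depth = 0;
    root.node_id = 0;
  feature.push_back(NA_INTEGER); threshold.push_back(NA_REAL);
  left.push_back(NA_INTEGER); right.push_back(NA_INTEGER);
  n_node.push_back(n); n_events.push_back(0); depth_out.push_back(0);
    stack.push_back(std::move(root));
  }

  while (!stack.empty()) {
    NodeWork nw = std::move(stack.back());
    stack.pop_back();
    const int m = static_cast<int>(nw.rows.size());

    // distinct event times within the node
    std::vector<double> et;
    int tot_events = 0;
    for (int q : nw.rows) {
      if (event[q] == 1) { et.push_back(time[q]); ++tot_events; }
    }
    std::sort(et.begin(), et.end());
    et.erase(std::unique(et.begin(), et.end()), et.end());
    const int ntimes = static_cast<int>(et.size());

    n_node[nw.node_id] = m;
    n_events[nw.node_id] = tot_events;
    depth_out[nw.node_id] = nw.depth;

    bool make_leaf = false;
    if (m < 2 * min_node_size) make_leaf = true;
    if (tot_events < min_events_to_split) make_leaf = true;
    if (max_depth >= 0 && nw.depth >= max_depth) make_leaf = true;
    if (ntimes == 0) make_leaf = true;

    int best_feature = -1;
    double best_threshold = NA_REAL, best_stat = 0.0;

    if (!make_leaf) {
      // risk_idx[q]: number of distinct event times <= time of row q, i.e. the
      // row is at risk at event-time slots 0 .. risk_idx-1
      std::vector<int> risk_idx(m);
      std::vector<double> d_tot(ntimes, 0.0), y_tot(ntimes, 0.0);
      for (int a = 0; a < m; ++a) {
        const int q = nw.rows[a];
        const int k = static_cast<int>(
            std::upper_bound(et.begin(), et.end(), time[q]) - et.begin());
        risk_idx[a] = k;
        if (event[q] == 1 && k > 0 && et[k - 1] == time[q]) d_tot[k - 1] += 1.0;
      }
      // y_tot[j] = #rows with risk_idx > j
      {
        std::vector<double> hist(ntimes + 1, 0.0);
        for (int a = 0; a < m; ++a) hist[risk_idx[a]] += 1.0;
        double suffix = 0.0;
        for (int j = ntimes; j >= 1; --j) {
          suffix += hist[j];
          y_tot[j - 1] = suffix;
        }
      }

      std::vector<int> order(m);
      std::vector<double> y1(ntimes), d1(ntimes);
      for (int f = 0; f < nfeat; ++f) {
        for (int a = 0; a < m; ++a) order[a] = a;
        std::stable_sort(order.begin(), order.end(),
                         [&](int a, int b) { return Z(nw.rows[a], f) < Z(nw.rows[b], f); });
        std::fill(y1.begin(), y1.end(), 0.0);
        std::fill(d1.begin(), d1.end(), 0.0);
        for (int s = 0; s < m - 1; ++s) {
          const int a = order[s];
          const int q = nw.rows[a];
          for (int j = 0; j < risk_idx[a]; ++j) y1[j] += 1.0;
          if (event[q] == 1 && risk_idx[a] > 0 &&
              et[risk_idx[a] - 1] == time[q])
            d1[risk_idx[a] - 1] += 1.0;
          const double zlo = Z(nw.rows[order[s]], f);
          const double zhi = Z(nw.rows[order[s + 1]], f);
          if (!(zlo < zhi)) continue; // not a boundary between distinct values
          const int nl = s + 1, nr = m - nl;
          if (nl < min_node_size || nr < min_node_size) continue;
          const double stat = logrank_from_counts(y1, d1, y_tot, d_tot);
          if (stat > best_stat) {
            best_stat = stat;
            best_feature = f;
            best_threshold = 0.5 * (zlo + zhi);
          }
        }
      }
      if (best_feature < 0 || best_stat <= 0) make_leaf = true;
    }

    if (make_leaf) {
      for (int q : nw.rows) leaf_of_row[q] = nw.node_id + 1;
      continue;
    }

    NodeWork lw, rw;
    lw.depth = rw.depth = nw.depth + 1;
    for (int q : nw.rows) {
      if (Z(q, best_feature) <= best_threshold) lw.rows.push_back(q);
      else rw.rows.push_back(q);
    }
    // register children
    lw.node_id = static_cast<int>(feature.size());
    feature.push_back(NA_INTEGER); threshold.push_back(NA_REAL);
    left.push_back(NA_INTEGER); right.push_back(NA_INTEGER);
    n_node.push_back(0); n_events.push_back(0); depth_out.push_back(lw.depth);
    rw.node_id = static_cast<int>(feature.size());
    feature.push_back(NA_INTEGER); threshold.push_back(NA_REAL);
    left.push_back(NA_INTEGER); right.push_back(NA_INTEGER);
    n_node.push_back(0); n_events.push_back(0); depth_out.push_back(rw.depth);

    feature[nw.node_id] = best_feature + 1;
    threshold[nw.node_id] = best_threshold;
    left[nw.node_id] = lw.node_id + 1;
    right[nw.node_id] = rw.node_id + 1;

    stack.push_back(std::move(rw));
    stack.push_back(std::move(lw));
  }

  return List::create(
      _["feature"] = wrap(feature), _["threshold"] = wrap(threshold),
      _["left"] = wrap(left), _["right"] = wrap(right),
      _["n"] = wrap(n_node), _["events"] = wrap(n_events),
      _["depth"] = wrap(depth_out), _["leaf_of_row"] = leaf_of_row);
}

// Route rows of Z through the tree; "z <= threshold goes left". Returns the
// 1-based node id of the leaf each row lands in.
// [[Rcpp::export(name = ".route_tree_cpp")]]
IntegerVector route_tree_cpp(IntegerVector feature, NumericVector threshold,
                             IntegerVector left, IntegerVector right,
                             NumericMatrix Z) {
  const int n = Z.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      const double z = Z(i, feature[node] - 1);
      if (!R_finite(z)) stop("non-finite rotated feature value in row %d", i + 1);
      node = (z <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = node + 1;
  }
  return out;
}
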