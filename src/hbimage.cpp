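#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------- regression trees for gradient boosting ----------
//
// Trees are serialized as numeric matrices with one row per node and
// columns {feature (0-based, -1 = leaf), threshold, left, right, value};
// x[feature] <= threshold descends left. Splits are exact (all midpoints
// between distinct sorted values), chosen by maximal SSE reduction with
// deterministic ties (lowest feature index, then lowest split position).

struct Node {
  int feature;
  double threshold;
  int left, right;
  double value;
};

static int build_node(const NumericMatrix& X,
                      const std::vector<double>& resid,
                      const std::vector<int>& idx, int depth,
                      int max_depth, int min_obs,
                      std::vector<Node>& nodes) {
  const int me = (int)nodes.size();
  const int n = (int)idx.size();
  double sum_all = 0.0, ss_all = 0.0;
  for (int i : idx) { sum_all += resid[i]; ss_all += resid[i] * resid[i]; }
  nodes.push_back(Node{-1, 0.0, -1, -1, sum_all / n});
  if (depth >= max_depth || n < 2 * min_obs) return me;
  const double sse_all = ss_all - sum_all * sum_all / n;

  const int p = X.ncol();
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<int> ord(idx);
  std::vector<double> xv(n), rv(n);
  for (int f = 0; f < p; ++f) {
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
    for (int i = 0; i < n; ++i) {
      xv[i] = X(ord[i], f);
      rv[i] = resid[ord[i]];
    }
    double sl = 0.0, ssl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += rv[i];
      ssl += rv[i] * rv[i];
      if (xv[i] == xv[i + 1]) continue;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_obs || nr < min_obs) continue;
      const double sr = sum_all - sl, ssr = ss_all - ssl;
      const double sse = (ssl - sl * sl / nl) + (ssr - sr * sr / nr);
      const double gain = sse_all - sse;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xv[i] + xv[i + 1]);
      }
    }
  }
  if (best_f < 0) return me;

  std::vector<int> li, ri;
  li.reserve(n);
  ri.reserve(n);
  for (int i : idx) {
    if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
  }
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  const int l = build_node(X, resid, li, depth + 1, max_depth, min_obs, nodes);
  const int r = build_node(X, resid, ri, depth + 1, max_depth, min_obs, nodes);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

static double tree_pred(const NumericMatrix& T, const double* x) {
  int node = 0;
  while ((int)T(node, 0) >= 0) {
    const int f = (int)T(node, 0);
    node = (x[f] <= T(node, 1)) ? (int)T(node, 2) : (int)T(node, 3);
  }
  return T(node, 4);
}

// [[Rcpp::export]]
List gbm_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                 int max_depth, double learning_rate, int min_obs) {
  const int n = X.nrow(), p = X.ncol();
  const double init = mean(y);
  std::vector<double> pred(n, init), resid(n), xrow(p);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];
    std::vector<Node> nodes;
    build_node(X, resid, all, 0, max_depth, min_obs, nodes);
    NumericMatrix Tm((int)nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      Tm(k, 0) = nodes[k].feature;
      Tm(k, 1) = nodes[k].threshold;
      Tm(k, 2) = nodes[k].left;
      Tm(k, 3) = nodes[k].right;
      Tm(k, 4) = nodes[k].value;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      pred[i] += learning_rate * tree_pred(Tm, xrow.data());
    }
    trees[t] = Tm;
  }
  return List::create(_["init"] = init, _["trees"] = trees,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export]]
NumericVector gbm_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  const double init = as<double>(model["init"]);
  const double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  NumericVector out(n, init);
  std::vector<double> xrow(p);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix Tm = trees[t];
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      out[i] += lr * tree_pred(Tm, xrow.data());
    }
  }
  return out;
}

// ---------- Hough circle accumulator ----------
//
// Votes over a 1-pixel (center row, center col) grid for each candidate
// radius. Edge coordinates are 1-based (R convention). Equal maximal
// votes resolve to the larger radius; within a radius, to the lowest
// linear accumulator index. Fully deterministic.

// [[Rcpp::export]]
List hough_best_circle_cpp(IntegerVector edge_row, IntegerVector edge_col,
                           int H, int W, IntegerVector radii) {
  const int n = edge_row.size();
  std::vector<int> acc((size_t)H * W);
  long best_votes = -1;
  int best_r = 0, best_row = 0, best_col = 0;
  for (int ri = 0; ri < radii.size(); ++ri) {
    const int r = radii[ri];
    std::fill(acc.begin(), acc.end(), 0);
    const int na = std::max(16, (int)std::ceil(2.0 * M_PI * r));
    for (int a = 0; a < na; ++a) {
      const double th = 2.0 * M_PI * a / na;
      const double dr = r * std::sin(th);
      const double dc = r * std::cos(th);
      for (int i = 0; i < n; ++i) {
        const int cy = (int)std::lround(edge_row[i] - dr);
        const int cx = (int)std::lround(edge_col[i] - dc);
        if (cy >= 1 && cy <= H && cx >= 1 && cx <= W)
          acc[(size_t)(cy - 1) * W + (cx - 1)]++;
      }
    }
    long mv = -1;
    size_t mi = 0;
    for (size_t k = 0; k < acc.size(); ++k) {
      if (acc[k] > mv) { mv = acc[k]; mi = k; }
    }
    if (mv >= best_votes) {  // >=: larger radius wins ties
      best_votes = mv;
      best_r = r;
      best_row = (int)(mi / W) + 1;
      best_col = (int)(mi % W) + 1;
    }
  }
  return List::create(_["row"] = best_row, _["col"] = best_col,
                      _["radius"] = best_r,
                      _["votes"] = (double)best_votes);
}
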