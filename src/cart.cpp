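// Greedy CART classifier (gini impurity, depth-limited) used by the decision
// tree and random forest baselines.  Feature subsampling (mtry) draws from
// R's RNG so forests are reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // go left if x <= threshold
  int left, right;
  int pred;         // 0-based majority class
};

static double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    double p = (double)cnt[k] / n;
    s += p * p;
  }
  return 1.0 - s;
}

// [[Rcpp::export]]
List cart_fit(NumericMatrix X, IntegerVector y, int n_classes,
              int max_depth = 10, int min_samples_split = 2, int mtry = 0) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("cart_fit: X and y sizes differ");
  std::vector<Node> nodes;
  // stack of (node index, sample indices, depth)
  struct Work { int node; std::vector<int> idx; int depth; };
  std::vector<Work> stack;
  {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    nodes.push_back(Node{-1, 0.0, -1, -1, 0});
    stack.push_back(Work{0, all, 0});
  }
  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();
    int m = (int)w.idx.size();
    std::vector<int> cnt(n_classes, 0);
    for (int i = 0; i < m; ++i) cnt[y[w.idx[i]]]++;
    int pred = 0;
    for (int k = 1; k < n_classes; ++k) if (cnt[k] > cnt[pred]) pred = k;
    nodes[w.node].pred = pred;
    double parent_gini = gini_from_counts(cnt, m);
    bool pure = (cnt[pred] == m);
    if (w.depth >= max_depth || m < min_samples_split || pure) continue;

    // candidate features
    std::vector<int> feats;
    if (mtry > 0 && mtry < p) {
      // partial Fisher-Yates with R RNG
      std::vector<int> pool = feat_pool;
      feats.reserve(mtry);
      int avail = p;
      for (int t = 0; t < mtry; ++t) {
        int j = (int)(unif_rand() * avail);
        if (j >= avail) j = avail - 1;
        feats.push_back(pool[j]);
        pool[j] = pool[--avail];
      }
    } else {
      feats = feat_pool;
    }

    double best_score = parent_gini - 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double,int>> vals(m);
    std::vector<int> lc(n_classes);
    for (size_t fj = 0; fj < feats.size(); ++fj) {
      int f = feats[fj];
      for (int i = 0; i < m; ++i)
        vals[i] = std::make_pair(X(w.idx[i], f), y[w.idx[i]]);
      std::sort(vals.begin(), vals.end());
      std::fill(lc.begin(), lc.end(), 0);
      int nl = 0;
      for (int i = 0; i < m - 1; ++i) {
        lc[vals[i].second]++;
        nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        int nr = m - nl;
        double gl = gini_from_counts(lc, nl);
        std::vector<int> rc(n_classes);
        for (int k = 0; k < n_classes; ++k) rc[k] = cnt[k] - lc[k];
        double gr = gini_from_counts(rc, nr);
        double score = (nl * gl + nr * gr) / m;
        if (score < best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) continue;

    std::vector<int> li, ri;
    for (int i = 0; i < m; ++i) {
      if (X(w.idx[i], best_feat) <= best_thr) li.push_back(w.idx[i]);
      else ri.push_back(w.idx[i]);
    }
    if (li.empty() || ri.empty()) continue;
    nodes[w.node].feature = best_feat;
    nodes[w.node].threshold = best_thr;
    int l = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, pred});
    int r = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, pred});
    nodes[w.node].left = l;
    nodes[w.node].right = r;
    stack.push_back(Work{l, std::move(li), w.depth + 1});
    stack.push_back(Work{r, std::move(ri), w.depth + 1});
  }

  int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), pred(nn);
  NumericVector threshold(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["pred"] = pred);
}

// [[Rcpp::export]]
IntegerVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
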