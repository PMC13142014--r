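// Random-forest engine with per-feature split-candidate sampling weights.
//
// Trees are CART-style: axis-aligned splits at midpoints between adjacent
// distinct observed values, Gini impurity (classification) or variance
// reduction (regression). At every node a set of min(mtry, #positive-weight
// features) distinct candidate features is drawn without replacement with
// probability proportional to the supplied weights, so features with zero
// weight can never be chosen as split variables.
//
// All randomness flows from a splitmix64 stream seeded once per forest and
// advanced deterministically (per tree, then per draw), which makes every
// result bit-reproducible for a given seed independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct SplitRng {
  uint64_t s;
  explicit SplitRng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in {0, ..., n-1}; n is always far below 2^52 here
  int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct GrownTree {
  std::vector<int> feature;      // -1 for leaves
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;  // -1 for leaves
  std::vector<double> pred;      // regression: node mean; classification: majority class
  std::vector<double> probs;     // classification: n_nodes * K class fractions
  std::vector<int> oob;          // out-of-bag row indices (0-based)
};

struct WorkItem {
  int node;
  int begin, end; // range into the index buffer
};

const double MIN_DECREASE = 1e-12;

// Draw m distinct features without replacement, probability proportional to
// weights over the active (positive-weight) set. Result sorted ascending so
// that impurity ties break toward the lower feature index.
void draw_candidates(const std::vector<int>& active,
                     const std::vector<double>& active_w,
                     double total_w, int m, SplitRng& rng,
                     std::vector<int>& out) {
  out.clear();
  std::vector<double> cw(active_w);
  double tot = total_w;
  const int na = (int)active.size();
  for (int d = 0; d < m; ++d) {
    double u = rng.unif() * tot;
    double cum = 0.0;
    int pick = -1;
    for (int j = 0; j < na; ++j) {
      if (cw[j] <= 0.0) continue;
      cum += cw[j];
      if (u < cum) { pick = j; break; }
    }
    if (pick < 0) { // fp slack: take the last remaining positive weight
      for (int j = na - 1; j >= 0; --j)
        if (cw[j] > 0.0) { pick = j; break; }
    }
    if (pick < 0) break;
    out.push_back(active[pick]);
    tot -= cw[pick];
    cw[pick] = 0.0;
  }
  std::sort(out.begin(), out.end());
}

int add_node(GrownTree& tr, int K) {
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.pred.push_back(0.0);
  if (K > 0) tr.probs.insert(tr.probs.end(), K, 0.0);
  return (int)tr.feature.size() - 1;
}

void grow_tree(const NumericMatrix& X, const NumericVector& y,
               bool classification, int K, int mtry, int min_node_size,
               const std::vector<int>& active,
               const std::vector<double>& active_w, double total_w,
               bool bootstrap, SplitRng& rng, GrownTree& tr) {
  const int n = X.nrow();

  // bootstrap sample of size n with replacement (or the full sample)
  std::vector<int> idx(n);
  std::vector<char> inbag(n, 0);
  for (int i = 0; i < n; ++i) {
    int k = bootstrap ? rng.below(n) : i;
    idx[i] = k;
    inbag[k] = 1;
  }
  for (int i = 0; i < n; ++i)
    if (!inbag[i]) tr.oob.push_back(i);

  const int mtry_eff = std::min<int>(mtry, (int)active.size());

  std::vector<WorkItem> stack;
  int root = add_node(tr, classification ? K : 0);
  stack.push_back({root, 0, n});

  std::vector<int> cand;
  std::vector<std::pair<double, double> > xy; // (x value, response)
  std::vector<int> cls_parent(K), cls_left(K);

  while (!stack.empty()) {
    WorkItem w = stack.back();
    stack.pop_back();
    const int nn = w.end - w.begin;

    // node statistics + leaf prediction
    bool pure;
    if (classification) {
      std::fill(cls_parent.begin(), cls_parent.end(), 0);
      for (int i = w.begin; i < w.end; ++i) cls_parent[(int)y[idx[i]]]++;
      int maxc = 0, argc = 0;
      for (int c = 0; c < K; ++c) {
        tr.probs[(size_t)w.node * K + c] = (double)cls_parent[c] / nn;
        if (cls_parent[c] > maxc) { maxc = cls_parent[c]; argc = c; }
      }
      tr.pred[w.node] = argc; // tie -> lower class index (strict >)
      pure = (maxc == nn);
    } else {
      double s = 0.0, mn = R_PosInf, mx = R_NegInf;
      for (int i = w.begin; i < w.end; ++i) {
        double v = y[idx[i]];
        s += v;
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      tr.pred[w.node] = s / nn;
      pure = (mx - mn <= 0.0);
    }

    if (pure || nn <= min_node_size || mtry_eff < 1) continue; // leaf

    draw_candidates(active, active_w, total_w, mtry_eff, rng, cand);

    // best split among candidates; ties break toward the lower feature
    // index (candidates ascending, strict improvement) then lower threshold
    double best_dec = -1.0, best_thr = 0.0;
    int best_f = -1;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      const int f = cand[ci];
      xy.clear();
      for (int i = w.begin; i < w.end; ++i)
        xy.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
      std::sort(xy.begin(), xy.end());
      if (xy.front().first >= xy.back().first) continue; // constant feature

      if (classification) {
        std::fill(cls_left.begin(), cls_left.end(), 0);
        double SP = 0.0;
        for (int c = 0; c < K; ++c)
          SP += (double)cls_parent[c] * cls_parent[c];
        double SL = 0.0; // running sum of squared left counts
        for (int i = 0; i < nn - 1; ++i) {
          int c = (int)xy[i].second;
          SL += 2.0 * cls_left[c] + 1.0;
          cls_left[c]++;
          if (xy[i + 1].first > xy[i].first) {
            const int nl = i + 1, nr = nn - nl;
            double SR = 0.0;
            for (int cc = 0; cc < K; ++cc) {
              double rc = cls_parent[cc] - cls_left[cc];
              SR += rc * rc;
            }
            double dec = (SL / nl + SR / nr - SP / nn) / nn;
            if (dec > best_dec) {
              double mid = xy[i].first + (xy[i + 1].first - xy[i].first) / 2.0;
              if (mid >= xy[i + 1].first) mid = xy[i].first;
              best_dec = dec;
              best_f = f;
              best_thr = mid;
            }
          }
        }
      } else {
        double SPs = 0.0;
        for (int i = 0; i < nn; ++i) SPs += xy[i].second;
        double SLs = 0.0;
        for (int i = 0; i < nn - 1; ++i) {
          SLs += xy[i].second;
          if (xy[i + 1].first > xy[i].first) {
            const int nl = i + 1, nr = nn - nl;
            double SRs = SPs - SLs;
            double dec = (SLs * SLs / nl + SRs * SRs / nr - SPs * SPs / nn) / nn;
            if (dec > best_dec) {
              double mid = xy[i].first + (xy[i + 1].first - xy[i].first) / 2.0;
              if (mid >= xy[i + 1].first) mid = xy[i].first;
              best_dec = dec;
              best_f = f;
              best_thr = mid;
            }
          }
        }
      }
    }

    if (best_f < 0 || best_dec <= MIN_DECREASE) continue; // leaf

    // partition indices in place: x <= threshold to the left
    int lo = w.begin, hi = w.end - 1;
    while (lo <= hi) {
      if (X(idx[lo], best_f) <= best_thr) {
        ++lo;
      } else {
        std::swap(idx[lo], idx[hi]);
        --hi;
      }
    }
    const int mid_pos = lo;
    if (mid_pos == w.begin || mid_pos == w.end) continue; // cannot happen; guard

    tr.feature[w.node] = best_f;
    tr.threshold[w.node] = best_thr;
    int lnode = add_node(tr, classification ? K : 0);
    int rnode = add_node(tr, classification ? K : 0);
    tr.left[w.node] = lnode;
    tr.right[w.node] = rnode;
    stack.push_back({rnode, mid_pos, w.end});
    stack.push_back({lnode, w.begin, mid_pos});
  }
}

// tree traversal for one sample; `pf` is the permuted feature (-1 none)
inline int descend(const IntegerVector& feature, const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int row, int pf, int prow) {
  int node = 0;
  while (feature[node] >= 0) {
    const int f = feature[node];
    const double v = (f == pf) ? X(prow, f) : X(row, f);
    node = (v <= threshold[node]) ? left[node] : right[node];
  }
  return node;
}

} // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, bool classification,
                     int n_classes, int mtry, int n_trees,
                     NumericVector weights, int min_node_size, double seed,
                     bool bootstrap) {
  const int p = X.ncol();
  std::vector<int> active;
  std::vector<double> active_w;
  double total_w = 0.0;
  for (int j = 0; j < p; ++j) {
    if (weights[j] > 0.0) {
      active.push_back(j);
      active_w.push_back(weights[j]);
      total_w += weights[j];
    }
  }
  if (active.empty()) stop("all feature selection weights are zero");

  SplitRng master((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x1234567ULL);
  List trees(n_trees);
  const int K = classification ? n_classes : 0;

  for (int t = 0; t < n_trees; ++t) {
    SplitRng rng(master.next());
    GrownTree tr;
    grow_tree(X, y, classification, n_classes, mtry, min_node_size,
              active, active_w, total_w, bootstrap, rng, tr);
    const int nn = (int)tr.feature.size();
    List tl;
    if (classification) {
      NumericMatrix pm(nn, K);
      for (int i = 0; i < nn; ++i)
        for (int c = 0; c < K; ++c) pm(i, c) = tr.probs[(size_t)i * K + c];
      tl = List::create(_["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
                        _["threshold"] = NumericVector(tr.threshold.begin(), tr.threshold.end()),
                        _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
                        _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
                        _["pred"] = NumericVector(tr.pred.begin(), tr.pred.end()),
                        _["probs"] = pm,
                        _["oob"] = IntegerVector(tr.oob.begin(), tr.oob.end()));
    } else {
      tl = List::create(_["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
                        _["threshold"] = NumericVector(tr.threshold.begin(), tr.threshold.end()),
                        _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
                        _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
                        _["pred"] = NumericVector(tr.pred.begin(), tr.pred.end()),
                        _["oob"] = IntegerVector(tr.oob.begin(), tr.oob.end()));
    }
    trees[t] = tl;
  }
  return trees;
}

// Average class proportions (classification, n x K) or tree means
// (regression, length n) over all trees.
// [[Rcpp::export]]
SEXP cpp_predict_forest(List trees, NumericMatrix X, bool classification,
                        int n_classes) {
  const int n = X.nrow();
  const int T = trees.size();
  if (classification) {
    NumericMatrix out(n, n_classes);
    for (int t = 0; t < T; ++t) {
      List tl = trees[t];
      IntegerVector feature = tl["feature"], left = tl["left"], right = tl["right"];
      NumericVector threshold = tl["threshold"];
      NumericMatrix probs = tl["probs"];
      for (int i = 0; i < n; ++i) {
        int leaf = descend(feature, threshold, left, right, X, i, -1, -1);
        for (int c = 0; c < n_classes; ++c) out(i, c) += probs(leaf, c);
      }
    }
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < n_classes; ++c) out(i, c) /= T;
    return out;
  } else {
    NumericVector out(n);
    for (int t = 0; t < T; ++t) {
      List tl = trees[t];
      IntegerVector feature = tl["feature"], left = tl["left"], right = tl["right"];
      NumericVector threshold = tl["threshold"], pred = tl["pred"];
      for (int i = 0; i < n; ++i) {
        int leaf = descend(feature, threshold, left, right, X, i, -1, -1);
        out[i] += pred[leaf];
      }
    }
    for (int i = 0; i < n; ++i) out[i] /= T;
    return out;
  }
}

// Sum of per-tree OOB predictions per sample (class proportions or means)
// plus the number of trees for which each sample was out-of-bag.
// [[Rcpp::export]]
List cpp_oob_aggregate(List trees, NumericMatrix X, bool classification,
                       int n_classes) {
  const int n = X.nrow();
  const int T = trees.size();
  IntegerVector count(n);
  NumericMatrix agg(n, classification ? n_classes : 1);
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    IntegerVector feature = tl["feature"], left = tl["left"], right = tl["right"];
    IntegerVector oob = tl["oob"];
    NumericVector threshold = tl["threshold"];
    if (classification) {
      NumericMatrix probs = tl["probs"];
      for (int k = 0; k < oob.size(); ++k) {
        const int i = oob[k];
        int leaf = descend(feature, threshold, left, right, X, i, -1, -1);
        for (int c = 0; c < n_classes; ++c) agg(i, c) += probs(leaf, c);
        count[i]++;
      }
    } else {
      NumericVector pred = tl["pred"];
      for (int k = 0; k < oob.size(); ++k) {
        const int i = oob[k];
        int leaf = descend(feature, threshold, left, right, X, i, -1, -1);
        agg(i, 0) += pred[leaf];
        count[i]++;
      }
    }
  }
  return List::create(_["agg"] = agg, _["count"] = count);
}

// Out-of-bag permutation importance: for each tree, each feature used by
// that tree has its OOB values permuted n_perm times; the mean increase in
// the tree's OOB loss (error rate / MSE) is recorded. Features unused by a
// tree contribute 0 for that tree; scores are averaged over all trees.
// [[Rcpp::export]]
NumericVector cpp_permutation_importance(List trees, NumericMatrix X,
                                         NumericVector y, bool classification,
                                         int n_classes, int n_perm,
                                         double seed) {
  const int p = X.ncol();
  const int T = trees.size();
  NumericVector imp(p);
  SplitRng master((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x7654321ULL);

  std::vector<int> used;
  std::vector<char> used_flag(p);
  std::vector<int> perm;

  for (int t = 0; t < T; ++t) {
    SplitRng rng(master.next());
    List tl = trees[t];
    IntegerVector feature = tl["feature"], left = tl["left"], right = tl["right"];
    IntegerVector oob = tl["oob"];
    NumericVector threshold = tl["threshold"], pred = tl["pred"];
    const int m = oob.size();
    if (m == 0) continue;

    NumericMatrix probs;
    if (classification) probs = as<NumericMatrix>(tl["probs"]);

    std::fill(used_flag.begin(), used_flag.end(), 0);
    used.clear();
    for (int i = 0; i < feature.size(); ++i) {
      int f = feature[i];
      if (f >= 0 && !used_flag[f]) {
        used_flag[f] = 1;
        used.push_back(f);
      }
    }
    if (used.empty()) continue;
    std::sort(used.begin(), used.end());

    // baseline OOB loss of this tree
    double base = 0.0;
    for (int k = 0; k < m; ++k) {
      const int i = oob[k];
      int leaf = descend(feature, threshold, left, right, X, i, -1, -1);
      if (classification) {
        base += ((int)pred[leaf] != (int)y[i]) ? 1.0 : 0.0;
      } else {
        double e = pred[leaf] - y[i];
        base += e * e;
      }
    }
    base /= m;

    for (size_t uf = 0; uf < used.size(); ++uf) {
      const int f = used[uf];
      double delta = 0.0;
      for (int rep = 0; rep < n_perm; ++rep) {
        perm.resize(m);
        for (int k = 0; k < m; ++k) perm[k] = k;
        for (int k = m - 1; k > 0; --k)
          std::swap(perm[k], perm[rng.below(k + 1)]);
        double loss = 0.0;
        for (int k = 0; k < m; ++k) {
          const int i = oob[k];
          const int prow = oob[perm[k]];
          int leaf = descend(feature, threshold, left, right, X, i, f, prow);
          if (classification) {
            loss += ((int)pred[leaf] != (int)y[i]) ? 1.0 : 0.0;
          } else {
            double e = pred[leaf] - y[i];
            loss += e * e;
          }
        }
        delta += loss / m - base;
      }
      imp[f] += delta / n_perm;
    }
  }
  for (int j = 0; j < p; ++j) imp[j] /= T;
  return imp;
}
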