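// Random forest: CART trees on bootstrap samples with mtry random feature
// subsets, out-of-bag votes, and permutation (mean-decrease-in-accuracy /
// increase-in-MSE) importance.  Uses R's RNG so results are reproducible
// under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var;              // -1 for leaf
  std::vector<double> val;           // x <= val goes left
  std::vector<int> left, right;
  std::vector<double> pred;          // class index or mean
};

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// sample mtry distinct feature indices out of p
void sample_features(int p, int mtry, std::vector<int> &pool,
                     std::vector<int> &out) {
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < mtry; ++i) {
    int j = i + rand_int(p - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct Builder {
  const NumericMatrix &X;
  const std::vector<double> &y;      // class index (classif) or value
  const std::vector<double> &w;      // sample weights
  int n_classes;                     // 0 => regression
  int mtry, min_node;
  Tree tree;
  std::vector<double> imp_impurity;  // per-feature impurity decrease

  Builder(const NumericMatrix &X_, const std::vector<double> &y_,
          const std::vector<double> &w_, int n_classes_, int mtry_,
          int min_node_)
      : X(X_), y(y_), w(w_), n_classes(n_classes_), mtry(mtry_),
        min_node(min_node_), imp_impurity(X_.ncol(), 0.0) {}

  int make_leaf(const std::vector<int> &idx) {
    double pred;
    if (n_classes > 0) {
      std::vector<double> cw(n_classes, 0.0);
      for (int i : idx) cw[(int)y[i]] += w[i];
      pred = (double)(std::max_element(cw.begin(), cw.end()) - cw.begin());
    } else {
      double s = 0, sw = 0;
      for (int i : idx) { s += w[i] * y[i]; sw += w[i]; }
      pred = sw > 0 ? s / sw : 0.0;
    }
    tree.var.push_back(-1);
    tree.val.push_back(0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(pred);
    return (int)tree.var.size() - 1;
  }

  bool is_pure(const std::vector<int> &idx) {
    for (size_t i = 1; i < idx.size(); ++i)
      if (y[idx[i]] != y[idx[0]]) return false;
    return true;
  }

  // score to maximize: sum_k wk_side^2 / W_side (classification) or
  // S_side^2 / W_side (regression), summed over sides
  int build(std::vector<int> &idx, std::vector<int> &pool,
            std::vector<int> &feats) {
    int n_node = (int)idx.size();
    if (n_node < std::max(2, min_node) || is_pure(idx))
      return make_leaf(idx);

    sample_features((int)X.ncol(), mtry, pool, feats);

    int best_f = -1;
    double best_score = -1.0, best_split = 0.0, node_score, w_node = 0;
    std::vector<double> cw_tot(n_classes > 0 ? n_classes : 0, 0.0);
    double s_tot = 0;
    for (int i : idx) {
      w_node += w[i];
      if (n_classes > 0) cw_tot[(int)y[i]] += w[i];
      else s_tot += w[i] * y[i];
    }
    if (n_classes > 0) {
      node_score = 0;
      for (double c : cw_tot) node_score += c * c;
      node_score /= w_node;
    } else {
      node_score = s_tot * s_tot / w_node;
    }

    std::vector<std::pair<double, int>> ord(n_node);
    std::vector<double> cw_left(n_classes > 0 ? n_classes : 0);
    for (int f : feats) {
      for (int i = 0; i < n_node; ++i)
        ord[i] = std::make_pair(X(idx[i], f), idx[i]);
      std::sort(ord.begin(), ord.end());
      if (ord.front().first == ord.back().first) continue;  // constant

      std::fill(cw_left.begin(), cw_left.end(), 0.0);
      double w_left = 0, s_left = 0, cls_left = 0;
      for (int i = 0; i < n_node - 1; ++i) {
        int s = ord[i].second;
        w_left += w[s];
        if (n_classes > 0) {
          int c = (int)y[s];
          cls_left += w[s] * (2 * cw_left[c] + w[s]);  // update sum cw^2
          cw_left[c] += w[s];
        } else {
          s_left += w[s] * y[s];
        }
        if (ord[i].first == ord[i + 1].first) continue;  // not a boundary
        double w_right = w_node - w_left, score;
        if (w_left <= 0 || w_right <= 0) continue;
        if (n_classes > 0) {
          double cls_right = 0;
          for (int c = 0; c < n_classes; ++c) {
            double cr = cw_tot[c] - cw_left[c];
            cls_right += cr * cr;
          }
          score = cls_left / w_left + cls_right / w_right;
        } else {
          double s_right = s_tot - s_left;
          score = s_left * s_left / w_left + s_right * s_right / w_right;
        }
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_split = (ord[i].first + ord[i + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0 || best_score <= node_score + 1e-12)
      return make_leaf(idx);

    imp_impurity[best_f] += best_score - node_score;

    std::vector<int> idx_l, idx_r;
    for (int i : idx)
      (X(i, best_f) <= best_split ? idx_l : idx_r).push_back(i);
    if (idx_l.empty() || idx_r.empty()) return make_leaf(idx);

    int node = (int)tree.var.size();
    tree.var.push_back(best_f);
    tree.val.push_back(best_split);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(0);
    int l = build(idx_l, pool, feats);
    int r = build(idx_r, pool, feats);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

// predict sample i, optionally overriding feature `of` with value `ov`
inline double tree_predict(const Tree &t, const NumericMatrix &X, int i,
                           int of = -1, double ov = 0.0) {
  int node = 0;
  while (t.var[node] >= 0) {
    double x = (t.var[node] == of) ? ov : X(i, t.var[node]);
    node = (x <= t.val[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

void features_used(const Tree &t, std::vector<int> &out, int p) {
  std::vector<bool> seen(p, false);
  for (int v : t.var)
    if (v >= 0) seen[v] = true;
  out.clear();
  for (int f = 0; f < p; ++f)
    if (seen[f]) out.push_back(f);
}

List tree_to_list(const Tree &t) {
  return List::create(_["var"] = IntegerVector(t.var.begin(), t.var.end()),
                      _["val"] = NumericVector(t.val.begin(), t.val.end()),
                      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
                      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
                      _["pred"] = NumericVector(t.pred.begin(), t.pred.end()));
}

Tree tree_from_list(const List &l) {
  Tree t;
  IntegerVector var = l["var"], left = l["left"], right = l["right"];
  NumericVector val = l["val"], pred = l["pred"];
  t.var.assign(var.begin(), var.end());
  t.val.assign(val.begin(), val.end());
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.pred.assign(pred.begin(), pred.end());
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_classes, int n_trees,
                int mtry, int min_node, NumericVector sample_weights,
                bool importance) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> wv(sample_weights.begin(), sample_weights.end());

  RNGScope rng;

  NumericMatrix oob_votes;           // n x n_classes (classification)
  NumericVector oob_sum(n), oob_cnt(n);
  if (n_classes > 0) oob_votes = NumericMatrix(n, n_classes);

  NumericVector imp_perm(p), imp_imp(p);
  List trees(n_trees);
  std::vector<int> idx, oob_idx, pool((size_t)p), feats;
  std::vector<int> inbag(n);
  std::vector<double> perm_vals;
  std::vector<int> perm_order;

  // bootstrap draws proportional to sample weight, so class reweighting
  // rebalances the bags themselves (as well as impurity and votes)
  std::vector<double> cum_w(n);
  double tot_w = 0;
  for (int i = 0; i < n; ++i) {
    tot_w += wv[i];
    cum_w[i] = tot_w;
  }
  for (int b = 0; b < n_trees; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      double u = unif_rand() * tot_w;
      int j = (int)(std::lower_bound(cum_w.begin(), cum_w.end(), u) -
                    cum_w.begin());
      if (j >= n) j = n - 1;
      idx.push_back(j);
      inbag[j]++;
    }
    Builder bl(X, yv, wv, n_classes, mtry, min_node);
    bl.build(idx, pool, feats);
    const Tree &t = bl.tree;
    trees[b] = tree_to_list(t);
    for (int f = 0; f < p; ++f) imp_imp[f] += bl.imp_impurity[f];

    oob_idx.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_idx.push_back(i);
    if (oob_idx.empty()) continue;

    // OOB aggregation + baseline error for permutation importance
    double base = 0;  // correct count (classif) or SSE (regression)
    std::vector<double> oob_pred(oob_idx.size());
    for (size_t k = 0; k < oob_idx.size(); ++k) {
      int i = oob_idx[k];
      double pr = tree_predict(t, X, i);
      oob_pred[k] = pr;
      if (n_classes > 0) {
        oob_votes(i, (int)pr) += 1.0;
        if ((int)pr == (int)yv[i]) base += 1.0;
      } else {
        oob_sum[i] += pr;
        oob_cnt[i] += 1.0;
        base += (pr - yv[i]) * (pr - yv[i]);
      }
    }

    if (!importance) continue;
    int m = (int)oob_idx.size();
    features_used(t, feats, p);
    perm_order.resize(m);
    perm_vals.resize(m);
    for (int f : feats) {
      for (int k = 0; k < m; ++k) perm_order[k] = k;
      for (int k = m - 1; k > 0; --k)
        std::swap(perm_order[k], perm_order[rand_int(k + 1)]);
      for (int k = 0; k < m; ++k)
        perm_vals[k] = X(oob_idx[perm_order[k]], f);
      double permuted = 0;
      for (int k = 0; k < m; ++k) {
        int i = oob_idx[k];
        double pr = tree_predict(t, X, i, f, perm_vals[k]);
        if (n_classes > 0)
          permuted += ((int)pr == (int)yv[i]) ? 1.0 : 0.0;
        else
          permuted += (pr - yv[i]) * (pr - yv[i]);
      }
      if (n_classes > 0)
        imp_perm[f] += (base - permuted) / m;    // decrease in accuracy
      else
        imp_perm[f] += (permuted - base) / m;    // increase in MSE
    }
  }
  for (int f = 0; f < p; ++f) {
    imp_perm[f] /= n_trees;
    imp_imp[f] /= n_trees;
  }
  return List::create(_["trees"] = trees, _["oob_votes"] = oob_votes,
                      _["oob_sum"] = oob_sum, _["oob_cnt"] = oob_cnt,
                      _["importance_permutation"] = imp_perm,
                      _["importance_impurity"] = imp_imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
List rf_predict_cpp(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), n_trees = trees.size();
  NumericMatrix votes;
  NumericVector mean_pred(n);
  if (n_classes > 0) votes = NumericMatrix(n, n_classes);
  for (int b = 0; b < n_trees; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) {
      double pr = tree_predict(t, X, i);
      if (n_classes > 0) votes(i, (int)pr) += 1.0;
      else mean_pred[i] += pr / n_trees;
    }
  }
  return List::create(_["votes"] = votes, _["mean"] = mean_pred);
}
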