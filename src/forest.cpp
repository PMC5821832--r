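#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// CART-style classification trees used as the base learner for the
// conditional permutation importance forest. Trees are grown on subsamples
// drawn without replacement; split selection is Gini with mtry random
// candidates. All randomness comes from R's RNG stream so results are
// fully reproducible under set.seed().

static int majority_class(const std::vector<int>& counts) {
  int best = 0;
  for (size_t c = 1; c < counts.size(); ++c)
    if (counts[c] > counts[best]) best = (int)c;  // tie -> lowest class
  return best;
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, int n_classes,
                   IntegerVector inbag, int mtry, int min_split) {
  const int p = X.ncol();
  std::vector<int> nvar, nleft, nright, npred;
  std::vector<double> nsplit;
  struct Item { int id; std::vector<int> idx; };
  std::vector<Item> stack;

  auto new_node = [&]() {
    nvar.push_back(-1); nsplit.push_back(0.0);
    nleft.push_back(-1); nright.push_back(-1); npred.push_back(0);
    return (int)(nvar.size() - 1);
  };

  std::vector<int> root_idx(inbag.begin(), inbag.end());
  int root = new_node();
  stack.push_back(Item{root, std::move(root_idx)});

  while (!stack.empty()) {
    Item it = std::move(stack.back());
    stack.pop_back();
    std::vector<int>& idx = it.idx;
    const int m = (int)idx.size();

    std::vector<int> counts(n_classes, 0);
    for (int i : idx) counts[y[i]]++;
    int maj = majority_class(counts);
    npred[it.id] = maj;
    if (counts[maj] == m || m < min_split) continue;

    // mtry candidates without replacement (partial Fisher-Yates), sorted so
    // score ties resolve to the lowest variable index deterministically
    std::vector<int> cand(p);
    for (int j = 0; j < p; ++j) cand[j] = j;
    int mt = std::min(mtry, p);
    for (int j = 0; j < mt; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(cand[j], cand[r]);
    }
    cand.resize(mt);
    std::sort(cand.begin(), cand.end());

    double base = 0.0;
    for (int c = 0; c < n_classes; ++c)
      base += (double)counts[c] * counts[c];
    base /= m;
    double best_score = base + 1e-12;  // must strictly improve on parent
    int best_var = -1;
    double best_split = 0.0;

    std::vector<int> ord(idx);
    std::vector<int> lc(n_classes);
    for (int v : cand) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, v), xb = X(b, v);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      std::fill(lc.begin(), lc.end(), 0);
      double suml = 0.0;
      for (int t = 0; t < m - 1; ++t) {
        int cls = y[ord[t]];
        suml += 2.0 * lc[cls] + 1.0;  // incremental sum of squared counts
        lc[cls]++;
        double xv = X(ord[t], v), xnext = X(ord[t + 1], v);
        if (xv == xnext) continue;
        double sumr = 0.0;
        for (int c = 0; c < n_classes; ++c) {
          double rc = counts[c] - lc[c];
          sumr += rc * rc;
        }
        double score = suml / (t + 1) + sumr / (m - t - 1);
        if (score > best_score) {
          best_score = score;
          best_var = v;
          best_split = (xv + xnext) / 2.0;
        }
      }
    }
    if (best_var < 0) continue;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_var) <= best_split) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) continue;
    nvar[it.id] = best_var;
    nsplit[it.id] = best_split;
    int L = new_node(), R = new_node();
    nleft[it.id] = L;
    nright[it.id] = R;
    stack.push_back(Item{L, std::move(li)});
    stack.push_back(Item{R, std::move(ri)});
  }

  return List::create(_["var"] = wrap(nvar), _["split"] = wrap(nsplit),
                      _["left"] = wrap(nleft), _["right"] = wrap(nright),
                      _["pred"] = wrap(npred));
}

static int tree_predict_row(const IntegerVector& var,
                            const NumericVector& split,
                            const IntegerVector& left,
                            const IntegerVector& right,
                            const IntegerVector& pred,
                            const NumericMatrix& X, int row,
                            int override_var, double override_val) {
  int node = 0;
  while (var[node] >= 0) {
    double x = (var[node] == override_var) ? override_val : X(row, var[node]);
    node = (x <= split[node]) ? left[node] : right[node];
  }
  return pred[node];
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(List tree, NumericMatrix X,
                               IntegerVector rows) {
  IntegerVector var = tree["var"];
  NumericVector split = tree["split"];
  IntegerVector left = tree["left"], right = tree["right"],
                pred = tree["pred"];
  IntegerVector out(rows.size());
  for (int i = 0; i < rows.size(); ++i)
    out[i] = tree_predict_row(var, split, left, right, pred, X, rows[i],
                              -1, 0.0);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_forest_votes(List trees, NumericMatrix X, int n_classes) {
  const int n = X.nrow();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < trees.size(); ++t) {
    List tree = trees[t];
    IntegerVector var = tree["var"];
    NumericVector split = tree["split"];
    IntegerVector left = tree["left"], right = tree["right"],
                  pred = tree["pred"];
    for (int i = 0; i < n; ++i) {
      int c = tree_predict_row(var, split, left, right, pred, X, i, -1, 0.0);
      votes(i, c)++;
    }
  }
  return votes;
}

// Permutation importance, unconditional or conditional (Strobl-style):
// for each tree and variable j used by that tree, the variable's
// out-of-bag values are permuted -- globally, or within strata defined by
// the tree's own split points of variables correlated with j -- and the
// drop in OOB accuracy is averaged over trees. Variables never used by a
// tree contribute exactly 0 for it (no prediction can change).
// [[Rcpp::export]]
NumericVector cpp_importance(List trees, List oob_list, NumericMatrix X,
                             IntegerVector y, int n_classes, List cond_list,
                             bool conditional) {
  const int p = X.ncol();
  const int ntree = trees.size();
  NumericVector imp(p);

  for (int t = 0; t < ntree; ++t) {
    List tree = trees[t];
    IntegerVector var = tree["var"];
    NumericVector split = tree["split"];
    IntegerVector left = tree["left"], right = tree["right"],
                  pred = tree["pred"];
    IntegerVector oob = oob_list[t];
    const int m = oob.size();
    if (m == 0) continue;

    // split points used by this tree, per variable
    std::vector<std::vector<double> > cuts(p);
    for (int nd = 0; nd < var.size(); ++nd)
      if (var[nd] >= 0) cuts[var[nd]].push_back(split[nd]);
    for (int j = 0; j < p; ++j) {
      std::sort(cuts[j].begin(), cuts[j].end());
      cuts[j].erase(std::unique(cuts[j].begin(), cuts[j].end()),
                    cuts[j].end());
    }

    int correct0 = 0;
    for (int i = 0; i < m; ++i) {
      int c = tree_predict_row(var, split, left, right, pred, X, oob[i],
                               -1, 0.0);
      if (c == y[oob[i]]) correct0++;
    }
    double acc0 = (double)correct0 / m;

    for (int j = 0; j < p; ++j) {
      if (cuts[j].empty()) continue;  // tree never splits on j: delta 0

      // stratum key per OOB sample: bins of conditioning variables against
      // this tree's cutpoints (empty conditioning set -> one global stratum)
      std::vector<std::vector<int> > key(m);
      if (conditional) {
        IntegerVector cj = cond_list[j];
        for (int zi = 0; zi < cj.size(); ++zi) {
          int z = cj[zi];
          if (cuts[z].empty()) continue;
          for (int i = 0; i < m; ++i) {
            double xz = X(oob[i], z);
            int bin = (int)(std::upper_bound(cuts[z].begin(), cuts[z].end(),
                                             xz) - cuts[z].begin());
            key[i].push_back(bin);
          }
        }
      }

      // group OOB positions by stratum key (lexicographic, deterministic)
      std::vector<int> order(m);
      for (int i = 0; i < m; ++i) order[i] = i;
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        if (key[a] != key[b]) return key[a] < key[b];
        return a < b;
      });

      // permute j's OOB values within each stratum (Fisher-Yates)
      std::vector<double> permuted(m);
      for (int i = 0; i < m; ++i) permuted[i] = X(oob[i], j);
      int g0 = 0;
      while (g0 < m) {
        int g1 = g0;
        while (g1 < m && key[order[g1]] == key[order[g0]]) g1++;
        for (int a = g1 - g0 - 1; a > 0; --a) {
          int b = (int)(unif_rand() * (a + 1));
          if (b > a) b = a;
          std::swap(permuted[order[g0 + a]], permuted[order[g0 + b]]);
        }
        g0 = g1;
      }

      int correct = 0;
      for (int i = 0; i < m; ++i) {
        int c = tree_predict_row(var, split, left, right, pred, X, oob[i],
                                 j, permuted[i]);
        if (c == y[oob[i]]) correct++;
      }
      imp[j] += acc0 - (double)correct / m;
    }
  }
  for (int j = 0; j < p; ++j) imp[j] /= ntree;
  return imp;
}
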