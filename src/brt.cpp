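// Gradient-boosted regression trees: squared-error loss, observation
// weights, bagging, best-first tree growth, missing values routed by a
// learned default direction at each split, per-split improvement
// accounting, and interleaved k-fold cross-validation with early stopping.
//
// Determinism: all randomness comes from a self-contained xorshift-based
// generator seeded from R, so identical seeds give identical models on any
// platform; std::mt19937 distributions are avoided because their mapping to
// bounded integers is implementation-defined.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeded xorshift64*, with Lemire-style bounded draw.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    // splitmix64 scrambling so small consecutive seeds give unrelated streams
    s = seed + 0x9E3779B97F4A7C15ULL;
    s = (s ^ (s >> 30)) * 0xBF58476D1CE4E5B9ULL;
    s = (s ^ (s >> 27)) * 0x94D049BB133111EBULL;
    s = s ^ (s >> 31);
    if (s == 0) s = 0x1ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int below(int n) {
    return (int)(((__uint128_t)next() * (__uint128_t)n) >> 64);
  }
};

// ---------------------------------------------------------------------------
// Flat tree representation. Node 0 is the root; leaves have var == -1.
struct Tree {
  std::vector<int> var, left, right, miss_right;
  std::vector<double> split, value;
  int add_leaf() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    miss_right.push_back(0); split.push_back(0.0); value.push_back(0.0);
    return (int)var.size() - 1;
  }
  int route(const double *xrow, int n, int p) const {
    (void)p;
    int node = 0;
    while (var[node] >= 0) {
      double x = xrow[(size_t)var[node] * n];
      bool go_right;
      if (ISNAN(x)) go_right = miss_right[node] != 0;
      else go_right = x > split[node];
      node = go_right ? right[node] : left[node];
    }
    return node;
  }
};

// Per-leaf working data during growth.
struct LeafWork {
  int node;                              // node index in the tree
  std::vector<std::vector<int> > order;  // per var: in-leaf rows sorted by x
  std::vector<int> rows;                 // all in-leaf rows
  double sum_z, sum_w;                   // weighted residual sums over rows
  int n_rows;
  // cached best split
  bool has_split;
  int best_var, miss_dir;
  double best_gain, best_cut;
};

struct SplitScan {
  double gain, cut;
  int miss_dir;  // 0 = left, 1 = right
  bool found;
};

static SplitScan scan_var(const std::vector<int> &ord, const double *xcol,
                          const double *z, const double *w,
                          double sum_z, double sum_w, int n_rows,
                          double min_node) {
  SplitScan out; out.found = false; out.gain = 0.0; out.cut = 0.0; out.miss_dir = 0;
  int n_obs = (int)ord.size();
  if (n_obs < 2) return out;
  // sums over rows with observed x for this var
  double s_obs = 0.0, w_obs = 0.0;
  for (int k = 0; k < n_obs; ++k) { s_obs += w[ord[k]] * z[ord[k]]; w_obs += w[ord[k]]; }
  double s_mis = sum_z - s_obs, w_mis = sum_w - w_obs;
  int n_mis = n_rows - n_obs;
  double parent = (sum_w > 0.0) ? sum_z * sum_z / sum_w : 0.0;
  double sl = 0.0, wl = 0.0;
  for (int k = 0; k < n_obs - 1; ++k) {
    int i = ord[k];
    sl += w[i] * z[i]; wl += w[i];
    double x0 = xcol[i], x1 = xcol[ord[k + 1]];
    if (x1 <= x0) continue;                 // not a boundary between values
    double sr = s_obs - sl, wr = w_obs - wl;
    // place the missing group on each side; keep the better direction
    for (int dir = 0; dir < 2; ++dir) {
      double SL = sl, WL = wl, SR = sr, WR = wr;
      if (n_mis > 0) {
        if (dir == 0) { SL += s_mis; WL += w_mis; }
        else          { SR += s_mis; WR += w_mis; }
      } else if (dir == 1) break;           // no missing rows: dirs identical
      // node size measured in weight so that duplicating an observation
      // and doubling its weight are exactly equivalent
      if (WL < min_node || WR < min_node) continue;
      if (WL <= 0.0 || WR <= 0.0) continue;
      double gain = SL * SL / WL + SR * SR / WR - parent;
      if (gain > 0.0 && (!out.found || gain > out.gain + 1e-12)) {
        out.found = true; out.gain = gain;
        out.cut = (x0 + x1) / 2.0; out.miss_dir = dir;
      }
    }
  }
  return out;
}

static void find_best_split(LeafWork &lw, const double *X, int n, int p,
                            const double *z, const double *w, double min_node) {
  lw.has_split = false; lw.best_gain = 0.0;
  if (lw.sum_w < 2 * min_node) return;
  for (int j = 0; j < p; ++j) {
    SplitScan sc = scan_var(lw.order[j], X + (size_t)j * n, z, w,
                            lw.sum_z, lw.sum_w, lw.n_rows, min_node);
    if (sc.found && (!lw.has_split || sc.gain > lw.best_gain + 1e-12)) {
      lw.has_split = true;
      lw.best_gain = sc.gain; lw.best_var = j;
      lw.best_cut = sc.cut; lw.miss_dir = sc.miss_dir;
    }
  }
}

// Grow one regression tree on the bagged rows against residuals z.
// `imp` (length p) accumulates the weighted SSE improvement per variable.
static Tree grow_tree(const double *X, int n, int p,
                      const double *z, const double *w,
                      std::vector<int> bag,
                      std::vector<std::vector<int> > bag_order,
                      int depth, double min_node, double *imp) {
  Tree tr;
  tr.var.reserve(2 * depth + 1); tr.left.reserve(2 * depth + 1);
  tr.right.reserve(2 * depth + 1); tr.miss_right.reserve(2 * depth + 1);
  tr.split.reserve(2 * depth + 1); tr.value.reserve(2 * depth + 1);
  LeafWork root;
  root.node = tr.add_leaf();
  root.rows = std::move(bag);
  root.order = std::move(bag_order);
  root.sum_z = 0.0; root.sum_w = 0.0; root.n_rows = (int)root.rows.size();
  for (size_t k = 0; k < root.rows.size(); ++k) {
    root.sum_z += w[root.rows[k]] * z[root.rows[k]];
    root.sum_w += w[root.rows[k]];
  }
  find_best_split(root, X, n, p, z, w, min_node);

  std::vector<LeafWork> leaves;
  leaves.push_back(std::move(root));

  for (int s = 0; s < depth; ++s) {
    int pick = -1; double best = 0.0;
    for (size_t l = 0; l < leaves.size(); ++l)
      if (leaves[l].has_split && (pick < 0 || leaves[l].best_gain > best + 1e-12)) {
        pick = (int)l; best = leaves[l].best_gain;
      }
    if (pick < 0) break;
    LeafWork lw = std::move(leaves[pick]);
    leaves.erase(leaves.begin() + pick);

    int jv = lw.best_var;
    double cut = lw.best_cut;
    int mdir = lw.miss_dir;
    const double *xcol = X + (size_t)jv * n;
    imp[jv] += lw.best_gain;

    LeafWork L, R;
    L.node = tr.add_leaf(); R.node = tr.add_leaf();
    tr.var[lw.node] = jv; tr.split[lw.node] = cut;
    tr.miss_right[lw.node] = mdir;
    tr.left[lw.node] = L.node; tr.right[lw.node] = R.node;

    L.sum_z = L.sum_w = R.sum_z = R.sum_w = 0.0;
    L.rows.reserve(lw.rows.size()); R.rows.reserve(lw.rows.size());
    for (size_t k = 0; k < lw.rows.size(); ++k) {
      int i = lw.rows[k];
      double x = xcol[i];
      bool go_right = ISNAN(x) ? (mdir != 0) : (x > cut);
      (go_right ? R : L).rows.push_back(i);
      if (go_right) { R.sum_z += w[i] * z[i]; R.sum_w += w[i]; }
      else          { L.sum_z += w[i] * z[i]; L.sum_w += w[i]; }
    }
    L.n_rows = (int)L.rows.size(); R.n_rows = (int)R.rows.size();
    L.order.resize(p); R.order.resize(p);
    for (int j = 0; j < p; ++j) {
      L.order[j].reserve(L.rows.size()); R.order[j].reserve(R.rows.size());
    }
    for (int j = 0; j < p; ++j) {     // stable partition keeps sort order
      const std::vector<int> &po = lw.order[j];
      for (size_t k = 0; k < po.size(); ++k) {
        int i = po[k];
        double x = xcol[i];
        bool go_right = ISNAN(x) ? (mdir != 0) : (x > cut);
        (go_right ? R.order[j] : L.order[j]).push_back(i);
      }
    }
    find_best_split(L, X, n, p, z, w, min_node);
    find_best_split(R, X, n, p, z, w, min_node);
    leaves.push_back(std::move(L));
    leaves.push_back(std::move(R));
  }
  // terminal predictions: weighted mean residual
  for (size_t l = 0; l < leaves.size(); ++l) {
    const LeafWork &lw = leaves[l];
    tr.value[lw.node] = (lw.sum_w > 0.0) ? lw.sum_z / lw.sum_w : 0.0;
  }
  return tr;
}

// Draw floor(bag_fraction * n_train) distinct training rows.
static std::vector<int> draw_bag(const std::vector<int> &train, double bag_fraction,
                                 Rng &rng) {
  int nt = (int)train.size();
  int nb = (int)std::floor(bag_fraction * nt);
  if (nb < 1) nb = 1;
  if (nb >= nt) return train;
  std::vector<int> pool = train;
  for (int k = 0; k < nb; ++k) {          // partial Fisher-Yates
    int j = k + rng.below(nt - k);
    std::swap(pool[k], pool[j]);
  }
  pool.resize(nb);
  std::sort(pool.begin(), pool.end());
  return pool;
}

static std::vector<std::vector<int> > order_for_bag(
    const std::vector<std::vector<int> > &global_order,
    const std::vector<char> &in_bag, int p) {
  std::vector<std::vector<int> > out(p);
  for (int j = 0; j < p; ++j) {
    out[j].reserve(global_order[j].size());
    for (size_t k = 0; k < global_order[j].size(); ++k)
      if (in_bag[global_order[j][k]]) out[j].push_back(global_order[j][k]);
  }
  return out;
}

// Presort rows by each variable (missing excluded). Ties broken by row index.
static std::vector<std::vector<int> > presort(const double *X, int n, int p) {
  std::vector<std::vector<int> > ord(p);
  for (int j = 0; j < p; ++j) {
    const double *xcol = X + (size_t)j * n;
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) if (!ISNAN(xcol[i])) idx.push_back(i);
    std::stable_sort(idx.begin(), idx.end(),
                     [xcol](int a, int b) { return xcol[a] < xcol[b]; });
    ord[j] = std::move(idx);
  }
  return ord;
}

// One boosting run over a fixed training subset; predictions maintained for
// all rows so held-out error can be tracked by the caller.
struct Booster {
  const double *X; int n, p;
  const double *y, *w;
  std::vector<int> train;
  std::vector<std::vector<int> > train_order;
  int depth; double min_node;
  double lr, bag_fraction, init;
  Rng rng;
  std::vector<double> F;

  Booster(const double *X_, int n_, int p_, const double *y_, const double *w_,
          const std::vector<int> &train_, int depth_, double lr_,
          double bag_fraction_, double min_node_, uint64_t seed)
      : X(X_), n(n_), p(p_), y(y_), w(w_), train(train_), depth(depth_),
        min_node(min_node_), lr(lr_), bag_fraction(bag_fraction_), rng(seed) {
    double sy = 0.0, sw = 0.0;
    for (size_t k = 0; k < train.size(); ++k) {
      sy += w[train[k]] * y[train[k]]; sw += w[train[k]];
    }
    init = (sw > 0.0) ? sy / sw : 0.0;
    F.assign(n, init);
    std::vector<char> in_train(n, 0);
    for (size_t k = 0; k < train.size(); ++k) in_train[train[k]] = 1;
    std::vector<std::vector<int> > g = presort(X, n, p);
    train_order = order_for_bag(g, in_train, p);
  }

  std::vector<double> z_buf;
  std::vector<char> in_bag_buf;

  Tree step(double *imp) {
    std::vector<int> bag;
    std::vector<std::vector<int> > bag_order;
    if (bag_fraction >= 1.0) {
      bag = train; bag_order = train_order;
    } else {
      bag = draw_bag(train, bag_fraction, rng);
      in_bag_buf.assign(n, 0);
      for (size_t k = 0; k < bag.size(); ++k) in_bag_buf[bag[k]] = 1;
      bag_order = order_for_bag(train_order, in_bag_buf, p);
    }
    z_buf.resize(n);
    for (int i = 0; i < n; ++i) z_buf[i] = y[i] - F[i];
    Tree tr = grow_tree(X, n, p, z_buf.data(), w, std::move(bag),
                        std::move(bag_order), depth, min_node, imp);
    for (int i = 0; i < n; ++i)
      F[i] += lr * tr.value[tr.route(X + i, n, p)];
    return tr;
  }
};

// [[Rcpp::export]]
List brt_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int depth, double learning_rate, int n_trees,
                 double bag_fraction, double min_node, double seed) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> train(n);
  for (int i = 0; i < n; ++i) train[i] = i;
  Booster bo(REAL(X), n, p, REAL(y), REAL(w), train, depth, learning_rate,
             bag_fraction, min_node, (uint64_t)seed);
  NumericMatrix imp(n_trees, p);
  std::vector<int> tvar, tleft, tright, tmiss, toffset;
  std::vector<double> tsplit, tvalue;
  toffset.push_back(0);
  std::vector<double> step_imp(p);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(step_imp.begin(), step_imp.end(), 0.0);
    Tree tr = bo.step(step_imp.data());
    for (int j = 0; j < p; ++j) imp(t, j) = step_imp[j];
    tvar.insert(tvar.end(), tr.var.begin(), tr.var.end());
    tleft.insert(tleft.end(), tr.left.begin(), tr.left.end());
    tright.insert(tright.end(), tr.right.begin(), tr.right.end());
    tmiss.insert(tmiss.end(), tr.miss_right.begin(), tr.miss_right.end());
    tsplit.insert(tsplit.end(), tr.split.begin(), tr.split.end());
    tvalue.insert(tvalue.end(), tr.value.begin(), tr.value.end());
    toffset.push_back((int)tvar.size());
  }
  return List::create(
      _["init"] = bo.init, _["n_trees"] = n_trees,
      _["learning_rate"] = learning_rate,
      _["node_var"] = wrap(tvar), _["node_left"] = wrap(tleft),
      _["node_right"] = wrap(tright), _["node_miss_right"] = wrap(tmiss),
      _["node_split"] = wrap(tsplit), _["node_value"] = wrap(tvalue),
      _["tree_offset"] = wrap(toffset), _["improvement"] = imp,
      _["train_fitted"] = wrap(bo.F));
}

// [[Rcpp::export]]
NumericVector brt_predict_cpp(List fit, NumericMatrix X, int n_trees) {
  int n = X.nrow(), p = X.ncol();
  IntegerVector var = fit["node_var"], left = fit["node_left"],
                right = fit["node_right"], miss = fit["node_miss_right"],
                off = fit["tree_offset"];
  NumericVector split = fit["node_split"], value = fit["node_value"];
  double init = fit["init"], lr = fit["learning_rate"];
  int total = fit["n_trees"];
  if (n_trees > total) n_trees = total;
  NumericVector out(n, init);
  const double *Xp = REAL(X);
  for (int t = 0; t < n_trees; ++t) {
    int base = off[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (var[base + node] >= 0) {
        double x = Xp[(size_t)var[base + node] * n + i];
        bool go_right = ISNAN(x) ? (miss[base + node] != 0)
                                 : (x > split[base + node]);
        node = go_right ? right[base + node] : left[base + node];
      }
      out[i] += lr * value[base + node];
    }
  }
  return out;
}

// Interleaved k-fold cross-validation: one tree per fold per iteration,
// mean held-out squared error tracked each iteration, early stop when no
// improvement for `patience` iterations.
// [[Rcpp::export]]
List brt_cv_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                IntegerVector fold, int n_folds,
                int depth, double learning_rate, int max_trees,
                double bag_fraction, double min_node, double seed,
                int patience, int min_iter) {
  int n = X.nrow(), p = X.ncol();
  std::vector<Booster *> boosters;
  std::vector<std::vector<int> > heldout(n_folds);
  for (int f = 0; f < n_folds; ++f) {
    std::vector<int> train;
    for (int i = 0; i < n; ++i) {
      if (fold[i] == f + 1) heldout[f].push_back(i);
      else train.push_back(i);
    }
    boosters.push_back(new Booster(REAL(X), n, p, REAL(y), REAL(w), train,
                                   depth, learning_rate, bag_fraction,
                                   min_node, (uint64_t)seed + 7919ULL * (f + 1)));
  }
  const double *yv = REAL(y), *wv = REAL(w);
  std::vector<double> cv_err;
  cv_err.reserve(1024);
  int best_iter = 0; double best_err = R_PosInf;
  std::vector<double> imp(p);
  for (int t = 1; t <= max_trees; ++t) {
    double sse = 0.0, sw = 0.0;
    for (int f = 0; f < n_folds; ++f) {
      boosters[f]->step(imp.data());
      for (size_t k = 0; k < heldout[f].size(); ++k) {
        int i = heldout[f][k];
        double d = yv[i] - boosters[f]->F[i];
        sse += wv[i] * d * d; sw += wv[i];
      }
    }
    double err = (sw > 0.0) ? sse / sw : R_PosInf;
    cv_err.push_back(err);
    if (err < best_err - 1e-12) { best_err = err; best_iter = t; }
    if (patience > 0 && t - best_iter >= patience && t >= min_iter) break;
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (size_t f = 0; f < boosters.size(); ++f) delete boosters[f];
  return List::create(_["cv_error"] = wrap(cv_err),
                      _["best_iter"] = best_iter,
                      _["best_error"] = best_err);
}

// O(n^2) concordant/discordant pair counting for Kendall tau-b, with tie
// counts needed by the variance formula. Small n (<= years) so quadratic
// cost is irrelevant; the win is calling this once per subdivision from C.
// [[Rcpp::export]]
List kendall_counts_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  long long C = 0, D = 0, TX = 0, TY = 0, TXY = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx == 0 && dy == 0) ++TXY;
      else if (dx == 0) ++TX;
      else if (dy == 0) ++TY;
      else if ((dx > 0) == (dy > 0)) ++C;
      else ++D;
    }
  return List::create(_["C"] = (double)C, _["D"] = (double)D,
                      _["tx"] = (double)TX, _["ty"] = (double)TY,
                      _["txy"] = (double)TXY);
}
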