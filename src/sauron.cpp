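// Core tree growth and traversal for the simultaneous
// regression/classification random forest (SAURON-RF).
//
// Trees are grown greedily on bootstrap samples of size N.  The split
// criterion is the improvement in *weighted* MSE, where the per-sample
// weights are the class-imbalance weights w* supplied from R; the same
// weights define the normalized leaf weights used for leaf averages.
// Each leaf additionally stores the mode of the discrete class labels of
// its bootstrap members, which is what makes every tree (and hence the
// forest, by plurality vote) a classifier as well as a regressor.
//
// All randomness comes from per-tree std::mt19937 streams seeded from R,
// so fits are bit-reproducible across platforms for a fixed seed.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

// draw from [0, n) without std::uniform_int_distribution (whose output is
// implementation-defined); modulo bias is irrelevant at these sizes
inline int draw_below(std::mt19937 &rng, int n) {
  return static_cast<int>(rng() % static_cast<uint32_t>(n));
}

struct NodeJob {
  int node_id;
  std::vector<int> obs;  // positions into the bootstrap index vector
};

}  // namespace

// Grow one tree; returns the flat node arrays plus per-leaf aggregates.
static List grow_tree(const NumericMatrix &X, const NumericVector &y,
                      const NumericVector &wstar, const IntegerVector &didx,
                      int k, int mtry, int min_leaf, uint32_t seed) {
  const int N = X.nrow(), P = X.ncol();
  std::mt19937 rng(seed);

  std::vector<int> boot(N);
  for (int i = 0; i < N; ++i) boot[i] = draw_below(rng, N);

  std::vector<int> split_var, left, right;
  std::vector<double> split_val;
  std::vector<int> leaf_of_obs(N, -1);

  std::vector<int> feat_pool(P);
  for (int f = 0; f < P; ++f) feat_pool[f] = f;

  std::vector<NodeJob> stack;
  {
    NodeJob root;
    root.node_id = 0;
    root.obs.resize(N);
    for (int i = 0; i < N; ++i) root.obs[i] = i;
    split_var.push_back(-1);
    split_val.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    stack.push_back(std::move(root));
  }

  std::vector<std::pair<double, int> > xs;  // (feature value, obs position)

  while (!stack.empty()) {
    NodeJob job = std::move(stack.back());
    stack.pop_back();
    const int n = static_cast<int>(job.obs.size());

    double ymin = R_PosInf, ymax = R_NegInf;
    for (int j = 0; j < n; ++j) {
      const double yy = y[boot[job.obs[j]]];
      if (yy < ymin) ymin = yy;
      if (yy > ymax) ymax = yy;
    }
    bool make_leaf = (n < 2 * min_leaf) || (ymax - ymin < 1e-12);

    int best_f = -1, best_cut = -1;
    double best_score = R_NegInf, best_point = 0.0;

    if (!make_leaf) {
      // sample mtry features without replacement (partial Fisher-Yates)
      for (int j = 0; j < mtry; ++j) {
        const int pick = j + draw_below(rng, P - j);
        std::swap(feat_pool[j], feat_pool[pick]);
      }
      for (int fj = 0; fj < mtry; ++fj) {
        const int f = feat_pool[fj];
        xs.clear();
        for (int j = 0; j < n; ++j)
          xs.push_back(std::make_pair(X(boot[job.obs[j]], f), job.obs[j]));
        std::sort(xs.begin(), xs.end());
        // prefix scan of weighted sums; score maximizes
        // sum_L(wy)^2/sum_L(w) + sum_R(wy)^2/sum_R(w)
        double tw = 0.0, twy = 0.0;
        for (int j = 0; j < n; ++j) {
          const int id = boot[xs[j].second];
          tw += wstar[id];
          twy += wstar[id] * y[id];
        }
        double lw = 0.0, lwy = 0.0;
        for (int j = 0; j < n - 1; ++j) {
          const int id = boot[xs[j].second];
          lw += wstar[id];
          lwy += wstar[id] * y[id];
          if (j + 1 < min_leaf || n - (j + 1) < min_leaf) continue;
          if (xs[j + 1].first <= xs[j].first) continue;  // not a cut point
          const double rw = tw - lw, rwy = twy - lwy;
          if (lw <= 0.0 || rw <= 0.0) continue;
          const double score = lwy * lwy / lw + rwy * rwy / rw;
          if (score > best_score) {
            best_score = score;
            best_f = f;
            best_cut = j;
            best_point = 0.5 * (xs[j].first + xs[j + 1].first);
          }
        }
      }
      if (best_f < 0) make_leaf = true;
    }

    if (make_leaf) {
      for (int j = 0; j < n; ++j) leaf_of_obs[job.obs[j]] = job.node_id;
      continue;
    }

    NodeJob lj, rj;
    for (int j = 0; j < n; ++j) {
      if (X(boot[job.obs[j]], best_f) <= best_point)
        lj.obs.push_back(job.obs[j]);
      else
        rj.obs.push_back(job.obs[j]);
    }
    const int lid = static_cast<int>(split_var.size());
    const int rid = lid + 1;
    lj.node_id = lid;
    rj.node_id = rid;
    split_var[job.node_id] = best_f;
    split_val[job.node_id] = best_point;
    left[job.node_id] = lid;
    right[job.node_id] = rid;
    for (int c = 0; c < 2; ++c) {
      split_var.push_back(-1);
      split_val.push_back(0.0);
      left.push_back(-1);
      right.push_back(-1);
    }
    stack.push_back(std::move(rj));
    stack.push_back(std::move(lj));
  }

  // per-leaf aggregates: members keyed by *original* sample id with
  // bootstrap duplicates collapsed, normalized weights, weighted mean,
  // class mode (ties -> lowest class index)
  const int n_nodes = static_cast<int>(split_var.size());
  std::vector<int> leaf_index(n_nodes, -1);
  std::vector<int> leaf_nodes;
  for (int v = 0; v < n_nodes; ++v)
    if (split_var[v] == -1) {
      leaf_index[v] = static_cast<int>(leaf_nodes.size());
      leaf_nodes.push_back(v);
    }
  const int n_leaves = static_cast<int>(leaf_nodes.size());

  std::vector<std::vector<int> > leaf_obs(n_leaves);
  for (int i = 0; i < N; ++i)
    leaf_obs[leaf_index[leaf_of_obs[i]]].push_back(boot[i]);

  std::vector<int> members_flat;
  std::vector<double> w_flat;
  IntegerVector leaf_ptr(n_leaves + 1);
  NumericVector leaf_pred(n_leaves);
  IntegerVector leaf_mode(n_leaves);
  std::vector<int> cnt(N, 0), cls(k);

  for (int l = 0; l < n_leaves; ++l) {
    const std::vector<int> &ids = leaf_obs[l];
    std::fill(cls.begin(), cls.end(), 0);
    double W = 0.0;
    std::vector<int> uniq;
    for (size_t j = 0; j < ids.size(); ++j) {
      const int id = ids[j];
      if (cnt[id] == 0) uniq.push_back(id);
      cnt[id] += 1;
      W += wstar[id];
      cls[didx[id] - 1] += 1;
    }
    std::sort(uniq.begin(), uniq.end());
    double pred = 0.0;
    for (size_t j = 0; j < uniq.size(); ++j) {
      const int id = uniq[j];
      // W == 0 can only occur when every member has zero class-distance
      // weight; fall back to plain bootstrap-count averaging
      const double w = (W > 0.0) ? cnt[id] * wstar[id] / W
                                 : cnt[id] / static_cast<double>(ids.size());
      members_flat.push_back(id);
      w_flat.push_back(w);
      pred += w * y[id];
      cnt[id] = 0;
    }
    leaf_ptr[l + 1] = static_cast<int>(members_flat.size());
    leaf_pred[l] = pred;
    int best_c = 0;
    for (int c = 1; c < k; ++c)
      if (cls[c] > cls[best_c]) best_c = c;
    leaf_mode[l] = best_c + 1;
  }

  IntegerVector node_leaf(n_nodes);
  for (int v = 0; v < n_nodes; ++v) node_leaf[v] = leaf_index[v];

  return List::create(
      _["split_var"] = IntegerVector(split_var.begin(), split_var.end()),
      _["split_val"] = NumericVector(split_val.begin(), split_val.end()),
      _["left"] = IntegerVector(left.begin(), left.end()),
      _["right"] = IntegerVector(right.begin(), right.end()),
      _["node_leaf"] = node_leaf, _["leaf_ptr"] = leaf_ptr,
      _["leaf_members"] = IntegerVector(members_flat.begin(),
                                        members_flat.end()),
      _["leaf_w"] = NumericVector(w_flat.begin(), w_flat.end()),
      _["leaf_pred"] = leaf_pred, _["leaf_mode"] = leaf_mode,
      _["boot_ids"] = IntegerVector(boot.begin(), boot.end()));
}

// [[Rcpp::export(name = ".sauron_grow")]]
List sauron_grow(NumericMatrix X, NumericVector y, NumericVector wstar,
                 IntegerVector didx, int k, int num_trees, int mtry,
                 int min_leaf, NumericVector tree_seeds) {
  List trees(num_trees);
  for (int b = 0; b < num_trees; ++b)
    trees[b] = grow_tree(X, y, wstar, didx, k, mtry, min_leaf,
                         static_cast<uint32_t>(tree_seeds[b]));
  return trees;
}

static inline int drop_down(const IntegerVector &split_var,
                            const NumericVector &split_val,
                            const IntegerVector &left,
                            const IntegerVector &right,
                            const NumericMatrix &Xq, int row) {
  int v = 0;
  while (split_var[v] != -1)
    v = (Xq(row, split_var[v]) <= split_val[v]) ? left[v] : right[v];
  return v;
}

// Forest prediction for a matrix of queries.
//
// Per query: per-tree leaf modes vote; the plurality class (ties -> lowest
// class index) is the point class.  Tree weights are 1/B when the point
// class equals the training modal class, otherwise only agreeing trees get
// weight 1/#agreeing.  The point value is the tree-weighted average of leaf
// means; optionally the forest-wide per-training-sample weights
// w_i(x) = sum_b w_b(x) I(i in leaf_b) w_i^{leaf_b} are accumulated.
// [[Rcpp::export(name = ".sauron_forecast")]]
List sauron_forecast(List trees, NumericMatrix Xq, int k, int modal_class,
                     int n_train, bool want_weights) {
  const int B = trees.size(), nq = Xq.nrow();
  NumericMatrix votes(nq, k);
  IntegerVector point_class(nq);
  NumericVector point_value(nq);
  NumericMatrix Wout = want_weights ? NumericMatrix(nq, n_train)
                                    : NumericMatrix(0, 0);

  // unpack once
  std::vector<IntegerVector> sv(B), lf(B), rt(B), nl(B), lp(B), lm(B), mem(B);
  std::vector<NumericVector> spv(B), lw(B), lpred(B);
  for (int b = 0; b < B; ++b) {
    List t = trees[b];
    sv[b] = t["split_var"];
    spv[b] = t["split_val"];
    lf[b] = t["left"];
    rt[b] = t["right"];
    nl[b] = t["node_leaf"];
    lp[b] = t["leaf_ptr"];
    mem[b] = t["leaf_members"];
    lw[b] = t["leaf_w"];
    lpred[b] = t["leaf_pred"];
    lm[b] = t["leaf_mode"];
  }

  std::vector<int> leaf_hit(B), cls(k);
  for (int q = 0; q < nq; ++q) {
    std::fill(cls.begin(), cls.end(), 0);
    for (int b = 0; b < B; ++b) {
      const int node = drop_down(sv[b], spv[b], lf[b], rt[b], Xq, q);
      const int l = nl[b][node];
      leaf_hit[b] = l;
      cls[lm[b][l] - 1] += 1;
    }
    int pc = 0;
    for (int c = 0; c < k; ++c) {
      votes(q, c) = cls[c] / static_cast<double>(B);
      if (cls[c] > cls[pc]) pc = c;
    }
    point_class[q] = pc + 1;

    int n_agree = 0;
    if (pc + 1 != modal_class)
      for (int b = 0; b < B; ++b)
        if (lm[b][leaf_hit[b]] == pc + 1) ++n_agree;

    double val = 0.0;
    for (int b = 0; b < B; ++b) {
      double wb;
      if (pc + 1 == modal_class)
        wb = 1.0 / B;
      else
        wb = (lm[b][leaf_hit[b]] == pc + 1) ? 1.0 / n_agree : 0.0;
      if (wb == 0.0) continue;
      const int l = leaf_hit[b];
      val += wb * lpred[b][l];
      if (want_weights)
        for (int j = lp[b][l]; j < lp[b][l + 1]; ++j)
          Wout(q, mem[b][j]) += wb * lw[b][j];
    }
    point_value[q] = val;
  }

  List out = List::create(_["votes"] = votes, _["point_class"] = point_class,
                          _["point_value"] = point_value);
  if (want_weights) out.push_back(Wout, "weights");
  return out;
}
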