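// Sum-of-trees (BART) MCMC: Bayesian backfitting with grow/prune/change
// proposals, conjugate normal leaf prior N(0, sigma_mu^2), and a scaled
// inverse-chi-square error variance.  The response is expected centered and
// scaled to [-0.5, 0.5] by the R wrapper; all split values are observed
// predictor values, with the strict "< goes left, >= goes right" rule.
//
// Split rules are proposed by drawing a variable uniformly among those with
// at least two distinct values at the node and a split value uniformly among
// that variable's distinct node values excluding the minimum, so both
// children are always non-empty.  The same distribution defines the rule
// prior, so rule probabilities cancel from every Metropolis-Hastings ratio.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> left, right, var, depth, parent;
  std::vector<char> active;
  std::vector<double> split, leafval;
  std::vector<int> free_idx;

  void init() {
    left.assign(1, -1); right.assign(1, -1); var.assign(1, -1);
    depth.assign(1, 0); parent.assign(1, -1); active.assign(1, 1);
    split.assign(1, 0.0); leafval.assign(1, 0.0);
    free_idx.clear();
  }
  int new_node() {
    if (!free_idx.empty()) {
      int k = free_idx.back(); free_idx.pop_back();
      active[k] = 1; left[k] = -1; right[k] = -1; var[k] = -1;
      return k;
    }
    left.push_back(-1); right.push_back(-1); var.push_back(-1);
    depth.push_back(0); parent.push_back(-1); active.push_back(1);
    split.push_back(0.0); leafval.push_back(0.0);
    return (int)left.size() - 1;
  }
  void drop(int k) { active[k] = 0; left[k] = -1; right[k] = -1;
                     var[k] = -1; free_idx.push_back(k); }
  bool is_leaf(int k) const { return left[k] < 0; }
  bool is_nog(int k) const {
    return !is_leaf(k) && is_leaf(left[k]) && is_leaf(right[k]);
  }
  int n_alloc() const { return (int)left.size(); }
  void leaves(std::vector<int>& out) const {
    out.clear();
    for (int k = 0; k < n_alloc(); ++k)
      if (active[k] && is_leaf(k)) out.push_back(k);
  }
  void nogs(std::vector<int>& out) const {
    out.clear();
    for (int k = 0; k < n_alloc(); ++k)
      if (active[k] && is_nog(k)) out.push_back(k);
  }
};

// log marginal likelihood contribution of one leaf (constant terms that
// cancel across trees with identical membership unions are omitted)
inline double lml(double nn, double S, double s2, double smu2) {
  double denom = s2 + nn * smu2;
  return 0.5 * std::log(s2 / denom) + smu2 * S * S / (2.0 * s2 * denom);
}

inline double psplit(int d, double a, double b) {
  return a * std::pow(1.0 + d, -b);
}

inline int pick(int k) {  // uniform in 0..k-1, consumes one uniform
  int j = (int)(unif_rand() * k);
  return j >= k ? k - 1 : j;
}

// serialize subtree in preorder; returns the node's row index
int serialize_node(const Tree& tr, int node, int tree_id,
                   std::vector<double>& rows) {
  int my = (int)(rows.size() / 6);
  rows.push_back((double)tree_id);
  rows.push_back(tr.is_leaf(node) ? -1.0 : (double)tr.var[node]);
  rows.push_back(tr.split[node]);
  rows.push_back(tr.leafval[node]);
  rows.push_back(-1.0); rows.push_back(-1.0);
  if (!tr.is_leaf(node)) {
    int l = serialize_node(tr, tr.left[node], tree_id, rows);
    int r = serialize_node(tr, tr.right[node], tree_id, rows);
    rows[(size_t)my * 6 + 4] = (double)l;
    rows[(size_t)my * 6 + 5] = (double)r;
  }
  return my;
}

// single-row prediction of one serialized tree (matrix rows x 6)
inline double tree_pred_row(const NumericMatrix& tm, int root,
                            const NumericMatrix& X, int i,
                            int override_var, double override_val) {
  int node = root;
  for (;;) {
    int v = (int)tm(node, 1);
    if (v < 0) return tm(node, 3);
    double xv = (v == override_var) ? override_val : X(i, v);
    node = (xv < tm(node, 2)) ? (int)tm(node, 4) : (int)tm(node, 5);
  }
}

// root row indices of each tree within a serialized draw
std::vector<int> tree_roots(const NumericMatrix& tm, int m) {
  std::vector<int> roots;
  roots.reserve(m);
  int prev = -1;
  for (int r = 0; r < tm.nrow(); ++r) {
    int tid = (int)tm(r, 0);
    if (tid != prev) { roots.push_back(r); prev = tid; }
  }
  return roots;
}

}  // namespace

// [[Rcpp::export(name = ".bart_mcmc")]]
List bart_mcmc(NumericMatrix X, NumericVector z, int m, int n_burn,
               int n_post, double sigma_mu, double nu, double lambda,
               double alpha, double beta, double p_grow, double p_prune,
               double sigma2_init) {
  const int n = X.nrow(), p = X.ncol();
  const double smu2 = sigma_mu * sigma_mu;

  std::vector<Tree> trees(m);
  std::vector<std::vector<int> > leaf_of(m, std::vector<int>(n, 0));
  for (int t = 0; t < m; ++t) trees[t].init();

  std::vector<double> treefit((size_t)m * n, 0.0), fullfit(n, 0.0), r(n);
  double s2 = sigma2_init;

  List out_trees(n_post);
  NumericVector out_sigma2(n_post);
  NumericMatrix out_fit(n_post, n);

  std::vector<int> members, leaves_v, nogs_v, elig;
  std::vector<double> vals;
  std::vector<double> Svec;
  std::vector<int> cnt;

  for (int iter = 0; iter < n_burn + n_post; ++iter) {
    for (int t = 0; t < m; ++t) {
      Tree& tr = trees[t];
      std::vector<int>& lo = leaf_of[t];
      double* tf = &treefit[(size_t)t * n];
      for (int i = 0; i < n; ++i) r[i] = z[i] - fullfit[i] + tf[i];

      double u = unif_rand();
      if (u < p_grow) {
        // ---- GROW ----
        tr.leaves(leaves_v);
        int b = (int)leaves_v.size();
        int L = leaves_v[pick(b)];
        members.clear();
        for (int i = 0; i < n; ++i) if (lo[i] == L) members.push_back(i);
        // eligible variables: >= 2 distinct values at the node
        elig.clear();
        for (int j = 0; j < p; ++j) {
          double mn = X(members[0], j), mx = mn;
          for (size_t k = 1; k < members.size(); ++k) {
            double v = X(members[k], j);
            if (v < mn) mn = v; else if (v > mx) mx = v;
          }
          if (mx > mn) elig.push_back(j);
        }
        if (!elig.empty()) {
          int j = elig[pick((int)elig.size())];
          vals.clear();
          for (size_t k = 0; k < members.size(); ++k)
            vals.push_back(X(members[k], j));
          std::sort(vals.begin(), vals.end());
          vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
          double c = vals[1 + pick((int)vals.size() - 1)];
          double SL = 0, SR = 0; int nL = 0, nR = 0;
          for (size_t k = 0; k < members.size(); ++k) {
            int i = members[k];
            if (X(i, j) < c) { SL += r[i]; ++nL; } else { SR += r[i]; ++nR; }
          }
          int d = tr.depth[L];
          int P = tr.parent[L];
          int w2 = 0;
          tr.nogs(nogs_v); w2 = (int)nogs_v.size();
          int w2_new = w2 + 1 - ((P >= 0 && tr.is_nog(P)) ? 1 : 0);
          double pd = psplit(d, alpha, beta);
          double pd1 = psplit(d + 1, alpha, beta);
          double logalpha =
            std::log(p_prune / p_grow) + std::log((double)b) -
            std::log((double)w2_new) +
            std::log(pd) + 2.0 * std::log(1.0 - pd1) - std::log(1.0 - pd) +
            lml(nL, SL, s2, smu2) + lml(nR, SR, s2, smu2) -
            lml(nL + nR, SL + SR, s2, smu2);
          if (std::log(unif_rand()) < logalpha) {
            int cl = tr.new_node(), cr = tr.new_node();
            tr.left[L] = cl; tr.right[L] = cr;
            tr.var[L] = j; tr.split[L] = c;
            tr.parent[cl] = L; tr.parent[cr] = L;
            tr.depth[cl] = d + 1; tr.depth[cr] = d + 1;
            for (size_t k = 0; k < members.size(); ++k) {
              int i = members[k];
              lo[i] = (X(i, j) < c) ? cl : cr;
            }
          }
        }
      } else if (u < p_grow + p_prune) {
        // ---- PRUNE ----
        tr.nogs(nogs_v);
        int w2 = (int)nogs_v.size();
        if (w2 > 0) {
          int P = nogs_v[pick(w2)];
          int cl = tr.left[P], cr = tr.right[P];
          double SL = 0, SR = 0; int nL = 0, nR = 0;
          for (int i = 0; i < n; ++i) {
            if (lo[i] == cl) { SL += r[i]; ++nL; }
            else if (lo[i] == cr) { SR += r[i]; ++nR; }
          }
          tr.leaves(leaves_v);
          int b = (int)leaves_v.size();
          int d = tr.depth[P];
          double pd = psplit(d, alpha, beta);
          double pd1 = psplit(d + 1, alpha, beta);
          double logalpha =
            std::log(p_grow / p_prune) + std::log((double)w2) -
            std::log((double)(b - 1)) -
            (std::log(pd) + 2.0 * std::log(1.0 - pd1) -
             std::log(1.0 - pd)) -
            (lml(nL, SL, s2, smu2) + lml(nR, SR, s2, smu2) -
             lml(nL + nR, SL + SR, s2, smu2));
          if (std::log(unif_rand()) < logalpha) {
            for (int i = 0; i < n; ++i)
              if (lo[i] == cl || lo[i] == cr) lo[i] = P;
            tr.drop(cl); tr.drop(cr);
            tr.left[P] = -1; tr.right[P] = -1; tr.var[P] = -1;
          }
        }
      } else {
        // ---- CHANGE (rule of a no-grandchild node) ----
        tr.nogs(nogs_v);
        if (!nogs_v.empty()) {
          int P = nogs_v[pick((int)nogs_v.size())];
          int cl = tr.left[P], cr = tr.right[P];
          members.clear();
          double SL = 0, SR = 0; int nL = 0, nR = 0;
          for (int i = 0; i < n; ++i) {
            if (lo[i] == cl) { members.push_back(i); SL += r[i]; ++nL; }
            else if (lo[i] == cr) { members.push_back(i); SR += r[i]; ++nR; }
          }
          elig.clear();
          for (int j = 0; j < p; ++j) {
            double mn = X(members[0], j), mx = mn;
            for (size_t k = 1; k < members.size(); ++k) {
              double v = X(members[k], j);
              if (v < mn) mn = v; else if (v > mx) mx = v;
            }
            if (mx > mn) elig.push_back(j);
          }
          if (!elig.empty()) {
            int j = elig[pick((int)elig.size())];
            vals.clear();
            for (size_t k = 0; k < members.size(); ++k)
              vals.push_back(X(members[k], j));
            std::sort(vals.begin(), vals.end());
            vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
            double c = vals[1 + pick((int)vals.size() - 1)];
            double SLn = 0, SRn = 0; int nLn = 0, nRn = 0;
            for (size_t k = 0; k < members.size(); ++k) {
              int i = members[k];
              if (X(i, j) < c) { SLn += r[i]; ++nLn; }
              else { SRn += r[i]; ++nRn; }
            }
            double logalpha =
              lml(nLn, SLn, s2, smu2) + lml(nRn, SRn, s2, smu2) -
              lml(nL, SL, s2, smu2) - lml(nR, SR, s2, smu2);
            if (std::log(unif_rand()) < logalpha) {
              tr.var[P] = j; tr.split[P] = c;
              for (size_t k = 0; k < members.size(); ++k) {
                int i = members[k];
                lo[i] = (X(i, j) < c) ? cl : cr;
              }
            }
          }
        }
      }

      // ---- leaf means from the conjugate posterior ----
      int na = tr.n_alloc();
      Svec.assign(na, 0.0); cnt.assign(na, 0);
      for (int i = 0; i < n; ++i) { Svec[lo[i]] += r[i]; ++cnt[lo[i]]; }
      for (int k = 0; k < na; ++k) {
        if (!tr.active[k] || !tr.is_leaf(k)) continue;
        double denom = s2 + cnt[k] * smu2;
        double mean = (cnt[k] > 0) ? smu2 * Svec[k] / denom : 0.0;
        double var = (cnt[k] > 0) ? s2 * smu2 / denom : smu2;
        tr.leafval[k] = mean + std::sqrt(var) * norm_rand();
      }
      for (int i = 0; i < n; ++i) {
        double nf = tr.leafval[lo[i]];
        fullfit[i] += nf - tf[i];
        tf[i] = nf;
      }
    }

    // ---- sigma^2 from its scaled inverse-chi-square conditional ----
    double sse = 0;
    for (int i = 0; i < n; ++i) {
      double e = z[i] - fullfit[i];
      sse += e * e;
    }
    s2 = (nu * lambda + sse) / R::rchisq(nu + n);

    if (iter >= n_burn) {
      int d = iter - n_burn;
      std::vector<double> rows;
      for (int t = 0; t < m; ++t) serialize_node(trees[t], 0, t, rows);
      int nr = (int)(rows.size() / 6);
      NumericMatrix tm(nr, 6);
      for (int rr = 0; rr < nr; ++rr)
        for (int cc = 0; cc < 6; ++cc) tm(rr, cc) = rows[(size_t)rr * 6 + cc];
      colnames(tm) = CharacterVector::create("tree", "var", "split", "leaf",
                                             "left", "right");
      out_trees[d] = tm;
      out_sigma2[d] = s2;
      for (int i = 0; i < n; ++i) out_fit(d, i) = fullfit[i];
    }
  }

  return List::create(_["trees"] = out_trees, _["sigma2"] = out_sigma2,
                      _["train_fit"] = out_fit);
}

// [[Rcpp::export(name = ".bart_predict")]]
NumericMatrix bart_predict_cpp(List draws, NumericMatrix X, int m) {
  const int nd = draws.size(), n = X.nrow();
  NumericMatrix out(nd, n);
  for (int d = 0; d < nd; ++d) {
    NumericMatrix tm = draws[d];
    std::vector<int> roots = tree_roots(tm, m);
    for (int i = 0; i < n; ++i) {
      double acc = 0;
      for (size_t t = 0; t < roots.size(); ++t)
        acc += tree_pred_row(tm, roots[t], X, i, -1, 0.0);
      out(d, i) = acc;
    }
  }
  return out;
}

// Partial dependence draws: for each retained draw and evaluation value v,
// the average over all training rows of the draw's prediction with column j
// forced to v (Friedman's estimator, one value per posterior draw).  Trees
// that never split on j contribute a value independent of v, computed once.
// [[Rcpp::export(name = ".bart_pdp")]]
NumericMatrix bart_pdp_cpp(List draws, NumericMatrix X, int j,
                           NumericVector evals, int m) {
  const int nd = draws.size(), n = X.nrow(), ne = evals.size();
  NumericMatrix out(nd, ne);
  for (int d = 0; d < nd; ++d) {
    NumericMatrix tm = draws[d];
    std::vector<int> roots = tree_roots(tm, m);
    for (size_t t = 0; t < roots.size(); ++t) {
      int lo = roots[t];
      int hi = (t + 1 < roots.size()) ? roots[t + 1] : tm.nrow();
      bool uses_j = false;
      for (int rr = lo; rr < hi; ++rr)
        if ((int)tm(rr, 1) == j) { uses_j = true; break; }
      if (!uses_j) {
        double acc = 0;
        for (int i = 0; i < n; ++i)
          acc += tree_pred_row(tm, lo, X, i, -1, 0.0);
        acc /= n;
        for (int e = 0; e < ne; ++e) out(d, e) += acc;
      } else {
        for (int e = 0; e < ne; ++e) {
          double acc = 0;
          for (int i = 0; i < n; ++i)
            acc += tree_pred_row(tm, lo, X, i, j, evals[e]);
          out(d, e) += acc / n;
        }
      }
    }
  }
  return out;
}
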