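// Batch samplers for the Yule and uniform (PDA) null models, plus the
// per-tree summaries needed at Monte Carlo scale (Sackin index, canonical
// shape key). All randomness comes from R's RNG (unif_rand), so set.seed()
// in R fully determines the sample stream.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int unif_int(int n) {
  // uniform draw from 0..n-1 via R's RNG
  int k;
  do {
    k = (int)(n * unif_rand());
  } while (k >= n); // guard against the (theoretical) unif_rand() == 1.0
  return k;
}

// Grow one Yule tree: start from a cherry, repeatedly replace a uniformly
// chosen leaf with a cherry. Nodes are 1-based; parent 0 marks the root.
// Column-per-replicate matrix of parent pointers, 2n-1 nodes per tree.
// [[Rcpp::export]]
IntegerMatrix cpp_yule_parents(int n, int reps) {
  if (n < 2) stop("Yule sampling requires n >= 2");
  int m = 2 * n - 1;
  IntegerMatrix out(m, reps);
  std::vector<int> leaf(n);
  for (int r = 0; r < reps; ++r) {
    int* par = &out(0, r);
    par[0] = 0;       // root
    par[1] = 1; par[2] = 1;
    leaf[0] = 2; leaf[1] = 3; // 1-based ids of current leaves
    int next = 4;     // next unused 1-based id
    for (int j = 2; j < n; ++j) {
      int pick = unif_int(j);
      int v = leaf[pick];
      par[next - 1] = v; par[next] = v; // two children of v
      leaf[pick] = next;
      leaf[j] = next + 1;
      next += 2;
    }
  }
  return out;
}

// Remy-style growth of a uniform leaf-labelled bifurcating tree: at each
// step pick a uniform node v (including the root) and a side; insert a new
// internal node in v's place with v and a fresh leaf as its children.
// Equivalent in distribution to the uniform bracket-sequence construction.
// [[Rcpp::export]]
IntegerMatrix cpp_remy_parents(int n, int reps) {
  if (n < 2) stop("uniform sampling requires n >= 2");
  int m = 2 * n - 1;
  IntegerMatrix out(m, reps);
  for (int r = 0; r < reps; ++r) {
    int* par = &out(0, r);
    par[0] = 0; // single leaf, also the root
    int cnt = 1;
    for (int j = 1; j < n; ++j) {
      int v = unif_int(cnt) + 1;
      int u = cnt + 1, w = cnt + 2; // new internal, new leaf
      par[u - 1] = par[v - 1];
      par[v - 1] = u;
      par[w - 1] = u;
      // side choice: swap which child slot the old subtree occupies; child
      // order is derived from node ids in R, so record it by id order only
      // when needed -- shapes are order-invariant, so a side draw keeps the
      // stream aligned with the textbook algorithm without affecting output.
      (void)unif_rand();
      cnt += 2;
    }
  }
  return out;
}

// Sackin index (sum of leaf depths) for each column of a parent matrix.
// Node ids carry no order guarantee (Remy inserts parents after children),
// so depths are found by walking each leaf up to the root.
// [[Rcpp::export]]
IntegerVector cpp_parent_sackin(IntegerMatrix parents) {
  int m = parents.nrow(), reps = parents.ncol();
  IntegerVector out(reps);
  std::vector<bool> is_leaf(m);
  for (int r = 0; r < reps; ++r) {
    const int* par = &parents(0, r);
    std::fill(is_leaf.begin(), is_leaf.end(), true);
    for (int i = 0; i < m; ++i)
      if (par[i] > 0) is_leaf[par[i] - 1] = false;
    long total = 0;
    for (int i = 0; i < m; ++i) {
      if (!is_leaf[i]) continue;
      int d = 0;
      for (int v = i; par[v] > 0; v = par[v] - 1) ++d;
      total += d;
    }
    out[r] = (int)total;
  }
  return out;
}

// Canonical shape key ("L" / "(k1,k2)" with sorted children) per column.
// [[Rcpp::export]]
CharacterVector cpp_parent_shape_keys(IntegerMatrix parents) {
  int m = parents.nrow(), reps = parents.ncol();
  CharacterVector out(reps);
  std::vector<std::vector<int> > kids(m);
  std::vector<std::string> key(m);
  for (int r = 0; r < reps; ++r) {
    const int* par = &parents(0, r);
    for (int i = 0; i < m; ++i) kids[i].clear();
    int root = -1;
    for (int i = 0; i < m; ++i) {
      if (par[i] > 0) kids[par[i] - 1].push_back(i);
      else root = i;
    }
    // explicit-stack postorder (node ids carry no order guarantee)
    std::vector<std::pair<int, bool> > stack;
    stack.push_back(std::make_pair(root, false));
    while (!stack.empty()) {
      int v = stack.back().first;
      bool done = stack.back().second;
      stack.pop_back();
      if (!done) {
        stack.push_back(std::make_pair(v, true));
        for (size_t c = 0; c < kids[v].size(); ++c)
          stack.push_back(std::make_pair(kids[v][c], false));
      } else if (kids[v].empty()) {
        key[v] = "L";
      } else {
        std::vector<std::string> ck;
        ck.reserve(kids[v].size());
        for (size_t c = 0; c < kids[v].size(); ++c) ck.push_back(key[kids[v][c]]);
        std::sort(ck.begin(), ck.end());
        std::string s = "(";
        for (size_t c = 0; c < ck.size(); ++c) {
          if (c) s += ",";
          s += ck[c];
        }
        s += ")";
        key[v] = s;
      }
    }
    out[r] = key[root];
  }
  return out;
}
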