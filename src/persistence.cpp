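#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Superlevel-set persistence of a vertex-valued 2D field.
//
// Dimension 0: union-find over vertices entered in decreasing value order,
// foreground 8-connectivity, elder rule (survivor = component created earliest
// in the sweep, i.e. larger maximum, ties by row-major index).
//
// Dimension 1 by Alexander duality: holes of the superlevel set (8-connected)
// are the bounded 4-connected components of the complement. They are found by
// a sublevel sweep in increasing value order on the same vertex grid with
// 4-connectivity plus a virtual outer vertex (value -Inf) joined to every
// grid-boundary vertex. A finite dual component born at value b0 that merges
// at value m yields the hole (birth = m, death = b0): the loop closes once
// every pixel of value >= m surrounds the region, and is filled when the
// region's own minimum enters the superlevel set.
//
// Zero-persistence pairs (birth == death) are dropped; the single essential
// 0-dim class gets death = min(field) as its sentinel.

static inline int uf_find(std::vector<int> &parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
  return root;
}

// [[Rcpp::export]]
DataFrame cpp_superlevel_persistence(NumericMatrix f) {
  const int nr = f.nrow(), nc = f.ncol();
  const int n = nr * nc;
  std::vector<double> val(n);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      val[r * nc + c] = f(r, c);
  for (int i = 0; i < n; ++i)
    if (!R_finite(val[i])) stop("filtration field must be finite");

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  std::vector<int> dim_out;
  std::vector<double> birth_out, death_out;
  std::vector<int> bpos_out, dpos_out;
  std::vector<bool> ess_out;

  // ---- dimension 0: decreasing sweep, 8-connectivity ----
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (val[a] != val[b]) return val[a] > val[b];
    return a < b;
  });
  {
    std::vector<int> parent(n), crank(n), bidx(n);
    std::vector<double> bval(n);
    std::vector<char> seen(n, 0);
    const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    int roots[8];
    for (int k = 0; k < n; ++k) {
      const int v = ord[k];
      const int r = v / nc, c = v % nc;
      int nroots = 0;
      for (int j = 0; j < 8; ++j) {
        const int rr = r + dr8[j], cc = c + dc8[j];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int u = rr * nc + cc;
        if (!seen[u]) continue;
        const int root = uf_find(parent, u);
        bool dup = false;
        for (int t = 0; t < nroots; ++t) if (roots[t] == root) { dup = true; break; }
        if (!dup) roots[nroots++] = root;
      }
      seen[v] = 1;
      if (nroots == 0) {
        parent[v] = v; crank[v] = k; bidx[v] = v; bval[v] = val[v];
      } else {
        int surv = roots[0];
        for (int t = 1; t < nroots; ++t)
          if (crank[roots[t]] < crank[surv]) surv = roots[t];
        for (int t = 0; t < nroots; ++t) {
          const int rt = roots[t];
          if (rt == surv) continue;
          if (bval[rt] != val[v]) {
            dim_out.push_back(0);
            birth_out.push_back(bval[rt]);
            death_out.push_back(val[v]);
            bpos_out.push_back(bidx[rt]);
            dpos_out.push_back(v);
            ess_out.push_back(false);
          }
          parent[rt] = surv;
        }
        parent[v] = surv;
      }
    }
    // essential class: the eldest survivor; death sentinel = global minimum
    const int root = uf_find(parent, ord[0]);
    double vmin = val[0]; int imin = 0;
    for (int i = 1; i < n; ++i) if (val[i] < vmin) { vmin = val[i]; imin = i; }
    dim_out.push_back(0);
    birth_out.push_back(bval[root]);
    death_out.push_back(vmin);
    bpos_out.push_back(bidx[root]);
    dpos_out.push_back(imin);
    ess_out.push_back(true);
  }

  // ---- dimension 1: increasing dual sweep, 4-connectivity + outer vertex ----
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (val[a] != val[b]) return val[a] < val[b];
    return a < b;
  });
  {
    const int OUTER = n;
    std::vector<int> parent(n + 1), crank(n + 1), bidx(n + 1);
    std::vector<double> bval(n + 1);
    std::vector<char> seen(n + 1, 0);
    parent[OUTER] = OUTER; crank[OUTER] = -1; bidx[OUTER] = -1;
    bval[OUTER] = R_NegInf; seen[OUTER] = 1;
    const int dr4[4] = {-1, 0, 0, 1};
    const int dc4[4] = {0, -1, 1, 0};
    int roots[5];
    for (int k = 0; k < n; ++k) {
      const int v = ord[k];
      const int r = v / nc, c = v % nc;
      int nroots = 0;
      for (int j = 0; j < 4; ++j) {
        const int rr = r + dr4[j], cc = c + dc4[j];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int u = rr * nc + cc;
        if (!seen[u]) continue;
        const int root = uf_find(parent, u);
        bool dup = false;
        for (int t = 0; t < nroots; ++t) if (roots[t] == root) { dup = true; break; }
        if (!dup) roots[nroots++] = root;
      }
      if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) {
        const int root = uf_find(parent, OUTER);
        bool dup = false;
        for (int t = 0; t < nroots; ++t) if (roots[t] == root) { dup = true; break; }
        if (!dup) roots[nroots++] = root;
      }
      seen[v] = 1;
      if (nroots == 0) {
        parent[v] = v; crank[v] = k; bidx[v] = v; bval[v] = val[v];
      } else {
        int surv = roots[0];
        for (int t = 1; t < nroots; ++t)
          if (crank[roots[t]] < crank[surv]) surv = roots[t];
        for (int t = 0; t < nroots; ++t) {
          const int rt = roots[t];
          if (rt == surv) continue;
          if (val[v] != bval[rt]) {
            dim_out.push_back(1);
            birth_out.push_back(val[v]);   // loop closes here
            death_out.push_back(bval[rt]); // filled at the region minimum
            bpos_out.push_back(v);
            dpos_out.push_back(bidx[rt]);
            ess_out.push_back(false);
          }
          parent[rt] = surv;
        }
        parent[v] = surv;
      }
    }
  }

  const int m = (int)dim_out.size();
  IntegerVector dim(m), br(m), bc(m), dr(m), dc(m);
  NumericVector birth(m), death(m);
  LogicalVector ess(m);
  for (int i = 0; i < m; ++i) {
    dim[i] = dim_out[i];
    birth[i] = birth_out[i];
    death[i] = death_out[i];
    br[i] = bpos_out[i] / nc + 1;  // 1-based row
    bc[i] = bpos_out[i] % nc + 1;  // 1-based col
    dr[i] = dpos_out[i] / nc + 1;
    dc[i] = dpos_out[i] % nc + 1;
    ess[i] = ess_out[i];
  }
  return DataFrame::create(
    _["dim"] = dim, _["birth"] = birth, _["death"] = death,
    _["birth_row"] = br, _["birth_col"] = bc,
    _["death_row"] = dr, _["death_col"] = dc,
    _["essential"] = ess);
}
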