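// Vietoris-Rips persistent homology over Z/2 in dimensions 0-2, with
// representative cycles.
//
// Algorithm outline:
//   * dim 0: union-find over edges in filtration order (single linkage).
//   * dims >= 1: persistent cohomology in the anti-transpose formulation
//     (columns = d-simplices in reverse filtration order, rows = (d+1)-cofacets,
//     pivot = oldest cofacet), with clearing: d-simplices already paired as
//     deaths in dimension d-1 are skipped.  This yields the same (birth, death)
//     simplex pairing as homology reduction.
//   * representatives: a second, homology-side reduction restricted to the
//     death columns found above, processed in filtration order.  Columns that
//     reduce to zero in the full reduction are never added to any other column,
//     so the restricted reduction reproduces the reduced death columns exactly;
//     the reduced column at a death simplex is a cycle representing the class
//     that dies there.
//
// Simplices are keyed by their vertex tuple encoded in base n (int64), so the
// filtration total order (diameter, dimension, lexicographic vertices) is the
// numeric order on (diameter, key) within a fixed dimension.
//
// Truncation: simplices are only enumerated up to
//   thresh = min(max_scale, enclosing radius),
// where the enclosing radius r = min_i max_j d(i,j).  For t >= r the complex
// is a cone, hence acyclic in dimensions >= 1; every positive-persistence
// class is born and dies at or before r, so the truncated diagram (after
// dropping zero-persistence pairs) equals the full one.

#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef std::pair<double, int64_t> Ent;  // (diameter, encoded vertex tuple)

struct PairRec {
  int dim;
  double birth, death;
  int64_t birth_key, death_key;  // death_key = -1 for essential classes
};

// ---------- small helpers -------------------------------------------------

static inline double dget(const std::vector<double>& d, int n, int i, int j) {
  return d[(size_t)i * n + j];
}

// XOR (symmetric difference) of two ascending-sorted entry lists.
static std::vector<Ent> xor_merge(const std::vector<Ent>& a,
                                  const std::vector<Ent>& b) {
  std::vector<Ent> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) {
      ++i;
      ++j;
    } else if (a[i] < b[j]) {
      out.push_back(a[i++]);
    } else {
      out.push_back(b[j++]);
    }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  return out;
}

static inline int64_t enc2(int a, int b, int n) {
  return (int64_t)a * n + b;  // a < b
}
static inline int64_t enc3(int a, int b, int c, int n) {
  return ((int64_t)a * n + b) * n + c;  // a < b < c
}
static inline int64_t enc4(int a, int b, int c, int e, int n) {
  return (((int64_t)a * n + b) * n + c) * n + e;
}

// ---------- cofacet / facet enumeration -----------------------------------

// Cofacets of edge key (dim 1 -> triangles), diameter-filtered.
static void edge_cofacets(int64_t key, double diam, const std::vector<double>& d,
                          int n, double thresh, std::vector<Ent>& out) {
  int a = (int)(key / n), b = (int)(key % n);
  out.clear();
  for (int c = 0; c < n; ++c) {
    if (c == a || c == b) continue;
    double m = std::max(diam, std::max(dget(d, n, a, c), dget(d, n, b, c)));
    if (m <= thresh) {
      int v0 = a, v1 = b, v2 = c;  // sort the triple
      if (v2 < v1) std::swap(v1, v2);
      if (v1 < v0) std::swap(v0, v1);
      if (v2 < v1) std::swap(v1, v2);
      out.push_back(Ent(m, enc3(v0, v1, v2, n)));
    }
  }
  std::sort(out.begin(), out.end());
}

// Cofacets of triangle key (dim 2 -> tetrahedra), diameter-filtered.
static void tri_cofacets(int64_t key, double diam, const std::vector<double>& d,
                         int n, double thresh, std::vector<Ent>& out) {
  int a = (int)(key / ((int64_t)n * n));
  int b = (int)((key / n) % n);
  int c = (int)(key % n);
  out.clear();
  for (int e = 0; e < n; ++e) {
    if (e == a || e == b || e == c) continue;
    double m = std::max(diam, std::max(dget(d, n, a, e),
                                       std::max(dget(d, n, b, e), dget(d, n, c, e))));
    if (m <= thresh) {
      int v[4] = {a, b, c, e};
      std::sort(v, v + 4);
      out.push_back(Ent(m, enc4(v[0], v[1], v[2], v[3], n)));
    }
  }
  std::sort(out.begin(), out.end());
}

// Facets of a (d+1)-simplex for the homology (representative) pass.
static void facets_of(int64_t key, int dimp1, const std::vector<double>& d, int n,
                      std::vector<Ent>& out) {
  out.clear();
  if (dimp1 == 2) {  // triangle -> 3 edges
    int a = (int)(key / ((int64_t)n * n));
    int b = (int)((key / n) % n);
    int c = (int)(key % n);
    out.push_back(Ent(dget(d, n, a, b), enc2(a, b, n)));
    out.push_back(Ent(dget(d, n, a, c), enc2(a, c, n)));
    out.push_back(Ent(dget(d, n, b, c), enc2(b, c, n)));
  } else {  // tetrahedron -> 4 triangles
    int64_t nn = (int64_t)n * n;
    int a = (int)(key / (nn * n));
    int b = (int)((key / nn) % n);
    int c = (int)((key / n) % n);
    int e = (int)(key % n);
    int v[4] = {a, b, c, e};
    for (int skip = 0; skip < 4; ++skip) {
      int w[3], k = 0;
      for (int t = 0; t < 4; ++t)
        if (t != skip) w[k++] = v[t];
      double m = std::max(dget(d, n, w[0], w[1]),
                          std::max(dget(d, n, w[0], w[2]), dget(d, n, w[1], w[2])));
      out.push_back(Ent(m, enc3(w[0], w[1], w[2], n)));
    }
  }
  std::sort(out.begin(), out.end());
}

// ---------- cohomology reduction for one dimension ------------------------

// columns: d-simplices (diam, key), NOT yet filtered for clearing.
// cleared: keys of d-simplices that are deaths in dimension d-1.
// Emits pairs and fills `death_keys_of_dim` (all pivots, including
// zero-persistence ones, needed for clearing the next dimension).
static void cohom_reduce(int d, std::vector<Ent> columns,
                         const std::unordered_set<int64_t>& cleared,
                         const std::vector<double>& dist, int n, double thresh,
                         bool truncated_by_user, std::vector<PairRec>& pairs,
                         std::unordered_set<int64_t>& pivot_keys) {
  // reverse filtration order
  std::sort(columns.begin(), columns.end(),
            [](const Ent& a, const Ent& b) { return b < a; });
  std::unordered_map<int64_t, int> pivot_of;  // cofacet key -> stored column idx
  std::vector<std::vector<Ent> > stored;
  std::vector<Ent> col, cof;
  for (size_t ci = 0; ci < columns.size(); ++ci) {
    const Ent& sigma = columns[ci];
    if (cleared.count(sigma.second)) continue;
    if (d == 1)
      edge_cofacets(sigma.second, sigma.first, dist, n, thresh, cof);
    else
      tri_cofacets(sigma.second, sigma.first, dist, n, thresh, cof);
    col = cof;
    while (!col.empty()) {
      std::unordered_map<int64_t, int>::iterator it = pivot_of.find(col.front().second);
      if (it == pivot_of.end()) break;
      col = xor_merge(col, stored[it->second]);
    }
    if (!col.empty()) {
      Ent piv = col.front();
      pivot_of[piv.second] = (int)stored.size();
      stored.push_back(col);
      pivot_keys.insert(piv.second);
      PairRec pr;
      pr.dim = d;
      pr.birth = sigma.first;
      pr.death = piv.first;
      pr.birth_key = sigma.second;
      pr.death_key = piv.second;
      pairs.push_back(pr);
    } else if (truncated_by_user) {
      // class still alive at the user's cutoff: censored (infinite) bar
      PairRec pr;
      pr.dim = d;
      pr.birth = sigma.first;
      pr.death = R_PosInf;
      pr.birth_key = sigma.second;
      pr.death_key = -1;
      pairs.push_back(pr);
    }
    // else: zero-persistence class beyond the enclosing radius; dropped
  }
}

// ---------- representative pass for one dimension -------------------------

// Reduce only the death columns (in filtration order); the reduced column at
// each death is the representative cycle of the class that dies there.
static void representative_pass(
    int d, const std::vector<PairRec>& pairs, const std::vector<double>& dist,
    int n, std::unordered_map<int64_t, std::vector<int64_t> >& reps) {
  std::vector<Ent> deaths;  // (d+1)-simplices
  for (size_t i = 0; i < pairs.size(); ++i)
    if (pairs[i].dim == d && pairs[i].death_key >= 0)
      deaths.push_back(Ent(pairs[i].death, pairs[i].death_key));
  std::sort(deaths.begin(), deaths.end());
  std::unordered_map<int64_t, int> pivot_of;  // facet key -> stored idx
  std::vector<std::vector<Ent> > stored;
  std::unordered_map<int64_t, double> want;  // death_key -> birth (positive only)
  for (size_t i = 0; i < pairs.size(); ++i)
    if (pairs[i].dim == d && pairs[i].death_key >= 0 &&
        pairs[i].death > pairs[i].birth)
      want[pairs[i].death_key] = pairs[i].birth;
  std::vector<Ent> col;
  for (size_t ci = 0; ci < deaths.size(); ++ci) {
    facets_of(deaths[ci].second, d + 1, dist, n, col);
    while (!col.empty()) {
      std::unordered_map<int64_t, int>::iterator it = pivot_of.find(col.back().second);
      if (it == pivot_of.end()) break;
      col = xor_merge(col, stored[it->second]);
    }
    if (col.empty()) continue;  // cannot happen for a true death column
    pivot_of[col.back().second] = (int)stored.size();
    if (want.count(deaths[ci].second)) {
      std::vector<int64_t> cyc(col.size());
      for (size_t k = 0; k < col.size(); ++k) cyc[k] = col[k].second;
      reps[deaths[ci].second] = cyc;
    }
    stored.push_back(col);
  }
}

// ---------- main entry ----------------------------------------------------

// [[Rcpp::export(name = ".rips_cpp")]]
List rips_cpp(NumericMatrix dmat, int max_dim, double max_scale,
              bool with_representatives) {
  int n = dmat.nrow();
  std::vector<double> dist((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) dist[(size_t)i * n + j] = dmat(i, j);

  // enclosing radius
  double r_enc = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double mx = 0;
    for (int j = 0; j < n; ++j) mx = std::max(mx, dget(dist, n, i, j));
    r_enc = std::min(r_enc, mx);
  }
  double thresh = std::min(max_scale, r_enc);
  bool truncated_by_user = max_scale < r_enc;

  // ---- edges ----
  std::vector<Ent> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = dget(dist, n, i, j);
      if (w <= thresh) edges.push_back(Ent(w, enc2(i, j, n)));
    }
  std::sort(edges.begin(), edges.end());

  // ---- dim 0: union-find (elder rule: the component holding the smallest
  // vertex index survives a merge) ----
  std::vector<int> parent(n);
  std::vector<std::vector<int> > members(n);
  for (int i = 0; i < n; ++i) {
    parent[i] = i;
    members[i].push_back(i);
  }
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  std::vector<PairRec> pairs;
  std::unordered_set<int64_t> mst_keys;
  std::vector<std::vector<int> > dim0_reps;
  std::vector<double> dim0_deaths;
  for (size_t e = 0; e < edges.size(); ++e) {
    int a = (int)(edges[e].second / n), b = (int)(edges[e].second % n);
    int ra = find(a), rb = find(b);
    if (ra == rb) continue;
    mst_keys.insert(edges[e].second);
    int amin = *std::min_element(members[ra].begin(), members[ra].end());
    int bmin = *std::min_element(members[rb].begin(), members[rb].end());
    int survivor = (amin < bmin) ? ra : rb;
    int absorbed = (survivor == ra) ? rb : ra;
    if (edges[e].first > 0) {  // drop zero-persistence (duplicate points)
      dim0_deaths.push_back(edges[e].first);
      dim0_reps.push_back(members[absorbed]);
    }
    parent[absorbed] = survivor;
    members[survivor].insert(members[survivor].end(), members[absorbed].begin(),
                             members[absorbed].end());
    members[absorbed].clear();
    members[absorbed].shrink_to_fit();
  }
  // essential dim-0 classes (one per remaining component)
  std::vector<std::vector<int> > essential0;
  for (int i = 0; i < n; ++i)
    if (find(i) == i && !members[i].empty()) essential0.push_back(members[i]);

  // ---- dims >= 1: cohomology with clearing ----
  std::unordered_set<int64_t> pivots1, pivots2;
  if (max_dim >= 1) {
    cohom_reduce(1, edges, mst_keys, dist, n, thresh, truncated_by_user, pairs,
                 pivots1);
  }
  if (max_dim >= 2) {
    std::vector<Ent> tris;
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double dab = dget(dist, n, a, b);
        if (dab > thresh) continue;
        for (int c = b + 1; c < n; ++c) {
          double m = std::max(dab, std::max(dget(dist, n, a, c), dget(dist, n, b, c)));
          if (m <= thresh) tris.push_back(Ent(m, enc3(a, b, c, n)));
        }
      }
    cohom_reduce(2, tris, pivots1, dist, n, thresh, truncated_by_user, pairs,
                 pivots2);
  }

  // ---- representatives ----
  std::unordered_map<int64_t, std::vector<int64_t> > reps1, reps2;
  if (with_representatives) {
    if (max_dim >= 1) representative_pass(1, pairs, dist, n, reps1);
    if (max_dim >= 2) representative_pass(2, pairs, dist, n, reps2);
  }

  // ---- assemble output (filtration-ordered within dimension) ----
  std::vector<int> out_dim;
  std::vector<double> out_birth, out_death;
  List out_reps;
  // dim 0 finite bars
  {
    std::vector<size_t> idx(dim0_deaths.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
      return dim0_deaths[a] < dim0_deaths[b];
    });
    for (size_t k = 0; k < idx.size(); ++k) {
      out_dim.push_back(0);
      out_birth.push_back(0.0);
      out_death.push_back(dim0_deaths[idx[k]]);
      if (with_representatives) {
        IntegerVector v(dim0_reps[idx[k]].size());
        for (size_t t = 0; t < dim0_reps[idx[k]].size(); ++t)
          v[t] = dim0_reps[idx[k]][t] + 1;
        out_reps.push_back(v);
      } else {
        out_reps.push_back(R_NilValue);
      }
    }
    for (size_t k = 0; k < essential0.size(); ++k) {
      out_dim.push_back(0);
      out_birth.push_back(0.0);
      out_death.push_back(R_PosInf);
      if (with_representatives) {
        IntegerVector v(essential0[k].size());
        for (size_t t = 0; t < essential0[k].size(); ++t)
          v[t] = essential0[k][t] + 1;
        out_reps.push_back(v);
      } else {
        out_reps.push_back(R_NilValue);
      }
    }
  }
  // dims >= 1, positive persistence only
  for (int d = 1; d <= max_dim; ++d) {
    std::vector<size_t> idx;
    for (size_t i = 0; i < pairs.size(); ++i)
      if (pairs[i].dim == d && pairs[i].death > pairs[i].birth) idx.push_back(i);
    std::stable_sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
      if (pairs[a].birth != pairs[b].birth) return pairs[a].birth < pairs[b].birth;
      return pairs[a].birth_key < pairs[b].birth_key;
    });
    for (size_t k = 0; k < idx.size(); ++k) {
      const PairRec& pr = pairs[idx[k]];
      out_dim.push_back(d);
      out_birth.push_back(pr.birth);
      out_death.push_back(pr.death);
      SEXP rep = R_NilValue;
      if (with_representatives && pr.death_key >= 0) {
        std::unordered_map<int64_t, std::vector<int64_t> >& reps =
            (d == 1) ? reps1 : reps2;
        std::unordered_map<int64_t, std::vector<int64_t> >::iterator it =
            reps.find(pr.death_key);
        if (it != reps.end()) {
          int nv = d + 1;  // vertices per d-simplex
          IntegerMatrix m((int)it->second.size(), nv);
          for (size_t r = 0; r < it->second.size(); ++r) {
            int64_t key = it->second[r];
            for (int c = nv - 1; c >= 0; --c) {
              m(r, c) = (int)(key % n) + 1;
              key /= n;
            }
          }
          rep = m;
        }
      }
      out_reps.push_back(rep);
    }
  }

  return List::create(_["dimension"] = out_dim, _["birth"] = out_birth,
                      _["death"] = out_death, _["representatives"] = out_reps,
                      _["enclosing_radius"] = r_enc, _["threshold"] = thresh);
}
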