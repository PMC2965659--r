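// Triad census by canonical classification and the Metropolis sampler /
// change statistics for exponential random graph models. These are the
// inner loops of the package; everything else lives in R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Arc bit layout for a labelled 3-node digraph (a,b,c):
// bit 0: a->b, 1: b->a, 2: a->c, 3: c->a, 4: b->c, 5: c->b
static const int ARC_FROM[6] = {0, 1, 0, 2, 1, 2};
static const int ARC_TO[6]   = {1, 0, 2, 0, 2, 1};

// the six permutations of {0,1,2}
static const int PERMS[6][3] = {
  {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

static int triad_class_table[64];
static bool triad_table_built = false;

static int apply_perm(int code, const int *p) {
  int out = 0;
  for (int b = 0; b < 6; ++b) {
    if (!(code & (1 << b))) continue;
    int f = p[ARC_FROM[b]], t = p[ARC_TO[b]];
    for (int b2 = 0; b2 < 6; ++b2)
      if (ARC_FROM[b2] == f && ARC_TO[b2] == t) { out |= (1 << b2); break; }
  }
  return out;
}

static int canonical_code(int code) {
  int best = code;
  for (int k = 0; k < 6; ++k) {
    int c = apply_perm(code, PERMS[k]);
    if (c < best) best = c;
  }
  return best;
}

// Representatives of the 16 Davis-Leinhardt classes, in conventional order
// 003 012 102 021D 021U 021C 111D 111U 030T 030C 201 120D 120U 120C 210 300.
// Arcs written on nodes a=0, b=1, c=2.
static int representative_code(int cls) {
  switch (cls) {
  case 0:  return 0;                                        // 003
  case 1:  return 1;                                        // 012: a->b
  case 2:  return 1 | 2;                                    // 102: a<->b
  case 3:  return 2 | 16;                                   // 021D: b->a, b->c
  case 4:  return 1 | 32;                                   // 021U: a->b, c->b
  case 5:  return 1 | 16;                                   // 021C: a->b->c
  case 6:  return 1 | 2 | 32;                               // 111D: a<->b<-c
  case 7:  return 1 | 2 | 16;                               // 111U: a<->b->c
  case 8:  return 1 | 32 | 4;                               // 030T: a->b<-c, a->c
  case 9:  return 2 | 32 | 4;                               // 030C: a->c->b->a
  case 10: return 1 | 2 | 16 | 32;                          // 201: a<->b<->c
  case 11: return 2 | 16 | 4 | 8;                           // 120D: b->a, b->c, a<->c
  case 12: return 1 | 32 | 4 | 8;                           // 120U: a->b<-c, a<->c
  case 13: return 1 | 16 | 4 | 8;                           // 120C: a->b->c, a<->c
  case 14: return 1 | 16 | 32 | 4 | 8;                      // 210
  case 15: return 63;                                       // 300
  }
  return -1;
}

static void build_triad_table() {
  if (triad_table_built) return;
  int canon_of_class[16];
  for (int c = 0; c < 16; ++c)
    canon_of_class[c] = canonical_code(representative_code(c));
  for (int code = 0; code < 64; ++code) {
    int canon = canonical_code(code);
    int cls = -1;
    for (int c = 0; c < 16; ++c)
      if (canon_of_class[c] == canon) { cls = c; break; }
    triad_class_table[code] = cls;
  }
  triad_table_built = true;
}

static inline int triple_code(const IntegerMatrix &A, int i, int j, int k) {
  return A(i,j) | (A(j,i) << 1) | (A(i,k) << 2) | (A(k,i) << 3) |
         (A(j,k) << 4) | (A(k,j) << 5);
}

// [[Rcpp::export(name = ".triad_census_cpp")]]
IntegerVector triad_census_cpp(IntegerMatrix A) {
  build_triad_table();
  int n = A.nrow();
  IntegerVector out(16);
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 1; j < n - 1; ++j)
      for (int k = j + 1; k < n; ++k)
        out[triad_class_table[triple_code(A, i, j, k)]]++;
  return out;
}

// class index of each of the 64 labelled 3-node digraph codes
// [[Rcpp::export(name = ".triad_class_of_code_cpp")]]
IntegerVector triad_class_of_code_cpp() {
  build_triad_table();
  IntegerVector out(64);
  for (int c = 0; c < 64; ++c) out[c] = triad_class_table[c];
  return out;
}

// ---------------------------------------------------------------------------
// ERGM statistics. ids: 0 edges, 1 mutual, 2 asym, 3 triad_201, 4 triad_021C,
// 5 instar2, 6 outstar2, 7 cycle3.

// [[Rcpp::export(name = ".ergm_stats_cpp")]]
NumericVector ergm_stats_cpp(IntegerMatrix A, IntegerVector ids) {
  build_triad_table();
  int n = A.nrow(), p = ids.size();
  NumericVector out(p);
  IntegerVector census;
  bool have_census = false;
  for (int s = 0; s < p; ++s) {
    int id = ids[s];
    double v = 0.0;
    if (id == 0) {
      for (int i = 0; i < n; ++i) for (int j = 0; j < n; ++j) v += A(i,j);
    } else if (id == 1 || id == 2) {
      for (int i = 0; i < n - 1; ++i) for (int j = i + 1; j < n; ++j) {
        int m = A(i,j) + A(j,i);
        if (id == 1 && m == 2) v += 1;
        if (id == 2 && m == 1) v += 1;
      }
    } else if (id == 3 || id == 4) {
      if (!have_census) { census = triad_census_cpp(A); have_census = true; }
      v = (id == 3) ? census[10] : census[5];
    } else if (id == 5) {
      for (int j = 0; j < n; ++j) {
        double d = 0; for (int i = 0; i < n; ++i) d += A(i,j);
        v += d * (d - 1) / 2.0;
      }
    } else if (id == 6) {
      for (int i = 0; i < n; ++i) {
        double d = 0; for (int j = 0; j < n; ++j) d += A(i,j);
        v += d * (d - 1) / 2.0;
      }
    } else if (id == 7) {
      for (int i = 0; i < n; ++i) for (int j = 0; j < n; ++j) {
        if (!A(i,j)) continue;
        for (int k = 0; k < n; ++k) if (A(j,k) && A(k,i)) v += 1;
      }
      v /= 3.0;
    }
    out[s] = v;
  }
  return out;
}

// change statistics of adding arc i->j (A(i,j) must be 0 on entry)
static void delta_add(const IntegerMatrix &A, int i, int j,
                      const IntegerVector &ids, double *d) {
  int n = A.nrow();
  for (int s = 0; s < ids.size(); ++s) {
    int id = ids[s];
    double v = 0.0;
    switch (id) {
    case 0: v = 1.0; break;
    case 1: v = A(j,i) ? 1.0 : 0.0; break;
    case 2: v = A(j,i) ? -1.0 : 1.0; break;
    case 3: case 4: {
      int target = (id == 3) ? 10 : 5;
      int bit_ij = 1; // code for (a=i, b=j, c=k): i->j is bit 0
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        int code = A(i,j) | (A(j,i) << 1) | (A(i,k) << 2) | (A(k,i) << 3) |
                   (A(j,k) << 4) | (A(k,j) << 5);
        // A(i,j) is 0 by contract; 'code' is the before state
        int after = code | bit_ij;
        v += (triad_class_table[after] == target) -
             (triad_class_table[code] == target);
      }
      break;
    }
    case 5: { double din = 0; for (int a = 0; a < n; ++a) din += A(a,j);
              v = din; break; }
    case 6: { double dout = 0; for (int b = 0; b < n; ++b) dout += A(i,b);
              v = dout; break; }
    case 7: { for (int k = 0; k < n; ++k)
                if (k != i && k != j && A(j,k) && A(k,i)) v += 1;
              break; }
    }
    d[s] = v;
  }
}

// [[Rcpp::export(name = ".ergm_delta_cpp")]]
NumericVector ergm_delta_cpp(IntegerMatrix A, int i, int j, IntegerVector ids) {
  build_triad_table();
  if (A(i,j) != 0) stop("arc must be absent when computing an add-delta");
  std::vector<double> d(ids.size());
  delta_add(A, i, j, ids, d.data());
  return NumericVector(d.begin(), d.end());
}

// Design matrix for maximum pseudo-likelihood: one row per ordered pair,
// change statistics evaluated with the arc itself removed.
// [[Rcpp::export(name = ".ergm_mple_cpp")]]
List ergm_mple_cpp(IntegerMatrix A, IntegerVector ids) {
  build_triad_table();
  int n = A.nrow(), p = ids.size(), m = n * (n - 1);
  NumericMatrix X(m, p);
  IntegerVector y(m);
  std::vector<double> d(p);
  int r = 0;
  for (int i = 0; i < n; ++i) for (int j = 0; j < n; ++j) {
    if (i == j) continue;
    int yij = A(i,j);
    A(i,j) = 0;
    delta_add(A, i, j, ids, d.data());
    A(i,j) = yij;
    for (int s = 0; s < p; ++s) X(r, s) = d[s];
    y[r] = yij;
    ++r;
  }
  return List::create(_["x"] = X, _["y"] = y);
}

// Single-arc-toggle Metropolis-Hastings sampler. Records the statistic
// vector every `thin` proposals after `burn` proposals.
// [[Rcpp::export(name = ".ergm_sample_cpp")]]
List ergm_sample_cpp(IntegerMatrix A0, NumericVector theta, IntegerVector ids,
                     int burn, int n_keep, int thin, bool keep_graphs) {
  build_triad_table();
  IntegerMatrix A = clone(A0);
  int n = A.nrow(), p = ids.size();
  NumericVector stats = ergm_stats_cpp(A, ids);
  NumericMatrix trace(n_keep, p);
  List snapshots(keep_graphs ? n_keep : 0);
  std::vector<double> d(p);
  long total = (long)burn + (long)n_keep * thin;
  long accepted = 0;
  int kept = 0;
  RNGScope scope;
  for (long t = 0; t < total; ++t) {
    int i = (int)(unif_rand() * n);
    int j = (int)(unif_rand() * (n - 1));
    if (j >= i) ++j;
    if (i >= n) i = n - 1; // guard against unif_rand() == 1
    int yij = A(i,j);
    A(i,j) = 0;
    delta_add(A, i, j, ids, d.data());
    double lr = 0.0;
    for (int s = 0; s < p; ++s) lr += theta[s] * d[s];
    if (yij == 1) lr = -lr; // toggling off
    if (lr >= 0 || unif_rand() < std::exp(lr)) {
      A(i,j) = 1 - yij;
      ++accepted;
      for (int s = 0; s < p; ++s)
        stats[s] += (yij == 1 ? -d[s] : d[s]);
    } else {
      A(i,j) = yij;
    }
    if (t >= burn && ((t - burn + 1) % thin == 0) && kept < n_keep) {
      for (int s = 0; s < p; ++s) trace(kept, s) = stats[s];
      if (keep_graphs) snapshots[kept] = clone(A);
      ++kept;
    }
  }
  return List::create(_["trace"] = trace, _["final"] = A,
                      _["graphs"] = snapshots,
                      _["acceptance_rate"] = (double)accepted / (double)total);
}
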