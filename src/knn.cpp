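#include <Rcpp.h>
using namespace Rcpp;

// Exact k-nearest-neighbour scan used by the point-symmetry measure: for
// each query (a reflected point) the mean Euclidean distance to its knear
// nearest pool points with pairwise-distinct coordinates. `groups` holds a
// group id per pool row, identical for rows with identical coordinates;
// once a neighbour is chosen its whole group is excluded. Ties are broken
// by the lower pool index (strict < keeps the first minimum).
// [[Rcpp::export]]
NumericVector knear_mean_dist_cpp(NumericMatrix Q, NumericMatrix P,
                                  int knear, IntegerVector groups) {
  const int m = Q.nrow(), p = P.nrow(), d = Q.ncol();
  if (P.ncol() != d) stop("query/pool dimension mismatch");
  if (groups.size() != p) stop("groups length mismatch");
  NumericVector out(m);
  std::vector<double> dist(p);
  const double* q = REAL(Q);
  const double* pp = REAL(P);
  const int* grp = INTEGER(groups);
  // duplicates are rare; group exclusion only needs the scan when they exist
  bool has_dups = false;
  for (int j = 0; j < p; ++j)
    if (grp[j] != j + 1) { has_dups = true; break; }
  for (int i = 0; i < m; ++i) {
    // column-major: accumulate squared distances one coordinate at a time
    const double q0 = q[i];
    const double* p0 = pp;
    for (int j = 0; j < p; ++j) {
      const double diff = q0 - p0[j];
      dist[j] = diff * diff;
    }
    for (int k = 1; k < d; ++k) {
      const double qk = q[i + (R_xlen_t)k * m];
      const double* pk = pp + (R_xlen_t)k * p;
      for (int j = 0; j < p; ++j) {
        const double diff = qk - pk[j];
        dist[j] += diff * diff;
      }
    }
    double acc = 0.0;
    for (int t = 0; t < knear; ++t) {
      int best = -1;
      double bd = R_PosInf;
      for (int j = 0; j < p; ++j) {
        if (dist[j] < bd) {
          bd = dist[j];
          best = j;
        }
      }
      if (best < 0)
        stop("fewer than knear points with distinct coordinates available");
      acc += std::sqrt(bd);
      if (has_dups) {
        const int g = grp[best];
        for (int j = 0; j < p; ++j)
          if (grp[j] == g) dist[j] = R_PosInf;
      } else {
        dist[best] = R_PosInf;
      }
    }
    out[i] = acc / knear;
  }
  return out;
}

// Group id per row such that rows with exactly equal coordinates share the
// id of the first such row (1-based).
// [[Rcpp::export]]
IntegerVector coordinate_groups_cpp(NumericMatrix P) {
  const int p = P.nrow(), d = P.ncol();
  IntegerVector groups(p);
  for (int i = 0; i < p; ++i) {
    int g = i + 1;
    for (int j = 0; j < i; ++j) {
      bool same = true;
      for (int k = 0; k < d; ++k) {
        if (P(i, k) != P(j, k)) { same = false; break; }
      }
      if (same) { g = groups[j]; break; }
    }
    groups[i] = g;
  }
  return groups;
}
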