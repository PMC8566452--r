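#include "cellsq.h"
using namespace Rcpp;

// Geometry queries on a triangulated closed surface.  All index matrices
// arriving from R are 0-based (the R wrappers subtract 1 once, at mesh
// construction).

// [[Rcpp::export]]
List cpp_tri_geometry(const NumericMatrix &pos, const IntegerMatrix &tri) {
  const int M = tri.nrow();
  NumericVector area(M);
  NumericMatrix normal(M, 3), centroid(M, 3);
  NumericVector t2sum(M);
  double vol = 0.0, total_area = 0.0;
  int n_degenerate = 0;
  for (int t = 0; t < M; ++t) {
    Vec3 a = row3(pos, tri(t, 0)), b = row3(pos, tri(t, 1)), c = row3(pos, tri(t, 2));
    Vec3 nv = cross(b - a, c - a);
    double nn = norm(nv);
    area[t] = 0.5 * nn;
    total_area += area[t];
    if (nn < 1e-300) { ++n_degenerate; nn = 1.0; }
    normal(t, 0) = nv.x / nn; normal(t, 1) = nv.y / nn; normal(t, 2) = nv.z / nn;
    Vec3 T = (1.0 / 3.0) * (a + b + c);
    centroid(t, 0) = T.x; centroid(t, 1) = T.y; centroid(t, 2) = T.z;
    Vec3 ta = a - T, tb = b - T, tc = c - T;
    t2sum[t] = dot(ta, ta) + dot(tb, tb) + dot(tc, tc);
    vol += dot(cross(a, b), c) / 6.0; // signed tetrahedron with the origin
  }
  return List::create(_["area"] = area, _["normal"] = normal,
                      _["centroid"] = centroid, _["t2sum"] = t2sum,
                      _["volume"] = vol, _["total_area"] = total_area,
                      _["n_degenerate"] = n_degenerate);
}

// [[Rcpp::export]]
NumericVector cpp_edge_lengths(const NumericMatrix &pos, const IntegerMatrix &edges) {
  const int E = edges.nrow();
  NumericVector len(E);
  for (int e = 0; e < E; ++e)
    len[e] = norm(row3(pos, edges(e, 0)) - row3(pos, edges(e, 1)));
  return len;
}

// [[Rcpp::export]]
NumericVector cpp_dihedrals(const NumericMatrix &pos, const IntegerMatrix &tri,
                            const IntegerMatrix &edges, const IntegerMatrix &edge_tri,
                            const IntegerMatrix &edge_opp) {
  const int E = edges.nrow();
  NumericVector th(E);
  for (int e = 0; e < E; ++e) {
    int t1 = edge_tri(e, 0), t2 = edge_tri(e, 1);
    Vec3 a1 = row3(pos, tri(t1, 0)), b1 = row3(pos, tri(t1, 1)), c1 = row3(pos, tri(t1, 2));
    Vec3 a2 = row3(pos, tri(t2, 0)), b2 = row3(pos, tri(t2, 1)), c2 = row3(pos, tri(t2, 2));
    Vec3 n1 = cross(b1 - a1, c1 - a1), n2 = cross(b2 - a2, c2 - a2);
    double l1 = norm(n1), l2 = norm(n2);
    if (l1 < 1e-300 || l2 < 1e-300) { th[e] = NA_REAL; continue; }
    n1 = (1.0 / l1) * n1; n2 = (1.0 / l2) * n2;
    th[e] = dihedral_angle(n1, n2, row3(pos, edges(e, 0)), row3(pos, edge_opp(e, 1)));
  }
  return th;
}
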