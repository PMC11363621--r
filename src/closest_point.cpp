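#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision
// Detection, 5.1.5. Writes the closest point into out[3].
static inline void closest_point_triangle(const double *p, const double *a,
                                          const double *b, const double *c,
                                          double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
    return;
  }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom;
  double w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

//' Closest points on a triangle mesh (brute force over triangles)
//'
//' @param pts n x 3 query points.
//' @param V m x 3 mesh vertices.
//' @param F k x 3 1-based face indices.
//' @return list(points = n x 3 closest surface points, dist = n distances).
//' @keywords internal
// [[Rcpp::export(name = ".mesh_closest_points")]]
List mesh_closest_points(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  const int n = pts.nrow(), m = V.nrow(), k = F.nrow();
  if (k < 1 || m < 3) stop("mesh has no triangles");

  // column-major copies into contiguous xyz triplets
  std::vector<double> P(3 * n), W(3 * m);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = pts(i, 0); P[3 * i + 1] = pts(i, 1); P[3 * i + 2] = pts(i, 2);
  }
  for (int i = 0; i < m; ++i) {
    W[3 * i] = V(i, 0); W[3 * i + 1] = V(i, 1); W[3 * i + 2] = V(i, 2);
  }
  std::vector<int> fa(k), fb(k), fc(k);
  std::vector<double> cx(k), cy(k), cz(k), rad(k); // bounding spheres
  for (int j = 0; j < k; ++j) {
    int ia = F(j, 0) - 1, ib = F(j, 1) - 1, ic = F(j, 2) - 1;
    if (ia < 0 || ib < 0 || ic < 0 || ia >= m || ib >= m || ic >= m)
      stop("face index out of range");
    fa[j] = ia; fb[j] = ib; fc[j] = ic;
    double gx = (W[3 * ia] + W[3 * ib] + W[3 * ic]) / 3.0;
    double gy = (W[3 * ia + 1] + W[3 * ib + 1] + W[3 * ic + 1]) / 3.0;
    double gz = (W[3 * ia + 2] + W[3 * ib + 2] + W[3 * ic + 2]) / 3.0;
    cx[j] = gx; cy[j] = gy; cz[j] = gz;
    double r2 = 0.0;
    const int idx[3] = {ia, ib, ic};
    for (int t = 0; t < 3; ++t) {
      double dx = W[3 * idx[t]] - gx, dy = W[3 * idx[t] + 1] - gy,
             dz = W[3 * idx[t] + 2] - gz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[j] = std::sqrt(r2);
  }

  NumericMatrix out(n, 3);
  NumericVector dist(n);
  double q[3];
  for (int i = 0; i < n; ++i) {
    const double *p = &P[3 * i];
    double best = R_PosInf, bx = 0, by = 0, bz = 0;
    for (int j = 0; j < k; ++j) {
      // bounding-sphere reject: triangle cannot beat current best
      double dx = p[0] - cx[j], dy = p[1] - cy[j], dz = p[2] - cz[j];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[j];
      if (dc > 0.0 && dc * dc >= best) continue;
      closest_point_triangle(p, &W[3 * fa[j]], &W[3 * fb[j]], &W[3 * fc[j]], q);
      double ex = p[0] - q[0], ey = p[1] - q[1], ez = p[2] - q[2];
      double d2 = ex * ex + ey * ey + ez * ez;
      if (d2 < best) { best = d2; bx = q[0]; by = q[1]; bz = q[2]; }
    }
    out(i, 0) = bx; out(i, 1) = by; out(i, 2) = bz;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["points"] = out, _["dist"] = dist);
}
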