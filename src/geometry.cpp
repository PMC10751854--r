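#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Deterministic sub-voxel ray jitter: keeps scan rays off mesh vertices/edges
// without changing which voxel centers are evaluated.
static const double JIT_Y = 1.09e-4;
static const double JIT_Z = 2.31e-4;

static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision Detection 5.1.5.
static void closest_pt_triangle(const double p[3], const double a[3],
                                const double b[3], const double c[3],
                                double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
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
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Nearest point on a triangle mesh for each query point.
// Returns squared-free distances, 1-based nearest face index, and foot points.
// [[Rcpp::export]]
List cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np);
  IntegerVector face(np);
  NumericMatrix foot(np, 3);

  // face centroids and bounding radii for early rejection
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double gx = (V(i0, 0) + V(i1, 0) + V(i2, 0)) / 3.0;
    double gy = (V(i0, 1) + V(i1, 1) + V(i2, 1)) / 3.0;
    double gz = (V(i0, 2) + V(i1, 2) + V(i2, 2)) / 3.0;
    cx[f] = gx; cy[f] = gy; cz[f] = gz;
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      int iv = F(f, k) - 1;
      double dx = V(iv, 0) - gx, dy = V(iv, 1) - gy, dz = V(iv, 2) - gz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }

  for (int p = 0; p < np; ++p) {
    double q[3] = {P(p, 0), P(p, 1), P(p, 2)};
    double best = R_PosInf;
    int bestf = 0;
    double bestpt[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      double dx = q[0] - cx[f], dy = q[1] - cy[f], dz = q[2] - cz[f];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[f];
      if (dc > 0.0 && dc * dc >= best) continue;
      int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
      double a[3] = {V(i0, 0), V(i0, 1), V(i0, 2)};
      double b[3] = {V(i1, 0), V(i1, 1), V(i1, 2)};
      double c[3] = {V(i2, 0), V(i2, 1), V(i2, 2)};
      double pt[3];
      closest_pt_triangle(q, a, b, c, pt);
      double ex = q[0] - pt[0], ey = q[1] - pt[1], ez = q[2] - pt[2];
      double d2 = ex * ex + ey * ey + ez * ez;
      if (d2 < best) {
        best = d2;
        bestf = f + 1;
        bestpt[0] = pt[0]; bestpt[1] = pt[1]; bestpt[2] = pt[2];
      }
    }
    dist[p] = std::sqrt(best);
    face[p] = bestf;
    foot(p, 0) = bestpt[0]; foot(p, 1) = bestpt[1]; foot(p, 2) = bestpt[2];
  }
  return List::create(_["distance"] = dist, _["face"] = face, _["point"] = foot);
}

// Ray/triangle crossing in index space: ray along +x at (py, pz).
// Returns true and sets *x to the crossing abscissa when the (py,pz) point is
// strictly inside the yz-projection of the triangle.
static inline bool tri_cross(double py, double pz,
                             double x0, double y0, double z0,
                             double x1, double y1, double z1,
                             double x2, double y2, double z2, double *x) {
  double d = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
  if (std::fabs(d) < 1e-14) return false;  // ray-parallel face; jitter avoids grazing
  double u = ((py - y0) * (z2 - z0) - (pz - z0) * (y2 - y0)) / d;
  double v = ((y1 - y0) * (pz - z0) - (z1 - z0) * (py - y0)) / d;
  if (u < 0.0 || v < 0.0 || u + v > 1.0) return false;
  *x = x0 + u * (x1 - x0) + v * (x2 - x0);
  return true;
}

// Scanline voxelization of a closed mesh. V is given in voxel-index space
// (0-based continuous coordinates); voxel centers sit at integer positions.
// Returns a logical vector over the nx*ny*nz grid in column-major (i fastest)
// order: TRUE where the voxel center is inside the mesh (ray-parity test).
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           int nx, int ny, int nz) {
  const int nf = F.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector out(nvox, false);
  std::vector<std::vector<double> > rows((size_t)ny * nz);

  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double x0 = V(i0, 0), y0 = V(i0, 1), z0 = V(i0, 2);
    double x1 = V(i1, 0), y1 = V(i1, 1), z1 = V(i1, 2);
    double x2 = V(i2, 0), y2 = V(i2, 1), z2 = V(i2, 2);
    double ymin = std::min(y0, std::min(y1, y2)), ymax = std::max(y0, std::max(y1, y2));
    double zmin = std::min(z0, std::min(z1, z2)), zmax = std::max(z0, std::max(z1, z2));
    int jlo = std::max(0, (int)std::ceil(ymin - JIT_Y));
    int jhi = std::min(ny - 1, (int)std::floor(ymax - JIT_Y));
    int klo = std::max(0, (int)std::ceil(zmin - JIT_Z));
    int khi = std::min(nz - 1, (int)std::floor(zmax - JIT_Z));
    for (int k = klo; k <= khi; ++k) {
      double pz = k + JIT_Z;
      for (int j = jlo; j <= jhi; ++j) {
        double py = j + JIT_Y;
        double x;
        if (tri_cross(py, pz, x0, y0, z0, x1, y1, z1, x2, y2, z2, &x))
          rows[(size_t)j + (size_t)ny * k].push_back(x);
      }
    }
  }

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &xs = rows[(size_t)j + (size_t)ny * k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t m = xs.size();
      // voxel i is inside iff an odd number of crossings lie below i
      size_t c = 0;
      for (int i = 0; i < nx; ++i) {
        while (c < m && xs[c] < (double)i) ++c;
        if (c & 1) out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return out;
}

// Ray-parity inside test for arbitrary points (same convention as the
// voxelizer, ray along +x with the deterministic jitter applied to the point).
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    double px = P(p, 0), py = P(p, 1) + JIT_Y, pz = P(p, 2) + JIT_Z;
    int crossings = 0;
    for (int f = 0; f < nf; ++f) {
      int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
      double x;
      if (tri_cross(py, pz,
                    V(i0, 0), V(i0, 1), V(i0, 2),
                    V(i1, 0), V(i1, 1), V(i1, 2),
                    V(i2, 0), V(i2, 1), V(i2, 2), &x) && x > px)
        ++crossings;
    }
    out[p] = (crossings & 1) != 0;
  }
  return out;
}

// For each row of P, the 1-based index of the nearest row of Q
// (ties broken by the lowest index via strict improvement).
// [[Rcpp::export]]
IntegerVector cpp_nearest_row(NumericMatrix P, NumericMatrix Q) {
  const int np = P.nrow(), nq = Q.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double px = P(p, 0), py = P(p, 1), pz = P(p, 2);
    double best = R_PosInf;
    int besti = 0;
    for (int q = 0; q < nq; ++q) {
      double dx = px - Q(q, 0), dy = py - Q(q, 1), dz = pz - Q(q, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; besti = q + 1; }
    }
    out[p] = besti;
  }
  return out;
}
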