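// 3D image operations: trilinear resampling, similarity metrics, morphology.
// Volume convention: 3D R arrays dim (Z, Y, X), column-major, doubles.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector dims3(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  return d;
}

static inline double tri_sample(const double* v, int Z, int Y, int X,
                                double z, double y, double x) {
  if (z < 0 || y < 0 || x < 0 || z > Z - 1 || y > Y - 1 || x > X - 1) return 0.0;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int z1 = std::min(z0 + 1, Z - 1), y1 = std::min(y0 + 1, Y - 1), x1 = std::min(x0 + 1, X - 1);
  double fz = z - z0, fy = y - y0, fx = x - x0;
  const size_t ZY = (size_t)Z * Y;
  #define V(a,b,c) v[(size_t)(a) + (size_t)Z * (b) + ZY * (c)]
  double c00 = V(z0, y0, x0) * (1 - fz) + V(z1, y0, x0) * fz;
  double c10 = V(z0, y1, x0) * (1 - fz) + V(z1, y1, x0) * fz;
  double c01 = V(z0, y0, x1) * (1 - fz) + V(z1, y0, x1) * fz;
  double c11 = V(z0, y1, x1) * (1 - fz) + V(z1, y1, x1) * fz;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fx) + c1 * fx;
}

// out[p] = vol[p + t]  (pull resampling; out-of-field -> 0)
// [[Rcpp::export]]
NumericVector resample_translate3d(NumericVector vol, NumericVector t) {
  IntegerVector d = dims3(vol);
  const int Z = d[0], Y = d[1], X = d[2];
  NumericVector out(vol.size());
  out.attr("dim") = d;
  // exact integer zero shift: bitwise copy
  if (t[0] == 0.0 && t[1] == 0.0 && t[2] == 0.0) { std::copy(vol.begin(), vol.end(), out.begin()); return out; }
  size_t o = 0;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z, ++o)
        out[o] = tri_sample(vol.begin(), Z, Y, X, z + t[0], y + t[1], x + t[2]);
  return out;
}

// Rigid pull resample: p' = R (p - c) + c + t, angles (rad) about z, y, x axes.
// [[Rcpp::export]]
NumericVector resample_rigid3d(NumericVector vol, NumericVector angles, NumericVector t) {
  IntegerVector d = dims3(vol);
  const int Z = d[0], Y = d[1], X = d[2];
  const double cz = (Z - 1) / 2.0, cy = (Y - 1) / 2.0, cx = (X - 1) / 2.0;
  const double a = angles[0], b = angles[1], g = angles[2];
  const double ca = std::cos(a), sa = std::sin(a), cb = std::cos(b), sb = std::sin(b),
               cg = std::cos(g), sg = std::sin(g);
  // R = Rz(a) * Ry(b) * Rx(g) acting on (z, y, x) coordinates
  double R[3][3] = {
    {cb * cg, -cb * sg, sb},
    {sa * sb * cg + ca * sg, -sa * sb * sg + ca * cg, -sa * cb},
    {-ca * sb * cg + sa * sg, ca * sb * sg + sa * cg, ca * cb}};
  NumericVector out(vol.size());
  out.attr("dim") = d;
  size_t o = 0;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z, ++o) {
        const double pz = z - cz, py = y - cy, px = x - cx;
        const double qz = R[0][0] * pz + R[0][1] * py + R[0][2] * px + cz + t[0];
        const double qy = R[1][0] * pz + R[1][1] * py + R[1][2] * px + cy + t[1];
        const double qx = R[2][0] * pz + R[2][1] * py + R[2][2] * px + cx + t[2];
        out[o] = tri_sample(vol.begin(), Z, Y, X, qz, qy, qx);
      }
  return out;
}

// Pull resample through a dense per-voxel displacement field (Z,Y,X,3).
// [[Rcpp::export]]
NumericVector resample_dispfield3d(NumericVector vol, NumericVector disp) {
  IntegerVector d = dims3(vol);
  const int Z = d[0], Y = d[1], X = d[2];
  const size_t nv = (size_t)Z * Y * X;
  NumericVector out(vol.size());
  out.attr("dim") = d;
  size_t o = 0;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z, ++o)
        out[o] = tri_sample(vol.begin(), Z, Y, X,
                            z + disp[o], y + disp[o + nv], x + disp[o + 2 * nv]);
  return out;
}

// Normalized cross-correlation, optionally restricted to mask > 0.
// Returns NA when either image has zero variance on the support.
// [[Rcpp::export]]
double ncc3d(NumericVector a, NumericVector b, Nullable<NumericVector> mask = R_NilValue) {
  if (a.size() != b.size()) stop("size mismatch");
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0; size_t n = 0;
  if (mask.isNotNull()) {
    NumericVector m(mask);
    if (m.size() != a.size()) stop("mask size mismatch");
    for (R_xlen_t i = 0; i < a.size(); ++i) if (m[i] > 0) {
      sa += a[i]; sb += b[i]; saa += a[i] * a[i]; sbb += b[i] * b[i]; sab += a[i] * b[i]; ++n;
    }
  } else {
    n = a.size();
    for (R_xlen_t i = 0; i < a.size(); ++i) {
      sa += a[i]; sb += b[i]; saa += a[i] * a[i]; sbb += b[i] * b[i]; sab += a[i] * b[i];
    }
  }
  if (n < 2) return NA_REAL;
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// Mean-pool downsampling by 2 along every axis (floor semantics).
// [[Rcpp::export]]
NumericVector downsample2(NumericVector vol) {
  IntegerVector d = dims3(vol);
  const int Z = d[0], Y = d[1], X = d[2];
  const int Zo = std::max(1, Z / 2), Yo = std::max(1, Y / 2), Xo = std::max(1, X / 2);
  NumericVector out((size_t)Zo * Yo * Xo);
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo);
  const size_t ZY = (size_t)Z * Y;
  size_t o = 0;
  for (int x = 0; x < Xo; ++x)
    for (int y = 0; y < Yo; ++y)
      for (int z = 0; z < Zo; ++z, ++o) {
        double s = 0; int cnt = 0;
        for (int dx = 0; dx < 2; ++dx) for (int dy = 0; dy < 2; ++dy) for (int dz = 0; dz < 2; ++dz) {
          int zz = 2 * z + dz, yy = 2 * y + dy, xx = 2 * x + dx;
          if (zz < Z && yy < Y && xx < X) { s += vol[(size_t)zz + (size_t)Z * yy + ZY * xx]; ++cnt; }
        }
        out[o] = s / cnt;
      }
  return out;
}

// 6-connected component labelling of a binary volume.
// [[Rcpp::export]]
IntegerVector label_components6(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int Z = d[0], Y = d[1], X = d[2];
  const size_t ZY = (size_t)Z * Y, nv = ZY * X;
  IntegerVector lab(nv);
  lab.attr("dim") = d;
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < nv; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear(); stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int x = (int)(p / ZY), r = (int)(p % ZY), y = r / Z, z = r % Z;
      const int dz[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dx[6] = {0,0,0,0,1,-1};
      for (int q = 0; q < 6; ++q) {
        int zz = z + dz[q], yy = y + dy[q], xx = x + dx[q];
        if (zz < 0 || yy < 0 || xx < 0 || zz >= Z || yy >= Y || xx >= X) continue;
        size_t pp = (size_t)zz + (size_t)Z * yy + ZY * xx;
        if (mask[pp] && !lab[pp]) { lab[pp] = next; stack.push_back(pp); }
      }
    }
  }
  return lab;
}

// Fill internal holes: background is flood-filled from the volume faces;
// anything neither foreground nor outside-background becomes foreground.
// [[Rcpp::export]]
IntegerVector fill_holes3d(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int Z = d[0], Y = d[1], X = d[2];
  const size_t ZY = (size_t)Z * Y, nv = ZY * X;
  std::vector<char> outside(nv, 0);
  std::vector<size_t> stack;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        if (z != 0 && z != Z - 1 && y != 0 && y != Y - 1 && x != 0 && x != X - 1) continue;
        size_t p = (size_t)z + (size_t)Z * y + ZY * x;
        if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  while (!stack.empty()) {
    size_t p = stack.back(); stack.pop_back();
    int x = (int)(p / ZY), r = (int)(p % ZY), y = r / Z, z = r % Z;
    const int dz[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dx[6] = {0,0,0,0,1,-1};
    for (int q = 0; q < 6; ++q) {
      int zz = z + dz[q], yy = y + dy[q], xx = x + dx[q];
      if (zz < 0 || yy < 0 || xx < 0 || zz >= Z || yy >= Y || xx >= X) continue;
      size_t pp = (size_t)zz + (size_t)Z * yy + ZY * xx;
      if (!mask[pp] && !outside[pp]) { outside[pp] = 1; stack.push_back(pp); }
    }
  }
  IntegerVector out(nv);
  out.attr("dim") = d;
  for (size_t p = 0; p < nv; ++p) out[p] = (mask[p] || !outside[p]) ? 1 : 0;
  return out;
}
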