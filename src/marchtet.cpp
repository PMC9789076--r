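// Iso-surface extraction by marching tetrahedra on a 3D scalar field.
// Each grid cell is split into 24 tetrahedra through its body centre and
// the 6 face centres; because shared faces are subdivided symmetrically via
// their face centre, the triangulation is consistent between neighbouring
// cells and the surface of a solid mask is watertight. Vertex coordinates
// are in 0-based grid units (corner (i,j,k) of the field at (i,j,k)).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct P3 { double x, y, z; };

static inline P3 lerp(const P3& a, const P3& b, double fa, double fb,
                      double iso) {
  double t = (fb == fa) ? 0.5 : (iso - fa) / (fb - fa);
  P3 p = { a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
           a.z + t * (b.z - a.z) };
  return p;
}

static void do_tet(const P3 v[4], const double f[4], double iso,
                   std::vector<double>& verts) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = f[i] > iso; nin += in[i]; }
  if (nin == 0 || nin == 4) return;
  int a[4], b[4], na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) (in[i] ? a[na++] : b[nb++]) = i;
  auto push = [&](const P3& p) {
    verts.push_back(p.x); verts.push_back(p.y); verts.push_back(p.z);
  };
  if (nin == 1 || nin == 3) {
    const int apex = (nin == 1) ? a[0] : b[0];
    const int* other = (nin == 1) ? b : a;
    for (int i = 0; i < 3; ++i)
      push(lerp(v[apex], v[other[i]], f[apex], f[other[i]], iso));
  } else {  // nin == 2: quad split into two triangles
    P3 p0 = lerp(v[a[0]], v[b[0]], f[a[0]], f[b[0]], iso);
    P3 p1 = lerp(v[a[0]], v[b[1]], f[a[0]], f[b[1]], iso);
    P3 p2 = lerp(v[a[1]], v[b[1]], f[a[1]], f[b[1]], iso);
    P3 p3 = lerp(v[a[1]], v[b[0]], f[a[1]], f[b[0]], iso);
    push(p0); push(p1); push(p2);
    push(p0); push(p2); push(p3);
  }
}

// [[Rcpp::export]]
List march_tetrahedra(const NumericVector& field, const IntegerVector& dims,
                      double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto F = [&](int i, int j, int k) -> double {
    return field[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  // corner order: bit 0 -> +x, bit 1 -> +y, bit 2 -> +z
  static const int face_corners[6][4] = {
    {0, 1, 3, 2}, {4, 5, 7, 6},   // z- and z+ faces
    {0, 1, 5, 4}, {2, 3, 7, 6},   // y- and y+
    {0, 2, 6, 4}, {1, 3, 7, 5} }; // x- and x+
  std::vector<double> verts;
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        P3 cp[8];
        double cf[8];
        double fmin = R_PosInf, fmax = R_NegInf;
        for (int c = 0; c < 8; ++c) {
          const int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          cp[c] = { (double)(i + dx), (double)(j + dy), (double)(k + dz) };
          cf[c] = F(i + dx, j + dy, k + dz);
          if (cf[c] < fmin) fmin = cf[c];
          if (cf[c] > fmax) fmax = cf[c];
        }
        if (fmin > iso || fmax <= iso) continue;
        P3 bc = { i + 0.5, j + 0.5, k + 0.5 };
        double bf = 0;
        for (int c = 0; c < 8; ++c) bf += cf[c] / 8.0;
        for (int fc = 0; fc < 6; ++fc) {
          P3 fp = { 0, 0, 0 };
          double ff = 0;
          for (int e = 0; e < 4; ++e) {
            const int c = face_corners[fc][e];
            fp.x += cp[c].x / 4.0; fp.y += cp[c].y / 4.0;
            fp.z += cp[c].z / 4.0; ff += cf[c] / 4.0;
          }
          for (int e = 0; e < 4; ++e) {
            const int c1 = face_corners[fc][e];
            const int c2 = face_corners[fc][(e + 1) % 4];
            const P3 tv[4] = { cp[c1], cp[c2], fp, bc };
            const double tf[4] = { cf[c1], cf[c2], ff, bf };
            do_tet(tv, tf, iso, verts);
          }
        }
      }
    }
  }
  const R_xlen_t ntri = verts.size() / 9;
  NumericMatrix V(ntri * 3, 3);
  IntegerMatrix Fc(ntri, 3);
  for (R_xlen_t t = 0; t < ntri * 3; ++t) {
    V(t, 0) = verts[3 * t];
    V(t, 1) = verts[3 * t + 1];
    V(t, 2) = verts[3 * t + 2];
  }
  for (R_xlen_t t = 0; t < ntri; ++t) {
    Fc(t, 0) = 3 * t + 1; Fc(t, 1) = 3 * t + 2; Fc(t, 2) = 3 * t + 3;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}
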