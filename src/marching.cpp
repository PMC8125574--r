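#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Marching tetrahedra over a regular grid of implicit-field samples.
// Each grid cube is split into six tetrahedra sharing the 0-7 diagonal;
// this decomposition tiles space consistently across cube faces, so the
// extracted surface is watertight (every edge shared by exactly two
// triangles) whenever the field is nonzero on the grid boundary.
// Inside is value < 0; surface vertices are placed by linear interpolation
// along crossing tetrahedron edges and deduplicated by grid-edge key.

static const int TET[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct VertexBank {
  std::unordered_map<int64_t, int> index;
  std::vector<double> xyz;
  // interpolated point on grid edge (ga, gb), values va, vb (opposite signs)
  int get(int64_t ga, int64_t gb, double va, double vb,
          const double* gx, const double* gy, const double* gz,
          int nx, int ny) {
    int64_t a = ga < gb ? ga : gb, b = ga < gb ? gb : ga;
    int64_t key = a * 2147483647LL + b;
    auto it = index.find(key);
    if (it != index.end()) return it->second;
    double t = va / (va - vb);
    if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
    int ax = (int)(ga % nx), ay = (int)((ga / nx) % ny), az = (int)(ga / ((int64_t)nx * ny));
    int bx = (int)(gb % nx), by = (int)((gb / nx) % ny), bz = (int)(gb / ((int64_t)nx * ny));
    double px = gx[ax] + t * (gx[bx] - gx[ax]);
    double py = gy[ay] + t * (gy[by] - gy[ay]);
    double pz = gz[az] + t * (gz[bz] - gz[az]);
    int id = (int)(xyz.size() / 3);
    xyz.push_back(px); xyz.push_back(py); xyz.push_back(pz);
    index.emplace(key, id);
    return id;
  }
  void point(int id, double* p) const {
    p[0] = xyz[3 * id]; p[1] = xyz[3 * id + 1]; p[2] = xyz[3 * id + 2];
  }
};

static inline void triNormal(const double* a, const double* b, const double* c,
                             double* n) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  n[0] = u[1] * v[2] - u[2] * v[1];
  n[1] = u[2] * v[0] - u[0] * v[2];
  n[2] = u[0] * v[1] - u[1] * v[0];
}

// emit triangle (i, j, k), flipping so the normal points toward `out`
static void emitTri(std::vector<int>& faces, const VertexBank& bank,
                    int i, int j, int k, const double* out) {
  double a[3], b[3], c[3], n[3];
  bank.point(i, a); bank.point(j, b); bank.point(k, c);
  triNormal(a, b, c, n);
  double cx = (a[0] + b[0] + c[0]) / 3.0, cy = (a[1] + b[1] + c[1]) / 3.0,
         cz = (a[2] + b[2] + c[2]) / 3.0;
  double d = n[0] * (out[0] - cx) + n[1] * (out[1] - cy) + n[2] * (out[2] - cz);
  if (d >= 0) { faces.push_back(i); faces.push_back(j); faces.push_back(k); }
  else        { faces.push_back(i); faces.push_back(k); faces.push_back(j); }
}

// [[Rcpp::export(name = ".marchingTets")]]
List marchingTets(NumericVector values, IntegerVector dims,
                  NumericVector gridX, NumericVector gridY, NumericVector gridZ) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((int64_t)nx * ny * nz != (int64_t)values.size())
    stop("values length does not match dims");
  const double* val = values.begin();
  const double* gx = gridX.begin();
  const double* gy = gridY.begin();
  const double* gz = gridZ.begin();

  VertexBank bank;
  std::vector<int> faces;
  faces.reserve(1 << 18);

  int64_t corner[8];
  double cval[8], cpos[8][3];
  for (int iz = 0; iz + 1 < nz; ++iz) {
    for (int iy = 0; iy + 1 < ny; ++iy) {
      int64_t base = (int64_t)nx * (iy + (int64_t)ny * iz);
      for (int ix = 0; ix + 1 < nx; ++ix) {
        bool anyNeg = false, anyPos = false;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          int64_t g = base + (ix + dx) + (int64_t)nx * (dy + (int64_t)ny * dz);
          corner[c] = g;
          double v = val[g];
          if (v == 0.0) v = 1e-12;  // treat exact zero as outside
          cval[c] = v;
          if (v < 0) anyNeg = true; else anyPos = true;
          cpos[c][0] = gx[ix + dx]; cpos[c][1] = gy[iy + dy]; cpos[c][2] = gz[iz + dz];
        }
        if (!anyNeg || !anyPos) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TET[t];
          int in[4], nin = 0, outv[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (cval[T[k]] < 0) in[nin++] = T[k]; else outv[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int A = in[0];
            int p1 = bank.get(corner[A], corner[outv[0]], cval[A], cval[outv[0]], gx, gy, gz, nx, ny);
            int p2 = bank.get(corner[A], corner[outv[1]], cval[A], cval[outv[1]], gx, gy, gz, nx, ny);
            int p3 = bank.get(corner[A], corner[outv[2]], cval[A], cval[outv[2]], gx, gy, gz, nx, ny);
            double ref[3] = {
              (cpos[outv[0]][0] + cpos[outv[1]][0] + cpos[outv[2]][0]) / 3.0,
              (cpos[outv[0]][1] + cpos[outv[1]][1] + cpos[outv[2]][1]) / 3.0,
              (cpos[outv[0]][2] + cpos[outv[1]][2] + cpos[outv[2]][2]) / 3.0};
            emitTri(faces, bank, p1, p2, p3, ref);
          } else if (nin == 3) {
            int D = outv[0];
            int p1 = bank.get(corner[D], corner[in[0]], cval[D], cval[in[0]], gx, gy, gz, nx, ny);
            int p2 = bank.get(corner[D], corner[in[1]], cval[D], cval[in[1]], gx, gy, gz, nx, ny);
            int p3 = bank.get(corner[D], corner[in[2]], cval[D], cval[in[2]], gx, gy, gz, nx, ny);
            emitTri(faces, bank, p1, p2, p3, cpos[D]);
          } else {  // nin == 2: quad ring (A-C, A-D, B-D, B-C)
            int A = in[0], B = in[1], C = outv[0], D = outv[1];
            int q0 = bank.get(corner[A], corner[C], cval[A], cval[C], gx, gy, gz, nx, ny);
            int q1 = bank.get(corner[A], corner[D], cval[A], cval[D], gx, gy, gz, nx, ny);
            int q2 = bank.get(corner[B], corner[D], cval[B], cval[D], gx, gy, gz, nx, ny);
            int q3 = bank.get(corner[B], corner[C], cval[B], cval[C], gx, gy, gz, nx, ny);
            double ref[3] = {(cpos[C][0] + cpos[D][0]) / 2.0,
                             (cpos[C][1] + cpos[D][1]) / 2.0,
                             (cpos[C][2] + cpos[D][2]) / 2.0};
            emitTri(faces, bank, q0, q1, q2, ref);
            emitTri(faces, bank, q0, q2, q3, ref);
          }
        }
      }
    }
  }

  int nV = (int)(bank.xyz.size() / 3);
  NumericMatrix V(nV, 3);
  for (int i = 0; i < nV; ++i) {
    V(i, 0) = bank.xyz[3 * i]; V(i, 1) = bank.xyz[3 * i + 1]; V(i, 2) = bank.xyz[3 * i + 2];
  }
  int nF = (int)(faces.size() / 3);
  IntegerMatrix F(nF, 3);
  for (int i = 0; i < nF; ++i) {
    F(i, 0) = faces[3 * i] + 1; F(i, 1) = faces[3 * i + 1] + 1; F(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
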