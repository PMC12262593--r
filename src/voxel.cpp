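// Voxel-level primitives for chromatin-domain analysis.
//
// Conventions: 3D arrays arrive as R arrays with dim = c(nz, ny, nx), i.e.
// column-major with z fastest; 2D masks are plain (nrow = y, ncol = x)
// matrices. Connectivity is 8-neighbourhood in 2D and its 3D analogue, the
// full 26-neighbourhood; hole filling floods the complement with the minimal
// (4- resp. 6-) connectivity so that diagonal "cracks" do not leak.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- 2D labels

// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) {
    if (!mask(y, x) || lab(y, x)) continue;
    ++next;
    stack.push_back(y + x * ny);
    lab(y, x) = next;
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int cy = idx % ny, cx = idx / ny;
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) {
        if (!dx && !dy) continue;
        int yy = cy + dy, xx = cx + dx;
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (mask(yy, xx) && !lab(yy, xx)) {
          lab(yy, xx) = next;
          stack.push_back(yy + xx * ny);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------- 3D labels

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int z = idx % nz, y = (idx / nz) % ny, x = idx / ((R_xlen_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                xx < 0 || xx >= nx) continue;
            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ------------------------------------------------------------- morphology

// the full 3x3(x3) cube structuring element is separable into per-axis
// 1D max filters
static void dilateLines(int *v, R_xlen_t nLines, R_xlen_t lineLen,
                        R_xlen_t stride, R_xlen_t lineStride) {
  std::vector<int> buf(lineLen);
  for (R_xlen_t l = 0; l < nLines; ++l) {
    int *base = v + l * lineStride;
    for (R_xlen_t i = 0; i < lineLen; ++i) {
      int a = base[i * stride];
      if (i > 0) a = a || base[(i - 1) * stride];
      if (i + 1 < lineLen) a = a || base[(i + 1) * stride];
      buf[i] = a;
    }
    for (R_xlen_t i = 0; i < lineLen; ++i) base[i * stride] = buf[i];
  }
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate2d(LogicalMatrix mask, int iterations) {
  int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix cur = clone(mask);
  int *v = LOGICAL(cur);
  for (int it = 0; it < iterations; ++it) {
    // along rows (stride 1, one line per column)
    for (int x = 0; x < nx; ++x)
      dilateLines(v + (R_xlen_t)x * ny, 1, ny, 1, 0);
    // along columns (stride ny, one line per row)
    for (int y = 0; y < ny; ++y)
      dilateLines(v + y, 1, nx, ny, 0);
  }
  return cur;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate3d(LogicalVector mask, IntegerVector dim,
                           int iterations) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector cur = clone(mask);
  int *v = LOGICAL(cur);
  R_xlen_t strideY = nz, strideX = (R_xlen_t)nz * ny;
  for (int it = 0; it < iterations; ++it) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)      // along z
        dilateLines(v + y * strideY + x * strideX, 1, nz, 1, 0);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z)      // along y
        dilateLines(v + z + x * strideX, 1, ny, strideY, 0);
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)      // along x
        dilateLines(v + z + y * strideY, 1, nx, strideX, 0);
  }
  cur.attr("dim") = dim;
  return cur;
}

// Hole filling: flood the complement from the image border (4-connectivity);
// anything unreachable is a hole and becomes foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill2d(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix outside(ny, nx);
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) {
    if ((y == 0 || y == ny - 1 || x == 0 || x == nx - 1) &&
        !mask(y, x) && !outside(y, x)) {
      outside(y, x) = true;
      stack.push_back(y + x * ny);
    }
  }
  const int dys[4] = {1, -1, 0, 0}, dxs[4] = {0, 0, 1, -1};
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int cy = idx % ny, cx = idx / ny;
    for (int k = 0; k < 4; ++k) {
      int yy = cy + dys[k], xx = cx + dxs[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      if (!mask(yy, xx) && !outside(yy, xx)) {
        outside(yy, xx) = true;
        stack.push_back(yy + xx * ny);
      }
    }
  }
  LogicalMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
    out(y, x) = !outside(y, x);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_fill3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector outside(n);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    int z = i % nz, y = (i / nz) % ny, x = i / ((R_xlen_t)nz * ny);
    bool border = z == 0 || z == nz - 1 || y == 0 || y == ny - 1 ||
                  x == 0 || x == nx - 1;
    if (border && !mask[i] && !outside[i]) { outside[i] = true; stack.push_back(i); }
  }
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t idx = stack.back(); stack.pop_back();
    int z = idx % nz, y = (idx / nz) % ny, x = idx / ((R_xlen_t)nz * ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!mask[j] && !outside[j]) { outside[j] = true; stack.push_back(j); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = !outside[i];
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------- contour perimeter

// Moore-neighbour boundary tracing with Jacob's stopping criterion; chain-code
// step lengths 1 (axial) and sqrt(2) (diagonal). Expects a single connected
// region; returns 0 for an empty mask and 4 (unit-square convention) for a
// single pixel.
// [[Rcpp::export]]
double cpp_perimeter(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  int sy = -1, sx = -1;
  for (int x = 0; x < nx && sy < 0; ++x)
    for (int y = 0; y < ny; ++y)
      if (mask(y, x)) { sy = y; sx = x; break; }
  if (sy < 0) return 0.0;
  // clockwise Moore neighbourhood starting west
  const int dys[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dxs[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double len[8] = {1, std::sqrt(2.0), 1, std::sqrt(2.0),
                         1, std::sqrt(2.0), 1, std::sqrt(2.0)};
  auto fg = [&](int y, int x) {
    return y >= 0 && y < ny && x >= 0 && x < nx && mask(y, x);
  };
  bool isolated = true;
  for (int k = 0; k < 8; ++k)
    if (fg(sy + dys[k], sx + dxs[k])) { isolated = false; break; }
  if (isolated) return 4.0;
  double per = 0.0;
  int cy = sy, cx = sx;
  int back = 0;          // search starts at the backtrack direction (west)
  int firstMove = -1;
  long guard = 0, maxSteps = 8L * (long)ny * (long)nx + 16;
  while (true) {
    int move = -1;
    for (int k = 0; k < 8; ++k) {
      int dir = (back + k) % 8;
      if (fg(cy + dys[dir], cx + dxs[dir])) { move = dir; break; }
    }
    if (move < 0) break;  // unreachable given the isolated-pixel check
    if (firstMove < 0) firstMove = move;
    else if (cy == sy && cx == sx && move == firstMove) break;
    per += len[move];
    cy += dys[move];
    cx += dxs[move];
    // backtrack: the direction pointing at the previous pixel, advanced one
    back = (move + 5) % 8;
    if (++guard > maxSteps) break;
  }
  return per;
}

// --------------------------------------- cross-correlation shift search

// Exhaustive search over integer corrections (dx, dy) applied to `mov`;
// Pearson correlation between ref[y, x] and mov[y - dy, x - dx] over the
// overlap. Candidates are visited in tie-break order (smallest |dx| + |dy|,
// then dy, then dx) so a strict ">" update implements the tie rule.
// [[Rcpp::export]]
List cpp_best_shift(NumericMatrix ref, NumericMatrix mov, int maxShift,
                    double minOverlapFrac) {
  int ny = ref.nrow(), nx = ref.ncol();
  struct Cand { int dy, dx; };
  std::vector<Cand> cands;
  for (int dy = -maxShift; dy <= maxShift; ++dy)
    for (int dx = -maxShift; dx <= maxShift; ++dx)
      cands.push_back({dy, dx});
  std::stable_sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    int sa = std::abs(a.dx) + std::abs(a.dy), sb = std::abs(b.dx) + std::abs(b.dy);
    if (sa != sb) return sa < sb;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dx < b.dx;
  });
  double best = R_NegInf;
  int bdy = 0, bdx = 0;
  long bestN = 0;
  bool any = false;
  double minN = minOverlapFrac * (double)ny * (double)nx;
  for (const Cand &c : cands) {
    int y0 = std::max(0, c.dy), y1 = std::min(ny, ny + c.dy);
    int x0 = std::max(0, c.dx), x1 = std::min(nx, nx + c.dx);
    long n = (long)(y1 - y0) * (long)(x1 - x0);
    if (n < 2 || n < minN) continue;
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    for (int x = x0; x < x1; ++x) {
      const double *ra = &ref(0, x);
      const double *rb = &mov(0, x - c.dx);
      for (int y = y0; y < y1; ++y) {
        double a = ra[y], b = rb[y - c.dy];
        sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      }
    }
    double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
    if (va <= 0 || vb <= 0) continue;
    double r = (sab - sa * sb / n) / std::sqrt(va * vb);
    if (r > best) { best = r; bdy = c.dy; bdx = c.dx; bestN = n; any = true; }
  }
  return List::create(_["dx"] = bdx, _["dy"] = bdy, _["corr"] = best,
                      _["n"] = (double)bestN, _["valid"] = any);
}

// ------------------------------------------------- isosurface mesh area

// 3x3x3 box-mean filter (zero outside); used to regularize a binary voxel
// field before meshing.
// [[Rcpp::export]]
NumericVector cpp_boxmean3(NumericVector field, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int z = i % nz, y = (i / nz) % ny, x = i / ((R_xlen_t)nz * ny);
    double s = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
              xx < 0 || xx >= nx) continue;
          s += field[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
        }
    out[i] = s / 27.0;
  }
  out.attr("dim") = dim;
  return out;
}

static inline double triArea(const double a[3], const double b[3],
                             const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w0 = u[1] * v[2] - u[2] * v[1];
  double w1 = u[2] * v[0] - u[0] * v[2];
  double w2 = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
}

// Marching tetrahedra: each grid cell is split into 6 tetrahedra around the
// main diagonal; the level surface is triangulated with linear interpolation
// along crossing edges, in physical (z, y, x) coordinates given by `spacing`.
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector field, IntegerVector dim,
                     NumericVector spacing, double level) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  // cube corner offsets (z, y, x)
  const int co[8][3] = {{0, 0, 0}, {0, 0, 1}, {0, 1, 1}, {0, 1, 0},
                        {1, 0, 0}, {1, 0, 1}, {1, 1, 1}, {1, 1, 0}};
  // 6 tetrahedra sharing the diagonal corner0 - corner6
  const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                          {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  double area = 0.0;
  double val[8], pos[8][3];
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        bool anyIn = false, anyOut = false;
        for (int k = 0; k < 8; ++k) {
          int zz = z + co[k][0], yy = y + co[k][1], xx = x + co[k][2];
          val[k] = field[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
          pos[k][0] = zz * sz; pos[k][1] = yy * sy; pos[k][2] = xx * sx;
          if (val[k] > level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int vid[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (val[vid[k]] > level) in[nin++] = vid[k];
            else out[nout++] = vid[k];
          }
          if (nin == 0 || nin == 4) continue;
          auto interp = [&](int a, int b, double p[3]) {
            double tt = (level - val[a]) / (val[b] - val[a]);
            for (int d = 0; d < 3; ++d)
              p[d] = pos[a][d] + tt * (pos[b][d] - pos[a][d]);
          };
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int *base = (nin == 1) ? out : in;
            double p0[3], p1[3], p2[3];
            interp(apex, base[0], p0);
            interp(apex, base[1], p1);
            interp(apex, base[2], p2);
            area += triArea(p0, p1, p2);
          } else {  // 2 in, 2 out -> quad
            double q0[3], q1[3], q2[3], q3[3];
            interp(in[0], out[0], q0);
            interp(in[0], out[1], q1);
            interp(in[1], out[1], q2);
            interp(in[1], out[0], q3);
            area += triArea(q0, q1, q2) + triArea(q0, q2, q3);
          }
        }
      }
  return area;
}
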