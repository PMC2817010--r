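#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-region primitives for binary voxel grids.
// Grids are logical arrays with a dim attribute of length 2 or 3;
// 2D inputs are treated as single-slice volumes, so connectivity 6
// degenerates to 4-connectivity and 26 to 8-connectivity in-plane.

static void get_dims(const LogicalVector &mask, int &nx, int &ny, int &nz) {
  RObject d = mask.attr("dim");
  if (d.isNULL()) stop("mask must be an array with a dim attribute");
  IntegerVector dims(d);
  if (dims.size() == 2) {
    nx = dims[0]; ny = dims[1]; nz = 1;
  } else if (dims.size() == 3) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
  } else {
    stop("mask must be a 2D or 3D array");
  }
}

// neighbour offsets for the requested connectivity (6 or 26)
static void build_offsets(int connectivity, std::vector<int> &dx,
                          std::vector<int> &dy, std::vector<int> &dz) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manhattan = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manhattan != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
}

// [[Rcpp::export(name = ".flood_fill_cc")]]
LogicalVector flood_fill_cc(LogicalVector mask, int seed_idx, int connectivity) {
  int nx, ny, nz;
  get_dims(mask, nx, ny, nz);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seed_idx < 1 || seed_idx > n) stop("seed index out of range");
  int s = seed_idx - 1;
  if (!mask[s]) stop("seed voxel is not inside the mask");

  std::vector<int> dx, dy, dz;
  build_offsets(connectivity, dx, dy, dz);
  int noff = (int)dx.size();

  LogicalVector out(n, false);
  out.attr("dim") = mask.attr("dim");
  std::vector<int> stack;
  stack.push_back(s);
  out[s] = true;
  int nxy = nx * ny;
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int z = idx / nxy, rem = idx % nxy, y = rem / nx, x = rem % nx;
    for (int k = 0; k < noff; ++k) {
      int X = x + dx[k], Y = y + dy[k], Z = z + dz[k];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      int j = X + nx * Y + nxy * Z;
      if (mask[j] && !out[j]) { out[j] = true; stack.push_back(j); }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".label_cc")]]
IntegerVector label_cc(LogicalVector mask, int connectivity) {
  int nx, ny, nz;
  get_dims(mask, nx, ny, nz);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> dx, dy, dz;
  build_offsets(connectivity, dx, dy, dz);
  int noff = (int)dx.size();
  int nxy = nx * ny;

  IntegerVector lab(n, 0);
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int z = idx / nxy, rem = idx % nxy, y = rem / nx, x = rem % nx;
      for (int k = 0; k < noff; ++k) {
        int X = x + dx[k], Y = y + dy[k], Z = z + dz[k];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int j = X + nx * Y + nxy * Z;
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}
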