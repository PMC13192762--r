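#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labeling of a 3D logical array.
// connectivity: 6 (face) or 26 (face+edge+corner). Returns an integer
// array of the same dim; background voxels are 0, components are
// numbered 1..k in raster-scan order of first occurrence.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector out(n, 0);

  // neighbour offsets strictly "before" the current voxel in raster order
  std::vector<int> dy, dx, dz;
  for (int z = -1; z <= 0; ++z)
    for (int x = -1; x <= 1; ++x)
      for (int y = -1; y <= 1; ++y) {
        if (z == 0 && (x > 0 || (x == 0 && y >= 0))) continue;
        int manh = std::abs(y) + std::abs(x) + std::abs(z);
        if (connectivity == 6 && manh != 1) continue;
        dy.push_back(y); dx.push_back(x); dz.push_back(z);
      }

  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // label 0 unused sentinel

  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)x * ny + y;
        if (!mask[idx]) continue;
        int lab = 0;
        for (size_t k = 0; k < dy.size(); ++k) {
          int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0) continue;
          R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)xx * ny + yy;
          int nl = out[nidx];
          if (nl > 0) {
            if (lab == 0) lab = nl;
            else uf_union(parent, lab, nl);
          }
        }
        if (lab == 0) {
          lab = (int)parent.size();
          parent.push_back(lab);
        }
        out[idx] = lab;
      }
    }
  }

  // flatten and renumber 1..k in first-occurrence order
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (out[i] == 0) continue;
    int r = uf_find(parent, out[i]);
    if (newlab[r] == 0) newlab[r] = ++next;
    out[i] = newlab[r];
  }
  out.attr("dim") = dims;
  return out;
}
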