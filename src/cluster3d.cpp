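#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a 3-D logical array under
// 6/18/26-connectivity, iterative flood fill.

static void neighbour_offsets(int conn, std::vector<std::array<int,3> > &off) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector arr, IntegerVector dim, int conn = 26) {
  if (conn != 6 && conn != 18 && conn != 26) stop("connectivity must be 6, 18 or 26");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nv = (long)nx * ny * nz;
  IntegerVector lab(nv, 0);
  std::vector<std::array<int,3> > off;
  neighbour_offsets(conn, off);
  std::vector<long> stack;
  int cur = 0;
  for (long s = 0; s < nv; ++s) {
    if (!arr[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((long)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        long w = xx + (long)nx * (yy + (long)ny * zz);
        if (arr[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = cur;
  return lab;
}

// Fast path for the Monte Carlo null simulation: size of the largest
// connected suprathreshold component.
// [[Rcpp::export(name = ".max_cluster_cpp")]]
int max_cluster_cpp(LogicalVector arr, IntegerVector dim, int conn = 26) {
  IntegerVector lab = label3d_cpp(arr, dim, conn);
  int ncomp = lab.attr("n_components");
  if (ncomp == 0) return 0;
  std::vector<int> sizes(ncomp + 1, 0);
  for (long i = 0; i < (long)lab.size(); ++i) if (lab[i]) ++sizes[lab[i]];
  int mx = 0;
  for (int c = 1; c <= ncomp; ++c) if (sizes[c] > mx) mx = sizes[c];
  return mx;
}
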