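// 3-D connected-component labeling on voxel grids (6/18/26 connectivity)
// and a batched max-cluster-size routine for Monte-Carlo extent simulation.

#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

static void make_neighbors(int connectivity, std::vector<std::array<int,3>>& nb) {
  nb.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        nb.push_back({dx, dy, dz});
      }
}

// Label connected components of a binary 3-D image (passed as a flat 0/1
// vector in column-major x-fastest order).  Labels are 1..n_clusters in
// scan order of the first voxel encountered; background is 0.
// [[Rcpp::export(name = ".label_clusters_cpp")]]
IntegerVector label_clusters_cpp(IntegerVector img, IntegerVector dims,
                                 int connectivity = 6) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz;
  std::vector<std::array<int,3>> nb;
  make_neighbors(connectivity, nb);
  IntegerVector lab(V, 0);
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < V; ++v) {
    if (!img[v] || lab[v]) continue;
    lab[v] = ++next;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
      for (auto& o : nb) {
        int xo = x + o[0], yo = y + o[1], zo = z + o[2];
        if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz) continue;
        int w = xo + nx * (yo + ny * zo);
        if (img[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Max cluster size for each column of a V x nsim binary matrix (each column
// one simulated suprathreshold map on the same grid).
// [[Rcpp::export(name = ".max_cluster_batch_cpp")]]
IntegerVector max_cluster_batch_cpp(LogicalMatrix maps, IntegerVector dims,
                                    int connectivity = 6) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz, nsim = maps.ncol();
  std::vector<std::array<int,3>> nb;
  make_neighbors(connectivity, nb);
  IntegerVector out(nsim, 0);
  std::vector<int> lab(V), stack;
  for (int s = 0; s < nsim; ++s) {
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
    std::fill(lab.begin(), lab.end(), 0);
    int best = 0;
    for (int v = 0; v < V; ++v) {
      if (!maps(v, s) || lab[v]) continue;
      int size = 1;
      lab[v] = 1;
      stack.clear();
      stack.push_back(v);
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
        for (auto& o : nb) {
          int xo = x + o[0], yo = y + o[1], zo = z + o[2];
          if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz) continue;
          int w = xo + nx * (yo + ny * zo);
          if (maps(w, s) && !lab[w]) { lab[w] = 1; stack.push_back(w); ++size; }
        }
      }
      if (size > best) best = size;
    }
    out[s] = best;
  }
  return out;
}
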