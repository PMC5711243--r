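#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected component of a thresholded voxel set containing a seed.
// `pass` is the predicate array (already thresholded), column-major 3D.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(LogicalVector pass, IntegerVector dims,
                              IntegerVector seed0, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<char> visited((size_t)n, 0);

  auto idx = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };

  const R_xlen_t s = idx(seed0[0], seed0[1], seed0[2]);
  if (!pass[s]) return out;  // caller raises the seed error

  std::queue<std::array<int, 3>> q;
  q.push({seed0[0], seed0[1], seed0[2]});
  visited[(size_t)s] = 1;
  out[s] = TRUE;

  const bool full = (connectivity == 26);
  while (!q.empty()) {
    auto v = q.front(); q.pop();
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
          if (manh == 0) continue;
          if (!full && manh != 1) continue;
          int i = v[0] + di, j = v[1] + dj, k = v[2] + dk;
          if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
            continue;
          R_xlen_t t = idx(i, j, k);
          if (visited[(size_t)t] || !pass[t]) continue;
          visited[(size_t)t] = 1;
          out[t] = TRUE;
          q.push({i, j, k});
        }
  }
  return out;
}
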