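#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra: each grid cell is split
// into six tetrahedra around its main diagonal; every tetrahedron crossed
// by the iso level contributes one or two triangles with vertices linearly
// interpolated along crossing edges.  Interpolated vertices are shared via
// a global-edge key, so the resulting surface of a bounded region is
// watertight (every edge borders exactly two faces).
//
// field: column-major 3D double array; vertices returned in continuous
// 0-based voxel-index coordinates.

struct MeshAccum {
  std::map<std::pair<R_xlen_t, R_xlen_t>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

// [[Rcpp::export(name = ".marching_tetrahedra_cpp")]]
List marching_tetrahedra_cpp(NumericVector field, IntegerVector dims,
                             double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };

  MeshAccum M;

  // cube corner offsets, binary order (x fastest)
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  // six tetrahedra sharing diagonal corner0 - corner7
  static const int tets[6][4] = {
    {0,5,1,7},{0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7}
  };

  auto edge_point = [&](R_xlen_t ga, R_xlen_t gb, double va, double vb,
                        const double pa[3], const double pb[3]) -> int {
    std::pair<R_xlen_t, R_xlen_t> key = (ga < gb)
      ? std::make_pair(ga, gb) : std::make_pair(gb, ga);
    auto it = M.edge_vertex.find(key);
    if (it != M.edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    M.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    M.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    M.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)M.vx.size();  // 1-based
    M.edge_vertex[key] = id;
    return id;
  };

  double cv[8]; double cp[8][3]; R_xlen_t cg[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          cg[c] = gid(ii, jj, kk);
          cv[c] = field[cg[c]];
          cp[c][0] = ii; cp[c][1] = jj; cp[c][2] = kk;
          (cv[c] >= iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[T[c]] >= iso) in[nin++] = T[c];
            else out[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int *others = (nin == 1) ? out : in;
            int e[3];
            for (int c = 0; c < 3; ++c)
              e[c] = edge_point(cg[apex], cg[others[c]], cv[apex],
                                cv[others[c]], cp[apex], cp[others[c]]);
            M.f0.push_back(e[0]); M.f1.push_back(e[1]); M.f2.push_back(e[2]);
          } else {  // nin == 2: quad split into two triangles
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int eac = edge_point(cg[a], cg[c], cv[a], cv[c], cp[a], cp[c]);
            int ead = edge_point(cg[a], cg[d], cv[a], cv[d], cp[a], cp[d]);
            int ebd = edge_point(cg[b], cg[d], cv[b], cv[d], cp[b], cp[d]);
            int ebc = edge_point(cg[b], cg[c], cv[b], cv[c], cp[b], cp[c]);
            M.f0.push_back(eac); M.f1.push_back(ead); M.f2.push_back(ebd);
            M.f0.push_back(eac); M.f1.push_back(ebd); M.f2.push_back(ebc);
          }
        }
      }

  int nv = (int)M.vx.size(), nf = (int)M.f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = M.vx[v]; V(v, 1) = M.vy[v]; V(v, 2) = M.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = M.f0[f]; F(f, 1) = M.f1[f]; F(f, 2) = M.f2[f];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
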