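#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Regular-grid two-probe solvent-excluded volume machinery.
//
// Grid flags are built per probe:
//   viable[v]   : a probe centre can sit at v (no atom within vdW + probe)
//   exterior[v] : viable and flood-fill-connected (6-neighbourhood) to the
//                 box boundary
// The solvent-excluded region for a probe is the complement of the union of
// probe spheres centred on the chosen centre set (all viable centres, or
// exterior-connected centres only).

struct Grid {
  int nx, ny, nz;
  double x0, y0, z0, h;
  size_t size() const { return (size_t)nx * ny * nz; }
  inline size_t idx(int i, int j, int k) const {
    return ((size_t)k * ny + j) * nx + i;
  }
};

// mark grid points within (radius[a] + extra) of any atom
static void mark_atoms(const Grid &g, const NumericMatrix &xyz,
                       const NumericVector &radius, double extra,
                       std::vector<char> &occ) {
  int na = xyz.nrow();
  for (int a = 0; a < na; ++a) {
    double r = radius[a] + extra;
    double r2 = r * r;
    double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int i0 = std::max(0, (int)std::floor((ax - r - g.x0) / g.h));
    int i1 = std::min(g.nx - 1, (int)std::ceil((ax + r - g.x0) / g.h));
    int j0 = std::max(0, (int)std::floor((ay - r - g.y0) / g.h));
    int j1 = std::min(g.ny - 1, (int)std::ceil((ay + r - g.y0) / g.h));
    int k0 = std::max(0, (int)std::floor((az - r - g.z0) / g.h));
    int k1 = std::min(g.nz - 1, (int)std::ceil((az + r - g.z0) / g.h));
    for (int k = k0; k <= k1; ++k) {
      double dz = g.z0 + k * g.h - az;
      for (int j = j0; j <= j1; ++j) {
        double dy = g.y0 + j * g.h - ay;
        double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = g.x0 + i * g.h - ax;
          if (dx * dx + dyz2 <= r2) occ[g.idx(i, j, k)] = 1;
        }
      }
    }
  }
}

// BFS flood fill of 'free' voxels (occ == 0) from the box boundary
static void flood_exterior(const Grid &g, const std::vector<char> &occ,
                           std::vector<char> &ext) {
  std::queue<size_t> q;
  auto push = [&](int i, int j, int k) {
    size_t v = g.idx(i, j, k);
    if (!occ[v] && !ext[v]) { ext[v] = 1; q.push(v); }
  };
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i) { push(i, j, 0); push(i, j, g.nz - 1); }
  for (int k = 0; k < g.nz; ++k)
    for (int i = 0; i < g.nx; ++i) { push(i, 0, k); push(i, g.ny - 1, k); }
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j) { push(0, j, k); push(g.nx - 1, j, k); }
  while (!q.empty()) {
    size_t v = q.front(); q.pop();
    int i = v % g.nx, j = (v / g.nx) % g.ny, k = v / ((size_t)g.nx * g.ny);
    if (i > 0) push(i - 1, j, k);
    if (i < g.nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < g.ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < g.nz - 1) push(i, j, k + 1);
  }
}

// mark the union of spheres of radius rp centred on centres[v] == 1;
// the union over a solid voxel set equals the set itself plus the balls
// around its surface voxels, so only surface centres are expanded
static void dilate(const Grid &g, const std::vector<char> &centres,
                   double rp, std::vector<char> &covered) {
  // pad the ball radius by a third of a voxel: a discrete sphere whose
  // boundary voxels must have centres inside rp systematically
  // undershoots the nominal radius; h/3 compensates the mean radial
  // quantization so the effective reach is rp on average
  double rpad = rp + g.h / 3.0;
  int rr = (int)std::ceil(rpad / g.h);
  double rp2 = rpad * rpad;
  std::vector<int> di, dj, dk;
  for (int k = -rr; k <= rr; ++k)
    for (int j = -rr; j <= rr; ++j)
      for (int i = -rr; i <= rr; ++i)
        if ((double)(i * i + j * j + k * k) * g.h * g.h <= rp2) {
          di.push_back(i); dj.push_back(j); dk.push_back(k);
        }
  size_t nb = di.size();
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        size_t v = g.idx(i, j, k);
        if (!centres[v]) continue;
        covered[v] = 1;
        bool surface = (i == 0 || j == 0 || k == 0 || i == g.nx - 1 ||
                        j == g.ny - 1 || k == g.nz - 1) ||
          !centres[g.idx(i - 1, j, k)] || !centres[g.idx(i + 1, j, k)] ||
          !centres[g.idx(i, j - 1, k)] || !centres[g.idx(i, j + 1, k)] ||
          !centres[g.idx(i, j, k - 1)] || !centres[g.idx(i, j, k + 1)];
        if (!surface) continue;
        for (size_t b = 0; b < nb; ++b) {
          int ii = i + di[b], jj = j + dj[b], kk = k + dk[b];
          if (ii < 0 || jj < 0 || kk < 0 ||
              ii >= g.nx || jj >= g.ny || kk >= g.nz) continue;
          covered[g.idx(ii, jj, kk)] = 1;
        }
      }
}

// label 6-connected components of mask; returns component id per voxel
// (0 = not in mask), component voxel counts, and whether each touches the
// box boundary
static int label_components(const Grid &g, const std::vector<char> &mask,
                            std::vector<int> &lab,
                            std::vector<size_t> &counts,
                            std::vector<char> &touches) {
  int ncomp = 0;
  for (size_t s = 0; s < g.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++ncomp;
    counts.push_back(0);
    touches.push_back(0);
    std::queue<size_t> q;
    lab[s] = ncomp; q.push(s);
    while (!q.empty()) {
      size_t v = q.front(); q.pop();
      ++counts[ncomp - 1];
      int i = v % g.nx, j = (v / g.nx) % g.ny, k = v / ((size_t)g.nx * g.ny);
      if (i == 0 || j == 0 || k == 0 || i == g.nx - 1 || j == g.ny - 1 ||
          k == g.nz - 1)
        touches[ncomp - 1] = 1;
      const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int t = 0; t < 6; ++t) {
        int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
        if (ii < 0 || jj < 0 || kk < 0 ||
            ii >= g.nx || jj >= g.ny || kk >= g.nz) continue;
        size_t w = g.idx(ii, jj, kk);
        if (mask[w] && !lab[w]) { lab[w] = ncomp; q.push(w); }
      }
    }
  }
  return ncomp;
}

//' @noRd
// [[Rcpp::export(name = ".cavity_grid_cpp")]]
List cavity_grid_cpp(NumericMatrix xyz, NumericVector radius,
                     double small_probe, double large_probe,
                     double spacing) {
  int na = xyz.nrow();
  if (na < 1) stop("no atoms");
  double margin = large_probe + 2.0 * spacing;
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  double rmax = 0.0;
  for (int a = 0; a < na; ++a) {
    xmin = std::min(xmin, xyz(a, 0)); xmax = std::max(xmax, xyz(a, 0));
    ymin = std::min(ymin, xyz(a, 1)); ymax = std::max(ymax, xyz(a, 1));
    zmin = std::min(zmin, xyz(a, 2)); zmax = std::max(zmax, xyz(a, 2));
    rmax = std::max(rmax, (double)radius[a]);
  }
  margin += rmax;
  Grid g;
  g.h = spacing;
  g.x0 = xmin - margin; g.y0 = ymin - margin; g.z0 = zmin - margin;
  g.nx = (int)std::ceil((xmax + margin - g.x0) / spacing) + 1;
  g.ny = (int)std::ceil((ymax + margin - g.y0) / spacing) + 1;
  g.nz = (int)std::ceil((zmax + margin - g.z0) / spacing) + 1;
  if (g.size() > (size_t)5e8) stop("grid too large; increase spacing");

  double voxel = spacing * spacing * spacing;

  // ---- large probe: accessibility-limited solvent-excluded region ----
  std::vector<char> forb_L(g.size(), 0);
  mark_atoms(g, xyz, radius, large_probe, forb_L);
  std::vector<char> ext_L(g.size(), 0);
  flood_exterior(g, forb_L, ext_L); // exterior-connected viable centres
  std::vector<char> cov_L(g.size(), 0);
  dilate(g, ext_L, large_probe, cov_L); // solvent region reachable from out

  // ---- small probe: fit-anywhere solvent-excluded region (molecule) ----
  std::vector<char> forb_S(g.size(), 0);
  mark_atoms(g, xyz, radius, small_probe, forb_S);
  std::vector<char> viable_S(g.size(), 0);
  for (size_t v = 0; v < g.size(); ++v) viable_S[v] = !forb_S[v];
  std::vector<char> cov_S(g.size(), 0);
  dilate(g, viable_S, small_probe, cov_S);

  size_t nexcl_L = 0, nexcl_S = 0;
  std::vector<char> cav(g.size(), 0);
  for (size_t v = 0; v < g.size(); ++v) {
    bool eL = !cov_L[v], eS = !cov_S[v];
    if (eL) ++nexcl_L;
    if (eS) ++nexcl_S;
    cav[v] = eL && !eS;
  }

  std::vector<int> lab(g.size(), 0);
  std::vector<size_t> counts;
  std::vector<char> touches;
  int ncomp = label_components(g, cav, lab, counts, touches);

  // components touching the boundary are artefacts of the box, not cavity
  std::vector<double> compvol;
  double total = 0.0;
  std::vector<char> keep(ncomp, 0);
  for (int c = 0; c < ncomp; ++c) {
    if (touches[c]) continue;
    keep[c] = 1;
    double vol = counts[c] * voxel;
    compvol.push_back(vol);
    total += vol;
  }

  // centre coordinates of cavity voxels (kept components), for inspection
  size_t ncav = 0;
  for (size_t v = 0; v < g.size(); ++v)
    if (lab[v] && keep[lab[v] - 1]) ++ncav;
  NumericMatrix pts(ncav, 3);
  size_t row = 0;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        size_t v = g.idx(i, j, k);
        if (lab[v] && keep[lab[v] - 1]) {
          pts(row, 0) = g.x0 + i * g.h;
          pts(row, 1) = g.y0 + j * g.h;
          pts(row, 2) = g.z0 + k * g.h;
          ++row;
        }
      }

  return List::create(
    _["cavity_volume"] = total,
    _["component_volumes"] = NumericVector(compvol.begin(), compvol.end()),
    _["excluded_volume_large"] = nexcl_L * voxel,
    _["excluded_volume_small"] = nexcl_S * voxel,
    _["cavity_points"] = pts,
    _["grid_dim"] = IntegerVector::create(g.nx, g.ny, g.nz));
}
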