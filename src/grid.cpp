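#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Grid label codes shared with the R side:
//   0 solvent, 1 protein, 2 pocket, 3 deep pocket
// Linear index convention: idx = i + nx*(j + ny*k), 0-based here,
// 1-based after return to R.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
IntegerVector grid_classify_cpp(NumericMatrix coords, NumericVector radii,
                                NumericVector origin, double spacing,
                                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(nx * ny * nz, 0);
  const int na = coords.nrow();
  for (int a = 0; a < na; ++a) {
    const double r = radii[a];
    const double r2 = r * r;
    const double ax = coords(a, 0) - origin[0];
    const double ay = coords(a, 1) - origin[1];
    const double az = coords(a, 2) - origin[2];
    const int i0 = std::max(0, (int)std::ceil((ax - r) / spacing));
    const int i1 = std::min(nx - 1, (int)std::floor((ax + r) / spacing));
    const int j0 = std::max(0, (int)std::ceil((ay - r) / spacing));
    const int j1 = std::min(ny - 1, (int)std::floor((ay + r) / spacing));
    const int k0 = std::max(0, (int)std::ceil((az - r) / spacing));
    const int k1 = std::min(nz - 1, (int)std::floor((az + r) / spacing));
    for (int k = k0; k <= k1; ++k) {
      const double dz = k * spacing - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = j * spacing - ay;
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = i * spacing - ax;
          if (dx * dx + dyz <= r2) lab[lin(i, j, k, nx, ny)] = 1;
        }
      }
    }
  }
  return lab;
}

// Ligsite-style scan: along each lattice direction, maximal runs of
// non-protein points bounded by protein points at both ends increment a
// per-point bounded count; solvent points reaching min_bounded become pocket.
// [[Rcpp::export]]
IntegerVector grid_mark_cpp(IntegerVector labels, IntegerVector dims,
                            IntegerMatrix dirs, int min_bounded) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> cnt(n, 0);
  std::vector<int> run;
  for (int d = 0; d < dirs.nrow(); ++d) {
    const int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          // start only at line entry points (predecessor outside the grid)
          const int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 && pk < nz)
            continue;
          int ci = i, cj = j, ck = k;
          bool left_bounded = false;
          run.clear();
          while (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 && ck < nz) {
            const int idx = lin(ci, cj, ck, nx, ny);
            if (labels[idx] == 1) {
              if (left_bounded)
                for (size_t q = 0; q < run.size(); ++q) cnt[run[q]]++;
              run.clear();
              left_bounded = true;
            } else if (left_bounded) {
              run.push_back(idx);
            }
            ci += dx; cj += dy; ck += dz;
          }
          // trailing run not bounded on the right: discarded
        }
      }
    }
  }
  IntegerVector out = clone(labels);
  for (int idx = 0; idx < n; ++idx)
    if (out[idx] == 0 && cnt[idx] >= min_bounded) out[idx] = 2;
  return out;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of every grid point to the nearest solvent-labeled point, in Å.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n,
                   std::vector<int>& v, std::vector<double>& z) {
  // lower envelope of parabolas over the finite sites only
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INFINITY; z[1] = INFINITY;
      continue;
    }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;  // cannot underflow: z[0] = -inf and s is finite
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  if (k < 0) {  // no finite site on this line
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector grid_solvent_dist_cpp(IntegerVector labels, IntegerVector dims,
                                    double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> d2(n);
  for (int idx = 0; idx < n; ++idx)
    d2[idx] = (labels[idx] == 0) ? 0.0 : INFINITY;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d2[lin(i, j, k, nx, ny)];
      edt_1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) d2[lin(i, j, k, nx, ny)] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d2[lin(i, j, k, nx, ny)];
      edt_1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) d2[lin(i, j, k, nx, ny)] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d2[lin(i, j, k, nx, ny)];
      edt_1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) d2[lin(i, j, k, nx, ny)] = d[k];
    }
  NumericVector out(n);
  for (int idx = 0; idx < n; ++idx)
    out[idx] = (d2[idx] == INFINITY) ? R_PosInf : std::sqrt(d2[idx]) * spacing;
  return out;
}

// Connected components of pocket/deep points under 26-neighbour adjacency.
// Component ids are assigned in order of the smallest member linear index.
// [[Rcpp::export]]
IntegerVector grid_components_cpp(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector comp(n, 0);
  int next_id = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (labels[start] < 2 || comp[start] != 0) continue;
    ++next_id;
    comp[start] = next_id;
    q.push(start);
    while (!q.empty()) {
      const int idx = q.front(); q.pop();
      const int i = idx % nx;
      const int j = (idx / nx) % ny;
      const int k = idx / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const int nb = lin(ii, jj, kk, nx, ny);
            if (labels[nb] >= 2 && comp[nb] == 0) {
              comp[nb] = next_id;
              q.push(nb);
            }
          }
    }
  }
  return comp;
}

// One-shot deep-volume evaluation used inside the Monte Carlo sampler:
// classify -> mark -> deep -> components -> target-contact filter.
// Returns total deep volume (Å^3) over clusters contacting the target atoms.
// [[Rcpp::export]]
double deep_volume_cpp(NumericMatrix coords, NumericVector radii,
                       NumericMatrix target_coords, NumericVector target_radii,
                       NumericVector origin, double spacing, IntegerVector dims,
                       IntegerMatrix dirs, int min_bounded, double burial,
                       double contact_tol) {
  IntegerVector lab = grid_classify_cpp(coords, radii, origin, spacing, dims);
  lab = grid_mark_cpp(lab, dims, dirs, min_bounded);
  const int n = lab.size();
  // deep test by direct ball scan around each pocket point (equivalent to
  // the exact distance transform for the strict burial threshold)
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int rmax = (int)std::floor(burial / spacing);
  const double b2 = (burial / spacing) * (burial / spacing);
  std::vector<int> off;
  for (int dk = -rmax; dk <= rmax; ++dk)
    for (int dj = -rmax; dj <= rmax; ++dj)
      for (int di = -rmax; di <= rmax; ++di)
        if ((double)(di * di + dj * dj + dk * dk) <= b2) {
          off.push_back(di); off.push_back(dj); off.push_back(dk);
        }
  for (int idx = 0; idx < n; ++idx) {
    if (lab[idx] != 2) continue;
    const int i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
    bool near_solvent = false;
    for (size_t q = 0; q < off.size(); q += 3) {
      const int ii = i + off[q], jj = j + off[q + 1], kk = k + off[q + 2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      if (lab[lin(ii, jj, kk, nx, ny)] == 0) { near_solvent = true; break; }
    }
    if (!near_solvent) lab[idx] = 3;
  }
  IntegerVector comp = grid_components_cpp(lab, dims);
  int ncomp = 0;
  for (int idx = 0; idx < n; ++idx) ncomp = std::max(ncomp, (int)comp[idx]);
  if (ncomp == 0) return 0.0;
  std::vector<bool> contact(ncomp + 1, false);
  std::vector<int> deep_count(ncomp + 1, 0);
  const int nt = target_coords.nrow();
  for (int idx = 0; idx < n; ++idx) {
    const int c = comp[idx];
    if (c == 0) continue;
    if (lab[idx] == 3) deep_count[c]++;
    if (!contact[c]) {
      const double px = origin[0] + (idx % nx) * spacing;
      const double py = origin[1] + ((idx / nx) % ny) * spacing;
      const double pz = origin[2] + (idx / (nx * ny)) * spacing;
      for (int t = 0; t < nt; ++t) {
        const double thr = target_radii[t] + contact_tol;
        const double dx = px - target_coords(t, 0);
        const double dy = py - target_coords(t, 1);
        const double dz = pz - target_coords(t, 2);
        if (dx * dx + dy * dy + dz * dz <= thr * thr) { contact[c] = true; break; }
      }
    }
  }
  double vol = 0.0;
  const double cell = spacing * spacing * spacing;
  for (int c = 1; c <= ncomp; ++c)
    if (contact[c]) vol += deep_count[c] * cell;
  return vol;
}
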