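#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Neighbor shells on the cubic lattice. Order 1 = 6 face neighbors; order 2
// adds the 12 edge neighbors (18 total). Contact energy counts each unordered
// voxel pair once, so total-energy loops use only the "positive" half-shell.
static const int OFF1[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};
static const int OFF2[18][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},
  {1,1,0},{1,-1,0},{-1,1,0},{-1,-1,0},
  {1,0,1},{1,0,-1},{-1,0,1},{-1,0,-1},
  {0,1,1},{0,1,-1},{0,-1,1},{0,-1,-1}
};
static const int HALF1[3][3] = { {1,0,0},{0,1,0},{0,0,1} };
static const int HALF2[9][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1}
};

static inline const int (*shell(int order, int &n))[3] {
  if (order == 2) { n = 18; return OFF2; }
  n = 6; return OFF1;
}
static inline const int (*half_shell(int order, int &n))[3] {
  if (order == 2) { n = 9; return HALF2; }
  n = 3; return HALF1;
}

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Contact + area-constraint energy change for copying candidate_id onto the
// voxel at (x,y,z). All id-indexed vectors are padded so element [id] is the
// record for cell id (element [0] = medium).
static double delta_energy_site(const int *spin, int nx, int ny, int nz,
                                const int *kind_of, const NumericMatrix &J,
                                double lam, const double *target,
                                const int *area, int x, int y, int z,
                                int cand, int order) {
  int cur = spin[vidx(x, y, z, nx, ny)];
  if (cand == cur) return 0.0;
  int n_off; const int (*off)[3] = shell(order, n_off);
  int kc = kind_of[cur], kn = kind_of[cand];
  double de = 0.0;
  for (int i = 0; i < n_off; ++i) {
    int xx = x + off[i][0], yy = y + off[i][1], zz = z + off[i][2];
    if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
      continue;
    int nid = spin[vidx(xx, yy, zz, nx, ny)];
    int kk = kind_of[nid];
    if (nid != cur)  de -= J(kc, kk);
    if (nid != cand) de += J(kn, kk);
  }
  if (cur > 0) {
    double d = (double)area[cur] - target[cur];
    de += lam * ((d - 1.0) * (d - 1.0) - d * d);
  }
  if (cand > 0) {
    double d = (double)area[cand] - target[cand];
    de += lam * ((d + 1.0) * (d + 1.0) - d * d);
  }
  return de;
}

// [[Rcpp::export]]
double cpp_delta_energy(IntegerVector spin, IntegerVector dims,
                        IntegerVector kind_of, NumericMatrix J, double lam,
                        NumericVector target, IntegerVector area,
                        IntegerVector site, int candidate_id, int order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  return delta_energy_site(spin.begin(), nx, ny, nz, kind_of.begin(), J, lam,
                           target.begin(), area.begin(),
                           site[0] - 1, site[1] - 1, site[2] - 1,
                           candidate_id, order);
}

// [[Rcpp::export]]
double cpp_total_energy(IntegerVector spin, IntegerVector dims,
                        IntegerVector kind_of, NumericMatrix J, double lam,
                        NumericVector target, IntegerVector area, int order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n_off; const int (*off)[3] = half_shell(order, n_off);
  const int *sp = spin.begin();
  const int *kind = kind_of.begin();
  double e = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = sp[vidx(x, y, z, nx, ny)];
        for (int i = 0; i < n_off; ++i) {
          int xx = x + off[i][0], yy = y + off[i][1], zz = z + off[i][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int b = sp[vidx(xx, yy, zz, nx, ny)];
          if (a != b) e += J(kind[a], kind[b]);
        }
      }
  int max_id = area.size() - 1;
  for (int id = 1; id <= max_id; ++id) {
    if (area[id] < 0) continue;  // id not in use
    double d = (double)area[id] - target[id];
    e += lam * d * d;
  }
  return e;
}

static inline bool metro_accept(double de, double temperature) {
  if (de <= 0.0) return true;
  return unif_rand() < std::exp(-de / temperature);
}

// One Monte Carlo step: nx*ny*nz copy attempts. spin and area are modified
// in place (callers wanting value semantics clone first). Returns the number
// of accepted flips. Uses R's RNG so runs are reproducible via set.seed().
// [[Rcpp::export]]
int cpp_mcs_inplace(IntegerVector spin, IntegerVector dims,
                    IntegerVector kind_of, NumericMatrix J, double lam,
                    NumericVector target, IntegerVector area,
                    double temperature, int order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n_vox = (R_xlen_t)nx * ny * nz;
  int n_off; const int (*off)[3] = shell(order, n_off);
  int *sp = spin.begin();
  int *ar = area.begin();
  int accepted = 0;
  for (R_xlen_t att = 0; att < n_vox; ++att) {
    R_xlen_t v = (R_xlen_t)(unif_rand() * n_vox);
    if (v >= n_vox) v = n_vox - 1;
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    int k = (int)(unif_rand() * n_off);
    if (k >= n_off) k = n_off - 1;
    int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
    if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
      continue;  // fixed walls: attempts never cross the boundary
    int cur = sp[v];
    int cand = sp[vidx(xx, yy, zz, nx, ny)];
    if (cand == cur) continue;
    if (cur > 0 && ar[cur] <= 1) continue;  // cells may not vanish
    double de = delta_energy_site(sp, nx, ny, nz, kind_of.begin(), J, lam,
                                  target.begin(), ar, x, y, z, cand, order);
    if (metro_accept(de, temperature)) {
      sp[v] = cand;
      if (cur > 0) --ar[cur];
      if (cand > 0) ++ar[cand];
      ++accepted;
    }
  }
  return accepted;
}

// Shared-rule helper: how many of n proposals at fixed dE are accepted.
// [[Rcpp::export]]
int cpp_metropolis_accept(int n, double de, double temperature) {
  int acc = 0;
  for (int i = 0; i < n; ++i)
    if (metro_accept(de, temperature)) ++acc;
  return acc;
}

// One MCS of the alpha field, in place: `substeps` explicit diffusion
// substeps (6-point stencil, zero-flux boundaries), then decay by (1 - mu),
// then secretion of s onto source voxels.
// [[Rcpp::export]]
void cpp_field_step_inplace(NumericVector conc, IntegerVector dims,
                            LogicalVector source, double D, double mu,
                            double s, int substeps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n_vox = (R_xlen_t)nx * ny * nz;
  double *c = conc.begin();
  double alpha = D / (double)substeps;
  if (alpha > 0.0) {
    // Ghost-cell padding: mirroring the edge value into the ghost layer makes
    // the zero-flux boundary term vanish, so the interior update is
    // branch-free.
    int px = nx + 2, py = ny + 2, pz = nz + 2;
    R_xlen_t pxy = (R_xlen_t)px * py;
    std::vector<double> a((R_xlen_t)px * py * pz), b((R_xlen_t)px * py * pz);
    double *cur = a.data(), *nxt = b.data();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        std::copy(c + vidx(0, y, z, nx, ny), c + vidx(0, y, z, nx, ny) + nx,
                  cur + 1 + px * (y + 1) + pxy * (z + 1));
    for (int stp = 0; stp < substeps; ++stp) {
      // refresh ghost faces (zero-flux mirror)
      for (int z = 1; z <= nz; ++z)
        for (int y = 1; y <= ny; ++y) {
          double *row = cur + px * y + pxy * z;
          row[0] = row[1];
          row[nx + 1] = row[nx];
        }
      for (int z = 1; z <= nz; ++z) {
        double *pl = cur + pxy * z;
        std::copy(pl + px, pl + px + px, pl);
        std::copy(pl + px * ny, pl + px * ny + px, pl + px * (ny + 1));
      }
      std::copy(cur + pxy, cur + pxy + pxy, cur);
      std::copy(cur + pxy * nz, cur + pxy * nz + pxy, cur + pxy * (nz + 1));
      for (int z = 1; z <= nz; ++z)
        for (int y = 1; y <= ny; ++y) {
          double *r = cur + px * y + pxy * z;
          double *o = nxt + px * y + pxy * z;
          for (int x = 1; x <= nx; ++x) {
            double cv = r[x];
            o[x] = cv + alpha * (r[x - 1] + r[x + 1] + r[x - px] + r[x + px] +
                                 r[x - pxy] + r[x + pxy] - 6.0 * cv);
          }
        }
      std::swap(cur, nxt);
    }
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        std::copy(cur + 1 + px * (y + 1) + pxy * (z + 1),
                  cur + 1 + px * (y + 1) + pxy * (z + 1) + nx,
                  c + vidx(0, y, z, nx, ny));
  }
  double keep = 1.0 - mu;
  for (R_xlen_t v = 0; v < n_vox; ++v) c[v] *= keep;
  const int *src = source.begin();
  for (R_xlen_t v = 0; v < n_vox; ++v) if (src[v]) c[v] += s;
}

// Per-cell sum over the cell's voxels of max(c - floor, 0).
// [[Rcpp::export]]
NumericVector cpp_supra_floor_sums(NumericVector conc, IntegerVector spin,
                                   int max_id, double floor_abs) {
  NumericVector out(max_id + 1);
  const double *c = conc.begin();
  const int *sp = spin.begin();
  R_xlen_t n = conc.size();
  for (R_xlen_t v = 0; v < n; ++v) {
    int id = sp[v];
    if (id > 0) {
      double x = c[v] - floor_abs;
      if (x > 0.0) out[id] += x;
    }
  }
  return out;
}
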