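// Cellular-Potts (GGH) lattice kernel: incremental Hamiltonian, Metropolis
// voxel-copy attempts and the Monte-Carlo-step sweep.
//
// Conventions shared with the R layer:
//   - grid is a flat integer vector in column-major (x fastest) order,
//     value 0 = medium, >0 = cell identifier;
//   - per-id vectors (type, target volume, ...) are indexed id + 1;
//   - type codes: 0 medium, 1 vascular, 2 normal, 3 tumor, 4 donor,
//     5 acceptor;
//   - cell major-axis length is sqrt(12*lambda_max + 1) voxels, lambda_max
//     the largest eigenvalue of the voxel-coordinate covariance (exact for a
//     straight one-voxel-thick segment). Moments use unwrapped coordinates,
//     so elongated cells must not wrap a periodic axis.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Lattice {
  int nx, ny, nz, n;
  bool px, py, pz;
};

inline void unflatten(const Lattice &L, int v, int &x, int &y, int &z) {
  x = v % L.nx;
  y = (v / L.nx) % L.ny;
  z = v / (L.nx * L.ny);
}

// neighbor voxel index or -1 when off a non-periodic edge
inline int neighborIndex(const Lattice &L, int v, int dx, int dy, int dz) {
  int x, y, z;
  unflatten(L, v, x, y, z);
  x += dx; y += dy; z += dz;
  if (L.px) { x = (x + L.nx) % L.nx; } else if (x < 0 || x >= L.nx) return -1;
  if (L.py) { y = (y + L.ny) % L.ny; } else if (y < 0 || y >= L.ny) return -1;
  if (L.pz) { z = (z + L.nz) % L.nz; } else if (z < 0 || z >= L.nz) return -1;
  return x + L.nx * (y + L.ny * z);
}

// neighborhood offset table: first 6 are the von Neumann faces, full table
// is the 26-voxel Moore shell
const int OFF[26][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},
  {1,1,0},{1,-1,0},{-1,1,0},{-1,-1,0},
  {1,0,1},{1,0,-1},{-1,0,1},{-1,0,-1},
  {0,1,1},{0,1,-1},{0,-1,1},{0,-1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1},
  {-1,1,1},{-1,1,-1},{-1,-1,1},{-1,-1,-1}};

struct Moments {
  double n, sx, sy, sz, sxx, syy, szz, sxy, sxz, syz;
  Moments() : n(0), sx(0), sy(0), sz(0), sxx(0), syy(0), szz(0),
              sxy(0), sxz(0), syz(0) {}
  void add(double x, double y, double z, double s) {
    n += s; sx += s * x; sy += s * y; sz += s * z;
    sxx += s * x * x; syy += s * y * y; szz += s * z * z;
    sxy += s * x * y; sxz += s * x * z; syz += s * y * z;
  }
  double axisLength() const {
    if (n <= 0) return 0.0;
    if (n == 1) return 1.0;
    arma::mat33 C;
    double mx = sx / n, my = sy / n, mz = sz / n;
    C(0, 0) = sxx / n - mx * mx;
    C(1, 1) = syy / n - my * my;
    C(2, 2) = szz / n - mz * mz;
    C(0, 1) = C(1, 0) = sxy / n - mx * my;
    C(0, 2) = C(2, 0) = sxz / n - mx * mz;
    C(1, 2) = C(2, 1) = syz / n - my * mz;
    arma::vec3 ev = arma::eig_sym(C);
    double lmax = ev(2);
    if (lmax < 0) lmax = 0;
    return std::sqrt(12.0 * lmax + 1.0);
  }
};

struct Engine {
  Lattice L;
  IntegerVector grid;
  IntegerVector type;       // by id+1
  NumericVector targetVol;  // voxels, by id+1
  NumericVector targetAxis; // voxels, by id+1 (0 = constraint off)
  LogicalVector frozen;     // by id+1
  NumericMatrix J;          // 6 x 6 type-pair contact energies
  double lambdaVol, lambdaLen, mu, temperature;
  int nNbhd;                // 6 or 26
  NumericVector field;      // chemotaxis field (length 0 = off)
  bool connectivity;        // reject retractions that split a cell locally
  std::vector<double> vol;
  std::vector<Moments> mom;
  std::vector<double> axisLen; // cached current length, by id+1
  bool useLen;

  void init() {
    int maxId = type.size() - 1;
    vol.assign(maxId + 1, 0.0);
    mom.assign(maxId + 1, Moments());
    useLen = lambdaLen > 0;
    for (int v = 0; v < L.n; ++v) {
      int id = grid[v];
      if (id > 0) {
        vol[id] += 1.0;
        if (useLen) {
          int x, y, z;
          unflatten(L, v, x, y, z);
          mom[id].add(x, y, z, 1.0);
        }
      }
    }
    axisLen.assign(maxId + 1, 0.0);
    if (useLen)
      for (int id = 1; id <= maxId; ++id) axisLen[id] = mom[id].axisLength();
  }

  double deltaH(int src, int tgt) {
    int ss = grid[src], st = grid[tgt];
    if (ss == st) return 0.0;
    int ts = ss > 0 ? type[ss] : 0;
    int tt = st > 0 ? type[st] : 0;
    double dH = 0.0;
    // adhesion over the neighborhood of the target voxel
    for (int k = 0; k < nNbhd; ++k) {
      int j = neighborIndex(L, tgt, OFF[k][0], OFF[k][1], OFF[k][2]);
      if (j < 0) continue;
      int sj = grid[j];
      int tj = sj > 0 ? type[sj] : 0;
      dH += J(ts, tj) * (ss != sj) - J(tt, tj) * (st != sj);
    }
    // volume constraint
    if (ss > 0) {
      double d = vol[ss] - targetVol[ss];
      dH += lambdaVol * ((d + 1.0) * (d + 1.0) - d * d);
    }
    if (st > 0) {
      double d = vol[st] - targetVol[st];
      dH += lambdaVol * ((d - 1.0) * (d - 1.0) - d * d);
    }
    // elongation constraint (cells with a target major axis)
    if (useLen) {
      int x, y, z;
      unflatten(L, tgt, x, y, z);
      if (ss > 0 && targetAxis[ss] > 0) {
        Moments m = mom[ss];
        m.add(x, y, z, 1.0);
        double d0 = axisLen[ss] - targetAxis[ss];
        double d1 = m.axisLength() - targetAxis[ss];
        dH += lambdaLen * (d1 * d1 - d0 * d0);
      }
      if (st > 0 && targetAxis[st] > 0) {
        Moments m = mom[st];
        m.add(x, y, z, -1.0);
        double d0 = axisLen[st] - targetAxis[st];
        double d1 = m.axisLength() - targetAxis[st];
        dH += lambdaLen * (d1 * d1 - d0 * d0);
      }
    }
    // chemotaxis work term (not part of the state Hamiltonian)
    if (field.size() > 0 && mu != 0)
      dH += -mu * (field[src] - field[tgt]);
    return dH;
  }

  bool accept(double dH) {
    if (dH <= 0) return true;
    if (temperature <= 0) return false;
    return unif_rand() < std::exp(-dH / temperature);
  }

  // local 6-connectivity tests.  Cells must stay face-connected (the
  // perfusion fields exchange flux across faces only), so:
  //  - an expansion must place the new voxel face-adjacent to its cell;
  //  - a retraction must leave the cell's face-neighbors of the lost voxel
  //    mutually connected by face-steps within the 26-shell.
  // Both are local (hence approximate) versions of the standard GGH
  // connectivity constraint.
  bool expandTouchesFace(int tgt, int id) {
    for (int k = 0; k < 6; ++k) {
      int j = neighborIndex(L, tgt, OFF[k][0], OFF[k][1], OFF[k][2]);
      if (j >= 0 && grid[j] == id) return true;
    }
    return false;
  }

  bool retractKeepsConnected(int tgt, int id) {
    int coord[26][3];
    bool isFace[26];
    int cnt = 0, nFace = 0;
    for (int k = 0; k < 26; ++k) {
      int j = neighborIndex(L, tgt, OFF[k][0], OFF[k][1], OFF[k][2]);
      if (j >= 0 && grid[j] == id) {
        coord[cnt][0] = OFF[k][0];
        coord[cnt][1] = OFF[k][1];
        coord[cnt][2] = OFF[k][2];
        isFace[cnt] = (k < 6);
        if (k < 6) ++nFace;
        ++cnt;
      }
    }
    if (nFace <= 1) return true; // at most one face link: nothing to sever
    // BFS over shell members, adjacency = Manhattan distance 1 (faces)
    bool seen[26] = {false};
    int stack[26];
    int top = 0;
    int start = -1;
    for (int i = 0; i < cnt; ++i)
      if (isFace[i]) { start = i; break; }
    stack[top++] = start;
    seen[start] = true;
    while (top > 0) {
      int i = stack[--top];
      for (int j2 = 0; j2 < cnt; ++j2) {
        if (seen[j2]) continue;
        int dd = std::abs(coord[i][0] - coord[j2][0]) +
                 std::abs(coord[i][1] - coord[j2][1]) +
                 std::abs(coord[i][2] - coord[j2][2]);
        if (dd == 1) {
          seen[j2] = true;
          stack[top++] = j2;
        }
      }
    }
    for (int i = 0; i < cnt; ++i)
      if (isFace[i] && !seen[i]) return false;
    return true;
  }

  void applyCopy(int src, int tgt) {
    int ss = grid[src], st = grid[tgt];
    int x, y, z;
    unflatten(L, tgt, x, y, z);
    if (ss > 0) {
      vol[ss] += 1.0;
      if (useLen) {
        mom[ss].add(x, y, z, 1.0);
        if (targetAxis[ss] > 0) axisLen[ss] = mom[ss].axisLength();
      }
    }
    if (st > 0) {
      vol[st] -= 1.0;
      if (useLen) {
        mom[st].add(x, y, z, -1.0);
        if (targetAxis[st] > 0) axisLen[st] = mom[st].axisLength();
      }
    }
    grid[tgt] = ss;
  }
};

Engine makeEngine(IntegerVector grid, IntegerVector dims,
                  LogicalVector periodic, IntegerVector type,
                  NumericVector targetVol, NumericVector targetAxis,
                  LogicalVector frozen, NumericMatrix J, double lambdaVol,
                  double lambdaLen, double mu, double temperature, int nbhd,
                  NumericVector field, bool connectivity) {
  Engine E;
  E.L.nx = dims[0]; E.L.ny = dims[1]; E.L.nz = dims[2];
  E.L.n = dims[0] * dims[1] * dims[2];
  E.L.px = periodic[0]; E.L.py = periodic[1]; E.L.pz = periodic[2];
  E.grid = grid;
  E.type = type; E.targetVol = targetVol; E.targetAxis = targetAxis;
  E.frozen = frozen; E.J = J;
  E.lambdaVol = lambdaVol; E.lambdaLen = lambdaLen;
  E.mu = mu; E.temperature = temperature;
  E.nNbhd = (nbhd == 6) ? 6 : 26;
  E.field = field;
  E.connectivity = connectivity;
  E.init();
  return E;
}

} // namespace

// [[Rcpp::export]]
double cpm_delta_h(IntegerVector grid, IntegerVector dims,
                   LogicalVector periodic, IntegerVector type,
                   NumericVector targetVol, NumericVector targetAxis,
                   LogicalVector frozen, NumericMatrix J, double lambdaVol,
                   double lambdaLen, double mu, double temperature, int nbhd,
                   NumericVector field, int src, int tgt) {
  Engine E = makeEngine(clone(grid), dims, periodic, type, targetVol,
                        targetAxis, frozen, J, lambdaVol, lambdaLen, mu,
                        temperature, nbhd, field, false);
  return E.deltaH(src, tgt);
}

// [[Rcpp::export]]
List cpm_attempt_copy(IntegerVector grid, IntegerVector dims,
                      LogicalVector periodic, IntegerVector type,
                      NumericVector targetVol, NumericVector targetAxis,
                      LogicalVector frozen, NumericMatrix J, double lambdaVol,
                      double lambdaLen, double mu, double temperature,
                      int nbhd, NumericVector field, bool connectivity,
                      int src, int tgt) {
  RNGScope scope;
  Engine E = makeEngine(clone(grid), dims, periodic, type, targetVol,
                        targetAxis, frozen, J, lambdaVol, lambdaLen, mu,
                        temperature, nbhd, field, connectivity);
  double dH = E.deltaH(src, tgt);
  bool acc = false;
  int ssC = E.grid[src], stC = E.grid[tgt];
  bool allowed = !E.connectivity ||
    ((ssC == 0 || E.expandTouchesFace(tgt, ssC)) &&
     (stC == 0 || E.retractKeepsConnected(tgt, stC)));
  if (E.grid[src] != E.grid[tgt] && allowed) {
    acc = E.accept(dH);
    if (acc) E.applyCopy(src, tgt);
  }
  return List::create(_["accepted"] = acc, _["deltaH"] = dH,
                      _["grid"] = E.grid);
}

// One MCS = n-voxel random copy attempts. Returns the updated grid plus
// per-id volumes and cached major-axis lengths for registry synchronisation.
// [[Rcpp::export]]
List cpm_run_mcs(IntegerVector grid, IntegerVector dims,
                 LogicalVector periodic, IntegerVector type,
                 NumericVector targetVol, NumericVector targetAxis,
                 LogicalVector frozen, NumericMatrix J, double lambdaVol,
                 double lambdaLen, double mu, double temperature, int nbhd,
                 NumericVector field, bool connectivity, int nSteps) {
  RNGScope scope;
  Engine E = makeEngine(clone(grid), dims, periodic, type, targetVol,
                        targetAxis, frozen, J, lambdaVol, lambdaLen, mu,
                        temperature, nbhd, field, connectivity);
  int n = E.L.n;
  long attempts = 0, accepted = 0;
  for (int s = 0; s < nSteps; ++s) {
    for (int a = 0; a < n; ++a) {
      int v = (int)(unif_rand() * n);
      if (v >= n) v = n - 1;
      int k = (int)(unif_rand() * E.nNbhd);
      if (k >= E.nNbhd) k = E.nNbhd - 1;
      int u = neighborIndex(E.L, v, OFF[k][0], OFF[k][1], OFF[k][2]);
      if (u < 0) continue;
      int ss = E.grid[v], st = E.grid[u];
      if (ss == st) continue;
      if ((ss > 0 && E.frozen[ss]) || (st > 0 && E.frozen[st])) continue;
      if (E.connectivity) {
        if (ss > 0 && !E.expandTouchesFace(u, ss)) continue;
        if (st > 0 && !E.retractKeepsConnected(u, st)) continue;
      }
      ++attempts;
      double dH = E.deltaH(v, u);
      if (E.accept(dH)) {
        E.applyCopy(v, u);
        ++accepted;
      }
    }
  }
  int maxId = type.size() - 1;
  NumericVector vol(maxId), len(maxId);
  for (int id = 1; id <= maxId; ++id) {
    vol[id - 1] = E.vol[id];
    len[id - 1] = E.useLen ? E.mom[id].axisLength() : NA_REAL;
  }
  return List::create(_["grid"] = E.grid, _["volumes"] = vol,
                      _["axisLengths"] = len, _["attempts"] = attempts,
                      _["accepted"] = accepted);
}

// Per-cell voxel count, centroid and major-axis length from the grid alone.
// [[Rcpp::export]]
List cell_shape_stats(IntegerVector grid, IntegerVector dims, int maxId) {
  Lattice L;
  L.nx = dims[0]; L.ny = dims[1]; L.nz = dims[2];
  L.n = L.nx * L.ny * L.nz;
  L.px = L.py = L.pz = false;
  std::vector<Moments> mom(maxId + 1);
  for (int v = 0; v < L.n; ++v) {
    int id = grid[v];
    if (id > 0 && id <= maxId) {
      int x, y, z;
      unflatten(L, v, x, y, z);
      mom[id].add(x, y, z, 1.0);
    }
  }
  NumericVector vol(maxId), len(maxId), cx(maxId), cy(maxId), cz(maxId);
  for (int id = 1; id <= maxId; ++id) {
    const Moments &m = mom[id];
    vol[id - 1] = m.n;
    len[id - 1] = m.axisLength();
    cx[id - 1] = m.n > 0 ? m.sx / m.n : NA_REAL;
    cy[id - 1] = m.n > 0 ? m.sy / m.n : NA_REAL;
    cz[id - 1] = m.n > 0 ? m.sz / m.n : NA_REAL;
  }
  return List::create(_["volume"] = vol, _["axisLength"] = len,
                      _["cx"] = cx, _["cy"] = cy, _["cz"] = cz);
}

// Mean of a field over each cell's voxels (0 = medium is skipped).
// [[Rcpp::export]]
List cell_field_means(IntegerVector grid, NumericVector field, int maxId) {
  NumericVector sum(maxId);
  NumericVector cnt(maxId);
  int n = grid.size();
  for (int v = 0; v < n; ++v) {
    int id = grid[v];
    if (id > 0 && id <= maxId) {
      sum[id - 1] += field[v];
      cnt[id - 1] += 1.0;
    }
  }
  NumericVector mean(maxId);
  for (int i = 0; i < maxId; ++i)
    mean[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  return List::create(_["mean"] = mean, _["count"] = cnt);
}
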