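// Explicit finite-difference reaction-diffusion steppers on the voxel
// lattice (6-neighbor face stencil, automatic sub-stepping for stability).
//
// Three fields are served:
//   - cellular pO2: tissue-wide diffusion, optional periodic wrap per axis,
//     per-voxel uptake rate, sourced from vascular voxels at step start;
//   - vascular pO2: diffusion restricted to faces shared by two conductive
//     (vascular) voxels, with clamped ghost donor/acceptor neighbors on the
//     lattice faces;
//   - VEGF: tissue-wide diffusion with first-order decay and secretion into
//     a voxel set.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double MAX_ALPHA = 0.15; // < 1/6 keeps the explicit stencil stable

// wrapped/clipped neighbor index tables along one axis; -1 marks a closed
// non-periodic edge
void axisTables(int n, bool periodic, std::vector<int> &minus,
                std::vector<int> &plus) {
  minus.resize(n);
  plus.resize(n);
  for (int i = 0; i < n; ++i) {
    minus[i] = (i > 0) ? i - 1 : (periodic ? n - 1 : -1);
    plus[i] = (i < n - 1) ? i + 1 : (periodic ? 0 : -1);
  }
}

} // namespace

// Cellular pO2 step over dt seconds. Sources the field at vascular voxels,
// diffuses with per-axis periodic wrap, applies per-voxel uptake (clamped at
// zero) and optional first-order decay. Returns the updated field and the
// per-vascular-voxel leak (sourced value minus end-of-step value).
// [[Rcpp::export]]
List step_cellular_cpp(NumericVector conc, IntegerVector dims,
                       LogicalVector periodic, double D, double h, double dt,
                       NumericVector uptakeRate, double decay,
                       IntegerVector vascIdx, NumericVector vascValues) {
  int nx = dims[0], ny = dims[1], nz = dims[2], n = nx * ny * nz;
  NumericVector c = clone(conc);
  int nv = vascIdx.size();
  for (int i = 0; i < nv; ++i) c[vascIdx[i]] = vascValues[i];
  NumericVector sourced(nv);
  for (int i = 0; i < nv; ++i) sourced[i] = c[vascIdx[i]];

  double alphaTotal = D * dt / (h * h);
  int nsub = (alphaTotal > 0) ? (int)std::ceil(alphaTotal / MAX_ALPHA) : 1;
  if (nsub < 1) nsub = 1;
  double dts = dt / nsub;
  double alpha = alphaTotal / nsub;
  double decayFac = (decay > 0) ? std::exp(-decay * dts) : 1.0;
  bool haveUptake = uptakeRate.size() == n;

  std::vector<int> xm, xp, ym, yp, zm, zp;
  axisTables(nx, periodic[0], xm, xp);
  axisTables(ny, periodic[1], ym, yp);
  axisTables(nz, periodic[2], zm, zp);

  std::vector<double> buf(n);
  for (int s = 0; s < nsub; ++s) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        int base = nx * (y + ny * z);
        int bym = (ym[y] >= 0) ? nx * (ym[y] + ny * z) : -1;
        int byp = (yp[y] >= 0) ? nx * (yp[y] + ny * z) : -1;
        int bzm = (zm[z] >= 0) ? nx * (y + ny * zm[z]) : -1;
        int bzp = (zp[z] >= 0) ? nx * (y + ny * zp[z]) : -1;
        for (int x = 0; x < nx; ++x) {
          int v = base + x;
          double cv = c[v];
          double acc = 0.0;
          if (xm[x] >= 0) acc += c[base + xm[x]] - cv;
          if (xp[x] >= 0) acc += c[base + xp[x]] - cv;
          if (bym >= 0) acc += c[bym + x] - cv;
          if (byp >= 0) acc += c[byp + x] - cv;
          if (bzm >= 0) acc += c[bzm + x] - cv;
          if (bzp >= 0) acc += c[bzp + x] - cv;
          buf[v] = cv + alpha * acc;
        }
      }
    }
    for (int v = 0; v < n; ++v) {
      double cv = buf[v];
      if (haveUptake && uptakeRate[v] > 0) {
        cv -= uptakeRate[v] * dts;
        if (cv < 0) cv = 0;
      }
      if (decayFac != 1.0) cv *= decayFac;
      c[v] = cv;
    }
  }

  NumericVector leak(nv);
  for (int i = 0; i < nv; ++i) leak[i] = sourced[i] - c[vascIdx[i]];
  return List::create(_["conc"] = c, _["leak"] = leak);
}

// Vascular pO2 diffusion over dt seconds: flux only across faces joining
// two conductive voxels; donor/acceptor boundary voxels exchange with a
// clamped ghost neighbor. Non-periodic (the ghost layer is the boundary).
// [[Rcpp::export]]
NumericVector diffuse_vascular_cpp(NumericVector conc, IntegerVector dims,
                                   LogicalVector cond, double D, double h,
                                   double dt, IntegerVector donorIdx,
                                   double donorVal, IntegerVector accIdx,
                                   double accVal) {
  int nx = dims[0], ny = dims[1], nz = dims[2], n = nx * ny * nz;
  NumericVector c = clone(conc);

  // compact list of conductive voxels and their conductive face neighbors
  std::vector<int> nodes;
  nodes.reserve(n / 4);
  for (int v = 0; v < n; ++v)
    if (cond[v]) nodes.push_back(v);
  int m = (int)nodes.size();
  std::vector<int> nbr(6 * (size_t)m, -1);
  for (int i = 0; i < m; ++i) {
    int v = nodes[i];
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    int cand[6] = {x > 0 ? v - 1 : -1,
                   x < nx - 1 ? v + 1 : -1,
                   y > 0 ? v - nx : -1,
                   y < ny - 1 ? v + nx : -1,
                   z > 0 ? v - nx * ny : -1,
                   z < nz - 1 ? v + nx * ny : -1};
    for (int k = 0; k < 6; ++k)
      if (cand[k] >= 0 && cond[cand[k]]) nbr[6 * (size_t)i + k] = cand[k];
  }

  double alphaTotal = D * dt / (h * h);
  int nsub = (alphaTotal > 0) ? (int)std::ceil(alphaTotal / MAX_ALPHA) : 1;
  if (nsub < 1) nsub = 1;
  double alpha = alphaTotal / nsub;

  // ghost donor/acceptor flux enters the same explicit update as the
  // neighbor flux (all terms evaluated at the pre-step state), so the
  // steady state matches the ideal chain with clamped ghost end nodes
  std::vector<int> nodeOf(n, -1);
  for (int i = 0; i < m; ++i) nodeOf[nodes[i]] = i;
  std::vector<double> delta(m);
  for (int s = 0; s < nsub; ++s) {
    for (int i = 0; i < m; ++i) {
      int v = nodes[i];
      double cv = c[v];
      double acc = 0.0;
      for (int k = 0; k < 6; ++k) {
        int u = nbr[6 * (size_t)i + k];
        if (u >= 0) acc += c[u] - cv;
      }
      delta[i] = alpha * acc;
    }
    for (int i = 0; i < donorIdx.size(); ++i) {
      int j = nodeOf[donorIdx[i]];
      if (j >= 0) delta[j] += alpha * (donorVal - c[donorIdx[i]]);
    }
    for (int i = 0; i < accIdx.size(); ++i) {
      int j = nodeOf[accIdx[i]];
      if (j >= 0) delta[j] += alpha * (accVal - c[accIdx[i]]);
    }
    for (int i = 0; i < m; ++i) c[nodes[i]] += delta[i];
  }
  return c;
}

// VEGF step over dt seconds: secretion into a voxel set, diffusion with
// periodic wrap, first-order decay.
// [[Rcpp::export]]
NumericVector vegf_step_cpp(NumericVector conc, IntegerVector dims,
                            LogicalVector periodic, double D, double h,
                            double dt, double decay, IntegerVector secretIdx,
                            double rate) {
  NumericVector c = clone(conc);
  for (int i = 0; i < secretIdx.size(); ++i) c[secretIdx[i]] += rate * dt;
  IntegerVector novasc(0);
  NumericVector noval(0);
  NumericVector noUptake(0);
  List out = step_cellular_cpp(c, dims, periodic, D, h, dt, noUptake, decay,
                               novasc, noval);
  return out["conc"];
}
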