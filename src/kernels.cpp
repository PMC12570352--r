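// Compiled kernels for the hot paths: hierarchical-grid neighbor sweeps with
// pair-potential evaluation, Poisson-disc sampling and overlap relaxation.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrap_d(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

// potential kinds: 1 harmonic repulsion, 2 weak piecewise harmonic,
// 3 continuous square well, 4 pseudo hard sphere.  Returns energy, writes
// dU/dr to *du.
static inline double pot_eval(int kind, double r, double k, double sig,
                              double p3, double rc, double *du) {
  switch (kind) {
  case 1: { // U = k/2 (r - sig)^2 for r <= sig
    if (r <= sig) { *du = k * (r - sig); return 0.5 * k * (r - sig) * (r - sig); }
    *du = 0.0; return 0.0;
  }
  case 2: { // piecewise harmonic well: k stiffness, sig contact, p3 depth, rc cutoff
    double w = rc - sig;
    if (r < sig) { *du = k * (r - sig); return 0.5 * k * (r - sig) * (r - sig) - p3; }
    if (r < sig + 0.5 * w) {
      *du = 4.0 * p3 * (r - sig) / (w * w);
      return -p3 + 2.0 * p3 * (r - sig) * (r - sig) / (w * w);
    }
    if (r < rc) {
      *du = -4.0 * p3 * (r - rc) / (w * w);
      return -2.0 * p3 * (r - rc) * (r - rc) / (w * w);
    }
    *du = 0.0; return 0.0;
  }
  case 3: { // continuous square well: k depth eps, sig well radius, p3 width
    double x = (r - sig) / p3;
    double t = std::tanh(x);
    *du = 0.5 * k * (1.0 - t * t) / p3;
    return -0.5 * k * (1.0 - t);
  }
  case 4: { // pseudo hard sphere (cut-shifted 50-49 Mie), k = eps, rc = (50/49) sig
    if (r >= rc) { *du = 0.0; return 0.0; }
    double pref = 50.0 * std::pow(50.0 / 49.0, 49.0) * k;
    double s50 = std::pow(sig / r, 50.0), s49 = std::pow(sig / r, 49.0);
    *du = pref * (-50.0 * s50 + 49.0 * s49) / r;
    return pref * (s50 - s49) + k;
  }
  default: *du = 0.0; return 0.0;
  }
}

struct CellGrid {
  int nc[3];
  double cs[3];
  double org[3];
  std::vector<int> head, nxt;
  bool periodic;
  int idx(int cx, int cy, int cz) const {
    return (cz * nc[1] + cy) * nc[0] + cx;
  }
  int cell_of(const double *x) const {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double u = (x[d] - org[d]) / cs[d];
      int k = (int)std::floor(u);
      if (periodic) {
        k %= nc[d]; if (k < 0) k += nc[d];
      } else {
        if (k < 0) k = 0;
        if (k >= nc[d]) k = nc[d] - 1;
      }
      c[d] = k;
    }
    return idx(c[0], c[1], c[2]);
  }
};

static void build_grid(CellGrid &g, const NumericMatrix &pos,
                       const std::vector<int> &members,
                       double cell, const double *box, bool periodic,
                       const double *lo) {
  g.periodic = periodic;
  // cap the resolution so sparse levels with tiny cutoffs stay cheap
  int cap = std::max(3, (int)std::ceil(2.0 * std::cbrt((double)members.size() + 1.0)));
  for (int d = 0; d < 3; ++d) {
    g.nc[d] = std::min(cap, std::max(1, (int)std::floor(box[d] / cell)));
    g.cs[d] = box[d] / g.nc[d];
    g.org[d] = lo[d];
  }
  g.head.assign((size_t)g.nc[0] * g.nc[1] * g.nc[2], -1);
  g.nxt.assign(pos.nrow(), -1);
  for (int m : members) {
    double x[3] = {pos(m, 0), pos(m, 1), pos(m, 2)};
    int c = g.cell_of(x);
    g.nxt[m] = g.head[c];
    g.head[c] = m;
  }
}

// [[Rcpp::export]]
List cpp_pair_sweep(NumericMatrix ppos, NumericVector pcut,
                    IntegerVector plevel, int nlevels,
                    NumericVector level_cell, NumericVector level_maxcut,
                    NumericVector box, bool periodic,
                    IntegerVector ptype, IntegerVector pmol,
                    NumericMatrix molpos,
                    IntegerMatrix kind, NumericMatrix pk, NumericMatrix psig,
                    NumericMatrix pp3, NumericMatrix prc,
                    bool want_pairs, bool want_forces) {
  const int P = ppos.nrow();
  const int M = molpos.nrow();
  const int T = kind.nrow();
  double bx[3] = {box[0], box[1], box[2]};

  // binning origin: box-aligned for periodic systems, bounding box otherwise
  double lo[3] = {-bx[0] / 2, -bx[1] / 2, -bx[2] / 2};
  if (!periodic && P > 0) {
    for (int d = 0; d < 3; ++d) {
      double mn = ppos(0, d);
      for (int i = 1; i < P; ++i) mn = std::min(mn, ppos(i, d));
      lo[d] = mn;
    }
  }

  std::vector<std::vector<int>> members(nlevels);
  for (int i = 0; i < P; ++i) members[plevel[i] - 1].push_back(i);
  std::vector<CellGrid> grids(nlevels);
  for (int l = 0; l < nlevels; ++l)
    build_grid(grids[l], ppos, members[l], level_cell[l], bx, periodic, lo);

  std::vector<int> out_i, out_j;
  std::vector<double> out_r;
  NumericMatrix F(want_forces ? M : 0, 3), Tq(want_forces ? M : 0, 3);
  double virial = 0.0, energy = 0.0;

  std::vector<int> cells;
  cells.reserve(512);

  auto handle_pair = [&](int i, int j) {
    if (i == j) return;
    double dx[3];
    for (int d = 0; d < 3; ++d) {
      dx[d] = ppos(i, d) - ppos(j, d);
      if (periodic) dx[d] = wrap_d(dx[d], bx[d]);
    }
    double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
    double gate = 0.5 * (pcut[i] + pcut[j]);
    if (r2 >= gate * gate) return;
    double r = std::sqrt(r2);
    int mi = pmol[i] - 1, mj = pmol[j] - 1;
    bool same_mol = (mi == mj);
    if (want_pairs && !same_mol) {
      out_i.push_back(i + 1);
      out_j.push_back(j + 1);
      out_r.push_back(r);
    }
    if (!want_forces || same_mol || T == 0) return;
    int ti = ptype[i] - 1, tj = ptype[j] - 1;
    int kd = kind(ti, tj);
    if (kd == 0) return;
    double rc = prc(ti, tj);
    if (r >= rc) return;
    double du, rr = (r < 1e-12) ? 1e-12 : r;
    energy += pot_eval(kd, r, pk(ti, tj), psig(ti, tj), pp3(ti, tj), rc, &du);
    double fmag = -du; // force on i along +dx
    double f[3] = {fmag * dx[0] / rr, fmag * dx[1] / rr, fmag * dx[2] / rr};
    // lever arms about the molecule centers (min image)
    double ai[3], aj[3], rm[3];
    for (int d = 0; d < 3; ++d) {
      ai[d] = ppos(i, d) - molpos(mi, d);
      aj[d] = ppos(j, d) - molpos(mj, d);
      rm[d] = molpos(mi, d) - molpos(mj, d);
      if (periodic) {
        ai[d] = wrap_d(ai[d], bx[d]);
        aj[d] = wrap_d(aj[d], bx[d]);
        rm[d] = wrap_d(rm[d], bx[d]);
      }
      F(mi, d) += f[d];
      F(mj, d) -= f[d];
    }
    Tq(mi, 0) += ai[1] * f[2] - ai[2] * f[1];
    Tq(mi, 1) += ai[2] * f[0] - ai[0] * f[2];
    Tq(mi, 2) += ai[0] * f[1] - ai[1] * f[0];
    Tq(mj, 0) -= aj[1] * f[2] - aj[2] * f[1];
    Tq(mj, 1) -= aj[2] * f[0] - aj[0] * f[2];
    Tq(mj, 2) -= aj[0] * f[1] - aj[1] * f[0];
    virial += f[0] * rm[0] + f[1] * rm[1] + f[2] * rm[2];
  };

  for (int l = 0; l < nlevels; ++l) {
    const CellGrid &g = grids[l];
    // same-level sweep over nearest-neighbor cells; pair once via i < j
    for (int i : members[l]) {
      double x[3] = {ppos(i, 0), ppos(i, 1), ppos(i, 2)};
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double u = (x[d] - g.org[d]) / g.cs[d];
        int k = (int)std::floor(u);
        if (periodic) { k %= g.nc[d]; if (k < 0) k += g.nc[d]; }
        else { if (k < 0) k = 0; if (k >= g.nc[d]) k = g.nc[d] - 1; }
        c[d] = k;
      }
      cells.clear();
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int cc[3] = {c[0] + ox, c[1] + oy, c[2] + oz};
            bool ok = true;
            for (int d = 0; d < 3; ++d) {
              if (periodic) {
                cc[d] %= g.nc[d]; if (cc[d] < 0) cc[d] += g.nc[d];
              } else if (cc[d] < 0 || cc[d] >= g.nc[d]) { ok = false; break; }
            }
            if (!ok) continue;
            int ci = g.idx(cc[0], cc[1], cc[2]);
            bool dup = false;
            for (int e : cells) if (e == ci) { dup = true; break; }
            if (!dup) cells.push_back(ci);
          }
      for (int ci : cells)
        for (int j = g.head[ci]; j != -1; j = g.nxt[j])
          if (j > i) handle_pair(i, j);
    }
    // cross-level sweep: this (coarser) level against all finer levels
    for (int lf = l + 1; lf < nlevels; ++lf) {
      const CellGrid &gf = grids[lf];
      for (int i : members[l]) {
        double x[3] = {ppos(i, 0), ppos(i, 1), ppos(i, 2)};
        double s = 0.5 * (pcut[i] + level_maxcut[lf]);
        int lo_c[3], hi_c[3];
        for (int d = 0; d < 3; ++d) {
          lo_c[d] = (int)std::floor((x[d] - s - gf.org[d]) / gf.cs[d]);
          hi_c[d] = (int)std::floor((x[d] + s - gf.org[d]) / gf.cs[d]);
          if (hi_c[d] - lo_c[d] + 1 >= gf.nc[d]) { lo_c[d] = 0; hi_c[d] = gf.nc[d] - 1; }
        }
        for (int cx = lo_c[0]; cx <= hi_c[0]; ++cx)
          for (int cy = lo_c[1]; cy <= hi_c[1]; ++cy)
            for (int cz = lo_c[2]; cz <= hi_c[2]; ++cz) {
              int cc[3] = {cx, cy, cz};
              bool ok = true;
              for (int d = 0; d < 3; ++d) {
                if (periodic) {
                  cc[d] %= gf.nc[d]; if (cc[d] < 0) cc[d] += gf.nc[d];
                } else if (cc[d] < 0 || cc[d] >= gf.nc[d]) { ok = false; break; }
              }
              if (!ok) continue;
              for (int j = gf.head[gf.idx(cc[0], cc[1], cc[2])]; j != -1; j = gf.nxt[j])
                handle_pair(i, j);
            }
      }
    }
  }

  List out = List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                          _["r"] = wrap(out_r), _["virial"] = virial,
                          _["energy"] = energy);
  if (want_forces) { out["F"] = F; out["Tq"] = Tq; }
  return out;
}

// ---------------------------------------------------------------------------
// Poisson-disc (Bridson) sampling for polydisperse spheres in a periodic or
// closed box.  Species are picked uniformly among those with remaining quota;
// the pairwise minimum distance is r_i + r_j.

// [[Rcpp::export]]
List cpp_poisson_disc(NumericVector box, NumericVector radii,
                      NumericVector target, int ktrials, bool periodic) {
  const int S = radii.size();
  double bx[3] = {box[0], box[1], box[2]};
  double rmax = 0.0;
  for (int s = 0; s < S; ++s) rmax = std::max(rmax, radii[s]);
  double cell = 2.0 * rmax;                 // max pair minimum distance
  int nc[3]; double cs[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(bx[d] / cell));
    cs[d] = bx[d] / nc[d];
  }
  std::vector<int> head((size_t)nc[0] * nc[1] * nc[2], -1), nxt;
  std::vector<double> px, py, pz;
  std::vector<int> sp;
  std::vector<double> quota(target.begin(), target.end());

  auto cell_idx = [&](double x, double y, double z) {
    int c[3]; double xyz[3] = {x, y, z};
    for (int d = 0; d < 3; ++d) {
      int k = (int)std::floor(xyz[d] / cs[d]);
      if (periodic) { k %= nc[d]; if (k < 0) k += nc[d]; }
      else { if (k < 0) k = 0; if (k >= nc[d]) k = nc[d] - 1; }
      c[d] = k;
    }
    return (c[2] * nc[1] + c[1]) * nc[0] + c[0];
  };
  auto conflict = [&](double x, double y, double z, double r) {
    int cx = (int)std::floor(x / cs[0]), cy = (int)std::floor(y / cs[1]),
        cz = (int)std::floor(z / cs[2]);
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          int cc[3] = {cx + ox, cy + oy, cz + oz};
          bool ok = true;
          for (int d = 0; d < 3; ++d) {
            if (periodic) { cc[d] %= nc[d]; if (cc[d] < 0) cc[d] += nc[d]; }
            else if (cc[d] < 0 || cc[d] >= nc[d]) { ok = false; break; }
          }
          if (!ok) continue;
          for (int j = head[(cc[2] * nc[1] + cc[1]) * nc[0] + cc[0]]; j != -1;
               j = nxt[j]) {
            double dx = x - px[j], dy = y - py[j], dz = z - pz[j];
            if (periodic) {
              dx = wrap_d(dx, bx[0]); dy = wrap_d(dy, bx[1]); dz = wrap_d(dz, bx[2]);
            }
            double dmin = r + radii[sp[j]];
            if (dx * dx + dy * dy + dz * dz < dmin * dmin) return true;
          }
        }
    return false;
  };
  auto remaining = [&]() {
    std::vector<int> rem;
    for (int s = 0; s < S; ++s) if (quota[s] > 0) rem.push_back(s);
    return rem;
  };
  auto add_point = [&](double x, double y, double z, int s) {
    px.push_back(x); py.push_back(y); pz.push_back(z); sp.push_back(s);
    quota[s] -= 1.0;
    nxt.push_back(-1);
    int c = cell_idx(x, y, z);
    nxt.back() = head[c];
    head[c] = (int)px.size() - 1;
  };

  std::vector<int> active;
  {
    std::vector<int> rem = remaining();
    if (!rem.empty()) {
      int s = rem[(int)(unif_rand() * rem.size())];
      add_point(unif_rand() * bx[0], unif_rand() * bx[1], unif_rand() * bx[2], s);
      active.push_back(0);
    }
  }
  while (!active.empty()) {
    std::vector<int> rem = remaining();
    if (rem.empty()) break;
    int ai = (int)(unif_rand() * active.size());
    int p = active[ai];
    bool found = false;
    for (int t = 0; t < ktrials; ++t) {
      int s = rem[(int)(unif_rand() * rem.size())];
      double rmin = radii[sp[p]] + radii[s];
      // uniform in the annulus volume [rmin, 2 rmin]
      double rad = rmin * std::cbrt(1.0 + 7.0 * unif_rand());
      double u = 2.0 * unif_rand() - 1.0, phi = 2.0 * M_PI * unif_rand();
      double st = std::sqrt(1.0 - u * u);
      double x = px[p] + rad * st * std::cos(phi);
      double y = py[p] + rad * st * std::sin(phi);
      double z = pz[p] + rad * u;
      if (periodic) {
        x -= bx[0] * std::floor(x / bx[0]);
        y -= bx[1] * std::floor(y / bx[1]);
        z -= bx[2] * std::floor(z / bx[2]);
      } else if (x < 0 || y < 0 || z < 0 || x >= bx[0] || y >= bx[1] || z >= bx[2])
        continue;
      if (conflict(x, y, z, radii[s])) continue;
      add_point(x, y, z, s);
      active.push_back((int)px.size() - 1);
      found = true;
      break;
    }
    if (!found) {
      active[ai] = active.back();
      active.pop_back();
    }
  }
  int N = (int)px.size();
  NumericMatrix pos(N, 3);
  IntegerVector species(N);
  for (int i = 0; i < N; ++i) {
    pos(i, 0) = px[i]; pos(i, 1) = py[i]; pos(i, 2) = pz[i];
    species[i] = sp[i] + 1;
  }
  return List::create(_["positions"] = pos, _["species"] = species);
}

// ---------------------------------------------------------------------------
// Overlap relaxation for dense sphere packing: Gauss-Seidel projection of
// overlapping pairs (steepest descent on the harmonic overlap energy with
// per-pair optimal step), with optional box annealing from an inflated start.

// [[Rcpp::export]]
List cpp_pack_relax(NumericMatrix pos_in, NumericVector radii,
                    NumericVector box, bool periodic, double tol,
                    int max_sweeps, double inflate, double shrink) {
  const int N = pos_in.nrow();
  NumericMatrix pos(clone(pos_in));
  double bx0[3] = {box[0], box[1], box[2]};
  double scale = inflate;
  double rmax = 0.0;
  for (int i = 0; i < N; ++i) rmax = std::max(rmax, radii[i]);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) pos(i, d) *= scale;

  double max_ov = 1.0;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double bx[3] = {bx0[0] * scale, bx0[1] * scale, bx0[2] * scale};
    double cell = 2.0 * rmax;
    int nc[3]; double cs[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(bx[d] / cell));
      cs[d] = bx[d] / nc[d];
    }
    std::vector<int> head((size_t)nc[0] * nc[1] * nc[2], -1), nxt(N, -1);
    for (int i = 0; i < N; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double x = pos(i, d);
        if (periodic) x -= bx[d] * std::floor(x / bx[d]);
        int k = (int)std::floor(x / cs[d]);
        if (k < 0) k = 0; if (k >= nc[d]) k = nc[d] - 1;
        c[d] = k;
      }
      int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      nxt[i] = head[ci]; head[ci] = i;
    }
    max_ov = 0.0;
    for (int i = 0; i < N; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double x = pos(i, d);
        if (periodic) x -= bx[d] * std::floor(x / bx[d]);
        int k = (int)std::floor(x / cs[d]);
        if (k < 0) k = 0; if (k >= nc[d]) k = nc[d] - 1;
        c[d] = k;
      }
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int cc[3] = {c[0] + ox, c[1] + oy, c[2] + oz};
            bool ok = true;
            for (int d = 0; d < 3; ++d) {
              if (periodic) { cc[d] %= nc[d]; if (cc[d] < 0) cc[d] += nc[d]; }
              else if (cc[d] < 0 || cc[d] >= nc[d]) { ok = false; break; }
            }
            if (!ok) continue;
            for (int j = head[(cc[2] * nc[1] + cc[1]) * nc[0] + cc[0]]; j != -1;
                 j = nxt[j]) {
              if (j <= i) continue;
              double dx[3];
              for (int d = 0; d < 3; ++d) {
                dx[d] = pos(i, d) - pos(j, d);
                if (periodic) dx[d] = wrap_d(dx[d], bx[d]);
              }
              double sig = radii[i] + radii[j];
              double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
              if (r2 >= sig * sig) continue;
              double r = std::sqrt(r2);
              double ov = (sig - r) / sig;
              if (ov > max_ov) max_ov = ov;
              double push;
              double ux[3];
              if (r < 1e-9) { // coincident: random kick
                double u = 2.0 * unif_rand() - 1.0, phi = 2.0 * M_PI * unif_rand();
                double st = std::sqrt(1.0 - u * u);
                ux[0] = st * std::cos(phi); ux[1] = st * std::sin(phi); ux[2] = u;
                push = 0.5 * sig;
              } else {
                for (int d = 0; d < 3; ++d) ux[d] = dx[d] / r;
                push = 0.5 * (sig - r) * 1.02; // slight over-projection
              }
              for (int d = 0; d < 3; ++d) {
                pos(i, d) += push * ux[d];
                pos(j, d) -= push * ux[d];
              }
            }
          }
      if (periodic)
        for (int d = 0; d < 3; ++d)
          pos(i, d) -= bx[d] * std::floor(pos(i, d) / bx[d]);
    }
    if (scale > 1.0 && max_ov < 0.2) {
      double s_new = std::max(1.0, scale * (1.0 - shrink));
      double f = s_new / scale;
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d) pos(i, d) *= f;
      scale = s_new;
    } else if (scale <= 1.0 && max_ov < tol) {
      break;
    }
  }
  return List::create(_["positions"] = pos, _["sweeps"] = sweep + 1,
                      _["max_overlap"] = max_ov, _["converged"] =
                        (scale <= 1.0 && max_ov < tol));
}
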