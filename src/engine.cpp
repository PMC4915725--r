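// Coarse-grained engine: breakable bilinear bonds, harmonic angles,
// class-resolved truncated Lennard-Jones pairs, Verlet neighbour list with
// cell binning, Langevin velocity-Verlet integration, axial Berendsen-style
// box relaxation and strain-controlled box pulling.
//
// Units: A, fs, amu, kcal/mol. a[A/fs^2] = F/m * ACC; stress GPa via GPA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const double ACC = 4.184e-4;           // (kcal/mol/A)/amu -> A/fs^2
static const double GPA = 6.9479;             // kcal/mol/A^3 -> GPa
static const double KB  = 1.987204259e-3;     // kcal/mol/K
static const double GUARD = 0.8;              // minimum pair distance, A

// ---- deterministic RNG (splitmix64 -> xorshift128+, Box-Muller) ----------
struct Rng {
  uint64_t s0, s1;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    auto sm = [](uint64_t &x) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    uint64_t x = seed;
    s0 = sm(x); s1 = sm(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 <= 1e-300) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---- system ---------------------------------------------------------------
struct System {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, mass;
  std::vector<int> species;           // 0 collagen, 1 mineral
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> br0, br1, brb, bk0, bk1;
  std::vector<int> broken;
  // angles
  std::vector<int> ai, aj, ak;
  std::vector<double> aphi0, akb;     // phi0 in radians
  // pair classes: 0 coll-coll, 1 min-min, 2 inter
  double sig[3], eps[3], cut[3];
  bool shift_lj;
  double ushift[3];
  double Lx, Ly, Lz;
  // exclusions: sorted per-bead lists
  std::vector<std::vector<int>> excl;
  // neighbour list
  double skin, max_cut;
  std::vector<int> nli, nlj, nlc;
  std::vector<double> x0, y0, z0;     // positions at last build
  bool nl_valid = false;
  // forces / virials / energies
  std::vector<double> fx, fy, fz, wxx;
  double Ebond, Eangle, Elj[3];
  int n_degenerate = 0;
  int err_i = -1, err_j = -1;

  double mindx(double dx) const { return dx - Lx * std::round(dx / Lx); }

  bool excluded(int i, int j) const {
    const std::vector<int> &e = excl[i];
    return std::binary_search(e.begin(), e.end(), j);
  }

  void build_neighbors() {
    double rc = max_cut + skin;
    nli.clear(); nlj.clear(); nlc.clear();
    // cell binning; x periodic
    int ncx = std::max(1, (int)std::floor(Lx / rc));
    double cellx = Lx / ncx;
    double ymin = *std::min_element(y.begin(), y.end());
    double ymax = *std::max_element(y.begin(), y.end());
    double zmin = *std::min_element(z.begin(), z.end());
    double zmax = *std::max_element(z.begin(), z.end());
    int ncy = std::max(1, (int)std::floor((ymax - ymin) / rc) + 1);
    int ncz = std::max(1, (int)std::floor((zmax - zmin) / rc) + 1);
    std::vector<std::vector<int>> cells(ncx * ncy * ncz);
    auto cellof = [&](int i) {
      double xb = x[i] - Lx * std::floor(x[i] / Lx);
      int cx = std::min(ncx - 1, (int)(xb / cellx));
      int cy = std::min(ncy - 1, std::max(0, (int)((y[i] - ymin) / rc)));
      int cz = std::min(ncz - 1, std::max(0, (int)((z[i] - zmin) / rc)));
      return (cz * ncy + cy) * ncx + cx;
    };
    for (int i = 0; i < n; ++i) cells[cellof(i)].push_back(i);
    double rc2 = rc * rc;
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c1 = (cz * ncy + cy) * ncx + cx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ny_ = cy + dy, nz_ = cz + dz;
                if (ny_ < 0 || ny_ >= ncy || nz_ < 0 || nz_ >= ncz) continue;
                int nx_ = ((cx + dx) % ncx + ncx) % ncx;
                int c2 = (nz_ * ncy + ny_) * ncx + nx_;
                if (c2 < c1) continue;
                for (size_t a = 0; a < cells[c1].size(); ++a) {
                  size_t bstart = (c1 == c2) ? a + 1 : 0;
                  for (size_t b = bstart; b < cells[c2].size(); ++b) {
                    int i = cells[c1][a], j = cells[c2][b];
                    if (i == j) continue;
                    int ii = std::min(i, j), jj = std::max(i, j);
                    double ddx = mindx(x[ii] - x[jj]);
                    double ddy = y[ii] - y[jj], ddz = z[ii] - z[jj];
                    double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
                    if (r2 > rc2) continue;
                    int cls = (species[ii] == species[jj])
                                ? (species[ii] == 0 ? 0 : 1) : 2;
                    double cc = cut[cls] + skin;
                    if (r2 > cc * cc) continue;
                    if (excluded(ii, jj)) continue;
                    nli.push_back(ii); nlj.push_back(jj); nlc.push_back(cls);
                  }
                }
              }
        }
    // duplicates possible when ncx < 3 (same cell pair reached via both x
    // wraps); deduplicate to keep each pair once
    if (ncx < 3) {
      std::vector<size_t> idx(nli.size());
      for (size_t k = 0; k < idx.size(); ++k) idx[k] = k;
      std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
        if (nli[a] != nli[b]) return nli[a] < nli[b];
        return nlj[a] < nlj[b];
      });
      std::vector<int> ui, uj, uc;
      for (size_t k = 0; k < idx.size(); ++k) {
        size_t id = idx[k];
        if (!ui.empty() && ui.back() == nli[id] && uj.back() == nlj[id])
          continue;
        ui.push_back(nli[id]); uj.push_back(nlj[id]); uc.push_back(nlc[id]);
      }
      nli.swap(ui); nlj.swap(uj); nlc.swap(uc);
    }
    x0 = x; y0 = y; z0 = z;
    nl_valid = true;
  }

  bool need_rebuild() const {
    if (!nl_valid) return true;
    double lim2 = (skin / 2) * (skin / 2);
    for (int i = 0; i < n; ++i) {
      double dx = mindx(x[i] - x0[i]);
      double dy = y[i] - y0[i], dz = z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  // returns false on guard-distance error
  bool compute_forces(bool allow_breaking) {
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
    wxx.assign(n, 0.0);
    Ebond = Eangle = 0.0; Elj[0] = Elj[1] = Elj[2] = 0.0;
    n_degenerate = 0; err_i = err_j = -1;

    // bonds (bilinear, breakable)
    for (size_t b = 0; b < bi.size(); ++b) {
      if (broken[b]) continue;
      int i = bi[b], j = bj[b];
      double dx = mindx(x[i] - x[j]);
      double dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double r0 = br0[b], r1 = br1[b], rb = brb[b];
      double e10 = 0.5 * bk0[b] * (r1 - r0) * (r1 - r0);
      if (r >= rb) {  // ruptured: no force and no stored energy
        if (allow_breaking) broken[b] = 1;
        continue;
      }
      double dudr, e;
      if (r < r1) {
        dudr = bk0[b] * (r - r0);
        e = 0.5 * bk0[b] * (r - r0) * (r - r0);
      } else {
        dudr = bk1[b] * (r - r0);
        e = e10 + 0.5 * bk1[b] * ((r - r0) * (r - r0) - (r1 - r0) * (r1 - r0));
      }
      Ebond += e;
      double fscale = -dudr / r;
      fx[i] += fscale * dx; fy[i] += fscale * dy; fz[i] += fscale * dz;
      fx[j] -= fscale * dx; fy[j] -= fscale * dy; fz[j] -= fscale * dz;
      double w = dudr * dx * dx / r;   // tension-positive axial virial
      wxx[i] += 0.5 * w; wxx[j] += 0.5 * w;
    }

    // angles (harmonic in the angle)
    for (size_t a = 0; a < ai.size(); ++a) {
      int i = ai[a], j = aj[a], k = ak[a];
      double d1x = mindx(x[i] - x[j]), d1y = y[i] - y[j], d1z = z[i] - z[j];
      double d2x = mindx(x[k] - x[j]), d2y = y[k] - y[j], d2z = z[k] - z[j];
      double r1s = d1x * d1x + d1y * d1y + d1z * d1z;
      double r2s = d2x * d2x + d2y * d2y + d2z * d2z;
      double r1 = std::sqrt(r1s), r2 = std::sqrt(r2s);
      double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
      c = std::max(-1.0, std::min(1.0, c));
      double s = std::sqrt(1.0 - c * c);
      double dth = std::acos(c) - aphi0[a];
      Eangle += 0.5 * akb[a] * dth * dth;
      if (s < 1e-8) { n_degenerate++; continue; }  // collinear: zero force
      double coef = -akb[a] * dth / s;
      double a11 = coef * c / r1s;
      double a12 = -coef / (r1 * r2);
      double a22 = coef * c / r2s;
      double fix = a11 * d1x + a12 * d2x, fiy = a11 * d1y + a12 * d2y,
             fiz = a11 * d1z + a12 * d2z;
      double fkx = a22 * d2x + a12 * d1x, fky = a22 * d2y + a12 * d1y,
             fkz = a22 * d2z + a12 * d1z;
      fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
      fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
      fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
      double w = -(fix * d1x + fkx * d2x);
      wxx[i] += w / 3; wxx[j] += w / 3; wxx[k] += w / 3;
    }

    // pairs
    if (need_rebuild()) build_neighbors();
    for (size_t p = 0; p < nli.size(); ++p) {
      int i = nli[p], j = nlj[p], cls = nlc[p];
      double dx = mindx(x[i] - x[j]);
      double dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut[cls] * cut[cls]) continue;
      if (r2 < GUARD * GUARD) { err_i = i; err_j = j; return false; }
      double sr2 = sig[cls] * sig[cls] / r2;
      double sr6 = sr2 * sr2 * sr2;
      double e = 4.0 * eps[cls] * (sr6 * sr6 - sr6);
      if (shift_lj) e -= ushift[cls];
      Elj[cls] += e;
      double dudr_r = -24.0 * eps[cls] * (2.0 * sr6 * sr6 - sr6) / r2;
      // dU/dr / r ; force on i = -dudr_r * delta
      fx[i] -= dudr_r * dx; fy[i] -= dudr_r * dy; fz[i] -= dudr_r * dz;
      fx[j] += dudr_r * dx; fy[j] += dudr_r * dy; fz[j] += dudr_r * dz;
      double w = dudr_r * dx * dx;      // = (dU/dr) dx^2 / r
      wxx[i] += 0.5 * w; wxx[j] += 0.5 * w;
    }
    return true;
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return 0.5 * ke / ACC;
  }

  // tension-positive axial virial stress in GPa over a subset
  double axial_stress(double volume, bool kinetic_term, int only_species) const {
    double w = 0.0;
    for (int i = 0; i < n; ++i) {
      if (only_species >= 0 && species[i] != only_species) continue;
      w += wxx[i];
      if (kinetic_term) w -= mass[i] * vx[i] * vx[i] / ACC;
    }
    return GPA * w / volume;
  }
};

static System make_system(const List &sys) {
  System S;
  NumericMatrix pos = sys["pos"], vel = sys["vel"];
  IntegerVector species = sys["species"];
  NumericVector mass = sys["mass"];
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.mass.resize(S.n); S.species.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.mass[i] = mass[i]; S.species[i] = species[i];
  }
  IntegerMatrix bonds = sys["bonds"];        // 0-based i, j
  NumericMatrix bpar = sys["bond_params"];   // r0 r1 rbreak k0 k1
  IntegerVector broken = sys["broken"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.bi.push_back(bonds(b, 0)); S.bj.push_back(bonds(b, 1));
    S.br0.push_back(bpar(b, 0)); S.br1.push_back(bpar(b, 1));
    S.brb.push_back(bpar(b, 2)); S.bk0.push_back(bpar(b, 3));
    S.bk1.push_back(bpar(b, 4));
    S.broken.push_back(broken[b]);
  }
  IntegerMatrix angles = sys["angles"];      // 0-based i j k
  NumericMatrix apar = sys["angle_params"];  // phi0_rad kB
  for (int a = 0; a < angles.nrow(); ++a) {
    S.ai.push_back(angles(a, 0)); S.aj.push_back(angles(a, 1));
    S.ak.push_back(angles(a, 2));
    S.aphi0.push_back(apar(a, 0)); S.akb.push_back(apar(a, 1));
  }
  NumericMatrix lj = sys["lj"];              // rows: coll, mineral, inter
  for (int c = 0; c < 3; ++c) {
    S.sig[c] = lj(c, 0); S.eps[c] = lj(c, 1); S.cut[c] = lj(c, 2);
    double sr6 = std::pow(S.sig[c] / S.cut[c], 6.0);
    S.ushift[c] = 4.0 * S.eps[c] * (sr6 * sr6 - sr6);
  }
  S.shift_lj = as<bool>(sys["shift_lj"]);
  NumericVector box = sys["box"];
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.skin = as<double>(sys["skin"]);
  S.max_cut = std::max(S.cut[0], std::max(S.cut[1], S.cut[2]));
  // exclusions: 1-2 and 1-3
  S.excl.assign(S.n, {});
  for (size_t b = 0; b < S.bi.size(); ++b) {
    S.excl[std::min(S.bi[b], S.bj[b])].push_back(std::max(S.bi[b], S.bj[b]));
  }
  for (size_t a = 0; a < S.ai.size(); ++a) {
    S.excl[std::min(S.ai[a], S.ak[a])].push_back(std::max(S.ai[a], S.ak[a]));
  }
  for (int i = 0; i < S.n; ++i) {
    std::sort(S.excl[i].begin(), S.excl[i].end());
    S.excl[i].erase(std::unique(S.excl[i].begin(), S.excl[i].end()),
                    S.excl[i].end());
  }
  return S;
}

static List pack_state(const System &S) {
  NumericMatrix pos(S.n, 3), vel(S.n, 3), force(S.n, 3);
  NumericVector wxx(S.n);
  for (int i = 0; i < S.n; ++i) {
    pos(i, 0) = S.x[i]; pos(i, 1) = S.y[i]; pos(i, 2) = S.z[i];
    vel(i, 0) = S.vx[i]; vel(i, 1) = S.vy[i]; vel(i, 2) = S.vz[i];
    force(i, 0) = S.fx[i]; force(i, 1) = S.fy[i]; force(i, 2) = S.fz[i];
    wxx[i] = S.wxx[i];
  }
  return List::create(
    _["pos"] = pos, _["vel"] = vel, _["force"] = force, _["wxx"] = wxx,
    _["broken"] = IntegerVector(S.broken.begin(), S.broken.end()),
    _["Lx"] = S.Lx);
}

// [[Rcpp::export]]
List cpp_compute_forces(List sys, bool allow_breaking = false) {
  System S = make_system(sys);
  bool ok = S.compute_forces(allow_breaking);
  if (!ok)
    stop("compute_forces: beads %d and %d closer than the %.1f A guard distance",
         S.err_i + 1, S.err_j + 1, GUARD);
  List out = pack_state(S);
  out["E_bond"] = S.Ebond;
  out["E_angle"] = S.Eangle;
  out["E_lj_coll"] = S.Elj[0];
  out["E_lj_min"] = S.Elj[1];
  out["E_lj_inter"] = S.Elj[2];
  out["kinetic"] = S.kinetic();
  out["n_degenerate_angles"] = S.n_degenerate;
  return out;
}

// [[Rcpp::export]]
List cpp_run(List sys, int n_steps, double dt,
             double temperature, double damping, bool thermostat,
             bool barostat, double baro_tau, double baro_modulus_gpa,
             double pull_rate_A_fs, double volume_factor,
             int sample_every, int frame_every,
             bool kinetic_stress, int seed, bool allow_breaking = true) {
  System S = make_system(sys);
  Rng rng((uint64_t)seed * 2654435761ULL + 12345ULL);
  double Lx_start = S.Lx;
  std::vector<double> xstart = S.x, ystart = S.y, zstart = S.z;

  if (!S.compute_forces(allow_breaking))
    stop("run: beads %d and %d closer than the guard distance",
         S.err_i + 1, S.err_j + 1);

  int n_samples = (sample_every > 0) ? n_steps / sample_every + 1 : 0;
  int ncol = 14;
  NumericMatrix samples(std::max(n_samples, 0), ncol);
  int srow = 0;
  List frames;
  std::vector<int> frame_steps;

  auto volume = [&]() { return volume_factor * S.Lx; };
  auto record = [&](int step) {
    if (srow >= samples.nrow()) return;
    double ke = S.kinetic();
    double temp = (S.n > 0) ? 2.0 * ke / (3.0 * S.n * KB) : 0.0;
    int nb = 0;
    for (size_t b = 0; b < S.broken.size(); ++b) nb += S.broken[b];
    double rmsd = 0.0;
    for (int i = 0; i < S.n; ++i) {
      double dx = S.mindx(S.x[i] - xstart[i]);
      double dy = S.y[i] - ystart[i], dz = S.z[i] - zstart[i];
      rmsd += dx * dx + dy * dy + dz * dz;
    }
    rmsd = std::sqrt(rmsd / S.n);
    samples(srow, 0) = step;
    samples(srow, 1) = step * dt;
    samples(srow, 2) = S.Lx;
    samples(srow, 3) = S.axial_stress(volume(), kinetic_stress, -1);
    samples(srow, 4) = S.axial_stress(volume(), kinetic_stress, 1);
    samples(srow, 5) = temp;
    samples(srow, 6) = S.Ebond;
    samples(srow, 7) = S.Eangle;
    samples(srow, 8) = S.Elj[0];
    samples(srow, 9) = S.Elj[1];
    samples(srow, 10) = S.Elj[2];
    samples(srow, 11) = nb;
    samples(srow, 12) = ke;
    samples(srow, 13) = rmsd;
    srow++;
  };
  auto snap_frame = [&](int step) {
    NumericMatrix pos(S.n, 3);
    for (int i = 0; i < S.n; ++i) {
      pos(i, 0) = S.x[i]; pos(i, 1) = S.y[i]; pos(i, 2) = S.z[i];
    }
    frames.push_back(List::create(_["step"] = step, _["pos"] = pos,
                                  _["Lx"] = S.Lx,
                                  _["broken"] = IntegerVector(S.broken.begin(),
                                                              S.broken.end())));
  };

  if (sample_every > 0) record(0);
  if (frame_every > 0) snap_frame(0);

  double sq_noise_base = (thermostat && temperature > 0)
    ? std::sqrt(2.0 * KB * temperature / (damping * dt * ACC)) : 0.0;

  for (int step = 1; step <= n_steps; ++step) {
    // half kick
    for (int i = 0; i < S.n; ++i) {
      double inv = ACC / S.mass[i];
      S.vx[i] += 0.5 * dt * S.fx[i] * inv;
      S.vy[i] += 0.5 * dt * S.fy[i] * inv;
      S.vz[i] += 0.5 * dt * S.fz[i] * inv;
    }
    // drift
    for (int i = 0; i < S.n; ++i) {
      S.x[i] += dt * S.vx[i];
      S.y[i] += dt * S.vy[i];
      S.z[i] += dt * S.vz[i];
    }
    // box updates (affine remap of x and vx)
    double mu = 1.0;
    if (pull_rate_A_fs != 0.0) {
      double Lnew = S.Lx + pull_rate_A_fs * dt;
      mu *= Lnew / S.Lx;
    }
    if (barostat) {
      double sax = S.axial_stress(volume(), kinetic_stress, -1);
      double dmu = -(dt / baro_tau) * sax / baro_modulus_gpa;
      dmu = std::max(-2e-4, std::min(2e-4, dmu));
      mu *= 1.0 + dmu;
    }
    if (mu != 1.0) {
      S.Lx *= mu;
      for (int i = 0; i < S.n; ++i) { S.x[i] *= mu; S.vx[i] *= mu; }
      // scale the list's reference positions too: the skin criterion then
      // accounts for the (small) affine distortion instead of forcing a
      // rebuild every step
      if (S.nl_valid) for (int i = 0; i < S.n; ++i) S.x0[i] *= mu;
    }
    // wrap x
    for (int i = 0; i < S.n; ++i)
      S.x[i] -= S.Lx * std::floor(S.x[i] / S.Lx);

    if (!S.compute_forces(allow_breaking))
      stop("run: step %d, beads %d and %d closer than the guard distance",
           step, S.err_i + 1, S.err_j + 1);

    // Langevin friction + noise as forces
    if (thermostat) {
      for (int i = 0; i < S.n; ++i) {
        double fr = S.mass[i] / (damping * ACC);
        double sq = sq_noise_base * std::sqrt(S.mass[i]);
        S.fx[i] += -fr * S.vx[i] + sq * rng.gauss();
        S.fy[i] += -fr * S.vy[i] + sq * rng.gauss();
        S.fz[i] += -fr * S.vz[i] + sq * rng.gauss();
      }
    }
    // half kick
    for (int i = 0; i < S.n; ++i) {
      double inv = ACC / S.mass[i];
      S.vx[i] += 0.5 * dt * S.fx[i] * inv;
      S.vy[i] += 0.5 * dt * S.fy[i] * inv;
      S.vz[i] += 0.5 * dt * S.fz[i] * inv;
    }
    if (sample_every > 0 && step % sample_every == 0) record(step);
    if (frame_every > 0 && step % frame_every == 0) snap_frame(step);
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List out = pack_state(S);
  out["samples"] = samples;
  out["n_samples"] = srow;
  out["frames"] = frames;
  out["Lx_start"] = Lx_start;
  out["E_bond"] = S.Ebond;
  out["E_angle"] = S.Eangle;
  out["E_lj_coll"] = S.Elj[0];
  out["E_lj_min"] = S.Elj[1];
  out["E_lj_inter"] = S.Elj[2];
  out["kinetic"] = S.kinetic();
  return out;
}

// Keep candidate points whose minimum distance to any reference point is at
// least `cutoff` (x periodic with box length Lx). Used by the mineralizer.
// [[Rcpp::export]]
LogicalVector cpp_min_dist_keep(NumericMatrix cand, NumericMatrix ref,
                                double cutoff, double Lx) {
  int nc = cand.nrow(), nr = ref.nrow();
  LogicalVector keep(nc, true);
  double c2 = cutoff * cutoff;
  // bin reference points on a grid of cell size >= cutoff
  double cs = std::max(cutoff, 1.0);
  int ncx = std::max(1, (int)std::floor(Lx / cs));
  double cellx = Lx / ncx;
  double ymin = 1e30, ymax = -1e30, zmin = 1e30, zmax = -1e30;
  for (int i = 0; i < nr; ++i) {
    ymin = std::min(ymin, ref(i, 1)); ymax = std::max(ymax, ref(i, 1));
    zmin = std::min(zmin, ref(i, 2)); zmax = std::max(zmax, ref(i, 2));
  }
  int ncy = std::max(1, (int)std::floor((ymax - ymin) / cs) + 1);
  int ncz = std::max(1, (int)std::floor((zmax - zmin) / cs) + 1);
  std::vector<std::vector<int>> cells(ncx * ncy * ncz);
  auto wrap = [&](double xv) { return xv - Lx * std::floor(xv / Lx); };
  for (int i = 0; i < nr; ++i) {
    int cx = std::min(ncx - 1, (int)(wrap(ref(i, 0)) / cellx));
    int cy = std::min(ncy - 1, std::max(0, (int)((ref(i, 1) - ymin) / cs)));
    int cz = std::min(ncz - 1, std::max(0, (int)((ref(i, 2) - zmin) / cs)));
    cells[(cz * ncy + cy) * ncx + cx].push_back(i);
  }
  for (int i = 0; i < nc; ++i) {
    double xi = wrap(cand(i, 0)), yi = cand(i, 1), zi = cand(i, 2);
    int cx = std::min(ncx - 1, (int)(xi / cellx));
    int cy0 = (int)((yi - ymin) / cs), cz0 = (int)((zi - zmin) / cs);
    bool ok = true;
    for (int dz = -1; dz <= 1 && ok; ++dz)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          int cy = cy0 + dy, cz = cz0 + dz;
          if (cy < 0 || cy >= ncy || cz < 0 || cz >= ncz) continue;
          int cxx = ((cx + dx) % ncx + ncx) % ncx;
          const std::vector<int> &cell = cells[(cz * ncy + cy) * ncx + cxx];
          for (size_t kk = 0; kk < cell.size(); ++kk) {
            int j = cell[kk];
            double ddx = xi - wrap(ref(j, 0));
            ddx -= Lx * std::round(ddx / Lx);
            double ddy = yi - ref(j, 1), ddz = zi - ref(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) { ok = false; break; }
          }
        }
    keep[i] = ok;
  }
  return keep;
}
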