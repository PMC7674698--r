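// Photon Monte Carlo transport through the voxel phantom.
//
// Woodcock (delta) tracking with an energy-dependent global majorant;
// photoelectric events deposit the full photon energy in the interaction
// voxel; incoherent events sample the Klein-Nishina distribution (Kahn's
// rejection method) and deposit the electron share locally (kerma
// approximation: secondary-electron ranges are sub-voxel below 150 keV);
// photons escaping the grid terminate; photons falling below the cutoff
// deposit the residual locally. Coherent scattering is optional (dipole
// angular law) and off by default.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double u() { return (next() >> 11) * 1.1102230246251565e-16; } // [0,1)
  double u_open() { double v; do { v = u(); } while (v <= 0.0); return v; }
};

const double MEC2_KEV = 510.99895;

// Kahn's rejection sampling of the Klein-Nishina ratio x = E/E'
double kahn_x(double alpha, Xoshiro &rng) {
  const double p = (1.0 + 2.0 * alpha) / (9.0 + 2.0 * alpha);
  for (;;) {
    double r1 = rng.u(), r2 = rng.u(), r3 = rng.u();
    if (r1 <= p) {
      double x = 1.0 + 2.0 * alpha * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return x;
    } else {
      double x = (1.0 + 2.0 * alpha) / (1.0 + 2.0 * alpha * r2);
      double ct = 1.0 - (x - 1.0) / alpha;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) return x;
    }
  }
}

struct MuTable {
  // linear interpolation on a uniform-log energy grid
  int nE, nM;
  double lE0, dlE;
  const double *photo, *incoh, *coh, *tot, *maj;
  double frac_idx(double e_kev, int &i) const {
    double t = (std::log(e_kev) - lE0) / dlE;
    if (t < 0) t = 0;
    if (t > nE - 1.001) t = nE - 1.001;
    i = (int)t;
    return t - i;
  }
  double at(const double *m, int col, double e, int i, double f) const {
    const double *c = m + (size_t)col * nE;
    (void)e;
    return c[i] * (1.0 - f) + c[i + 1] * f;
  }
  double majorant(double e) const {
    int i; double f = frac_idx(e, i);
    return maj[i] * (1.0 - f) + maj[i + 1] * f;
  }
};

inline void rotate_dir(double *d, double ct, double phi, Xoshiro &) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double dz = d[2];
  if (std::fabs(dz) > 0.999999) {
    double sgn = dz > 0 ? 1.0 : -1.0;
    d[0] = st * cp; d[1] = sgn * st * sp; d[2] = sgn * ct;
  } else {
    double den = std::sqrt(1.0 - dz * dz);
    double nx = d[0] * ct + st * (d[0] * dz * cp - d[1] * sp) / den;
    double ny = d[1] * ct + st * (d[1] * dz * cp + d[0] * sp) / den;
    double nz = dz * ct - den * st * cp;
    d[0] = nx; d[1] = ny; d[2] = nz;
  }
  double n = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

struct Grid {
  const int *lab;
  int nx, ny, nz;
  double h;               // mm
  int label_at(const double *p) const {
    int ix = (int)(p[0] / h), iy = (int)(p[1] / h), iz = (int)(p[2] / h);
    return lab[(size_t)ix + (size_t)nx * (iy + (size_t)ny * iz)];
  }
  bool inside(const double *p) const {
    return p[0] > 0 && p[0] < nx * h && p[1] > 0 && p[1] < ny * h &&
           p[2] > 0 && p[2] < nz * h;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_transport(IntegerVector labels, IntegerVector dims, double voxel_mm,
                   IntegerVector mat_of_label, NumericVector egrid_kev,
                   NumericMatrix mu_photo, NumericMatrix mu_incoh,
                   NumericMatrix mu_coh, bool use_coherent,
                   List source_vox, NumericVector source_frac,
                   NumericVector line_kev, NumericVector line_prob,
                   double cutoff_kev, int n_hist, int n_batch, double seed) {
  if (n_hist < 1) stop("n_hist must be >= 1");
  if (n_batch < 1) stop("n_batch must be >= 1");
  const int nE = egrid_kev.size(), nM = mu_photo.ncol();
  const int n_lab = mat_of_label.size();  // label ids 0..n_lab-1

  // per-material totals and energy-wise majorant
  std::vector<double> tot((size_t)nE * nM), maj(nE, 0.0);
  for (int m = 0; m < nM; ++m)
    for (int i = 0; i < nE; ++i) {
      double t = mu_photo(i, m) + mu_incoh(i, m) +
                 (use_coherent ? mu_coh(i, m) : 0.0);
      tot[(size_t)m * nE + i] = t;
      if (t > maj[i]) maj[i] = t;
    }

  MuTable mt;
  mt.nE = nE; mt.nM = nM;
  mt.lE0 = std::log(egrid_kev[0]);
  mt.dlE = (std::log(egrid_kev[nE - 1]) - mt.lE0) / (nE - 1);
  mt.photo = REAL(mu_photo); mt.incoh = REAL(mu_incoh);
  mt.coh = REAL(mu_coh); mt.tot = tot.data(); mt.maj = maj.data();

  Grid g;
  g.lab = INTEGER(labels);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.h = voxel_mm;

  const int n_comp = source_vox.size();
  std::vector<std::vector<int>> cvox(n_comp);
  std::vector<double> cum(n_comp);
  double acc = 0.0;
  for (int c = 0; c < n_comp; ++c) {
    cvox[c] = as<std::vector<int>>(source_vox[c]);
    acc += source_frac[c];
    cum[c] = acc;
  }
  if (std::fabs(acc - 1.0) > 1e-9) stop("source fractions must sum to 1");

  const int n_lines = line_kev.size();
  std::vector<double> lcum(n_lines);
  acc = 0.0;
  for (int l = 0; l < n_lines; ++l) { acc += line_prob[l]; lcum[l] = acc; }

  NumericMatrix edep(n_batch, n_lab);   // keV sums per batch per label
  NumericVector emitted(n_batch);

  Xoshiro rng((uint64_t)seed);

  for (int ih = 0; ih < n_hist; ++ih) {
    const int b = (int)((double)ih * n_batch / n_hist);
    // source voxel
    double u = rng.u();
    int c = 0;
    while (c < n_comp - 1 && u > cum[c]) ++c;
    while (cvox[c].empty()) ++c;        // defensive; validated in R
    const std::vector<int> &vox = cvox[c];
    int vi = vox[(int)(rng.u() * vox.size()) % vox.size()] - 1; // 0-based
    int ix = vi % g.nx, iy = (vi / g.nx) % g.ny, iz = vi / (g.nx * g.ny);
    double pos[3] = { (ix + rng.u()) * g.h, (iy + rng.u()) * g.h,
                      (iz + rng.u()) * g.h };
    // emission line
    u = rng.u();
    int l = 0;
    while (l < n_lines - 1 && u > lcum[l]) ++l;
    double E = line_kev[l];
    emitted[b] += E;
    // isotropic direction
    double ct0 = 2.0 * rng.u() - 1.0, ph0 = 6.283185307179586 * rng.u();
    double st0 = std::sqrt(1.0 - ct0 * ct0);
    double dir[3] = { st0 * std::cos(ph0), st0 * std::sin(ph0), ct0 };

    double mu_mj = mt.majorant(E);
    for (;;) {
      double step = -std::log(rng.u_open()) / mu_mj * 10.0; // mm
      pos[0] += step * dir[0]; pos[1] += step * dir[1]; pos[2] += step * dir[2];
      if (!g.inside(pos)) break;                      // escaped
      int lab = g.label_at(pos);
      int m = mat_of_label[lab];
      int iE; double fE = mt.frac_idx(E, iE);
      double mu_t = mt.at(mt.tot, m, E, iE, fE);
      if (rng.u() * mu_mj > mu_t) continue;           // null collision
      double mu_ph = mt.at(mt.photo, m, E, iE, fE);
      double u2 = rng.u() * mu_t;
      if (u2 <= mu_ph) {                              // photoelectric
        edep(b, lab) += E;
        break;
      }
      double mu_co = use_coherent ? mt.at(mt.coh, m, E, iE, fE) : 0.0;
      if (use_coherent && u2 <= mu_ph + mu_co) {      // coherent: no E loss
        // dipole (1 + cos^2) angular law
        double ct;
        do { ct = 2.0 * rng.u() - 1.0; } while (rng.u() * 2.0 > 1.0 + ct * ct);
        rotate_dir(dir, ct, 6.283185307179586 * rng.u(), rng);
        continue;
      }
      // incoherent (Compton)
      double alpha = E / MEC2_KEV;
      double x = kahn_x(alpha, rng);
      double Enew = E / x;
      double ct = 1.0 - (x - 1.0) / alpha;
      edep(b, lab) += E - Enew;
      if (Enew < cutoff_kev) {                        // local cutoff deposit
        edep(b, lab) += Enew;
        break;
      }
      E = Enew;
      mu_mj = mt.majorant(E);
      rotate_dir(dir, ct, 6.283185307179586 * rng.u(), rng);
    }
  }
  // convert keV -> MeV
  for (int b = 0; b < n_batch; ++b) {
    emitted[b] /= 1000.0;
    for (int j = 0; j < n_lab; ++j) edep(b, j) /= 1000.0;
  }
  return List::create(_["edep_mev"] = edep, _["emitted_mev"] = emitted,
                      _["n_hist"] = n_hist);
}

// Distance (cm) from a fixed origin to the first real collision, for
// validating the delta-tracking free-path sampler against exp(-mu x) and,
// with isotropic emission (dir = c(0,0,0)), the 1/r^2 x exp(-mu r)
// first-collision density of a point source. Escapes are returned as Inf.
// [[Rcpp::export]]
NumericVector cpp_first_flight(IntegerVector labels, IntegerVector dims,
                               double voxel_mm, IntegerVector mat_of_label,
                               NumericVector egrid_kev,
                               NumericMatrix mu_photo, NumericMatrix mu_incoh,
                               NumericMatrix mu_coh, bool use_coherent,
                               NumericVector origin_mm, NumericVector dir,
                               double energy_kev, int n, double seed) {
  const int nE = egrid_kev.size(), nM = mu_photo.ncol();
  std::vector<double> tot((size_t)nE * nM), maj(nE, 0.0);
  for (int m = 0; m < nM; ++m)
    for (int i = 0; i < nE; ++i) {
      double t = mu_photo(i, m) + mu_incoh(i, m) +
                 (use_coherent ? mu_coh(i, m) : 0.0);
      tot[(size_t)m * nE + i] = t;
      if (t > maj[i]) maj[i] = t;
    }
  MuTable mt;
  mt.nE = nE; mt.nM = nM;
  mt.lE0 = std::log(egrid_kev[0]);
  mt.dlE = (std::log(egrid_kev[nE - 1]) - mt.lE0) / (nE - 1);
  mt.photo = REAL(mu_photo); mt.incoh = REAL(mu_incoh);
  mt.coh = REAL(mu_coh); mt.tot = tot.data(); mt.maj = maj.data();
  Grid g;
  g.lab = INTEGER(labels);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.h = voxel_mm;

  double nrm = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  const bool isotropic = nrm == 0.0;
  double d0[3] = { 0.0, 0.0, 1.0 };
  if (!isotropic) {
    d0[0] = dir[0]/nrm; d0[1] = dir[1]/nrm; d0[2] = dir[2]/nrm;
  }
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  double mu_mj = mt.majorant(energy_kev);
  int iE; double fE = mt.frac_idx(energy_kev, iE);
  for (int i = 0; i < n; ++i) {
    double pos[3] = { origin_mm[0], origin_mm[1], origin_mm[2] };
    if (isotropic) {
      double ct = 2.0 * rng.u() - 1.0, ph = 6.283185307179586 * rng.u();
      double st = std::sqrt(1.0 - ct * ct);
      d0[0] = st * std::cos(ph); d0[1] = st * std::sin(ph); d0[2] = ct;
    }
    double travelled = 0.0, res = R_PosInf;
    for (;;) {
      double step = -std::log(rng.u_open()) / mu_mj * 10.0;
      travelled += step;
      pos[0] += step * d0[0]; pos[1] += step * d0[1]; pos[2] += step * d0[2];
      if (!g.inside(pos)) break;
      int m = mat_of_label[g.label_at(pos)];
      if (rng.u() * mu_mj <= mt.at(mt.tot, m, energy_kev, iE, fE)) {
        res = travelled / 10.0;   // cm
        break;
      }
    }
    out[i] = res;
  }
  return out;
}

// Klein-Nishina sampler exposed for distribution-level validation.
// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy_kev, int n, double seed) {
  Xoshiro rng((uint64_t)seed);
  double alpha = energy_kev / MEC2_KEV;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double x = kahn_x(alpha, rng);
    out(i, 0) = energy_kev / x;
    out(i, 1) = 1.0 - (x - 1.0) / alpha;
  }
  colnames(out) = CharacterVector::create("energy_kev", "cos_theta");
  return out;
}
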