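#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel lattice helpers. The lattice is centered on the origin: axis i
// spans [-dims[i]*pitch/2, dims[i]*pitch/2].

// Amanatides & Woo traversal: visit voxels along a ray with chord lengths.
// Returns an (nvisited x 4) matrix: 1-based ix, iy, iz and chord (cm).
// [[Rcpp::export(name = ".siddon_cpp")]]
NumericMatrix siddon_cpp(NumericVector origin, NumericVector direction,
                         IntegerVector dims, double pitch) {
  double dx = direction[0], dy = direction[1], dz = direction[2];
  double norm = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (norm <= 0) stop("ray direction must be non-zero");
  dx /= norm; dy /= norm; dz /= norm;
  double d[3] = {dx, dy, dz};
  double o[3] = {origin[0], origin[1], origin[2]};
  double half[3];
  for (int i = 0; i < 3; ++i) half[i] = dims[i] * pitch / 2.0;

  // clip to the box
  double tmin = 0.0, tmax = R_PosInf;
  // allow origins inside the box: start from max(0, entry)
  tmin = R_NegInf;
  for (int i = 0; i < 3; ++i) {
    if (std::fabs(d[i]) < 1e-300) {
      if (o[i] <= -half[i] || o[i] >= half[i]) return NumericMatrix(0, 4);
    } else {
      double t1 = (-half[i] - o[i]) / d[i];
      double t2 = (half[i] - o[i]) / d[i];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmin < 0) tmin = 0;
  if (tmax <= tmin) return NumericMatrix(0, 4);

  // entry point, nudged inside
  double t = tmin;
  double eps = 1e-12 * (std::fabs(tmax) + 1.0);
  double p[3];
  for (int i = 0; i < 3; ++i) p[i] = o[i] + (t + eps) * d[i];
  int idx[3];
  for (int i = 0; i < 3; ++i) {
    idx[i] = (int)std::floor((p[i] + half[i]) / pitch);
    if (idx[i] < 0) idx[i] = 0;
    if (idx[i] >= dims[i]) idx[i] = dims[i] - 1;
  }
  int step[3];
  double tDelta[3], tMaxA[3];
  for (int i = 0; i < 3; ++i) {
    if (d[i] > 0) {
      step[i] = 1;
      tDelta[i] = pitch / d[i];
      tMaxA[i] = tmin + ((idx[i] + 1) * pitch - half[i] - o[i] - tmin * d[i]) / d[i];
      tMaxA[i] = ((idx[i] + 1) * pitch - half[i] - o[i]) / d[i];
    } else if (d[i] < 0) {
      step[i] = -1;
      tDelta[i] = -pitch / d[i];
      tMaxA[i] = (idx[i] * pitch - half[i] - o[i]) / d[i];
    } else {
      step[i] = 0;
      tDelta[i] = R_PosInf;
      tMaxA[i] = R_PosInf;
    }
  }

  std::vector<double> out;
  out.reserve(4 * (dims[0] + dims[1] + dims[2]));
  double tcur = tmin;
  while (tcur < tmax - 1e-14) {
    int ax = 0;
    if (tMaxA[1] < tMaxA[ax]) ax = 1;
    if (tMaxA[2] < tMaxA[ax]) ax = 2;
    double tnext = tMaxA[ax] < tmax ? tMaxA[ax] : tmax;
    double chord = tnext - tcur;
    if (chord > 0) {
      out.push_back(idx[0] + 1);
      out.push_back(idx[1] + 1);
      out.push_back(idx[2] + 1);
      out.push_back(chord);
    }
    if (tMaxA[ax] >= tmax) break;
    tcur = tMaxA[ax];
    tMaxA[ax] += tDelta[ax];
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= dims[ax]) break;
  }
  int n = out.size() / 4;
  NumericMatrix res(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) res(i, j) = out[4 * i + j];
  return res;
}

// log-log interpolation of material coefficients at energy E
static void interp_materials(const NumericMatrix &coef, const NumericVector &grid,
                             double E, std::vector<double> &out) {
  int ng = grid.size(), nm = coef.nrow();
  int j = 0;
  if (E <= grid[0]) j = 0;
  else if (E >= grid[ng - 1]) j = ng - 2;
  else {
    while (j < ng - 2 && grid[j + 1] < E) ++j;
  }
  double lx = std::log(E);
  double x0 = std::log(grid[j]), x1 = std::log(grid[j + 1]);
  double w = (lx - x0) / (x1 - x0);
  if (w < 0) w = 0;
  if (w > 1) w = 1;
  for (int m = 0; m < nm; ++m) {
    double y0 = std::log(coef(m, j)), y1 = std::log(coef(m, j + 1));
    out[m] = std::exp(y0 + w * (y1 - y0));
  }
}

static double kn_sigma(double E) {
  const double r_e = 2.8179403262e-13, mec2 = 0.51099895;
  double k = E / mec2;
  return 2.0 * M_PI * r_e * r_e *
    ((1 + k) / (k * k) * (2 * (1 + k) / (1 + 2 * k) - std::log(1 + 2 * k) / k) +
     std::log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / ((1 + 2 * k) * (1 + 2 * k)));
}

// sample the Klein-Nishina scattered-energy fraction eps = E'/E and
// polar cosine; rejection with a uniform proposal on [eps_min, 1]
static void sample_kn(double E, double &eps, double &mu_pol) {
  double k = E / 0.51099895;
  double eps_min = 1.0 / (1.0 + 2.0 * k);
  double fbound = std::max(2.0, eps_min + 1.0 / eps_min);
  for (;;) {
    double e = eps_min + unif_rand() * (1.0 - eps_min);
    double c = 1.0 - (1.0 / e - 1.0) / k;
    double f = e + 1.0 / e - (1.0 - c * c);
    if (unif_rand() * fbound <= f) {
      eps = e;
      mu_pol = c;
      return;
    }
  }
}

// rotate direction d by polar cosine mu_pol and uniform azimuth
static void rotate_direction(double d[3], double mu_pol) {
  double phi = 2.0 * M_PI * unif_rand();
  double sint = std::sqrt(std::max(0.0, 1.0 - mu_pol * mu_pol));
  double u = d[0], v = d[1], w = d[2];
  double a = std::sqrt(std::max(1e-30, 1.0 - w * w));
  double nu, nv, nw;
  if (a > 1e-10) {
    nu = u * mu_pol + sint * (u * w * std::cos(phi) - v * std::sin(phi)) / a;
    nv = v * mu_pol + sint * (v * w * std::cos(phi) + u * std::sin(phi)) / a;
    nw = w * mu_pol - sint * a * std::cos(phi);
  } else {
    nu = sint * std::cos(phi);
    nv = sint * std::sin(phi);
    nw = (w > 0 ? mu_pol : -mu_pol);
  }
  double nn = std::sqrt(nu * nu + nv * nv + nw * nw);
  d[0] = nu / nn; d[1] = nv / nn; d[2] = nw / nn;
}

// Analog photon Monte Carlo on the voxel lattice with delta tracking.
// mat_idx: 0-based material row per voxel, -1 = vacuum, in fill order
// (x fastest). mu/muen: (nmat x ngrid) linear coefficients (1/cm) on
// the energy grid; ne: electrons per cm^3 per material. The source is
// a monodirectional +x plane at x0 spanning [y1,y2] x [z1,z2].
// Deposits are tallied per material in MeV per batch.
// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(IntegerVector mat_idx, IntegerVector dims, double pitch,
                      NumericMatrix mu, NumericMatrix muen, NumericVector ne,
                      NumericVector grid, double E0,
                      double x0, double y1, double y2, double z1, double z2,
                      int n, int batches, bool scatter, double e_cutoff) {
  int nm = mu.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double half[3] = {nx * pitch / 2.0, ny * pitch / 2.0, nz * pitch / 2.0};
  NumericMatrix dep(nm, batches);
  double n_escape = 0.0;

  std::vector<double> mu_E(nm), muen_E(nm);
  double mu_maj = 0.0, E_cur = -1.0, sig_kn = 0.0;

  int per_batch = n / batches;
  if (per_batch < 1) stop("n must be >= batches");

  for (int b = 0; b < batches; ++b) {
    for (int h = 0; h < per_batch; ++h) {
      double pos[3] = {x0, y1 + unif_rand() * (y2 - y1),
                       z1 + unif_rand() * (z2 - z1)};
      double dir[3] = {1.0, 0.0, 0.0};
      double E = E0;
      if (E != E_cur) {
        interp_materials(mu, grid, E, mu_E);
        interp_materials(muen, grid, E, muen_E);
        mu_maj = 0.0;
        for (int m = 0; m < nm; ++m) if (mu_E[m] > mu_maj) mu_maj = mu_E[m];
        sig_kn = kn_sigma(E);
        E_cur = E;
      }

      // advance to the lattice box if outside
      bool alive = true;
      {
        double tmin = R_NegInf, tmax = R_PosInf;
        for (int i = 0; i < 3; ++i) {
          if (std::fabs(dir[i]) < 1e-300) {
            if (pos[i] <= -half[i] || pos[i] >= half[i]) { alive = false; break; }
          } else {
            double t1 = (-half[i] - pos[i]) / dir[i];
            double t2 = (half[i] - pos[i]) / dir[i];
            if (t1 > t2) std::swap(t1, t2);
            if (t1 > tmin) tmin = t1;
            if (t2 < tmax) tmax = t2;
          }
        }
        if (!alive || tmax <= std::max(tmin, 0.0)) { n_escape += 1; continue; }
        if (tmin > 0) {
          for (int i = 0; i < 3; ++i) pos[i] += (tmin + 1e-9 * pitch) * dir[i];
        }
      }

      while (alive) {
        double s = -std::log(unif_rand()) / mu_maj;
        for (int i = 0; i < 3; ++i) pos[i] += s * dir[i];
        int ix = (int)std::floor((pos[0] + half[0]) / pitch);
        int iy = (int)std::floor((pos[1] + half[1]) / pitch);
        int iz = (int)std::floor((pos[2] + half[2]) / pitch);
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
          n_escape += 1;
          break;  // escaped the lattice
        }
        int m = mat_idx[ix + nx * (iy + (long long)ny * iz)];
        if (m < 0) continue;              // vacuum: virtual collision
        double mu_c = mu_E[m];
        if (unif_rand() * mu_maj > mu_c) continue;  // virtual collision

        // real collision
        double p_compton = scatter ? std::min(1.0, ne[m] * sig_kn / mu_c) : 0.0;
        if (!scatter) {
          // kerma expectation deposit for the primary-only estimator
          dep(m, b) += E * (muen_E[m] / mu_c);
          alive = false;
        } else if (unif_rand() < p_compton) {
          double eps, mu_pol;
          sample_kn(E, eps, mu_pol);
          dep(m, b) += E * (1.0 - eps);
          E *= eps;
          if (E <= e_cutoff) {
            dep(m, b) += E;  // terminate below the table floor
            alive = false;
          } else {
            rotate_direction(dir, mu_pol);
            interp_materials(mu, grid, E, mu_E);
            interp_materials(muen, grid, E, muen_E);
            mu_maj = 0.0;
            for (int mm = 0; mm < nm; ++mm) if (mu_E[mm] > mu_maj) mu_maj = mu_E[mm];
            sig_kn = kn_sigma(E);
            E_cur = E;
          }
        } else {
          dep(m, b) += E;  // photoabsorption
          alive = false;
        }
      }
      // restore energy-dependent tables for the next history if needed
      if (E_cur != E0) {
        interp_materials(mu, grid, E0, mu_E);
        interp_materials(muen, grid, E0, muen_E);
        mu_maj = 0.0;
        for (int m = 0; m < nm; ++m) if (mu_E[m] > mu_maj) mu_maj = mu_E[m];
        sig_kn = kn_sigma(E0);
        E_cur = E0;
      }
    }
  }
  return List::create(_["dep_MeV"] = dep, _["histories"] = per_batch * batches,
                      _["n_escape"] = n_escape);
}
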