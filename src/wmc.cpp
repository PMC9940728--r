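#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Unpolarized Fresnel reflection coefficient for internal incidence,
// n1 (medium) -> n2 (outside), ci = |cos(theta_i)|.
static inline double fresnel_R(double n1, double n2, double ci) {
  if (ci < 0.0) ci = 0.0;
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine.
static inline double hg_cos(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c < -1.0) c = -1.0;
  if (c > 1.0) c = 1.0;
  return c;
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and azimuth phi.
static inline void spin(double &ux, double &uy, double &uz,
                        double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

// Scattering-only reference walk in a semi-infinite half-space (z > 0),
// pencil beam entering at the origin along +z. Steps are sampled at unit
// scattering coefficient, so recorded pathlengths are dimensionless (mean
// free paths). At each boundary hit the photon weight is split: the Fresnel
// transmitted fraction escapes (cumulative path and weight recorded), the
// reflected fraction continues. Photons are terminated when the weight
// falls below wmin or the cumulative path exceeds max_path; the residual
// weight is then tallied as escaping at the termination pathlength ("tail
// capture": in a non-absorbing half-space every photon eventually escapes,
// so dropping the residual would bias Rd low at small mu_a; recording it at
// a pathlength that is a lower bound of the true escape path gives exact
// weight conservation at mu_a = 0 and an upward bias bounded by
// w * exp(-mu_a * max_path / mu_s) otherwise). Uses R's RNG: seed with
// set.seed() before calling.
// [[Rcpp::export(name = ".wmc_run")]]
List wmc_run(int n_photons, double n_medium, double n_outside, double g,
             double max_path, double wmin) {
  std::vector<double> paths, weights;
  paths.reserve(n_photons * 4);
  weights.reserve(n_photons * 4);
  GetRNGstate();
  for (int i = 0; i < n_photons; ++i) {
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, s_tot = 0.0;
    bool alive = true;
    while (alive) {
      double u = unif_rand();
      if (u <= 0.0) u = 1e-300;
      double step = -std::log(u);
      // propagate, resolving (possibly one) boundary hit within the step
      while (step > 0.0) {
        if (uz < 0.0 && z + uz * step <= 0.0) {
          double s_b = -z / uz;  // distance to boundary
          s_tot += s_b;
          step -= s_b;
          z = 0.0;
          double R = fresnel_R(n_medium, n_outside, -uz);
          double esc = (1.0 - R) * w;
          if (esc > 0.0) {
            paths.push_back(s_tot);
            weights.push_back(esc);
          }
          w *= R;
          if (w < wmin || s_tot > max_path) { alive = false; break; }
          uz = -uz;  // specular internal reflection
        } else {
          z += uz * step;
          s_tot += step;
          step = 0.0;
        }
      }
      if (alive && s_tot > max_path) alive = false;
      if (!alive) {
        if (w > 0.0) {  // tail capture of the residual weight
          paths.push_back(s_tot);
          weights.push_back(w);
        }
        break;
      }
      double ct = hg_cos(g);
      double phi = 2.0 * M_PI * unif_rand();
      spin(ux, uy, uz, ct, phi);
    }
  }
  PutRNGstate();
  return List::create(_["escaped_paths"] = wrap(paths),
                      _["escape_weights"] = wrap(weights),
                      _["n_launched"] = n_photons);
}

// Reweight one reference walk ensemble to diffuse reflectance for vectors
// of absorption and scattering coefficients: Rd_j = (1/N) sum_i w_i *
// exp(-mua_j * L_ij), physical path L_ij = path_i / mus_j.
// [[Rcpp::export(name = ".wmc_reflectance")]]
NumericVector wmc_reflectance(NumericVector paths, NumericVector weights,
                              int n_launched, NumericVector mua,
                              NumericVector mus) {
  int nl = mua.size(), ne = paths.size();
  NumericVector rd(nl);
  for (int j = 0; j < nl; ++j) {
    double k = mua[j] / mus[j];
    double acc = 0.0;
    for (int i = 0; i < ne; ++i)
      acc += weights[i] * std::exp(-k * paths[i]);
    rd[j] = acc / n_launched;
  }
  return rd;
}

// As .wmc_reflectance, but also returns dRd/dk where k = mua/mus is the
// per-wavelength decay constant: dRd/dk = -(1/N) sum_i w_i path_i
// exp(-k path_i). Used for analytic Jacobians in reflectance fitting.
// [[Rcpp::export(name = ".wmc_reflectance_grad")]]
List wmc_reflectance_grad(NumericVector paths, NumericVector weights,
                          int n_launched, NumericVector mua,
                          NumericVector mus) {
  int nl = mua.size(), ne = paths.size();
  NumericVector rd(nl), dk(nl);
  for (int j = 0; j < nl; ++j) {
    double k = mua[j] / mus[j];
    double acc = 0.0, dacc = 0.0;
    for (int i = 0; i < ne; ++i) {
      double e = weights[i] * std::exp(-k * paths[i]);
      acc += e;
      dacc -= e * paths[i];
    }
    rd[j] = acc / n_launched;
    dk[j] = dacc / n_launched;
  }
  return List::create(_["rd"] = rd, _["drd_dk"] = dk);
}

// Direct absorption-sampling Monte Carlo in physical units: steps sampled
// at mu_t = mua + mus, survival weighting by the single-scattering albedo
// at each scattering event. Independent estimator used to cross-check the
// pathlength-reweighting scheme.
// [[Rcpp::export(name = ".wmc_direct")]]
double wmc_direct(int n_photons, double n_medium, double n_outside, double g,
                  double mua, double mus, double max_path, double wmin) {
  double mut = mua + mus;
  double albedo = mus / mut;
  double acc = 0.0;
  GetRNGstate();
  for (int i = 0; i < n_photons; ++i) {
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, s_tot = 0.0;
    bool alive = true;
    while (alive) {
      double u = unif_rand();
      if (u <= 0.0) u = 1e-300;
      double step = -std::log(u) / mut;
      while (step > 0.0) {
        if (uz < 0.0 && z + uz * step <= 0.0) {
          double s_b = -z / uz;
          s_tot += s_b;
          step -= s_b;
          z = 0.0;
          double R = fresnel_R(n_medium, n_outside, -uz);
          acc += (1.0 - R) * w;
          w *= R;
          if (w < wmin || s_tot > max_path) { alive = false; break; }
          uz = -uz;
        } else {
          z += uz * step;
          s_tot += step;
          step = 0.0;
        }
      }
      if (!alive) break;
      if (s_tot > max_path) break;
      w *= albedo;  // absorption taken at each interaction
      if (w < wmin) break;
      double ct = hg_cos(g);
      double phi = 2.0 * M_PI * unif_rand();
      spin(ux, uy, uz, ct, phi);
    }
  }
  PutRNGstate();
  return acc / n_photons;
}
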