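// Photon-transport Monte Carlo in slab geometry.
//
// Normally incident pencil beam on a homogeneous slab [0, d] (z = 0 the
// illuminated top, z = d the lower/detection boundary). Free paths sampled
// with rate mut, Henyey-Greenstein scattering, implicit capture with
// Russian roulette (compensated so that per-photon weight bookkeeping
// telescopes exactly), probabilistic Fresnel reflection at both interfaces.
// Transmitted photons are binned by ambient-medium exit angle; zero-scatter
// exits through the bottom are the ballistic tally.
//
// Randomness comes from R's own generator (unif_rand), so results are
// bit-reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double fresnel_R(double n1, double n2, double mu) {
  // unpolarized power reflectance, incidence cosine mu from medium n1 -> n2
  double sin_i2 = 1.0 - mu * mu;
  double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;
  double ct = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * mu - n2 * ct) / (n1 * mu + n2 * ct);
  double rp = (n1 * ct - n2 * mu) / (n1 * ct + n2 * mu);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_cos(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline void spin(double &ux, double &uy, double &uz,
                        double costh, double phi) {
  double sinth = std::sqrt(std::max(0.0, 1.0 - costh * costh));
  double cosph = std::cos(phi), sinph = std::sin(phi);
  if (std::fabs(uz) > 0.99999999) {
    ux = sinth * cosph;
    uy = sinth * sinph;
    uz = costh * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = sinth * (ux * uz * cosph - uy * sinph) / den + ux * costh;
    double ny = sinth * (uy * uz * cosph + ux * sinph) / den + uy * costh;
    double nz = -sinth * cosph * den + uz * costh;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

// [[Rcpp::export(name = ".mc_slab")]]
List mc_slab(double d, double mus, double mua, double g,
             double n_slab, double n_ambient,
             int n_photons, int n_angle_bins, int n_z_bins,
             double w_roulette, double p_survive) {
  const double mut = mus + mua;
  const double albedo = (mut > 0.0) ? mus / mut : 0.0;
  const double R_spec = fresnel_R(n_ambient, n_slab, 1.0);
  const double dth = (M_PI / 2.0) / n_angle_bins;
  const double dz = d / std::max(1, n_z_bins);

  long double S_t = 0.0L, S_r = 0.0L, S_a = 0.0L, S_b = 0.0L;
  double S2_t = 0.0, S2_r = 0.0, S2_a = 0.0, S2_b = 0.0;
  std::vector<long double> S_bin(n_angle_bins, 0.0L);
  std::vector<double> S2_bin(n_angle_bins, 0.0);
  std::vector<long double> flu(std::max(1, n_z_bins), 0.0L);
  std::vector<double> flu2(std::max(1, n_z_bins), 0.0);
  std::vector<double> fl_c(std::max(1, n_z_bins), 0.0);

  for (int ip = 0; ip < n_photons; ip++) {
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - R_spec;
    double t_c = 0.0, r_c = R_spec, a_c = 0.0, b_c = 0.0;
    int bin = -1; double bin_w = 0.0;
    if (n_z_bins > 0) std::fill(fl_c.begin(), fl_c.end(), 0.0);
    long nscat = 0;
    bool alive = true;

    while (alive) {
      double u = unif_rand();
      if (u <= 0.0) u = 1e-300;
      double s = (mut > 0.0) ? -std::log(u) / mut : 1e30;

      while (s > 0.0) {
        double db;
        if (uz > 0.0)       db = (d - z) / uz;
        else if (uz < 0.0)  db = -z / uz;
        else                db = 1e30;

        if (db > s) {            // collision inside the medium
          double z_new = z + s * uz;
          if (n_z_bins > 0 && nscat > 0 && std::fabs(uz) > 1e-12) {
            // diffuse track-length fluence estimator
            double zl = std::min(z, z_new), zh = std::max(z, z_new);
            int b0 = std::max(0, (int)(zl / dz));
            int b1 = std::min(n_z_bins - 1, (int)(zh / dz));
            for (int b = b0; b <= b1; b++) {
              double seg = std::min(zh, (b + 1) * dz) - std::max(zl, b * dz);
              if (seg > 0.0) fl_c[b] += w * seg / std::fabs(uz);
            }
          }
          z = z_new;
          s = 0.0;
          if (mut <= 0.0) { alive = false; break; }
          // implicit capture: log the exact weight difference as absorbed
          double w_new = w * albedo;
          a_c += w - w_new;
          w = w_new;
          nscat++;
          spin(ux, uy, uz, hg_cos(g, unif_rand()), 2.0 * M_PI * unif_rand());
          if (w < w_roulette) {   // Russian roulette, compensated
            if (unif_rand() < p_survive) {
              double w_up = w / p_survive;
              a_c += w - w_up;
              w = w_up;
            } else {
              a_c += w;
              alive = false;
            }
          }
          if (!alive) break;
        } else {                 // boundary hit
          double z_new = (uz > 0.0) ? d : 0.0;
          if (n_z_bins > 0 && nscat > 0 && std::fabs(uz) > 1e-12) {
            double zl = std::min(z, z_new), zh = std::max(z, z_new);
            int b0 = std::max(0, (int)(zl / dz));
            int b1 = std::min(n_z_bins - 1, (int)(zh / dz));
            for (int b = b0; b <= b1; b++) {
              double seg = std::min(zh, (b + 1) * dz) - std::max(zl, b * dz);
              if (seg > 0.0) fl_c[b] += w * seg / std::fabs(uz);
            }
          }
          s -= db;
          z = z_new;
          double mu_i = std::fabs(uz);
          double R = fresnel_R(n_slab, n_ambient, mu_i);
          if (unif_rand() < R) {
            uz = -uz;            // internal reflection, continue leftover path
          } else {               // photon escapes
            if (uz > 0.0) {      // bottom: transmission
              t_c += w;
              if (nscat == 0) {
                b_c += w;
              } else {
                double sin_amb = (n_slab / n_ambient) * std::sqrt(1.0 - mu_i * mu_i);
                if (sin_amb > 1.0) sin_amb = 1.0;
                double th = std::asin(sin_amb);
                int b = (int)(th / dth);
                if (b >= n_angle_bins) b = n_angle_bins - 1;
                bin = b; bin_w = w;
              }
            } else {             // top: reflection
              r_c += w;
            }
            alive = false;
          }
          if (!alive) break;
        }
      }
      if (mut <= 0.0 && alive) alive = false;  // safety, cannot happen
    }

    S_t += t_c;  S2_t += t_c * t_c;
    S_r += r_c;  S2_r += r_c * r_c;
    S_a += a_c;  S2_a += a_c * a_c;
    S_b += b_c;  S2_b += b_c * b_c;
    if (bin >= 0) { S_bin[bin] += bin_w; S2_bin[bin] += bin_w * bin_w; }
    if (n_z_bins > 0)
      for (int b = 0; b < n_z_bins; b++) {
        flu[b] += (long double)fl_c[b];
        flu2[b] += fl_c[b] * fl_c[b];
      }
  }

  NumericVector bins(n_angle_bins), bins2(n_angle_bins);
  for (int i = 0; i < n_angle_bins; i++) {
    bins[i] = (double)S_bin[i];
    bins2[i] = S2_bin[i];
  }
  NumericVector fluence(n_z_bins > 0 ? n_z_bins : 0);
  NumericVector fluence2(n_z_bins > 0 ? n_z_bins : 0);
  for (int i = 0; i < (n_z_bins > 0 ? n_z_bins : 0); i++) {
    fluence[i] = (double)flu[i];
    fluence2[i] = flu2[i];
  }

  return List::create(
    _["sum_t"] = (double)S_t, _["sum2_t"] = S2_t,
    _["sum_r"] = (double)S_r, _["sum2_r"] = S2_r,
    _["sum_a"] = (double)S_a, _["sum2_a"] = S2_a,
    _["sum_b"] = (double)S_b, _["sum2_b"] = S2_b,
    _["sum_total"] = (double)(S_t + S_r + S_a),
    _["bins"] = bins, _["bins2"] = bins2,
    _["fluence"] = fluence, _["fluence2"] = fluence2);
}
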