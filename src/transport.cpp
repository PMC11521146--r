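// Photon-packet Monte Carlo in a semi-infinite turbid half-space (z >= 0)
// with tilted source/detector fibers, plus the phase-function samplers and
// the composed-rotation sampler for effective phase functions.
//
// Conventions: lengths in mm, z positive into the tissue, source footprint
// centred at the origin, detectors along +x.  Absorption is continuous
// Beer-Lambert weight attenuation; scattering-order tallies count scattering
// events only.  The transport kernel uses an explicitly seeded counter-free
// xoshiro256++ stream so identical seeds give byte-identical tallies; the
// small samplers below use R's RNG (set.seed()).
//
// For perpendicular probes (tilt = 0) the geometry is azimuthally symmetric
// and the kernel scores by expectation: every surface-exiting photon whose
// refracted direction clears the acceptance cone contributes to detector k
// the fraction of its exit ring that overlaps the detector footprint.  This
// is the standard symmetry variance reduction and is exact in expectation.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "rng.h"
using namespace Rcpp;

namespace {

const double WEIGHT_MIN = 1e-4;   // Russian roulette trigger
const double ROULETTE_P = 0.1;    // survival probability

// fam: 0 = HG(p1), 1 = MHG(alpha = p1, gHG = p2), 2 = MPC(alpha = p1, N = p2)
template <class RNG>
inline double sample_hg(RNG &rng, double g) {
  if (std::fabs(g) < 1e-12) return 2.0 * rng.unif() - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
  double mu = (1.0 + g * g - t * t) / (2.0 * g);
  return std::max(-1.0, std::min(1.0, mu));
}

template <class RNG>
inline double sample_cos2(RNG &rng) {
  // density (3/2) mu^2 on [-1, 1]: inverse CDF
  double u = 2.0 * rng.unif() - 1.0;
  return (u < 0 ? -1.0 : 1.0) * std::pow(std::fabs(u), 1.0 / 3.0);
}

template <class RNG>
inline double sample_pc(RNG &rng, double N) {
  // density (N+1)/2^(N+1) (1+mu)^N on [-1, 1]
  double mu = 2.0 * std::pow(rng.unif(), 1.0 / (N + 1.0)) - 1.0;
  return std::max(-1.0, std::min(1.0, mu));
}

template <class RNG>
inline double sample_mu(RNG &rng, int fam, double p1, double p2) {
  switch (fam) {
  case 0: return sample_hg(rng, p1);
  case 1: return (rng.unif() < p1) ? sample_hg(rng, p2) : sample_cos2(rng);
  default: return (rng.unif() < p1) ? sample_pc(rng, p2) : sample_cos2(rng);
  }
}

// random azimuth as (cos, sin) without trig calls (von Neumann rejection)
template <class RNG>
inline void rand_azimuth(RNG &rng, double &cp, double &sp) {
  double a, b, n;
  do {
    a = 2.0 * rng.unif() - 1.0;
    b = 2.0 * rng.unif() - 1.0;
    n = a * a + b * b;
  } while (n > 1.0 || n < 1e-12);
  cp = (a * a - b * b) / n;
  sp = 2.0 * a * b / n;
}

// Unpolarized Fresnel reflectance for internal incidence cosine ci,
// refracting from index n1 into n2; ct_out receives the transmitted cosine.
inline double fresnel_r(double ci, double n1, double n2, double &ct_out) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 * si / n2;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  ct_out = ct;
  if (si < 1e-9) {
    double r = (n1 - n2) / (n1 + n2);
    return r * r;
  }
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and azimuth (cp,sp).
inline void spin(double &ux, double &uy, double &uz, double ct,
                 double cp, double sp) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double uxn = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double uyn = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double uzn = -st * cp * den + uz * ct;
    ux = uxn; uy = uyn; uz = uzn;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// Fraction of the circle of radius re (centred at the origin) lying inside
// the disk of radius rf centred at distance rho along +x.
inline double ring_overlap(double re, double rho, double rf) {
  if (re < 1e-12) return (rho <= rf) ? 1.0 : 0.0;
  double c = (re * re + rho * rho - rf * rf) / (2.0 * re * rho);
  if (c >= 1.0) return 0.0;
  if (c <= -1.0) return 1.0;
  return std::acos(c) / M_PI;
}

struct RRng {  // adaptor so the samplers can also run off R's RNG
  inline double unif() { return R::unif_rand(); }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_sample_mu(int n, int fam, double p1, double p2) {
  RRng rng;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_mu(rng, fam, p1, p2);
  return out;
}

// Direction cosine relative to the initial direction after s composed
// scattering events (free rotations, uniform azimuth).
// [[Rcpp::export]]
NumericVector cpp_effective_mu(int n, int s, int fam, double p1, double p2) {
  RRng rng;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double mu = 1.0;  // start along the initial direction
    for (int k = 0; k < s; ++k) {
      double mu2 = sample_mu(rng, fam, p1, p2);
      double cp, sp;
      rand_azimuth(rng, cp, sp);
      double smu = std::sqrt(std::max(0.0, 1.0 - mu * mu));
      double smu2 = std::sqrt(std::max(0.0, 1.0 - mu2 * mu2));
      mu = mu * mu2 + smu * smu2 * cp;
      mu = std::max(-1.0, std::min(1.0, mu));
    }
    out[i] = mu;
  }
  return out;
}

// Launch sampler exposed for geometry tests: positions uniform on the source
// footprint disk, directions uniform (in solid angle) within the in-tissue
// acceptance cone about the refracted source axis.
// [[Rcpp::export]]
NumericMatrix cpp_sample_launch(int n, double tilt_rad, double fib_radius,
                                double na, double n_in, bool index_matched) {
  RRng rng;
  double sin_ax = index_matched ? std::sin(tilt_rad)
                                : std::sin(tilt_rad) / n_in;
  double cos_ax = std::sqrt(1.0 - sin_ax * sin_ax);
  double cos_cone = std::cos(std::asin(na / n_in));
  NumericMatrix out(n, 6);  // x y z ux uy uz
  for (int i = 0; i < n; ++i) {
    double r = fib_radius * std::sqrt(rng.unif());
    double cth, sth, cps, sps;
    rand_azimuth(rng, cth, sth);
    double w = cos_cone + (1.0 - cos_cone) * rng.unif();
    double sw = std::sqrt(std::max(0.0, 1.0 - w * w));
    rand_azimuth(rng, cps, sps);
    // axis (sin_ax, 0, cos_ax); basis e1 = (cos_ax, 0, -sin_ax), e2 = (0,1,0)
    out(i, 0) = r * cth;
    out(i, 1) = r * sth;
    out(i, 2) = 0.0;
    out(i, 3) = w * sin_ax + sw * cps * cos_ax;
    out(i, 4) = sw * sps;
    out(i, 5) = w * cos_ax - sw * cps * sin_ax;
  }
  return out;
}

// Full transport run.
//
// det_rho: detector centre distances along +x.  The source tilts toward +x
// (its in-tissue axis is the refraction of the external tilt), detectors
// tilt the opposite way so their acceptance cones look back toward the
// source: a detector accepts external exit directions within asin(na/n_out)
// of (sin(tilt), 0, -cos(tilt)).
//
// Returns per-detector reflectance weights, batch sums, weighted
// scattering-order histograms (s = 1..s_cap, overflow in the last bin),
// weighted depth histograms of the scattering events of detected photons,
// optional per-detector path-length histograms (for Beer-Lambert mu_a
// reweighting), and the weight-conservation ledger.
// [[Rcpp::export]]
List cpp_transport(double n_photons, int n_batches,
                   double mu_s, double mu_a,
                   int fam, double p1, double p2,
                   double n_in, double n_out,
                   double tilt_rad, double fib_radius, double na,
                   NumericVector det_rho,
                   double max_path, double max_depth_kill,
                   double depth_bin, double depth_max,
                   int s_cap,
                   bool record_paths, bool record_depth,
                   double path_bin, double seed1, double seed2,
                   bool index_matched) {
  int n = (int)n_photons;
  int n_det = det_rho.size();
  bool radial = std::fabs(tilt_rad) < 1e-12;
  Xoshiro256 rng(((uint64_t)seed1 << 32) ^ (uint64_t)seed2);

  double sin_ax = index_matched ? std::sin(tilt_rad)
                                : std::sin(tilt_rad) / n_in;
  double cos_ax = std::sqrt(1.0 - sin_ax * sin_ax);
  double cos_cone = std::cos(std::asin(na / n_in));
  // detector acceptance: at an index-matched fiber face the cone is
  // asin(na/n_in) about the internal tilted axis; otherwise asin(na/n_out)
  // about the external axis, tested on the refracted exit direction
  double cos_acc = index_matched ? std::cos(std::asin(na / n_in))
                                 : std::cos(std::asin(na / n_out));
  double det_ax_x = std::sin(tilt_rad);
  double det_ax_z = -std::cos(tilt_rad);
  double r2 = fib_radius * fib_radius;

  int n_zbin = (int)std::ceil(depth_max / depth_bin);
  int n_lbin = record_paths ? (int)std::ceil(max_path / path_bin) : 1;
  NumericVector refl(n_det);
  NumericMatrix batch(n_batches, n_det);
  NumericMatrix ps(s_cap, n_det);             // row s-1 = order s (weighted)
  NumericMatrix psn(s_cap, n_det);            // same, unweighted counts
  NumericMatrix zhist(n_zbin + 1, n_det);     // last row = overflow
  NumericMatrix lhist(record_paths ? n_lbin : 1, record_paths ? n_det : 1);
  NumericVector n_detected(n_det);            // fractional under symmetry
  double w_escaped = 0, w_absorbed = 0, w_killed = 0;
  double w_roulette_killed = 0, w_roulette_gain = 0;

  std::vector<double> evz;
  evz.reserve(1024);
  std::vector<double> fdet(n_det);

  for (int i = 0; i < n; ++i) {
    int b = (int)((double)i * n_batches / n);
    // launch
    double r = fib_radius * std::sqrt(rng.unif());
    double cth, sth, cps, sps;
    rand_azimuth(rng, cth, sth);
    double x = r * cth, y = r * sth, z = 0.0;
    double w = cos_cone + (1.0 - cos_cone) * rng.unif();
    double sw = std::sqrt(std::max(0.0, 1.0 - w * w));
    rand_azimuth(rng, cps, sps);
    double ux = w * sin_ax + sw * cps * cos_ax;
    double uy = sw * sps;
    double uz = w * cos_ax - sw * cps * sin_ax;
    double wt = 1.0, L = 0.0;
    int s = 0;
    if (record_depth) evz.clear();

    double step = -std::log(rng.unif()) / mu_s;
    bool alive = true;
    while (alive) {
      double d_bound = (uz < 0.0) ? (-z / uz) : HUGE_VAL;
      if (d_bound < step) {
        // hit the surface before the next scattering event
        x += ux * d_bound; y += uy * d_bound; z = 0.0;
        L += d_bound;
        if (mu_a > 0) {
          double att = std::exp(-mu_a * d_bound);
          w_absorbed += wt * (1.0 - att);
          wt *= att;
        }
        step -= d_bound;
        double ci = -uz, ct = 0.0;
        if (index_matched && s >= 1) {
          // matched fiber faces: detection decided on the internal
          // direction before any Fresnel event; the footprint fraction of
          // the exit weight either enters the fiber (in-cone: detected) or
          // is lost into the glass (off-cone), the remainder sees the
          // ordinary tissue-air boundary
          double f_sum = 0.0;
          bool in_cone = (ux * det_ax_x + uz * det_ax_z) >= cos_acc;
          if (radial) {
            in_cone = (-uz) >= cos_acc;
            double re = std::sqrt(x * x + y * y);
            for (int k = 0; k < n_det; ++k) {
              fdet[k] = ring_overlap(re, det_rho[k], fib_radius);
              f_sum += fdet[k];
            }
          } else {
            for (int k = 0; k < n_det; ++k) {
              double dx = x - det_rho[k];
              fdet[k] = 0.0;
              if (dx * dx + y * y <= r2) {
                fdet[k] = 1.0;
                f_sum = 1.0;
                break;  // footprints do not overlap
              }
            }
          }
          if (f_sum > 0.0) {
            if (in_cone) {
              int si_bin = (s <= s_cap) ? s - 1 : s_cap - 1;
              int lb = 0;
              if (record_paths) {
                lb = (int)(L / path_bin);
                if (lb >= n_lbin) lb = n_lbin - 1;
              }
              for (int k = 0; k < n_det; ++k) {
                double wk = wt * fdet[k];
                if (wk <= 0.0) continue;
                refl[k] += wk;
                batch(b, k) += wk;
                n_detected[k] += fdet[k];
                ps(si_bin, k) += wk;
                psn(si_bin, k) += fdet[k];
                if (record_paths) lhist(lb, k) += wk;
                if (record_depth) {
                  for (size_t e = 0; e < evz.size(); ++e) {
                    int zb = (int)(evz[e] / depth_bin);
                    if (zb >= n_zbin) zb = n_zbin;
                    zhist(zb, k) += wk;
                  }
                }
              }
            } else {
              w_escaped += wt * f_sum;  // lost into the fiber glass
            }
            wt *= (1.0 - f_sum);
            if (wt <= 0.0) { alive = false; break; }
          }
        }
        double R = fresnel_r(ci, n_in, n_out, ct);
        if (rng.unif() < R) {
          uz = -uz;  // internal reflection, finish the remaining step
          continue;
        }
        // transmit: refract and test the detectors
        double scale = n_in / n_out;  // tangential sines scale by n1/n2
        double ex = ux * scale, ez = -ct;
        double f_sum = 0.0;
        if (s >= 1 && !index_matched) {
          if (radial) {
            if (-ez >= cos_acc) {
              double re = std::sqrt(x * x + y * y);
              for (int k = 0; k < n_det; ++k) {
                double f = ring_overlap(re, det_rho[k], fib_radius);
                fdet[k] = f;
                f_sum += f;
              }
            }
          } else {
            double dp = ex * det_ax_x + ez * det_ax_z;
            if (dp >= cos_acc) {
              for (int k = 0; k < n_det; ++k) {
                double dx = x - det_rho[k];
                fdet[k] = 0.0;
                if (dx * dx + y * y <= r2) {
                  fdet[k] = 1.0;
                  f_sum += 1.0;
                  break;  // footprints do not overlap
                }
              }
            }
          }
        }
        if (f_sum > 0.0) {
          int si_bin = (s <= s_cap) ? s - 1 : s_cap - 1;
          int lb = 0;
          if (record_paths) {
            lb = (int)(L / path_bin);
            if (lb >= n_lbin) lb = n_lbin - 1;
          }
          for (int k = 0; k < n_det; ++k) {
            double wk = wt * fdet[k];
            if (wk <= 0.0) continue;
            refl[k] += wk;
            batch(b, k) += wk;
            n_detected[k] += fdet[k];
            ps(si_bin, k) += wk;
            psn(si_bin, k) += fdet[k];
            if (record_paths) lhist(lb, k) += wk;
            if (record_depth) {
              for (size_t e = 0; e < evz.size(); ++e) {
                int zb = (int)(evz[e] / depth_bin);
                if (zb >= n_zbin) zb = n_zbin;
                zhist(zb, k) += wk;
              }
            }
          }
          w_escaped += wt * (1.0 - f_sum);
        } else {
          w_escaped += wt;
        }
        alive = false;
      } else {
        // full step: scattering event
        x += ux * step; y += uy * step; z += uz * step;
        L += step;
        if (mu_a > 0) {
          double att = std::exp(-mu_a * step);
          w_absorbed += wt * (1.0 - att);
          wt *= att;
        }
        if (L > max_path || z > max_depth_kill) {
          w_killed += wt;
          alive = false;
          break;
        }
        ++s;
        if (record_depth) evz.push_back(z);
        double mu = sample_mu(rng, fam, p1, p2);
        double cp, sp;
        rand_azimuth(rng, cp, sp);
        spin(ux, uy, uz, mu, cp, sp);
        if (wt < WEIGHT_MIN) {
          if (rng.unif() < ROULETTE_P) {
            w_roulette_gain += wt * (1.0 / ROULETTE_P - 1.0);
            wt /= ROULETTE_P;
          } else {
            w_roulette_killed += wt;
            alive = false;
            break;
          }
        }
        step = -std::log(rng.unif()) / mu_s;
      }
    }
  }

  return List::create(
    _["reflectance_w"] = refl,
    _["batch_w"] = batch,
    _["ps_w"] = ps,
    _["ps_n"] = psn,
    _["depth_w"] = zhist,
    _["path_w"] = lhist,
    _["n_detected"] = n_detected,
    _["ledger"] = NumericVector::create(
      _["detected"] = sum(refl),
      _["escaped"] = w_escaped,
      _["absorbed"] = w_absorbed,
      _["killed"] = w_killed,
      _["roulette_killed"] = w_roulette_killed,
      _["roulette_gain"] = w_roulette_gain));
}
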