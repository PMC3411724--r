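// Euler-Maruyama cores for the overdamped dynamics of a DNA-bead tether.
// All quantities in SI units; R wrappers handle unit conversion.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bouchiat et al. a2..a7 (must match the R-side constants)
static const double BA[6] = {-0.5164228, -2.737418, 16.07497,
                             -38.87607, 39.49944, -14.17718};

// WLC force (N) at extension z (m)
static inline double wlc_force_SI(double z, double Lc, double Lp, double kT) {
  double x = z / Lc;
  if (x < 0.0) x = 0.0;
  if (x > 0.99999) x = 0.99999; // guard; the integrator rejects such steps
  double om = 1.0 - x;
  double p = 0.25 / (om * om) - 0.25 + x;
  double xp = x;
  for (int i = 0; i < 6; ++i) {
    xp *= x; // x^(i+2)
    p += BA[i] * xp;
  }
  return kT / Lp * p;
}

// Faxen-corrected drag (N s/m) for motion perpendicular to the wall,
// bead centre at height h
static inline double drag_perp_SI(double h, double R, double eta) {
  double u = R / h;
  double corr = 1.0 - 1.125 * u + 0.5 * u * u * u;
  if (corr < 0.05) corr = 0.05; // clamp very close to the wall
  return 6.0 * M_PI * eta * R / corr;
}

// Vertical tether dynamics under a per-step magnetic force schedule.
// force_N: length n_steps or length 1 (constant force).
// Returns boxcar-averaged frames of z plus (for thermal = false) the drag
// budget: per-frame drag force and running maxima of drag and drag/F_mag.
// [[Rcpp::export(name = ".cpp_sim_tether")]]
List cpp_sim_tether(NumericVector force_N, int n_steps, double dt,
                    double z0, double Lc, double Lp, double kT,
                    double Rbead, double eta, bool thermal,
                    int out_every, double max_step_frac) {
  const bool const_force = (force_N.size() == 1);
  if (!const_force && force_N.size() < n_steps)
    stop("force schedule shorter than the number of steps");
  const int n_frames = n_steps / out_every;
  NumericVector zf(n_frames), dragf(n_frames), Ff(n_frames);
  double z = z0, acc = 0.0, drag_acc = 0.0, F_acc = 0.0;
  double drag_max = 0.0, ratio_max = 0.0;
  int frame = 0, in_win = 0;
  for (int i = 0; i < n_steps; ++i) {
    const double Fm = const_force ? force_N[0] : force_N[i];
    const double g = drag_perp_SI(z + Rbead, Rbead, eta);
    const double Fw = wlc_force_SI(z, Lc, Lp, kT);
    double dz = dt * (Fm - Fw) / g;
    if (!thermal) {
      const double fd = std::fabs(Fm - Fw); // = gamma * |dz/dt|
      if (fd > drag_max) drag_max = fd;
      if (Fm > 0.0 && fd / Fm > ratio_max) ratio_max = fd / Fm;
      drag_acc += fd;
    } else {
      dz += std::sqrt(2.0 * kT * dt / g) * norm_rand();
    }
    if (std::fabs(dz) > max_step_frac * Lc)
      stop("integration unstable: step exceeds %g * L_c (reduce dt)",
           max_step_frac);
    z += dz;
    if (z < 0.0) z = -z;             // reflecting wall
    if (z > 0.99999 * Lc) z = 0.99999 * Lc;
    acc += z;
    F_acc += Fm;
    if (++in_win == out_every) {
      zf[frame] = acc / out_every;
      dragf[frame] = drag_acc / out_every;
      Ff[frame] = F_acc / out_every;
      acc = drag_acc = F_acc = 0.0;
      in_win = 0;
      ++frame;
    }
  }
  return List::create(_["z"] = zf, _["drag"] = dragf, _["F_mag"] = Ff,
                      _["drag_max"] = drag_max, _["ratio_max"] = ratio_max,
                      _["z_final"] = z);
}

// Transverse pendulum mode at constant stiffness: Ornstein-Uhlenbeck.
// [[Rcpp::export(name = ".cpp_sim_ou")]]
NumericVector cpp_sim_ou(int n_steps, double dt, double k, double gamma,
                         double kT, double x0, bool thermal, int out_every) {
  const int n_frames = n_steps / out_every;
  NumericVector xf(n_frames);
  const double a = k / gamma;
  const double s = thermal ? std::sqrt(2.0 * kT * dt / gamma) : 0.0;
  double x = x0, acc = 0.0;
  int frame = 0, in_win = 0;
  for (int i = 0; i < n_steps; ++i) {
    x += -a * x * dt + (thermal ? s * norm_rand() : 0.0);
    acc += x;
    if (++in_win == out_every) {
      xf[frame++] = acc / out_every;
      acc = 0.0;
      in_win = 0;
    }
  }
  return xf;
}
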