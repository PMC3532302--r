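#include <Rcpp.h>
#include <cmath>

// Fixed-step RK4 integration of the adaptive CPR system. The model terms
// are duplicated here from the R level for speed; the test suite asserts
// agreement between this right-hand side and the R implementation.

namespace {

struct Pars {
  double r, K, h_max, n, k_min, k_var, q_k, theta_min, theta_max, delta;
  double p, theta_p, sigma_p, phi_max, a, b, q_phi, T;
  bool punishment_on;
};

inline double growth(const Pars &pp, double R) {
  return pp.r * R * (1.0 - R / pp.K);
}

inline double half_sat(const Pars &pp, double th) {
  return pp.k_min + pp.k_var * std::pow(th, pp.q_k);
}

inline double harvest(const Pars &pp, double R, double th) {
  return pp.n * pp.h_max * R / (half_sat(pp, th) + R);
}

inline double punish(const Pars &pp, double th) {
  if (!pp.punishment_on) return 0.0;
  double z = (th - pp.theta_p) / pp.sigma_p;
  return pp.p * std::exp(-0.5 * z * z);
}

inline double decay(const Pars &pp, double t) {
  return 1.0 / (1.0 + std::exp(pp.a * (t / pp.T - pp.b)));
}

inline double gradient(const Pars &pp, double R, double th, double t) {
  double k = half_sat(pp, th);
  double dk = pp.k_var * pp.q_k * std::pow(th, pp.q_k - 1.0);
  double denom = (k + R) * (k + R);
  double dG = -pp.n * pp.h_max * R * dk / denom;
  double dpow = (pp.q_phi == 1.0) ? 1.0 : pp.q_phi * std::pow(th, pp.q_phi - 1.0);
  double dF = pp.phi_max * dpow * decay(pp, t) * growth(pp, R);
  double dP = 0.0;
  if (pp.punishment_on)
    dP = -punish(pp, th) * (th - pp.theta_p) / (pp.sigma_p * pp.sigma_p);
  return dG + dF - dP;
}

// derivative of (R, H, theta, Gint) where Gint accumulates gross production;
// carrying it inside the integrator makes the conservation identity
// R + H - Gint = R0 hold to machine precision when punishment is off.
inline void deriv(const Pars &pp, double t, const double y[4], double dy[4]) {
  double R = y[0] > 0.0 ? y[0] : 0.0;
  double th = y[2];
  if (th < pp.theta_min) th = pp.theta_min;
  if (th > pp.theta_max) th = pp.theta_max;
  double g = (y[0] > 0.0) ? growth(pp, R) : 0.0;
  double G = (y[0] > 0.0) ? harvest(pp, R, th) : 0.0;
  double P = punish(pp, th);
  double dth = pp.delta * gradient(pp, R, th, t);
  if ((th <= pp.theta_min && dth < 0.0) || (th >= pp.theta_max && dth > 0.0))
    dth = 0.0;
  dy[0] = g - G;
  dy[1] = G - P;
  dy[2] = dth;
  dy[3] = g;
}

Pars unpack(const Rcpp::List &params) {
  Pars pp;
  pp.r = params["r"]; pp.K = params["K"]; pp.h_max = params["h_max"];
  pp.n = params["n"]; pp.k_min = params["k_min"]; pp.k_var = params["k_var"];
  pp.q_k = params["q_k"]; pp.theta_min = params["theta_min"];
  pp.theta_max = params["theta_max"]; pp.delta = params["delta"];
  pp.p = params["p"]; pp.theta_p = params["theta_p"];
  pp.sigma_p = params["sigma_p"]; pp.phi_max = params["phi_max"];
  pp.a = params["a"]; pp.b = params["b"]; pp.q_phi = params["q_phi"];
  pp.T = params["T"]; pp.punishment_on = params["punishment_on"];
  return pp;
}

} // namespace

// [[Rcpp::export(name = ".integrate_round_cpp")]]
Rcpp::NumericMatrix integrate_round_cpp(Rcpp::List params,
                                        double R0, double H0, double theta0,
                                        double dt, double dt_out) {
  Pars pp = unpack(params);
  int n_out = (int) std::lround(pp.T / dt_out);
  int sub = (int) std::ceil(dt_out / dt - 1e-9);
  if (sub < 1) sub = 1;
  double h = dt_out / sub;

  Rcpp::NumericMatrix out(n_out + 1, 5);
  double y[4] = {R0, H0, theta0, 0.0};
  double k1[4], k2[4], k3[4], k4[4], tmp[4];

  out(0, 0) = 0.0; out(0, 1) = y[0]; out(0, 2) = y[1];
  out(0, 3) = y[2]; out(0, 4) = y[3];

  for (int i = 0; i < n_out; ++i) {
    for (int s = 0; s < sub; ++s) {
      double t = i * dt_out + s * h;
      deriv(pp, t, y, k1);
      for (int j = 0; j < 4; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
      deriv(pp, t + 0.5 * h, tmp, k2);
      for (int j = 0; j < 4; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
      deriv(pp, t + 0.5 * h, tmp, k3);
      for (int j = 0; j < 4; ++j) tmp[j] = y[j] + h * k3[j];
      double t_end = t + h;
      if (t_end > pp.T) t_end = pp.T;
      deriv(pp, t_end, tmp, k4);
      for (int j = 0; j < 4; ++j)
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      // absorbing floor at zero resource, projection of the trait bounds
      if (y[0] < 0.0) y[0] = 0.0;
      if (y[2] < pp.theta_min) y[2] = pp.theta_min;
      if (y[2] > pp.theta_max) y[2] = pp.theta_max;
      for (int j = 0; j < 4; ++j) {
        if (!std::isfinite(y[j]))
          Rcpp::stop("non-finite state at t = %f during integration", t + h);
      }
    }
    out(i + 1, 0) = (i + 1) * dt_out;
    out(i + 1, 1) = y[0]; out(i + 1, 2) = y[1];
    out(i + 1, 3) = y[2]; out(i + 1, 4) = y[3];
  }
  Rcpp::colnames(out) =
    Rcpp::CharacterVector::create("t", "R", "H", "theta", "gint");
  return out;
}
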