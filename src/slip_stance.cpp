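#include <Rcpp.h>
#include <cmath>

// Planar point-mass SLIP stance: foot pinned at the origin, massless linear
// leg spring of rest length l0 and stiffness k, gravity -g on y.  The system
// is conservative, so fixed-step RK4 accuracy is checkable via energy drift.

namespace {

struct State { double x, y, vx, vy; };

inline State deriv(const State& s, double k, double mass, double l0, double g) {
  double L  = std::sqrt(s.x * s.x + s.y * s.y);
  double Fs = k * (l0 - L) / L;       // spring force per unit leg vector
  State d;
  d.x  = s.vx;
  d.y  = s.vy;
  d.vx = Fs * s.x / mass;
  d.vy = Fs * s.y / mass - g;
  return d;
}

inline State rk4_step(const State& s, double h, double k, double mass,
                      double l0, double g) {
  State k1 = deriv(s, k, mass, l0, g);
  State s2 = {s.x + 0.5 * h * k1.x, s.y + 0.5 * h * k1.y,
              s.vx + 0.5 * h * k1.vx, s.vy + 0.5 * h * k1.vy};
  State k2 = deriv(s2, k, mass, l0, g);
  State s3 = {s.x + 0.5 * h * k2.x, s.y + 0.5 * h * k2.y,
              s.vx + 0.5 * h * k2.vx, s.vy + 0.5 * h * k2.vy};
  State k3 = deriv(s3, k, mass, l0, g);
  State s4 = {s.x + h * k3.x, s.y + h * k3.y,
              s.vx + h * k3.vx, s.vy + h * k3.vy};
  State k4 = deriv(s4, k, mass, l0, g);
  State out;
  out.x  = s.x  + h / 6.0 * (k1.x  + 2 * k2.x  + 2 * k3.x  + k4.x);
  out.y  = s.y  + h / 6.0 * (k1.y  + 2 * k2.y  + 2 * k3.y  + k4.y);
  out.vx = s.vx + h / 6.0 * (k1.vx + 2 * k2.vx + 2 * k3.vx + k4.vx);
  out.vy = s.vy + h / 6.0 * (k1.vy + 2 * k2.vy + 2 * k3.vy + k4.vy);
  return out;
}

inline double leg_len(const State& s) {
  return std::sqrt(s.x * s.x + s.y * s.y);
}

} // namespace

//' @title SLIP stance integration (internal)
//' @description Integrates one stance phase of the planar SLIP model from a
//'   touchdown state until leg length returns to its rest value (takeoff),
//'   using fixed-step RK4 with bisection on the step size to locate the
//'   takeoff event to 1e-9 s.  Returns a matrix with columns
//'   t, x, y, vx, vy, Fy; the last row is the refined takeoff point.
//' @keywords internal
// [[Rcpp::export(name = ".slip_stance_cpp")]]
Rcpp::NumericMatrix slip_stance_cpp(double k, double mass, double l0, double g,
                                    double x0, double y0, double vx0, double vy0,
                                    double dt, double max_t) {
  if (k <= 0 || mass <= 0 || l0 <= 0 || dt <= 0)
    Rcpp::stop("k, mass, l0 and dt must all be positive");

  State s = {x0, y0, vx0, vy0};
  std::vector<double> T, X, Y, VX, VY;
  const int max_steps = (int)std::ceil(max_t / dt);
  T.reserve(4096); X.reserve(4096); Y.reserve(4096);
  VX.reserve(4096); VY.reserve(4096);

  double t = 0.0;
  bool compressed = false;   // must leave L = l0 before takeoff can trigger
  T.push_back(t); X.push_back(s.x); Y.push_back(s.y);
  VX.push_back(s.vx); VY.push_back(s.vy);

  State s_prev = s;
  double t_prev = t;
  bool took_off = false;

  for (int i = 0; i < max_steps; ++i) {
    s_prev = s; t_prev = t;
    s = rk4_step(s, dt, k, mass, l0, g);
    t += dt;
    if (s.y <= 0.0)
      Rcpp::stop("SLIP stance failure: mass reached the ground (y <= 0) at t = %f s", t);
    double L = leg_len(s);
    if (L < l0) compressed = true;
    if (compressed && L >= l0) { took_off = true; break; }
    T.push_back(t); X.push_back(s.x); Y.push_back(s.y);
    VX.push_back(s.vx); VY.push_back(s.vy);
  }
  if (!took_off)
    Rcpp::stop("SLIP stance failure: no takeoff within %f s horizon", max_t);

  // Bisection on the step size from the last pre-crossing state: halve the
  // step until the takeoff time is bracketed to within 1e-9 s.
  double lo = 0.0, hi = t - t_prev;
  while (hi - lo > 1e-9) {
    double mid = 0.5 * (lo + hi);
    State sm = rk4_step(s_prev, mid, k, mass, l0, g);
    if (compressed && leg_len(sm) >= l0) hi = mid; else lo = mid;
  }
  State s_to = rk4_step(s_prev, hi, k, mass, l0, g);
  double t_to = t_prev + hi;
  T.push_back(t_to); X.push_back(s_to.x); Y.push_back(s_to.y);
  VX.push_back(s_to.vx); VY.push_back(s_to.vy);

  const int n = (int)T.size();
  Rcpp::NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    double L = std::sqrt(X[i] * X[i] + Y[i] * Y[i]);
    double Fy = k * (l0 - L) * Y[i] / L;
    if (Fy < 0) Fy = 0;      // roundoff guard at the endpoints where L ~ l0
    out(i, 0) = T[i];  out(i, 1) = X[i];  out(i, 2) = Y[i];
    out(i, 3) = VX[i]; out(i, 4) = VY[i]; out(i, 5) = Fy;
  }
  Rcpp::colnames(out) =
    Rcpp::CharacterVector::create("t", "x", "y", "vx", "vy", "Fy");
  return out;
}
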