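#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Species order: m00, m10, m01, m11, l  (uM)
// Rate order:    k1, k2, k1_given_2, k2_given_1,
//                km1, km2, km1_given_2, km2_given_1
// The right-hand sides are the mass-action equations of the four-state
// scheme; the two linear conservation laws (total macromolecule, total
// ligand) are satisfied identically, so classic RK4 preserves them to
// rounding error at every step.
static inline void rhs(const double *y, const double *k, double *dy) {
  const double m00 = y[0], m10 = y[1], m01 = y[2], m11 = y[3], l = y[4];
  const double k1 = k[0], k2 = k[1], k12 = k[2], k21 = k[3];
  const double km1 = k[4], km2 = k[5], km12 = k[6], km21 = k[7];
  dy[0] = km1 * m10 + km2 * m01 - (k1 + k2) * l * m00;
  dy[1] = k1 * l * m00 + km21 * m11 - (km1 + k21 * l) * m10;
  dy[2] = k2 * l * m00 + km12 * m11 - (km2 + k12 * l) * m01;
  dy[3] = (k12 * m01 + k21 * m10) * l - (km12 + km21) * m11;
  dy[4] = km1 * m10 + km2 * m01 + (km21 + km12) * m11 -
          ((k1 + k2) * m00 + k21 * m10 + k12 * m01) * l;
}

static inline void rk4_step(double *y, const double *k, double h,
                            double *k1v, double *k2v, double *k3v,
                            double *k4v, double *yt) {
  rhs(y, k, k1v);
  for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k1v[i];
  rhs(yt, k, k2v);
  for (int i = 0; i < 5; ++i) yt[i] = y[i] + 0.5 * h * k2v[i];
  rhs(yt, k, k3v);
  for (int i = 0; i < 5; ++i) yt[i] = y[i] + h * k3v[i];
  rhs(yt, k, k4v);
  for (int i = 0; i < 5; ++i)
    y[i] += h / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
}

// [[Rcpp::export(name = ".binding_derivs_cpp")]]
NumericVector binding_derivs_cpp(NumericVector y, NumericVector k) {
  double dy[5];
  rhs(REAL(y), REAL(k), dy);
  return NumericVector(dy, dy + 5);
}

// Integrate with fixed-step RK4, recording every `stride` steps, until the
// relative per-recorded-step change of every species has stayed below
// `threshold` for `window` consecutive records, or `max_records` records
// have been taken.  A negative excursion beyond -neg_tol * scale aborts
// with negative = true so the caller can retry with a halved step.
// [[Rcpp::export(name = ".rk4_equilibrate_cpp")]]
List rk4_equilibrate_cpp(NumericVector y0, NumericVector k, double h,
                         int stride, double threshold, int window,
                         double max_records, double neg_tol) {
  double y[5], prev[5];
  double k1v[5], k2v[5], k3v[5], k4v[5], yt[5];
  const double *kp = REAL(k);
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  const double scale = y0[0] + y0[1] + y0[2] + y0[3] + y0[4];
  const double floor_c = 1e-12 * (scale > 0 ? scale : 1.0);

  std::vector<double> times, states;
  times.reserve(1024);
  states.reserve(1024 * 5);
  bool converged = false, negative = false;
  int consec = 0;
  long long rec = 0, nmax = (long long)max_records;

  while (rec < nmax) {
    for (int i = 0; i < 5; ++i) prev[i] = y[i];
    for (int s = 0; s < stride; ++s) rk4_step(y, kp, h, k1v, k2v, k3v, k4v, yt);
    ++rec;
    for (int i = 0; i < 5; ++i) {
      if (y[i] < -neg_tol * (scale > 0 ? scale : 1.0)) negative = true;
    }
    if (negative) break;
    times.push_back(rec * (double)stride * h);
    for (int i = 0; i < 5; ++i) states.push_back(y[i]);
    double relmax = 0.0;
    for (int i = 0; i < 5; ++i) {
      double denom = std::fabs(y[i]) > floor_c ? std::fabs(y[i]) : floor_c;
      double r = std::fabs(y[i] - prev[i]) / denom;
      if (r > relmax) relmax = r;
    }
    if (relmax < threshold) {
      if (++consec >= window) { converged = true; break; }
    } else {
      consec = 0;
    }
    if (rec % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  int nrec = (int)times.size();
  NumericMatrix st(nrec, 5);
  for (int r = 0; r < nrec; ++r)
    for (int i = 0; i < 5; ++i) st(r, i) = states[r * 5 + i];
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["states"] = st, _["converged"] = converged,
                      _["negative"] = negative,
                      _["n_steps"] = (double)rec * stride);
}

// Fixed-step RK4 sampled at the requested output times (sorted, >= 0).
// Each inter-output interval is covered by full steps of size h plus one
// shorter closing step so the output times are hit exactly.
// [[Rcpp::export(name = ".rk4_course_cpp")]]
NumericMatrix rk4_course_cpp(NumericVector y0, NumericVector k, double h,
                             NumericVector out_times, double neg_tol) {
  double y[5];
  double k1v[5], k2v[5], k3v[5], k4v[5], yt[5];
  const double *kp = REAL(k);
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  const double scale = y0[0] + y0[1] + y0[2] + y0[3] + y0[4];
  const int nout = out_times.size();
  NumericMatrix out(nout, 5);
  bool negative = false;
  double t = 0.0;
  for (int j = 0; j < nout && !negative; ++j) {
    double target = out_times[j];
    long long nfull = (long long)std::floor((target - t) / h + 1e-12);
    for (long long s = 0; s < nfull; ++s)
      rk4_step(y, kp, h, k1v, k2v, k3v, k4v, yt);
    t += nfull * h;
    double rem = target - t;
    if (rem > 1e-14 * (target > 1.0 ? target : 1.0)) {
      rk4_step(y, kp, rem, k1v, k2v, k3v, k4v, yt);
      t = target;
    }
    for (int i = 0; i < 5; ++i) {
      out(j, i) = y[i];
      if (y[i] < -neg_tol * (scale > 0 ? scale : 1.0)) negative = true;
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("negative") = negative;
  return out;
}
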