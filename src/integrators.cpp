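// Compiled model right-hand sides and an adaptive Dormand-Prince 5(4)
// integrator with dense output.  Systems:
//   0  MePD (3-dim, minutes time scale, delta inside the RHS)
//   1  KNDy with constant external (Gl, Ge) input (3-dim)
//   2  one-way coupled MePD -> KNDy (6-dim)
//   3  MePD plus variational equations (3 + 9 = 12-dim), used for
//      monodromy matrices in limit-cycle shooting
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parameter vector layouts (fixed order, see R/params.R):
// MePD:  delta alpha Kp c_ll c_li c_il c_le c_ie a_l a_i a_e
//        theta_l theta_i theta_e beta1 beta2                        (16)
// KNDy:  d_D d_N d_v k_D k_N p_v v0 K_D K_N K_v1 K_v2 k m I0        (14)
// Coupling: j_l j_e                                                 (2)

static inline double clip500(double x) {
  if (x > 500.0) return 500.0;
  if (x < -500.0) return -500.0;
  return x;
}

// sigmoid response, zero at F = 0 by construction
static inline double phi_c(double a, double F, double th) {
  return 1.0 / (1.0 + std::exp(clip500(-a * (F - th)))) -
         1.0 / (1.0 + std::exp(clip500(a * th)));
}

static inline double dphi_c(double a, double F, double th) {
  double s = 1.0 / (1.0 + std::exp(clip500(-a * (F - th))));
  return a * s * (1.0 - s);
}

// MePD RHS on the minutes scale (dG/dT = delta * f(G))
static void mepd_f(const double* x, const double* p, double* dx) {
  const double delta = p[0], alpha = p[1], Kp = p[2];
  const double cll = p[3], cli = p[4], cil = p[5], cle = p[6], cie = p[7];
  const double al = p[8], ai = p[9], ae = p[10];
  const double thl = p[11], thi = p[12], the = p[13];
  const double b1 = p[14], b2 = p[15];
  const double Fl = (1 - b2) * cll * x[0] - (1 - b1) * cil * x[1] + alpha * Kp;
  const double Fi = (1 - b2) * cli * x[0] + (1 - alpha) * Kp;
  const double Fe = (1 - b2) * cle * x[0] - (1 - b1) * cie * x[1];
  dx[0] = delta * (-x[0] + (1 - x[0]) * phi_c(al, Fl, thl));
  dx[1] = delta * (-x[1] + (1 - x[1]) * phi_c(ai, Fi, thi));
  dx[2] = delta * (-x[2] + (1 - x[2]) * phi_c(ae, Fe, the));
}

// analytic Jacobian of the minutes-scale MePD RHS
static void mepd_J(const double* x, const double* p, double* J /*3x3 col-major*/) {
  const double delta = p[0], alpha = p[1], Kp = p[2];
  const double cll = p[3], cli = p[4], cil = p[5], cle = p[6], cie = p[7];
  const double a[3]  = {p[8], p[9], p[10]};
  const double th[3] = {p[11], p[12], p[13]};
  const double b1 = p[14], b2 = p[15];
  const double F[3] = {
    (1 - b2) * cll * x[0] - (1 - b1) * cil * x[1] + alpha * Kp,
    (1 - b2) * cli * x[0] + (1 - alpha) * Kp,
    (1 - b2) * cle * x[0] - (1 - b1) * cie * x[1]};
  // dF_k / dG_j (only Gl, Gi enter the inputs)
  const double dF[3][3] = {
    {(1 - b2) * cll, -(1 - b1) * cil, 0.0},
    {(1 - b2) * cli, 0.0, 0.0},
    {(1 - b2) * cle, -(1 - b1) * cie, 0.0}};
  for (int k = 0; k < 3; ++k) {
    const double ph = phi_c(a[k], F[k], th[k]);
    const double dp = dphi_c(a[k], F[k], th[k]);
    for (int j = 0; j < 3; ++j) {
      double v = (1 - x[k]) * dp * dF[k][j];
      if (j == k) v += -1.0 - ph;
      J[j * 3 + k] = delta * v;  // column-major: J[row = k, col = j]
    }
  }
}

// KNDy RHS with external (Gl, Ge) input weighted by (j_l, j_e)
static void kndy_f(const double* x, const double* q, double gl, double ge,
                   double jl, double je, double* dx) {
  const double dD = q[0], dN = q[1], dv = q[2], kD = q[3], kN = q[4];
  const double pv = q[5], v0 = q[6], KD = q[7], KN = q[8];
  const double Kv1 = q[9], Kv2 = q[10], kk = q[11], m = q[12], I0 = q[13];
  const double D = x[0], N = x[1], v = x[2];
  const double I = I0 + pv * N * N / (N * N + KN * KN) * v + jl * gl - je * ge;
  dx[0] = kD * v * v / (v * v + Kv1 * Kv1) - dD * D;
  dx[1] = kN * v * v / (v * v + Kv2 * Kv2) * KD * KD / (KD * KD + D * D) - dN * N;
  dx[2] = v0 / (1.0 + std::exp(clip500(kk * (-I + m)))) - dv * v;
}

struct Sys {
  int id, dim;
  const double* pm;   // MePD params (16) or NULL
  const double* pk;   // KNDy params (14) or NULL
  double jl, je, gl, ge;  // coupling weights; constant ext input for id==1
  void operator()(const double* x, double* dx) const {
    switch (id) {
    case 0: mepd_f(x, pm, dx); break;
    case 1: kndy_f(x, pk, gl, ge, jl, je, dx); break;
    case 2:
      mepd_f(x, pm, dx);
      kndy_f(x + 3, pk, x[0], x[2], jl, je, dx + 3);
      break;
    case 3: {  // variational: x[3..11] is the 3x3 matrix V (col-major), V' = J V
      mepd_f(x, pm, dx);
      double J[9];
      mepd_J(x, pm, J);
      for (int c = 0; c < 3; ++c)
        for (int r = 0; r < 3; ++r) {
          double s = 0.0;
          for (int k = 0; k < 3; ++k) s += J[k * 3 + r] * x[3 + c * 3 + k];
          dx[3 + c * 3 + r] = s;
        }
      break;
    }
    }
  }
};

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double a71 = 35.0 / 384, a73 = 500.0 / 1113, a74 = 125.0 / 192,
                    a75 = -2187.0 / 6784, a76 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;
// dense-output coefficients (Hairer's dopri5)
static const double d1 = -12715105075.0 / 11282082432.0,
                    d3 = 87487479700.0 / 32700410799.0,
                    d4 = -10690763975.0 / 1880347072.0,
                    d5 = 701980252875.0 / 199316789632.0,
                    d6 = -1453857185.0 / 822651844.0,
                    d7 = 69997945.0 / 29380423.0;

// Integrate sys over [t0, t1], writing dense output on the uniform grid
// t0 + i*dt_out.  Returns number of accepted steps; throws on failure.
static long dopri5(const Sys& sys, std::vector<double>& y, double t0, double t1,
                   double dt_out, double rtol, double atol,
                   NumericMatrix& out, long maxsteps) {
  const int n = sys.dim;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), ynew(n), r1(n), r2(n), r3(n), r4(n), r5(n);
  double t = t0;
  const long nout = out.nrow();
  long iout = 0;
  // record t0
  for (int i = 0; i < n; ++i) out(0, i + 1) = y[i];
  out(0, 0) = t0;
  iout = 1;

  sys(y.data(), k1.data());
  // initial step heuristic
  double h = dt_out > 0 ? dt_out : (t1 - t0) / 100.0;
  {
    double d0 = 0, d1n = 0;
    for (int i = 0; i < n; ++i) {
      double sc = atol + rtol * std::fabs(y[i]);
      d0 += (y[i] / sc) * (y[i] / sc);
      d1n += (k1[i] / sc) * (k1[i] / sc);
    }
    d0 = std::sqrt(d0 / n); d1n = std::sqrt(d1n / n);
    if (d1n > 1e-10) h = std::min(h, 0.01 * d0 / d1n + 1e-6);
    if (h <= 0 || !std::isfinite(h)) h = 1e-6;
  }
  long nstep = 0;
  bool last = false;
  while (t < t1 && !last) {
    if (++nstep > maxsteps) stop("dopri5: maximum step count exceeded");
    if (t + h >= t1) { h = t1 - t; last = true; }
    if (h < 1e-14 * std::max(1.0, std::fabs(t)))
      stop("dopri5: step size underflow at t = %f", t);
    // stages
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    sys(ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sys(ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sys(ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    sys(ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    sys(ytmp.data(), k6.data());
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (a71 * k1[i] + a73 * k3[i] + a74 * k4[i] +
                            a75 * k5[i] + a76 * k6[i]);
    sys(ynew.data(), k7.data());
    // error estimate
    double err = 0;
    for (int i = 0; i < n; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      err += (e / sc) * (e / sc);
    }
    err = std::sqrt(err / n);
    if (err <= 1.0 && std::isfinite(err)) {
      // accept; dense output over (t, t+h]
      if (iout < nout) {
        for (int i = 0; i < n; ++i) {
          double dy = ynew[i] - y[i];
          double bspl = h * k1[i] - dy;
          r1[i] = y[i];
          r2[i] = dy;
          r3[i] = bspl;
          r4[i] = dy - h * k7[i] - bspl;
          r5[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                       d6 * k6[i] + d7 * k7[i]);
        }
        while (iout < nout) {
          double tg = t0 + iout * dt_out;
          if (tg > t + h + 1e-12 * std::fabs(t + h)) break;
          double th = (tg - t) / h, th1 = 1.0 - th;
          for (int i = 0; i < n; ++i)
            out(iout, i + 1) =
                r1[i] + th * (r2[i] + th1 * (r3[i] + th * (r4[i] + th1 * r5[i])));
          out(iout, 0) = tg;
          ++iout;
        }
      }
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      last = false;
      double fac = std::isfinite(err) ? 0.9 * std::pow(err, -0.2) : 0.1;
      h *= std::max(0.1, std::min(0.9, fac));
    }
  }
  // make sure the final grid point is filled (guards rounding at t1)
  if (iout == nout - 1) {
    for (int i = 0; i < n; ++i) out(iout, i + 1) = y[i];
    out(iout, 0) = t1;
    ++iout;
  }
  if (iout < nout)
    stop("dopri5: dense output incomplete (%ld of %ld points)", iout, nout);
  return nstep;
}

static Sys make_sys(int system, const NumericVector& pm, const NumericVector& pk,
                    const NumericVector& cpl, const NumericVector& ext) {
  Sys s;
  s.id = system;
  s.dim = (system == 2) ? 6 : (system == 3 ? 12 : 3);
  s.pm = (pm.size() == 16) ? &pm[0] : (const double*)nullptr;
  s.pk = (pk.size() == 14) ? &pk[0] : (const double*)nullptr;
  s.jl = cpl.size() == 2 ? cpl[0] : 0.0;
  s.je = cpl.size() == 2 ? cpl[1] : 0.0;
  s.gl = ext.size() == 2 ? ext[0] : 0.0;
  s.ge = ext.size() == 2 ? ext[1] : 0.0;
  if ((system == 0 || system == 2 || system == 3) && s.pm == nullptr)
    stop("MePD parameter vector of length 16 required");
  if ((system == 1 || system == 2) && s.pk == nullptr)
    stop("KNDy parameter vector of length 14 required");
  return s;
}

// [[Rcpp::export]]
NumericVector mepd_rhs_cpp(NumericVector state, NumericVector pm) {
  NumericVector dx(3);
  mepd_f(&state[0], &pm[0], &dx[0]);
  return dx;
}

// [[Rcpp::export]]
NumericMatrix mepd_jac_cpp(NumericVector state, NumericVector pm) {
  NumericMatrix J(3, 3);
  mepd_J(&state[0], &pm[0], &J[0]);
  return J;
}

// [[Rcpp::export]]
NumericVector kndy_rhs_cpp(NumericVector state, NumericVector pk,
                           NumericVector ext, NumericVector cpl) {
  NumericVector dx(3);
  kndy_f(&state[0], &pk[0], ext[0], ext[1], cpl[0], cpl[1], &dx[0]);
  return dx;
}

// [[Rcpp::export]]
List integrate_cpp(int system, NumericVector pm, NumericVector pk,
                   NumericVector cpl, NumericVector ext, NumericVector init,
                   double t0, double t1, double dt_out, double rtol,
                   double atol, double maxsteps) {
  Sys s = make_sys(system, pm, pk, cpl, ext);
  if ((int)init.size() != s.dim) stop("init has wrong length for this system");
  long nout = (long)std::floor((t1 - t0) / dt_out + 0.5) + 1;
  NumericMatrix out(nout, s.dim + 1);
  std::vector<double> y(init.begin(), init.end());
  long nstep = dopri5(s, y, t0, t1, dt_out, rtol, atol, out, (long)maxsteps);
  return List::create(_["grid"] = out, _["nstep"] = nstep);
}

// Flow map of the MePD system with monodromy (variational) matrix.
// Returns the endpoint x(T; x0) and dx(T)/dx0.
// [[Rcpp::export]]
List flow_mepd_cpp(NumericVector pm, NumericVector x0, double tend,
                   double rtol, double atol) {
  Sys s = make_sys(3, pm, NumericVector(0), NumericVector(0), NumericVector(0));
  std::vector<double> y(12, 0.0);
  for (int i = 0; i < 3; ++i) y[i] = x0[i];
  y[3] = y[7] = y[11] = 1.0;  // identity
  NumericMatrix out(2, 13);
  dopri5(s, y, 0.0, tend, tend, rtol, atol, out, 10000000L);
  NumericVector xe(3);
  NumericMatrix M(3, 3);
  for (int i = 0; i < 3; ++i) xe[i] = y[i];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) M(r, c) = y[3 + c * 3 + r];
  return List::create(_["x"] = xe, _["monodromy"] = M);
}
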