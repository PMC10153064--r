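// Compiled fast path for the closed-loop reach simulation.
// Mirrors the R reference implementation step for step (same operation
// order, same conventions); run_reach(engine = "reference") is the oracle
// this core is tested against.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Plant {
  double dt;
  double A[9];        // column-major 3x3 absolute-angle inertia constants
  double Irot[3];
  double Llink[3];    // moving link lengths
  double q0[3];
  double lo[3], hi[3];
  double klim, blim, wlim;
  double r[3];        // wrapping radii
  // muscle
  double fmax[6], l0[6], vmax;
  double b[3], d[3];
  int actmodel;       // 0 IAM, 1 O1, 2 O3
  int forcemodel;     // 0 FMAX, 1 FLV
  double aO1[2], aO3[3], bO3[3];
  // control
  double Kp[3], Kv[3];
  int tau_steps;
  double tau;
  double lambda, sigmin;
  // plan
  double px0[2], pxt[2], Tp;
};

struct State {
  double q[3], qd[3];
  double a[6], a1[6], a2[6];
};

inline void inertia(const Plant& P, const double q[3], double M[9]) {
  double th[3] = {q[0], q[0] + q[1], q[0] + q[1] + q[2]};
  double Mabs[9];
  for (int k = 0; k < 3; ++k)
    for (int l = 0; l < 3; ++l)
      Mabs[k + 3 * l] = P.A[k + 3 * l] * std::cos(th[k] - th[l]);
  for (int k = 0; k < 3; ++k) Mabs[k + 3 * k] += P.Irot[k];
  // M = t(Lm) Mabs Lm, Lm lower-triangular ones:
  // (Mabs Lm)[k,l] = sum_{i>=l} Mabs[k,i]; then reverse-cumsum over rows
  double T1[9];
  for (int k = 0; k < 3; ++k) {
    double s = 0;
    for (int l = 2; l >= 0; --l) {
      s += Mabs[k + 3 * l];
      T1[k + 3 * l] = s;
    }
  }
  for (int l = 0; l < 3; ++l) {
    double s = 0;
    for (int k = 2; k >= 0; --k) {
      s += T1[k + 3 * l];
      M[k + 3 * l] = s;
    }
  }
  // symmetrise as in R
  for (int k = 0; k < 3; ++k)
    for (int l = 0; l < k; ++l) {
      double m = 0.5 * (M[k + 3 * l] + M[l + 3 * k]);
      M[k + 3 * l] = m;
      M[l + 3 * k] = m;
    }
}

inline void bias(const Plant& P, const double q[3], const double qd[3],
                 double c[3]) {
  double th[3] = {q[0], q[0] + q[1], q[0] + q[1] + q[2]};
  double thd[3] = {qd[0], qd[0] + qd[1], qd[0] + qd[1] + qd[2]};
  double cabs[3];
  for (int k = 0; k < 3; ++k) {
    double s = 0;
    for (int l = 0; l < 3; ++l)
      s += P.A[k + 3 * l] * std::sin(th[k] - th[l]) * thd[l] * thd[l];
    cabs[k] = s;
  }
  double s = 0;
  for (int k = 2; k >= 0; --k) {
    s += cabs[k];
    c[k] = s;
  }
}

inline void solve3(const double M[9], const double b[3], double x[3]) {
  double a11 = M[0], a21 = M[1], a31 = M[2];
  double a12 = M[3], a22 = M[4], a32 = M[5];
  double a13 = M[6], a23 = M[7], a33 = M[8];
  double c11 = a22 * a33 - a23 * a32;
  double c12 = a13 * a32 - a12 * a33;
  double c13 = a12 * a23 - a13 * a22;
  double det = a11 * c11 + a21 * c12 + a31 * c13;
  double c21 = a23 * a31 - a21 * a33;
  double c22 = a11 * a33 - a13 * a31;
  double c23 = a13 * a21 - a11 * a23;
  double c31 = a21 * a32 - a22 * a31;
  double c32 = a12 * a31 - a11 * a32;
  double c33 = a11 * a22 - a12 * a21;
  x[0] = (c11 * b[0] + c12 * b[1] + c13 * b[2]) / det;
  x[1] = (c21 * b[0] + c22 * b[1] + c23 * b[2]) / det;
  x[2] = (c31 * b[0] + c32 * b[1] + c33 * b[2]) / det;
}

// semi-implicit Euler with implicit one-sided limit spring-damper and
// implicit joint damping D (FV tangent damping of the muscles)
inline bool step_dyn(const Plant& P, State& S, const double T[3],
                     const double D[3]) {
  for (int k = 0; k < 3; ++k)
    if (!std::isfinite(S.q[k]) || !std::isfinite(S.qd[k])) return false;
  double M[9], c[3];
  inertia(P, S.q, M);
  bias(P, S.q, S.qd, c);
  double rhs[3];
  for (int k = 0; k < 3; ++k) rhs[k] = T[k] - c[k];
  double damp[3] = {D[0], D[1], D[2]};
  bool implicit_terms = damp[0] > 0 || damp[1] > 0 || damp[2] > 0;
  for (int k = 0; k < 3; ++k) {
    double pen = 0;
    if (S.q[k] > P.hi[k]) pen = S.q[k] - P.hi[k];
    else if (S.q[k] < P.lo[k]) pen = S.q[k] - P.lo[k];
    if (pen != 0) {
      double ap = std::fabs(pen);
      double sg = (pen > 0) - (pen < 0);
      rhs[k] -= P.klim * sg * ap * ap / (ap + P.wlim);
      double kt = P.klim * (ap * ap + 2 * ap * P.wlim) /
                  ((ap + P.wlim) * (ap + P.wlim));
      damp[k] += P.blim + kt * P.dt;
      implicit_terms = true;
    }
  }
  double qdn[3];
  if (implicit_terms) {
    double Meff[9];
    for (int i = 0; i < 9; ++i) Meff[i] = M[i];
    double b2[3];
    for (int k = 0; k < 3; ++k) {
      Meff[k + 3 * k] += P.dt * damp[k];
      b2[k] = M[k] * S.qd[0] + M[k + 3] * S.qd[1] + M[k + 6] * S.qd[2] +
              P.dt * rhs[k];
    }
    solve3(Meff, b2, qdn);
  } else {
    double acc[3];
    solve3(M, rhs, acc);
    for (int k = 0; k < 3; ++k) qdn[k] = S.qd[k] + P.dt * acc[k];
  }
  for (int k = 0; k < 3; ++k) {
    S.qd[k] = qdn[k];
    S.q[k] += P.dt * qdn[k];
  }
  return true;
}

inline bool muscle_geo(const Plant& P, const double q[3], const double qd[3],
                       double lt[6], double vt[6]) {
  for (int j = 0; j < 6; ++j) {
    int k = j / 2;
    double s = (j % 2 == 0) ? 1.0 : -1.0;
    double l = P.l0[j] - s * P.r[k] * (q[k] - P.q0[k]);
    if (l <= 0) return false;
    lt[j] = l / P.l0[j];
    vt[j] = s * P.r[k] * qd[k] / (P.l0[j] * P.vmax);
  }
  return true;
}

inline void force_cap(const Plant& P, const double lt[6], const double vt[6],
                      double F[6]) {
  if (P.forcemodel == 0) {
    for (int j = 0; j < 6; ++j) F[j] = P.fmax[j];
    return;
  }
  for (int j = 0; j < 6; ++j) {
    double fl = std::exp(-std::pow(
        std::fabs((std::pow(lt[j], P.b[1]) - 1.0) / P.b[2]), P.b[0]));
    double v = vt[j] > 1.0 ? 1.0 : vt[j];
    double fv = (v > 0) ? (1.0 - v) / (1.0 + P.d[0] * v)
                        : P.d[1] - (P.d[1] - 1.0) * (1.0 + v) /
                              (1.0 - P.d[2] * v);
    F[j] = P.fmax[j] * fl * fv;
  }
}

inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

inline void act_step(const Plant& P, State& S, const double u[6]) {
  if (P.actmodel == 0) {
    for (int j = 0; j < 6; ++j) S.a[j] = u[j];
  } else if (P.actmodel == 1) {
    for (int j = 0; j < 6; ++j) {
      double A = (u[j] > S.a[j]) ? P.aO1[0] * (0.5 + 1.5 * S.a[j])
                                 : P.aO1[1] / (0.5 + 1.5 * S.a[j]);
      S.a[j] = clamp01(S.a[j] + P.dt * (u[j] - S.a[j]) / A);
    }
  } else {
    for (int j = 0; j < 6; ++j) {
      double a1 = S.a1[j], a2 = S.a2[j], a = S.a[j];
      double a1n = a1 + P.dt * (u[j] - (P.bO3[0] + (1 - P.bO3[0]) * u[j]) * a1) / P.aO3[0];
      double a2n = a2 + P.dt * (a1 - (P.bO3[1] + (1 - P.bO3[1]) * a1) * a2) / P.aO3[1];
      double an  = a  + P.dt * (a2 - (P.bO3[2] + (1 - P.bO3[2]) * a2) * a) / P.aO3[2];
      S.a1[j] = clamp01(a1n);
      S.a2[j] = clamp01(a2n);
      S.a[j] = clamp01(an);
    }
  }
}

inline void fk(const Plant& P, const double q[3], const double qd[3],
               double x[2], double xd[2], double J[6]) {
  double th[3] = {q[0], q[0] + q[1], q[0] + q[1] + q[2]};
  double u[3], v[3];
  for (int i = 0; i < 3; ++i) {
    u[i] = P.Llink[i] * std::cos(th[i]);
    v[i] = P.Llink[i] * std::sin(th[i]);
  }
  x[0] = u[0] + u[1] + u[2];
  x[1] = v[0] + v[1] + v[2];
  double Su = 0, Sv = 0;
  for (int k = 2; k >= 0; --k) {
    Su += u[k];
    Sv += v[k];
    J[2 * k] = -Sv;      // row 1
    J[2 * k + 1] = Su;   // row 2
  }
  xd[0] = J[0] * qd[0] + J[2] * qd[1] + J[4] * qd[2];
  xd[1] = J[1] * qd[0] + J[3] * qd[1] + J[5] * qd[2];
}

// damped Moore-Penrose pseudo-inverse of the 2x3 Jacobian (J column-major
// 2x3 in J[6]); Jp is 3x2 (column-major Jp[6])
inline void pinv(const Plant& P, const double J[6], double Jp[6]) {
  double G11 = J[0] * J[0] + J[2] * J[2] + J[4] * J[4];
  double G22 = J[1] * J[1] + J[3] * J[3] + J[5] * J[5];
  double G12 = J[0] * J[1] + J[2] * J[3] + J[4] * J[5];
  double tr = G11 + G22;
  double dis = std::sqrt(std::max((G11 - G22) * (G11 - G22) / 4 + G12 * G12, 0.0));
  double evmin = tr / 2 - dis;
  if (evmin < P.sigmin * P.sigmin) {
    G11 += P.lambda * P.lambda;
    G22 += P.lambda * P.lambda;
  }
  double det = G11 * G22 - G12 * G12;
  double i11 = G22 / det, i22 = G11 / det, i12 = -G12 / det;
  for (int k = 0; k < 3; ++k) {
    double Jt1 = J[2 * k], Jt2 = J[2 * k + 1];
    Jp[k] = Jt1 * i11 + Jt2 * i12;       // column 1
    Jp[k + 3] = Jt1 * i12 + Jt2 * i22;   // column 2
  }
}

inline void plan_pos(const Plant& P, double t, double x[2]) {
  double s = t / P.Tp;
  if (s < 0) s = 0;
  if (s > 1) s = 1;
  double f = ((6 * s - 15) * s + 10) * s * s * s;
  x[0] = P.px0[0] + (P.pxt[0] - P.px0[0]) * f;
  x[1] = P.px0[1] + (P.pxt[1] - P.px0[1]) * f;
}

inline void plan_vel(const Plant& P, double t, double v[2]) {
  double s = t / P.Tp;
  double f = (t >= 0 && t < P.Tp)
                 ? (30 * s * s * s * s - 60 * s * s * s + 30 * s * s) / P.Tp
                 : 0.0;
  v[0] = (P.pxt[0] - P.px0[0]) * f;
  v[1] = (P.pxt[1] - P.px0[1]) * f;
}

inline void excitation(const Plant& P, const double Td[3], const double F[6],
                       double u[6]) {
  for (int j = 0; j < 6; ++j) u[j] = 0;
  for (int k = 0; k < 3; ++k) {
    if (Td[k] > 0) {
      double uu = Td[k] / (P.r[k] * F[2 * k]);
      u[2 * k] = uu > 1 ? 1 : uu;
    } else if (Td[k] < 0) {
      double uu = Td[k] / (-P.r[k] * F[2 * k + 1]);
      u[2 * k + 1] = uu > 1 ? 1 : uu;
    }
  }
}

// one plant step under excitation u; records applied forces/torque
inline bool plant_step_c(const Plant& P, State& S, const double u[6],
                         double Fa[6], double T[3]) {
  act_step(P, S, u);
  double lt[6], vt[6], F[6];
  if (!muscle_geo(P, S.q, S.qd, lt, vt)) return false;
  force_cap(P, lt, vt, F);
  for (int j = 0; j < 6; ++j) Fa[j] = F[j] * S.a[j];
  for (int k = 0; k < 3; ++k) T[k] = P.r[k] * (Fa[2 * k] - Fa[2 * k + 1]);
  double D[3] = {0, 0, 0};
  if (P.forcemodel == 1) {
    for (int j = 0; j < 6; ++j) {
      double slope;
      if (vt[j] > 1.0) slope = 0.0;
      else if (vt[j] > 0)
        slope = (1 + P.d[0]) / ((1 + P.d[0] * vt[j]) * (1 + P.d[0] * vt[j]));
      else
        slope = (P.d[1] - 1) * (1 + P.d[2]) /
                ((1 - P.d[2] * vt[j]) * (1 - P.d[2] * vt[j]));
      double fl = std::exp(-std::pow(
          std::fabs((std::pow(lt[j], P.b[1]) - 1.0) / P.b[2]), P.b[0]));
      int k = j / 2;
      D[k] += P.r[k] * P.r[k] * P.fmax[j] * fl * slope * S.a[j] /
              (P.l0[j] * P.vmax);
    }
  }
  return step_dyn(P, S, T, D);
}

inline bool control_c(const Plant& P, const State& S, const double u_prev[6],
                      double t, double u[6]) {
  State pred = S;
  double Fa[6], T[3];
  for (int i = 0; i < P.tau_steps; ++i)
    if (!plant_step_c(P, pred, u_prev, Fa, T)) return false;
  double x[2], xd[2], J[6], Jp[6];
  fk(P, pred.q, pred.qd, x, xd, J);
  double lt[6], vt[6];
  if (!muscle_geo(P, pred.q, pred.qd, lt, vt)) return false;
  double tref = t + P.tau;
  double xdp[2], vdp[2];
  plan_pos(P, tref, xdp);
  plan_vel(P, tref, vdp);
  pinv(P, J, Jp);
  double Td[3];
  for (int k = 0; k < 3; ++k)
    Td[k] = P.Kp[k] * (Jp[k] * (xdp[0] - x[0]) + Jp[k + 3] * (xdp[1] - x[1])) +
            P.Kv[k] * (Jp[k] * (vdp[0] - xd[0]) + Jp[k + 3] * (vdp[1] - xd[1]));
  double F[6];
  force_cap(P, lt, vt, F);
  excitation(P, Td, F, u);
  return true;
}

Plant unpack(List pk) {
  Plant P;
  P.dt = as<double>(pk["dt"]);
  NumericVector A = pk["A"], Irot = pk["Irot"], Ll = pk["Llink"],
                q0 = pk["q0"], lo = pk["lo"], hi = pk["hi"], r = pk["r"],
                fmax = pk["fmax"], l0 = pk["l0"], b = pk["b"], d = pk["d"],
                aO1 = pk["aO1"], aO3 = pk["aO3"], bO3 = pk["bO3"],
                Kp = pk["Kp"], Kv = pk["Kv"], px0 = pk["px0"],
                pxt = pk["pxt"];
  for (int i = 0; i < 9; ++i) P.A[i] = A[i];
  for (int i = 0; i < 3; ++i) {
    P.Irot[i] = Irot[i]; P.Llink[i] = Ll[i]; P.q0[i] = q0[i];
    P.lo[i] = lo[i]; P.hi[i] = hi[i]; P.r[i] = r[i];
    P.b[i] = b[i]; P.d[i] = d[i]; P.aO3[i] = aO3[i]; P.bO3[i] = bO3[i];
    P.Kp[i] = Kp[i]; P.Kv[i] = Kv[i];
  }
  for (int j = 0; j < 6; ++j) { P.fmax[j] = fmax[j]; P.l0[j] = l0[j]; }
  P.vmax = as<double>(pk["vmax"]);
  P.klim = as<double>(pk["klim"]);
  P.blim = as<double>(pk["blim"]);
  P.wlim = as<double>(pk["wlim"]);
  P.actmodel = as<int>(pk["actmodel"]);
  P.forcemodel = as<int>(pk["forcemodel"]);
  P.aO1[0] = aO1[0]; P.aO1[1] = aO1[1];
  P.tau_steps = as<int>(pk["tau_steps"]);
  P.tau = as<double>(pk["tau"]);
  P.lambda = as<double>(pk["lambda"]);
  P.sigmin = as<double>(pk["sigmin"]);
  P.px0[0] = px0[0]; P.px0[1] = px0[1];
  P.pxt[0] = pxt[0]; P.pxt[1] = pxt[1];
  P.Tp = as<double>(pk["Tp"]);
  return P;
}

} // namespace

// [[Rcpp::export(name = ".reach_core")]]
List reach_core(List pk, int N) {
  Plant P = unpack(pk);
  State S;
  for (int k = 0; k < 3; ++k) { S.q[k] = P.q0[k]; S.qd[k] = 0; }
  for (int j = 0; j < 6; ++j) { S.a[j] = 0; S.a1[j] = 0; S.a2[j] = 0; }
  double u_prev[6] = {0, 0, 0, 0, 0, 0};

  NumericMatrix X(N + 1, 2), Q(N + 1, 3), QD(N + 1, 3), U(N + 1, 6),
      Am(N + 1, 6), FORCE(N + 1, 6), TORQ(N + 1, 3);
  double x[2], xd[2], J[6];
  for (int i = 0; i < N; ++i) {
    double t = i * P.dt;
    for (int k = 0; k < 3; ++k) { Q(i, k) = S.q[k]; QD(i, k) = S.qd[k]; }
    fk(P, S.q, S.qd, x, xd, J);
    X(i, 0) = x[0]; X(i, 1) = x[1];
    double u[6], Fa[6], T[3];
    if (!control_c(P, S, u_prev, t, u))
      stop("simulation blow-up at t = %f s", t);
    if (!plant_step_c(P, S, u, Fa, T))
      stop("simulation blow-up at t = %f s", t);
    for (int j = 0; j < 6; ++j) {
      U(i, j) = u[j]; Am(i, j) = S.a[j]; FORCE(i, j) = Fa[j];
      u_prev[j] = u[j];
    }
    for (int k = 0; k < 3; ++k) TORQ(i, k) = T[k];
    for (int k = 0; k < 3; ++k)
      if (!std::isfinite(S.q[k])) stop("simulation blow-up at t = %f s", t);
  }
  for (int k = 0; k < 3; ++k) { Q(N, k) = S.q[k]; QD(N, k) = S.qd[k]; }
  fk(P, S.q, S.qd, x, xd, J);
  X(N, 0) = x[0]; X(N, 1) = x[1];
  for (int j = 0; j < 6; ++j) {
    U(N, j) = u_prev[j]; Am(N, j) = S.a[j];
    FORCE(N, j) = FORCE(N - 1, j);
  }
  for (int k = 0; k < 3; ++k) TORQ(N, k) = TORQ(N - 1, k);
  return List::create(_["x"] = X, _["q"] = Q, _["qdot"] = QD, _["u"] = U,
                      _["a"] = Am, _["forces"] = FORCE, _["torque"] = TORQ);
}
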