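// Fixed-step RK4 integrators for the eight-state apoptosis-switch model and
// its adjoint (costate) system.  Controls are piecewise constant on the node
// grid, so pulse edges are placed exactly on nodes by the R callers; the
// apoptosis indicator is re-evaluated inside every RHS evaluation.
#include <Rcpp.h>
using namespace Rcpp;

struct Pars {
  double lS1, k1, k2, alpha, lk, lJ, K, lS2, k3, k4, beta, mu3;
  double l1, k5, k6, gamma, l3, muB, l2, k7, k8, delta, muX;
  double r, k9, k10, T0, muT, muS, Js, gD, muJ, muD;
};

// canonical order; must match .param_order in R/stat_params.R
static Pars unpack(const NumericVector& p) {
  Pars P;
  P.lS1 = p[0];  P.k1 = p[1];   P.k2 = p[2];    P.alpha = p[3];
  P.lk = p[4];   P.lJ = p[5];   P.K = p[6];     P.lS2 = p[7];
  P.k3 = p[8];   P.k4 = p[9];   P.beta = p[10]; P.mu3 = p[11];
  P.l1 = p[12];  P.k5 = p[13];  P.k6 = p[14];   P.gamma = p[15];
  P.l3 = p[16];  P.muB = p[17]; P.l2 = p[18];   P.k7 = p[19];
  P.k8 = p[20];  P.delta = p[21]; P.muX = p[22];
  P.r = p[23];   P.k9 = p[24];  P.k10 = p[25];  P.T0 = p[26];
  P.muT = p[27]; P.muS = p[28]; P.Js = p[29];   P.gD = p[30];
  P.muJ = p[31]; P.muD = p[32];
  return P;
}

static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static inline double indicator(double B, double X, double Bth, double Xth,
                               bool smooth, double kk) {
  if (!smooth) return (B < Bth && X > Xth) ? 1.0 : 0.0;
  return sigm(kk * (Bth - B)) * sigm(kk * (X - Xth));
}

static inline void rhs8(const double* y, double uS, double uD, const Pars& P,
                        double Bth, double Xth, bool smooth, double kk,
                        double* dy) {
  const double S1 = y[0], S3 = y[1], B = y[2], X = y[3];
  const double T = y[4], S = y[5], J = y[6], D = y[7];
  const double k2s = P.k2 * P.k2, k4s = P.k4 * P.k4;
  const double k6s = P.k6 * P.k6, k8s = P.k8 * P.k8, k10s = P.k10 * P.k10;
  const double I = indicator(B, X, Bth, Xth, smooth, kk);
  dy[0] = P.lS1 * S + P.k1 * k2s / (k2s + P.alpha * S3 * S3) - S1;
  dy[1] = (P.lk + P.lJ * J) / (P.K + P.lS2 * S) +
          P.k3 * k4s / (k4s + P.beta * S1 * S1) - P.mu3 * S3;
  dy[2] = P.l1 + P.k5 * k6s / (k6s + P.gamma * S1 * S1) + P.l3 * S3 - P.muB * B;
  dy[3] = P.l2 + P.k7 * k8s / (k8s + P.delta * B * B) - P.muX * X;
  const double phi = S1 * S1 / (k10s + S1 * S1);
  dy[4] = P.r * (1.0 - P.k9 * phi * I) * T * (1.0 - T / P.T0) - P.muT * T * I;
  dy[5] = uS - P.muS * S;
  dy[6] = P.Js - P.gD * D * J - P.muJ * J;
  dy[7] = uD - P.muD * D;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix sim_rk4_cpp(NumericVector times, NumericVector y0,
                          NumericVector params, NumericVector thresholds,
                          NumericVector uS, NumericVector uD, double dt_max,
                          bool smooth, double smooth_k) {
  const int m = times.size() - 1;
  if (uS.size() != m || uD.size() != m)
    stop("control vectors must have length(times) - 1");
  const Pars P = unpack(params);
  const double Bth = thresholds[2], Xth = thresholds[3];
  NumericMatrix out(m + 1, 8);
  double y[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  for (int j = 0; j < 8; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }
  for (int i = 0; i < m; ++i) {
    const double t0 = times[i], t1 = times[i + 1];
    const double span = t1 - t0;
    if (span <= 0) stop("time grid must be strictly increasing");
    const int nsub = std::max(1, (int)std::ceil(span / dt_max));
    const double h = span / nsub;
    const double us = uS[i], ud = uD[i];
    for (int s = 0; s < nsub; ++s) {
      rhs8(y, us, ud, P, Bth, Xth, smooth, smooth_k, k1);
      for (int j = 0; j < 8; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
      rhs8(tmp, us, ud, P, Bth, Xth, smooth, smooth_k, k2);
      for (int j = 0; j < 8; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
      rhs8(tmp, us, ud, P, Bth, Xth, smooth, smooth_k, k3);
      for (int j = 0; j < 8; ++j) tmp[j] = y[j] + h * k3[j];
      rhs8(tmp, us, ud, P, Bth, Xth, smooth, smooth_k, k4);
      for (int j = 0; j < 8; ++j) {
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (y[j] < 0.0) y[j] = 0.0;  // admissible states are non-negative
        if (!R_finite(y[j]))
          stop("state became non-finite near t = %f", t0 + s * h);
      }
    }
    for (int j = 0; j < 8; ++j) out(i + 1, j) = y[j];
  }
  return out;
}

// -dH/dx for H = L + lambda . f, with the indicator value I supplied by the
// caller (frozen forward-pass value in hard mode, recomputed sigmoid in
// smooth mode, where its B/X derivatives enter the tumour row).
static inline void adj_rhs(const double* y, const double* lam, double I,
                           const Pars& P, const double* w, bool smooth,
                           double kk, double Bth, double Xth, double* dl) {
  const double S1 = y[0], S3 = y[1], B = y[2], X = y[3];
  const double T = y[4], S = y[5], J = y[6], D = y[7];
  const double A1 = w[0], A2 = w[1], A3 = w[2], Tbar = w[7];
  const double k2s = P.k2 * P.k2, k4s = P.k4 * P.k4;
  const double k6s = P.k6 * P.k6, k8s = P.k8 * P.k8, k10s = P.k10 * P.k10;
  const double D1 = k2s + P.alpha * S3 * S3;
  const double D2 = k4s + P.beta * S1 * S1;
  const double D3 = k6s + P.gamma * S1 * S1;
  const double D4 = k8s + P.delta * B * B;
  const double D5 = P.K + P.lS2 * S;
  const double df1dS3 = -2.0 * P.k1 * k2s * P.alpha * S3 / (D1 * D1);
  const double df2dS1 = -2.0 * P.k3 * k4s * P.beta * S1 / (D2 * D2);
  const double df2dS = -(P.lk + P.lJ * J) * P.lS2 / (D5 * D5);
  const double df2dJ = P.lJ / D5;
  const double df3dS1 = -2.0 * P.k5 * k6s * P.gamma * S1 / (D3 * D3);
  const double df4dB = -2.0 * P.k7 * k8s * P.delta * B / (D4 * D4);
  const double phi = S1 * S1 / (k10s + S1 * S1);
  const double dphi = 2.0 * S1 * k10s / ((k10s + S1 * S1) * (k10s + S1 * S1));
  const double logis = T * (1.0 - T / P.T0);
  const double df5dS1 = -P.r * P.k9 * I * dphi * logis;
  const double df5dT =
      P.r * (1.0 - P.k9 * phi * I) * (1.0 - 2.0 * T / P.T0) - P.muT * I;
  double df5dB = 0.0, df5dX = 0.0;
  if (smooth) {
    const double sB = sigm(kk * (Bth - B)), sX = sigm(kk * (X - Xth));
    const double dIdB = -kk * sB * (1.0 - sB) * sX;
    const double dIdX = kk * sX * (1.0 - sX) * sB;
    df5dB = (-P.r * P.k9 * phi * logis - P.muT * T) * dIdB;
    df5dX = (-P.r * P.k9 * phi * logis - P.muT * T) * dIdX;
  }
  dl[0] = -(-lam[0] + lam[1] * df2dS1 + lam[2] * df3dS1 + lam[4] * df5dS1);
  dl[1] = -(lam[0] * df1dS3 - lam[1] * P.mu3 + lam[2] * P.l3);
  dl[2] = -(2.0 * A2 * B + lam[3] * df4dB - lam[2] * P.muB + lam[4] * df5dB);
  dl[3] = -(-2.0 * A3 * X - lam[3] * P.muX + lam[4] * df5dX);
  dl[4] = -(2.0 * A1 * (T - Tbar) + lam[4] * df5dT);
  dl[5] = -(lam[0] * P.lS1 + lam[1] * df2dS - lam[5] * P.muS);
  dl[6] = -(lam[1] * df2dJ + lam[6] * (-P.gD * D - P.muJ));
  dl[7] = -(lam[6] * (-P.gD * J) - lam[7] * P.muD);
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix adjoint_rk4_cpp(NumericVector times, NumericMatrix states,
                              NumericVector params, NumericVector thresholds,
                              NumericVector weights, NumericVector indicator,
                              double dt_max, bool smooth, double smooth_k) {
  const int m = times.size() - 1;
  if (states.nrow() != m + 1 || states.ncol() != 8)
    stop("states must be a (length(times) x 8) matrix");
  const Pars P = unpack(params);
  const double Bth = thresholds[2], Xth = thresholds[3];
  const double* w = REAL(weights);
  NumericMatrix out(m + 1, 8);
  double lam[8], k1[8], k2[8], k3[8], k4[8], tmp[8], yi[8], y1[8];
  for (int j = 0; j < 8; ++j) { lam[j] = 0.0; out(m, j) = 0.0; }
  for (int i = m - 1; i >= 0; --i) {
    const double span = times[i + 1] - times[i];
    const int nsub = std::max(1, (int)std::ceil(span / dt_max));
    const double h = span / nsub;
    const double Ifroz = indicator[i];  // forward-pass value, frozen per interval
    for (int j = 0; j < 8; ++j) {
      yi[j] = states(i, j);
      y1[j] = states(i + 1, j);
    }
    for (int s = nsub - 1; s >= 0; --s) {
      // linear interpolation of the forward states inside the interval
      const double a0 = (double)s / nsub, a1 = (double)(s + 1) / nsub;
      const double am = 0.5 * (a0 + a1);
      double ys0[8], ysm[8], ys1[8];
      for (int j = 0; j < 8; ++j) {
        ys0[j] = yi[j] + a1 * (y1[j] - yi[j]);  // right edge (backward start)
        ysm[j] = yi[j] + am * (y1[j] - yi[j]);
        ys1[j] = yi[j] + a0 * (y1[j] - yi[j]);  // left edge (backward end)
      }
      double Ia = smooth ? sigm(smooth_k * (Bth - ys0[2])) * sigm(smooth_k * (ys0[3] - Xth)) : Ifroz;
      double Ib = smooth ? sigm(smooth_k * (Bth - ysm[2])) * sigm(smooth_k * (ysm[3] - Xth)) : Ifroz;
      double Ic = smooth ? sigm(smooth_k * (Bth - ys1[2])) * sigm(smooth_k * (ys1[3] - Xth)) : Ifroz;
      adj_rhs(ys0, lam, Ia, P, w, smooth, smooth_k, Bth, Xth, k1);
      for (int j = 0; j < 8; ++j) tmp[j] = lam[j] - 0.5 * h * k1[j];
      adj_rhs(ysm, tmp, Ib, P, w, smooth, smooth_k, Bth, Xth, k2);
      for (int j = 0; j < 8; ++j) tmp[j] = lam[j] - 0.5 * h * k2[j];
      adj_rhs(ysm, tmp, Ib, P, w, smooth, smooth_k, Bth, Xth, k3);
      for (int j = 0; j < 8; ++j) tmp[j] = lam[j] - h * k3[j];
      adj_rhs(ys1, tmp, Ic, P, w, smooth, smooth_k, Bth, Xth, k4);
      for (int j = 0; j < 8; ++j) {
        lam[j] -= h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (!R_finite(lam[j])) stop("costate became non-finite");
      }
    }
    for (int j = 0; j < 8; ++j) out(i, j) = lam[j];
  }
  return out;
}
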