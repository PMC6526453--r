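#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Wiener diffusion first-passage-time machinery, within-trial diffusion
// coefficient fixed at s = 1.  The process starts at z = zr * a between an
// absorbing lower boundary at 0 and an upper boundary at a, with drift v.
// "lower" quantities refer to absorption at 0; upper-boundary quantities are
// obtained by the reflection (v, zr) -> (-v, 1 - zr).

static const double PI_ = 3.14159265358979323846;

// Probability of absorption at the lower boundary.  Stable in both drift
// directions: exponents are kept non-positive on each branch.
static double p_lower_scalar(double v, double a, double zr) {
  double z = zr * a;
  if (std::fabs(v) < 1e-10) return 1.0 - zr;
  if (v > 0) {
    // (e^{-2vz} - e^{-2va}) / (1 - e^{-2va})
    double num = std::expm1(-2.0 * v * z) - std::expm1(-2.0 * v * a);
    double den = -std::expm1(-2.0 * v * a);
    return num / den;
  }
  // v < 0: multiply through by e^{2va}
  return std::expm1(2.0 * v * (a - z)) / std::expm1(2.0 * v * a);
}

// Defective CDF of absorption time at the lower boundary, large-time series:
//   F_lo(t) = P_lo - (pi/a^2) e^{-vz} sum_k k sin(k pi zr) e^{-lambda_k t} / lambda_k,
//   lambda_k = (v^2 + k^2 pi^2 / a^2) / 2.
// Adaptively truncated; the partial result is clamped to [0, P_lo] so that
// penalty-region parameter probes cannot return values outside the defective
// range even when the series cancels badly.
static double cdf_lower_scalar(double t, double v, double a, double zr) {
  if (t <= 0.0) return 0.0;
  double P = p_lower_scalar(v, a, zr);
  double z = zr * a;
  double pref = PI_ / (a * a);
  double e0 = -v * z - 0.5 * v * v * t;     // drift part of the exponent
  double q2 = PI_ * PI_ * t / (2.0 * a * a);
  double v2 = v * v;
  double th = PI_ * zr;
  double s1 = std::sin(th), c1 = std::cos(th);
  double sk = s1, ck = c1;                   // sin(k th), cos(k th)
  double E = std::exp(e0 - q2);              // exp(e0 - k^2 q2) at k = 1
  // incremental: E_{k+1} = E_k * exp(-(2k+1) q2)
  double step = std::exp(-3.0 * q2);         // exp factor for k=1 -> k=2
  double w2 = std::exp(-2.0 * q2);
  double sum = 0.0;
  const int kmax = 20000;
  for (int k = 1; k <= kmax; ++k) {
    double lam = 0.5 * (v2 + (double)k * k * PI_ * PI_ / (a * a));
    sum += (double)k * sk * E / lam;
    double bound = pref * E * (double)(k + 1) / lam;
    if (k >= 3 && bound < 1e-12) break;
    // advance recurrences
    double sk1 = sk * c1 + ck * s1;
    double ck1 = ck * c1 - sk * s1;
    sk = sk1; ck = ck1;
    E *= step;
    step *= w2;
  }
  double F = P - pref * sum;
  if (F < 0.0) F = 0.0;
  if (F > P) F = P;
  return F;
}

// Defective density of absorption at the lower boundary.  Representation is
// chosen by the scaled time t/a^2: the small-time (image/images) series for
// t/a^2 below 0.12, the large-time (Fourier) series otherwise.
static double pdf_lower_scalar(double t, double v, double a, double zr) {
  if (t <= 0.0) return 0.0;
  double z = zr * a;
  double tn = t / (a * a);
  double e0 = -v * z - 0.5 * v * v * t;
  if (tn < 0.12) {
    // g(t) = e^{e0} * a / sqrt(2 pi t^3) * sum_k (zr + 2k) exp(-a^2 (zr+2k)^2 / (2t))
    double pref = a / std::sqrt(2.0 * PI_ * t * t * t);
    double sum = 0.0;
    for (int k = 0; k <= 100; ++k) {
      double mx = 0.0;
      for (int sgn = 0; sgn < 2; ++sgn) {
        if (sgn == 1 && k == 0) continue;
        double u = zr + 2.0 * (sgn == 0 ? k : -k);
        double term = u * std::exp(-a * a * u * u / (2.0 * t));
        sum += term;
        if (std::fabs(term) > mx) mx = std::fabs(term);
      }
      if (k >= 2 && mx < 1e-16) break;
    }
    double g = std::exp(e0) * pref * sum;
    return g > 0.0 ? g : 0.0;
  }
  // large-time
  double pref = PI_ / (a * a);
  double q2 = PI_ * PI_ * t / (2.0 * a * a);
  double th = PI_ * zr;
  double s1 = std::sin(th), c1 = std::cos(th);
  double sk = s1, ck = c1;
  double E = std::exp(e0 - q2);
  double step = std::exp(-3.0 * q2);
  double w2 = std::exp(-2.0 * q2);
  double sum = 0.0;
  for (int k = 1; k <= 20000; ++k) {
    sum += (double)k * sk * E;
    if (k >= 3 && E * (double)(k + 1) * pref < 1e-13) break;
    double sk1 = sk * c1 + ck * s1;
    double ck1 = ck * c1 - sk * s1;
    sk = sk1; ck = ck1;
    E *= step;
    step *= w2;
  }
  double g = pref * sum;
  return g > 0.0 ? g : 0.0;
}

// [[Rcpp::export]]
NumericVector wfpt_p_lower_cpp(NumericVector v, NumericVector a, NumericVector zr) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = p_lower_scalar(v[i], a[i], zr[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector wfpt_cdf_cpp(NumericVector t, double v, double a, double zr, bool upper) {
  int n = t.size();
  NumericVector out(n);
  double vv = upper ? -v : v;
  double zz = upper ? 1.0 - zr : zr;
  for (int i = 0; i < n; ++i) out[i] = cdf_lower_scalar(t[i], vv, a, zz);
  return out;
}

// [[Rcpp::export]]
NumericVector wfpt_pdf_cpp(NumericVector t, double v, double a, double zr, bool upper) {
  int n = t.size();
  NumericVector out(n);
  double vv = upper ? -v : v;
  double zz = upper ? 1.0 - zr : zr;
  for (int i = 0; i < n; ++i) out[i] = pdf_lower_scalar(t[i], vv, a, zz);
  return out;
}

// Quadrature-mixed defective CDFs on a grid of decision times.
// v_nodes/v_w: nodes and weights for the across-trial drift distribution;
// zr_nodes/zr_w: nodes and weights for the starting-point distribution.
// Returns the (weight-averaged) lower and upper defective CDFs evaluated at
// each tau, plus the averaged lower-boundary choice probability.
// [[Rcpp::export]]
List wfpt_mix_cdf_grid_cpp(NumericVector tau, double a,
                           NumericVector v_nodes, NumericVector v_w,
                           NumericVector zr_nodes, NumericVector zr_w) {
  int nt = tau.size();
  int ni = v_nodes.size();
  int nj = zr_nodes.size();
  NumericVector Flo(nt), Fup(nt);
  double C = PI_ / (a * a);

  // per-node constants
  std::vector<double> EZlo(ni * nj), EZup(ni * nj), Pij(ni * nj), wij(ni * nj);
  double p_lo = 0.0;
  for (int i = 0; i < ni; ++i) {
    for (int j = 0; j < nj; ++j) {
      double v = v_nodes[i], zr = zr_nodes[j];
      int id = i * nj + j;
      EZlo[id] = std::exp(-v * a * zr);
      EZup[id] = std::exp(v * a * (1.0 - zr));
      Pij[id] = p_lower_scalar(v, a, zr);
      wij[id] = v_w[i] * zr_w[j];
      p_lo += wij[id] * Pij[id];
    }
  }

  // sine tables per zr node, grown on demand
  int Kcap = 256;
  std::vector< std::vector<double> > sinj(nj);
  std::vector<double> s1(nj), c1(nj), cprev(nj);
  for (int j = 0; j < nj; ++j) {
    double th = PI_ * zr_nodes[j];
    s1[j] = std::sin(th); c1[j] = std::cos(th);
    sinj[j].resize(Kcap + 1);
    sinj[j][0] = 0.0;
    double sk = s1[j], ck = c1[j];
    for (int k = 1; k <= Kcap; ++k) {
      sinj[j][k] = sk;
      double sk1 = sk * c1[j] + ck * s1[j];
      double ck1 = ck * c1[j] - sk * s1[j];
      sk = sk1; ck = ck1;
    }
  }
  auto grow_sin = [&](int need) {
    int old = Kcap;
    while (Kcap < need) Kcap *= 2;
    for (int j = 0; j < nj; ++j) {
      sinj[j].resize(Kcap + 1);
      // rebuild from scratch for simplicity (rare path)
      double sk = s1[j], ck = c1[j];
      for (int k = 1; k <= Kcap; ++k) {
        sinj[j][k] = sk;
        double sk1 = sk * c1[j] + ck * s1[j];
        double ck1 = ck * c1[j] - sk * s1[j];
        sk = sk1; ck = ck1;
      }
    }
    (void)old;
  };

  std::vector<double> Bbuf;   // exp(-k^2 q2), index k
  std::vector<double> Ev(ni);
  double pia2 = PI_ * PI_ / (a * a);

  for (int it = 0; it < nt; ++it) {
    double t = tau[it];
    if (t <= 0.0) { Flo[it] = 0.0; Fup[it] = 0.0; continue; }
    double q2 = PI_ * PI_ * t / (2.0 * a * a);
    // incremental exp(-k^2 q2)
    Bbuf.clear();
    Bbuf.push_back(1.0);                     // k = 0 unused
    double B = std::exp(-q2);
    double step = std::exp(-3.0 * q2);
    double w2 = std::exp(-2.0 * q2);
    Bbuf.push_back(B);
    int kfill = 1;
    for (int i = 0; i < ni; ++i) Ev[i] = std::exp(-0.5 * v_nodes[i] * v_nodes[i] * t);

    double flo = 0.0, fup = 0.0;
    for (int i = 0; i < ni; ++i) {
      double v2 = v_nodes[i] * v_nodes[i];
      for (int j = 0; j < nj; ++j) {
        int id = i * nj + j;
        double plo = C * EZlo[id] * Ev[i];
        double pup = C * EZup[id] * Ev[i];
        double pmax = plo > pup ? plo : pup;
        double Slo = 0.0, Sup = 0.0;
        double sgn = 1.0;                    // (-1)^(k+1)
        const std::vector<double>& sj = sinj[j];
        for (int k = 1; k <= 20000; ++k) {
          if (k > kfill) {
            // extend Bbuf: B_{k} = B_{k-1} * exp(-(2k-1) q2)
            double last = Bbuf[kfill];
            // step currently holds exp(-(2*kfill+1)*q2)
            last *= step;
            step *= w2;
            Bbuf.push_back(last);
            ++kfill;
          }
          if (k > Kcap) grow_sin(k);
          double lam = 0.5 * (v2 + (double)k * (double)k * pia2);
          double base = (double)k * Bbuf[k] / lam;
          double term = base * sj[k];
          Slo += term;
          Sup += sgn * term;
          sgn = -sgn;
          if (k >= 3 && pmax * base * 1.5 < 1e-10 && Bbuf[k] < Bbuf[k - 1])
            break;
        }
        double fl = Pij[id] - plo * Slo;
        if (fl < 0.0) fl = 0.0;
        if (fl > Pij[id]) fl = Pij[id];
        double qup = 1.0 - Pij[id];
        double fu = qup - pup * Sup;
        if (fu < 0.0) fu = 0.0;
        if (fu > qup) fu = qup;
        flo += wij[id] * fl;
        fup += wij[id] * fu;
      }
    }
    Flo[it] = flo;
    Fup[it] = fup;
  }
  return List::create(_["F_lower"] = Flo, _["F_upper"] = Fup, _["p_lower"] = p_lo);
}

// Euler simulation of diffusion trials with across-trial variabilities.
// Boundary crossing uses the continuity correction: the absorbing boundaries
// are moved inward by 0.5826 * sqrt(dt) (Broadie-Glasserman-Kou), removing
// the leading O(sqrt(dt)) bias of discretely monitored crossings.
// Returns responses (1 = upper, 0 = lower) and RTs (decision time + t0 draw).
// [[Rcpp::export]]
List sim_wiener_cpp(int n, double v, double a, double zr, double t0,
                    double sv, double szr, double st0,
                    double dt, int max_steps, bool boundary_correction) {
  IntegerVector resp(n);
  NumericVector rt(n);
  double sq = std::sqrt(dt);
  double c = boundary_correction ? 0.5826 * sq : 0.0;
  double lo = c, hi = a - c;
  if (hi <= lo) stop("step size too large for boundary separation");
  for (int i = 0; i < n; ++i) {
    double vi = v + (sv > 0 ? sv * norm_rand() : 0.0);
    double zri = zr + (szr > 0 ? szr * (unif_rand() - 0.5) : 0.0);
    double t0i = t0 + (st0 > 0 ? st0 * (unif_rand() - 0.5) : 0.0);
    double x = zri * a;
    if (x <= lo) x = lo + 1e-12;
    if (x >= hi) x = hi - 1e-12;
    int stepi = 0;
    int r = -1;
    double drift = vi * dt;
    while (stepi < max_steps) {
      ++stepi;
      x += drift + sq * norm_rand();
      if (x <= lo) { r = 0; break; }
      if (x >= hi) { r = 1; break; }
    }
    if (r < 0) stop("simulated walk exceeded the step cap; increase max_steps");
    resp[i] = r;
    rt[i] = t0i + (double)stepi * dt;
  }
  return List::create(_["response"] = resp, _["rt"] = rt);
}

// Evaluate the signed CDF at points x from grid defective CDFs, averaging
// over nondecision-time nodes.  tau_grid must be uniformly spaced from 0.
// [[Rcpp::export]]
NumericVector signed_cdf_eval_cpp(NumericVector x, double h, int ngrid,
                                  NumericVector Flo, NumericVector Fup,
                                  double p_lo,
                                  NumericVector t0_nodes, NumericVector t0_w) {
  int n = x.size(), nk = t0_nodes.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = std::fabs(x[i]);
    bool neg = x[i] < 0.0;
    double g = 0.0;
    for (int k = 0; k < nk; ++k) {
      double tau = ax - t0_nodes[k];
      double F = 0.0;
      if (tau > 0.0) {
        double u = tau / h;
        int id = (int)u;
        if (id >= ngrid - 1) {
          F = neg ? Flo[ngrid - 1] : Fup[ngrid - 1];
        } else {
          double fr = u - id;
          const NumericVector& FF = neg ? Flo : Fup;
          F = FF[id] * (1.0 - fr) + FF[id + 1] * fr;
        }
      }
      g += t0_w[k] * (neg ? (p_lo - F) : (p_lo + F));
    }
    out[i] = g;
  }
  return out;
}
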