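#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <utility>
using namespace Rcpp;

// Slope bound for refinement stages: local warp slopes are kept within
// [1/SLOPE_B, SLOPE_B]. Without this the normalized objective can be
// gamed by pinching (gamma' -> 0), which deletes mismatched features
// instead of matching them.
static const double SLOPE_B = 4.0;

// Elastic matching of square-root velocity curves by dynamic programming.
//
// All q matrices are M x 2, rows sampled on a uniform parameter grid.
// Open curves: t_i = i/(M-1), i = 0..M-1, inner products by the trapezoidal
// rule. Closed curves are passed in extended form (first row appended, so
// M+1 rows spanning one full period); the trapezoidal rule on the extended
// grid then equals the rectangle rule on the period.

// Catmull-Rom cubic interpolation (clamped at the ends). Linear
// interpolation systematically shortens a curving q and biases the
// matching objective; cubic interpolation makes the bias negligible.
static inline double q_interp(const NumericMatrix& q, double pos, int col) {
  const int n = q.nrow();
  int lo = (int)std::floor(pos);
  if (lo >= n - 1) return q(n - 1, col);
  if (lo < 0) return q(0, col);
  const double w = pos - lo;
  const double p1 = q(lo, col), p2 = q(lo + 1, col);
  const double p0 = (lo > 0) ? q(lo - 1, col) : 2.0 * p1 - p2;
  const double p3 = (lo < n - 2) ? q(lo + 2, col) : 2.0 * p2 - p1;
  return p1 + 0.5 * w * (p2 - p0 +
         w * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
              w * (3.0 * (p1 - p2) + p3 - p0)));
}

// Best monotone reparametrization gamma of q2 (endpoints pinned) maximizing
// the L2 inner product <q1, (q2 o gamma) * sqrt(gamma')>. Neighbour slope
// moves (di, dj) are supplied as an integer matrix. Returns the piecewise
// linear gamma on the grid and the achieved inner product.
// [[Rcpp::export]]
List cpp_dp_match(const NumericMatrix q1, const NumericMatrix q2,
                  const IntegerMatrix nbrs, const bool pin_ends = true) {
  const int M = q1.nrow();          // grid points (including both endpoints)
  if (q2.nrow() != M) stop("grid size mismatch");
  const int K = nbrs.nrow();
  const double dt = 1.0 / (M - 1);
  const double NEG = -1e30;

  std::vector<double> val((size_t)M * M, NEG);
  std::vector<int> pred((size_t)M * M, -1);
  if (pin_ends) {
    val[0] = 0.0;
  } else {
    for (int j = 0; j < M; ++j) val[j] = 0.0;  // start anywhere on q2
  }

  // f(a, b) = <q1[a], q2(b)> with b fractional
  for (int i = 1; i < M; ++i) {
    for (int j = 1; j < M; ++j) {
      double best = NEG;
      int bestk = -1;
      for (int k = 0; k < K; ++k) {
        const int di = nbrs(k, 0), dj = nbrs(k, 1);
        const int pi = i - di, pj = j - dj;
        if (pi < 0 || pj < 0) continue;
        const double pv = val[(size_t)pi * M + pj];
        if (pv <= NEG / 2) continue;
        const double rs = std::sqrt((double)dj / (double)di);
        // trapezoid over the di unit steps of the segment
        double seg = 0.0;
        for (int s = 0; s <= di; ++s) {
          const int a = pi + s;
          const double b = pj + (double)dj * s / di;
          const double f = q1(a, 0) * q_interp(q2, b, 0) +
                           q1(a, 1) * q_interp(q2, b, 1);
          seg += (s == 0 || s == di) ? 0.5 * f : f;
        }
        const double cand = pv + seg * rs * dt;
        if (cand > best) { best = cand; bestk = k; }
      }
      val[(size_t)i * M + j] = best;
      pred[(size_t)i * M + j] = bestk;
    }
  }

  int end_j = M - 1;
  if (!pin_ends) {
    double best_end = NEG;
    for (int j = 1; j < M; ++j) {
      const double v = val[(size_t)(M - 1) * M + j];
      if (v > best_end) { best_end = v; end_j = j; }
    }
  }
  const double ip = val[(size_t)(M - 1) * M + end_j];
  if (ip <= NEG / 2) stop("no monotone path found (grid too small for slope set)");

  // backtrack gamma
  NumericVector gamma(M);
  {
    int i = M - 1, j = end_j;
    std::vector<double> g(M, NA_REAL);
    g[M - 1] = (double)end_j / (M - 1);
    while (i > 0) {
      const int k = pred[(size_t)i * M + j];
      const int di = nbrs(k, 0), dj = nbrs(k, 1);
      for (int s = 0; s < di; ++s)
        g[i - di + s] = (double)(j - dj + (double)dj * s / di) / (M - 1);
      i -= di; j -= dj;
    }
    g[0] = (double)j / (M - 1);
    // fill any untouched interior nodes (cannot happen, but be safe)
    for (int a = 0; a < M; ++a) gamma[a] = g[a];
  }
  return List::create(_["gamma"] = gamma, _["ip"] = ip);
}

// Segment-wise objective used by the refinement: for piecewise-linear gamma
// the contribution of segment [t_i, t_{i+1}] is
//   sqrt(gamma') * h * (f_i + f_{i+1}) / 2,  f_i = <q1_i, q2(gamma_i)>,
// which on a DP path reproduces the DP edge costs exactly.
static double seg_cost(const NumericMatrix& q1, const NumericMatrix& q2,
                       int i, double gi, double gi1, double h) {
  const int Mq = q2.nrow();   // gamma positions live on q2's grid
  const double gdot = (gi1 - gi) / h;
  if (gdot <= 0) return -1e30;
  const double fi = q1(i, 0) * q_interp(q2, gi * (Mq - 1), 0) +
                    q1(i, 1) * q_interp(q2, gi * (Mq - 1), 1);
  const double fi1 = q1(i + 1, 0) * q_interp(q2, gi1 * (Mq - 1), 0) +
                     q1(i + 1, 1) * q_interp(q2, gi1 * (Mq - 1), 1);
  return std::sqrt(gdot) * h * 0.5 * (fi + fi1);
}

// Norm of the warped curve over one segment (trapezoid, weight gamma'):
// the discrete warp does not preserve the L2 norm exactly, so the
// refinement maximizes the normalized inner product
//   <q1, (q2 o g) sqrt(g')> / ||(q2 o g) sqrt(g')||.
static double seg_den(const NumericMatrix& q2, double gi, double gi1,
                      double h) {
  const int M = q2.nrow();
  const double gdot = (gi1 - gi) / h;
  if (gdot <= 0) return 1e30;
  const double x0 = q_interp(q2, gi * (M - 1), 0),
               y0 = q_interp(q2, gi * (M - 1), 1),
               x1 = q_interp(q2, gi1 * (M - 1), 0),
               y1 = q_interp(q2, gi1 * (M - 1), 1);
  return gdot * h * 0.5 * (x0 * x0 + y0 * y0 + x1 * x1 + y1 * y1);
}

// window objective: contribution of segments [i0, i1) to num and den
static void window_nd(const NumericMatrix& q1, const NumericMatrix& q2,
                      const NumericVector& g, int i0, int i1, double h,
                      double* num, double* den) {
  double n = 0.0, d = 0.0;
  for (int i = i0; i < i1; ++i) {
    n += seg_cost(q1, q2, i, g[i], g[i + 1], h);
    d += seg_den(q2, g[i], g[i + 1], h);
  }
  *num = n; *den = d;
}

// Multiscale refinement of a DP reparametrization, maximizing the
// normalized inner product <q1,(q2 o g) sqrt(g')>/||(q2 o g) sqrt(g')||.
// Coarse-to-fine block moves (each coarse node is line-searched with the
// nodes inside its window interpolated linearly) remove the low-frequency
// part of the DP lattice error, which plain per-node descent cannot reach
// in few passes; stride-1 passes then polish the slope-quantization
// zig-zag. Endpoints stay fixed.
// [[Rcpp::export]]
List cpp_refine_gamma(const NumericMatrix q1, const NumericMatrix q2,
                      NumericVector gamma, const int passes = 3) {
  const int M = q1.nrow();
  const double h = 1.0 / (M - 1);
  NumericVector g = clone(gamma);
  const double gr = 0.3819660112501051;
  double num = 0.0, den = 0.0;
  window_nd(q1, q2, g, 0, M - 1, h, &num, &den);

  std::vector<int> strides;
  for (int s = M / 4; s >= 1; s /= 2) strides.push_back(s);

  for (int cyc = 0; cyc < passes; ++cyc) {
  for (size_t li = 0; li < strides.size(); ++li) {
    const int s = strides[li];
    const int npass = (s == 1) ? 2 : 1;
    for (int p = 0; p < npass; ++p) {
      for (int i = s; i <= M - 1 - s; i += s) {
        const int i0 = i - s, i1 = i + s;
        const double span_h = s * h;
        const double lo0 = std::max(g[i0] + span_h / SLOPE_B,
                                    g[i1] - span_h * SLOPE_B);
        const double hi0 = std::min(g[i0] + span_h * SLOPE_B,
                                    g[i1] - span_h / SLOPE_B);
        if (hi0 <= lo0) continue;
        double nw0, dw0;
        window_nd(q1, q2, g, i0, i1, h, &nw0, &dw0);
        const double n_out = num - nw0, d_out = den - dw0;
        NumericVector gw(2 * s + 1);
        // phi(x): window nodes linear from g[i0] to x to g[i1]
        struct Eval {
          const NumericMatrix &q1, &q2;
          NumericVector &gw; const NumericVector &g;
          int i0, i1, s; double h, n_out, d_out;
          double operator()(double x) {
            for (int j = 0; j <= s; ++j) {
              gw[j] = g[i0] + (x - g[i0]) * j / s;
              gw[s + j] = x + (g[i1] - x) * j / s;
            }
            double n = 0.0, d = 0.0;
            for (int j = 0; j < 2 * s; ++j) {
              n += seg_cost(q1, q2, i0 + j, gw[j], gw[j + 1], h);
              d += seg_den(q2, gw[j], gw[j + 1], h);
            }
            return (n_out + n) / std::sqrt(d_out + d);
          }
        } phi = { q1, q2, gw, g, i0, i1, s, h, n_out, d_out };
        double lo = lo0, hi = hi0;
        double x1 = lo + gr * (hi - lo), x2 = hi - gr * (hi - lo);
        double f1 = phi(x1), f2 = phi(x2);
        for (int it = 0; it < 20; ++it) {
          if (f1 > f2) {
            hi = x2; x2 = x1; f2 = f1; x1 = lo + gr * (hi - lo); f1 = phi(x1);
          } else {
            lo = x1; x1 = x2; f1 = f2; x2 = hi - gr * (hi - lo); f2 = phi(x2);
          }
        }
        const double xbest = (f1 > f2) ? x1 : x2;
        const double fbest = (f1 > f2) ? f1 : f2;
        const double fcur = (n_out + nw0) / std::sqrt(d_out + dw0);
        if (fbest > fcur) {
          for (int j = 0; j <= s; ++j) {
            g[i0 + j] = g[i0] + (xbest - g[i0]) * j / s;
            g[i + j] = xbest + (g[i1] - xbest) * j / s;
          }
          double nw1, dw1;
          window_nd(q1, q2, g, i0, i1, h, &nw1, &dw1);
          num = n_out + nw1; den = d_out + dw1;
        }
      }
    }
  }
  }
  const double ip = num / std::sqrt(den);
  return List::create(_["gamma"] = g, _["ip"] = ip);
}

// Apply a piecewise-linear reparametrization to q: (q o gamma) * sqrt(gamma').
// gamma is given on the same uniform grid as q (values in [0,1]).
// [[Rcpp::export]]
NumericMatrix cpp_warp_q(const NumericMatrix q, const NumericVector gamma) {
  const int M = q.nrow();
  NumericMatrix out(M, 2);
  for (int i = 0; i < M; ++i) {
    const double pos = gamma[i] * (M - 1);
    // centred finite difference of gamma for the local stretch
    double gdot;
    if (i == 0) gdot = (gamma[1] - gamma[0]) * (M - 1);
    else if (i == M - 1) gdot = (gamma[M - 1] - gamma[M - 2]) * (M - 1);
    else gdot = (gamma[i + 1] - gamma[i - 1]) * (M - 1) / 2.0;
    if (gdot < 0) gdot = 0;
    const double rs = std::sqrt(gdot);
    out(i, 0) = q_interp(q, pos, 0) * rs;
    out(i, 1) = q_interp(q, pos, 1) * rs;
  }
  return out;
}

// Optimal planar rotation R maximizing sum_i w_i <q1_i, R q2_i>.
// [[Rcpp::export]]
NumericMatrix cpp_opt_rotation(const NumericMatrix q1, const NumericMatrix q2,
                               const NumericVector w) {
  const int M = q1.nrow();
  double C = 0.0, S = 0.0;
  for (int i = 0; i < M; ++i) {
    C += w[i] * (q1(i, 0) * q2(i, 0) + q1(i, 1) * q2(i, 1));
    S += w[i] * (q1(i, 1) * q2(i, 0) - q1(i, 0) * q2(i, 1));
  }
  const double th = std::atan2(S, C);
  NumericMatrix R(2, 2);
  R(0, 0) = std::cos(th); R(0, 1) = -std::sin(th);
  R(1, 0) = std::sin(th); R(1, 1) = std::cos(th);
  return R;
}

// cyclic Catmull-Rom interpolation on a closed q (period M rows)
static inline double q_interp_cyc(const NumericMatrix& q, double pos, int col) {
  const int n = q.nrow();
  double pm = pos - n * std::floor(pos / n);  // wrap into [0, n)
  if (pm >= n) pm -= n;
  const int lo = (int)std::floor(pm);
  const double w = pm - lo;
  const double p0 = q((lo - 1 + n) % n, col), p1 = q(lo, col),
               p2 = q((lo + 1) % n, col), p3 = q((lo + 2) % n, col);
  return p1 + 0.5 * w * (p2 - p0 +
         w * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
              w * (3.0 * (p1 - p2) + p3 - p0)));
}

// Apply a closed-curve match: sample q2 (cyclically) at absolute vertex
// positions and scale by sqrt of the local stretch. positions has M+1
// entries spanning one full period.
// [[Rcpp::export]]
NumericMatrix cpp_warp_closed(const NumericMatrix q2,
                              const NumericVector positions,
                              const NumericMatrix R) {
  const int Me = positions.size();
  const int M = Me - 1;
  NumericMatrix out(Me, 2);
  for (int i = 0; i < Me; ++i) {
    double gdot;  // stretch in curve-parameter units (positions are in
                  // vertex units; one period of M vertices maps to [0,1])
    if (i == 0) gdot = positions[1] - positions[0];
    else if (i == Me - 1) gdot = positions[Me - 1] - positions[Me - 2];
    else gdot = (positions[i + 1] - positions[i - 1]) / 2.0;
    if (gdot < 0) gdot = 0;
    const double rs = std::sqrt(gdot);
    const double x = q_interp_cyc(q2, positions[i], 0) * rs;
    const double y = q_interp_cyc(q2, positions[i], 1) * rs;
    out(i, 0) = R(0, 0) * x + R(0, 1) * y;
    out(i, 1) = R(1, 0) * x + R(1, 1) * y;
  }
  return out;
}

static NumericMatrix rotate_q(const NumericMatrix& q, const NumericMatrix& R) {
  const int M = q.nrow();
  NumericMatrix out(M, 2);
  for (int i = 0; i < M; ++i) {
    out(i, 0) = R(0, 0) * q(i, 0) + R(0, 1) * q(i, 1);
    out(i, 1) = R(1, 0) * q(i, 0) + R(1, 1) * q(i, 1);
  }
  return out;
}

static NumericMatrix extend_closed(const NumericMatrix& q, int shift) {
  // cyclic shift by `shift` rows, then append the first row (M+1 x 2)
  const int M = q.nrow();
  NumericMatrix out(M + 1, 2);
  for (int i = 0; i <= M; ++i) {
    const int src = (i + shift) % M;
    out(i, 0) = q(src, 0);
    out(i, 1) = q(src, 1);
  }
  return out;
}


// Banded micro-refinement of a closed-curve match. Each node position may
// move by one of `nu` offsets within +/- radius (vertex units); the best
// monotone offset path with equal first/last offset (preserving the cyclic
// winding) is found exactly by DP on the small offset lattice, maximizing
// a Dinkelbach linearization N - lambda*D of the normalized inner product
// N/sqrt(D). Unlike coordinate descent this is globally optimal within the
// band, so it does not stall on correlated node moves.
static double micro_refine_closed(const NumericMatrix& q1e,
                                  const NumericMatrix& q2,
                                  const NumericMatrix& R,
                                  std::vector<double>& pos,
                                  double radius, int nu) {
  const int Me = (int)pos.size();
  const int M = Me - 1;
  const double h = 1.0 / M;
  std::vector<double> off(nu);
  for (int a = 0; a < nu; ++a)
    off[a] = -radius + 2.0 * radius * a / (nu - 1);
  std::vector<double> F((size_t)Me * nu), N((size_t)Me * nu);
  for (int i = 0; i < Me; ++i) for (int a = 0; a < nu; ++a) {
    const double p = pos[i] + off[a];
    const double x = q_interp_cyc(q2, p, 0), y = q_interp_cyc(q2, p, 1);
    const double xr = R(0, 0) * x + R(0, 1) * y,
                 yr = R(1, 0) * x + R(1, 1) * y;
    F[(size_t)i * nu + a] = q1e(i, 0) * xr + q1e(i, 1) * yr;
    N[(size_t)i * nu + a] = xr * xr + yr * yr;
  }
  const int c = (nu - 1) / 2;           // zero offset index
  double num0 = 0.0, den0 = 0.0;
  for (int i = 0; i < M; ++i) {
    const double dp = pos[i + 1] - pos[i];
    if (dp <= 0) continue;
    num0 += std::sqrt(dp) * h * 0.5 *
            (F[(size_t)i * nu + c] + F[(size_t)(i + 1) * nu + c]);
    den0 += dp * h * 0.5 *
            (N[(size_t)i * nu + c] + N[(size_t)(i + 1) * nu + c]);
  }
  double best_nip = num0 / std::sqrt(den0);

  std::vector<double> val((size_t)Me * nu);
  std::vector<int> pred((size_t)Me * nu);
  std::vector<int> choice(Me), best_path;
  for (int round = 0; round < 2; ++round) {
    const double lam = num0 / (2.0 * den0);
    double run_best = -1e30;
    for (int u0 = 0; u0 < nu; ++u0) {
      for (int a = 0; a < nu; ++a)
        val[a] = (a == u0) ? 0.0 : -1e30;
      for (int i = 1; i < Me; ++i) {
        for (int b = 0; b < nu; ++b) {
          double best = -1e30; int bk = -1;
          const double pb = pos[i] + off[b];
          for (int a = 0; a < nu; ++a) {
            const double pv = val[(size_t)(i - 1) * nu + a];
            if (pv <= -1e29) continue;
            const double dp = pb - (pos[i - 1] + off[a]);
            if (dp < 1.0 / SLOPE_B || dp > SLOPE_B) continue;
            const double sn = std::sqrt(dp) * h * 0.5 *
              (F[(size_t)(i - 1) * nu + a] + F[(size_t)i * nu + b]);
            const double sd = dp * h * 0.5 *
              (N[(size_t)(i - 1) * nu + a] + N[(size_t)i * nu + b]);
            const double cand = pv + sn - lam * sd;
            if (cand > best) { best = cand; bk = a; }
          }
          val[(size_t)i * nu + b] = best;
          pred[(size_t)i * nu + b] = bk;
        }
      }
      const double end = val[(size_t)(Me - 1) * nu + u0];
      if (end > run_best && end > -1e29) {
        run_best = end;
        choice[Me - 1] = u0;
        for (int i = Me - 1; i > 0; --i)
          choice[i - 1] = pred[(size_t)i * nu + choice[i]];
        best_path = choice;
      }
    }
    if (best_path.empty()) break;
    // evaluate the true normalized inner product of the best path
    double num1 = 0.0, den1 = 0.0;
    for (int i = 0; i < M; ++i) {
      const double dp = (pos[i + 1] + off[best_path[i + 1]]) -
                        (pos[i] + off[best_path[i]]);
      if (dp <= 0) continue;
      num1 += std::sqrt(dp) * h * 0.5 *
              (F[(size_t)i * nu + best_path[i]] +
               F[(size_t)(i + 1) * nu + best_path[i + 1]]);
      den1 += dp * h * 0.5 *
              (N[(size_t)i * nu + best_path[i]] +
               N[(size_t)(i + 1) * nu + best_path[i + 1]]);
    }
    const double nip1 = num1 / std::sqrt(den1);
    if (nip1 > best_nip) {
      for (int i = 0; i < Me; ++i) pos[i] += off[best_path[i]];
      best_nip = nip1;
      // recompute state tables around the moved positions
      for (int i = 0; i < Me; ++i) for (int a = 0; a < nu; ++a) {
        const double p = pos[i] + off[a];
        const double x = q_interp_cyc(q2, p, 0), y = q_interp_cyc(q2, p, 1);
        const double xr = R(0, 0) * x + R(0, 1) * y,
                     yr = R(1, 0) * x + R(1, 1) * y;
        F[(size_t)i * nu + a] = q1e(i, 0) * xr + q1e(i, 1) * yr;
        N[(size_t)i * nu + a] = xr * xr + yr * yr;
      }
      num0 = num1; den0 = den1;
    } else break;
  }
  return best_nip;
}


// Banded micro-refinement for open curves: node positions may move by one
// of `nu` offsets within +/- radius (grid units of q2), endpoints pinned;
// the best monotone offset path is found exactly by DP on the offset
// lattice, maximizing a Dinkelbach linearization of the normalized inner
// product.
// [[Rcpp::export]]
List cpp_micro_open(const NumericMatrix q1, const NumericMatrix q2,
                    NumericVector gamma, const double radius,
                    const int nu) {
  const int M = q1.nrow();
  const double h = 1.0 / (M - 1);
  std::vector<double> pos(M);
  for (int i = 0; i < M; ++i) pos[i] = gamma[i] * (M - 1);
  std::vector<double> off(nu);
  for (int a = 0; a < nu; ++a)
    off[a] = -radius + 2.0 * radius * a / (nu - 1);
  const int c = (nu - 1) / 2;
  std::vector<double> F((size_t)M * nu), N((size_t)M * nu);
  for (int i = 0; i < M; ++i) for (int a = 0; a < nu; ++a) {
    const double p = pos[i] + off[a];
    const double x = q_interp(q2, p, 0), y = q_interp(q2, p, 1);
    F[(size_t)i * nu + a] = q1(i, 0) * x + q1(i, 1) * y;
    N[(size_t)i * nu + a] = x * x + y * y;
  }
  double num0 = 0.0, den0 = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    const double dp = (pos[i + 1] - pos[i]) / (M - 1);
    if (dp <= 0) continue;
    num0 += std::sqrt(dp) * h * 0.5 *
            (F[(size_t)i * nu + c] + F[(size_t)(i + 1) * nu + c]);
    den0 += dp * h * 0.5 *
            (N[(size_t)i * nu + c] + N[(size_t)(i + 1) * nu + c]);
  }
  double best_nip = num0 / std::sqrt(den0);
  std::vector<double> val((size_t)M * nu);
  std::vector<int> pred((size_t)M * nu), choice(M);
  for (int round = 0; round < 2; ++round) {
    const double lam = num0 / (2.0 * den0);
    for (int a = 0; a < nu; ++a)
      val[a] = (a == c) ? 0.0 : -1e30;      // start offset pinned at 0
    for (int i = 1; i < M; ++i) {
      for (int b = 0; b < nu; ++b) {
        double best = -1e30; int bk = -1;
        const double pb = pos[i] + off[b];
        for (int a = 0; a < nu; ++a) {
          const double pv = val[(size_t)(i - 1) * nu + a];
          if (pv <= -1e29) continue;
          const double slope = pb - (pos[i - 1] + off[a]);
          // positions are in row units; nodes are (M-1)h = 1 row apart
          if (slope < 1.0 / SLOPE_B || slope > SLOPE_B) continue;
          const double dp = slope / (M - 1);
          const double sn = std::sqrt(dp) * h * 0.5 *
            (F[(size_t)(i - 1) * nu + a] + F[(size_t)i * nu + b]);
          const double sd = dp * h * 0.5 *
            (N[(size_t)(i - 1) * nu + a] + N[(size_t)i * nu + b]);
          const double cand = pv + sn - lam * sd;
          if (cand > best) { best = cand; bk = a; }
        }
        val[(size_t)i * nu + b] = best;
        pred[(size_t)i * nu + b] = bk;
      }
    }
    if (val[(size_t)(M - 1) * nu + c] <= -1e29) break;
    choice[M - 1] = c;                       // end offset pinned at 0
    for (int i = M - 1; i > 0; --i)
      choice[i - 1] = pred[(size_t)i * nu + choice[i]];
    double num1 = 0.0, den1 = 0.0;
    for (int i = 0; i < M - 1; ++i) {
      const double dp = ((pos[i + 1] + off[choice[i + 1]]) -
                         (pos[i] + off[choice[i]])) / (M - 1);
      if (dp <= 0) continue;
      num1 += std::sqrt(dp) * h * 0.5 *
              (F[(size_t)i * nu + choice[i]] +
               F[(size_t)(i + 1) * nu + choice[i + 1]]);
      den1 += dp * h * 0.5 *
              (N[(size_t)i * nu + choice[i]] +
               N[(size_t)(i + 1) * nu + choice[i + 1]]);
    }
    const double nip1 = num1 / std::sqrt(den1);
    if (nip1 > best_nip) {
      for (int i = 0; i < M; ++i) pos[i] += off[choice[i]];
      best_nip = nip1;
      for (int i = 0; i < M; ++i) for (int a = 0; a < nu; ++a) {
        const double p = pos[i] + off[a];
        const double x = q_interp(q2, p, 0), y = q_interp(q2, p, 1);
        F[(size_t)i * nu + a] = q1(i, 0) * x + q1(i, 1) * y;
        N[(size_t)i * nu + a] = x * x + y * y;
      }
      num0 = num1; den0 = den1;
    } else break;
  }
  NumericVector g(M);
  for (int i = 0; i < M; ++i) g[i] = pos[i] / (M - 1);
  return List::create(_["gamma"] = g, _["ip"] = best_nip);
}

// Joint alignment of two closed SRVF curves (M x 2, no duplicated endpoint):
// searches every `stride`-th cyclic seed of q2; for each seed alternates
// rotation (2D Procrustes) and DP reparametrization `rot_iters` times.
// Returns the best seed, rotation, gamma (on the extended M+1 grid) and the
// inner product it achieves.
// [[Rcpp::export]]
List cpp_align_closed(const NumericMatrix q1, const NumericMatrix q2,
                      const int stride, const int rot_iters,
                      const bool do_rotation, const IntegerMatrix nbrs,
                      const int top = 0, const int refine_passes = 0) {
  const int M = q1.nrow();
  if (q2.nrow() != M) stop("grid size mismatch");
  NumericMatrix q1e = extend_closed(q1, 0);
  const int Me = M + 1;
  NumericVector w(Me);
  for (int i = 0; i < Me; ++i) w[i] = (i == 0 || i == Me - 1) ? 0.5 / M : 1.0 / M;

  // candidate seeds: every stride-th start vertex; optionally keep only the
  // `top` best under a cheap rotation-only (no reparametrization) score
  std::vector<int> seeds;
  for (int seed = 0; seed < M; seed += stride) seeds.push_back(seed);
  if (top > 0 && (int)seeds.size() > top) {
    std::vector<std::pair<double, int> > scored;
    for (size_t si = 0; si < seeds.size(); ++si) {
      const int seed = seeds[si];
      double C = 0.0, S = 0.0, plain = 0.0;
      for (int i = 0; i < M; ++i) {
        const int j = (i + seed) % M;
        C += q1(i, 0) * q2(j, 0) + q1(i, 1) * q2(j, 1);
        S += q1(i, 1) * q2(j, 0) - q1(i, 0) * q2(j, 1);
      }
      plain = C / M;
      const double score = do_rotation ? std::sqrt(C * C + S * S) / M : plain;
      scored.push_back(std::make_pair(-score, seed));
    }
    std::sort(scored.begin(), scored.end());
    seeds.clear();
    for (int si = 0; si < top; ++si) seeds.push_back(scored[si].second);
  }

  double best_ip = -2.0;
  int best_seed = 0;
  NumericVector best_gamma(Me);
  NumericMatrix best_R = NumericMatrix::diag(2, 1.0);

  for (size_t si = 0; si < seeds.size(); ++si) {
    const int seed = seeds[si];
    NumericMatrix q2e = extend_closed(q2, seed);
    // identity gamma
    NumericVector gamma(Me);
    for (int i = 0; i < Me; ++i) gamma[i] = (double)i / M;
    NumericMatrix R = NumericMatrix::diag(2, 1.0);
    double ip = -2.0;
    for (int it = 0; it < rot_iters; ++it) {
      if (do_rotation) {
        NumericMatrix qw = cpp_warp_q(q2e, gamma);
        R = cpp_opt_rotation(q1e, qw, w);
      }
      NumericMatrix q2r = rotate_q(q2e, R);
      List m = cpp_dp_match(q1e, q2r, nbrs);
      gamma = m["gamma"];
      ip = as<double>(m["ip"]);
    }
    if (refine_passes > 0) {
      NumericMatrix q2r = rotate_q(q2e, R);
      List rr = cpp_refine_gamma(q1e, q2r, gamma, std::min(refine_passes, 2));
      gamma = rr["gamma"];
      ip = as<double>(rr["ip"]);
    }
    if (ip > best_ip) {
      best_ip = ip;
      best_seed = seed;
      best_gamma = clone(gamma);
      best_R = clone(R);
    }
  }

  double best_delta = 0.0;
  if (refine_passes > 0) {
    // Continuous start-point refinement. An integer seed plus an
    // endpoint-pinned gamma cannot represent a warp whose optimal cyclic
    // offset falls between vertices: the DP then compensates by distorting
    // gamma and gets stuck in that basin. Candidate sub-vertex offsets
    // delta therefore get their own rotation/DP/refinement runs on the
    // cyclically resampled curve, and the winner is polished by
    // golden-section rounds on delta alternating with gamma refinement
    // and rotation updates (each accepted only when the normalized inner
    // product improves).
    // effort scales with refine_passes: light settings for bulk distance
    // matrices, full settings for single-pair accuracy
    const bool deep = refine_passes >= 5;
    const double cand_all[9] = { 0.0, -1.0, -0.75, -0.5, -0.25,
                                 0.25, 0.5, 0.75, 1.0 };
    const double cand_lite[3] = { 0.0, -0.5, 0.5 };
    const double* cand = cand_all; (void)cand_lite;
    const int ncand = deep ? 9 : 0;   // the micro band below already covers
    const int nrounds = deep ? 8 : 0; // +/- half a vertex of cyclic shift
    NumericVector gamma = clone(best_gamma);

    for (int ci = 0; ci < ncand; ++ci) {
      const double delta = cand[ci];
      NumericMatrix q2d(M, 2);
      double nrm2 = 0.0;
      for (int j = 0; j < M; ++j) {
        q2d(j, 0) = q_interp_cyc(q2, j + best_seed + delta, 0);
        q2d(j, 1) = q_interp_cyc(q2, j + best_seed + delta, 1);
        nrm2 += q2d(j, 0) * q2d(j, 0) + q2d(j, 1) * q2d(j, 1);
      }
      const double nrm = std::sqrt(nrm2 / M);
      for (int j = 0; j < M; ++j) { q2d(j, 0) /= nrm; q2d(j, 1) /= nrm; }
      NumericMatrix q2e = extend_closed(q2d, 0);
      NumericVector g(Me);
      for (int i = 0; i < Me; ++i) g[i] = (double)i / M;
      NumericMatrix Rd = NumericMatrix::diag(2, 1.0);
      for (int it = 0; it < rot_iters; ++it) {
        if (do_rotation) {
          NumericMatrix qw = cpp_warp_q(q2e, g);
          Rd = cpp_opt_rotation(q1e, qw, w);
        }
        NumericMatrix q2r = rotate_q(q2e, Rd);
        List m = cpp_dp_match(q1e, q2r, nbrs);
        g = m["gamma"];
      }
      NumericMatrix q2r = rotate_q(q2e, Rd);
      List rr = cpp_refine_gamma(q1e, q2r, g, refine_passes);
      const double ip = as<double>(rr["ip"]);
      if (ip > best_ip) {
        best_ip = ip;
        best_delta = delta;
        best_R = clone(Rd);
        NumericVector gref = rr["gamma"];
        gamma = clone(gref);
      }
    }

    // polish rounds: golden-section on delta, gamma refinement, rotation
    const int pad = 4;
    const int n2 = M + 2 * pad + 1;
    const double span = n2 - 1;
    const double h = 1.0 / M;
    const double gr = 0.3819660112501051;
    NumericMatrix q2m(n2, 2);
    for (int outer = 0; outer < nrounds; ++outer) {
      for (int i = 0; i < n2; ++i) {
        const int src = ((i - pad + best_seed) % M + M) % M;
        const double x = q2(src, 0), y = q2(src, 1);
        q2m(i, 0) = best_R(0, 0) * x + best_R(0, 1) * y;
        q2m(i, 1) = best_R(1, 0) * x + best_R(1, 1) * y;
      }
      std::vector<double> slope(Me - 1);
      for (int i = 0; i < Me - 1; ++i)
        slope[i] = (gamma[i + 1] - gamma[i]) / h;
      struct EvalD {
        const NumericMatrix &q1e, &q2m; const NumericVector &gamma;
        const std::vector<double>& slope; int Me, M, pad; double h;
        double operator()(double d) {
          double num = 0.0, den = 0.0, fprev = 0.0, nprev = 0.0;
          for (int i = 0; i < Me; ++i) {
            const double pos = gamma[i] * M + pad + d;
            const double x = q_interp(q2m, pos, 0), y = q_interp(q2m, pos, 1);
            const double f = q1e(i, 0) * x + q1e(i, 1) * y,
                         nn = x * x + y * y;
            if (i > 0 && slope[i - 1] > 0) {
              num += std::sqrt(slope[i - 1]) * h * 0.5 * (fprev + f);
              den += slope[i - 1] * h * 0.5 * (nprev + nn);
            }
            fprev = f; nprev = nn;
          }
          return num / std::sqrt(den);
        }
      } nipd = { q1e, q2m, gamma, slope, Me, M, pad, h };
      double lo = best_delta - 0.3, hi = best_delta + 0.3;
      double x1 = lo + gr * (hi - lo), x2 = hi - gr * (hi - lo);
      double f1 = nipd(x1), f2 = nipd(x2);
      for (int it = 0; it < 20; ++it) {
        if (f1 > f2) { hi = x2; x2 = x1; f2 = f1;
          x1 = lo + gr * (hi - lo); f1 = nipd(x1);
        } else { lo = x1; x1 = x2; f1 = f2;
          x2 = hi - gr * (hi - lo); f2 = nipd(x2);
        }
      }
      const double dcand = (f1 > f2) ? x1 : x2;
      const double duse = (nipd(dcand) > nipd(best_delta)) ? dcand : best_delta;
      NumericVector gg(Me);
      for (int i = 0; i < Me; ++i)
        gg[i] = (gamma[i] * M + pad + duse) / span;
      List rr = cpp_refine_gamma(q1e, q2m, gg, refine_passes);
      const double ipr = as<double>(rr["ip"]);
      if (ipr > best_ip) {
        best_ip = ipr;
        best_delta = duse;
        NumericVector ggr = rr["gamma"];
        for (int i = 0; i < Me; ++i)
          gamma[i] = (ggr[i] * span - pad - duse) / M;
      }
      // rotation update against the current warp (accepted via the next
      // round's refinement; skip on the final round so the returned
      // rotation matches the returned gamma)
      if (do_rotation && outer < nrounds - 1) {
        NumericVector positions(Me);
        for (int i = 0; i < Me; ++i)
          positions[i] = gamma[i] * M + best_seed + best_delta;
        NumericMatrix qw = cpp_warp_closed(q2, positions,
                                           NumericMatrix::diag(2, 1.0));
        NumericMatrix Rn = cpp_opt_rotation(q1e, qw, w);
        // accept only if it does not hurt the normalized inner product
        double num = 0.0, den = 0.0, fprev = 0.0, nprev = 0.0;
        for (int i = 0; i < Me; ++i) {
          const double x0 = qw(i, 0), y0 = qw(i, 1);
          const double x = Rn(0, 0) * x0 + Rn(0, 1) * y0,
                       y = Rn(1, 0) * x0 + Rn(1, 1) * y0;
          const double f = q1e(i, 0) * x + q1e(i, 1) * y,
                       nn = x * x + y * y;
          if (i > 0) {
            num += h * 0.5 * (fprev + f);
            den += h * 0.5 * (nprev + nn);
          }
          fprev = f; nprev = nn;
        }
        if (num / std::sqrt(den) > best_ip) best_R = Rn;
      }
    }
    // banded micro-DP over node positions: exact within a shrinking band
    {
      std::vector<double> pos(Me);
      for (int i = 0; i < Me; ++i)
        pos[i] = gamma[i] * M + best_seed + best_delta;
      double nip = best_ip;
      const double radii[3] = { 0.5, 0.2, 0.08 };
      for (int rr = 0; rr < 3; ++rr)
        nip = micro_refine_closed(q1e, q2, best_R, pos, radii[rr], 11);
      if (do_rotation) {
        NumericVector pv(Me);
        for (int i = 0; i < Me; ++i) pv[i] = pos[i];
        NumericMatrix qw = cpp_warp_closed(q2, pv, best_R);
        NumericMatrix Rn = cpp_opt_rotation(q1e, qw, w);
        NumericMatrix Rc(2, 2);   // compose: Rn acts after best_R
        Rc(0, 0) = Rn(0, 0) * best_R(0, 0) + Rn(0, 1) * best_R(1, 0);
        Rc(0, 1) = Rn(0, 0) * best_R(0, 1) + Rn(0, 1) * best_R(1, 1);
        Rc(1, 0) = Rn(1, 0) * best_R(0, 0) + Rn(1, 1) * best_R(1, 0);
        Rc(1, 1) = Rn(1, 0) * best_R(0, 1) + Rn(1, 1) * best_R(1, 1);
        std::vector<double> pos2 = pos;
        double nip2 = micro_refine_closed(q1e, q2, Rc, pos2, 0.08, 11);
        if (nip2 > nip) { nip = nip2; pos = pos2; best_R = Rc; }
      }
      if (nip > best_ip) {
        best_ip = nip;
        best_delta = pos[0] - best_seed;
        for (int i = 0; i < Me; ++i)
          best_gamma[i] = (pos[i] - pos[0]) / M;
      } else {
        best_gamma = gamma;
      }
    }
  }

  NumericVector positions(Me);
  for (int i = 0; i < Me; ++i)
    positions[i] = best_gamma[i] * M + best_seed + best_delta;
  return List::create(_["ip"] = best_ip, _["seed"] = best_seed,
                      _["rotation"] = best_R, _["gamma"] = best_gamma,
                      _["delta"] = best_delta, _["positions"] = positions);
}
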