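#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Fixed-step RK4 integration of a neural-mass network.
//
// The network is described by J second-order synaptic transforms (alpha
// kernels), P populations and K vesicle pools.  State layout:
//   [y_0, z_0, y_1, z_1, ..., y_{J-1}, z_{J-1}, A_0, ..., A_{K-1}]
// where (y_j, z_j) are a post-synaptic potential contribution and its time
// derivative, and A_k is the readily-releasable pool occupancy of a
// habituating connection.
//
// Membrane potentials are linear read-outs of the y_j (o_* arrays), firing
// rates follow the origin-crossing sigmoid, and each transform is driven by
// C * W * S(u_source) terms (d_* arrays, W = pool occupancy or 1) plus an
// optional share of the extrinsic gamma-shaped pulse train.

// [[Rcpp::export]]
List simulate_cpp(NumericVector H, NumericVector tau, NumericVector gain,
                  IntegerVector d_tr, IntegerVector d_src, NumericVector d_C,
                  IntegerVector d_pool,
                  IntegerVector o_pop, IntegerVector o_tr, NumericVector o_w,
                  IntegerVector p_src, NumericVector n1, NumericVector n2,
                  double e0, double r, double u0, double Qmax,
                  double in_w, int in_n, double P0, NumericVector onsets,
                  int n_pop, double t0, double t1, double dt) {
  const int J = H.size();
  const int K = p_src.size();
  const int D = d_tr.size();
  const int O = o_pop.size();
  const int P = n_pop;
  const int nd = 2 * J + K;

  const double S0 = 2.0 * e0 / (1.0 + std::exp(r * u0));
  // beyond this lag a pulse is < 1e-12 of its peak; truncated for speed
  const double cutoff = in_w * (in_n + 50.0);

  std::vector<double> onv(onsets.begin(), onsets.end());

  auto input_rate = [&](double t) -> double {
    double s = 0.0;
    for (size_t i = 0; i < onv.size(); ++i) {
      double x = t - onv[i];
      if (x <= 0.0 || x > cutoff) continue;
      double xw = x / in_w;
      s += std::pow(xw, (double)in_n) * std::exp(-xw);
    }
    return P0 * s;
  };

  std::vector<double> u(P), S(P), q(J);

  auto deriv = [&](double t, const std::vector<double>& st,
                   std::vector<double>& dst) {
    std::fill(u.begin(), u.end(), 0.0);
    for (int i = 0; i < O; ++i) u[o_pop[i]] += o_w[i] * st[2 * o_tr[i]];
    for (int p = 0; p < P; ++p)
      S[p] = 2.0 * e0 / (1.0 + std::exp(r * (u0 - u[p]))) - S0;
    const double pt = input_rate(t);
    for (int j = 0; j < J; ++j) q[j] = gain[j] * pt;
    for (int i = 0; i < D; ++i) {
      const double w = (d_pool[i] >= 0) ? st[2 * J + d_pool[i]] : 1.0;
      q[d_tr[i]] += d_C[i] * w * S[d_src[i]];
    }
    for (int j = 0; j < J; ++j) {
      dst[2 * j] = st[2 * j + 1];
      dst[2 * j + 1] = (H[j] / tau[j]) * q[j] -
                       2.0 * st[2 * j + 1] / tau[j] -
                       st[2 * j] / (tau[j] * tau[j]);
    }
    for (int k = 0; k < K; ++k) {
      const double Q = S[p_src[k]];
      const double A = st[2 * J + k];
      double dA = n2[k] * (1.0 - A);
      if (Q > 0.0) dA -= n1[k] * (Q / Qmax) * A;
      dst[2 * J + k] = dA;
    }
  };

  const int ns = (int)std::llround((t1 - t0) / dt);
  if (ns < 1) stop("t_span must cover at least one integration step");
  const int nt = ns + 1;

  NumericVector t_out(nt);
  NumericMatrix U_out(nt, P), A_out(nt, K), Y_out(nt, J);

  std::vector<double> st(nd, 0.0), stmp(nd), k1(nd), k2(nd), k3(nd), k4(nd);
  for (int k = 0; k < K; ++k) st[2 * J + k] = 1.0;  // pools start replete

  auto record = [&](int row, double t) {
    t_out[row] = t;
    std::fill(u.begin(), u.end(), 0.0);
    for (int i = 0; i < O; ++i) u[o_pop[i]] += o_w[i] * st[2 * o_tr[i]];
    for (int p = 0; p < P; ++p) U_out(row, p) = u[p];
    for (int k = 0; k < K; ++k) A_out(row, k) = st[2 * J + k];
    for (int j = 0; j < J; ++j) Y_out(row, j) = st[2 * j];
  };

  record(0, t0);
  for (int s = 0; s < ns; ++s) {
    const double t = t0 + s * dt;
    deriv(t, st, k1);
    for (int i = 0; i < nd; ++i) stmp[i] = st[i] + 0.5 * dt * k1[i];
    deriv(t + 0.5 * dt, stmp, k2);
    for (int i = 0; i < nd; ++i) stmp[i] = st[i] + 0.5 * dt * k2[i];
    deriv(t + 0.5 * dt, stmp, k3);
    for (int i = 0; i < nd; ++i) stmp[i] = st[i] + dt * k3[i];
    deriv(t + dt, stmp, k4);
    for (int i = 0; i < nd; ++i)
      st[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < nd; ++i)
      if (!std::isfinite(st[i]))
        stop("state became non-finite at t = %f s", t + dt);
    record(s + 1, t + dt);
  }

  return List::create(_["t"] = t_out, _["U"] = U_out, _["A"] = A_out,
                      _["Y"] = Y_out);
}
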