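#include <Rcpp.h>
using namespace Rcpp;

// Mass-action right-hand side of the six-species bivalent binding network.
// Species order: R, P, C3, C4, CC, D. When clamp_P is set, free protein is
// held at zero (wash-out dissociation protocol).
static inline void rhs(const double* s, const double* k, bool clamp_P,
                       double* d) {
  const double kon3 = k[0], koff3 = k[1], kon4 = k[2], koff4 = k[3],
               kC3 = k[4], kC4 = k[5];
  const double R = s[0], P = clamp_P ? 0.0 : s[1], C3 = s[2], C4 = s[3],
               CC = s[4], D = s[5];

  const double v_on3 = kon3 * R * P, v_off3 = koff3 * C3;
  const double v_on4 = kon4 * R * P, v_off4 = koff4 * C4;
  const double v_c4 = kC4 * C3, v_o4 = koff4 * CC;
  const double v_c3 = kC3 * C4, v_o3 = koff3 * CC;
  const double v_d3 = kon4 * C3 * P, v_dr3 = koff4 * D;
  const double v_d4 = kon3 * C4 * P, v_dr4 = koff3 * D;

  // terms are paired per domain so that exchanging the KH3/KH4 labels
  // permutes only operands of commutative additions: the label-swap
  // symmetry then holds bit-exactly in floating point
  d[0] = (v_off3 - v_on3) + (v_off4 - v_on4);
  d[1] = clamp_P ? 0.0
                 : ((v_off3 - v_on3) + (v_off4 - v_on4)) +
                       ((v_dr3 - v_d3) + (v_dr4 - v_d4));
  d[2] = (v_on3 - v_off3) + (v_o4 - v_c4) + (v_dr3 - v_d3);
  d[3] = (v_on4 - v_off4) + (v_o3 - v_c3) + (v_dr4 - v_d4);
  d[4] = (v_c4 + v_c3) - (v_o4 + v_o3);
  d[5] = (v_d3 + v_d4) - (v_dr3 + v_dr4);
}

// Classical fixed-step RK4 over the network. stop_tol < 0 disables the
// equilibrium check; otherwise the relative derivative criterion
// max_i |dC_i/dt| * 1s / max(C_i, 1e-15) < stop_tol is evaluated at every
// stored step.
// [[Rcpp::export(name = ".rk4_core_cpp")]]
List rk4_core_cpp(NumericVector params, NumericVector init, double dt,
                  int n_steps, int store_every, bool clamp_P,
                  double stop_tol, double neg_floor) {
  const double* k = params.begin();
  double s[6], d[6], k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int i = 0; i < 6; ++i) s[i] = init[i];
  if (clamp_P) s[1] = 0.0;

  const int n_store = n_steps / store_every + 1;
  NumericMatrix out(n_store, 7);
  out(0, 0) = 0.0;
  for (int j = 0; j < 6; ++j) out(0, j + 1) = s[j];

  int row = 0;
  bool converged = false;
  const double half = dt / 2.0, sixth = dt / 6.0;

  int i = 1;
  for (; i <= n_steps; ++i) {
    rhs(s, k, clamp_P, k1);
    for (int j = 0; j < 6; ++j) tmp[j] = s[j] + half * k1[j];
    rhs(tmp, k, clamp_P, k2);
    for (int j = 0; j < 6; ++j) tmp[j] = s[j] + half * k2[j];
    rhs(tmp, k, clamp_P, k3);
    for (int j = 0; j < 6; ++j) tmp[j] = s[j] + dt * k3[j];
    rhs(tmp, k, clamp_P, k4);
    for (int j = 0; j < 6; ++j) {
      s[j] += sixth * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (s[j] < neg_floor) {
        stop("integration error: concentration %g M fell below the round-off floor at t = %g s",
             s[j], i * dt);
      }
      if (s[j] < 0.0) s[j] = 0.0;
    }

    if (i % store_every == 0) {
      ++row;
      out(row, 0) = i * dt;
      for (int j = 0; j < 6; ++j) out(row, j + 1) = s[j];
      if (stop_tol >= 0.0) {
        rhs(s, k, clamp_P, d);
        double worst = 0.0;
        for (int j = 0; j < 6; ++j) {
          double den = s[j] > 1e-15 ? s[j] : 1e-15;
          double rel = std::abs(d[j]) / den;
          if (rel > worst) worst = rel;
        }
        if (worst < stop_tol) {
          converged = true;
          break;
        }
      }
    }
  }

  rhs(s, k, clamp_P, d);
  NumericVector state(6), deriv(6);
  for (int j = 0; j < 6; ++j) {
    state[j] = s[j];
    deriv[j] = d[j];
  }
  return List::create(_["trajectory"] = out(Range(0, row), _),
                      _["state"] = state, _["deriv"] = deriv,
                      _["converged"] = converged,
                      _["t_final"] = out(row, 0));
}
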