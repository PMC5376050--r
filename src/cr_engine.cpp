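// Compiled cores: exact conditional-response transition-matrix assembly,
// batch evaluation of strategies over the simplex, and the per-round
// agent-based simulation loop. All randomness uses R's RNG (unif_rand),
// so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// binomial coefficient table up to n
std::vector<std::vector<double>> binom_table(int n) {
  std::vector<std::vector<double>> C(n + 1, std::vector<double>(n + 1, 0.0));
  for (int i = 0; i <= n; ++i) {
    C[i][0] = 1.0;
    for (int j = 1; j <= i; ++j) {
      C[i][j] = C[i - 1][j - 1] + (j <= i - 1 ? C[i - 1][j] : 0.0);
    }
  }
  return C;
}

// convolve one multinomial group (k players, destination probs p[3]) into
// the (N+1)x(N+1) grid over (n_R', n_P'); grid and work are flattened
// row-major: idx = r * (N+1) + p.
void convolve_group(std::vector<double>& grid, std::vector<double>& work,
                    int k, const double* p, int N,
                    const std::vector<std::vector<double>>& C) {
  if (k == 0) return;
  const int W = N + 1;
  std::fill(work.begin(), work.end(), 0.0);
  std::vector<double> pow0(k + 1), pow1(k + 1), pow2(k + 1);
  pow0[0] = pow1[0] = pow2[0] = 1.0;
  for (int t = 1; t <= k; ++t) {
    pow0[t] = pow0[t - 1] * p[0];
    pow1[t] = pow1[t - 1] * p[1];
    pow2[t] = pow2[t - 1] * p[2];
  }
  for (int i = 0; i <= k; ++i) {
    for (int j = 0; j <= k - i; ++j) {
      double pr = C[k][i] * C[k - i][j] * pow0[i] * pow1[j] * pow2[k - i - j];
      if (pr == 0.0) continue;
      for (int r = 0; r + i < W; ++r) {
        const double* src = &grid[r * W];
        double* dst = &work[(r + i) * W + j];
        for (int q = 0; q + j < W; ++q) {
          if (src[q] != 0.0) dst[q] += pr * src[q];
        }
      }
    }
  }
  grid.swap(work);
}

// destination probabilities for the 9 (action x outcome) groups
// gamma: 3x3, rows W,T,L; cols minus, stay, plus
void destination_probs(const double* gamma, double dest[9][3]) {
  for (int q = 0; q < 3; ++q) {
    for (int o = 0; o < 3; ++o) {
      int g = q * 3 + o;
      for (int d = 0; d < 3; ++d) dest[g][d] = 0.0;
      // gamma is column-major 3x3: [o + 3*col]
      dest[g][q] += gamma[o + 3 * 1];            // stay
      dest[g][(q + 1) % 3] += gamma[o + 3 * 2];  // plus = counter-clockwise
      dest[g][(q + 2) % 3] += gamma[o + 3 * 0];  // minus = clockwise
    }
  }
}

// assemble the full K x K transition matrix for one gamma
void build_matrix(const double* gamma, int N, int K,
                  const IntegerVector& comp_state,
                  const NumericVector& comp_prob,
                  const IntegerMatrix& comp_groups,
                  const IntegerMatrix& states,
                  const std::vector<std::vector<double>>& C,
                  const std::vector<int>& state_of_grid,
                  double* M /* K x K, column-major */) {
  const int W = N + 1;
  double dest[9][3];
  destination_probs(gamma, dest);
  std::vector<double> grid(W * W), work(W * W);
  std::fill(M, M + (size_t)K * K, 0.0);
  const int ncomp = comp_state.size();
  for (int c = 0; c < ncomp; ++c) {
    int s = comp_state[c] - 1; // row (from-state)
    double pc = comp_prob[c];
    std::fill(grid.begin(), grid.end(), 0.0);
    grid[0] = 1.0;
    for (int g = 0; g < 9; ++g) {
      convolve_group(grid, work, comp_groups(c, g), dest[g], N, C);
    }
    for (int r = 0; r < W; ++r) {
      for (int p = 0; p + r < W; ++p) {
        double v = grid[r * W + p];
        if (v == 0.0) continue;
        int sp = state_of_grid[r * W + p];
        M[(size_t)sp * K + s] += pc * v; // column-major M[s, sp]
      }
    }
  }
}

std::vector<int> grid_lookup(const IntegerMatrix& states, int N, int K) {
  const int W = N + 1;
  std::vector<int> look(W * W, -1);
  for (int i = 0; i < K; ++i) {
    look[states(i, 0) * W + states(i, 1)] = i;
  }
  return look;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix build_cr_matrix_cpp(NumericMatrix gamma, int N, int K,
                                  IntegerVector comp_state,
                                  NumericVector comp_prob,
                                  IntegerMatrix comp_groups,
                                  IntegerMatrix states) {
  auto C = binom_table(N);
  auto look = grid_lookup(states, N, K);
  NumericMatrix M(K, K);
  build_matrix(REAL(gamma), N, K, comp_state, comp_prob, comp_groups,
               states, C, look, REAL(M));
  return M;
}

// Evaluate many CR strategies: for each row (W-,W+,T-,T+,L-,L+) build the
// transition matrix, solve the stationary distribution, and return
// (tau_cr, f_cr, ok). ok = 0 flags samples whose stationary solve failed
// (reducible/periodic corner cases); their tau/f are NA.
// [[Rcpp::export]]
NumericMatrix eval_gammas_cpp(NumericMatrix gammas, int N, int K,
                              IntegerVector comp_state,
                              NumericVector comp_prob,
                              IntegerMatrix comp_groups,
                              IntegerMatrix states,
                              NumericMatrix theta,
                              NumericVector tie_frac) {
  auto C = binom_table(N);
  auto look = grid_lookup(states, N, K);
  const int n = gammas.nrow();
  NumericMatrix out(n, 3);
  arma::mat M(K, K), A(K, K);
  arma::vec b(K), pi(K);
  arma::mat Theta(theta.begin(), K, K, false);
  arma::vec tf(tie_frac.begin(), K, false);
  double gm[9];
  for (int i = 0; i < n; ++i) {
    // gamma matrix column-major: rows W,T,L x cols minus, stay, plus
    gm[0] = gammas(i, 0); gm[1] = gammas(i, 2); gm[2] = gammas(i, 4); // minus
    gm[3] = 1.0 - gammas(i, 0) - gammas(i, 1);                        // stay W
    gm[4] = 1.0 - gammas(i, 2) - gammas(i, 3);                        // stay T
    gm[5] = 1.0 - gammas(i, 4) - gammas(i, 5);                        // stay L
    gm[6] = gammas(i, 1); gm[7] = gammas(i, 3); gm[8] = gammas(i, 5); // plus
    build_matrix(gm, N, K, comp_state, comp_prob, comp_groups, states,
                 C, look, M.memptr());
    A = M.t() - arma::eye(K, K);
    A.row(K - 1).ones();
    b.zeros();
    b(K - 1) = 1.0;
    bool ok = arma::solve(pi, A, b, arma::solve_opts::no_approx);
    if (ok) {
      double resid = arma::abs(M.t() * pi - pi).max();
      if (resid > 1e-10 || pi.min() < -1e-10) ok = false;
    }
    if (!ok) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = 0.0;
      continue;
    }
    double tau = arma::dot(pi, tf);
    double f = arma::dot(pi, arma::sum(M % Theta, 1)) / (2.0 * M_PI);
    out(i, 0) = tau;
    out(i, 1) = f;
    out(i, 2) = 1.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Agent-based simulation core.
//
// policy codes: 0 = CR (params row: W-,W0,W+,T-,T0,T+,L-,L0,L+),
//               1 = NE mixed (uniform iid),
//               2 = independent shift (params row: R-,R0,R+,P-,P0,P+,S-,S0,S+),
//               3 = fixed action (params(i, 0) = action code 0/1/2).
// Returns 1-based opponent ids and 0/1/2 action codes per (round, player).
// [[Rcpp::export]]
List sim_core_cpp(IntegerVector policy, NumericMatrix params, int N, int rounds) {
  IntegerMatrix action(rounds, N), opp(rounds, N);
  std::vector<int> perm(N), cur(N), prev_outcome(N); // outcome 0=W,1=T,2=L
  RNGScope scope;

  // round-1 actions: fixed policies play their action, everyone else uniform
  for (int i = 0; i < N; ++i) {
    if (policy[i] == 3) {
      cur[i] = (int)params(i, 0);
    } else {
      cur[i] = (int)std::floor(unif_rand() * 3.0);
      if (cur[i] == 3) cur[i] = 2;
    }
  }

  for (int t = 0; t < rounds; ++t) {
    // uniform perfect matching: shuffle then pair consecutive entries
    for (int i = 0; i < N; ++i) perm[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int k = 0; k < N / 2; ++k) {
      int u = perm[2 * k], v = perm[2 * k + 1];
      opp(t, u) = v + 1;
      opp(t, v) = u + 1;
    }
    for (int i = 0; i < N; ++i) action(t, i) = cur[i];
    // outcomes: (mine - theirs) mod 3 -> 0 tie, 1 win, 2 lose
    for (int i = 0; i < N; ++i) {
      int d = (cur[i] - cur[opp(t, i) - 1] + 3) % 3;
      prev_outcome[i] = (d == 0) ? 1 : (d == 1 ? 0 : 2); // 0=W,1=T,2=L
    }
    if (t == rounds - 1) break;
    // next-round decisions
    for (int i = 0; i < N; ++i) {
      switch (policy[i]) {
      case 0: { // conditional response on own previous outcome
        int o = prev_outcome[i];
        double u = unif_rand();
        double pm = params(i, 3 * o), p0 = params(i, 3 * o + 1);
        int delta = (u < pm) ? 2 : (u < pm + p0 ? 0 : 1);
        cur[i] = (cur[i] + delta) % 3;
        break;
      }
      case 1: { // NE mixed
        int a = (int)std::floor(unif_rand() * 3.0);
        cur[i] = (a == 3) ? 2 : a;
        break;
      }
      case 2: { // independent shift conditioned on own current action
        int q = cur[i];
        double u = unif_rand();
        double pm = params(i, 3 * q), p0 = params(i, 3 * q + 1);
        int delta = (u < pm) ? 2 : (u < pm + p0 ? 0 : 1);
        cur[i] = (cur[i] + delta) % 3;
        break;
      }
      default: // fixed action
        break;
      }
    }
  }
  return List::create(_["action"] = action, _["opponent"] = opp);
}
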