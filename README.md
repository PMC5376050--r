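# rpscycle

Social cycling and conditional responses in finite-population
Rock–Paper–Scissors.

## The problem

Populations of people playing iterated Rock–Paper–Scissors under random
pairwise matching look, player by player, almost perfectly Nash: each
individual's long-run action frequencies are close to (1/3, 1/3, 1/3).
Yet at the *population* level the social state
**s**(t) = (n_R(t), n_P(t), n_S(t)) — the occupancy triple counting how
many of the N players hold each action — drifts persistently
counter-clockwise around the centroid **c**₀ = (N/3, N/3, N/3) of the
triangular state plane: R-rich states give way to P-rich ones, then to
S-rich ones, and back. `rpscycle` provides the statistic that detects
this collective cycling, the microscopic model that explains it, and the
simulation and estimation machinery to connect the two. It is aimed at
researchers in behavioural game theory, evolutionary dynamics, and
non-equilibrium statistical physics who work with discrete-round game
trajectories.

## The model

**Cycling statistic.** Each transition **s**(t) → **s**(t+1) gets a
rotation angle θ(t) ∈ (−π, π) at the centroid: zero if the transition is
not a rotation around **c**₀ (no movement, an endpoint at the centroid,
or collinearity), otherwise magnitude acos(u·v/|u||v|) with
u = **s**(t) − **c**₀, v = **s**(t+1) − **c**₀ and sign from the triple
product (u × v)·(1,1,1); positive means counter-clockwise
(R → P → S → R). The net cycle count over [t₀, t₁] is
C = Σθ/2π and the cycling frequency is f = C/(t₁ − t₀) cycles per round.

**Conditional response (CR) strategies.** A CR player looks only at her
own last outcome O ∈ {W, T, L} and shifts her action clockwise with
probability O₋, counter-clockwise with probability O₊, or repeats it
with O₀ = 1 − O₋ − O₊. Six probabilities
Γ = {W₋, W₊; T₋, T₊; L₋, L₊} define the strategy; win-stay lose-shift is
a corner of the family.

**Exact finite-population chain.** Under uniform random matching of the
N players into N/2 pairs, the pair-type composition
(n_rr, n_pp, n_ss, n_rp, n_ps, n_sr) of a round has an exact
hypergeometric-type law with normalisation (N−1)!!. Conditioning on the
composition fixes every player's outcome, and independent CR responses
convolve into an exact transition matrix M[**s**′|**s**] over the
(N+1)(N+2)/2 social states. From its stationary distribution π* the
package computes:

- the steady-state cycling frequency
  f_cr = (1/2π) Σ π*(s) M[s′|s] θ(s→s′),
- the tie fraction τ_cr = Σ π*(s)[Σ_q n_q(n_q−1)]/(N(N−1)),
- the expected payoff per round g_cr = g₀ + (a − 2)(1/3 − τ_cr)/2,
  where a > 1 is the winning payoff (tie 1, loss 0) and g₀ = (1+a)/3 is
  the Nash mixed-strategy benchmark.

The independent-decision null model — next action depends only on one's
own current action — is built the same way and predicts near-zero
cycling, which is the contrast that makes win–lose–tie conditioning the
explanation of the observed collective motion.

## Worked example

```r
library(rpscycle)

# a win-stay lose-shift-like CR strategy
gamma <- cr_strategy(0.001, 0.004, 0.063, 0.791, 0.989, 0.001)
fit <- cr_model(gamma, N = 6, a = 4)
fit
#> <cr_model> N = 6, a = 4
#>   cycling frequency f_cr  = +0.1890 cycles/round
#>   tie fraction      tau   = 0.2662
#>   expected payoff   g_cr  = 1.7338  (Nash benchmark g0 = 1.6667)
#>   payoff gap        g_cr - g0 = +0.0336 * (a - 2)
```

A homogeneous population of such players cycles counter-clockwise at
0.189 cycles per round in the steady state, ties 26.6% of its pairs,
and each player earns 0.0336·(a − 2) per round more than the Nash
benchmark. Simulating one 300-round session and measuring its cycling
frequency with the trajectory statistic:

```r
traj <- simulate_session(session_config(N = 6, rounds = 300, a = 4,
                                        policies = policy_cr(gamma), seed = 1))
session_cycling(traj)
#> # A tibble: 1 × 5
#>      t0    t1 n_transitions net_cycles frequency
#>   <int> <int>         <int>      <dbl>     <dbl>
#> 1     1   300           299       67.4     0.226
```

A single 300-round session scatters around the exact value; batches
(`batch_sessions()`) recover it. The packaged table of 59 per-session
empirical cycling frequencies feeds the population pipeline:

```r
summarize_populations(session_frequencies())
#> # A tibble: 5 × 5
#>       a   n_s     mu  sigma   delta
#>   <dbl> <int>  <dbl>  <dbl>   <dbl>
#> 1   1.1    11 0.0308 0.0188 0.00566
#> 2   2      12 0.027  0.0286 0.00827
#> 3   4      12 0.0312 0.0263 0.00759
#> 4   9      12 0.0221 0.0275 0.00793
#> 5 100      12 0.0175 0.0254 0.00732
```

Every payoff group cycles significantly (`test_positive_frequency()`,
exact one-sided signed-rank: p = 0.0034 for the a = 2 group), and the
correlation of frequency with the payoff parameter is not significant
(`rank_correlation()`).

A command-line interface wrapping these functions ships in
`inst/cli/rpscycle.R` (subcommands `exact`, `simulate`, `analyze`,
`summarize`, `sample`).

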