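---
title: "Social cycling and conditional responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social cycling and conditional responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpscycle)
```

## The system

Iterated Rock–Paper–Scissors in a finite population of even size $N$,
played in discrete rounds under the random pairwise-matching protocol:
each round the $N$ players are partitioned uniformly at random into
$N/2$ pairs, each pair plays once, and each player sees only her own
action, her opponent's action, and her own payoff. The winning action
earns $a > 1$, a tie earns 1, a loss earns 0. The evolutionarily
neutral point is $a = 2$: the Nash mixed strategy (play each action
with probability $1/3$) is evolutionarily unstable below it and stable
above it, and its benchmark payoff is $g_0 = (1 + a)/3$ per round.

The population's **social state** is the occupancy triple
$\mathbf{s} = (n_R, n_P, n_S)$, a point on the triangular lattice plane
$n_R + n_P + n_S = N$, which has $(N+1)(N+2)/2$ points. States are
enumerated in a fixed canonical order — descending $n_R$, then
descending $n_P$ — which is the index used by all matrices in the
package.

## The cycling statistic

A transition $\mathbf{s}(t) \to \mathbf{s}(t+1)$ receives a rotation
angle $\theta(t)$ at the plane's centroid
$\mathbf{c}_0 = (N/3, N/3, N/3)$. With $u = \mathbf{s}(t) -
\mathbf{c}_0$ and $v = \mathbf{s}(t+1) - \mathbf{c}_0$:

* $\theta = 0$ when the transition is not a rotation around the
  centroid: $u = 0$ or $v = 0$ (an endpoint is the centroid), or $u$,
  $v$ collinear with it. Degeneracy is decided on the exact integer
  vectors $3\mathbf{s} - (N, N, N)$, so no floating-point tolerance
  enters the decision; in particular an exactly reversed step and a
  step through the centroid both count as non-rotations.
* otherwise $|\theta| = \arccos\!\big(u \cdot v / (|u||v|)\big) \in
  (0, \pi)$ and $\mathrm{sign}(\theta) = \mathrm{sign}\big((u \times v)
  \cdot (1,1,1)\big)$.

The sign convention makes transitions from $R$-rich toward $P$-rich
states positive, i.e. positive $\theta$ is counter-clockwise in the
$R \to P \to S$ orientation. Over an interval $[t_0, t_1]$ the net
cycle count is $C = \sum_t \theta(t) / 2\pi$ and the **cycling
frequency** is

$$ f_{t_0,t_1} = \frac{C}{t_1 - t_0}, $$

normalised by the number of *transitions*: a 300-round session has 299
transitions, so $f_{1,300} = C / 299$. We chose this normalisation
(over $t_1 - t_0 + 1$) because it is the only one under which
"frequency × elapsed transitions = cycles" holds identically, e.g. a
trajectory that winds the hexagon of permutations of $(3,2,1)$ once
every six transitions has $f = 1/6$ exactly. Closed loops that avoid
the centroid and collinearity yield integer $C$ (a winding number);
the test suite checks this against an independent `atan2`-based oracle.

## The conditional-response model

A **CR strategy** is the six-parameter rule
$\Gamma = \{W_-, W_+; T_-, T_+; L_-, L_+\}$: after outcome
$O \in \{W, T, L\}$ the player shifts clockwise with probability $O_-$,
counter-clockwise with $O_+$, and repeats her action with
$O_0 = 1 - O_- - O_+$. All six parameters are probabilities with
$O_- + O_+ \le 1$ per outcome; `cr_strategy()` enforces this.

For a homogeneous CR population the model is solved **exactly**:

1. *Pairing law.* Given $\mathbf{s}$, the pair-type composition
   $(n_{rr}, n_{pp}, n_{ss}, n_{rp}, n_{ps}, n_{sr})$ of a round has
   probability equal to the number of labeled perfect matchings
   realising it,
   $n_R!\,n_P!\,n_S! \big/ \big(2^{n_{rr}} n_{rr}!\, 2^{n_{pp}}
   n_{pp}!\, 2^{n_{ss}} n_{ss}!\, n_{rp}!\, n_{ps}!\, n_{sr}!\big)$,
   divided by $(N-1)!! = 1 \cdot 3 \cdots (N-1)$. The implementation is
   validated against exhaustive enumeration of all matchings (15 at
   $N = 6$, 105 at $N = 8$) to machine precision.
2. *Outcomes.* A composition fixes the per-action win/tie/lose counts
   through the dominance relations (R beats S, P beats R, S beats P).
3. *Responses.* Conditional on the composition, players respond
   independently, so the next-state law is the convolution of nine
   (action × outcome) multinomial groups. Averaging over compositions
   gives the row $M[\cdot\,|\,\mathbf{s}]$.

Two implementations of this assembly exist: a plain-R reference path
(`engine = "r"`) written for readability, and a compiled path
(`engine = "cpp"`, the default) used throughout; the suite asserts they
agree to $10^{-12}$. A third, structurally different route — the
agent-based simulator — is checked against the matrix by chi-square
tests (below).

The stationary distribution $\pi^*$ solves the dense linear system
$\pi^* M = \pi^*$, $\sum \pi^* = 1$ (one balance equation replaced by
normalisation), with residual required below $10^{-12}$. Before
solving, the chain is checked for irreducibility (strongly connected
components of the positive-entry digraph) and aperiodicity (gcd of BFS
level differences). Degenerate strategies at simplex corners — everyone
always stays, everyone shifts deterministically — produce reducible or
periodic chains; these raise errors naming the recurrent classes
rather than returning a time-average, because a silently averaged
answer would mask modelling errors while the strategies of interest
are all interior points.

Steady-state observables:

* cycling frequency $f_{cr} = \frac{1}{2\pi} \sum_{\mathbf{s},
  \mathbf{s}'} \pi^*(\mathbf{s}) M[\mathbf{s}'|\mathbf{s}]\,
  \theta_{\mathbf{s}\to\mathbf{s}'}$;
* tie fraction $\tau_{cr} = \sum_\mathbf{s} \pi^*(\mathbf{s})
  \frac{n_R(n_R-1) + n_P(n_P-1) + n_S(n_S-1)}{N(N-1)}$, which equals
  the expected fraction of tie pairs among the $N/2$ pairs (the suite
  cross-checks the identity against the pairing law);
* expected payoff $g_{cr} = g_0 + (a-2)\,(1/3 - \tau_{cr})/2$,
  equivalently $\tau_{cr} + (1 - \tau_{cr})\,a/2$, from per-pair payoff
  accounting: a tie pair pays $1 + 1$, a decided pair pays $a + 0$.
  Only $g_{cr}$ depends on $a$; $\pi^*$, $f_{cr}$, $\tau_{cr}$ depend
  on $(\Gamma, N)$ alone.

By the model's cyclic symmetry, $M$ and $\pi^*$ are invariant under the
relabeling $(n_R, n_P, n_S) \to (n_S, n_R, n_P)$ and each player's
stationary action marginal is exactly uniform — a CR population is
indistinguishable from Nash play at the level of individual action
frequencies, which is precisely why the cycling statistic is needed.
With uniform responses ($\Gamma$ all $1/3$) the model collapses to iid
uniform play: $\pi^*$ is the multinomial law, $f_{cr} = 0$,
$\tau_{cr} = 1/3$, $g_{cr} = g_0$; these limits are asserted at solver
tolerance.

The **independent-decision null model** (`independent_model_frequency()`)
replaces outcome-conditioning with action-conditioning: each player's
next action depends only on her current action through a
(stay, ccw, cw) triple. Built with the same convolution machinery, it
satisfies detailed balance whenever the triples are shift-symmetric and
yields near-zero frequencies even when fed profiles estimated from
strongly cycling CR data — the package's central contrast.

## The simulator (synthetic-data generator)

`simulate_session()` reproduces the laboratory protocol that motivates
the package: populations of $N = 6$, 300 rounds, a fixed winning payoff
$a \in \{1.1, 2, 4, 9, 100\}$, uniform random matching each round.
These are the generator's defaults; $N$, rounds, $a$ and the policy mix
are parameters. Four agent policies are available (CR, Nash-mixed,
independent-shift, fixed action), and policies may be heterogeneous
within a session — the exact engine assumes homogeneity, the simulator
does not.

Choices the protocol leaves open:

* *Round 1.* CR agents have no prior outcome; they (and all
  non-fixed policies) open uniformly at random. This matches the
  uniform stationary marginal and adds no free parameter.
* *Batches.* `batch_sessions()` derives one child seed per session from
  the master seed via a single `sample.int()` draw under
  `set.seed(master)`, giving reproducible, independent streams.
* *Payoffs are recorded* per round even though CR dynamics ignore $a$,
  so written trajectories remain sufficient for payoff analyses.

The generator emulates the protocol's structure, not human behaviour:
agents are stationary policy followers. Real players drift, learn
within a session, and differ from one another, so passing
parameter-recovery tests on synthetic data demonstrates estimator
correctness, not that laboratory data are CR-distributed. The
40-second decision window of the laboratory setting has no simulator
analogue and is assumed behaviourally irrelevant.

## Estimators and tests

`estimate_cr_parameters()` classifies each player transition by the
outcome at $t$ and the shift direction at $t+1$ and returns per-outcome
maximum-likelihood proportions with binomial standard errors;
`estimate_shift_profile()` does the same conditioned on the current
action. Cells with no events are reported as `NA` with a zero count,
never as silent zeros. On counts, the shift profile is exactly the
outcome-frequency-weighted mixture of the CR estimates — an identity
the suite asserts. Transitions use all consecutive round pairs (every
round of a complete trajectory has an outcome).

`summarize_populations()` reports per-group mean $\mu$, sample standard
deviation $\sigma$ ($n-1$ denominator) and SEM
$\delta = \sigma/\sqrt{n_s}$.

`test_positive_frequency()` is a one-sided signed-rank test of median
zero against median above zero. Ties in $|f|$ take average ranks, and
for $n \le 25$ the p-value is **exact**: the positive-rank sum is
compared with the full randomisation distribution over all $2^n$ sign
assignments, computed by dynamic programming over doubled ranks (so
average ranks stay integral). This is why the test is implemented here
rather than delegated to `stats::wilcox.test()`, which abandons
exactness in the presence of ties; the two agree closely on tie-free
data, and a two-sided p (twice the smaller tail) is reported alongside
the one-sided value.

`rank_correlation()` is Spearman's correlation with average ranks and
the two-sided t-approximation p-value
(`stats::cor.test(..., exact = FALSE)`). Session-level frequency
tables are analysed at their reporting precision; in particular the
group means of the packaged 59-session table are correlated with $a$
at three decimals, where the two groups sharing $\mu = 0.031$ are
genuine ties handled by average ranks.

## The strategy-simplex study

`sample_uniform_strategies()` draws each outcome triple
$(O_-, O_0, O_+)$ independently and uniformly from the 2-simplex (flat
Dirichlet, via normalised exponentials), so any single parameter has
marginal density $2(1-x)$ — a property the suite verifies by a
Kolmogorov–Smirnov test. `payoff_coefficient_report()` evaluates every
sample **exactly** with the Markov engine and accumulates the payoff
coefficient $(g_{cr} - g_0)/(a - 2) = (1/3 - \tau_{cr})/2 \in
[-1/3, 1/6]$, its mean, and a 200-bin histogram over the full range.
Most of the simplex underperforms the Nash benchmark (the mean
coefficient is negative), while the best sampled strategies approach
the $1/6$ bound with cycling frequencies that may be near zero,
strongly positive, or strongly negative — high payoff does not pin
down collective behaviour. Samples whose chain lacks a unique
stationary law (a measure-zero set under the flat simplex) are
excluded and counted in the report.

The study runs at $2 \times 10^4$ samples by default scale — enough to
pin the mean coefficient to about $\pm 3 \times 10^{-4}$ (three
standard errors) — with per-sample cost dominated by one dense solve
over the 28 states of the $N = 6$ plane, so larger runs scale
linearly. The engine guards the dense representation at
$(N+1)(N+2)/2 > 5000$ states.

## Numerical and testing choices

* Stationary solves: dense LU with residual bound $10^{-12}$;
  comparisons with three-decimal reference values use round-half-even.
* The Monte-Carlo/exact consistency check runs a $10^6$-round
  homogeneous CR session. Transition counts are compared row-wise
  against $M$ — valid without correction, since next states are iid
  draws of $M[\cdot|\mathbf{s}]$ conditional on the source state — with
  small-expectation cells pooled (threshold 5) and the per-row Pearson
  statistics summed into one global chi-square at $\alpha = 0.01$.
  Occupancies are compared with $\pi^*$ on draws thinned to every 10th
  round, because the raw occupancy sequence is autocorrelated and the
  plain chi-square test assumes independent draws.
* Parameter recovery is tested at $10^5$ rounds within three binomial
  standard errors.
* Trajectory files are validated structurally on read (contiguous
  rounds, perfect matchings, action codes) and outcomes are always
  recomputed from actions — payoff columns are verified, never
  trusted.

## Limitations

* The exact engine covers homogeneous populations; heterogeneity lives
  only in the simulator.
* Only the single-parameter payoff matrix (win $a$, tie 1, loss 0) is
  implemented; general payoff matrices would need a larger
  conditional-response parameterisation.
* No learning or adaptation of $\Gamma$ within a session, and no
  optimisation over the strategy simplex beyond uniform sampling.
* The dense linear-algebra engine targets small populations (the
  laboratory scale $N = 6$; anything up to a few thousand states is
  fine); very large $N$ would need sparse or spectral methods.
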