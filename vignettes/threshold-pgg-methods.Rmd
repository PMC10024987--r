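---
title: "Methods: asymmetric threshold public goods games in threshpgg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetric threshold public goods games in threshpgg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threshpgg)
```

## The game

Two players face a threshold public goods problem. Player $i \in \{1, 2\}$
receives an integer endowment $e_i$ (coins) and chooses a contribution
$c_i \in \{0, 1, \dots, e_i\}$. Contributions are weighted by integer
productivity factors $p_i$; the *collective contribution* is
$p_1 c_1 + p_2 c_2$. If it reaches a threshold $\theta$ (non-strict,
$\ge$), each player earns a reward $r_i$ on top of what they kept:

$$\pi_i(c_1, c_2) \;=\; \begin{cases}
e_i - c_i + r_i & \text{if } p_1 c_1 + p_2 c_2 \ge \theta,\\
e_i - c_i & \text{otherwise.}
\end{cases}$$

This is a coordination game rather than a dominance-solvable dilemma:
reaching the threshold is jointly profitable whenever the required cost
is below the rewards, but each player prefers the co-player to carry it.
The game has a (possibly empty) set of *cooperative* pure Nash
equilibria in which the threshold is met — with equal productivities
these pin the collective contribution to exactly $\theta$ — and, when no
player can profitably reach the threshold alone, a *defective*
equilibrium at $(0, 0)$. Note that any below-threshold equilibrium must
be $(0, 0)$: a contributing player in a failing group always gains by
withdrawing.

## Canonical treatments and default parameters

Asymmetry enters through either the endowments or the productivities.
The package ships five canonical configurations built by
`make_treatment()`:

| treatment | $e$ | $p$ | $r$ | $\theta$ |
|---|---|---|---|---|
| `full_equality` | (12, 12) | (1, 1) | (10, 10) | 12 |
| `moderate_endowment` | (16, 8) | (1, 1) | (10, 10) | 12 |
| `strong_endowment` | (18, 6) | (1, 1) | (10, 10) | 12 |
| `moderate_productivity` | (8, 8) | (2, 1) | (10, 10) | 12 |
| `strong_productivity` | (6, 6) | (3, 1) | (10, 10) | 12 |

Three rules fix these numbers. First, the asymmetry ratios are 2:1
(moderate) and 3:1 (strong) in exactly one dimension, with rewards held
constant across treatments so payoff scales are comparable. Second, the
threshold always follows the *half-endowment rule*
$\theta = (p_1 e_1 + p_2 e_2)/2$, so that both players contributing half
of their endowment meets the threshold exactly; endowments are even so
that this profile is integer. Third, magnitudes were chosen so that the
game's qualitative equilibrium structure is the interesting one: many
cooperative equilibria everywhere; full defection an equilibrium under
equality and endowment inequality but *not* under productivity
inequality (the productive player profitably provides the good alone,
at cost $\lceil\theta/p_1\rceil < r_1$); and all selection-heuristic
profiles integer.

One sizing choice deserves a note. For the strong productivity
treatment we use $e = (6, 6)$ rather than scaling up to $(8, 8)$
(i.e. $\theta = 16$). Under $(8, 8)$ the benchmark prediction of the
evolutionary analysis breaks in an instructive way: replicator dynamics
from uniform initial conditions converges to the strict equilibrium
$(5, 1)$, in which the low-productivity player retains a small positive
contribution, rather than to a solo-provision profile. With $(6, 6)$
(and at every other even size we examined except $(8, 8)$) the uniform
start converges to $(c_1, 0)$, matching the stylised expectation that
productivity inequality shifts the whole burden to the productive
player. Since the treatment magnitudes are otherwise free parameters,
we fixed the default where the qualitative benchmark holds; all
magnitudes remain overridable via `make_treatment(..., overrides)` or a
config file.

Configurations with odd endowments are accepted but flagged
(`half_integer = FALSE`), because the half-endowment profile then falls
between integer contributions and the relative-split heuristics lose
their exact solution.

## Equilibrium enumeration and selection heuristics

`enumerate_pure_nash()` scans all $(e_1+1)(e_2+1)$ profiles against the
payoff matrices. The Nash convention is: *equilibrium* means no strictly
improving unilateral deviation (deviations that tie are allowed);
strictness is reported separately, since profiles with $c_i = r_i$ sit
exactly on the tie boundary (the deviation to 0 neither gains nor
loses). Payoff comparisons use a $10^{-9}$ tolerance; with integer
endowments and the default rewards all payoffs are exact, so the
tolerance only matters for user-supplied fractional rewards.

Five selection heuristics pick one cooperative equilibrium as a focal
point:

* **EAC** — equal absolute contributions, $c_1 = c_2$;
* **ERC** — equal relative contributions, $c_1/e_1 = c_2/e_2$; by the
  half-endowment threshold rule this is always the profile
  $(e_1/2,\, e_2/2)$ in canonical treatments;
* **ECC** — equal collective contributions, interpreted here as equal
  *effective* contributions $p_1 c_1 = p_2 c_2$;
* **EP** — equal payoffs $\pi_1 = \pi_2$, with a documented fallback to
  the cooperative equilibrium minimising $|\pi_1 - \pi_2|$ (needed
  under strong endowment inequality, where no exact equal-payoff
  cooperative equilibrium exists);
* **MCP** — maximal collective payoff $\pi_1 + \pi_2$; ties break toward
  the smaller contribution gap $|c_1 - c_2|$, then lexicographically.

EAC, ERC and ECC deliberately have *no* fallback: when their defining
equation has no integer solution inside the cooperative set the
heuristic returns `NULL` rather than silently rounding. A `nearest`
mode returns the cooperative equilibrium minimising the condition's
absolute residual for users who want a selection regardless.

The structural facts the test suite pins down: EAC and ERC single out
the same profile under full equality and under productivity inequality,
and necessarily diverge under endowment inequality; and under
productivity inequality MCP selects solo provision by the productive
player — efficient, but maximally unequal in payoffs, which is exactly
the efficiency-versus-fairness tension the game is designed to exhibit.

## One-shot evolutionary and learning dynamics

Strategies of role $i$ are the contribution levels $0..e_i$; a
population state is a pair of probability vectors $(x, y)$, one per
role. Four dynamics are implemented; each treats the co-role's current
mixture as the opponent environment.

* **Replicator** (`run_replicator`): the standard two-population
  equation $\dot x_c = x_c (f_c(y) - \bar f(x, y))$ and symmetrically
  for $y$. Integration is fixed-step RK4 with `step_size` $dt = 0.01$
  and `time_horizon` 2000; each step clips negative round-off mass at
  zero and renormalises when $|\sum x - 1| < 10^{-6}$ (larger drift
  aborts with a diagnostic — in practice drift stays near machine
  precision). Convergence is declared when the state change per unit
  time drops below `convergence_tol` $= 10^{-8}$; near a strict
  equilibrium the decay is exponential, so this triggers quickly.
* **Best response** (`run_best_response`): discrete updates moving a
  `step_size` fraction of each role's mass toward the uniform mixture
  over that role's current best responses, ties split equally.
* **Birth–death** (`run_birth_death`): a pairwise-comparison process in
  two finite subpopulations of size $N$ (default 100). Per step a role
  is chosen uniformly, then a focal and a model individual of that
  role; the focal copies the model with the Fermi probability
  $1/(1 + e^{-\beta(\pi_\text{model} - \pi_\text{focal})})$
  ($\beta$ = `selection_strength`, default 1), or, with probability
  $\mu$ (default 0.01), adopts a uniformly random contribution.
  Initial counts are apportioned from the initial state by largest
  remainder, so point masses start monomorphic and are absorbing at
  $\mu = 0$.
* **Introspection** (`introspection_stationary`): a single pair of
  players; each step one player is chosen uniformly, a uniformly random
  *alternative* contribution (excluding the current one) is considered,
  and the switch is accepted with the same Fermi probability. This
  yields a Markov chain over joint profiles that is irreducible and
  aperiodic for finite $\beta$; the exact mode builds the full
  transition matrix (at most a few hundred states at the defaults) and
  solves $\pi P = \pi$ directly, the simulated mode estimates $\pi$
  from one long seeded run. At $\beta = 0$ the proposal chain is
  doubly stochastic and the stationary distribution is exactly uniform
  — a useful analytic anchor the tests assert.

Initial conditions come in three kinds: `uniform` (all contributions
equally weighted), `random` (a symmetric Dirichlet(1) draw per role),
and `empirical` (a normalised supplied distribution, e.g. the
first-round histogram of a cohort from the synthetic-experiment
module). The interesting phenomenon the package reproduces as a
property: from uniform starts the deterministic dynamics select either
full defection (equality and endowment treatments) or solo provision by
the productive player (productivity treatments) — never the
half-endowment split — while from empirical-style starts concentrated
on the ERC profile every dynamic retains the ERC outcome. Equilibrium
selection by these dynamics is therefore initial-condition-dominated in
this game class, which is precisely why empirical starting distributions
matter.

`modal_outcome()` summarises a final state by the profile maximising
$x_{c_1} y_{c_2}$, breaking ties toward the lexicographically smallest
$(c_1, c_2)$ so results are deterministic.

## Repeated game over reactive strategies

A deterministic *reactive strategy* is an opening contribution plus a
response map from the co-player's previous contribution to one's own
next contribution. Joint play is then a deterministic walk on the
finite profile space, so it enters a cycle within
$(e_1+1)(e_2+1) + 1$ rounds; `play_repeated()` detects the cycle and
reports limit-of-means payoffs averaged over one full cycle
(a finite-round mode mirrors a 20-round session instead). Stochastic
reactive strategies are deliberately excluded: determinism keeps payoff
evaluation exact and cycle detection trivial.

Because "all reactive strategies" is a huge space
($\prod (e_i+1)^{e_j+2}$ maps), evolutionary selection runs over three
tractable families, documented as stand-ins: all *constant* strategies,
a *linear*-response grid $c \mapsto \mathrm{clip}(a + b\,c_\text{other})$,
and a seeded *random sample* of response maps. The constant family is
the important baseline: constant-strategy repeated payoffs equal
one-shot payoffs, so the repeated analysis restricted to it must — and,
by test, does — reproduce the one-shot equilibrium and dynamics results
exactly. `best_cycle_payoff_scan()` confirms the other structural
anchor: the most profitable strategy pair sustains per-round play at a
maximal-collective-payoff cooperative equilibrium (solo provision under
productivity inequality).

## Synthetic experiment generator

`simulate_session()` produces experiment-shaped data without any human
subjects: per treatment, `n_pairs` pairs (default 14) with fixed roles
play 20 rounds (game 1), then partners are re-matched by a random
derangement of pairs with all roles swapped for another 20 rounds
(game 2), so every subject plays each role exactly once and never meets
the same partner twice. The derangement scheme is an assumption — real
lab matching protocols vary — and cohort sizes are desk-scale, not a
replication of any particular study's sample.

Agents follow a deliberately simple directional-learning model
(`agent_model()`): openings are drawn from a mixture over four
dispositions — the ERC half-endowment profile (default weight 0.6), the
EAC equilibrium profile (0.2), zero (0.1), and uniform random (0.1) —
and after each round an agent who failed while contributing less than
half their endowment raises their contribution by `step` (default 1)
with probability `adjust_up_prob` (0.5), an agent in an over-threshold
(non-effective) success lowers it with probability `adjust_down_prob`
(0.3), and any contribution is replaced by a uniform draw with
probability `noise_prob` (0.05). These defaults make synthetic cohorts
show rising success curves with slower coordination under endowment
inequality, qualitatively like behavioural data. The model is a
generator, not a fitted description: it has no fairness preferences, no
cross-game learning, no role-dependent parameters, and no strategic
anticipation, so passing tests demonstrate that the *pipeline* (metrics,
empirical initial conditions, reports) is correct on data with the right
shape — not that the agent model explains real behaviour.

## Outcome metrics

A *group* is one pair within one game (the two games of a session count
as distinct groups). A group-round is *successful* when the collective
contribution meets or exceeds $\theta$ and *effective* when it equals
$\theta$ exactly, so effectiveness implies success row by row. Summary
rates average group-first (mean over a group's rounds, then across
groups), which weights groups equally when counts differ; per-round
curves aggregate across groups at each round index. Contribution
summaries report per-role absolute means and relative means
$c_i / e_i$. Failing rounds are partitioned against the half-endowment
baseline into only-player-1-below, only-player-2-below, both-below, and
a residual category that is impossible for equal-productivity canonical
configurations and is therefore flagged as an anomaly check.
`conditional_response()` estimates the probability that a player who
failed while below half raises their contribution next round, using
within-game within-pair transitions only (round 20 has no successor;
the game-1 to game-2 boundary is a new partner and role, so it never
counts). When no transition qualifies the probability is `NA`, never a
silent zero. Optional percentile bootstrap intervals (seeded, resampling
groups) are available for the rates; no inferential tests are provided
by design.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; the pipeline derives
per-stage sub-seeds from one global seed via a deterministic string
hash (`derive_seed()`), so stages are decoupled but the whole pipeline
is fixed by a single integer. The test-suite and acceptance problem
sizes are chosen for desk-scale runs: 200 randomized games for the
equilibrium oracle comparison, replicator horizons of a few hundred
time units (convergence typically occurs before $t = 25$), $10^6$
introspection steps for the simulated-versus-exact comparison, and
synthetic cohorts of 14 pairs (500 pairs where binomial concentration
at $\pm 0.05$ is asserted).

## Known limitations

* Only two-player games; no $n$-player or continuous-contribution
  variants, and no loss-risk (climate-dilemma) payoff structures.
* Pure-strategy equilibrium analysis only; mixed equilibria and
  refinements (risk dominance, trembling-hand) are out of scope.
* The reactive-strategy families are coarse subsets of the full
  reactive space; results over them are existence demonstrations, not
  characterisations.
* The agent model is a stand-in generator (see above), and the metrics
  are descriptive; no statistical comparison machinery across
  treatments is included.
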