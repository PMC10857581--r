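---
title: "Stationary dynamics of cooperation in hybrid teams playing the collective-risk dilemma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary dynamics of cooperation in hybrid teams playing the collective-risk dilemma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcrd)
```

## The model

The collective-risk dilemma (CRD) is a one-shot threshold public goods game.
Each of the $N$ members of a group holds an endowment $b$ and chooses to
cooperate — contribute a fraction $c$ of $b$ — or defect and contribute
nothing. If at least $M$ members cooperate the group is safe; otherwise every
member loses its remaining endowment with probability $r$. The expected
payoffs given $j$ cooperators in the group are

$$\pi_D(j) = b\,\bigl(1 - r + r\,\theta(j - M)\bigr), \qquad
  \pi_C(j) = \pi_D(j) - cb,$$

with $\theta$ the Heaviside step under the convention $\theta(0) = 1$
(exactly $M$ cooperators suffice). Cooperators always pay $cb$ more than
defectors in the same group — the defection incentive — and a cooperator that
misses the goal under full risk nets $-cb$; payoffs are not clamped.

`hybridcrd` studies this game in *hybrid* groups: $N - a$ seats are filled by
adaptive individuals sampled from a population of size $Z$, and $a$ seats by
fixed-behavior stochastic agents. The agent block is perfectly correlated and
acts all-or-none: in each interaction all $a$ agents cooperate with
probability $p$, or none do. The expected payoff of an adaptive player facing
$i$ adaptive cooperators (itself included when cooperating) is therefore the
two-point mixture

$$\Pi_{C(D)}(i, a, p) = p\,\pi_{C(D)}(i + a) + (1 - p)\,\pi_{C(D)}(i).$$

Modeling the block as $a$ independent Bernoulli($p$) agents is a tempting
generalization but a different model — it changes every downstream surface —
and is deliberately out of scope.

## Social learning and the stationary chain

Adaptive strategies evolve by a pairwise-comparison process. The *fitness* of
a strategy in population state $k$ (cooperators among $Z$) is its expected
payoff over all groups the focal player can land in, with co-players drawn
without replacement — a hypergeometric average:

$$f_C(k) = \binom{Z-1}{N-a-1}^{-1} \sum_{i=0}^{N-a-1}
  \binom{k-1}{i}\binom{Z-k}{N-a-1-i}\,\Pi_C(i+1, a, p),$$

and analogously for $f_D(k)$ with weights $\binom{k}{i}\binom{Z-k-1}{N-a-1-i}$
and $\Pi_D(i, a, p)$. All binomials route through `binom_safe()` (zero outside
its domain) so boundary states evaluate to empty sums rather than errors;
$f_C(0)$ and $f_D(Z)$ are undefined (no such focal player) and returned as 0,
and the pair-selection factors below vanish exactly there, so the values are
never consumed. The coefficients are exact in double precision for any
practical $Z$ (group seats are small), so no log-space tricks are needed in
the fitness sums.

At each revision event a focal individual is drawn uniformly from the
population; with probability $\mu$ it mutates to the opposite strategy;
otherwise it draws a role model uniformly among the other $Z-1$ individuals
(nothing happens if their strategies match) and imitates with the Fermi
probability $\bigl(1 + e^{-\beta(f_{\text{rm}} - f_{\text{focal}})}\bigr)^{-1}$,
where $\beta \ge 0$ is the selection strength. This yields a birth–death
Markov chain on $k \in \{0, \dots, Z\}$ with transition probabilities

$$T^+(k) = \frac{Z-k}{Z}\Bigl(\mu + (1-\mu)\,\frac{k}{Z-1}\,P(D\!\to\!C)\Bigr),
\qquad
T^-(k) = \frac{k}{Z}\Bigl(\mu + (1-\mu)\,\frac{Z-k}{Z-1}\,P(C\!\to\!D)\Bigr).$$

**Why the additive mutation term.** An imitation-only variant of these
transitions (available as `transitions = "printed"`) makes $k = 0$ and
$k = Z$ absorbing, so the long-run distribution degenerates onto the
boundaries and none of the stationary observables below are well defined.
The additive $\mu$ inflow is the standard pairwise-comparison-with-mutation
form and matches the revision protocol stated above; it is the package
default, and `stationary_distribution()` refuses non-ergodic configurations
($\mu = 0$ or the imitation-only form) rather than returning a degenerate
answer. The role-model draw is a *no-op* when strategies match — the
$k/(Z-1)$ factor encodes drawing uniformly among the others, not resampling
until a different strategy appears — and the agent-based simulator mirrors
this convention exactly.

**Solving for the stationary distribution.** The chain is a reversible
birth–death process, so its stationary vector has the closed product form
$P(k) \propto \prod_{j=0}^{k-1} T^+(j)/T^-(j+1)$, which the package
accumulates in log space and which satisfies detailed balance
$P(k)T^+(k) = P(k+1)T^-(k+1)$ to machine rounding — including in tails where
$P(k)$ falls below $10^{-30}$. The eigenvector of the transposed transition
matrix at eigenvalue 1 is also computed and the two are compared: a sup-norm
disagreement above $10^{-8}$ aborts the solve. The product form is returned
as `distribution` because a dense eigen solve carries $\sim 10^{-16}$
*absolute* noise per component and therefore cannot represent the relative
structure of the far tails; the raw eigenvector is kept in
`eigen_distribution` for inspection. In practice the sup-norm residual at
the default $Z = 100$ is below $10^{-10}$ across the parameter plane. Fermi
probabilities are computed with `plogis`, which is overflow-safe for any
$\beta$.

## Observables and controls

From the stationary vector the package reports the cooperation level
$\bar{C} = \sum_k P(k)\,k/Z$ and the group success rate
$\bar{s}_G = \sum_k P(k)\,s_G(k)$, where $s_G(k)$ is the probability that a
randomly assembled group meets the threshold:

$$s_G(k) = \binom{Z}{N-a}^{-1} \sum_{h=0}^{N-a}
  \binom{k}{h}\binom{Z-k}{N-a-h}
  \bigl(p\,\theta(h + a - M) + (1-p)\,\theta(h - M)\bigr).$$

$s_G(k)$ is non-decreasing in $k$ and affine in $p$ at fixed $k$; the
end-to-end $\bar{s}_G(p)$ need not be monotone because $P(k)$ itself moves
with $p$ — the interior dip in success for balanced teams at high risk is
exactly this effect.

Whether a hybrid team "gains" depends on the baseline. Two controls are
supported, differing only in the group size of the agent-free population:

* **substitution** — the agents replaced $a$ of $N$ adaptive members; the
  control plays in groups of $N$;
* **addition** — the agents were appended to a team of $N - a$; the control
  plays in groups of $N - a$.

`control_delta()` reports hybrid-minus-control differences for both metrics.
In the control, $p$ is formally inert ($a = 0$); the constructor zeroes it to
preclude accidental use. An addition control can face a threshold larger
than its group size (e.g. 2 adaptive members against $M = 3$): `crd_model()`
therefore accepts $M > N$ as a legal unreachable-threshold configuration, in
which $s_G \equiv 0$.

```{r delta-example}
hyb <- crd_model(N = 6, M = 3, a = 2, p = 0.8, r = 0.3)
glance(control_delta(hyb, "addition"))
```

## Parameters and scenario presets

| parameter | meaning | default | units |
|---|---|---|---|
| `N` | group size | 6 | seats |
| `M` | cooperator threshold | 3 | seats |
| `r` | risk of loss when threshold missed | — | probability |
| `b` | endowment | 1 | currency |
| `c` | contribution fraction | 0.1 | of `b` |
| `a` | agents per group | 0 | seats |
| `p` | agent-block cooperation probability | — | probability |
| `Z` | adaptive population size | 100 | individuals |
| `mu` | mutation probability per revision | 0.01 | probability |
| `beta` | selection strength | 2 | inverse payoff |

The three presets in `crd_scenario()` fix $N = 6$, $M = 3$ and vary the team
composition — `"a2"` ($a < M < N-a$: the adaptive side can reach the
threshold alone), `"a3"` ($a = M = N-a$: either side can), `"a4"`
($a > M > N-a$: only the agents can) — with $Z = 100$, $\mu = 0.01$,
$\beta = 2$, $b = 1$, $c = 0.1$. These constants are the study conditions
for every sweep and test in the package and are not tuned per analysis.
`run_sweep()` defaults to a $51 \times 51$ lattice over
$(r, p) \in [0,1]^2$, a resolution at which every qualitative structure of
the plane (the risk boundary, the interior success dip, the sign pattern of
the control deltas) is already stable; the grid density is a flag, not a
model parameter.

One consequence worth stating explicitly: in the `"a4"` composition the
adaptive players can never influence success ($N - a < M$ with the block
absent, $h + a \ge M$ always with it), so $f_C - f_D = -cb$ at every grid
point and $\bar{C}$ is *constant* across the whole $(r, p)$ plane at the
mutation–selection floor — about 0.095 at $\beta c b = 0.2$, $\mu = 0.01$,
$Z = 100$. "No cooperation" in this regime means this floor, not
$\bar{C} = 0$: with nonzero mutation and weak effective selection the
stationary mass near $k = 0$ is finite, and the agent-based simulator
reproduces the same floor independently.

## The agent-based oracle

`run_abm()` simulates the revision protocol itself — focal draw, mutation,
role-model draw with the no-op convention, Fermi imitation — rather than the
aggregated chain. Since individuals are exchangeable given $k$, and fitness
in the default `"exact"` mode is the hypergeometric expectation above, the
draws are realized by strategy type; this is the identical stochastic
process, runs in O(1) per step, and is bit-reproducible under a seed. In
exact-fitness mode the simulator and the chain share transition
probabilities *exactly*, so comparing empirical occupancy against $P(k)$ (or
per-state move frequencies against $T^\pm(k)$) tests the update rule and the
stationary solver with no estimation noise in between — that is its purpose
as a validation oracle. A `"sampled"` fitness mode, which re-estimates
fitness from freshly drawn groups at every imitation event (fresh agent-block
realization per group, matching the marginal semantics of the payoff and
success formulas), is provided for robustness probes only.

The validation runs used throughout the tests operate at $Z = 20$ with
$1.1 \times 10^6$ steps ($10^5$ discarded as burn-in): at this size the
total-variation distance between empirical occupancy and the analytical
stationary vector is typically 0.01–0.03, and shrinks visibly between
$10^4$ and $10^6$ steps. Larger $Z$ mixes more slowly (excursions between
cooperative and defecting regimes become rarer), which is why the oracle runs
at a reduced population size while the analytical chain uses $Z = 100$.

## What the simulated conditions do and do not show

Everything in the package operates on the model's own terms: a well-mixed
population, one perfectly correlated agent block per group, binary
strategies, and imitation as the only learning channel. Passing tests
demonstrate internal correctness — formulas against enumeration, solver
against closed form, simulator against chain — under exactly these
assumptions. They say nothing about structured populations, heterogeneous or
independently acting agents, repeated play, or human learning beyond
imitation; the model is a thought experiment whose value is the clean
qualitative map of when adding or substituting machine teammates helps, and
those maps should be read as regime diagrams, not calibrated predictions.

## Numerical conventions, in one place

* $\theta(0) = 1$; all threshold tests go through `heaviside()`.
* Out-of-domain binomials are 0 (`binom_safe()`), never errors.
* Boundary fitness values are 0 by convention and provably never consumed.
* Stationary solves: product form returned; eigen cross-check mandatory at
  $10^{-8}$ sup-norm, typically passing at $10^{-10}$.
* Degenerate chains ($\mu = 0$, imitation-only transitions) are refused with
  an explanation, not silently regularized.
* Sweep serialization keeps doubles bit-exact (17 significant digits in CSV
  and JSON); JSON output records the full model including the transition
  convention.
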