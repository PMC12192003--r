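---
title: "Expected income under reputation-based partner choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected income under reputation-based partner choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdrep)
```

## The model and its assumptions

`ipdrep` analyses a stylized trading society. Every agent has a fixed
reputation $q \in [0,1]$, which plays a double role: it is the
probability that the agent cooperates in any Prisoner's Dilemma game it
plays, and it is the trait by which partners are chosen. Games are
arranged in rounds: a first player is drawn uniformly from the
population, $n$ distinct candidates are drawn uniformly from the
remaining agents, and the candidate with the highest reputation becomes
the second player. Both players then cooperate or defect independently
with probability equal to their own reputation and collect the matrix
payoffs $T > R > P > S$ (defaults $5, 3, 1, 0$, with $2R > T + S$).

Three assumptions make the model solvable:

* **Frozen reputations.** Reputations are drawn once from a density
  $p(x)$ on $[0,1]$ and never updated. There is no learning, no
  strategy adaptation, and no feedback from play to reputation.
* **Well-mixed population.** Any agent can meet any other; there is no
  spatial or network structure.
* **Large population.** In the limit $N \to \infty$ the expected income
  of an agent depends only on its own reputation, the density $p$, the
  group size $n$ and the payoffs:
  $$I(q) = I_1(q) + n F(q)^{n-1} I_2(q),$$
  where $I_1(q) = \int_0^1 p_{\max}(x)\, G(q,x)\,dx$ is the expected
  gain as first player against the order-statistic density
  $p_{\max}(x) = n F(x)^{n-1} p(x)$, $I_2(q) = \int_0^1 p(x)\,
  G(q,x)\,dx$ the gain as second player, and $n F(q)^{n-1}$ the
  probability of being the most reputable of the $n$ sampled
  candidates. We adopt the convention $0^0 = 1$ so that at $n = 1$ the
  lone candidate is always chosen and $I = I_1 + I_2$ holds for every
  $q$, including $q = 0$; without it the uniform-density line
  $I_{n=1}(q) = 6 - 3q$ would break at the origin. Finite-$N$ effects
  are deliberately left to the simulator.

The society is summarized by $E(I) = \int_0^1 p(x) I(x)\,dx$ and a
dispersion. We report the dispersion as the standard deviation
$\sigma(I) = \sqrt{\int_0^1 p(x) (I(x) - E(I))^2 dx}$ rather than the
variance: it carries the units of income, which is what one wants when
reading it as a measure of income inequality (for the uniform density
at $n = 1$ it is exactly $\sqrt{3}/2 \approx 0.866$).

## Parameters that matter

* `n` (integer $\ge 1$, default 2) — the candidate-group size, the
  strength of selective assortment. At $n = 1$ partner choice is blind
  and defection is optimal; at $n = 2$ it is already the *worst*
  strategy for the defector, because a larger candidate pool raises the
  expected reputation of the chosen partner and hence the defector's
  probability of pocketing $T$ rather than $P$ — but also starves the
  defector of second-player games entirely.
* `T, R, P, S` (payoff units, default $5,3,1,0$) — validated strictly
  as a PD by default; `strict = FALSE` admits other dilemma orderings
  (Snowdrift, Stag Hunt) without mislabeling them.
* `a` (dimensionless, default 5) — slope of the `exp_decreasing`
  density $\propto e^{-ax} - e^{-a}$; larger $a$ concentrates the
  society at low reputations. The subtracted $e^{-a}$ forces
  $p(1) = 0$, and the prefactor $a e^a / (e^a - a - 1)$ normalizes.
  The default 5 is the slope used throughout the reported analyses.

We treat the six named densities (`uniform`, `linear_increasing`,
`linear_decreasing`, `exp_decreasing`, `hump`, `ushape`) as six
distinct cases even though the two decreasing ones are variants of one
scenario; each has its own closed-form CDF and appears as its own row
in `reproduce_table1()`.

## Numerical choices

**Income evaluation.** $G(q,x)$ is affine in the opponent reputation
$x$, so both integrals collapse to two moments of $p$: its mean and the
mean of the max of $n$ draws. `ipd_model()` computes these once —
closed form for the uniform ($n/(n+1)$) and linear-increasing
($2n/(2n+1)$) CDF powers, adaptive quadrature (`stats::integrate`,
absolute tolerance $10^{-12}$) otherwise, since the exponential case
has no elementary general-$n$ antiderivative. Every income evaluation
afterwards is exact arithmetic in those moments. The test suite keeps
an independent route alive: direct quadrature of
$p_{\max}(x) G(q,x)$ and the polynomial closed forms
`closed_form_income_uniform()` / `closed_form_income_linear()` must
agree with the moment path to $10^{-8}$ on a 101-point grid for
$n = 1, \dots, 10$.

**Extrema.** `find_extrema()` scans a 1001-point grid (configurable),
brackets sign changes of the discrete derivative, and refines each
bracket with `stats::optimize` at tolerance $10^{-10}$, giving
locations to about $10^{-6}$. Boundary values at $q = 0$ and $q = 1$
are always reported as separate `boundary` rows, so curves whose
global maximum sits at $q = 1$ (uniform and linear-increasing cases
with $n \ge 3$) are classified as boundary maxima rather than missed.
Flat curves (all payoffs equal) produce no spurious interior extrema
because derivative changes below $10^{-12}$ relative are ignored. One
borderline case is worth flagging: for the linear-increasing density at
$n = 2$ the interior minimum refines to $q = 0.13519$, a value
sometimes quoted as "near 0.134"; both are consistent at the $0.002$
location tolerance we apply to such comparisons.

**Defector income.** For $n \ge 2$ a $q = 0$ agent never wins the
candidate contest, so its income is pure first-player income,
$(1+5n)/(1+n)$ for the uniform and $(1+10n)/(1+2n)$ for the
linear-increasing density, both increasing in $n$. At $n = 1$ the
premise fails — the lone candidate plays regardless of reputation —
so `defector_income()` rejects $n = 1$ instead of returning a number
that contradicts $I_{n=1}(0)$.

**Sampling.** `sample_reputations()` inverts the CDF: closed-form
quantiles for the uniform and the two linear cases, and for the rest a
tabulated inverse on an 8193-point grid sharpened by damped Newton
steps (skipped where the density vanishes, e.g. at the flat CDF point
of the U-shaped case — the tabulated value is already within grid
resolution there, and that point carries no probability mass). No
rejection sampling, so draw counts are exact and reproducible.
Tabulated custom densities are linearly interpolated; a trapezoid
integral off unity by less than $10^{-3}$ is renormalized, anything
worse is rejected as a likely user error.

## What the simulator does and does not emulate

`simulate()` replays the finite-$N$ process literally: reputations
frozen at the start, first player uniform over all $N$, candidates
sampled *without replacement excluding the first player* (self-play is
impossible; the per-agent selection probability is $n/(N-1)$), maximal
reputation wins with uniform random tie-breaking (a measure-zero event
for continuous densities, but required for reproducibility with
discretized custom densities), realized payoffs accumulated per agent.
One RNG stream per run, seeded from the call.

`binned_income_curve()` rescales per-agent accumulated income by
`agents / iterations`, restoring comparability with the analytic
$I(q)$, whose natural unit is one sweep of $N$ games; iterations are
otherwise decoupled from $N$. `compare_report()` compares each
occupied reputation bin against the mean of $I(q_i)$ over the agents
actually in the bin (not the bin midpoint), which removes curvature
bias, and flags bins beyond 3 standard errors.

The default validation scale in the tests — $N = 10^4$ agents,
$10^4$ iterations, 20 bins, every built-in density $\times$
$n \in \{1,2,3,5,10\}$ — keeps roughly 500 agents per bin, large
enough that the 3-SE criterion is sharp, and runs in seconds per
configuration. What passing those checks shows is that the simulator
and the analytic limit agree *with each other* under the model's own
assumptions; it says nothing about real societies, where reputations
drift, interactions are structured, and payoffs vary between
encounters.

## Known limitations

* Reputation dynamics (updating from past play), spatial or graph
  topologies, strategy memory and alternative dilemma games are out of
  scope; the payoff container accepts non-PD orderings only so that
  such extensions are not silently mislabeled.
* The analytic module is exact only in the large-$N$ limit. At small
  $N$ the candidate pool excludes the first player, which shifts the
  order statistic by $O(1/N)$; this shows up as bias only when $N$ is
  of order $n$.
* Society dispersion from a simulation (`simulated_society_summary()`)
  includes game and selection noise on top of the reputation-driven
  spread, and therefore overestimates the analytic $\sigma(I)$ unless
  `iterations` grows faster than `agents`. The mean is unbiased either
  way.
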