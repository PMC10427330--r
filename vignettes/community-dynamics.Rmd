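---
title: "Conditional cooperation, rosy beliefs, and community dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional cooperation, rosy beliefs, and community dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condcoop)
```

## The model

`condcoop` couples two dynamics: the behaviour of conditional cooperators
inside a community, and the membership flows of the community itself.

**Threshold behaviour.** Each individual carries a *norm sensitivity*: a
threshold level of perceived cooperation above which they cooperate.
With thresholds distributed as a normal with mean $\mu$ and variance
$\sigma^2$, the fraction willing to cooperate when a fraction $p$ is
believed to cooperate is the CDF $F(p)$, and behaviour follows the
continuous-time threshold dynamic
$$\dot p = F(p) - p.$$
We deliberately do *not* truncate or renormalise $F$ on $[0,1]$:
$F(0) > 0$ means a few individuals cooperate unconditionally and
$F(1) < 1$ means a few never will. Depending on $(\mu, \sigma^2)$ the
fixed points $F(p) = p$ number three (a bistable **coordination
dilemma**: stable low- and high-cooperation states separated by an
unstable one) or one (a **cooperation dilemma**, with only a
low-cooperation state). A fixed point is stable iff $f(p^*) < 1$,
where $f = F'$. For $\mu > 1/2$, raising $\sigma^2$ merges the upper
two roots in a saddle-node tangency ($F(p)=p$, $f(p)=1$);
`critical_variance()` solves that system by damped Newton iteration
with an analytic Jacobian. For $\mu = 0.7$ the tangency sits at
$\sigma^2 \approx 0.0245$, i.e. about 0.025.

**Community membership.** The population of size $K$ splits into
susceptible outsiders $S$, insiders $I$, and discouraged outsiders
$D = K - S - I$ (carried as a residual so the total is conserved
exactly). Insiders are *naive* (fraction $1-y$) or *savvy* (fraction
$y$). Naive members hold a rosy belief that cooperation equals
$\tilde p$ and cooperate at the fixed level $F(\tilde p)$; savvy
members know the true mean cooperation
$\bar p = y\,p + (1-y)F(\tilde p)$ and their cooperation frequency $p$
tracks $F(\bar p)$. The *belief gap* $\Delta = \tilde p - \bar p$
drives both learning (naive $\to$ savvy at per-capita rate
$\lambda\Delta$) and disillusioned leaving (savvy $\to$ discouraged at
per-capita rate $\omega\Delta$). Joining is by contact
($\iota S I / K$) and discouragement wanes at rate $\varphi$. The
reduced state $(S, I, y, p)$ obeys
$$
\begin{aligned}
\dot S &= \varphi D - \iota S I / K,\\
\dot I &= \iota S I / K - \omega \Delta y I,\\
\dot y &= \lambda \Delta (1-y) - \omega \Delta y (1-y) - (\iota S/K)\,y,\\
\dot p &= F(\bar p) - p.
\end{aligned}
$$
Three consequences pin this form down and are verified in the test
suite: the savvy fraction at any mixed equilibrium is
$y^* = \lambda/(\lambda+\omega)$; savvy equilibria solve
$p = F(y^* p + (1-y^*)F(\tilde p))$; and the population split is the
closed form built on the reproduction ratio below. A raw
five-compartment head-count formulation (`raw_rhs()`,
`integrate_raw()`) — susceptible, naive, savvy, discouraged, savvy
cooperators — is integrated as an independent derivation oracle and
must agree with the reduced model to $10^{-6}$. In the raw model,
newly savvy individuals adopt the current savvy mean behaviour and
leavers are an unbiased sample of savvy cooperators; both choices are
forced by requiring the reduction to return $\dot p = F(\bar p) - p$
(an influx-dilution term in $\dot p$ would shift the savvy equilibria
off $p = F(\bar p)$).

**Reproduction ratio.** $\hat R = \iota / (\omega \Delta^* y^*)$
compares the per-capita joining rate of a small community in a fully
susceptible population with the per-capita discouragement rate at a
candidate behavioural equilibrium, in direct analogy with the basic
reproduction number of epidemiology. A mixed insider/outsider
equilibrium exists iff $\hat R > 1$, in which case
$$S^* = K/\hat R, \qquad
I^* = \frac{K(1 - 1/\hat R)}{1 + \omega\Delta^* y^*/\varphi}, \qquad
D^* = \frac{\omega\Delta^* y^*}{\varphi} I^*.$$
$\hat R$ is evaluated per candidate root, since several behavioural
equilibria can coexist.

## Parameters

| symbol | code | meaning | default |
|---|---|---|---|
| $\mu$ | `mean` | threshold-distribution location (probability scale) | 0.5 / 0.7 |
| $\sigma^2$ | `variance` | threshold-distribution variance | 0.04 |
| $\iota$ | `inflow` | contact/joining coefficient (per time) | 1 |
| $\lambda$ | `learning` | learning-speed coefficient (per time) | 1 |
| $\omega$ | `outflow` | leaving coefficient (per time) | 1 |
| $\varphi$ | `phi` | resusceptibility rate (per time) | 1 |
| $K$ | `K` | population size | 1 |
| $\tilde p$ | `p_tilde` | naive belief | `"auto"` |

The canonical threshold distributions are Normal(0.5, 0.04) for the
coordination dilemma and Normal(0.7, 0.04) for the cooperation
dilemma. `p_tilde = "auto"` resolves to the high-cooperation fixed
point of the coordination reference ($\approx 0.99317$), the level a
booster of the community would plausibly broadcast; it is
self-confirming ($F(\tilde p) = \tilde p$) only in the coordination
dilemma. All rates are per unit model time; only ratios matter for the
behavioural equilibria ($\omega/\lambda$ through $y^*$), while
absolute rates set the population time scales. The dynamics are
homogeneous in $K$, so $K = 1$ loses nothing (tested by rescaling).

## What the package computes

* `fixed_points()`, `classify_dilemma()`, `naive_belief()`,
  `critical_variance()` — the one-dimensional threshold analysis.
* `integrate_community()` / `integrate_raw()` — adaptive
  Dormand–Prince 5(4) integration at rtol $10^{-9}$ / atol $10^{-12}$.
  No suitable ODE solver package is available in the supported
  dependency set, so the stepper is implemented in C++ inside the
  package; a fixed-step RK4 oracle in the test suite cross-checks it.
* `enumerate_equilibria()` — the all-outsider crash state (with the
  boundary behavioural attractor attached), the all-insider
  high-cooperation state (present only for self-confirming beliefs;
  it is a *line* of equilibria, neutral in $y$, reported once and
  classified `marginal_line` with the transverse spectrum deciding
  attraction), and every mixed equilibrium with $\hat R > 1$.
  Stability is numerical: eigenvalues of a central-difference Jacobian
  (relative step $10^{-7}$), with a $\pm 10^{-8}$ dead-band. At
  equilibria sitting on the $\Delta = 0$ boundary the Jacobian uses
  the smooth (unclamped) extension of the gap-driven flows, which
  equals the one-sided derivative from the admissible side.
* `crash_invasion_rate()` — the behaviour of a vanishingly small
  community: with $S = K$, the composition $(y, p)$ has its own
  dynamics, and the insider growth rate at its attractor is
  $r = \iota - \omega\Delta^\circ y^\circ$. This boundary system turns
  out to be **bistable** at intermediate inflow: a freshly seeded
  community is naive-dominated (high $\bar p$, small gap, often
  $r > 0$) while a collapsed community is savvy-dominated (low $p$,
  large gap, $r < 0$). The function relaxes from both sides; crash
  stability is judged at the collapse-side attractor (it governs
  whether a dead community rebounds), and the seed-side attractor is
  reported alongside. This two-sided reading is what reproduces the
  crash-only / bistable / community-only windows as inflow increases,
  and is the package's resolution of an open question in the source
  material's crash-condition statement.
* `scan_equilibria()`, `critical_ratio()`, `regime_diagram()` —
  continuation by grid enumeration with nearest-neighbour branch
  matching; folds are bracketed by changes in the mixed-equilibrium
  count and refined by bisection to $10^{-8}$, independently
  cross-checked by a damped-Newton solve of the tangency system
  $\{p = F(y p + (1-y)F(\tilde p)),\ y f(\cdot) = 1\}$.
  Pseudo-arclength continuation is unnecessary here: equilibria are
  cheap one-dimensional roots.
* `classify_attractor()` — classifies the long-run insider series as
  `fixed_point` (post-transient amplitude $< 10^{-6} K$),
  `limit_cycle`, or `bursting`. Peaks are the maxima of excursions of
  $I(t)$ above its mid-range level; the period is the median
  inter-peak interval; bursting requires troughs below $10^{-4} K$
  with quiescent gaps longer than five excursion widths. At least
  five post-transient peaks are required, otherwise the function
  demands a longer integration rather than guessing.

## Numerical choices

* Root finding on $[0,1]$: sign-change bracketing on a 2001-point
  uniform grid, bisection to $10^{-12}$; a grazing tangency (no sign
  change) is caught from near-zero local minima of $|F(p)-p|$ and
  flagged `marginal` ($|f(p^*)-1| < 10^{-8}$) instead of silently
  picking a side.
* Newton solves (tangency systems) are damped — the step is halved
  until the residual norm decreases — and initialised from coarse grid
  scans, so they converge from the correct branch.
* The belief-gap flows use $\max(\Delta, 0)$: the model is defined for
  rosy beliefs, and $\Delta \ge 0$ is forward-invariant from
  admissible states provided $F(\tilde p) \le \tilde p$; the clamp
  only matters for user-chosen inadmissible starts, and
  `belief_gap()` warns when it bites.
* The integrator clips numerical negativity below $10^{-8} K$ to zero
  at output time and errors on anything larger.
* CSV artifacts carry 17 significant digits, so round-trips are
  lossless and repeated runs byte-identical.

## Simulated worlds and what a green test establishes

The test suite generates its inputs; nothing is fitted to data. Random
parameter draws use threshold means in $[0.25, 0.8]$, variances in
$[0.005, 0.09]$, rates in roughly $[0.05, 2]$ and rosy beliefs
$\tilde p \in [0.85, 0.999]$ constrained by $F(\tilde p)\le\tilde p$ —
the regime the model is about. Green tests establish internal
consistency (closed forms vs. integration, raw vs. reduced
formulations, scan folds vs. tangency solves) and reproduction of the
qualitative regime structure (fold counts and ordering, hysteresis
windows, cycling and bursting) under the canonical parameter values.
They do not establish anything about empirical communities: the model
has no data interface, thresholds are exactly normal and unimodal, the
population is well-mixed and infinite (no demographic noise), and
entry/exit is uncorrelated with individual type.

## Known limitations

* Oscillation classification relies on peak statistics of $I(t)$;
  exotic attractors (quasi-periodic, chaotic) would be reported as
  `limit_cycle` or `bursting` by their peak signature.
* Fold refinement assumes the mixed-equilibrium count changes by a
  detectable amount across the fold on the scan grid; folds narrower
  than the grid spacing need a finer grid.
* The boundary (crash) analysis covers the two physically motivated
  basins; a hypothetical third boundary attractor would be missed.
* The TOML reader supports the subset used by run configs (sections,
  scalars, flat arrays), not the full TOML standard.
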