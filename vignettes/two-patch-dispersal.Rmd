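---
title: "Dispersal and total population size in two-patch models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersal and total population size in two-patch models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twopatch)
```

## The question

A population living on two habitat patches connected by symmetric
dispersal reaches, in the long run, a total size that may be larger or
smaller than the sum of the two carrying capacities. Conservation
measures that raise connectivity (corridors, stepping stones,
translocation) effectively raise the dispersal rate, so the shape of the
map from dispersal rate to asymptotic total population size decides
whether such measures help or hurt. This package computes that map, its
closed-form features, and the exact parameter conditions separating the
four qualitative outcomes.

## Models

Both patches are *sources*: isolated, each converges to its carrying
capacity. Patch $i \in \{A, B\}$ has intrinsic growth rate $r_i$ and
carrying capacity $K_i$.

**Discrete time (Beverton–Holt).** Growth acts first,
$f_i(N) = r_i N / (1 + \xi_i N)$ with competition strength
$\xi_i = (r_i - 1)/K_i$ and $r_i > 1$; then a fraction
$\delta \in [0, 1]$ of each patch's output moves to the other patch:
$$N_{A,t+1} = (1-\delta) f_A(N_{A,t}) + \delta f_B(N_{B,t}), \qquad
  N_{B,t+1} = (1-\delta) f_B(N_{B,t}) + \delta f_A(N_{A,t}).$$
$\delta = 0.5$ is perfect mixing (the patches are equal after one step)
and $\delta \in (0.5, 1]$ is the replacement regime, with $\delta = 1$
swapping the patch outputs entirely.

**Continuous time (logistic).** $f_i(N) = r_i N (1 - N/K_i)$ with
$r_i > 0$ and $\xi_i = r_i / K_i$, coupled by a flux
$\delta_c (N_A - N_B)$, $\delta_c \ge 0$. Perfect mixing is the limit
$\delta_c \to \infty$; there is no replacement regime.

The object of study is the dispersal-response function
$$H(\delta) = N_A(\delta) + N_B(\delta) - (K_A + K_B),$$
where $(N_A(\delta), N_B(\delta))$ is the globally attracting positive
equilibrium. $H > 0$ means dispersal is beneficial. $H$ is either
strictly monotone or unimodal, it vanishes at $\delta = 0$, and it can
vanish at most once more. Four scenarios exhaust the possibilities:
monotonically beneficial, unimodally beneficial, beneficial turning
detrimental, and monotonically detrimental. Equal carrying capacities
are neutral: $H \equiv 0$ regardless of dispersal.

## Closed forms and classification

All analytic quantities are implemented symbol-faithfully from the
parameters alone:

* the second zero $\tilde\delta$ of $H$ (a rational expression in
  $r_i, K_i$; reported only when it falls in $(0, 1]$),
* the maximum subpopulation sizes $\bar N_B$ (largest root of a
  quadratic $a y^2 + b y + c$) and $\bar N_A$, and from them the argmax
  $\delta_{max}$,
* the right derivative
  $H'(0^+) = (r_A - r_B)(K_A - K_B) / ((r_A - 1)(r_B - 1))$,
* the complete-replacement equilibrium $N_A(1), N_B(1)$ and the maximum
  attainable total,
* continuous-time limits $H_c(\infty)$, $H_c'(0^+)$, the
  large-dispersal slope criterion, and the threshold constants
  $\kappa_d$ and $\kappa_c$.

The classifiers (`classify()`) first canonicalize the patch labels
(discrete: $r_B \le r_A$; continuous: $K_A \le K_B$), dispatch the
degenerate equalities ($K_A = K_B$ neutral; $r_A = r_B$ folded into
monotonically detrimental, matching its qualitative shape), then apply
the threshold inequalities on the capacity ratio $K_B / K_A$ (discrete)
or the competition strengths $\xi_A, \xi_B$ (continuous).

Two genuinely open design points were resolved as follows.

**Orientation of $\kappa_d$.** The two printed forms of the discrete
threshold constant conflict in orientation: evaluated with the faster
patch in the denominator the constant falls below 1, which would make
the unimodal band $[\rho, \kappa\rho)$ empty. We use the orientation
with the faster growth rate in the numerator, which is always above 1
and is the numerically verifiable one: the unimodal worked example's
capacity ratio then falls inside the band, and random draws confirm the
band boundaries against the numeric argmax.

**Restricted-range classification.** For comparison with continuous
time, discrete models can be classified on $[0, 0.5]$
(`classify(m, range = "half")`). The authoritative route compares the
closed-form $\tilde\delta$ and $\delta_{max}$ against $0.5$, which
sidesteps the $\kappa$ orientation question entirely; the
threshold-inequality route is kept as an independent cross-check in the
test suite and agrees on all non-boundary draws.

A continuous-time worked example whose published qualitative label
disagrees with the classification conditions (its competition strengths
satisfy the beneficial-turning-detrimental inequality) is deliberately
not used as a golden fixture; the classifier follows the conditions.

## Numerical choices

* **Discrete equilibrium.** The coupled map is globally convergent, so
  we iterate from $(K_A, K_B)$ until the step change is below $10^{-8}$,
  then polish with Newton on the fixed-point residual using the analytic
  Jacobian, to a sup-norm residual of $10^{-12}$. Iteration alone slows
  down near scenario thresholds; the Newton tail makes every equilibrium
  cheap and uniformly accurate. Grid sweeps warm-start Newton from the
  neighbouring grid point and fall back to plain iteration if the polish
  strays.
* **Continuous steady state.** Integration with `deSolve::ode` (lsoda,
  which copes with the stiffness induced by large $\delta_c$) until the
  field norm is below $10^{-9}$, then the same damped-Newton polish on
  the vector field. "Infinite dispersal" is represented by the
  closed-form limit; $\delta_c = 10^4$ serves as the numerical stand-in
  when a finite evaluation is needed.
* **Anchor value.** $H(0)$ is returned as exactly 0 by definition rather
  than as a numerical difference, avoiding cancellation noise.
* **Default grids.** 201 points: uniform on $[0,1]$ in discrete mode;
  $\{0\} \cup$ 200 log-spaced points on $[10^{-4}, 10^4]$ in continuous
  mode. The log spacing matters: near the equal-growth-rate boundary the
  sign change of $H$ can sit far below any uniform spacing, and a
  uniform grid then misrepresents the curve's shape. For the same reason
  the empirical classifier (`classify_empirical()`, used as an oracle
  against the analytic conditions) should be fed log-spaced curves when
  scanning random parameter sets; its zero tolerance is $10^{-8}$,
  comfortably above the $\sim 10^{-11}$ noise of polished equilibria and
  below the amplitude of genuine narrow response humps away from region
  boundaries.
* **Searches.** The argmax search seeds `stats::optimize`
  (golden-section) with a 101-point coarse scan — valid because $H$ is
  monotone or unimodal — and returns the endpoint when the scan peaks
  there; ties break toward smaller $\delta$. The zero search brackets
  the single possible sign change on a coarse grid and refines with
  `stats::uniroot`.
* **Boundary handling.** Threshold comparisons follow the non-strict /
  strict pattern of the classification statements; inputs within a
  relative $10^{-9}$ of a defining equality are flagged
  (`boundary = TRUE`) so that sweeps and property tests can exclude
  them rather than assert on coin-flip cases.

## The scenario sampler

`generate_scenario_params()` draws $r_i$ uniformly (defaults: $[1.1, 4]$
discrete, $[0.2, 3]$ continuous — well inside the source regime and wide
enough to populate all four scenarios) and $K_i$ uniformly on
$[0.5, 5]$, then rejection-samples on the analytic classification with a
$10^{-3}$ boundary margin. Equal capacities are enforced by construction
for the neutral target, which otherwise has probability zero. The
sampler is fully determined by its seed and restores the global RNG
state.

What these synthetic draws emulate is parameter heterogeneity between
two source patches under exact, symmetric, cost-free dispersal and
deterministic dynamics. They do not emulate demographic or environmental
stochasticity, dispersal mortality, asymmetric or density-dependent
dispersal, or source–sink configurations — so passing tests demonstrate
the correctness of the deterministic theory's implementation, not its
robustness to those real-world features.

## Problem sizes used in the test suite

Property tests use 50 parameter draws × 10 initial states for global
convergence, 200 non-boundary draws per time mode for
analytic-vs-empirical classifier agreement on 201-point curves, an $8^4$
parameter lattice per mode for label reachability, and 2001-point dense
scans as argmax oracles. These sizes resolve every feature of the worked
examples while keeping the full suite under a minute.

## Known limitations

* Only symmetric dispersal between exactly two source patches; no
  $n$-patch networks, no multi-species interactions.
* No closed-form argmax exists in continuous time (only existence is
  guaranteed in the unimodal scenario); `numeric_argmax_H()` is the tool
  there.
* Classification exactly on a region boundary is decided by the
  non-strict inequality of the governing statement and flagged, but
  boundary values themselves (does $\delta_{max}$ hit exactly 0 or 1?)
  carry no theoretical guarantee and are excluded from property tests.
* The replacement regime $\delta \in (0.5, 1]$ exists only in discrete
  time; comparisons between the two time modes are meaningful on the
  isolation-to-perfect-mixing range only.
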