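---
title: "Hierarchical estimation of ODE models from relative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical estimation of ODE models from relative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Quantitative models of signaling pathways are ordinary differential
equations

$$\dot x = f(x(t,\theta), \theta), \qquad x(t_0,\theta) = x_0(\theta),$$

whose states $x \in \mathbb{R}^{n_x}$ are species concentrations and whose
dynamic parameters $\theta \in \mathbb{R}^{n_\theta}$ (rate constants,
initial-condition parameters) must be estimated from data. Most of the data
available for such models — Western blots, qRT-PCR, much of mass
spectrometry and cytometry — are *relative*: the readout is proportional to
a concentration, with an unknown proportionality constant per blot,
antibody, or experiment. Writing $h$ for the observation map, a measurement
of observable $i$ at time $t_k$ is modelled as

$$\bar y_{i,k} = s \cdot h_i(x(t_k,\theta), \theta) + \varepsilon_{i,k},$$

with a scaling parameter $s$ and measurement noise $\varepsilon$. The noise
is Gaussian, $\varepsilon \sim \mathcal N(0, \sigma^2)$, or — more robust
when the data contain outliers — Laplace,
$\varepsilon \sim \mathrm{Laplace}(0, \sigma)$. Which records share an $s$
or a $\sigma$ is part of the experimental design: the common layout has one
pair per observable, Western-blot replicates often get one pair per
observable/replicate combination, and parameters may be shared across
observables or experiments. `hierode` expresses this as an explicit
record-to-group map (`parameter_structure()`), with the per-observable
layout as the default constructor.

Maximum-likelihood estimation minimizes the negative log-likelihood
$J(\theta, s, \sigma)$. The *standard* approach optimizes all parameters
$q = (\theta, s, \sigma)$ jointly — for the bundled case-study skeletons
that is 16 (`jakstat1`), 112 (`jakstat2`) and 28 (`rafmekerk`) variables,
of which 5, 54 and 16 are scaling/noise nuisance parameters.

## The hierarchical reformulation

The nuisance parameters enter $J$ only through the residuals, so at any
fixed $\theta$ the inner problem

$$(\hat s(\theta), \hat\sigma(\theta)) = \arg\min_{s,\sigma}
  J(\theta, s, \sigma)$$

can be solved *without further ODE simulation*, and the outer optimization
runs over $\theta$ alone:

$$\min_\theta\; J(\theta, \hat s(\theta), \hat\sigma(\theta)).$$

The value of the reformulation comes from the inner problem having
closed-form (or cheap one-dimensional) solutions:

* **Gaussian, linear scale.** For a group whose records share one $s$ and
  one $\sigma$,
  $\hat s = \sum_k \bar y_k h_k / \sum_k h_k^2$ and
  $\hat\sigma^2 = \tfrac1n \sum_k (\bar y_k - \hat s h_k)^2$ — the
  precision-weighted least-squares slope through the origin and the $1/n$
  (biased, maximum-likelihood) variance. `gaussian_inner()`.
* **Gaussian, log10 scale.** When residuals are formed on $\log_{10}$
  scale, $s$ acts additively in log space:
  $\log_{10}\hat s$ is the mean log-ratio, $\hat\sigma^2$ the $1/n$
  variance of the log-residuals. `log10_gaussian_inner()`.
* **Laplace.** $J$ is piecewise linear in $s$ with kinks at the jump
  points $s_k = \bar y_k / h_k$; the derivative between kinks is
  $-\frac1\sigma \sum_k |h_k| \operatorname{sgn}(\bar y_k/h_k - s)$.
  Sorting the jump points and checking the derivative sign at segment
  midpoints finds the minimizing kink — equivalently the $|h|$-weighted
  median of the ratios — after which
  $\hat\sigma = \tfrac1n \sum_k |\bar y_k - \hat s h_k|$.
  `laplace_inner_scaling()`, `laplace_inner_noise()`.
* **Coupled sharing.** If a scaling group spans several noise groups with
  unknown $\sigma$ (e.g. one $s$ shared across observables), no
  single-group formula applies. `solve_inner()` then alternates the
  closed-form block updates (precision-weighted $s$, then each $\sigma$)
  until the objective decrease falls below $10^{-10}$ or 100 iterations.
  The block updates are exact conditional minimizers, so the descent is
  monotone for Gaussian noise; for Laplace noise monotonicity is asserted
  each iteration and a violating update is replaced by a one-dimensional
  refinement over the group's jump-point range.

At the inner optimum the objective collapses to closed form —
$J = \sum_g \frac{n_g}{2}(\log(2\pi\hat\sigma_g^2) + 1)$ for Gaussian and
$J = \sum_g n_g(\log(2\hat\sigma_g) + 1)$ for Laplace — which the test
suite uses as an exact consistency check.

The outer gradient uses the envelope simplification: because the inner
stationarity conditions hold at $(\hat s, \hat\sigma)$ (everywhere for
Gaussian, almost everywhere for Laplace), the total derivative of the
profiled objective equals the partial derivative
$\partial J/\partial\theta$ at fixed $(\hat s, \hat\sigma)$, computed from
forward sensitivities. A point that is locally optimal for the joint
problem and interior to the bounds is locally optimal for the hierarchical
problem, and conversely the joint gradient vanishes at a hierarchical
optimum — both directions are tested.

## Numerical choices

* **Integration.** `deSolve::lsoda` (stiff-capable, as signaling models
  require), absolute/relative tolerances $10^{-8}/10^{-6}$. Sensitivities
  are integrated as one augmented variational system
  $\dot S_x = (\partial f/\partial x) S_x + \partial f/\partial\theta$;
  model plugins may supply analytic Jacobians (all built-ins do), otherwise
  central finite differences on the right-hand side are used. Integrator
  failures are encoded in the result and surface as $J = +\infty$, never as
  an exception, so multi-start optimization survives pathological draws.
* **Optimizer.** Bound-constrained L-BFGS-B on $\log_{10}$-transformed
  parameters (default bounds $[10^{-5}, 10^5]$), gradient tolerance
  `pgtol = 1e-8`, function tolerance `factr = 1e4`, at most 2000
  iterations. The tight tolerances matter for the best-likelihood
  agreement between the two formulations; the looser L-BFGS-B defaults
  stop the higher-dimensional joint problem visibly short of the optimum.
  A gradient-free Nelder-Mead fallback is exposed for Laplace problems,
  whose objective is non-smooth at the kinks; the default gradient-based
  treatment uses a valid subgradient element there (right-hand derivative
  in $s$) and flags the event.
* **Start points.** Uniform on the $\log_{10}$-transformed box, seeded.
  Starts are always drawn for the full vector $q$; hierarchical runs use
  the $\theta$ block. The two approaches therefore see *matched* starting
  points and a comparison isolates the effect of the reformulation — a
  stricter protocol than pooling independent multi-starts, and it is what
  `compare_approaches()` reports.
* **Convergence accounting.** A start counts as converged when its final
  $J$ is within a likelihood-ratio threshold —
  $\tfrac12\chi^2_{0.95,1} \approx 1.92$, configurable — of the best value
  found *across both approaches* (waterfall semantics). The degrees of
  freedom of this threshold are a documented choice, not a published
  value.
* **Degenerate cases.** A scaling group whose simulated observables are all
  zero is unidentifiable and raises an error naming the group. Noise-free
  groups yield $\hat\sigma = 0$; the objective layer floors $\sigma$ at
  $10^{-10}$ inside the likelihood and flags the result, keeping $J$
  finite in noise-free tests while the inner solvers remain pure functions
  of their inputs. Laplace records with $h = 0$ contribute no jump point
  (their term does not depend on $s$). In the Laplace kink-search, a
  segment with exactly zero derivative (even total weight) is a flat
  optimum; the lower adjacent jump point is returned, a deterministic
  tie-break that any equal-objective oracle accepts.

## The synthetic benchmark generator

The published calibration problems that motivate the method use
proprietary experimental data, so the package tests itself on synthetic
problems with known ground truth (`synthetic_spec()`,
`generate_problem()`). Three topologies mirror the archetypes of those
case studies:

* `conversion_reaction` — reversible $A \rightleftharpoons B$ with known
  initial composition $(1, 0)$; both species observed. The smallest
  well-posed two-scaling problem.
* `cascade3` — a three-tier phosphorylation cascade (RAF/MEK/ERK-type
  structure) observed in a *washout* design: at $t_0$ the cells are in a
  known stimulated state $x_0 = (0.9, 0.8, 0.6)$ and relax after stimulus
  reduction; the two lower tiers (pMEK-, pERK-like) are observed. The
  known nonzero initial phosphorylation anchors the absolute scale of the
  trajectories. This matters: in a zero-initial-condition activation
  cascade the first tier is a linear subsystem whose amplitude trades off
  exactly against downstream gain and the scaling parameters, so scalings
  are structurally non-identifiable there — a washout design (or,
  in the real pathway, feedback that pins absolute levels) removes the
  degeneracy.
* `spline_input_pathway` — a receptor-driven pathway (JAK-STAT-type
  structure) forced by a fixed smooth input $u(t) = e^{-0.2t} - e^{-2t}$.
  The input is a deliberate simplification: estimating the receptor time
  course itself (via splines) is case-study-specific machinery and out of
  scope here.

Defaults are chosen as a scientist would design such an experiment:
relative noise at 10% of the mean absolute scaled signal per group
(absolute $\log_{10}$ standard deviation for log-scale designs), true
scalings spread over $[1.5, 4]$, 10–20 time points equally spaced over the
response, with the $t = 0$ baseline sample included for linear-scale
designs (it anchors the known initial state; log-scale designs start after
$t_0$ because their observables must be strictly positive). Outliers, when
requested, follow a scale-contamination model: the chosen fraction of
records receives noise drawn with $5\times$ inflated scale. The grouping
recipes `per_observable`, `per_replicate` and `shared` generate the
analytic, replicate-blot and coupled inner-solver regimes respectively.

`benchmark_suite()` fixes three desk-scale instances — *small*
(conversion reaction), *medium* (input-driven pathway, three replicates
sharing scalings), *robust* (cascade with per-replicate scalings, Laplace
noise, 10% outliers) — used by the convergence comparison.

What the generator does *not* emulate: real immunoblot noise is neither
exactly Gaussian nor exactly Laplace and often heteroscedastic beyond the
per-group model; time points in real studies are irregular and sparse;
model misspecification (the real pathway is not the fitted ODE) is absent
by construction. Passing tests therefore demonstrate the correctness and
the comparative behaviour of the optimization machinery, not performance
on any particular laboratory dataset.

## Problem sizes used by the checks

The automated checks run the full pipeline at deliberately modest sizes,
chosen so the whole battery completes on a single CPU in well under an
hour while every claim is still exercised end-to-end: 200 random
single-group instances per noise configuration against a $40 \times 40$
grid-plus-refinement oracle; for the best-likelihood agreement, 50 matched
starts per approach on the conversion problem and, on the cascade — whose
joint formulation reaches the global basin in only a few percent of starts
— 50 hierarchical against 150 standard starts from the same seeded
sequence (published multistart protocols likewise scale the number of
starts to the problem); ten (tests) or six (acceptance script) seeded
replicates of the benchmark suite at six starts per approach for the
convergence comparison; and eight-to-ten seeded cascade replicates at
$n_k = 20$ time points for parameter recovery. The recovery check asks
that the truth lie within three times the Monte-Carlo spread of the
estimates and that scalings be recovered to 10% in the median across
replicates — medians, because a single replicate's scaling error at 10%
noise and $n_k = 20$ fluctuates by several percent around zero by sampling
alone.

## Known limitations

* Offset/background parameters (unspecific binding) are not eliminated
  analytically; only scalings and noise parameters are.
* Adjoint sensitivities are not implemented; forward sensitivities scale
  linearly in $n_\theta$ and are the right tool at these model sizes.
* Laplace optimization inherits the non-smoothness of the objective;
  L-BFGS-B with subgradients works well in practice here, but the
  Nelder-Mead fallback exists precisely because no gradient-based
  guarantee is available at kinks.
* The coupled (coordinate-descent) inner solver handles scaling groups
  that mix linear and log10 observables only by refusing them; such
  designs are rare and better expressed as separate groups.
* Profile likelihoods and confidence intervals are out of scope; the
  package reports point estimates and multi-start diagnostics.

## A worked example

```{r, eval = FALSE}
library(hierode)

# a synthetic Western-blot-style problem with known ground truth
gen <- generate_problem(synthetic_spec("cascade3", seed = 1, n_times = 20))
problem <- gen$problem
problem

# hierarchical multi-start estimation
fit <- multistart_optimize(problem, "hierarchical", n_starts = 10, seed = 1)
fit
glance(fit)

# compare against joint optimization with matched starts
cmp <- compare_approaches(problem, n_starts = 10, seed = 1)
cmp$summary
autoplot(cmp)      # waterfall plot
plot_fit(problem, unname(fit$best_parameters$theta),
         fit$best_parameters$scalings)
```
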