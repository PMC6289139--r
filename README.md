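# hierode

Hierarchical maximum-likelihood estimation of ODE model parameters from
**relative data** — Western blots, qRT-PCR, cytometry — where each
measurement is proportional to a model observable through an unknown
scaling factor.

## The problem and the method

A signaling-pathway model
$\dot x = f(x(t,\theta),\theta)$, $x(t_0) = x_0(\theta)$ is observed
through $h$, and a relative measurement of observable $i$ at time $t_k$ is

$$\bar y_{i,k} = s\, h_i(x(t_k,\theta),\theta) + \varepsilon_{i,k},
\qquad \varepsilon \sim \mathcal N(0,\sigma^2)\ \text{or}\
\mathrm{Laplace}(0,\sigma).$$

The scaling parameters $s$ and noise parameters $\sigma$ are nuisance
parameters that must normally be estimated jointly with the dynamic
parameters $\theta$, inflating the optimization problem (the bundled
case-study skeletons have 5, 54 and 16 such parameters on top of 11, 58
and 12 dynamic ones). `hierode` instead solves the **hierarchical**
reformulation

$$\min_\theta J(\theta, \hat s(\theta), \hat\sigma(\theta)),
\qquad (\hat s, \hat\sigma) = \arg\min_{s,\sigma} J(\theta, s, \sigma),$$

where the inner problem is solved *analytically* on the already-simulated
observables — no extra ODE integrations:

| noise / scale | $\hat s$ | $\hat\sigma$ |
|---|---|---|
| Gaussian, linear | $\sum_k \bar y_k h_k / \sum_k h_k^2$ | $\hat\sigma^2 = \frac1n\sum_k(\bar y_k - \hat s h_k)^2$ |
| Gaussian, log10 | $\log_{10}\hat s = \overline{\log_{10}\bar y - \log_{10} h}$ | $1/n$ variance of log-residuals |
| Laplace | kink-search over sorted jump points $\bar y_k/h_k$ ($\lvert h\rvert$-weighted median) | $\frac1n\sum_k \lvert\bar y_k - \hat s h_k\rvert$ |

Scaling/noise parameters may be shared across time points, replicates,
observables or experiments via an explicit record-to-group map; coupled
sharing patterns fall back to monotone coordinate descent with closed-form
blocks. The outer problem is solved by seeded multi-start L-BFGS-B on
log10-transformed parameters with exact forward-sensitivity gradients
(envelope theorem for the profiled objective), and
`compare_approaches()` benchmarks the hierarchical against the standard
joint formulation with matched starting points.

## Worked example

```r
library(hierode)

# synthetic Western-blot-style problem: 3-tier cascade, 2 observables,
# per-observable scaling and noise parameters, 10% Gaussian noise
gen <- generate_problem(synthetic_spec("cascade3", seed = 1, n_times = 20))
problem <- gen$problem
problem
#> <estimation_problem> model 'cascade3', 40 records, gaussian noise
#>   parameters: 10 total = 6 dynamic (outer) + 4 scaling/noise (inner)

fit <- multistart_optimize(problem, "hierarchical", n_starts = 10, seed = 1)
fit
#> <multistart_result> hierarchical approach, 10 starts (seed 1)
#>   best J = -35.07491, converged fraction = 0.3

round(unname(fit$best_parameters$scalings), 3)   # truth: 1.5, 4.0
#> [1] 1.459 3.922

cmp <- compare_approaches(problem, n_starts = 10, seed = 1)
cmp$summary
#> # A tibble: 2 × 6
#>   approach     n_starts converged_fraction best_J total_time cpu_per_converged
#> 1 standard           10                0.1  -34.7       51.2              51.2
#> 2 hierarchical       10                0.3  -35.1       41.9              14.0
autoplot(cmp)   # likelihood waterfall plot
```

The best negative log-likelihood (`best_J`) is the quantity both
approaches minimize; the `converged_fraction` counts starts whose final
value lies within a likelihood-ratio threshold (≈1.92) of the best value
found across both approaches; `cpu_per_converged` is total wall time
divided by the number of converged starts. Here the hierarchical
formulation (6 optimization variables instead of 10) converges three times
as often and costs a fraction of the time per converged start; the fitted
scalings recover the generating values 1.5 and 4.0 to a few percent.

Problems can also be defined from files — a PEtab-flavoured measurement
TSV, a parameter-structure TSV and a YAML bundle (`read_problem()`,
`write_problem()`) — and driven from the shell via the thin CLI in
`inst/cli/hierode` (`estimate`, `benchmark`, `simulate-data` subcommands).

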