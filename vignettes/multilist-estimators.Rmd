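---
title: "Comparing multiple-list population-size estimators by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing multiple-list population-size estimators by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recapsim)
```

Estimating the size of a hidden population from several partially
overlapping lists (service rosters, survey rounds, program registries) is a
standard problem in epidemiology, where such estimates drive the targeting
of HIV services to key populations.  The difficulty is that the population
size $N$ is not identified without assumptions on how encounter
probabilities vary — across individuals, across lists, or in response to a
first encounter — and different estimators respond very differently to
violations of those assumptions.  `recapsim` provides a tested pipeline for
studying exactly that: it simulates encounter histories under controlled
patterns of inhomogeneity and compares three estimators on the simulated
truth.

## The data-generating model

Each of $N$ population members is exposed to $K = 5$ lists.  Member $j$
appears on list $k$ with probability $p_{jk}$, and the capture indicators
$y_{jk} \sim \mathrm{Bernoulli}(p_{jk})$ are independent given the
probabilities.  Before any behavioral response, every $p_{jk}$ is
marginally $\mathrm{Beta}(\beta_1, \beta_2)$, with shapes solved from a
mean encounter probability $E(p)$ and a coefficient of variation
($\mathrm{cv} = 0.85$ across the study design):

$$ s = \frac{1-m}{m\,\mathrm{cv}^2} - 1,\qquad
   \beta_1 = m s,\qquad \beta_2 = (1-m)s. $$

```{r}
beta_shapes(0.025, 0.85)
```

Six patterns control how draws are shared:

* **Mh** (individual heterogeneity): one draw per individual, constant
  across lists.
* **Mt** (temporal variation): one draw per list, shared by everyone.
* **Mb** (behavioral response): the constant mean before first capture;
  afterwards the probability is multiplied by 0.5.
* **Mth, Mbh, Mtbh**: combinations of the above.

For the combined patterns the generator uses a shared-factor Gaussian
copula: standard-normal individual and temporal factors are averaged with
equal weights and mapped through the Beta quantile function.  This keeps
the *list-wise marginal distribution* of $p_{jk}$ exactly
$\mathrm{Beta}(\beta_1, \beta_2)$ for every pattern — the property the
design states — while inducing within-individual and within-list
correlation (each factor contributes half the variance of the Gaussian
score).  For single-effect patterns the construction reduces to a plain
Beta draw.  An alternative we considered, multiplying an individual draw
by a normalized list draw, inflates the list-wise coefficient of variation
to about 1.4 and destroys the Beta marginal, so it was rejected.

The all-zero history is unobservable: rows with no captures are removed at
generation, and again after truncating to the first $K_{use}$ lists
(`collapse_frequencies()`), since an individual seen only on list 5 is
invisible to a 3-list analysis.

The generator is validated against closed forms: the probability of a
first encounter on list $k$ for a Beta-heterogeneous individual is

$$ E[p_1(k)] = \frac{B(\beta_1 + 1, \beta_2 + k - 1)}{B(\beta_1, \beta_2)}, $$

whose sum over $k \le K$ is the expected observed fraction
(`expected_observed_fraction()`); at $E(p) = 0.2$ and five lists about
54.7% of the population is seen at least once.

```{r}
round(100 * expected_observed_fraction(beta_shapes(0.2, 0.85), 5), 1)
```

## The three estimators

### AIC-selected loglinear models (LLM-AIC)

The observed capture-history counts over the $2^K - 1$ observable cells
follow a Poisson loglinear model whose columns depend on the assumed
pattern (`llm_design()`): a capture-count column for exchangeable models, a
per-list indicator for temporal models, a post-first-capture exposure
column ($K - f(\omega)$, with $f$ the list of first capture) for
behavioral models, and for heterogeneity models one extra column that is a
fixed function of the capture count $c$ — `Poisson2` ($2^c - 1$, the study
default), `Darroch` ($c^2/2$) or `Gamma3.5`
($-\log(c + 3.5) + \log 3.5$).  The candidate set is
$\{Mb, Mt, Mh, Mbh, Mth\}$ for three or more lists; with two lists only
$\{M0, Mt\}$ are estimable from the three observable cells.  The
smallest-AIC converged fit is selected, with ties broken toward fewer
parameters.

All covariates vanish on the all-zero history, so the intercept
extrapolates to the unobserved cell and $\hat N = n + e^{\hat\beta_0}$ —
except under Mb, where that extrapolation is *algebraically inconsistent*:
the intercept converges to
$\log\{N p (1-p)^{K-1} (1-p_b)/p_b\}$, not to $\log\{N(1-p)^K\}$.  Because
the capture-count slope is $\mathrm{logit}(p_b)$ and the behavioral-column
slope is $\log(1-p_b) - \log(1-p)$, both probabilities are identified and
the factor $(p_b/(1-p_b)) \cdot ((1-p)/p)$ restores consistency; with it
the Mb estimator is exact under its own model.  We do **not** apply the
factor to Mbh: there the heterogeneity column contaminates the slope
recovery, and on Beta-heterogeneous behavioral populations the corrected
extrapolation lands about 32% below the truth versus about 10% for the
plain intercept, so the plain form is kept.

Uncertainty uses profile likelihood: for each candidate total $N$ the
all-zero cell is completed with $N - n$, the loglinear parameters are
re-maximized, and the Poisson profile is converted to the multinomial one
through the $\mathrm{Poisson}(N; N)$ total term.  The interval is the set
of integer $N$ within the $\chi^2_1$ quantile of the profile maximum,
located by a geometric grid plus bisection (deviance tolerance is the
integer grid itself); a monotone profile is reported as capped at `N_max`
(default $21n$) with a flag.  Estimates can legitimately explode on
zero-heavy tables; they are never truncated, and summaries render
anything beyond $10^9$ with a `> 10^9` sentinel.

### Bayesian model averaging over decomposable models (LLM-BMA)

Every chordal graph on the $K$ lists defines a decomposable loglinear
model — 8, 61 and 822 models for $K = 3, 4, 5$ (`enumerate_decomposable()`,
validated against a brute-force induced-cycle test).  Under a
hyper-Dirichlet prior with cell mass $\delta = 2^{-K}$ the marginal
likelihood of a completed table factorizes over clique and separator
margins into Dirichlet-multinomial terms, computed in log-Gamma space
(`log_marginal()`).  The posterior over the unobserved count $n_0$ is
evaluated *exactly* on the integer grid $0, \dots, n_{0,\max}$ — we prefer
the exact grid to a Laplace approximation because at these problem sizes
it is both cheap (margins are shared across models and cached per subset)
and free of approximation error.  Models carry a uniform prior; $N$
carries a reciprocal prior $p(N) \propto 1/N$ truncated to the grid
(uniform available), with $n_{0,\max} = 10N$ in study runs, reflecting the
premise that the target size is known within an order of magnitude.  The
point estimate is the posterior median, the interval the central 0.95
quantiles.  Model averaging needs at least three lists; the package
declines two-list tables.

### Bayesian nonparametric latent-class model (BLCM)

A truncated stick-breaking Dirichlet-process mixture of product-Bernoulli
capture profiles, with at most 10 classes and a
$\mathrm{Gamma}(0.25, 0.25)$ hyperprior on the concentration parameter.
The Gibbs sampler (implemented in C++, grouping individuals by distinct
history so a sweep costs $O(2^K \times \text{classes} \times K)$)
cycles through class assignments for observed and augmented all-zero
individuals, conjugate Beta updates of class-list capture probabilities,
stick-breaking fractions, the concentration parameter, and the unobserved
count $n_0$, which under the reciprocal prior on $N$ has a
negative-binomial conditional driven by the mixture probability of the
all-zero history.  Truncated stick-breaking (last stick absorbing the
remainder) was chosen over slice sampling because the study fixes the
truncation level anyway and it keeps the $n_0$ conditional in closed form.
If the all-zero probability underflows to zero, the $n_0$ draw is zero and
the event is counted and surfaced as a warning, never silently clamped.

Chain lengths: the full-study preset discards 500,000 burn-in iterations
and keeps 50,000 of 5,000,000 draws (thin 100) — hours per sample and far
beyond interactive use; the default (burn 10,000, keep 10,000 of 100,000)
and the `"desk"` preset (burn 2,000, keep 2,000 of 20,000) suffice for the
replicated sweeps in the tests, where split-chain scale reduction on
$\log N$ stays below 1.05 (`trace_diagnostics()`).  The posterior summary
is the median with central 0.95 quantiles (the median is robust to the
heavy upper tail of $N$ posteriors; the mean is not reported).

## Study orchestration and reproducibility

`study_config()` describes a full factorial design — replicates × patterns
× $E(p)$ × $N$, each sample analysed at 2–5 cumulative lists by the
enabled methods (the full design is $400 \times 6 \times 5 \times 3 =
36{,}000$ samples).  Every sample's seed derives deterministically from
the master seed and the cell coordinates (`derive_seed()`), so any single
sample can be regenerated in isolation and reruns are byte-identical.
Results are tidy data frames; `aggregate_tables()` pools the six
generating patterns within each design cell — mirroring how performance
must be judged for real populations, whose generating process is unknown —
and reports RMSE, bias, interval coverage and relative RMSE, with failed
or non-finite estimates included (they propagate to the `> 10^9`
renderings rather than being dropped).  `match_table()` cross-tabulates
generating patterns against AIC-best labels.

## Numerical choices and degenerate inputs

* All Beta, Gamma and Dirichlet-multinomial computations run in log-Gamma
  space; posterior grids are normalized by max-shifted exponentials.
* `cv = 0` is accepted by the generator as the homogeneous limit (every
  draw equals the mean); the shape solver itself requires `cv > 0` and
  rejects infeasible pairs ($m(1+\mathrm{cv}^2) \ge 1$).
* Singular or non-converged GLM fits are flagged and excluded from AIC
  selection; if no candidate converges the sample is recorded as a
  failure, which counts as non-covering in coverage summaries.
* AIC ties are broken by parameter count, then a fixed label order, making
  selection deterministic.
* The sampler validates its conditionals and stops on non-finite
  parameters rather than clamping.

## What the simulations do and do not show

The generator implements exactly the six stochastic patterns above:
closed population, perfect record linkage across lists, no refusal or
mark-misidentification process, and one global behavioral multiplier.
Real key-population data violate several of these at once, so passing
tests here demonstrate correctness of the estimators under the stated
models, not performance guarantees in the field.  Test and example
problem sizes (hundreds of replicates at $N = 1000$, reduced MCMC chains)
were chosen so the whole suite runs on a laptop; the full-scale presets
reproduce the complete design when time permits.

Known limitations: the two-list loglinear path cannot distinguish
heterogeneity from behavior (only $\{M0, Mt\}$ are estimable); profile
intervals for behavioral models use the intercept-extrapolated zero cell
and may sit asymmetrically around the corrected point estimate; and the
model-averaged posterior inherits whatever prior mass the grid cap
excludes (tail mass beyond $10N$ is negligible in the study cells but not
checked for arbitrary inputs).
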