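# recapsim

Simulation-based evaluation of multiple-list (capture–recapture)
estimators of closed-population size.

Public-health programs need the sizes of hidden key populations — for
example people who inject drugs, female sex workers or men who have sex
with men — to target and evaluate HIV services, and those sizes are
usually estimated from the overlap of several partial lists (service
rosters, survey rounds, registries). With `K` lists there are `2^K - 1`
observable capture histories and one unobservable all-zero history; the
population size `N = n + n0` is the observed count plus the "dark figure"
`n0`, which is not identified without assumptions on how encounter
probabilities vary. `recapsim` simulates populations in which that
variation is controlled, then measures how competing estimators cope.

## What it implements

**Generator.** Encounter histories `y_jk ~ Bernoulli(p_jk)` with
`p_jk ~ Beta(β1, β2)` list-wise, shapes solved from a mean `E(p)` and
coefficient of variation (`s = (1-m)/(m·cv²) - 1`, `β1 = m·s`,
`β2 = (1-m)·s`). Six patterns of inhomogeneity: individual heterogeneity
(Mh), temporal variation (Mt), a behavioral response halving the
probability after first capture (Mb), and their combinations (Mth, Mbh,
Mtbh), built from shared Gaussian factors mapped through the Beta
quantile so the list-wise Beta marginal is preserved in every pattern.
Closed forms validate the generator: the expected fraction first seen on
list `k` is `B(β1+1, β2+k-1) / B(β1, β2)`.

**Estimators.**

* **LLM-AIC** — Poisson loglinear models over the observable cells
  (`{Mb, Mt, Mh, Mbh, Mth}`, heterogeneity corrections Poisson2 / Darroch /
  Gamma3.5), AIC selection, `N̂ = n + exp(β0)` (with an exact
  slope-based correction of the zero-cell extrapolation under Mb), and
  profile-likelihood intervals.
* **LLM-BMA** — Bayesian model averaging over *all* decomposable
  loglinear models (8 / 61 / 822 models for 3–5 lists) with
  hyper-Dirichlet priors (`δ = 2^-K`), exact log-space evaluation of the
  posterior of `n0` on an integer grid capped at `10N`.
* **BLCM** — truncated stick-breaking Dirichlet-process mixture of
  product-Bernoulli capture profiles (≤ 10 classes,
  `α ~ Gamma(0.25, 0.25)`), Gibbs sampling in C++ with negative-binomial
  augmentation of `n0`.

**Evaluation.** Replicated study orchestration with deterministic
per-sample seeds, and RMSE / bias / interval coverage / model-matching
summaries pooled over the generating patterns, with `> 10^9` sentinel
rendering for effectively infinite loglinear estimates.

## Worked example

```r
library(recapsim)

spec <- generator_spec("Mh", N = 1000, mean_p = 0.2, seed = 42)
em   <- simulate_sample(spec)
em
#> Encounter matrix: 557 of 1000 individuals observed (Mh, E(p) = 0.2, 5 lists)

tab <- collapse_frequencies(em, 5)
estimate_llm_aic(tab)
#>    method    N_hat ci_low ci_high n_observed model_label      aic failed
#> 1 LLM-AIC 737.3875    690     793        557          Mh 175.4276  FALSE

bma_posterior(tab, n0_max = 10000)
#> Model-averaged posterior over 822 decomposable models: N_hat = 684 (95% interval 648-735)

run_blcm(em, blcm_config(preset = "desk", seed = 7))
#> Latent-class posterior (2000 draws): N_hat = 740 (95% interval 681-845)
```

The population is strongly heterogeneous (`cv = 0.85`), so about 54.7% of
it is ever observed (`expected_observed_fraction(beta_shapes(0.2, 0.85), 5)`)
and every method underestimates the true size of 1000 — AIC-selected
loglinear estimation lands at 737 (and correctly identifies Mh), model
averaging at 684, the latent-class model at 740. Quantifying exactly this
kind of shortfall across designs is what the package is for:

```r
study <- run_study(study_config(replicates = 50, patterns = c("Mh", "Mt"),
                                N_values = 1000, mean_p_values = 0.2,
                                K_range = 3:5, methods = "llm_aic",
                                master_seed = 1))
study$summary     # RMSE, bias, coverage per design cell
study$matching    # how often AIC picks the generating model
```

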