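# mecell — mixed-effects modeling of single-cell gene expression

Isogenic cells responding to the same stimulus behave differently, and for
stable, strongly induced reporters those differences persist for hours:
they reflect *extrinsic* variability — stable cell-to-cell differences in
expression machinery and physiology — rather than reaction-level
stochasticity. mecell treats this the way population pharmacometrics
treats patients: a standard gene-expression model is fitted to **every
cell individually**, while the population is described by a joint
parameter distribution estimated from all cells at once.

The package is aimed at quantitative biologists with longitudinal
single-cell fluorescence data under a known stimulus schedule (the
defaults emulate yeast under repeated hyperosmotic shocks in a
microfluidic device, observed for 10 h at 6-min resolution).

## The model

Each cell follows

```
dm/dt = k_m u(t) − g_m m        (reporter mRNA)
dp/dt = k_p m   − g_p p         (matured fluorescent protein)
```

driven by a shared stimulus signal u(t) ∈ [0,1] built from the valve
schedule (transport delay + first-order lag). Fluorescence reports
protein with a maturation delay τ and combined additive + multiplicative
Gaussian noise. Across the population, ln(k_m, g_m, k_p, g_p) ~ N(μ, Σ).
Because (c·k_m, k_p/c) produces identical protein trajectories, the
identifiable per-cell quantity is the composite production rate
k_mp = k_m·k_p; the population mean of ln k_p is clamped during
estimation.

Two estimators are provided and deliberately contrasted: the *naive*
approach (independent per-cell maximum-likelihood fits pooled into
empirical moments) and *SAEM* (stochastic approximation EM, estimating
the joint distribution from all trajectories simultaneously). Per-cell
parameters are then obtained as maximum a posteriori estimates under the
fitted population prior. A synthetic-data generator with planted lineage
inheritance and parameter–feature couplings makes the whole pipeline
testable end to end.

## Worked example

```r
library(mecell)

cfg   <- study_config(n_cells = 80, birth_range = c(60, 240))
study <- apply_qc_filters(generate_study(cfg, seed = 7))
input <- build_input(study$schedule)

fit <- fit_saem(study, input,
                saem_config(n_burnin = 150, n_sa = 100, seed = 7))
print(fit$population)
#> Log-normal population model (ln k_m, ln g_m, ln k_p, ln g_p)
#>   mu:    1.263  -2.672  0  -5.038
#>   SD:    0.3965  0.3058  0.3138  0.2366
#>   tau:   12 min;  sigma_add: 12.74896  sigma_mult: 0.1018383
```

The generating truth here was μ = (1.386, −2.526, 0, −5.116), log-SDs
(0.35, 0.30, 0.30, 0.25), τ = 12 min, σ_add = 10, σ_mult = 0.1 — the
delay and noise model are recovered, and the log-means land within a few
percent on 80 cells.

```r
maps <- fit_map_all(study, fit$population, input)
cor(log(maps$table$k_mp), log(study$truth$params$k_mp),
    method = "spearman")
#> [1] 0.9091186
```

The per-cell composite production rate k_mp is strongly recovered (rank
correlation 0.91 with the generating truth) even though k_m and k_p are
individually non-identifiable.

```r
env <- predict_population(fit$population, study$schedule, n = 2000,
                          with_noise = TRUE, input = input)
envelope_coverage(study, env)
#> [1] 0.9788621
```

Resampling the fitted distribution and re-simulating reproduces the
population: 98% of the observed data points fall inside the 95%
prediction band.

```r
inh <- inheritance_test(maps$table, study$lineage,
                        n_pairs = nrow(study$lineage), n_boot = 10000,
                        seed = 7, param_cols = c("k_mp", "g_m", "g_p"))
print(inh)
#> Mother/daughter inheritance bootstrap (52 MD pairs, 10000 resamples of 52)
#>  parameter   mean_md  mean_nmd closeness_pct p_value
#>       k_mp 0.5101194 0.6735721      24.26655  0.0359
#>        g_m 0.2922855 0.3436784      14.95375  0.1286
#>        g_p 0.2122447 0.2573231      17.51824  0.0894
```

MAP parameters of daughters are 15–24% closer to their own mother's than
to another mother's (the generator plants lineage correlation ρ = 0.3);
with only 52 pairs the bootstrap evidence is suggestive for k_mp and
weaker for the decay rates — power grows with the number of tracked
divisions.

Further analyses: `correlate_features()` (Spearman parameter–feature
matrix), `pca_rank()` (variance-weighted feature ranking),
`perceived_shock()` (per-cell stimulus intensity from volume traces),
`robustness_experiment()` (cell-count / horizon sweeps), and
`run_pipeline()` to execute the configured stages end to end with seeded,
bit-reproducible artifacts.

## The methods vignette

`vignettes/mecell-methods.Rmd` documents the model and its assumptions,
the SAEM implementation choices (proposal kernels, the ln k_p mean
constraint, the delay profile, annealing and error-update scheduling),
what the synthetic generator does and does not emulate, and known
limitations.
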