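# bisectmeta

Tools for studying **time perception and temporal metacognition** with the
two-interval bisection paradigm. In each trial-pair an observer bisects the
same stimulus interval twice (releasing a button at the perceived midpoint)
and then makes a second-order forced choice: *which of my two estimates was
closer to the true midpoint?* The package simulates such sessions, computes
the descriptive analyses used for them, and fits a hierarchical Bayesian
measurement model that separates **bisection precision** from
**metacognitive precision**.

## What it computes

**Ideal-observer re-sorting and the Metacognitive Index.** Trial-pairs are
re-sorted into "best"/"worst" sets twice: by the observer's own choices
(subjective) and by distance to the veridical midpoint (ideal). With `V` the
unbiased sample variance of each set,

```
MCI = (V_i.best / V_i.worst) / (V_s.best / V_s.worst)
```

equals 1 for an observer with perfect insight into their own trial-by-trial
accuracy and tends to 0 when the choices carry no information.

**A hierarchical Bayesian measurement model.** Per trial, the two estimates
are `I_k ~ Normal(phi_c, sigma_Ik)` with condition midpoints `phi_c` drawn
around a grand midpoint centred on the veridical one; the metacognitive
choice is Bernoulli with probability
`Phi(-(|I_1 - phi| - |I_2 - phi|) / sigma_m)` — a probit read-out of the
perceived error difference with metacognitive SD `sigma_m`. Subject-level
precisions (`1/sigma^2`, uniform group priors on [0, 100]) are coupled across
the V/A/AV modality conditions through a multivariate normal with a
subject-specific correlation `rho[s]` and an epsilon-regularised covariance.
Sampling is MCMC (JAGS via rjags; default 2 chains, 2000 burn-in, 5000
samples thinned by 20) with split rank-normalised R-hat diagnostics, 95%
highest-density intervals, DIC comparison of the full model against a
variant whose SDs are constrained equal across conditions, and
posterior-predictive MCI distributions.

**A forward simulator** generates sessions from the same generative model
(500 trials in blocks of 100, truncated estimates, optional early-session
drift, hierarchically sampled observers), standing in for raw subject data
and powering parameter-recovery checks.

## Worked example

```r
library(bisectmeta)

# five observers, 1.5 s interval, veridical subjective midpoint 0.75 s
group <- list(phi = 0.75, sigma_i1 = 0.15, sigma_i2 = 0.15,
              sigma_meta = 0.5, rho = 0.6, phi_sd = 0, subject_lsd = 0.2)
obs <- sample_observers(group, 5, seed = 42)
trials <- simulate_study(obs, total_duration = 1.5,
                         schedule = schedule_spec(100, 100), seed = 42)

head(describe_session(trials)[, c("subject_id", "condition", "mci",
                                  "relative_bisection")])
#>    subject_id condition       mci relative_bisection
#> 1         S01         A 0.1971093          0.4973373
#> 6         S01        AV 0.3012596          0.4955956
#> 11        S01         V 0.2986955          0.4972770
#> 2         S02         A 0.3872388          0.4962843
#> 7         S02        AV 0.2262481          0.4939150
#> 12        S02         V 0.3240417          0.4957554
```

`mci` is each cell's Metacognitive Index (these observers have moderate
metacognitive noise, 0.5 s, hence values well below 1);
`relative_bisection` is the mean estimate divided by the total duration, and
sits at 0.5 because the observers are unbiased.

```r
fit <- fit_hier_model(trials, hier_model_spec("full"),
                      mcmc_control(n_chains = 2, burn_in = 1000,
                                   n_samples = 3000, thin = 2, seed = 1))
summarize_midpoints(fit)
#>   condition      mean   hdi_low  hdi_high
#> 1         V 0.7522603 0.7434309 0.7606488
#> 2         A 0.7519122 0.7427645 0.7602506
#> 3        AV 0.7441179 0.7349305 0.7540167
#> 4   overall 0.7494301 0.7439753 0.7542542
```

The group posterior midpoints recover the generating 0.750 s within a few
milliseconds, with 95% HDIs of roughly ±10 ms. (At these reduced chain
lengths the fit may warn that some metacognitive-SD parameters mix slowly —
the midpoint parameters converge with R-hat ≈ 1.00; use the default
`mcmc_control()` for production-length chains.) `dic(fit, trials)` scores a
fitted variant for model comparison, and `posterior_predictive_mci(fit)`
pushes posterior draws back through the simulator to predict the MCI.

A command-line wrapper over the same functions lives at
`inst/cli/bisectmeta` (subcommands `simulate`, `describe`, `fit`, `compare`,
`ppc`, `pipeline`), and `run_pipeline()` orchestrates the full
simulate-describe-fit-compare-predict chain with a reproducibility manifest.

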