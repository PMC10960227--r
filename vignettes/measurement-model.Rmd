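---
title: "Measuring temporal bisection and metacognition: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring temporal bisection and metacognition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The paradigm and the measurement problem

In the modified temporal-bisection paradigm an observer is given a stimulus
of known total duration (for example 1.5 s) and asked to hold a button down
from stimulus onset and release it at the perceived midpoint. Each trial-pair
contains **two** such bisection attempts on identical intervals, followed by
a second-order forced choice: which of the two attempts was closer to the
true midpoint? Sessions comprise 500 trial-pairs in blocks of 100, with a
random 0–250 ms pre-stimulus delay (to defeat rhythmic strategies), a 500 ms
inter-stimulus interval, and tone feedback indicating whether the chosen
interval was in fact the closer one.

The task therefore yields, per trial-pair, two first-order measurements
(the bisection estimates `I1`, `I2`, in seconds) and one type-2 measurement
(the choice `r ∈ {1, 2}`). The measurement problem is to separate three
latent quantities per observer and modality condition (visual `V`, auditory
`A`, audiovisual `AV`):

* the **subjective midpoint** `phi` — where the observer believes the
  midpoint lies;
* the **bisection SDs** `sigma_I1`, `sigma_I2` — first-order precision;
* the **metacognitive SD** `sigma_m` — how noisily the observer can read out
  the difference between their own two errors.

# Descriptive layer: re-sorting and the Metacognitive Index

For each subject-condition cell the trial-pairs are re-sorted twice into
"best" and "worst" sets of equal length `n_trials`:

* **subjectively**, by the observer's own choice;
* **ideally**, by actual distance to the veridical midpoint
  (`total_duration / 2`), ties going to interval 1 — a deterministic
  tie-break for an event of measure zero in continuous data.

Re-sorting permutes values between sets and never alters them, so the
multiset of all estimates is preserved — a property the tests assert on
random data. The ideal-best set by construction minimises the mean squared
deviation from the veridical midpoint over all `2^n` per-pair selections
(checked against exhaustive enumeration for small `n`).

The Metacognitive Index is the ratio of variance ratios

> `MCI = (Vi.best / Vi.worst) / (Vs.best / Vs.worst)`,

computed with unbiased (`n − 1`) sample variances. The normalisation used by
the variance (n or n − 1) cancels in each ratio, so this choice does not
affect the MCI itself, only the reported variances. A perfect self-monitor
sorts exactly as the ideal observer and scores 1; choices uninformative
about accuracy leave the subjective ratio near 1 so the MCI falls toward the
(small) ideal ratio. Degenerate cells (zero variance in any term entering a
denominator) raise an error rather than returning infinities, because the
MCI is a ratio of ratios and silent infinities would corrupt downstream
group summaries.

Supporting descriptives follow the conventions of the paradigm's analyses:
histograms use 150 equal-width bins from zero to the total duration
(half-open bins, last bin closed); trial series are summarised in bins of 50
trials with t-based 95% confidence intervals, bin centres at the middle of
each bin's trial range, and a retained, flagged partial final bin; the
coefficient of variation (SD/mean) supports scalar-timing (Weber's law)
checks across base durations; and the trial-series autocorrelation is the
Pearson correlation of the series with its lag-k shift — the lagged-scatter
convention, chosen so a perfectly alternating series scores exactly −1 at
lag 1 (the n-divisor estimator of `stats::acf` shrinks that value by
`(n−1)/n`).

# Generative model of the observer

The forward simulator is the same model the Bayesian layer inverts:

* `I1 ~ Normal(phi_eff, sigma_I1)`, `I2 ~ Normal(phi_eff, sigma_I2)`,
  truncated to `[0, total_duration]` by resampling — a button release cannot
  precede onset or follow offset. The underlying inferential model is
  untruncated; at the SD scales of interest (0.08–0.43 s against a 0.75 s
  midpoint) the truncated mass is negligible, but the physical constraint is
  kept in the simulator because real responses obey it.
* Perceived errors are **absolute**: `Δk = |Ik − phi|`. The error difference
  read-out is `d̂Δ ~ Normal(Δ1 − Δ2, sigma_m)`, and interval 1 is chosen
  with probability `P(d̂Δ < 0) = Φ(−(Δ1 − Δ2)/sigma_m)`. We use the absolute
  form because signed errors would make the difference
  `(I1 − phi) − (I2 − phi) = I1 − I2` independent of the midpoint, which
  contradicts the task's "choose the attempt with the smaller error"
  semantics and the feedback rule (closest to the veridical midpoint). A
  `signed` error mode is retained behind a flag for sensitivity analysis.
  At `sigma_m = 0` the choice rule becomes the deterministic limit (1, 0, or
  1/2 at exact ties), which is the ideal-observer reference: such an
  observer scores MCI = 1 exactly.
* Optional **drift** reproduces the early "guessing" phase seen in trial
  series: `phi_eff(t) = phi + offset · exp(−(t−1)/decay)`. It is off by
  default because the inferential model assumes a static midpoint; it exists
  for robustness experiments only. Feedback is recorded but never alters the
  simulated observer, mirroring the absence of feedback-driven updating in
  the model.
* Hierarchical observers: `sample_observers()` draws subject SDs per role
  (interval 1, interval 2, metacognitive) from log-normals centred on the
  group values, equicorrelated across the three modality conditions with
  correlation `rho` (a shared-plus-private construction that is exact for
  any `rho ∈ [0, 1]`, including the degenerate endpoints). The log scale
  enforces positivity by construction. The default between-subject log-SD of
  0.2 (≈ ±20% parameter spread) reflects the magnitude of individual
  differences visible in small-N psychophysics of this kind.

The simulator's default schedule (500 trials, blocks of 100, 0–250 ms
jitter, 500 ms ISI, feedback on) *is* the study condition; tests and the
acceptance script use those defaults except where a reduced size is
explicitly part of the check. What the simulator does **not** emulate:
rhythm or counting strategies, attention lapses, feedback-driven learning,
modality-dominance interactions, and session-level fatigue. Passing tests
therefore demonstrate correctness of the machinery under the stated
generative assumptions, not that real observers satisfy those assumptions.

# Hierarchical Bayesian layer

For one duration condition (durations are always fitted separately), the
likelihood per trial `i` of subject `s` in condition `c` is

```
I1_i ~ Normal(mid_c, 1/tau[s,1,c])
I2_i ~ Normal(mid_c, 1/tau[s,2,c])
p_i  = Φ((Δ2 − Δ1) · sqrt(tau[s,3,c]))        Δk = |Ik − mid_c|
y_i  ~ Bernoulli(p_i)                          y = 1 when interval 1 chosen
```

with midpoint hierarchy `mid_c ~ Normal(mid_overall, sigma_Φ)` and
`mid_overall ~ Normal(true_mid, sigma_Mid)`. All precision parameters
(including the two midpoint spreads) carry Uniform priors on the precision
scale; the upper bound is 100 and the lower bound is 1e−6 rather than 0 so
that the log of a group mean precision is always defined (the excluded sliver
corresponds to SDs above 1000 s, far outside the data's support).

**Cross-condition coupling.** The repeated-measures structure is captured by
a multivariate normal over each subject's three condition log-precisions,
one 3-dimensional coupling per role, sharing a subject-specific correlation
`rho[s] ~ Uniform(0, 1)` and a common coupling scale, with covariance
`Σ_s = sc² · [(1−ρ_s)I + ρ_s J] + ε I` and `ε = 0.1` keeping the matrix
positive definite. We place the coupling on **log precisions** because it
guarantees positivity without truncation and mixes well; a literal
precision-scale coupling (floored at 1e−4) is available as
`mvn_scale = "precision"` for sensitivity analysis, since the graphical
model's text leaves the scale ambiguous. The `rho` prior is uniform on
(0, 1) — not (−1, 1) — matching the interpretation of the coupling as a
consistency-of-precision parameter. A single metacognitive SD per condition
is assumed (shared across the two intervals), matching the one metacognitive
column per condition in the subject-level summaries.

The **constrained** variant forces each subject's precisions to be equal
across the three conditions (one value per role); comparing it to the full
model by DIC asks whether condition-specific precision is needed at all.

**Sampling.** The model is sampled by MCMC with JAGS (rjags). Defaults
mirror the reference plan — 2 chains, 2000 burn-in, 5000 sampling iterations
thinned by 20 — and are fully configurable; the tests and the acceptance
script use shorter chains (e.g. 1000 burn-in, 1500 retained draws per chain
for midpoint recovery; 2000/5000 thinned by 4 for coverage checks), sizes at
which the recovery targets below are comfortably met on a single CPU.
Initial values are data-driven (empirical precisions, cell means) and each
chain receives a deterministic RNG seed derived from the user seed, so a fit
is reproducible end-to-end.

**Diagnostics and summaries.** Convergence is monitored with the split
rank-normalised R-hat (each chain halved, pooled draws rank-normalised
through the inverse normal CDF, then the classic between/within ratio); fits
exceeding the 1.05 threshold are flagged with a warning, never returned
silently. Interval summaries are 95% highest-density intervals: the shortest
contiguous window containing ⌈0.95 n⌉ sorted draws, which handles the skewed
SD posteriors better than equal-tail intervals.

**DIC.** Deviance is `D(θ) = −2 log L`. The default composition is the one
printed in the source analysis, `DIC = D̄ + 2 p_D` with
`p_D = 2 var[log L]`. Taken together these double the usual complexity
penalty, so the standard conventions are exposed as switches
(`gelman`: `D̄ + p_D` with `p_D = 2 var[log L]`; `spiegelhalter`:
`p_D = D̄ − D(θ̄)`). Only the relative ordering of variants matters for model
selection, and in the regimes the tests exercise the orderings agree.
Bernoulli log-masses are floored at probability 1e−12; a clamped probability
that contradicts an observed choice raises a warning.

**Posterior-predictive MCI.** Each retained draw is pushed back through the
forward simulator (one fresh session per subject and condition) and the MCI
is computed exactly as for data; the subject-mean per draw yields the
predictive distribution of the group MCI. Draws with degenerate variances
are dropped and counted. By default 100 evenly spaced draws are used — the
MCI of a 500-trial session is itself noisy, so more draws mainly resample
that noise.

# Numerical and design choices

* Internal unit is **seconds** everywhere; readers accept a `ms` flag. This
  keeps the Uniform(0, 100) precision priors on a sensible scale.
* Trial tables round-trip bit-exactly: numbers are written with 17
  significant digits and `feedback_correct` is always **recomputed** from
  the veridical midpoint on read, never trusted from a file.
* `choice_probability` at `sigma_m = 0` follows the limit rule rather than
  dividing by zero; everywhere else it is the closed-form normal CDF, which
  the tests pin against adaptive quadrature to 1e−8.
* Insufficient data (fewer than 2 trials overall or per subject-condition
  cell, multiple durations in one fit) raise documented errors before any
  sampling starts.
* Parameter-recovery coverage is assessed at 5 subjects × 3 conditions × 100
  trials with group values at the scale of the paradigm's fitted estimates
  (`sigma_I ≈ 0.15 s`, `sigma_m ≈ 0.5 s`): nominal 95% HDIs for group-level
  SDs should cover the generating values in ≥ 85% of replications (the
  slack reflects the small replication counts used), with max R-hat ≤ 1.05.

# Known limitations

* Midpoints are modelled at the condition level (two spread parameters);
  there is no subject-level midpoint node, so subject-specific biases load
  onto the subject's SDs. This matches the estimated-parameter inventory of
  the measurement model but limits per-subject bias inference.
* No trial-varying midpoint: the early learning phase visible in trial
  series is deliberately outside the model (the simulator's drift option
  exists to probe the consequences).
* DIC is the only model-comparison criterion implemented; no WAIC/LOO.
* The equicorrelated coupling assumes one correlation per subject shared
  across roles; richer covariance structures are not represented.
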