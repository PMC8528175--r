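# numgroup

Simulation and analysis of the **connectedness numerosity illusion**:
joining pairs of dots with thin lines makes a dot cloud look less numerous,
consistent with numerosity being computed over grouped objects rather than
raw elements. The illusion is strong under full attention, shrinks when
attention is consumed by a concurrent central task, and its magnitude
covaries with autistic-like traits (AQ). `numgroup` is an R package plus a
set of analysis scripts that rebuild this entire experimental programme in
silico, for psychophysicists who want a tested, reproducible pipeline for
2AFC numerosity experiments — stimulus generation, adaptive staircases,
psychometric fitting and group statistics — or a calibrated observer model
to study estimator behaviour.

## The model in brief

A stimulus has `N` dots, a fraction `f` of them joined pairwise (`f N / 2`
connectors). An observer groups each connected pair into one perceived
object with probability `p`, so the effective count is
`N_eff = N − Binomial(f N / 2, p)`, and reports a noisy estimate
`N̂ ~ Normal(N_eff, w · N_eff)` with internal Weber fraction `w`. The
expected bias of perceived numerosity is

```
bias% = −100 · (f/2) · p        # −20% at f = 0.4, p = 1;  −7% at p = 0.35
```

A 2AFC trial compares reference and probe estimates; probe numerosity is
driven by a QUEST staircase on log10 numerosity whose recommendation is
perturbed by Gaussian noise (SD 0.15 log units). Each observer × condition
cell is fitted with a cumulative Gaussian `Φ((x − µ)/σ)`, giving
PSE = µ, JND = Φ⁻¹(0.75)·σ, Weber fraction = JND/PSE and
bias% = 100(µ − N_ref)/N_ref. Group analyses: AQ median split,
repeated-measures ANOVA with partial eta squared and BIC-approximate log10
Bayes factors, Pearson correlations with default-prior (JZS) Bayes factors,
Jarque–Bera normality.

## Worked example

```r
library(numgroup)

expected_bias_percent(0.4, 1.0)    # analytic bias, obligatory grouping
#> [1] -20
expected_bias_percent(0.4, 0.35)   # grouping succeeds on 35% of pairs
#> [1] -7

co  <- sample_cohort(cohort_config(n_observers = 2, seed = 8))
obs <- co[1, ]                      # one synthetic observer (AQ = 4)
trials <- run_session(obs, 15, "connected", "single",
                      quest_config(15, seed = 11))
fit_cumulative_gaussian(aggregate_responses(trials))
#> <psychometric_fit> pse = 12.429, jnd = 2.042, WF = 0.1643, bias = -17.14%

bf_pearson(0.59, 18)               # log10 JZS Bayes factor for r = 0.59, n = 18
#> [1] 0.6840989
```

The fitted PSE of about 12.4 against a physical reference of 15 is the
illusion at work: with 40% of dots connected and this observer's grouping
probability near 1, three dot pairs fuse into three perceived objects, so
the connected patch matches an isolated patch of roughly 12 dots. The
Bayes factor 0.68 says data with that correlation favour a real AQ–bias
association over the null by a factor of about 5.

The full in-silico experiment (18 observers × numerosities 15/25/100 ×
isolated/connected × single/dual task, 180-trial sessions, 216 fits):

```r
res <- run_experiment(experiment_config(master_seed = 1))
res$summary                         # cell means and SDs
reproduce_defaults(master_seed = 1) # side-by-side table against the anchors
```

The numbered scripts under `analysis/` run the same workflow as a narrative:
`01_stimuli.R` (geometry audit), `02_cohort.R` (AQ calibration),
`03_experiment.R` (the full simulation, a few minutes on one CPU),
`04_group_stats.R` (ANOVA, correlations, Weber-fraction attention cost),
writing their tables under `results/`.

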