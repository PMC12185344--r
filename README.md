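# moodgamble

Simulation and analysis of longitudinal two-option gamble ("wheel of
fortune") experiments of the kind used to study risk taking and mood in
bipolar disorder and bipolar-risk cohorts: participants play short daily
sessions (20 trials) at home for weeks, choosing between two wheels that
each display a win probability, a win magnitude and a loss magnitude
(both 10–200 points), alongside daily mood self-reports (PANAS, happiness
VAS). The package is aimed at computational-psychiatry researchers who want
a tested, reproducible pipeline for this task family — and a synthetic-cohort
generator to develop and validate analyses before (or without) real data.

## The model

Each option's subjective utility weighs the loss component by a
participant-specific loss sensitivity λ, modulated trial-to-trial by the
previous outcome (outcome history, γ):

```
U = p_win · mag_win − (λ + γ · PrevOutc) · (1 − p_win) · mag_loss
```

with `PrevOutc` coded +1 after a win, −1 after a loss, 0 on a session's
first trial; γ > 0 means more loss avoidance after a win. Choices follow a
softmax with inverse temperature β (1/points):

```
p(left) = 1 / (1 + exp(β · (U_right − U_left)))
```

Each 20-trial session is fitted by Bayesian inference under Normal priors on
(λ, γ, log β) — random-walk Metropolis by default, MAP + Laplace in fast
mode — and the session-wise estimates feed hierarchical location-scale
regressions that test an ordered-group ("bipolar gradient") contrast on both
the mean and the day-to-day variability of each quantity, and a
drug × time (lithium/placebo × baseline/post) interaction in the patient
arm. Model-free counterparts (choice curves over utility-difference bins,
win/loss dimension slopes, the outcome-history contrast) and mood analyses
(instability as within-person SD, happiness–outcome coupling,
mood → choice-noisiness coupling) round out the pipeline.

## Worked example

Simulate one session from known parameters and fit it back:

```r
library(moodgamble)

set.seed(1)
s <- simulate_session(lambda = 1, gamma = 0.3, beta = 0.2, n_trials = 20)
fit <- fit_session(s, method = "mcmc", n_warmup = 2000, n_iter = 2000, seed = 2)
tidy(fit)
#> # A tibble: 4 × 5
#>   parameter   mean     sd ci_lower ci_upper
#>   <chr>      <dbl>  <dbl>    <dbl>    <dbl>
#> 1 lambda     0.757  0.280   0.0629    1.19
#> 2 gamma      0.185  0.236  -0.251     0.713
#> 3 log_beta  -2.23   0.719  -3.84     -1.00
#> 4 beta       0.107 NA       0.0216    0.367
```

All three generating values sit inside their 95% credible intervals; with
only 20 trials the posteriors are wide — this is exactly why sessions are
fitted under informative priors and then pooled hierarchically.

Cohort-level inference (a small synthetic cohort; the gradient regression
uses volunteer sessions plus the patients' pre-randomisation baseline):

```r
library(dplyr)
set.seed(3)
cfg <- cohort_config(group_sizes = c(low_mdq = 8, high_mdq = 8,
                                     bd_lithium = 4, bd_placebo = 4),
                     days_volunteer = 12, days_baseline = 4, days_post = 8)
cohort <- generate_cohort(cfg)
fits <- fit_sessions(cohort$trials, method = "map", seed = 4)
grad <- fit_location_scale(
  fits |>
    left_join(select(cohort$participants, participant_id, age, gender),
              by = "participant_id") |>
    filter(phase %in% c("none", "pre")),
  outcome = "gamma_mean")
tidy(grad) |> filter(submodel == "mean")
#> # A tibble: 6 × 7
#>   term        submodel estimate std_error ci_lower ci_upper significant
#> 1 (Intercept) mean      0.0795    0.0206    0.0391  0.120   TRUE
#> 2 day_c       mean     -0.00278   0.00549  -0.0135  0.00797 FALSE
#> 3 g_linear    mean     -0.00427   0.0407   -0.0841  0.0756  FALSE
#> 4 g_quadratic mean     -0.0144    0.0336   -0.0802  0.0513  FALSE
#> 5 age_z       mean     -0.0190    0.0203   -0.0587  0.0207  FALSE
#> 6 gender_c    mean     -0.102     0.0386   -0.178  -0.0263  TRUE
```

`g_linear` is the gradient coefficient: the linear ordered-factor contrast
across low-MDQ ≤ high-MDQ ≤ bipolar groups. At this toy sample size the
default group differences are not detectable — the calibration and power
properties of the full design are exercised in the test suite. An effect is
declared when the 95% credible interval excludes zero.

The end-to-end pipeline (simulate → fit → model-free → group inference →
mood), with per-stage seeds and byte-reproducible CSV outputs:

```r
run_pipeline(pipeline_config(), out_dir = "pipeline_out")
# or: Rscript scripts/pipeline.R --out pipeline_out
```

## Acceptance script

`scripts/acceptance.R` recomputes the stimulus-design calibration from
scratch: it draws 10,000 gamble pairs from the default generator and reports
the percentage of pairs whose expected values differ by at most 20 points
and at most 5 points — the two design facts the task's "most choices are
hard" construction is defined by.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
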