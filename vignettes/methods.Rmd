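---
title: "Models and methods in moodgamble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in moodgamble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodgamble)
```

This vignette documents the models the package implements, the inference
machinery behind them, the synthetic world the cohort generator describes,
and the numerical and design choices a maintainer would want to know about.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## The decision model

On each trial a participant chooses between two wheels, each defined by a
win probability $p$, a win magnitude $m^+$ and a loss magnitude $m^-$
(points, 10–200). The subjective utility of an option is

$$U = p\,m^+ - (\lambda + \gamma\,s)\,(1-p)\,m^-,$$

where $\lambda$ is loss sensitivity ($\lambda = 1$: losses and rewards
weighted equally), $\gamma$ modulates the loss weight by the previous
trial's outcome, and $s$ codes that outcome. Choices are softmax in the
utility difference with inverse temperature $\beta$ (units 1/points):

$$p(\text{left}) = \frac{1}{1 + e^{\beta\,(U_\text{right} - U_\text{left})}}.$$

Design choices where the model description leaves freedom:

* **Outcome coding.** $s = +1$ after a win, $-1$ after a loss, $0$ on the
  first trial of a session. The symmetric ±1 coding keeps $\lambda$ the
  midpoint loss weight and makes $\gamma > 0$ read directly as "more
  loss-avoidant after a win". A continuous (points-valued) coding is a
  plausible alternative; the binary form matches the behavioural model's
  win/loss framing and is what the package implements.
* **No cross-session history.** Sessions are a day apart; the first trial
  of every session carries no history term rather than inheriting the
  previous day's last outcome.
* **Raw point utilities.** Utilities are not rescaled, so $\beta$ is
  interpretable per point; $\beta = 0.1$ turns a 10-point utility gap into
  a 0.27/0.73 choice split.
* **No learning.** Probabilities and magnitudes are fully displayed, so
  the model contains no learning rule, and reaction times are out of scope.

Numerical safety: the softmax exponent is clipped at $|\beta \Delta U| =
500$ and per-trial probabilities are floored at $10^{-12}$ inside the
log-likelihood. Neither bound is reachable at realistic parameter values.

## Per-session Bayesian fitting

Twenty trials cannot identify three parameters without regularisation, so
sessions are fitted under independent Normal priors on $(\lambda, \gamma,
\log\beta)$; $\beta$ lives on the log scale to enforce positivity. The
defaults are

* $\lambda \sim N(1, 1)$ — centred on reward/loss symmetry;
* $\gamma \sim N(0, 0.5)$ — centred on no history effect;
* $\log\beta \sim N(\log 0.1, 1)$ — centred on a choice sensitivity
  matched to the task's near-equal-EV design.

Two fitting modes share one log-posterior:

* **MCMC (default for single sessions):** adaptive random-walk Metropolis,
  4 chains × 1000 draws after 1000 warmup iterations, proposal scales tuned
  toward ~30% acceptance during warmup and then frozen. Convergence is
  monitored by split-$\widehat{R}$ (threshold 1.05); failures are flagged in
  the returned diagnostics, never silent.
* **MAP + Laplace (fast mode, default for cohort-scale runs):** BFGS mode
  finding plus a Normal approximation from the inverse Hessian. For this
  smooth 3-parameter posterior the approximation is good for means and
  credible intervals; the main caveat is that the skewed $\log\beta$
  posterior has its mode below its mean.

The parameter-recovery harness (`parameter_recovery()`) quantifies what
these fits can deliver: at 20 trials the posterior-mean estimates correlate
with the truth well above chance for all three parameters and improve
monotonically with trial count. Recovery is scored on the estimation scale
($\lambda$, $\gamma$, $\log\beta$). Session-to-session *variability* of
parameters is, by contrast, poorly recoverable at 20 trials — which is why
the group analyses compare means (and model the dispersion of session-wise
*estimates*, not of true parameters). Model comparison
(`compare_models()`) uses 5-fold cross-validation by trial within session;
the original studies' comparison criterion is not public, and out-of-sample log
predictive score is the standard choice that also penalises the extra
parameter of the full model under a null generative process.

## Hierarchical location-scale group inference

Session-wise quantities $y_{ij}$ (participant $i$, day $j$) are modelled as

$$y_{ij} \sim N(\mu_{ij}, \sigma_{ij}^2), \qquad
\mu_{ij} = x_{ij}^\top b + u_{0i} + d_{ij} u_{1i}, \qquad
\log \sigma_{ij} = w_{ij}^\top a + v_i,$$

with mean-submodel covariates (intercept, within-participant-centred day,
ordered-group contrasts, standardised age, centred gender) and random
intercepts and day slopes per participant; the dispersion submodel carries
the group contrasts, age and gender plus a random intercept. The log link
on $\sigma$ is assumed (positivity); group differences in day-to-day
variability are tested there. The drug × time analysis replaces the group
contrasts with centred drug, phase, their product (the effect of interest)
and a baseline-length covariate.

The ordered factor enters as **orthonormal polynomial contrasts**
(`gradient_codes()`): the linear term is "the gradient", and at three
levels the quadratic term absorbs unequal step sizes, so only the ordering
is assumed, not linearity. The decision rule is fixed at the central 95%
credible interval excluding zero, with no multiplicity correction.

**Inference engine.** No probabilistic-programming backend is available in
this environment, so the package ships its own: a joint MAP over all
parameters (fixed effects, random effects, log random-effect SDs) with
weakly-informative priors ($b, a \sim N(0, 10^2)$, $\log\tau \sim
N(0, 2^2)$), followed by a Laplace approximation whose fixed-effect block of
the inverse Hessian supplies posterior SDs and credible intervals. Two
numerical points matter:

* **The funnel.** When a variance component is truly ~0, the joint mode
  sends its $\log\tau$ to $-\infty$. The optimiser therefore bounds
  $\log\tau$ below at $10^{-3}$ times the outcome SD; a component pinned at
  the bound is treated as zero and dropped from the Hessian.
* **Calibration is tested, not assumed.** The acceptance suite checks that
  under a null cohort the gradient's 95% interval covers zero at its
  nominal rate across 50 seeded replicates, and that a monotone shift of
  0.2 outcome-SD per group step is detected in the majority of replicates
  at the study's sample sizes. Here "outcome SD" is the SD of the
  session-wise values being regressed (between- plus within-participant
  spread) — the conventional standardised-effect unit for this model's
  outcome.

Fits are deterministic (no Monte Carlo), which also makes the pipeline
byte-reproducible.

## Model-free statistics

* **Choice curves** bin trials by the *displayed* utility difference
  ($\lambda = 1$, $\gamma = 0$ — what the participant sees), using
  equal-count bins (default 7, matching the visual granularity such data
  are usually plotted at); first trials are included since displayed
  utilities carry no history term.
* **Dimension sensitivity** reports win- and loss-dimension slopes from a
  *joint* per-participant logistic regression of choice on both utility
  differences. Marginal fits would be confounded here by design: the
  near-equal-EV construction makes the reward- and loss-utility differences
  strongly correlated, so a loss-blind agent would still show a positive
  marginal loss slope. Under the generative model the joint win slope
  estimates $\beta$ and the loss slope $\beta\lambda$. The binned display
  curves remain marginal (they are descriptive).
* **The outcome-history contrast** is computed on the trials whose options
  differ most in loss utility — top 25% of $|\Delta\text{loss utility}|$ by
  default (a multiplicative change in loss weighting matters most there;
  the exact fraction is configurable, as the source design's bin rule is
  not fully specified). Ties in the "lower-loss option" label are excluded
  (the label is undefined), and a participant with an empty after-win or
  after-loss cell is flagged rather than silently dropped.
* **Predictive accuracy** scores the fitted model's modal choice against
  the observed one, counting exact ties 1/2. Note in-sample accuracy
  carries a small optimism (three fitted parameters per 20 trials).

## The synthetic world

`generate_cohort()` emulates the two-study design the analyses target:

* **Groups and schedule:** 37 / 40 / 19 / 16 participants (low MDQ, high
  MDQ, bipolar-lithium, bipolar-placebo); volunteers play 50 daily
  sessions; patients 14 baseline days plus 42 post-randomisation days (the
  design lengths; realized day counts in such studies run slightly lower,
  which the missing-at-random rate can emulate); 20 trials per session.
* **Stimuli:** option attributes on 10-point magnitude and 0.05 probability
  grids; pairs drawn by stratified rejection over three $|\Delta EV|$
  strata so that 76% of pairs fall within 5 points and 90% within 20 — the
  two facts the "most choices are hard" design is defined by. The original
  stimulus algorithm is not public; only its gap distribution is emulated.
* **Parameters:** participant-level $(\lambda, \gamma, \log\beta)$ are
  Normal around group means, with session-level jitter — the simplest
  structure consistent with the hierarchical regressions fitted downstream.
  Defaults encode the qualitative group structure reported for such
  cohorts: a step-change drop in $\lambda$ for patients (1.2 / 1.15 / 0.9),
  a continuous $\gamma$ gradient (0.10 / 0.05 / 0), equal $\log\beta$
  ($\log 0.1$), between-participant SDs (0.3 / 0.15 / 0.4) and
  session-level SDs (0.4 / 0.3 / 0.3) chosen so that single-session fits
  are informative but far from deterministic. Lithium effects default to
  zero (the trial this emulates found none on behaviour).
* **Mood:** daily PANAS scores around participant baselines with
  group-specific SDs (1.5 / 2.0 / 2.5 — instability rises along the
  gradient); happiness VAS changes couple to the session's summed net
  outcome at 4.2 VAS points per outcome-SD with residual SD 9.1 (a
  standardised coupling of ~0.4); in the patient group, same-day positive
  mood raises effective $\log\beta$ by 0.18 per within-person PANAS SD.
  "Net outcome" is the sum of realized signed points over the session's
  trials, standardised across sessions for comparability.

What the generator does **not** emulate: dropout beyond missing-at-random,
within-day mood dynamics, learning or fatigue across trials, stimulus
sequence effects, and any neural quantity. A green test therefore
establishes that the *pipeline* recovers what it simulates — not that real
cohorts satisfy the generative assumptions.

## Known limitations

* Credible intervals from the location-scale engine are Laplace
  (normal-approximation) intervals around a joint mode, not exact
  posteriors; their null calibration is verified by simulation in the
  acceptance suite, but strongly skewed posteriors (tiny groups, extreme
  dispersion effects) will be summarised less faithfully.
* Sessions are fitted independently and then pooled; a joint hierarchical
  model of all trials is deliberately out of scope, mirroring the two-stage
  design the analyses replicate.
* The Metropolis sampler is adequate for the 3-parameter session posterior
  but is not a general-purpose MCMC; split-$\widehat{R}$ above 1.05 is
  flagged and longer chains are the remedy.
* MDQ is not modelled as a continuous score; groups are categorical with an
  ordered contrast, as in the analyses this package implements.
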