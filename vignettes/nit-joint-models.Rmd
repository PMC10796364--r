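---
title: "Joint modelling of ICU trajectories and good outcome with an intervention transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of ICU trajectories and good outcome with an intervention transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitjm)
```

## The problem

Patients admitted with spontaneous subarachnoid haemorrhage (SAH) are
monitored intensively for about two weeks. Whether a patient reaches a *good
outcome* — discharge home or to rehabilitation within the 14-day window —
depends on baseline conditions (complications such as hydrocephalus or
respiratory failure), on the evolution of repeatedly measured markers
(consciousness level on the Glasgow Coma Scale, white-blood-cell count,
glucose), and on whether and when the ruptured aneurysm is secured by
clipping or embolisation. `nitjm` implements a joint model that combines all
three sources and updates a patient's outcome probability as measurements
accrue.

## The model

Each dynamic covariate $j$ for patient $i$ follows a linear mixed trajectory
that changes slope at the patient's neurological-intervention time
$\tilde t_i$:

$$
y_{ji}(t) = m_{ji}(t) + \varepsilon_{ji}(t), \qquad
m_{ji}(t) = \beta_j^\top x(t) + b_{ji}^\top z(t)
          + \tilde\beta_j \, t_+ + \tilde b_{ji}\, t_+,
$$

with $t_+ = \max(0, t - \tilde t_i)$, fixed basis $x(t) = (1, t)$, random
basis $z(t) = (1, t)$, residual $\varepsilon \sim N(0, \sigma_j^2)$ and
random effects $(b_{ji}, \tilde b_{ji}) \sim N(0, D_j)$, independent across
covariates. Before the intervention (and for patients never intervened) the
$t_+$ terms vanish, so the model reduces to an ordinary random-intercept /
random-slope trajectory. The hazard of good outcome shares the current
trajectory values:

$$
h_i(t) = h_0(t)\,
\exp\!\Big(\gamma^\top \omega_i + \sum_j \alpha_j\, m_{ji}(t)\Big),
$$

where $\omega_i$ are baseline covariates and $\alpha_j$ measures how a unit
shift in the modelled mean of covariate $j$ multiplies the rate of reaching
good outcome ($\mathrm{HR} = e^{\alpha_j}$). The *baseline joint model* is
the special case without the $t_+$ terms; the *NIT (neurological
intervention transition) model* includes them, so the intervention acts as a
patient-specific change point in both the trajectories and, through them,
the hazard.

Design choices that the data sources leave open, and how this package
resolves them:

* **Trajectory basis.** Linear in time with a slope change and no jump at
  $\tilde t_i$, keeping $m_{ji}$ continuous; a fixed intercept shift at the
  transition is available via `include_jump = TRUE`. Continuity is the
  physiologically conservative default — scores drift rather than jump at
  the moment of surgery — and a jump term is weakly identified from daily
  data.
* **Baseline hazard.** Piecewise constant on $\{0,2,\dots,14\}$ days (7
  pieces, configurable through `knots`). This family integrates cheaply and
  exactly against the log-linear trajectory terms and admits a simple
  normal prior on the log pieces.
* **Association.** Current-value only: $\alpha_j$ multiplies $m_{ji}(t)$.
  Slope or cumulative associations are out of scope.
* **Binary biomarkers.** Threshold-coded series (hyperglycaemia, WBC
  abnormality) are modelled as Gaussian trajectories of the 0/1 codes. The
  model reads $m_{ji}(t)$ as a latent abnormality propensity; this is a
  deliberate, documented simplification rather than an ordinal or logistic
  sub-model.
* **Competing outcomes.** The event is *good* outcome; patients with a poor
  outcome are censored at their recorded time. Hazard ratios below one
  therefore mean a lower rate of reaching good outcome, not a higher rate
  of harm.

## Preprocessing conventions

Measurement frequency in an ICU tracks illness severity, so raw series are
reduced to **daily averages**: day bin $d = \lceil t \rceil$ (time 0 counts
as day 1), bin mean placed at the representative time $d - 0.5$, capped at
the patient's event time for measurements on the event day. Threshold
dichotomization uses glucose $\ge$ 126 mg/dL (hyperglycaemia) and SpO2
$<$ 95% (low saturation) — stated clinical cutoffs — plus WBC outside
4–12 $\times 10^9$/L and creatinine $\ge$ 1.3 mg/dL, which are common
laboratory reference ranges supplied as overridable defaults because no
authoritative cutoffs exist for these two labels. Trajectory visualisation
uses local linear regression with tricube weights (span 0.75 by default)
with a pointwise normal-approximation 95% band.

## Estimation

Sub-models are fitted first: a Cox model with Breslow tie handling for the
baseline covariates (Breslow matches the joint model's full-likelihood
treatment of ties), and, per dynamic covariate, a marginal maximum-likelihood
linear mixed model on an unconstrained parametrization (log-Cholesky factor
of $D_j$, log $\sigma_j$) with standard errors from the observed information
— marginal ML rather than REML so the sub-model likelihood is commensurate
with the joint likelihood. Priors are centred at the sub-model estimates:

* $\gamma$, $\beta_j$, $\tilde\beta_j$, $\log h_0$ pieces: normal with SD =
  10 $\times$ the sub-model standard error (`inflation` argument);
* $\alpha_j$: $N(0, 2^2)$ — no sub-model estimate exists for associations;
* $\sigma_j^2$: inverse-gamma, $D_j$: inverse-Wishart, both weakly
  informative and centred at the sub-model values.

The posterior is sampled by Metropolis–Hastings-within-Gibbs:
$\sigma_j^2$ and $D_j$ by conjugate Gibbs updates; $\gamma$, $\alpha$, each
covariate's fixed effects, and the log baseline-hazard pieces by adaptive
random-walk MH (Robbins–Monro scaling of the proposal during warmup only,
targeting acceptance 0.234 for vector blocks and 0.44 for scalars, frozen
afterwards so detailed balance holds post-warmup); each patient's stacked
random effects by a joint random-walk MH step proposed along the Cholesky
factor of the current $D_j$. Cumulative hazards use 7-point Gauss–Legendre
quadrature on each subinterval delimited by the hazard knots and the
intervention time; the integrand is piecewise log-linear, for which this
rule is accurate far beyond the Monte-Carlo noise floor. Defaults are 2
chains of 4000 iterations with 2000 warmup; all randomness flows through R's
RNG, so a seed makes runs bit-reproducible. Convergence is monitored by
split-$\widehat R$ (warning above 1.1 on headline parameters) and a
Geyer-style effective sample size.

## Dynamic prediction and evaluation

For a patient still event-free at $T_s$, the probability of good outcome in
$(T_s, T_s + dt]$ is

$$
\pi_i(T_s, dt) = \mathbb E\left[\, 1 -
\frac{S_i(T_s + dt \mid \theta, b_i)}{S_i(T_s \mid \theta, b_i)} \,\right],
$$

averaging over thinned posterior draws $\theta$ and, within each, over MH
samples of $b_i$ conditional on the observations up to $T_s$ and survival
past $T_s$ (defaults: 50 posterior draws, 200 burn-in + 200 retained
random-effect samples each). Prediction uses only information available at
$T_s$: an intervention that happens later is unknown at prediction time and
is treated as absent.

Discrimination is summarised on the $(T_s, dt)$ grid
$\{1,2,3,5,7\}\times\{1,2,3,5,7\}$ days. Cases are patients with the event
inside the window; controls are patients known event-free through the window
end — including those administratively censored exactly at the horizon,
without which every cell with $T_s + dt = 14$ would be undefined; patients
censored strictly inside the window contribute no pairs. The marginal AUC
per $T_s$ is the pair-count-weighted average over that column; the overall
mean $\pm$ SD is unweighted over cells. Model comparisons split the grid
into an acute phase ($T_s + dt \le 3$ days, cells (1,1), (1,2), (2,1)) and a
sub-acute phase ($3 < T_s + dt \le 14$). A decile-wise comparison of
predicted probabilities against observed event fractions serves as the
calibration diagnostic.

## The synthetic cohort generator

No patient-level data ship with the package; `simulate_cohort()` generates
cohorts with exactly the structure the model assumes, so estimation and
prediction can be tested against known truth. The defaults emulate a 14-day
SAH ICU cohort:

* five binary complications at the reported prevalences (e.g. hydrocephalus
  0.3153, respiratory failure 0.2156) with log hazard ratios at the
  multivariate survival estimates (e.g. hydrocephalus HR 0.1821), plus an
  age column that does not enter the hazard;
* three dynamic covariates: a standardized GCS-like consciousness score
  (association $e^\alpha$ = 3.2802 per standardized unit) whose slope
  improves after intervention, and binary-coded WBC-abnormality and
  hyperglycaemia series (associations 0.5261 and 0.2681) modelled on the
  Gaussian scale, matching the estimation model;
* interventions scheduled with probability 0.6 at a uniform(0.5, 3)-day
  time — the timing law is a package choice, as no empirical distribution is
  reported; a scheduled intervention falling after the simulated event time
  never happens and is recorded as missing, which is self-consistent because
  the hazard before the event never activated the post-intervention branch;
* event times drawn by inverting the model's own cumulative hazard
  (Exponential(1) deviate, bisection to $10^{-8}$ days), administrative
  censoring at day 14 only. The baseline-hazard level was calibrated once so
  that about half the simulated cohort reaches good outcome by day 14
  (measured 51% at $n = 2000$), matching the reported outcome prevalence of
  48.93%;
* one observation per covariate per day at representative times 0.5, 1.5,
  ..., truncated at the event time, i.e. the generator produces data already
  on the daily-average grid.

What the generator does **not** emulate: irregular and informative
measurement timing, missingness and dropout, within-day dynamics, correlated
baseline covariates, cross-covariate random-effect correlation, truly binary
biomarker measurements, and competing risks. Passing recovery and
discrimination tests on these cohorts therefore demonstrates internal
correctness of the estimation and prediction machinery — not clinical
validity on real ICU data.

## Numerical choices and degenerate inputs

* Quadrature: Gauss–Legendre, 7 nodes per subinterval; subintervals split at
  hazard knots and $\tilde t_i$, so the integrand is smooth on each.
* Event simulation: bisection on $(0, 14]$ to $10^{-8}$ days.
* Exponent guard: log-hazard terms above 700 make a proposal's likelihood
  $-\infty$ (rejected) rather than overflowing.
* `fit_lmm` falls back to ordinary least squares with a flag when the data
  are noiseless (exact-fit limit) or when patients have fewer observations
  than random effects (unidentifiable $D$, warned); a boundary estimate of
  $D$ gets a $10^{-8}$ ridge with a warning.
* Ties in time-dependent AUC count 1/2; cells without a case or a control
  are reported missing and excluded from summaries with a count.
* The posterior "p value" reported in summary tables is the two-sided tail
  probability $\min(1, 2\min(P(\theta > 0), P(\theta < 0)))$, floored at
  $2/\text{draws}$; tables otherwise mirror the usual HR / 95% CI / p
  layout.

## Problem sizes used by the test suite

The packaged tests run parameter recovery at $n = 300$ patients (mixed
model) and $n = 200$ with 20 replicate fits of 2 chains $\times$ 2000
iterations (joint-model coverage); the model-comparison study uses 10
replicate cohorts of $n = 500$ with 2 chains $\times$ 1000 iterations and
16 posterior draws $\times$ 120 retained random-effect samples per
prediction; calibration uses one $n = 2000$ cohort. These sizes are chosen
so the full suite runs on a laptop in minutes while keeping Monte-Carlo
noise well below the effects being tested. The recovery fixtures use
dispersed intervention times (uniform over 1–8 days): with all interventions
in the first three days, $t$ and $t_+$ are nearly collinear and the
post-intervention variance components are weakly identified — worth knowing
when designing real analyses, not only simulations.

## A small worked run

```{r example, eval = FALSE}
sim <- simulate_cohort(300, default_params(), seed = 1)
fit <- nitjm(sim$cohort, dynamic = c("gcs", "wbc_abnormal", "hyperglycemia"),
             baseline = names(default_params()$gamma), mode = "nit",
             chains = 2, iter = 2000, warmup = 1000, seed = 1)
summary(fit)
grid <- auc_grid(fit)
grid
```

## Known limitations

Single intervention transition only (no multi-state extension to
re-bleeding or delayed cerebral ischaemia); no model-selection criteria or
frailty terms; no IPCW correction of the AUC for censoring (administrative
censoring at a fixed horizon keeps the plain estimator interpretable here,
but it would be biased under informative censoring); binary biomarkers are
treated as Gaussian; random effects are independent across covariates.
Published hazard-ratio and AUC values for this model class come from
credentialed patient-level ICU data and depend on estimator settings that
are rarely reported in full, so the package targets the model class, its
mechanics, and the qualitative ordering of the two modelling approaches
rather than any exact published number.
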