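# nitjm

Joint models for dynamic prognosis after spontaneous subarachnoid
haemorrhage (SAH), with the neurological intervention (aneurysm clipping or
endovascular embolisation) as a patient-specific transition point. The
package is aimed at biostatisticians and critical-care researchers who want
to combine three kinds of prognostic information in one model: baseline
complications, repeatedly measured markers (GCS, white-blood-cell count,
glucose), and the timing of the securing intervention — and to turn the
fitted model into patient-level risk predictions that update as measurements
accrue.

## The model

Each dynamic covariate follows a piecewise linear mixed trajectory with a
slope change at the intervention time t̃ᵢ:

    y_ji(t) = m_ji(t) + ε_ji(t)
    m_ji(t) = β_j' x(t) + b_ji' z(t) + β̃_j t₊ + b̃_ji t₊,   t₊ = max(0, t − t̃ᵢ)

and the hazard of *good outcome* (discharge home or to rehabilitation within
14 days) shares the current trajectory values:

    h_i(t) = h₀(t) exp( γ' ω_i + Σ_j α_j m_ji(t) )

with piecewise-constant baseline hazard h₀ and baseline covariates ωᵢ.
Setting the t₊ terms to zero gives the ordinary ("baseline") joint model;
including them gives the NIT (neurological intervention transition) model.
Estimation is Bayesian: priors centred at separately fitted Cox and
mixed-model estimates, posterior sampled by adaptive
Metropolis–Hastings-within-Gibbs (compiled sampler, seed-reproducible).
Dynamic predictions π(Ts, dt) = P(event in (Ts, Ts+dt] | history up to Ts)
are evaluated with time-dependent AUCs on a (Ts, dt) grid.

Because the motivating cohort requires credentialed access, the package
ships a synthetic cohort generator (`simulate_cohort()`) that reproduces the
model's exact generative structure at realistic parameter values, enabling
parameter-recovery and discrimination studies with known truth.

## Worked example

```r
library(nitjm)
sim <- simulate_cohort(300, default_params(), seed = 1)
cohort <- sim$cohort
cohort
#> SAH cohort: 300 patients, 9558 longitudinal observations (gcs, hyperglycemia, wbc_abnormal), horizon 14 days
#>   events (good outcome): 149 (49.7%); interventions: 173

fit <- nitjm(cohort, dynamic = c("gcs", "wbc_abnormal", "hyperglycemia"),
             baseline = names(default_params()$gamma), mode = "nit",
             chains = 2, iter = 2000, warmup = 1000, seed = 1)
fit
#> nit joint model: 300 patients, dynamic [gcs, wbc_abnormal, hyperglycemia], 5 baseline covariate(s)
#>   2 chain(s) x 2000 iterations (1000 warmup), seed 1; fitted in 28.4 s
#>   association parameters (HR per unit of the trajectory mean):
#>            parameter     hr ci_low ci_high     p
#>            alpha_gcs 3.0818 2.4144  3.7714 0.001
#>   alpha_wbc_abnormal 0.4670 0.2647  0.7901 0.003
#>  alpha_hyperglycemia 0.2909 0.1350  0.5476 0.001
```

A higher modelled GCS trajectory multiplies the rate of good outcome by
about 3.1 per standardized unit (the generator's truth is 3.28), while WBC
abnormality and hyperglycaemia reduce it — their credible intervals exclude
1. Risk predictions for patients still in the ICU at day 3, over the next
two days:

```r
pr <- predict(fit, Ts = 3, dt = 2, n_theta = 20, n_b_draws = 100, n_burn = 100)
head(pr[order(-pr$pi), ], 5)
#>     patient_id Ts dt    pi
#> 243     P00259  3  2 0.758
#> 242     P00257  3  2 0.623
#> 222     P00237  3  2 0.521
#> 247     P00263  3  2 0.490
#> 62      P00064  3  2 0.483
```

`auc_grid(fit)` evaluates discrimination over Ts, dt ∈ {1, 2, 3, 5, 7} days
and `compare_models(grid_baseline, grid_nit)` contrasts the two modelling
approaches overall and in the acute (Ts + dt ≤ 3) and sub-acute phases. A
YAML-configured pipeline (`parse_config()` / `run_pipeline()`, or
`inst/scripts/nitjm.R` from a shell) chains
simulate → preprocess → fit → predict → evaluate → compare with per-stage
seeds and JSON sidecars.

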