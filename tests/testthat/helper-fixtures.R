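# Fixtures built in code: a tiny deterministic two-patient cohort, and a
# small helper to assemble cohorts from vectors.

make_cohort <- function(ids, time, event, tt = rep(NA_real_, length(ids)),
                        baseline = NULL, obs = NULL, horizon = 14) {
  baseline <- baseline %||% data.frame(patient_id = ids,
                                       x = rep_len(c(1, 0), length(ids)))
  obs <- obs %||% data.frame(patient_id = character(),
                             covariate = character(),
                             time_days = numeric(), value = numeric())
  sah_cohort(baseline,
             data.frame(patient_id = ids, event_time_days = time,
                        good_outcome = event,
                        intervention_time_days = tt),
             obs, horizon_days = horizon)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

two_patient_cohort <- function() {
  obs <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    covariate = c("gcs", "gcs", "wbc", "gcs", "wbc"),
    time_days = c(0.2, 0.9, 1.5, 2.3, 3.0),
    value = c(10, 12, 8, 7, 13))
  make_cohort(c("P1", "P2"), time = c(5, 10), event = c(1, 0),
              tt = c(2, NA), obs = obs)
}

# Simple single-covariate generative preset for fast simulation tests.
one_cov_params <- function(alpha = 1.0, gamma = -1.0, prev = 0.5,
                           beta = c(0, 0.05), beta_tilde = 0.15,
                           sds = c(0.7, 0.05, 0.08), sigma = 0.4,
                           log_h0 = rep(log(0.08), 7),
                           intervention_prob = 0.6) {
  nit_true_params(
    baseline_prev = c(x = prev), gamma = c(x = gamma),
    dynamic = list(score = list(beta = beta, beta_tilde = beta_tilde,
                                D = diag(sds^2), sigma = sigma,
                                alpha = alpha)),
    log_h0 = log_h0, intervention_prob = intervention_prob)
}

# Build a minimal nitjm-like object from a fixed parameter vector, so that
# prediction machinery can be exercised with known parameters.
degenerate_fit <- function(params, spec, cohort, n_draws = 10) {
  v <- nitjm:::params_to_vector(params, spec)
  m <- matrix(rep(v, each = n_draws), n_draws,
              dimnames = list(NULL, names(v)))
  draws <- structure(list(chains = list(m), par_names = names(v),
                          settings = list(chains = 1, iter = n_draws,
                                          warmup = 0, thin = 1, seed = 1)),
                     class = "nitjm_draws")
  structure(list(spec = spec, draws = draws, cohort = cohort),
            class = "nitjm")
}
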