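mvtnorm_logd <- function(x, S) {
  -0.5 * (length(x) * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(t(x) %*% solve(S) %*% x))
}

# Parameter sets used across the joint-model tests.
joint_setup <- function(mode = "nit", alpha = 0.8, gamma = -0.5,
                        beta = c(0.5, 0.1, 0.2), lambda = rep(log(0.1), 7),
                        sigma = 0.4, Dv = c(0.5, 0.02, 0.03)) {
  spec <- nitjm_spec(baseline = "x", dynamic = "score", mode = mode)
  q <- spec$design$q_fixed
  d <- spec$design$d_random
  params <- nitjm_params(gamma = c(x = gamma), alpha = c(score = alpha),
                         beta = matrix(beta[seq_len(q)], 1),
                         lambda = lambda, sigma = c(score = sigma),
                         D = list(diag(Dv[seq_len(d)])), spec = spec)
  list(spec = spec, params = params)
}

test_that("the hazard reduces to h0 and respects the transition branches", {
  s <- joint_setup(alpha = 0, gamma = 0)
  pat <- list(omega = c(x = 1), intervention_time_days = NA_real_)
  tt <- c(0.5, 2, 3.7, 9, 14)
  expect_equal(joint_hazard(pat, tt, s$params, NULL, s$spec),
               exp(s$params$lambda[nitjm:::h0_piece(tt, s$spec$knots)]))
  # before the transition the post-intervention terms are inert
  sn <- joint_setup(alpha = 0.8)
  sb <- joint_setup(mode = "baseline", alpha = 0.8)
  b3 <- matrix(c(0.3, -0.05, 0.4), 1)
  pat2 <- list(omega = c(x = 1), intervention_time_days = 2)
  patb <- list(omega = c(x = 1), intervention_time_days = NA_real_)
  t_pre <- c(0.3, 1.1, 1.999)
  expect_equal(joint_hazard(pat2, t_pre, sn$params, b3, sn$spec),
               joint_hazard(patb, t_pre, sb$params, b3[, 1:2, drop = FALSE],
                            sb$spec), tolerance = 1e-14)
  # continuity at the transition for the default (no-jump) design
  h_l <- joint_hazard(pat2, 3 - 1e-10, sn$params, b3, sn$spec)
  h_r <- joint_hazard(pat2, 3 + 1e-10, sn$params, b3, sn$spec)
  expect_lt(abs(h_l - h_r) / h_l, 1e-9)
})

test_that("Gauss-Legendre cumulative hazard matches closed forms and a fine grid", {
  s <- joint_setup(alpha = 0, gamma = 0)
  pat <- list(omega = c(x = 0), intervention_time_days = NA_real_)
  expect_lt(abs(joint_cumulative_hazard(pat, 10, s$params, NULL, s$spec) - 1),
            1e-10)
  expect_equal(joint_cumulative_hazard(pat, 0, s$params, NULL, s$spec), 0)
  # linear trajectory with alpha != 0: midpoint-Riemann oracle at 1e5 steps
  s2 <- joint_setup(alpha = 0.5, gamma = -0.4, beta = c(0.5, 0.25, -0.3))
  b <- matrix(c(0.2, 0.05, -0.1), 1)
  pat2 <- list(omega = c(x = 1), intervention_time_days = 2.3)
  for (upper in c(4, 11.7)) {
    n_steps <- 1e5
    mid <- (seq_len(n_steps) - 0.5) * upper / n_steps
    oracle <- sum(joint_hazard(pat2, mid, s2$params, b, s2$spec)) *
      upper / n_steps
    got <- joint_cumulative_hazard(pat2, upper, s2$params, b, s2$spec)
    expect_lt(abs(got - oracle) / oracle, 1e-6)
  }
})

test_that("joint log-likelihood matches a term-by-term transcription", {
  s <- joint_setup()
  obs <- data.frame(patient_id = c("P1", "P1", "P2", "P2"),
                    covariate = "score", time_days = c(0.5, 2.5, 1, 3),
                    value = c(0.9, 1.4, 0.2, 0.8))
  co <- make_cohort(c("P1", "P2"), time = c(4, 14), event = c(1, 0),
                    tt = c(2, NA),
                    baseline = data.frame(patient_id = c("P1", "P2"),
                                          x = c(1, 0)), obs = obs)
  b <- list(P1 = matrix(c(0.3, 0.02, -0.1), 1),
            P2 = matrix(c(-0.2, 0.01, 0), 1))
  ll <- joint_log_likelihood(s$params, b, co, s$spec)
  # independent transcription: Gaussian terms, delta log h - H, MVN prior
  p <- s$params
  man_long <- 0
  for (i in 1:4) {
    id <- obs$patient_id[i]
    tt_i <- if (id == "P1") 2 else NA_real_
    t <- obs$time_days[i]
    m <- p$beta[1, 1] + b[[id]][1, 1] + (p$beta[1, 2] + b[[id]][1, 2]) * t +
      (p$beta[1, 3] + b[[id]][1, 3]) * max(0, t - ifelse(is.na(tt_i), Inf,
                                                         tt_i))
    man_long <- man_long + dnorm(obs$value[i], m, p$sigma, log = TRUE)
  }
  man_surv <- 0
  for (i in 1:2) {
    id <- c("P1", "P2")[i]
    Ti <- c(4, 14)[i]
    di <- c(1, 0)[i]
    xi <- c(1, 0)[i]
    tt_i <- c(2, Inf)[i]
    logh <- function(t) {
      m <- p$beta[1, 1] + b[[id]][1, 1] + (p$beta[1, 2] + b[[id]][1, 2]) * t +
        (p$beta[1, 3] + b[[id]][1, 3]) * pmax(0, t - tt_i)
      p$lambda[pmax(1, findInterval(t, s$spec$knots, left.open = TRUE,
                                    rightmost.closed = TRUE))] +
        p$gamma[1] * xi + p$alpha[1] * m
    }
    n_steps <- 2e5
    mid <- (seq_len(n_steps) - 0.5) * Ti / n_steps
    H <- sum(exp(logh(mid))) * Ti / n_steps
    man_surv <- man_surv + unname(di * logh(Ti) - H)
  }
  man_prior <- sum(vapply(b, function(bi)
    mvtnorm_logd(drop(bi), p$D[[1]]), numeric(1)))
  comp <- attr(ll, "components")
  expect_equal(comp[["longitudinal"]], man_long, tolerance = 1e-12)
  expect_equal(comp[["survival"]], man_surv, tolerance = 1e-6)
  expect_equal(comp[["ranef_prior"]], man_prior, tolerance = 1e-12)
  expect_equal(as.numeric(ll), sum(comp), tolerance = 1e-12)
  # no longitudinal observations: survival and prior terms only
  co0 <- make_cohort(c("P1", "P2"), time = c(4, 14), event = c(1, 0),
                     tt = c(2, NA),
                     baseline = data.frame(patient_id = c("P1", "P2"),
                                           x = c(1, 0)))
  ll0 <- joint_log_likelihood(s$params, b, co0, s$spec)
  expect_equal(attr(ll0, "components")[["longitudinal"]], 0)
})

test_that("R and compiled joint log-likelihoods agree", {
  set.seed(31)
  sim <- simulate_cohort(25, one_cov_params(), seed = 8)
  s <- joint_setup(alpha = 0.6, gamma = -0.8, beta = c(0.2, 0.06, 0.11),
                   sigma = 0.5)
  co <- sim$cohort
  names(co$baseline)[names(co$baseline) == "x"] <- "x"
  dat <- nitjm:::prepare_joint_data(co, s$spec)
  n <- dat$n
  d <- dat$d
  set.seed(32)
  bcube <- array(rnorm(d * n) * 0.3, dim = c(d, n, 1))
  blist <- setNames(lapply(seq_len(n), function(i)
    matrix(bcube[, i, 1], 1)), dat$ids)
  cpp <- nitjm:::.cpp_joint_loglik(dat, list(
    gamma = unname(s$params$gamma), alpha = unname(s$params$alpha),
    beta = unname(s$params$beta), lambda = s$params$lambda,
    sigma = unname(s$params$sigma), D = s$params$D), bcube)
  rll <- joint_log_likelihood(s$params, blist, co, s$spec)
  comp <- attr(rll, "components")
  expect_equal(cpp$longitudinal, comp[["longitudinal"]], tolerance = 1e-10)
  expect_equal(cpp$survival, comp[["survival"]], tolerance = 1e-10)
  expect_equal(cpp$ranef_prior, comp[["ranef_prior"]], tolerance = 1e-10)
})

test_that("reduction identities hold exactly", {
  # NIT likelihood with beta_tilde = 0 and b_tilde = 0 equals the baseline
  # joint likelihood on the data components
  sn <- joint_setup(alpha = 0.7, beta = c(0.5, 0.1, 0))
  sb <- joint_setup(mode = "baseline", alpha = 0.7, beta = c(0.5, 0.1))
  obs <- data.frame(patient_id = c("P1", "P1", "P2"), covariate = "score",
                    time_days = c(1, 3.5, 2), value = c(0.8, 1.2, 0.5))
  co <- make_cohort(c("P1", "P2"), time = c(6, 14), event = c(1, 0),
                    tt = c(1.5, 2.5),
                    baseline = data.frame(patient_id = c("P1", "P2"),
                                          x = c(1, 0)), obs = obs)
  bn <- list(P1 = matrix(c(0.2, 0.03, 0), 1), P2 = matrix(c(-0.1, 0.05, 0), 1))
  bb <- lapply(bn, function(m) m[, 1:2, drop = FALSE])
  lln <- joint_log_likelihood(sn$params, bn, co, sn$spec)
  llb <- joint_log_likelihood(sb$params, bb, co, sb$spec)
  cn <- attr(lln, "components")
  cb <- attr(llb, "components")
  expect_equal(cn[["longitudinal"]], cb[["longitudinal"]], tolerance = 1e-10)
  expect_equal(cn[["survival"]], cb[["survival"]], tolerance = 1e-10)

  # alpha = 0: joint likelihood factorizes into (longitudinal + b prior) from
  # the mixed-model side plus the survival log-likelihood
  s0 <- joint_setup(alpha = 0)
  ll0 <- joint_log_likelihood(s0$params, bn, co, s0$spec)
  dat <- nitjm:::lmm_patient_data(co, "score", s0$spec$design)
  lmm_side <- nitjm:::lmm_conditional_loglik(
    drop(s0$params$beta), s0$params$sigma, s0$params$D[[1]], dat,
    lapply(names(dat), function(id) drop(bn[[id]])))
  pats <- nitjm:::cohort_patients(co, s0$spec)
  surv_side <- sum(vapply(pats, function(pt) {
    bi <- bn[[pt$id]]
    pt$good_outcome * log(joint_hazard(pt, pt$event_time_days, s0$params,
                                       bi, s0$spec)) -
      joint_cumulative_hazard(pt, pt$event_time_days, s0$params, bi, s0$spec)
  }, numeric(1)))
  expect_equal(as.numeric(ll0), lmm_side + surv_side, tolerance = 1e-10)
})

test_that("priors are centred on sub-model estimates with inflated spread", {
  sim <- simulate_cohort(120, one_cov_params(), seed = 14)
  spec <- nitjm_spec("x", "score", mode = "nit")
  cox <- fit_cox(sim$cohort, "x")
  lmm <- fit_lmm(sim$cohort, "score", spec$design)
  pr <- build_priors(cox, list(score = lmm), spec, inflation = 10)
  expect_equal(unname(pr$gamma$mean), unname(cox$gamma))
  expect_equal(unname(pr$gamma$sd), unname(10 * cox$se))
  expect_equal(unname(pr$alpha$mean), 0)
  expect_equal(unname(pr$alpha$sd), 2)
  expect_equal(unname(pr$beta$mean[1, ]), unname(lmm$beta_full))
  # doubling the inflation doubles every normal prior SD
  pr2 <- build_priors(cox, list(score = lmm), spec, inflation = 20)
  expect_equal(pr2$gamma$sd, 2 * pr$gamma$sd)
  expect_equal(pr2$beta$sd, 2 * pr$beta$sd)
  # a synthetic Cox fit: gamma-hat -1.7, SE 0.2 -> Normal(-1.7, 2^2)
  cox2 <- cox
  cox2$gamma[] <- -1.7
  cox2$se[] <- 0.2
  pr3 <- build_priors(cox2, list(score = lmm), spec, inflation = 10)
  expect_equal(unname(pr3$gamma$mean), -1.7)
  expect_equal(unname(pr3$gamma$sd), 2)
  expect_error(build_priors(cox, list(), spec), "score")
})

test_that("posterior summaries follow the tail-probability convention", {
  m <- matrix(0.7, 40, 1, dimnames = list(NULL, "theta"))
  s <- summarize_draws(m)
  expect_equal(s$hr, exp(0.7))
  expect_equal(s$ci_low, exp(0.7))
  expect_equal(s$ci_high, exp(0.7))
  expect_equal(s$p, 2 / 40)   # one-sided draws: the resolution bound
  sym <- matrix(c(rep(-1, 50), rep(1, 50)), 100, 1,
                dimnames = list(NULL, "theta"))
  expect_equal(summarize_draws(sym)$p, 1)
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  sim <- simulate_cohort(40, one_cov_params(), seed = 20)
  spec <- nitjm_spec("x", "score", mode = "nit")
  cox <- fit_cox(sim$cohort, "x")
  lmm <- fit_lmm(sim$cohort, "score", spec$design)
  pr <- build_priors(cox, list(score = lmm), spec)
  d1 <- run_mcmc(sim$cohort, spec, pr, chains = 2, iter = 200, warmup = 100,
                 seed = 99)
  d2 <- run_mcmc(sim$cohort, spec, pr, chains = 2, iter = 200, warmup = 100,
                 seed = 99)
  expect_identical(d1$chains, d2$chains)
  expect_identical(d1$b_chains, d2$b_chains)
  d3 <- run_mcmc(sim$cohort, spec, pr, chains = 1, iter = 200, warmup = 100,
                 seed = 100)
  expect_false(identical(d1$chains[[1]], d3$chains[[1]]))
})

test_that("sampler posterior matches the conjugate posterior on a tiny model", {
  # One patient, two observations, alpha pinned at zero and variance
  # parameters pinned by very tight priors: the posterior of the fixed
  # effects is then Gaussian with a closed form.
  co <- make_cohort("P1", time = 14, event = 0,
                    baseline = data.frame(patient_id = "P1", x = 1),
                    obs = data.frame(patient_id = c("P1", "P1"),
                                     covariate = "score",
                                     time_days = c(2, 10),
                                     value = c(1.0, 2.0)))
  spec <- nitjm_spec("x", "score", mode = "baseline")
  sigma0 <- 0.5
  D0 <- diag(c(1e-6, 1e-6))
  priors <- structure(list(
    gamma = list(mean = 0, sd = 1e-4),
    alpha = list(mean = c(score = 0), sd = c(score = 1e-6)),
    beta = list(mean = matrix(0, 1, 2), sd = matrix(1, 1, 2)),
    lambda = list(mean = rep(log(0.05), 7), sd = rep(1e-6, 7)),
    sigma2 = list(a = 2e6, b = sigma0^2 * (2e6 - 1)),
    D = list(nu = 2e6, S = list(D0 * (2e6 - 3)))), class = "nitjm_priors")
  draws <- run_mcmc(co, spec, priors, chains = 2, iter = 6000, warmup = 1000,
                    seed = 17)
  m <- as_matrix_draws(draws)
  # closed form: y ~ N(X beta, Z D0 Z' + sigma0^2 I), beta ~ N(0, I)
  X <- cbind(1, c(2, 10))
  V <- X %*% D0 %*% t(X) + diag(sigma0^2, 2)
  post_prec <- t(X) %*% solve(V) %*% X + diag(1, 2)
  post_mean <- solve(post_prec, t(X) %*% solve(V) %*% c(1, 2))
  for (k in 1:2) {
    par <- c("beta_score_(Intercept)", "beta_score_t")[k]
    mcse <- sd(m[, par]) / sqrt(draws$ess[par])
    expect_lt(abs(mean(m[, par]) - post_mean[k]), 3 * mcse + 0.01)
  }
})

test_that("fitted-model methods expose coherent posterior objects", {
  sim <- simulate_cohort(40, one_cov_params(), seed = 61)
  fit <- suppressWarnings(nitjm(sim$cohort, dynamic = "score",
                                baseline = "x", mode = "nit", chains = 2,
                                iter = 300, warmup = 150, seed = 62,
                                min_patients = 5))
  cf <- coef(fit)
  expect_named(cf)
  expect_true(all(c("alpha_score", "gamma_x") %in% names(cf)))
  pm <- posterior_params(fit)
  expect_s3_class(pm, "nitjm_params")
  expect_equal(unname(pm$alpha["score"]), unname(cf["alpha_score"]))
  expect_output(print(fit), "nit joint model")
  expect_output(print(summary(fit)), "Dynamic covariates")
  # posterior-predictive cohorts carry the fitted structure
  pp <- simulate(fit, nsim = 2, seed = 3, n = 25)
  expect_length(pp, 2)
  expect_s3_class(pp[[1]], "sah_cohort")
  expect_equal(n_patients(pp[[1]]), 25)
  expect_true("score" %in% pp[[1]]$observations$covariate)
  expect_false(identical(pp[[1]]$outcomes, pp[[2]]$outcomes))
})

test_that("with no longitudinal signal the gamma posterior tracks the Cox estimate", {
  sim <- simulate_cohort(150, one_cov_params(alpha = 0), seed = 23)
  spec <- nitjm_spec("x", "score", mode = "nit")
  cox <- fit_cox(sim$cohort, "x")
  lmm <- fit_lmm(sim$cohort, "score", spec$design)
  pr <- build_priors(cox, list(score = lmm), spec)
  pr$alpha$sd[] <- 1e-6    # association pinned at zero
  draws <- run_mcmc(sim$cohort, spec, pr, chains = 2, iter = 1500,
                    warmup = 750, seed = 29)
  s <- summarize_draws(draws, "gamma_x")
  expect_lt(abs(s$mean - unname(cox$gamma["x"])), 2 * s$sd)
})
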