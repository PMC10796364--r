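test_that("intervention-relative time is max(0, t - t_tilde)", {
  expect_equal(t_plus(5, 3), 2)
  expect_equal(t_plus(2, 3), 0)
  expect_equal(t_plus(3, 3), 0)
  expect_equal(t_plus(c(1, 4, 7), 4), c(0, 0, 3))
  expect_error(t_plus(-1, 3), "non-negative")
  expect_error(t_plus(1, NA), "finite")
})

test_that("design rows zero out post-intervention terms appropriately", {
  d <- lmm_design("nit")
  r1 <- design_row(d, 2, NULL)
  expect_equal(unname(r1$fixed), c(1, 2, 0))
  expect_equal(unname(r1$random), c(1, 2, 0))
  r2 <- design_row(d, 3, 2)
  expect_equal(unname(r2$fixed), c(1, 3, 1))
  dj <- lmm_design("nit", include_jump = TRUE)
  r3 <- design_row(dj, 2, 2)     # at the transition: jump on, slope zero
  expect_equal(unname(r3$fixed), c(1, 2, 1, 0))
  r4 <- design_row(dj, 1.5, 2)
  expect_equal(unname(r4$fixed), c(1, 1.5, 0, 0))
  # absent intervention: all post terms exactly zero
  r5 <- design_row(dj, 5, NA)
  expect_equal(unname(r5$fixed), c(1, 5, 0, 0))
})

make_lmm_cohort <- function(n, beta = c(1, 0.5), beta_tilde = 0.3,
                            sds = c(0.6, 0.08, 0.1), sigma = 0.3,
                            seed = 1, tt_prob = 0.6, n_obs = 14,
                            tt_range = c(0.5, 3)) {
  set.seed(seed)
  ids <- sprintf("P%03d", 1:n)
  tt <- ifelse(runif(n) < tt_prob, runif(n, tt_range[1], tt_range[2]),
               NA_real_)
  times <- seq(0.5, 13.5, length.out = n_obs)
  L <- diag(sds)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- drop(L %*% rnorm(3))
    tp <- if (is.na(tt[i])) rep(0, n_obs) else pmax(0, times - tt[i])
    mu <- beta[1] + b[1] + (beta[2] + b[2]) * times + (beta_tilde + b[3]) * tp
    data.frame(patient_id = ids[i], covariate = "score", time_days = times,
               value = mu + rnorm(n_obs, 0, sigma))
  }))
  make_cohort(ids, time = rep(14, n), event = rep(0, n), tt = tt, obs = obs)
}

test_that("noiseless fixed-effect data are recovered exactly", {
  n <- 12
  ids <- sprintf("P%d", 1:n)
  times <- seq(0.5, 13.5, by = 1)
  obs <- do.call(rbind, lapply(ids, function(id)
    data.frame(patient_id = id, covariate = "score", time_days = times,
               value = 1 + 2 * times)))
  co <- make_cohort(ids, time = rep(14, n), event = rep(0, n), obs = obs)
  fit <- fit_lmm(co, "score", lmm_design("baseline"))
  expect_true(isTRUE(fit$flags$exact_fit))
  expect_lt(max(abs(fit$beta_full - c(1, 2))), 1e-6)
})

test_that("marginal ML recovers generative parameters within 2 SE", {
  # dispersed intervention times keep the random slope and random
  # post-intervention slope well separated (identifiable)
  co <- make_lmm_cohort(300, seed = 2002, tt_range = c(1, 8))
  fit <- fit_lmm(co, "score", lmm_design("nit"))
  truth <- c(1, 0.5, 0.3)
  for (k in 1:3) {
    expect_lt(abs(fit$beta_full[k] - truth[k]), 2 * fit$se$beta_full[k])
  }
  expect_lt(abs(fit$sigma - 0.3), 2 * fit$se$sigma)
  truthD <- diag(c(0.6, 0.08, 0.1)^2)
  vd <- nitjm:::vech(truthD)
  est <- nitjm:::vech(fit$D)
  for (k in seq_along(vd)) {
    expect_lt(abs(est[k] - vd[k]), 2 * fit$se$D[k] + 1e-10)
  }
})

test_that("single observation per patient flags unidentifiable random effects", {
  n <- 20
  ids <- sprintf("P%d", 1:n)
  obs <- data.frame(patient_id = ids, covariate = "score", time_days = 1,
                    value = rnorm(n, 5))
  co <- make_cohort(ids, time = rep(14, n), event = rep(0, n), obs = obs)
  expect_warning(fit <- fit_lmm(co, "score", lmm_design("baseline"),
                                min_obs = 1),
                 "unidentifiable")
  expect_true(isTRUE(fit$flags$unidentifiable))
})

test_that("predicted means combine fixed and random parts linearly", {
  d <- lmm_design("nit")
  fit <- list(beta_full = c(0, 1, -1), design = d)
  expect_equal(predict_mean(fit, rep(0, 3), 3, NULL), 3)
  expect_equal(predict_mean(fit, rep(0, 3), 3, 2), 2)
  expect_equal(predict_mean(fit, c(0.5, 0, 0), 3, 2), 2.5)
  expect_error(predict_mean(fit, rep(0, 3), 15, NULL), "\\[0, 14\\]")
  # continuity of the default (no-jump) design at the transition
  lhs <- predict_mean(fit, c(0.1, 0.2, 0.3), 2 - 1e-9, 2)
  rhs <- predict_mean(fit, c(0.1, 0.2, 0.3), 2 + 1e-9, 2)
  expect_lt(abs(lhs - rhs), 1e-7)
  # with beta_tilde = 0 and b_tilde = 0 the nit design reduces to baseline
  fb <- list(beta_full = c(0.4, 1.2), design = lmm_design("baseline"))
  fn <- list(beta_full = c(0.4, 1.2, 0), design = d)
  for (t in c(0, 1.3, 5, 14)) {
    expect_equal(predict_mean(fn, c(0.3, -0.1, 0), t, 2),
                 predict_mean(fb, c(0.3, -0.1), t, NULL), tolerance = 1e-12)
  }
})

test_that("analytic marginal likelihood matches Monte-Carlo integration", {
  design <- lmm_design("baseline")
  set.seed(5)
  dat <- lapply(1:3, function(i) {
    t <- c(1, 6)
    m <- nitjm:::design_matrix(design, t, NULL)
    list(id = as.character(i), y = c(2, 3) + rnorm(2), t = t,
         X = m$X, Z = m$Z)
  })
  beta <- c(1.5, 0.2)
  D <- matrix(c(0.5, 0.1, 0.1, 0.05), 2)
  sigma <- 0.4
  theta <- c(log(diag(chol(D))),
             chol(D)[1, 2] * 0 + t(chol(D))[2, 1], log(sigma))
  # analytic value from the fitting kernel at fixed beta
  stack <- nitjm:::lmm_stack(dat)
  analytic <- -nitjm:::lmm_full_nll(c(beta, theta), stack, 2, 2)
  # Monte-Carlo integration over random effects, patient by patient
  nmc <- 100000
  L <- t(chol(D))
  total <- 0
  total_se2 <- 0
  set.seed(6)
  for (p in dat) {
    bs <- L %*% matrix(rnorm(2 * nmc), 2)
    mu <- drop(p$X %*% beta)
    dens <- exp(colSums(dnorm(p$y, mu + p$Z %*% bs, sigma, log = TRUE)))
    mhat <- mean(dens)
    total <- total + log(mhat)
    total_se2 <- total_se2 + (sd(dens) / sqrt(nmc) / mhat)^2
  }
  expect_lt(abs(analytic - total), 3 * sqrt(total_se2))
})

test_that("marginal ML agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  co <- make_lmm_cohort(80, tt_prob = 0, seed = 9)
  fit <- fit_lmm(co, "score", lmm_design("baseline"))
  obs <- co$observations
  lf <- lme4::lmer(value ~ time_days + (time_days | patient_id), data = obs,
                   REML = FALSE,
                   control = lme4::lmerControl(check.conv.grad = "ignore"))
  expect_equal(unname(fit$beta_full), unname(lme4::fixef(lf)),
               tolerance = 1e-3)
  expect_equal(fit$sigma, stats::sigma(lf), tolerance = 1e-2)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(diag(fit$D)),
               vc$vcov[vc$grp == "patient_id" & is.na(vc$var2)],
               tolerance = 0.05)
  expect_equal(as.numeric(fit$loglik), as.numeric(stats::logLik(lf)),
               tolerance = 1e-4)
})
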