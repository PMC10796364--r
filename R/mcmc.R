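# Bayesian estimation of the joint model by adaptive
# Metropolis-Hastings-within-Gibbs sampling.
#
# Blocks per iteration: (i) residual variances and random-effect covariances
# by conjugate Gibbs (inverse-gamma / inverse-Wishart); (ii) gamma, alpha,
# each covariate's fixed effects, and the log baseline-hazard pieces by
# adaptive random-walk MH (Robbins-Monro scaling during warmup only, target
# acceptance 0.234 for vector blocks and 0.44 for scalars); (iii) each
# patient's stacked random effects by joint random-walk MH.

flatten_priors <- function(priors, spec) {
  d <- spec$design$d_random
  J <- length(spec$dynamic)
  list(gamma_mean = as.numeric(priors$gamma$mean),
       gamma_sd = as.numeric(priors$gamma$sd),
       alpha_mean = as.numeric(priors$alpha$mean),
       alpha_sd = as.numeric(priors$alpha$sd),
       beta_mean = unname(priors$beta$mean),
       beta_sd = unname(priors$beta$sd),
       lambda_mean = priors$lambda$mean, lambda_sd = priors$lambda$sd,
       sigma2_a = priors$sigma2$a, sigma2_b = priors$sigma2$b,
       D_nu = priors$D$nu,
       D_S = array(unlist(priors$D$S), dim = c(d, d, J)))
}

default_inits <- function(priors, spec) {
  J <- length(spec$dynamic)
  d <- spec$design$d_random
  list(gamma = as.numeric(priors$gamma$mean),
       alpha = rep(0, J),
       beta = unname(priors$beta$mean),
       lambda = priors$lambda$mean,
       sigma = sqrt(priors$sigma2$b / (priors$sigma2$a - 1)),
       D = lapply(seq_len(J), function(j)
         priors$D$S[[j]] / (priors$D$nu[j] - d - 1)))
}

#' Run the MCMC sampler for a joint model
#'
#' @param cohort an `sah_cohort`.
#' @param spec a [nitjm_spec()].
#' @param priors a [build_priors()] result.
#' @param chains number of chains (run sequentially; >= 2 enables R-hat).
#' @param iter total iterations per chain (warmup included).
#' @param warmup adaptation iterations discarded from the posterior.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param b_thin keep every `b_thin`-th post-warmup random-effect state.
#' @param seed integer seed; chain seeds are derived deterministically, so
#'   the same `(cohort, spec, priors, seed)` gives bit-identical draws.
#' @param store_b store thinned per-patient random-effect draws.
#' @param inits optional initial values (defaults to prior centres).
#' @return a `nitjm_draws` object: per-chain draw matrices, acceptance rates
#'   per block, split R-hat and effective sample size per parameter.
#' @export
run_mcmc <- function(cohort, spec, priors, chains = 2, iter = 4000,
                     warmup = 2000, thin = 1, b_thin = 10, seed = 1,
                     store_b = TRUE, inits = NULL) {
  stopifnot(inherits(spec, "nitjm_spec"), inherits(priors, "nitjm_priors"),
            iter > warmup, chains >= 1)
  data <- prepare_joint_data(cohort, spec)
  fp <- flatten_priors(priors, spec)
  init <- inits %||% default_inits(priors, spec)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, chains)
  nm <- param_names(spec)
  chains_out <- vector("list", chains)
  b_out <- vector("list", chains)
  accept <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    res <- .cpp_run_mcmc(data, fp, init, as.integer(iter),
                         as.integer(warmup), as.integer(thin),
                         as.integer(b_thin), store_b)
    m <- res$draws
    colnames(m) <- nm
    chains_out[[ch]] <- m
    b_out[[ch]] <- if (store_b) res$b_draws[, , seq_len(res$n_b_kept),
                                            drop = FALSE] else NULL
    accept[[ch]] <- res$accept
  }
  diag <- mcmc_diagnostics(chains_out)
  structure(list(chains = chains_out, b_chains = b_out, par_names = nm,
                 accept = accept, rhat = diag$rhat, ess = diag$ess,
                 patient_ids = data$ids,
                 settings = list(chains = chains, iter = iter,
                                 warmup = warmup, thin = thin,
                                 b_thin = b_thin, seed = seed,
                                 chain_seeds = chain_seeds)),
            class = "nitjm_draws")
}

# Split R-hat and a Geyer-style effective sample size per parameter.
mcmc_diagnostics <- function(chains_list) {
  nm <- colnames(chains_list[[1]])
  n <- nrow(chains_list[[1]])
  half <- floor(n / 2)
  splits <- unlist(lapply(chains_list, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])), recursive = FALSE)
  rhat <- vapply(nm, function(par) {
    mat <- vapply(splits, function(s) s[, par], numeric(half))
    W <- mean(apply(mat, 2, var))
    B <- half * var(colMeans(mat))
    if (W < 1e-300) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  ess <- vapply(nm, function(par) {
    tot <- 0
    for (m in chains_list) {
      x <- m[, par]
      v <- var(x)
      if (v < 1e-300) {
        tot <- tot + length(x)
        next
      }
      ac <- stats::acf(x, lag.max = min(200, length(x) - 2), plot = FALSE,
                       demean = TRUE)$acf[-1]
      s <- 0
      for (k in seq_along(ac)) {
        if (ac[k] < 0.05) break
        s <- s + ac[k]
      }
      tot <- tot + length(x) / (1 + 2 * s)
    }
    tot
  }, numeric(1))
  list(rhat = rhat, ess = ess)
}

#' Merge the chains of a draws object into one matrix
#' @param draws a `nitjm_draws`.
#' @return matrix of posterior draws (rows) by parameter (columns).
#' @export
as_matrix_draws <- function(draws) {
  do.call(rbind, draws$chains)
}

#' Posterior summary table in hazard-ratio layout
#'
#' Per parameter: posterior mean and SD, HR = exp(posterior mean), 95%
#' credible interval = exp(2.5th/97.5th percentiles), and a two-sided
#' posterior tail probability p = min(1, 2 min(P(theta>0), P(theta<0))),
#' floored at 2/(number of draws) when no draw crosses zero.
#'
#' @param draws a `nitjm_draws` or a draws matrix with named columns.
#' @param pars optional parameter subset.
#' @return data.frame with one row per parameter.
#' @export
summarize_draws <- function(draws, pars = NULL) {
  m <- if (inherits(draws, "nitjm_draws")) as_matrix_draws(draws) else
    as.matrix(draws)
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  nd <- nrow(m)
  out <- do.call(rbind, lapply(colnames(m), function(par) {
    x <- m[, par]
    qs <- quantile(x, c(0.025, 0.975), names = FALSE)
    ptail <- 2 * min(mean(x > 0), mean(x < 0))
    data.frame(parameter = par, mean = mean(x), sd = sd(x),
               hr = exp(mean(x)), ci_low = exp(qs[1]), ci_high = exp(qs[2]),
               p = min(1, max(ptail, 2 / nd)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.nitjm_draws <- function(x, ...) {
  s <- x$settings
  cat(sprintf("MCMC draws: %d chain(s) x %d kept iterations (%d warmup, thin %d)\n",
              s$chains, nrow(x$chains[[1]]), s$warmup, s$thin))
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f\n",
              max(x$rhat), min(x$ess)))
  invisible(x)
}

#' Fit a neurological-intervention-transition joint model
#'
#' The central fitting function. Sub-models are fitted first (a Breslow-ties
#' Cox model on the baseline covariates; a marginal-ML linear mixed model
#' per dynamic covariate) and used to centre the priors; the joint posterior
#' is then sampled by adaptive MH-within-Gibbs. With `mode = "nit"` the
#' trajectories and hazard gain post-intervention slope terms in
#' intervention-relative time; `mode = "baseline"` is the ordinary joint
#' model without the intervention transition.
#'
#' @param cohort an `sah_cohort` (typically after [daily_average()] and
#'   [dichotomize()]).
#' @param dynamic names of longitudinal covariates.
#' @param baseline names of baseline covariates (may be empty).
#' @param mode `"nit"` or `"baseline"`.
#' @param include_jump allow a trajectory discontinuity at the intervention.
#' @param knots baseline-hazard knots.
#' @param chains,iter,warmup,thin,b_thin,seed MCMC settings, see
#'   [run_mcmc()].
#' @param inflation prior-SD inflation over sub-model standard errors.
#' @param min_patients floor passed to [fit_lmm()].
#' @return an object of class `nitjm`.
#' @export
nitjm <- function(cohort, dynamic, baseline = character(),
                  mode = c("nit", "baseline"), include_jump = FALSE,
                  knots = NULL, chains = 2, iter = 4000, warmup = 2000,
                  thin = 1, b_thin = 10, seed = 1, inflation = 10,
                  min_patients = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "sah_cohort"))
  t0 <- proc.time()[["elapsed"]]
  knots <- knots %||% seq(0, cohort$horizon_days, length.out = 8)
  spec <- nitjm_spec(baseline = baseline, dynamic = dynamic, mode = mode,
                     include_jump = include_jump, knots = knots,
                     horizon = cohort$horizon_days)
  cox_fit <- if (length(baseline)) fit_cox(cohort, baseline) else NULL
  lmm_fits <- lapply(setNames(dynamic, dynamic), function(cv)
    fit_lmm(cohort, cv, design = spec$design, min_patients = min_patients))
  priors <- build_priors(cox_fit, lmm_fits, spec, inflation = inflation)
  draws <- run_mcmc(cohort, spec, priors, chains = chains, iter = iter,
                    warmup = warmup, thin = thin, b_thin = b_thin,
                    seed = seed)
  headline <- c(if (length(baseline)) paste0("gamma_", baseline),
                paste0("alpha_", dynamic))
  bad <- headline[draws$rhat[headline] > 1.1]
  if (length(bad)) {
    warning(sprintf("split R-hat > 1.1 for: %s; consider longer chains",
                    paste(bad, collapse = ", ")))
  }
  structure(list(spec = spec, priors = priors, draws = draws,
                 sub = list(cox = cox_fit, lmm = lmm_fits),
                 cohort = cohort, seed = seed,
                 runtime = proc.time()[["elapsed"]] - t0,
                 call = match.call()),
            class = "nitjm")
}

#' @export
print.nitjm <- function(x, ...) {
  cat(sprintf("%s joint model: %d patients, dynamic [%s], %d baseline covariate(s)\n",
              x$spec$mode, n_patients(x$cohort),
              paste(x$spec$dynamic, collapse = ", "),
              length(x$spec$baseline)))
  s <- x$draws$settings
  cat(sprintf("  %d chain(s) x %d iterations (%d warmup), seed %d; fitted in %.1f s\n",
              s$chains, s$iter, s$warmup, s$seed, x$runtime))
  tab <- summarize_draws(x$draws,
                         pars = paste0("alpha_", x$spec$dynamic))
  tab[-1] <- lapply(tab[-1], round, 4)
  cat("  association parameters (HR per unit of the trajectory mean):\n")
  print(tab[c("parameter", "hr", "ci_low", "ci_high", "p")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.nitjm <- function(object, ...) {
  spec <- object$spec
  assoc <- summarize_draws(object$draws, paste0("alpha_", spec$dynamic))
  basel <- if (length(spec$baseline))
    summarize_draws(object$draws, paste0("gamma_", spec$baseline)) else NULL
  beta_pars <- grep("^beta_|^sigma_|^log_h0_", object$draws$par_names,
                    value = TRUE)
  longi <- summarize_draws(object$draws, beta_pars)
  structure(list(association = assoc, baseline = basel,
                 longitudinal = longi,
                 rhat = object$draws$rhat, ess = object$draws$ess,
                 mode = spec$mode),
            class = "summary.nitjm")
}

#' @export
print.summary.nitjm <- function(x, ...) {
  cat(sprintf("%s joint model - posterior summaries\n", x$mode))
  cat("\nDynamic covariates (HR per unit of trajectory mean):\n")
  a <- x$association
  a[-1] <- lapply(a[-1], round, 4)
  print(a[c("parameter", "hr", "ci_low", "ci_high", "p")], row.names = FALSE)
  if (!is.null(x$baseline)) {
    cat("\nBaseline covariates (HR):\n")
    b <- x$baseline
    b[-1] <- lapply(b[-1], round, 4)
    print(b[c("parameter", "hr", "ci_low", "ci_high", "p")],
          row.names = FALSE)
  }
  cat(sprintf("\nmax split R-hat %.3f, min ESS %.0f\n", max(x$rhat),
              min(x$ess)))
  invisible(x)
}

#' @export
coef.nitjm <- function(object, ...) {
  colMeans(as_matrix_draws(object$draws))
}

#' Posterior-mean parameter set of a fitted joint model
#' @param object a `nitjm` fit.
#' @return a [nitjm_params()] at the posterior means.
#' @export
posterior_params <- function(object) {
  vector_to_params(coef(object), object$spec)
}

#' @export
plot.nitjm <- function(x, pars = NULL, ...) {
  pars <- pars %||% c(paste0("alpha_", x$spec$dynamic),
                      if (length(x$spec$baseline))
                        paste0("gamma_", head(x$spec$baseline, 3)))
  op <- graphics::par(mfrow = c(length(pars), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (par in pars) {
    rng <- range(unlist(lapply(x$draws$chains, function(m) m[, par])))
    graphics::plot(x$draws$chains[[1]][, par], type = "l", ylim = rng,
                   ylab = par, xlab = "", col = 1, ...)
    if (length(x$draws$chains) > 1) {
      for (ch in 2:length(x$draws$chains)) {
        graphics::lines(x$draws$chains[[ch]][, par], col = ch)
      }
    }
  }
  invisible(x)
}

#' Posterior-predictive cohort simulation from a fitted model
#'
#' Simulates `nsim` cohorts from the posterior-mean parameters, resampling
#' baseline covariate rows and scheduled intervention times from the fitted
#' cohort.
#'
#' @param object a `nitjm` fit (nit mode).
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n patients per cohort (defaults to the fitted cohort size).
#' @param ... unused.
#' @return list of `sah_cohort`s.
#' @export
simulate.nitjm <- function(object, nsim = 1, seed = 1, n = NULL, ...) {
  spec <- object$spec
  if (spec$mode != "nit" || spec$include_jump) {
    stop("posterior-predictive simulation is implemented for the no-jump nit design",
         call. = FALSE)
  }
  pm <- posterior_params(object)
  out <- object$cohort$outcomes
  n <- n %||% nrow(out)
  tt_obs <- out$intervention_time_days
  p_int <- mean(!is.na(tt_obs))
  rng <- if (any(!is.na(tt_obs))) range(tt_obs, na.rm = TRUE) else c(0.5, 3)
  dynamic <- setNames(lapply(seq_along(spec$dynamic), function(j) {
    list(beta = unname(pm$beta[j, c("(Intercept)", "t")]),
         beta_tilde = unname(pm$beta[j, "t_plus"]),
         D = pm$D[[j]], sigma = unname(pm$sigma[j]),
         alpha = unname(pm$alpha[j]))
  }), spec$dynamic)
  prev <- vapply(spec$baseline, function(cv)
    mean(object$cohort$baseline[[cv]]), numeric(1))
  tp <- nit_true_params(baseline_prev = prev, gamma = pm$gamma,
                        dynamic = dynamic, log_h0 = pm$lambda,
                        knots = spec$knots, intervention_prob = p_int,
                        intervention_time = c(max(rng[1], 0.01), rng[2] +
                                                1e-6),
                        horizon = spec$horizon)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, nsim)
  lapply(seq_len(nsim), function(k)
    simulate_cohort(n, tp, seed = seeds[k])$cohort)
}
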