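# Piecewise linear mixed-effects trajectory sub-models.
#
# The default basis is linear in time with a patient-level random intercept
# and slope; in the intervention-transition ("nit") design the intervention
# adds a fixed and a random slope change in intervention-relative time
# t_plus = max(0, t - t_tilde), keeping the mean trajectory continuous at the
# transition. An optional jump term (fixed intercept shift at the transition)
# is available behind `include_jump`.

#' Time relative to the neurological intervention
#'
#' `t_plus(t, t_tilde) = max(0, t - t_tilde)`. Post-intervention basis terms
#' are functions of this quantity, so they vanish before the intervention.
#' Patients without an intervention are handled in [design_row()] (their
#' post-intervention entries are identically zero); passing a missing
#' `t_tilde` here is an error.
#'
#' @param t time in days (vectorized).
#' @param t_tilde intervention time in days.
#' @return `pmax(0, t - t_tilde)`.
#' @export
t_plus <- function(t, t_tilde) {
  if (any(!is.finite(t)) || any(!is.finite(t_tilde))) {
    stop("t and t_tilde must be finite; absent interventions are handled in design_row()",
         call. = FALSE)
  }
  if (any(t < 0) || any(t_tilde < 0)) {
    stop("t and t_tilde must be non-negative", call. = FALSE)
  }
  pmax(0, t - t_tilde)
}

#' Trajectory design specification
#'
#' @param mode `"baseline"` (fixed and random basis `(1, t)`) or `"nit"`
#'   (adds post-intervention slope terms in `t_plus`).
#' @param include_jump add a fixed intercept-at-transition term (indicator of
#'   `t >= t_tilde`), allowing a discontinuity at the intervention.
#' @param horizon study horizon in days.
#' @return an `lmm_design`.
#' @export
lmm_design <- function(mode = c("nit", "baseline"), include_jump = FALSE,
                       horizon = 14) {
  mode <- match.arg(mode)
  if (mode == "baseline" && include_jump) {
    stop("a jump term requires the nit design", call. = FALSE)
  }
  fixed <- c("(Intercept)", "t")
  random <- c("(Intercept)", "t")
  if (mode == "nit") {
    if (include_jump) fixed <- c(fixed, "jump")
    fixed <- c(fixed, "t_plus")
    random <- c(random, "t_plus")
  }
  structure(list(mode = mode, include_jump = include_jump, horizon = horizon,
                 fixed_names = fixed, random_names = random,
                 q_fixed = length(fixed), d_random = length(random)),
            class = "lmm_design")
}

#' @export
print.lmm_design <- function(x, ...) {
  cat(sprintf("trajectory design (%s%s): fixed [%s], random [%s], horizon %g days\n",
              x$mode, if (x$include_jump) ", with jump" else "",
              paste(x$fixed_names, collapse = ", "),
              paste(x$random_names, collapse = ", "), x$horizon))
  invisible(x)
}

#' Evaluate a design at one time point
#'
#' Returns the fixed- and random-effects regression rows at time `t`. All
#' post-intervention entries are exactly zero when `t < t_tilde` or when the
#' patient has no intervention (`t_tilde` missing/NA).
#'
#' @param design an [lmm_design()].
#' @param t time in days.
#' @param t_tilde intervention time in days, or `NULL`/`NA` for none.
#' @return list with named numeric vectors `fixed` and `random`.
#' @export
design_row <- function(design, t, t_tilde = NULL) {
  m <- design_matrix(design, t, t_tilde)
  list(fixed = setNames(m$X[1L, ], design$fixed_names),
       random = setNames(m$Z[1L, ], design$random_names))
}

# Vectorized design builder: X (length(t) x q_fixed), Z (length(t) x d_random)
design_matrix <- function(design, t, t_tilde = NULL) {
  stopifnot(inherits(design, "lmm_design"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > design$horizon + 1e-9)) {
    stop(sprintf("t must lie in [0, %g]", design$horizon), call. = FALSE)
  }
  has_int <- !is.null(t_tilde) && length(t_tilde) == 1 && !is.na(t_tilde)
  tp <- if (has_int) t_plus(t, t_tilde) else rep(0, length(t))
  X <- cbind(1, t)
  Z <- cbind(1, t)
  if (design$mode == "nit") {
    if (design$include_jump) {
      X <- cbind(X, if (has_int) as.numeric(t >= t_tilde) else rep(0, length(t)))
    }
    X <- cbind(X, tp)
    Z <- cbind(Z, tp)
  }
  colnames(X) <- design$fixed_names
  colnames(Z) <- design$random_names
  list(X = X, Z = Z)
}

# Assemble per-patient regression pieces for one longitudinal covariate.
lmm_patient_data <- function(cohort, covariate, design) {
  obs <- cohort$observations
  obs <- obs[obs$covariate == covariate, , drop = FALSE]
  if (!nrow(obs)) {
    stop(sprintf("no observations for covariate '%s'", covariate),
         call. = FALSE)
  }
  out <- cohort$outcomes
  ids <- out$patient_id
  tt <- setNames(out$intervention_time_days, ids)
  keep <- ids[ids %in% unique(obs$patient_id)]
  dat <- lapply(keep, function(id) {
    sub <- obs[obs$patient_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_days), , drop = FALSE]
    m <- design_matrix(design, sub$time_days, tt[[id]])
    list(id = id, y = sub$value, t = sub$time_days, X = m$X, Z = m$Z)
  })
  names(dat) <- keep
  dat
}

# Build D = L L' from the unconstrained log-Cholesky parametrization.
chol_from_par <- function(theta_d, d) {
  L <- matrix(0, d, d)
  diag(L) <- exp(theta_d[seq_len(d)])
  if (d > 1) L[lower.tri(L)] <- theta_d[-seq_len(d)]
  L
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

vech_names <- function(nm) {
  d <- length(nm)
  idx <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  sprintf("D[%s,%s]", nm[idx[, 1]], nm[idx[, 2]])
}

# Stack per-patient blocks for the compiled marginal-likelihood kernel.
lmm_stack <- function(dat) {
  list(y = unlist(lapply(dat, `[[`, "y"), use.names = FALSE),
       X = do.call(rbind, lapply(dat, `[[`, "X")),
       Z = do.call(rbind, lapply(dat, `[[`, "Z")),
       off = as.integer(c(0, cumsum(vapply(dat, function(p)
         length(p$y), numeric(1))))))
}

# Marginal Gaussian log-likelihood with beta profiled out by GLS
# (V_i = Z_i D Z_i' + sigma^2 I per patient, evaluated in compiled code).
lmm_profile <- function(theta, stack, q, d) {
  res <- .cpp_lmm_nll(theta, stack$y, stack$X, stack$Z, stack$off,
                      numeric(0))
  if (!res$ok || !is.finite(res$nll)) return(NULL)
  L <- chol_from_par(theta[seq_len(d * (d + 1) / 2)], d)
  list(nll = res$nll, beta = drop(res$beta), D = tcrossprod(L),
       sigma = exp(theta[length(theta)]))
}

# Full (beta, variance-parameter) negative marginal log-likelihood.
lmm_full_nll <- function(par, stack, q, d) {
  res <- .cpp_lmm_nll(par[-seq_len(q)], stack$y, stack$X, stack$Z,
                      stack$off, par[seq_len(q)])
  res$nll
}

#' Fit a linear mixed-effects trajectory sub-model
#'
#' Maximizes the marginal Gaussian likelihood (random effects integrated out
#' analytically) by BFGS on an unconstrained parametrization: log-Cholesky
#' factor for the random-effect covariance D and log residual SD. Standard
#' errors come from the observed information at the optimum, with a delta
#' method for the entries of D and sigma. Marginal ML (not REML) is used so
#' sub-model likelihoods are comparable with the joint model and usable for
#' prior construction.
#'
#' @param cohort an `sah_cohort`.
#' @param covariate name of the longitudinal covariate to model.
#' @param design an [lmm_design()]; defaults to the nit design when the
#'   cohort contains interventions, otherwise the baseline design.
#' @param min_patients minimum number of patients with at least `min_obs`
#'   observations.
#' @param min_obs see `min_patients`.
#' @return an object of class `sah_lmm` with elements `beta` (pre-transition
#'   fixed effects), `beta_tilde` (post-transition fixed effects),
#'   `beta_full`, `D`, `sigma`, `loglik`, `se` (named, for all parameters),
#'   `converged`, `gradient_norm` and flags.
#' @export
fit_lmm <- function(cohort, covariate, design = NULL,
                    min_patients = 10, min_obs = 2) {
  stopifnot(inherits(cohort, "sah_cohort"))
  if (is.null(design)) {
    has_int <- any(!is.na(cohort$outcomes$intervention_time_days))
    design <- lmm_design(if (has_int) "nit" else "baseline",
                         horizon = cohort$horizon_days)
  }
  dat <- lmm_patient_data(cohort, covariate, design)
  n_obs_per <- vapply(dat, function(p) length(p$y), numeric(1))
  if (sum(n_obs_per >= min_obs) < min_patients) {
    stop(sprintf(
      "need >= %d observations for >= %d patients (found %d) for covariate '%s'",
      min_obs, min_patients, sum(n_obs_per >= min_obs), covariate),
      call. = FALSE)
  }
  q <- design$q_fixed
  d <- design$d_random
  stack <- lmm_stack(dat)
  X_all <- stack$X
  y_all <- stack$y

  ols <- stats::lm.fit(X_all, y_all)
  ols_beta <- ols$coefficients
  ols_beta[is.na(ols_beta)] <- 0
  ols_sd <- sqrt(sum(ols$residuals^2) / max(1, length(y_all) - q))

  make_fit <- function(beta_full, D, sigma, se, loglik, converged,
                       gradient_norm, flags) {
    pre <- !grepl("jump|t_plus", design$fixed_names)
    structure(list(
      covariate = covariate, design = design,
      beta = setNames(beta_full[pre], design$fixed_names[pre]),
      beta_tilde = setNames(beta_full[!pre], design$fixed_names[!pre]),
      beta_full = setNames(beta_full, design$fixed_names),
      D = structure(D, dimnames = list(design$random_names,
                                       design$random_names)),
      sigma = sigma, loglik = loglik, se = se, converged = converged,
      gradient_norm = gradient_norm, flags = flags,
      n_patients = length(dat), n_obs = length(y_all)),
      class = "sah_lmm")
  }

  # Degenerate designs: too few observations per patient to identify D.
  if (max(n_obs_per) < d) {
    warning(sprintf(
      "covariate '%s': fewer observations per patient than random effects; random-effect covariance is unidentifiable",
      covariate))
    se <- list(beta_full = rep(NA_real_, q), sigma = NA_real_,
               D = rep(NA_real_, d * (d + 1) / 2))
    return(make_fit(ols_beta, matrix(0, d, d), ols_sd, se, NA_real_,
                    FALSE, NA_real_, list(unidentifiable = TRUE)))
  }
  # Exact-fit limit: data noiseless and fully explained by fixed effects.
  if (ols_sd < 1e-10) {
    se <- list(beta_full = rep(0, q), sigma = 0, D = rep(0, d * (d + 1) / 2))
    return(make_fit(ols_beta, matrix(0, d, d), ols_sd, se, Inf, TRUE, 0,
                    list(exact_fit = TRUE)))
  }

  n_vpar <- d * (d + 1) / 2 + 1
  theta0 <- c(log(rep(0.3 * ols_sd + 1e-3, d)), rep(0, d * (d - 1) / 2),
              log(0.8 * ols_sd))
  obj <- function(theta) {
    pr <- lmm_profile(theta, stack, q, d)
    if (is.null(pr) || !is.finite(pr$nll)) 1e10 else pr$nll
  }
  opt <- optim(theta0, obj, method = "BFGS",
               control = list(maxit = 400, reltol = 1e-12))
  pr <- lmm_profile(opt$par, stack, q, d)
  if (is.null(pr)) stop("mixed-model optimization failed", call. = FALSE)
  beta_hat <- pr$beta
  D_hat <- pr$D
  sigma_hat <- pr$sigma

  flags <- list()
  if (any(diag(D_hat) < 1e-8)) {
    D_hat <- D_hat + diag(1e-8, d)
    flags$boundary_ridge <- TRUE
    warning(sprintf(
      "covariate '%s': random-effect covariance at boundary; ridge of 1e-8 added",
      covariate))
  }

  par_hat <- c(beta_hat, opt$par)
  H <- tryCatch(optimHess(par_hat, lmm_full_nll, stack = stack, q = q,
                          d = d),
                error = function(e) NULL)
  cov_par <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  se_beta <- rep(NA_real_, q)
  se_sigma <- NA_real_
  se_D <- rep(NA_real_, d * (d + 1) / 2)
  if (!is.null(cov_par) && all(is.finite(diag(cov_par))) &&
      all(diag(cov_par) > -1e-8)) {
    dg <- pmax(diag(cov_par), 0)
    se_beta <- sqrt(dg[seq_len(q)])
    # Delta method: map variance parameters to (vech D, sigma).
    gfun <- function(theta) {
      L <- chol_from_par(theta[seq_len(d * (d + 1) / 2)], d)
      c(vech(tcrossprod(L)), exp(theta[length(theta)]))
    }
    th <- opt$par
    Jg <- matrix(0, d * (d + 1) / 2 + 1, n_vpar)
    for (k in seq_len(n_vpar)) {
      h <- 1e-5 * max(1, abs(th[k]))
      tp <- th; tp[k] <- tp[k] + h
      tm <- th; tm[k] <- tm[k] - h
      Jg[, k] <- (gfun(tp) - gfun(tm)) / (2 * h)
    }
    cov_v <- cov_par[q + seq_len(n_vpar), q + seq_len(n_vpar), drop = FALSE]
    vd <- diag(Jg %*% cov_v %*% t(Jg))
    vd <- pmax(vd, 0)
    se_D <- sqrt(vd[seq_len(d * (d + 1) / 2)])
    se_sigma <- sqrt(vd[length(vd)])
  }

  grad <- tryCatch({
    eps <- 1e-6
    g <- vapply(seq_along(opt$par), function(k) {
      tp <- opt$par; tp[k] <- tp[k] + eps
      tm <- opt$par; tm[k] <- tm[k] - eps
      (obj(tp) - obj(tm)) / (2 * eps)
    }, numeric(1))
    sqrt(sum(g^2))
  }, error = function(e) NA_real_)
  converged <- opt$convergence == 0
  if (!converged) {
    warning(sprintf(
      "covariate '%s': optimizer did not report convergence (final gradient norm %.3g)",
      covariate, grad))
  }

  se <- list(beta_full = setNames(se_beta, design$fixed_names),
             sigma = se_sigma,
             D = setNames(se_D, vech_names(design$random_names)))
  make_fit(beta_hat, D_hat, sigma_hat, se, -opt$value, converged, grad, flags)
}

#' @export
print.sah_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed trajectory model for '%s' (%s design)\n",
              x$covariate, x$design$mode))
  cat(sprintf("  %d patients, %d observations, marginal logLik %.3f\n",
              x$n_patients, x$n_obs, x$loglik))
  est <- data.frame(estimate = x$beta_full, se = x$se$beta_full)
  print(round(est, 4))
  cat(sprintf("  residual SD %.4f; random-effect SDs: %s\n", x$sigma,
              paste(sprintf("%.4f", sqrt(diag(x$D))), collapse = ", ")))
  invisible(x)
}

#' Predicted mean trajectory for one patient
#'
#' Deterministic inner product of the design rows with the fixed effects and
#' a supplied random-effect vector.
#'
#' @param fit an `sah_lmm` (or any list with `beta_full` and `design`).
#' @param b_i random-effect vector of length `design$d_random`.
#' @param t times in days (vectorized), within `[0, horizon]`.
#' @param t_tilde intervention time or `NULL`/`NA` for none.
#' @return numeric vector of means m(t).
#' @export
predict_mean <- function(fit, b_i, t, t_tilde = NULL) {
  design <- fit$design
  if (any(t < 0 | t > design$horizon)) {
    stop(sprintf("t must lie in [0, %g]", design$horizon), call. = FALSE)
  }
  m <- design_matrix(design, t, t_tilde)
  drop(m$X %*% fit$beta_full + m$Z %*% b_i)
}

# Conditional longitudinal log-density given random effects, plus the
# multivariate-normal random-effect log-prior (used in reduction tests and
# for building the joint likelihood from the sub-model side).
lmm_conditional_loglik <- function(beta_full, sigma, D, dat, b_list,
                                   include_prior = TRUE) {
  ll <- 0
  d <- nrow(D)
  Dinv <- solve(D)
  ldet <- determinant(D, logarithm = TRUE)$modulus
  for (k in seq_along(dat)) {
    p <- dat[[k]]
    b <- b_list[[k]]
    mu <- drop(p$X %*% beta_full + p$Z %*% b)
    ll <- ll + sum(dnorm(p$y, mu, sigma, log = TRUE))
    if (include_prior) {
      ll <- ll - 0.5 * (d * log(2 * pi) + as.numeric(ldet) +
                          drop(t(b) %*% Dinv %*% b))
    }
  }
  ll
}
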