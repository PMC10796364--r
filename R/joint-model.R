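# The neurological-intervention-transition (NIT) joint model.
#
# Shared-parameter joint model: each dynamic covariate follows a (piecewise)
# linear mixed trajectory m_j(t) whose slope may change at the
# patient-specific intervention time, and the hazard of good outcome is
#   h_i(t) = h0(t) * exp(gamma' omega_i + sum_j alpha_j m_ji(t))
# with a piecewise-constant log baseline hazard h0. The "baseline" joint
# model is the special case with no post-intervention terms.

# 7-point Gauss-Legendre rule on [-1, 1].
.gl7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
        0.1294849661688697))

#' Joint model specification
#'
#' @param baseline names of baseline covariates entering the hazard.
#' @param dynamic names of longitudinal covariates (each gets a trajectory
#'   sub-model and an association parameter alpha).
#' @param mode `"nit"` (trajectories and hazard gain post-intervention
#'   terms) or `"baseline"` (no intervention terms).
#' @param include_jump add a fixed intercept shift at the transition.
#' @param knots strictly increasing baseline-hazard knots spanning
#'   `[0, horizon]`; the log baseline hazard is constant on each interval.
#' @param horizon study horizon in days.
#' @return a `nitjm_spec`.
#' @export
nitjm_spec <- function(baseline, dynamic, mode = c("nit", "baseline"),
                       include_jump = FALSE, knots = seq(0, 14, by = 2),
                       horizon = 14) {
  mode <- match.arg(mode)
  if (length(dynamic) < 1) {
    stop("at least one dynamic covariate is required", call. = FALSE)
  }
  if (length(knots) < 2 || any(diff(knots) <= 0) ||
      abs(knots[1]) > 1e-12 || abs(knots[length(knots)] - horizon) > 1e-9) {
    stop("knots must be strictly increasing and span [0, horizon]",
         call. = FALSE)
  }
  design <- lmm_design(mode, include_jump = include_jump, horizon = horizon)
  structure(list(baseline = baseline, dynamic = dynamic, mode = mode,
                 include_jump = include_jump, knots = knots,
                 horizon = horizon, design = design,
                 n_pieces = length(knots) - 1L),
            class = "nitjm_spec")
}

#' @export
print.nitjm_spec <- function(x, ...) {
  cat(sprintf("%s joint model spec: %d baseline covariate(s), dynamic [%s]\n",
              x$mode, length(x$baseline), paste(x$dynamic, collapse = ", ")))
  cat(sprintf("  piecewise-constant log baseline hazard, %d pieces, knots: %s\n",
              x$n_pieces, paste(x$knots, collapse = ", ")))
  invisible(x)
}

#' Joint-model parameter set
#'
#' @param gamma named log-hazard-ratio vector for baseline covariates (may
#'   be length zero).
#' @param alpha named association vector, one entry per dynamic covariate.
#' @param beta fixed-effect matrix, one row per dynamic covariate, columns
#'   matching the design's fixed basis.
#' @param lambda log baseline-hazard pieces.
#' @param sigma named residual SDs per dynamic covariate.
#' @param D list of random-effect covariance matrices per dynamic covariate.
#' @param spec the `nitjm_spec` the parameters belong to.
#' @return a validated `nitjm_params` list.
#' @export
nitjm_params <- function(gamma, alpha, beta, lambda, sigma, D, spec) {
  stopifnot(inherits(spec, "nitjm_spec"))
  p <- length(spec$baseline)
  J <- length(spec$dynamic)
  q <- spec$design$q_fixed
  d <- spec$design$d_random
  beta <- rbind(beta)
  if (length(gamma) != p || length(alpha) != J || nrow(beta) != J ||
      ncol(beta) != q || length(lambda) != spec$n_pieces ||
      length(sigma) != J || length(D) != J) {
    stop("parameter dimensions do not match the spec", call. = FALSE)
  }
  if (any(!is.finite(c(gamma, alpha, beta, lambda, sigma)))) {
    stop("parameters must be finite", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  for (j in seq_len(J)) {
    Dj <- as.matrix(D[[j]])
    if (!isTRUE(all.equal(Dj, t(Dj))) ||
        inherits(tryCatch(chol(Dj), error = identity), "error")) {
      stop(sprintf("D for covariate '%s' is not symmetric positive definite",
                   spec$dynamic[j]), call. = FALSE)
    }
  }
  structure(list(gamma = setNames(as.numeric(gamma), spec$baseline),
                 alpha = setNames(as.numeric(alpha), spec$dynamic),
                 beta = structure(beta,
                                  dimnames = list(spec$dynamic,
                                                  spec$design$fixed_names)),
                 lambda = as.numeric(lambda),
                 sigma = setNames(as.numeric(sigma), spec$dynamic),
                 D = setNames(lapply(D, as.matrix), spec$dynamic)),
            class = "nitjm_params")
}

# Piece index of the piecewise-constant baseline hazard at time t
# (intervals (k_l, k_{l+1}]; t = 0 is clamped to the first piece).
h0_piece <- function(t, knots) {
  pmax(1L, findInterval(t, knots, left.open = TRUE, rightmost.closed = TRUE))
}

# Trajectory means m_j(t) for one patient: length(t) x J matrix.
trajectory_means <- function(t, t_tilde, params, b, spec) {
  m <- design_matrix(spec$design, t, t_tilde)
  M <- m$X %*% t(params$beta)
  if (!is.null(b)) M <- M + m$Z %*% t(rbind(b))
  M
}

#' Hazard of good outcome for one patient
#'
#' `h(t) = h0(t) exp(gamma' omega + sum_j alpha_j m_j(t))`, with the
#' trajectory means following the pre- or post-intervention branch of the
#' design depending on `t` and the patient's intervention time.
#'
#' @param patient list with `omega` (named baseline covariate values covering
#'   `spec$baseline`) and `intervention_time_days` (`NA` for none).
#' @param t times in days, in `(0, horizon]` (vectorized).
#' @param params a [nitjm_params()].
#' @param b random-effect matrix, one row per dynamic covariate (columns =
#'   random basis). `NULL` means all-zero random effects.
#' @param spec the `nitjm_spec`.
#' @return numeric vector of hazards.
#' @export
joint_hazard <- function(patient, t, params, b = NULL, spec) {
  omega <- patient$omega[spec$baseline]
  if (length(spec$baseline) && anyNA(omega)) {
    stop("patient omega is missing baseline covariates", call. = FALSE)
  }
  tt <- patient$intervention_time_days %||% NA_real_
  M <- trajectory_means(t, tt, params, b, spec)
  lp <- params$lambda[h0_piece(t, spec$knots)] +
    sum(params$gamma * omega) + drop(M %*% params$alpha)
  if (any(!is.finite(lp) & !is.infinite(lp))) {
    stop("non-finite hazard exponent; parameters: ",
         paste(utils::capture.output(str(params)), collapse = " "),
         call. = FALSE)
  }
  exp(lp)
}

# Quadrature nodes for the integral of the hazard over (from, upper]:
# subintervals delimited by the baseline-hazard knots and the intervention
# time, a 7-point Gauss-Legendre rule on each. Returns data.frame(t, w, piece).
quad_nodes <- function(upper, t_tilde, knots, from = 0) {
  if (upper <= from + 1e-14) {
    return(data.frame(t = numeric(), w = numeric(), piece = integer()))
  }
  brk <- knots[knots > from + 1e-12 & knots < upper - 1e-12]
  if (!is.na(t_tilde) && t_tilde > from + 1e-12 && t_tilde < upper - 1e-12) {
    brk <- c(brk, t_tilde)
  }
  brk <- sort(unique(c(from, brk, upper)))
  a <- brk[-length(brk)]
  bnd <- brk[-1]
  half <- (bnd - a) / 2
  mid <- (bnd + a) / 2
  t_nodes <- as.vector(outer(.gl7$x, half) + rep(mid, each = 7))
  w_nodes <- as.vector(outer(.gl7$w, half))
  data.frame(t = t_nodes, w = w_nodes, piece = h0_piece(t_nodes, knots))
}

#' Cumulative hazard for one patient
#'
#' Integral of [joint_hazard()] over `(0, t]`, by 7-point Gauss-Legendre
#' quadrature on each subinterval delimited by the baseline-hazard knots and
#' the intervention time. The integrand is piecewise log-linear in `t`, for
#' which this rule is accurate to well below 1e-8 relative error at the
#' parameter scales of this model.
#'
#' @inheritParams joint_hazard
#' @param t upper limits in `[0, horizon]` (vectorized).
#' @return numeric vector of cumulative hazards.
#' @export
joint_cumulative_hazard <- function(patient, t, params, b = NULL, spec) {
  tt <- patient$intervention_time_days %||% NA_real_
  vapply(t, function(u) {
    qn <- quad_nodes(u, tt, spec$knots)
    if (!nrow(qn)) return(0)
    h <- joint_hazard(patient, qn$t, params, b, spec)
    sum(qn$w * h)
  }, numeric(1))
}

# Patient list view of a cohort for the joint likelihood.
cohort_patients <- function(cohort, spec) {
  out <- cohort$outcomes
  bl <- cohort$baseline[match(out$patient_id, cohort$baseline$patient_id), ,
                        drop = FALSE]
  lapply(seq_len(nrow(out)), function(i) {
    list(id = out$patient_id[i],
         omega = setNames(as.numeric(bl[i, spec$baseline]), spec$baseline),
         event_time_days = out$event_time_days[i],
         good_outcome = out$good_outcome[i],
         intervention_time_days = out$intervention_time_days[i])
  })
}

#' Joint log-likelihood of longitudinal and survival data given random effects
#'
#' Sum over patients of the Gaussian longitudinal log-density, the survival
#' log-likelihood `delta * log h(T) - H(T)`, and the multivariate-normal
#' log-density of the random effects. The three components are attached as
#' the `"components"` attribute (`longitudinal`, `survival`, `ranef_prior`).
#'
#' @param params a [nitjm_params()].
#' @param b named list (by patient id) of random-effect matrices (rows =
#'   dynamic covariates, columns = random basis), or `NULL` for all zero.
#' @param cohort an `sah_cohort`.
#' @param spec the `nitjm_spec`.
#' @return the total log-likelihood with attribute `"components"`.
#' @export
joint_log_likelihood <- function(params, b, cohort, spec) {
  pats <- cohort_patients(cohort, spec)
  J <- length(spec$dynamic)
  d <- spec$design$d_random
  obs <- cohort$observations
  ll_long <- 0
  ll_surv <- 0
  ll_prior <- 0
  Dinv <- lapply(params$D, solve)
  ldet <- vapply(params$D, function(Dj)
    as.numeric(determinant(Dj, logarithm = TRUE)$modulus), numeric(1))
  for (pat in pats) {
    bi <- if (is.null(b)) matrix(0, J, d) else rbind(b[[pat$id]])
    for (j in seq_len(J)) {
      cv <- spec$dynamic[j]
      sel <- obs$patient_id == pat$id & obs$covariate == cv
      if (any(sel)) {
        tj <- obs$time_days[sel]
        yj <- obs$value[sel]
        M <- trajectory_means(tj, pat$intervention_time_days, params, bi,
                              spec)[, j]
        ll_long <- ll_long + sum(dnorm(yj, M, params$sigma[j], log = TRUE))
      }
      ll_prior <- ll_prior - 0.5 * (d * log(2 * pi) + ldet[j] +
                                      drop(bi[j, ] %*% Dinv[[j]] %*% bi[j, ]))
    }
    Ti <- pat$event_time_days
    ll_surv <- ll_surv +
      pat$good_outcome * log(joint_hazard(pat, Ti, params, bi, spec)) -
      joint_cumulative_hazard(pat, Ti, params, bi, spec)
  }
  total <- unname(ll_long + ll_surv + ll_prior)
  attr(total, "components") <- c(longitudinal = unname(ll_long),
                                 survival = unname(ll_surv),
                                 ranef_prior = unname(ll_prior))
  total
}

#' Build priors from separately fitted sub-models
#'
#' Regression-type parameters (gamma, beta, beta_tilde, log baseline-hazard
#' pieces) get normal priors centred at the sub-model estimates with SD =
#' `inflation` times the sub-model standard error; association parameters
#' alpha (which have no sub-model analogue) get Normal(0, 2^2); residual
#' variances get inverse-gamma priors and random-effect covariances
#' inverse-Wishart priors, both weakly informative and centred at the
#' sub-model values.
#'
#' @param cox_fit an `sah_cox` on the spec's baseline covariates.
#' @param lmm_fits named list of `sah_lmm` fits, one per dynamic covariate.
#' @param spec the `nitjm_spec`.
#' @param inflation multiplier applied to sub-model standard errors.
#' @return a `nitjm_priors` list.
#' @export
build_priors <- function(cox_fit, lmm_fits, spec, inflation = 10) {
  stopifnot(inherits(spec, "nitjm_spec"))
  p <- length(spec$baseline)
  J <- length(spec$dynamic)
  q <- spec$design$q_fixed
  d <- spec$design$d_random
  miss <- setdiff(spec$dynamic, names(lmm_fits))
  if (length(miss)) {
    stop(sprintf("missing longitudinal sub-model fit(s) for: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  fallback_sd <- function(s, centre) {
    s <- abs(s)
    bad <- !is.finite(s) | s < 1e-6
    s[bad] <- pmax(abs(centre[bad]), 1) * 0.1
    s
  }
  if (p) {
    stopifnot(inherits(cox_fit, "sah_cox"))
    miss <- setdiff(spec$baseline, names(cox_fit$gamma))
    if (length(miss)) {
      stop(sprintf("Cox fit is missing baseline covariate(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    gamma_mean <- cox_fit$gamma[spec$baseline]
    gamma_sd <- inflation * fallback_sd(cox_fit$se[spec$baseline], gamma_mean)
  } else {
    gamma_mean <- numeric(0)
    gamma_sd <- numeric(0)
  }

  beta_mean <- matrix(0, J, q, dimnames = list(spec$dynamic,
                                               spec$design$fixed_names))
  beta_sd <- beta_mean
  sigma_a <- rep(3, J)
  sigma_b <- numeric(J)
  D_nu <- rep(d + 2, J)
  D_S <- vector("list", J)
  for (j in seq_len(J)) {
    f <- lmm_fits[[spec$dynamic[j]]]
    bf <- f$beta_full
    common <- intersect(names(bf), spec$design$fixed_names)
    beta_mean[j, common] <- bf[common]
    se <- setNames(rep(NA_real_, q), spec$design$fixed_names)
    se[common] <- f$se$beta_full[common]
    beta_sd[j, ] <- inflation * fallback_sd(se, beta_mean[j, ])
    sigma_b[j] <- max(f$sigma^2, 1e-4) * (sigma_a[j] - 1)
    Dhat <- matrix(0, d, d)
    dn <- min(nrow(f$D), d)
    Dhat[seq_len(dn), seq_len(dn)] <- f$D[seq_len(dn), seq_len(dn)]
    if (any(diag(Dhat) < 1e-6)) Dhat <- Dhat + diag(1e-3, d)
    D_S[[j]] <- Dhat * (D_nu[j] - d - 1)
  }

  # Piecewise rates from the Breslow cumulative baseline hazard.
  lambda_mean <- rep(log(0.05), spec$n_pieces)
  if (!is.null(cox_fit) && inherits(cox_fit, "sah_cox")) {
    bh <- cox_fit$baseline_cumhaz
    Hfun <- stats::approxfun(c(0, bh$time), c(0, bh$hazard), method = "constant",
                             rule = 2, f = 0)
    for (k in seq_len(spec$n_pieces)) {
      a <- spec$knots[k]
      bnd <- spec$knots[k + 1]
      rate <- (Hfun(bnd) - Hfun(a)) / (bnd - a)
      lambda_mean[k] <- log(max(rate, 1e-4))
    }
  }

  structure(list(
    gamma = list(mean = gamma_mean, sd = gamma_sd),
    alpha = list(mean = setNames(rep(0, J), spec$dynamic),
                 sd = setNames(rep(2, J), spec$dynamic)),
    beta = list(mean = beta_mean, sd = beta_sd),
    lambda = list(mean = lambda_mean, sd = rep(2, spec$n_pieces)),
    sigma2 = list(a = sigma_a, b = sigma_b),
    D = list(nu = D_nu, S = D_S),
    inflation = inflation),
    class = "nitjm_priors")
}

# ---- flat parameter vector <-> structured parameters -----------------------

param_names <- function(spec) {
  q <- spec$design$q_fixed
  d <- spec$design$d_random
  c(if (length(spec$baseline)) paste0("gamma_", spec$baseline),
    paste0("alpha_", spec$dynamic),
    as.vector(t(outer(spec$dynamic, spec$design$fixed_names,
                      function(a, b) paste0("beta_", a, "_", b)))),
    paste0("log_h0_", seq_len(spec$n_pieces)),
    paste0("sigma_", spec$dynamic),
    unlist(lapply(spec$dynamic, function(cv)
      paste0(cv, "_", vech_names(spec$design$random_names)))))
}

params_to_vector <- function(params, spec) {
  setNames(c(params$gamma, params$alpha, as.vector(t(params$beta)),
             params$lambda, params$sigma,
             unlist(lapply(params$D, vech))),
           param_names(spec))
}

vector_to_params <- function(v, spec) {
  p <- length(spec$baseline)
  J <- length(spec$dynamic)
  q <- spec$design$q_fixed
  d <- spec$design$d_random
  K <- spec$n_pieces
  pos <- 0
  take <- function(k) {
    out <- v[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  gamma <- take(p)
  alpha <- take(J)
  beta <- matrix(take(J * q), J, q, byrow = TRUE)
  lambda <- take(K)
  sigma <- take(J)
  D <- lapply(seq_len(J), function(j) {
    M <- matrix(0, d, d)
    M[lower.tri(M, diag = TRUE)] <- take(d * (d + 1) / 2)
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    M
  })
  nitjm_params(gamma, alpha, beta, lambda, sigma, D, spec)
}

# ---- flattened data for the C++ sampler ------------------------------------

prepare_joint_data <- function(cohort, spec) {
  out <- cohort$outcomes
  n <- nrow(out)
  ids <- out$patient_id
  bl <- cohort$baseline[match(ids, cohort$baseline$patient_id), ,
                        drop = FALSE]
  miss <- setdiff(spec$baseline, names(bl))
  if (length(miss)) {
    stop(sprintf("baseline covariate(s) not in cohort: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  omega <- as.matrix(if (length(spec$baseline))
    bl[, spec$baseline, drop = FALSE] else matrix(0, n, 0))
  Tvec <- out$event_time_days
  delta <- as.integer(out$good_outcome)
  tt <- out$intervention_time_days
  tt[is.na(tt)] <- -1

  # Quadrature nodes over (0, T_i] per patient, flattened.
  qlist <- lapply(seq_len(n), function(i)
    quad_nodes(Tvec[i], if (tt[i] > 0) tt[i] else NA_real_, spec$knots))
  node_off <- c(0L, cumsum(vapply(qlist, nrow, integer(1))))
  qn <- do.call(rbind, qlist)
  node_designs <- lapply(seq_len(n), function(i) {
    design_matrix(spec$design, qlist[[i]]$t,
                  if (tt[i] > 0) tt[i] else NA_real_)
  })
  Xnode <- do.call(rbind, lapply(node_designs, `[[`, "X"))
  Znode <- do.call(rbind, lapply(node_designs, `[[`, "Z"))

  ev <- lapply(seq_len(n), function(i)
    design_matrix(spec$design, Tvec[i], if (tt[i] > 0) tt[i] else NA_real_))
  Xev <- do.call(rbind, lapply(ev, `[[`, "X"))
  Zev <- do.call(rbind, lapply(ev, `[[`, "Z"))

  obs <- cohort$observations
  obs_j <- lapply(spec$dynamic, function(cv) {
    sub <- obs[obs$covariate == cv, , drop = FALSE]
    idx <- match(sub$patient_id, ids)
    if (anyNA(idx)) stop("observation for unknown patient", call. = FALSE)
    ord <- order(idx, sub$time_days)
    sub <- sub[ord, , drop = FALSE]
    idx <- idx[ord]
    offs <- integer(n + 1)
    cnt <- tabulate(idx, nbins = n)
    offs[-1] <- cumsum(cnt)
    dm_rows <- lapply(which(cnt > 0), function(i) {
      rows <- (offs[i] + 1):offs[i + 1]
      design_matrix(spec$design, sub$time_days[rows],
                    if (tt[i] > 0) tt[i] else NA_real_)
    })
    list(y = sub$value,
         X = if (length(dm_rows)) do.call(rbind, lapply(dm_rows, `[[`, "X"))
         else matrix(0, 0, spec$design$q_fixed),
         Z = if (length(dm_rows)) do.call(rbind, lapply(dm_rows, `[[`, "Z"))
         else matrix(0, 0, spec$design$d_random),
         off = offs)
  })

  list(n = n, ids = ids, omega = omega, T = Tvec, delta = delta, tt = tt,
       node_w = if (is.null(qn)) numeric(0) else qn$w,
       node_piece = if (is.null(qn)) integer(0) else as.integer(qn$piece - 1L),
       node_off = as.integer(node_off),
       Xnode = Xnode, Znode = Znode, Xev = Xev, Zev = Zev,
       piece_ev = as.integer(h0_piece(Tvec, spec$knots) - 1L),
       obs = obs_j,
       p = ncol(omega), J = length(spec$dynamic),
       q = spec$design$q_fixed, d = spec$design$d_random,
       K = spec$n_pieces)
}
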