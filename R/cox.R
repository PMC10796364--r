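# Cox proportional-hazards screening of baseline covariates.
#
# The modelled event is the GOOD outcome (discharge home or to
# rehabilitation within the study window); patients with a poor outcome are
# treated as censored at their recorded time for this event. Hazard ratios
# below 1 therefore mean a lower instantaneous rate of achieving a good
# outcome. Ties are handled by the Breslow approximation, matching the
# piecewise-constant-hazard likelihood of the joint model.

#' Fit a Cox proportional hazards model for good outcome
#'
#' Thin, validated wrapper around [survival::coxph()] with Breslow tie
#' handling and a tight Newton-Raphson tolerance. The Breslow cumulative
#' baseline hazard is extracted as a step function for downstream prior
#' construction.
#'
#' @param cohort an `sah_cohort`.
#' @param covariate_names baseline covariate columns to include.
#' @return an object of class `sah_cox` with elements `gamma`, `se`, `vcov`,
#'   `table` (HR, 95% CI, Wald p per coefficient), `baseline_cumhaz`
#'   (data.frame `time`, `hazard`), `converged`, `monotone` and the
#'   underlying `coxph` fit in `model`.
#' @export
fit_cox <- function(cohort, covariate_names) {
  stopifnot(inherits(cohort, "sah_cohort"))
  if (!length(covariate_names)) stop("no covariates supplied", call. = FALSE)
  miss <- setdiff(covariate_names, names(cohort$baseline))
  if (length(miss)) {
    stop(sprintf("baseline covariate(s) not found: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- cohort$outcomes
  if (sum(out$good_outcome) < 1) stop("no events", call. = FALSE)
  bl <- cohort$baseline[match(out$patient_id, cohort$baseline$patient_id),
                        covariate_names, drop = FALSE]
  for (cv in covariate_names) {
    if (length(unique(bl[[cv]])) < 2) {
      stop(sprintf("covariate '%s' is constant", cv), call. = FALSE)
    }
  }
  Xr <- qr(cbind(as.matrix(bl)))
  if (Xr$rank < length(covariate_names)) {
    stop(sprintf("design is rank-deficient (collinear covariates among: %s)",
                 paste(covariate_names, collapse = ", ")), call. = FALSE)
  }
  dat <- cbind(data.frame(.time = out$event_time_days,
                          .status = out$good_outcome), bl)
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(sprintf("`%s`", covariate_names),
                                       collapse = " + ")))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  gamma <- coef(fit)
  names(gamma) <- covariate_names
  if (anyNA(gamma)) {
    stop("Cox fit produced undefined coefficients (rank deficiency)",
         call. = FALSE)
  }
  if (monotone) {
    warning("monotone partial likelihood: at least one coefficient is not identified; estimates reported but unreliable")
  }
  V <- vcov(fit)
  dimnames(V) <- list(covariate_names, covariate_names)
  se <- sqrt(diag(V))
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(
    gamma = gamma, se = se, vcov = V,
    table = hr_from_estimates(gamma, se),
    baseline_cumhaz = data.frame(time = bh$time, hazard = bh$hazard),
    converged = fit$iter < 100 && !monotone, monotone = monotone,
    n = nrow(out), n_events = sum(out$good_outcome), model = fit),
    class = "sah_cox")
}

# HR table from coefficient estimates and standard errors.
hr_from_estimates <- function(gamma, se) {
  z <- ifelse(se > 0, gamma / se, sign(gamma) * Inf)
  data.frame(covariate = names(gamma), gamma = unname(gamma),
             se = unname(se), hr = exp(unname(gamma)),
             ci_low = exp(unname(gamma) - qnorm(0.975) * unname(se)),
             ci_high = exp(unname(gamma) + qnorm(0.975) * unname(se)),
             p = ifelse(is.infinite(z), 0, 2 * pnorm(-abs(z))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hazard-ratio table of a Cox fit
#'
#' HR = exp(gamma), 95% CI = exp(gamma +/- 1.96 SE), two-sided Wald p.
#'
#' @param fit an `sah_cox`.
#' @return data.frame with columns `covariate`, `gamma`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
hr_table <- function(fit) {
  stopifnot(inherits(fit, "sah_cox"))
  if (!fit$converged) {
    warning("Cox fit did not converge cleanly; table may be unreliable")
  }
  fit$table
}

#' @export
print.sah_cox <- function(x, ...) {
  cat(sprintf("Cox model for good outcome: %d patients, %d events (Breslow ties)\n",
              x$n, x$n_events))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sah_cox <- function(object, ...) object$gamma

#' Univariate screening followed by a multivariate Cox model
#'
#' Fits one Cox model per candidate baseline covariate, selects candidates
#' with Wald p below `alpha_level`, then fits a single multivariate model on
#' the selected set. A candidate whose univariate fit fails is reported and
#' excluded rather than aborting the screen.
#'
#' @param cohort an `sah_cohort`.
#' @param candidates candidate baseline covariate names.
#' @param alpha_level selection threshold on the univariate Wald p-value.
#' @return an object of class `cox_screen` with `univariate` (per-candidate
#'   HR table with a `selected` flag and `status`), `selected`, and
#'   `multivariate` (HR table, or `NULL` when nothing was selected).
#' @export
univariate_screen <- function(cohort, candidates, alpha_level = 0.05) {
  if (!length(candidates)) stop("no candidate covariates", call. = FALSE)
  rows <- lapply(candidates, function(cv) {
    f <- tryCatch(suppressWarnings(fit_cox(cohort, cv)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      data.frame(covariate = cv, gamma = NA_real_, se = NA_real_,
                 hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, status = conditionMessage(f),
                 stringsAsFactors = FALSE)
    } else {
      cbind(f$table, status = if (f$converged) "ok" else "non-convergence")
    }
  })
  uni <- do.call(rbind, rows)
  uni$selected <- !is.na(uni$p) & uni$p < alpha_level & uni$status == "ok"
  selected <- uni$covariate[uni$selected]
  multi <- NULL
  multi_fit <- NULL
  if (length(selected)) {
    multi_fit <- fit_cox(cohort, selected)
    multi <- multi_fit$table
  } else {
    message("no covariate passed univariate screening; multivariate step skipped")
  }
  structure(list(univariate = uni, selected = selected,
                 multivariate = multi, multivariate_fit = multi_fit,
                 alpha_level = alpha_level),
            class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat("Univariate survival analysis (good outcome):\n")
  u <- x$univariate
  u[c("gamma", "se", "hr", "ci_low", "ci_high", "p")] <-
    lapply(u[c("gamma", "se", "hr", "ci_low", "ci_high", "p")], round, 4)
  print(u[c("covariate", "hr", "ci_low", "ci_high", "p", "selected")],
        row.names = FALSE)
  if (!is.null(x$multivariate)) {
    cat(sprintf("\nMultivariate model on %d selected covariate(s):\n",
                length(x$selected)))
    m <- x$multivariate
    m[-1] <- lapply(m[-1], round, 4)
    print(m[c("covariate", "hr", "ci_low", "ci_high", "p")],
          row.names = FALSE)
  } else {
    cat("\nNo covariate selected; multivariate step skipped.\n")
  }
  invisible(x)
}
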