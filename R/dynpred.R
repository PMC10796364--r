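# Dynamic individual prediction and time-dependent AUC evaluation.
#
# The dynamic prediction task (Ts, dt): for a patient still event-free at Ts,
# the probability of a good outcome in (Ts, Ts + dt] given the longitudinal
# history up to Ts, pi = 1 - S(Ts+dt | b) / S(Ts | b), averaged over the
# posterior and over random effects sampled conditional on the history.
# Prediction uses only information available at Ts: an intervention occurring
# after Ts is unknown at prediction time and is treated as absent.

#' Patients still at risk at the prediction start
#'
#' Patients with event time after `Ts` (neither a good outcome nor censoring
#' has occurred), carrying only observations at or before `Ts`.
#'
#' @param cohort an `sah_cohort`.
#' @param Ts prediction start in days, in `(0, horizon)`.
#' @return an `sah_cohort` of the risk set.
#' @export
risk_set <- function(cohort, Ts) {
  stopifnot(inherits(cohort, "sah_cohort"))
  if (Ts <= 0 || Ts >= cohort$horizon_days) {
    stop(sprintf("Ts must lie in (0, %g)", cohort$horizon_days),
         call. = FALSE)
  }
  keep <- cohort$outcomes$event_time_days > Ts
  if (!any(keep)) {
    stop(sprintf("risk set at Ts = %g is empty", Ts), call. = FALSE)
  }
  ids <- cohort$outcomes$patient_id[keep]
  obs <- cohort$observations
  obs <- obs[obs$patient_id %in% ids & obs$time_days <= Ts, , drop = FALSE]
  sah_cohort(cohort$baseline[cohort$baseline$patient_id %in% ids, ,
                             drop = FALSE],
             cohort$outcomes[keep, , drop = FALSE], obs,
             horizon_days = cohort$horizon_days)
}

# Prediction inputs: joint data over (0, Ts] with interventions after Ts
# masked, plus incremental quadrature blocks over (Ts, Ts + dt] per dt.
prepare_pred_data <- function(rs, spec, Ts, dts) {
  out <- rs$outcomes
  tt_eff <- out$intervention_time_days
  tt_eff[!is.na(tt_eff) & tt_eff > Ts] <- NA_real_
  cond <- sah_cohort(rs$baseline,
                     transform(out, event_time_days = Ts, good_outcome = 0,
                               intervention_time_days = tt_eff),
                     rs$observations, horizon_days = rs$horizon_days)
  data <- prepare_joint_data(cond, spec)
  n <- data$n
  ext <- lapply(dts, function(dt) {
    blocks <- lapply(seq_len(n), function(i) {
      tt_i <- if (data$tt[i] > 0) data$tt[i] else NA_real_
      qn <- quad_nodes(Ts + dt, tt_i, spec$knots, from = Ts)
      dm <- design_matrix(spec$design, qn$t, tt_i)
      list(w = qn$w, piece = as.integer(qn$piece - 1L), X = dm$X, Z = dm$Z)
    })
    list(w = unlist(lapply(blocks, `[[`, "w")),
         piece = unlist(lapply(blocks, `[[`, "piece")),
         off = as.integer(c(0, cumsum(vapply(blocks, function(b)
           length(b$w), numeric(1))))),
         X = do.call(rbind, lapply(blocks, `[[`, "X")),
         Z = do.call(rbind, lapply(blocks, `[[`, "Z")))
  })
  list(data = data, ext = ext)
}

# Evenly thinned subset of merged posterior draws.
thin_theta <- function(draws, n_theta) {
  m <- as_matrix_draws(draws)
  if (n_theta >= nrow(m)) return(m)
  m[unique(round(seq(1, nrow(m), length.out = n_theta))), , drop = FALSE]
}

#' Conditional event probability for risk-set patients
#'
#' For every patient at risk at `Ts`, the probability of the event in
#' `(Ts, Ts + dt]`: an average over thinned posterior draws and, within each
#' draw, over Metropolis-Hastings samples of the patient's random effects
#' conditional on the observations up to `Ts` and survival past `Ts`, of
#' `1 - S(Ts + dt)/S(Ts)`.
#'
#' @param object a fitted `nitjm` (or a list with `draws` and `spec`).
#' @param Ts prediction start (days).
#' @param dt prediction interval(s) in days; `Ts + max(dt)` must not exceed
#'   the horizon.
#' @param cohort cohort to predict for (defaults to the fitted cohort).
#' @param n_theta number of thinned posterior draws.
#' @param n_b_draws retained random-effect samples per posterior draw.
#' @param n_burn burn-in random-effect samples per posterior draw.
#' @return data.frame `patient_id, Ts, dt, pi`.
#' @export
conditional_event_probability <- function(object, Ts, dt, cohort = NULL,
                                          n_theta = 50, n_b_draws = 200,
                                          n_burn = 200) {
  spec <- object$spec
  cohort <- cohort %||% object$cohort
  if (any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  if (Ts + max(dt) > spec$horizon + 1e-9) {
    stop("Ts + dt must not exceed the horizon", call. = FALSE)
  }
  rs <- risk_set(cohort, Ts)
  pp <- prepare_pred_data(rs, spec, Ts, dt)
  theta <- thin_theta(object$draws, n_theta)
  res <- .cpp_cond_predict(pp$data, pp$ext, theta, as.integer(n_burn),
                           as.integer(n_b_draws))
  pi_mat <- res$pi
  data.frame(patient_id = rep(pp$data$ids, times = length(dt)),
             Ts = Ts, dt = rep(dt, each = length(pp$data$ids)),
             pi = as.vector(pi_mat), stringsAsFactors = FALSE)
}

#' Dynamic risk predictions from a fitted joint model
#'
#' @param object a `nitjm` fit.
#' @param Ts prediction start (days).
#' @param dt prediction interval(s) in days.
#' @param newdata optional `sah_cohort` (defaults to the fitted cohort).
#' @param ... passed to [conditional_event_probability()].
#' @return data.frame `patient_id, Ts, dt, pi`.
#' @export
predict.nitjm <- function(object, Ts, dt, newdata = NULL, ...) {
  conditional_event_probability(object, Ts = Ts, dt = dt, cohort = newdata,
                                ...)
}

#' Time-dependent AUC over a prediction window
#'
#' Cases are patients with the event in `(Ts, Ts + dt]`; controls are
#' patients known event-free through `Ts + dt` (event time beyond the window
#' end, or administrative censoring exactly at it); patients censored
#' strictly inside the window contribute no pairs. AUC = (concordant + 0.5
#' ties) / all case-control pairs.
#'
#' @param predictions data.frame with `patient_id` and `pi` (risk scores at
#'   this `(Ts, dt)`), or a named numeric vector.
#' @param cohort the `sah_cohort` the predictions refer to.
#' @param Ts,dt the prediction window.
#' @return the AUC (NA when there is no case or no control), with attributes
#'   `n_cases`, `n_controls`, `n_pairs`.
#' @export
auc_window <- function(predictions, cohort, Ts, dt) {
  if (is.data.frame(predictions)) {
    scores <- setNames(predictions$pi, predictions$patient_id)
  } else {
    scores <- predictions
  }
  out <- cohort$outcomes
  out <- out[out$event_time_days > Ts, , drop = FALSE]
  is_case <- out$good_outcome == 1 & out$event_time_days <= Ts + dt
  is_control <- out$event_time_days > Ts + dt |
    (out$good_outcome == 0 & out$event_time_days >= Ts + dt - 1e-9)
  cases <- out$patient_id[is_case]
  controls <- out$patient_id[is_control]
  if (!length(cases) || !length(controls)) {
    return(structure(NA_real_, n_cases = length(cases),
                     n_controls = length(controls), n_pairs = 0L))
  }
  miss <- setdiff(c(cases, controls), names(scores))
  if (length(miss)) {
    stop(sprintf("no prediction for patient(s): %s",
                 paste(head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  sc <- scores[cases]
  sn <- scores[controls]
  cmp <- outer(sc, sn, function(a, b) (a > b) + 0.5 * (a == b))
  structure(mean(cmp), n_cases = length(cases), n_controls = length(controls),
            n_pairs = length(sc) * length(sn))
}

#' Time-dependent AUC grid over prediction starts and intervals
#'
#' Fills every admissible `(Ts, dt)` cell (those with `Ts + dt <= horizon`
#' and at least one case and one control) with the windowed AUC of
#' [conditional_event_probability()] scores. The marginal AUC per `Ts` is
#' the pair-count-weighted average over that column's cells; the overall
#' mean +/- SD is the unweighted mean and sample SD over all filled cells.
#'
#' @param object a fitted `nitjm`.
#' @param cohort evaluation cohort (defaults to the fitted cohort).
#' @param Ts_list,dt_list grid values in days.
#' @param n_theta,n_b_draws,n_burn see [conditional_event_probability()].
#' @return a `nitjm_auc_grid`.
#' @export
auc_grid <- function(object, cohort = NULL, Ts_list = c(1, 2, 3, 5, 7),
                     dt_list = c(1, 2, 3, 5, 7), n_theta = 50,
                     n_b_draws = 200, n_burn = 200) {
  cohort <- cohort %||% object$cohort
  horizon <- object$spec$horizon
  A <- matrix(NA_real_, length(dt_list), length(Ts_list),
              dimnames = list(paste0("dt=", dt_list), paste0("Ts=", Ts_list)))
  pairs <- cases <- controls <- array(0L, dim(A), dimnames = dimnames(A))
  for (s in seq_along(Ts_list)) {
    Ts <- Ts_list[s]
    dts <- dt_list[Ts + dt_list <= horizon + 1e-9]
    if (!length(dts)) next
    preds <- tryCatch(
      conditional_event_probability(object, Ts, dts, cohort = cohort,
                                    n_theta = n_theta,
                                    n_b_draws = n_b_draws, n_burn = n_burn),
      error = function(e) NULL)
    if (is.null(preds)) next
    for (dt in dts) {
      k <- match(dt, dt_list)
      a <- auc_window(preds[preds$dt == dt, , drop = FALSE], cohort, Ts, dt)
      A[k, s] <- as.numeric(a)
      pairs[k, s] <- attr(a, "n_pairs")
      cases[k, s] <- attr(a, "n_cases")
      controls[k, s] <- attr(a, "n_controls")
    }
  }
  filled <- !is.na(A)
  marginal <- vapply(seq_along(Ts_list), function(s) {
    ok <- filled[, s]
    if (!any(ok)) return(NA_real_)
    sum(A[ok, s] * pairs[ok, s]) / sum(pairs[ok, s])
  }, numeric(1))
  names(marginal) <- colnames(A)
  structure(list(auc = A, pairs = pairs, cases = cases, controls = controls,
                 marginal = marginal,
                 mean = mean(A[filled]),
                 sd = if (sum(filled) > 1) sd(A[filled]) else NA_real_,
                 n_missing = sum(!filled & outer(dt_list, Ts_list, `+`)
                                 <= horizon + 1e-9),
                 Ts_list = Ts_list, dt_list = dt_list, horizon = horizon),
            class = "nitjm_auc_grid")
}

#' @export
print.nitjm_auc_grid <- function(x, digits = 4, ...) {
  cat("Time-dependent AUC grid (rows dt, columns Ts):\n")
  tab <- rbind(round(x$auc, digits), Marginal = round(x$marginal, digits))
  print(tab, na.print = "-")
  cat(sprintf("Mean AUC: %.4f +/- %.4f over %d cells",
              x$mean, x$sd, sum(!is.na(x$auc))))
  if (x$n_missing > 0) {
    cat(sprintf(" (%d admissible cell(s) missing)", x$n_missing))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.nitjm_auc_grid <- function(x, ...) {
  graphics::plot(x$Ts_list, x$marginal, type = "b", pch = 19,
                 xlab = "prediction start Ts (days)",
                 ylab = "marginal AUC", ylim = c(0.5, 1), ...)
  graphics::abline(h = x$mean, lty = 3)
  invisible(x)
}

#' Compare two AUC grids
#'
#' Cell-wise AUC differences (grid B minus grid A) together with phase
#' means: the acute phase collects cells with `Ts + dt <= acute_max`, the
#' sub-acute phase cells with `acute_max < Ts + dt <= horizon`.
#'
#' @param grid_a,grid_b `nitjm_auc_grid`s over the same `(Ts, dt)` grid,
#'   e.g. baseline and NIT joint models.
#' @param acute_max phase split in days.
#' @return a `nitjm_grid_comparison` with the cell-difference matrix,
#'   per-Ts marginal differences, and acute / sub-acute / overall means for
#'   each grid and their differences.
#' @export
compare_models <- function(grid_a, grid_b, acute_max = 3) {
  stopifnot(inherits(grid_a, "nitjm_auc_grid"),
            inherits(grid_b, "nitjm_auc_grid"))
  if (!identical(grid_a$Ts_list, grid_b$Ts_list) ||
      !identical(grid_a$dt_list, grid_b$dt_list)) {
    stop("the two grids have different (Ts, dt) structures", call. = FALSE)
  }
  horizon <- grid_a$horizon
  tot <- outer(grid_a$dt_list, grid_a$Ts_list, `+`)
  acute <- tot <= acute_max
  subacute <- tot > acute_max & tot <= horizon
  phase_mean <- function(A, mask) {
    v <- A[mask & !is.na(A)]
    if (length(v)) mean(v) else NA_real_
  }
  diff <- grid_b$auc - grid_a$auc
  structure(list(
    diff = diff,
    marginal_a = grid_a$marginal, marginal_b = grid_b$marginal,
    marginal_diff = grid_b$marginal - grid_a$marginal,
    acute_a = phase_mean(grid_a$auc, acute),
    acute_b = phase_mean(grid_b$auc, acute),
    subacute_a = phase_mean(grid_a$auc, subacute),
    subacute_b = phase_mean(grid_b$auc, subacute),
    overall_a = grid_a$mean, overall_b = grid_b$mean,
    acute_diff = phase_mean(diff, acute),
    subacute_diff = phase_mean(diff, subacute),
    overall_diff = mean(diff[!is.na(diff)]),
    acute_cells = which(acute, arr.ind = TRUE),
    acute_max = acute_max),
    class = "nitjm_grid_comparison")
}

#' @export
print.nitjm_grid_comparison <- function(x, ...) {
  cat("AUC grid comparison (B - A):\n")
  print(round(x$diff, 4), na.print = "-")
  cat(sprintf("\nacute phase (Ts+dt <= %g):     A %.4f  B %.4f  diff %+.4f\n",
              x$acute_max, x$acute_a, x$acute_b, x$acute_diff))
  cat(sprintf("sub-acute phase:               A %.4f  B %.4f  diff %+.4f\n",
              x$subacute_a, x$subacute_b, x$subacute_diff))
  cat(sprintf("overall mean:                  A %.4f  B %.4f  diff %+.4f\n",
              x$overall_a, x$overall_b, x$overall_diff))
  invisible(x)
}

#' @export
plot.nitjm_grid_comparison <- function(x, ...) {
  Ts <- as.numeric(sub("Ts=", "", names(x$marginal_a)))
  rng <- range(c(x$marginal_a, x$marginal_b), na.rm = TRUE)
  graphics::plot(Ts, x$marginal_a, type = "b", pch = 1, ylim = rng,
                 xlab = "prediction start Ts (days)", ylab = "marginal AUC",
                 ...)
  graphics::lines(Ts, x$marginal_b, type = "b", pch = 19, lty = 2)
  graphics::legend("bottomright", legend = c("model A", "model B"),
                   pch = c(1, 19), lty = c(1, 2), bty = "n")
  invisible(x)
}
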