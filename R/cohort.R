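# Cohort container, CSV I/O and preprocessing for 14-day ICU outcome studies.
#
# A cohort bundles three tables keyed by patient id:
#   * baseline:      one row per patient, binary comorbidities/complications
#                    coded 0/1 plus continuous covariates such as age (years);
#   * outcomes:      event time in days since admission, the good-outcome
#                    indicator (1 = discharged home/rehabilitation within the
#                    study window), and an optional neurological-intervention
#                    time;
#   * observations:  long-format repeated measurements (patient id, covariate
#                    name, time in days, value).

#' Construct a validated SAH cohort
#'
#' @param baseline data.frame with column `patient_id` plus baseline
#'   covariates (binary covariates coded 0/1; `age` in years).
#' @param outcomes data.frame with columns `patient_id`, `event_time_days`,
#'   `good_outcome` and optionally `intervention_time_days` (NA = no
#'   intervention).
#' @param observations data.frame with columns `patient_id`, `covariate`,
#'   `time_days`, `value`. May have zero rows.
#' @param horizon_days study horizon in days (administrative censoring time).
#'
#' @return An object of class `sah_cohort`.
#' @export
sah_cohort <- function(baseline, outcomes, observations,
                       horizon_days = 14) {
  stopifnot(is.data.frame(baseline), is.data.frame(outcomes),
            is.data.frame(observations))
  if (!is.numeric(horizon_days) || length(horizon_days) != 1 ||
      !is.finite(horizon_days) || horizon_days <= 0) {
    stop("`horizon_days` must be a single positive number", call. = FALSE)
  }
  req <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", name,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  req(baseline, "patient_id", "baseline")
  req(outcomes, c("patient_id", "event_time_days", "good_outcome"), "outcome")
  if (!"intervention_time_days" %in% names(outcomes)) {
    outcomes$intervention_time_days <- NA_real_
  }
  if (nrow(observations) == 0) {
    observations <- data.frame(patient_id = character(),
                               covariate = character(),
                               time_days = numeric(), value = numeric(),
                               stringsAsFactors = FALSE)
  }
  req(observations, c("patient_id", "covariate", "time_days", "value"),
      "long observation")

  baseline$patient_id <- as.character(baseline$patient_id)
  outcomes$patient_id <- as.character(outcomes$patient_id)
  observations$patient_id <- as.character(observations$patient_id)
  observations$covariate <- as.character(observations$covariate)

  dup <- unique(outcomes$patient_id[duplicated(outcomes$patient_id)])
  if (length(dup)) {
    stop(sprintf("duplicate patient id(s) in outcome table: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  dup <- unique(baseline$patient_id[duplicated(baseline$patient_id)])
  if (length(dup)) {
    stop(sprintf("duplicate patient id(s) in baseline table: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (!setequal(baseline$patient_id, outcomes$patient_id)) {
    stop("baseline and outcome tables must cover the same patient ids",
         call. = FALSE)
  }
  if (anyDuplicated(names(baseline))) {
    stop("baseline covariate names must be unique", call. = FALSE)
  }

  et <- outcomes$event_time_days
  if (any(!is.finite(et)) || any(et <= 0)) {
    stop("event_time_days must be finite and > 0 for every patient",
         call. = FALSE)
  }
  if (any(et > horizon_days)) {
    stop("event_time_days must not exceed the study horizon", call. = FALSE)
  }
  if (!all(outcomes$good_outcome %in% c(0, 1))) {
    stop("good_outcome must be 0/1", call. = FALSE)
  }
  it <- outcomes$intervention_time_days
  bad <- !is.na(it) & (it <= 0 | it > horizon_days)
  if (any(bad)) {
    stop(sprintf("intervention_time_days outside (0, %g] for patient(s): %s",
                 horizon_days,
                 paste(outcomes$patient_id[bad], collapse = ", ")),
         call. = FALSE)
  }

  if (nrow(observations)) {
    unknown <- setdiff(unique(observations$patient_id), outcomes$patient_id)
    if (length(unknown)) {
      stop(sprintf("observations refer to unknown patient id(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(observations$value))) {
      stop("observation values must be finite", call. = FALSE)
    }
    tt <- observations$time_days
    if (any(!is.finite(tt)) || any(tt < 0) || any(tt > horizon_days)) {
      stop(sprintf("observation time_days must lie in [0, %g]", horizon_days),
           call. = FALSE)
    }
    emap <- setNames(outcomes$event_time_days, outcomes$patient_id)
    late <- tt > emap[observations$patient_id] + 1e-9
    if (any(late)) {
      stop(sprintf(
        "observation(s) recorded after the patient's event time for id(s): %s",
        paste(unique(observations$patient_id[late]), collapse = ", ")),
        call. = FALSE)
    }
  }

  structure(list(baseline = baseline, outcomes = outcomes,
                 observations = observations, horizon_days = horizon_days),
            class = "sah_cohort")
}

#' @export
print.sah_cohort <- function(x, ...) {
  cat(sprintf("SAH cohort: %d patients, %d longitudinal observations (%s), horizon %g days\n",
              nrow(x$outcomes), nrow(x$observations),
              if (nrow(x$observations))
                paste(sort(unique(x$observations$covariate)), collapse = ", ")
              else "none",
              x$horizon_days))
  cat(sprintf("  events (good outcome): %d (%.1f%%); interventions: %d\n",
              sum(x$outcomes$good_outcome),
              100 * mean(x$outcomes$good_outcome),
              sum(!is.na(x$outcomes$intervention_time_days))))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort an `sah_cohort`.
#' @return integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$outcomes)

#' Load a cohort from three CSV files
#'
#' Expected headers: baseline `patient_id` + covariate columns; long table
#' `patient_id, covariate, time_days, value`; outcome table
#' `patient_id, event_time_days, good_outcome, intervention_time_days`
#' (empty field = no intervention). All invariants of [sah_cohort()] are
#' checked on load.
#'
#' @param baseline_path,long_path,outcome_path paths to the CSV files.
#' @param horizon_days study horizon in days.
#' @param quiet suppress the row-count message.
#' @return an `sah_cohort`.
#' @export
load_cohort <- function(baseline_path, long_path, outcome_path,
                        horizon_days = 14, quiet = FALSE) {
  for (p in c(baseline_path, long_path, outcome_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  baseline <- read.csv(baseline_path, stringsAsFactors = FALSE)
  long <- read.csv(long_path, stringsAsFactors = FALSE)
  outcomes <- read.csv(outcome_path, stringsAsFactors = FALSE)
  cohort <- sah_cohort(baseline, outcomes, long, horizon_days = horizon_days)
  if (!quiet) {
    message(sprintf("loaded cohort: %d patients, %d observations, %d baseline columns",
                    nrow(outcomes), nrow(long), ncol(baseline) - 1L))
  }
  cohort
}

#' Write a cohort to three CSV files
#'
#' @param cohort an `sah_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
save_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "sah_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    baseline = file.path(dir, paste0(prefix, "_baseline.csv")),
    long = file.path(dir, paste0(prefix, "_observations.csv")),
    outcome = file.path(dir, paste0(prefix, "_outcomes.csv"))
  )
  write.csv(cohort$baseline, paths[["baseline"]], row.names = FALSE)
  write.csv(cohort$observations, paths[["long"]], row.names = FALSE)
  write.csv(cohort$outcomes, paths[["outcome"]], row.names = FALSE)
  invisible(paths)
}

#' Replace observations of a cohort (revalidating)
#' @noRd
set_observations <- function(cohort, observations) {
  sah_cohort(cohort$baseline, cohort$outcomes, observations,
             horizon_days = cohort$horizon_days)
}

#' Daily averaging of longitudinal observations
#'
#' Measurement frequency in the ICU varies with illness severity, so raw
#' series are normalised to one value per calendar day from admission: all
#' values of a covariate falling in day bin d = ceiling(time) (time 0 counts
#' as day 1) are replaced by their arithmetic mean, placed at the
#' representative time d - 0.5. When d - 0.5 would exceed the patient's event
#' time (measurements on the event day) the representative time is capped at
#' the event time so the averaged cohort still satisfies the at-risk
#' invariant. The operation is idempotent.
#'
#' @param cohort an `sah_cohort`.
#' @return an `sah_cohort` with one observation per (patient, covariate, day).
#' @export
daily_average <- function(cohort) {
  stopifnot(inherits(cohort, "sah_cohort"))
  obs <- cohort$observations
  if (nrow(obs) == 0) {
    warning("cohort has no longitudinal observations; returned unchanged")
    return(cohort)
  }
  day <- pmax(1, ceiling(obs$time_days))
  agg <- aggregate(value ~ patient_id + covariate + day,
                   data = cbind(obs[c("patient_id", "covariate", "value")],
                                day = day),
                   FUN = mean)
  emap <- setNames(cohort$outcomes$event_time_days,
                   cohort$outcomes$patient_id)
  agg$time_days <- pmin(agg$day - 0.5, emap[agg$patient_id])
  agg <- agg[order(agg$patient_id, agg$covariate, agg$day),
             c("patient_id", "covariate", "time_days", "value")]
  rownames(agg) <- NULL
  set_observations(cohort, agg)
}

#' Define a threshold dichotomization rule
#'
#' @param covariate name of the raw longitudinal covariate.
#' @param kind one of `"at_least"` (abnormal when value >= cutoff),
#'   `"below"` (abnormal when value < cutoff) or `"outside_band"` (abnormal
#'   when value < lower or > upper).
#' @param cutoff threshold for `at_least`/`below` rules, in covariate units.
#' @param lower,upper band limits for `outside_band` rules.
#' @param output_name name of the derived binary series.
#' @return a `threshold_rule`.
#' @export
threshold_rule <- function(covariate, kind = c("at_least", "below",
                                               "outside_band"),
                           cutoff = NULL, lower = NULL, upper = NULL,
                           output_name) {
  kind <- match.arg(kind)
  if (kind == "outside_band") {
    if (is.null(lower) || is.null(upper) || lower >= upper) {
      stop("outside_band rules need lower < upper", call. = FALSE)
    }
  } else if (is.null(cutoff)) {
    stop(sprintf("rule '%s' needs a cutoff", kind), call. = FALSE)
  }
  structure(list(covariate = covariate, kind = kind, cutoff = cutoff,
                 lower = lower, upper = upper, output_name = output_name),
            class = "threshold_rule")
}

#' Default dichotomization rules
#'
#' Hyperglycaemia (glucose >= 126 mg/dL) and low oxygen saturation
#' (SpO2 < 95%) use their standard clinical cutoffs; WBC abnormality
#' (outside 4-12 x 10^9/L) and creatinine abnormality (>= 1.3 mg/dL) use
#' common laboratory reference ranges and are overridable.
#'
#' @return list of `threshold_rule`s.
#' @export
default_threshold_rules <- function() {
  list(
    threshold_rule("glucose", "at_least", cutoff = 126,
                   output_name = "hyperglycemia"),
    threshold_rule("spo2", "below", cutoff = 95,
                   output_name = "low_spo2"),
    threshold_rule("wbc", "outside_band", lower = 4, upper = 12,
                   output_name = "wbc_abnormal"),
    threshold_rule("creatinine", "at_least", cutoff = 1.3,
                   output_name = "creatinine_abnormal")
  )
}

#' Add threshold-dichotomized binary series to a cohort
#'
#' For each rule a new 0/1 series (1 = abnormal) is appended at the same
#' observation times; the original series are retained.
#'
#' @param cohort an `sah_cohort`.
#' @param rules list of [threshold_rule()]s.
#' @return an `sah_cohort` with the derived series added.
#' @export
dichotomize <- function(cohort, rules = default_threshold_rules()) {
  stopifnot(inherits(cohort, "sah_cohort"))
  if (inherits(rules, "threshold_rule")) rules <- list(rules)
  obs <- cohort$observations
  present <- unique(obs$covariate)
  new_list <- vector("list", length(rules))
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    if (!r$covariate %in% present) {
      stop(sprintf("dichotomization rule '%s' refers to absent covariate '%s'",
                   r$output_name, r$covariate), call. = FALSE)
    }
    sub <- obs[obs$covariate == r$covariate, ]
    flag <- switch(r$kind,
                   at_least = as.numeric(sub$value >= r$cutoff),
                   below = as.numeric(sub$value < r$cutoff),
                   outside_band = as.numeric(sub$value < r$lower |
                                               sub$value > r$upper))
    new_list[[k]] <- data.frame(patient_id = sub$patient_id,
                                covariate = r$output_name,
                                time_days = sub$time_days,
                                value = flag, stringsAsFactors = FALSE)
  }
  set_observations(cohort, rbind(obs, do.call(rbind, new_list)))
}

#' Descriptive cohort summary
#'
#' Per binary baseline covariate: count and percentage overall and by outcome
#' group; age: median and IQR; per dynamic covariate: mean and sample SD over
#' all observations, overall and by group. Empty strata are reported as 0
#' counts / NA statistics.
#'
#' @param object an `sah_cohort`.
#' @param ... unused.
#' @return a `summary.sah_cohort` list of data frames.
#' @export
summary.sah_cohort <- function(object, ...) {
  out <- object$outcomes
  grp <- list(all = rep(TRUE, nrow(out)),
              good = out$good_outcome == 1,
              poor = out$good_outcome == 0)
  bl <- object$baseline[match(out$patient_id, object$baseline$patient_id), ,
                        drop = FALSE]
  bin_cols <- setdiff(names(bl)[vapply(bl, function(col)
    is.numeric(col) && all(col %in% c(0, 1)), logical(1))], "patient_id")

  fmt <- function(n, tot) sprintf("%d (%.2f%%)", n, if (tot) 100 * n / tot else 0)
  rows <- lapply(bin_cols, function(cv) {
    cnt <- vapply(grp, function(g) sum(bl[[cv]][g]), numeric(1))
    tot <- vapply(grp, sum, numeric(1))
    data.frame(covariate = cv,
               n_all = cnt[["all"]], pct_all = 100 * cnt[["all"]] / max(tot[["all"]], 1),
               n_good = cnt[["good"]], n_poor = cnt[["poor"]],
               formatted_all = fmt(cnt[["all"]], tot[["all"]]),
               formatted_good = fmt(cnt[["good"]], tot[["good"]]),
               formatted_poor = fmt(cnt[["poor"]], tot[["poor"]]),
               stringsAsFactors = FALSE)
  })
  baseline_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character())

  age_tab <- NULL
  if ("age" %in% names(bl)) {
    age_tab <- do.call(rbind, lapply(names(grp), function(g) {
      a <- bl$age[grp[[g]]]
      data.frame(group = g,
                 median = if (length(a)) median(a) else NA_real_,
                 q1 = if (length(a)) unname(quantile(a, 0.25)) else NA_real_,
                 q3 = if (length(a)) unname(quantile(a, 0.75)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }

  obs <- object$observations
  dyn_tab <- NULL
  if (nrow(obs)) {
    gmap <- setNames(out$good_outcome, out$patient_id)
    obs_grp <- gmap[obs$patient_id]
    dyn_tab <- do.call(rbind, lapply(sort(unique(obs$covariate)), function(cv) {
      sel <- obs$covariate == cv
      stat <- function(keep) {
        v <- obs$value[sel & keep]
        c(mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) > 1) sd(v) else NA_real_,
          n = length(v))
      }
      s_all <- stat(TRUE); s_g <- stat(obs_grp == 1); s_p <- stat(obs_grp == 0)
      data.frame(covariate = cv,
                 mean_all = s_all[["mean"]], sd_all = s_all[["sd"]],
                 mean_good = s_g[["mean"]], sd_good = s_g[["sd"]],
                 mean_poor = s_p[["mean"]], sd_poor = s_p[["sd"]],
                 n_obs = s_all[["n"]], stringsAsFactors = FALSE)
    }))
  }

  structure(list(n = nrow(out), n_good = sum(out$good_outcome),
                 n_poor = sum(1 - out$good_outcome),
                 baseline = baseline_tab, age = age_tab, dynamic = dyn_tab),
            class = "summary.sah_cohort")
}

#' @export
print.summary.sah_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d good outcome, %d poor outcome\n",
              x$n, x$n_good, x$n_poor))
  if (nrow(x$baseline)) {
    cat("\nBaseline covariates, n (%):\n")
    print(x$baseline[c("covariate", "formatted_all", "formatted_good",
                       "formatted_poor")], row.names = FALSE)
  }
  if (!is.null(x$age)) {
    cat("\nAge, median (IQR):\n")
    print(x$age, row.names = FALSE)
  }
  if (!is.null(x$dynamic)) {
    cat("\nDynamic covariates, mean +/- SD over observations:\n")
    print(x$dynamic, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Locally weighted trajectory curve with pointwise 95% band
#'
#' Local linear regression with tricube weights (via [stats::loess()]),
#' evaluated on a regular grid over the study window, with a pointwise
#' normal-approximation confidence band, optionally per group.
#'
#' @param observations data.frame with columns `time_days` and `value`, and
#'   optionally the grouping column named by `group`.
#' @param span loess span (fraction of points in each local window).
#' @param group optional name of a grouping column.
#' @param n_grid number of evaluation points.
#' @param horizon upper end of the evaluation grid; defaults to the maximum
#'   observed time.
#' @return data.frame with columns `group`, `time_days`, `fit`, `se`,
#'   `lower`, `upper`.
#' @export
loess_curve <- function(observations, span = 0.75, group = NULL,
                        n_grid = 101, horizon = NULL) {
  stopifnot(is.data.frame(observations),
            all(c("time_days", "value") %in% names(observations)))
  g <- if (is.null(group)) rep("all", nrow(observations)) else {
    if (!group %in% names(observations)) {
      stop(sprintf("grouping column '%s' not found", group), call. = FALSE)
    }
    as.character(observations[[group]])
  }
  horizon <- horizon %||% max(observations$time_days)
  res <- lapply(sort(unique(g)), function(lev) {
    sub <- observations[g == lev, ]
    if (nrow(sub) < 5) {
      stop(sprintf("group '%s' has %d points; at least 5 are required",
                   lev, nrow(sub)), call. = FALSE)
    }
    grid <- seq(min(sub$time_days), min(horizon, max(sub$time_days)),
                length.out = n_grid)
    fit <- loess(value ~ time_days, data = sub, span = span, degree = 1,
                 family = "gaussian",
                 control = loess.control(surface = "direct"))
    pr <- predict(fit, newdata = data.frame(time_days = grid), se = TRUE)
    se <- pr$se.fit
    se[!is.finite(se)] <- 0
    data.frame(group = lev, time_days = grid, fit = as.numeric(pr$fit),
               se = se,
               lower = as.numeric(pr$fit) - 1.96 * se,
               upper = as.numeric(pr$fit) + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @importFrom stats loess.control
NULL
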