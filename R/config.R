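# YAML-configured pipeline: simulate -> preprocess -> fit -> predict ->
# evaluate -> compare, with per-stage seeds, JSON sidecars and a run log.

.config_schema <- list(
  seed = NULL,
  paths = c("input_dir", "output_dir"),
  simulate = c("n_patients"),
  thresholds = NULL,
  model = c("baseline", "dynamic", "mode", "include_jump", "knots"),
  mcmc = c("chains", "iter", "warmup", "thin", "b_thin", "inflation"),
  evaluation = c("Ts_list", "dt_list", "n_theta", "n_b_draws", "n_burn")
)

.config_defaults <- function() {
  list(
    seed = 1L,
    paths = list(input_dir = NULL, output_dir = "nitjm_output"),
    simulate = list(n_patients = 300L),
    thresholds = list(),
    model = list(baseline = c("cerebral_oedema", "cerebral_infarction",
                              "respiratory_failure", "hydrocephalus",
                              "vasospasm"),
                 dynamic = c("gcs", "wbc_abnormal", "hyperglycemia"),
                 mode = "both", include_jump = FALSE,
                 knots = seq(0, 14, by = 2)),
    mcmc = list(chains = 2L, iter = 2000L, warmup = 1000L, thin = 1L,
                b_thin = 10L, inflation = 10),
    evaluation = list(Ts_list = c(1, 2, 3, 5, 7), dt_list = c(1, 2, 3, 5, 7),
                      n_theta = 20L, n_b_draws = 150L, n_burn = 150L)
  )
}

#' Parse and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys by name, applies defaults, and
#' returns a fully resolved run configuration. The default evaluation grid is
#' Ts, dt in {1, 2, 3, 5, 7} days.
#'
#' @param path YAML file path.
#' @return a `nitjm_config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path) %||% list()
  unknown <- setdiff(names(raw), names(.config_schema))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (sec in names(raw)) {
    allowed <- .config_schema[[sec]]
    if (!is.null(allowed) && is.list(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), allowed)
      if (length(bad)) {
        stop(sprintf("unknown key(s) in '%s': %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  cfg <- .config_defaults()
  for (sec in names(raw)) {
    # thresholds is an unnamed list of rules and is replaced, not merged
    if (sec != "thresholds" && is.list(cfg[[sec]]) && is.list(raw[[sec]])) {
      cfg[[sec]] <- modifyList(cfg[[sec]], raw[[sec]])
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  if (is.null(cfg$paths$input_dir)) cfg$paths$input_dir <- cfg$paths$output_dir
  if (!cfg$model$mode %in% c("nit", "baseline", "both")) {
    stop("model mode must be one of nit, baseline, both", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "nitjm_config")
}

#' Write the effective configuration back to YAML
#'
#' [parse_config()] of the emitted file reproduces the configuration
#' (round-trip identity).
#'
#' @param config a `nitjm_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
emit_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + sum(utf8ToInt(stage))) %% (2147483647L - 1L) + 1L
}

config_rules <- function(cfg) {
  if (!length(cfg$thresholds)) return(default_threshold_rules())
  lapply(cfg$thresholds, function(r)
    threshold_rule(r$covariate, r$kind, cutoff = r$cutoff, lower = r$lower,
                   upper = r$upper, output_name = r$output_name))
}

write_sidecar <- function(path, stage, cfg_md5, seed, records, elapsed) {
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_md5 = cfg_md5,
         package_version = as.character(utils::packageVersion("nitjm")),
         records = records, elapsed_sec = round(elapsed, 3)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in their canonical order (`simulate`,
#' `preprocess`, `fit-cox`, `fit-lmm`, `fit-joint`, `predict`, `evaluate`,
#' `compare`). Every artifact gets a JSON sidecar recording the stage seed,
#' the MD5 of the effective configuration and the package version; a
#' `pipeline.log` records per-stage wall times and record counts. A stage
#' failure writes a `FAILED` marker and raises the error, retaining earlier
#' artifacts. Stages after `fit-joint` need the fits from the same call.
#'
#' @param config a `nitjm_config`.
#' @param stages character subset of the stage names above.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, stages = c("simulate", "preprocess")) {
  stopifnot(inherits(config, "nitjm_config"))
  all_stages <- c("simulate", "preprocess", "fit-cox", "fit-lmm",
                  "fit-joint", "predict", "evaluate", "compare")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!length(stages)) {
    message("no stages requested; nothing to do")
    return(invisible(list()))
  }
  stages <- all_stages[all_stages %in% stages]
  odir <- config$paths$output_dir
  if (!dir.exists(odir)) dir.create(odir, recursive = TRUE)
  cfg_path <- file.path(odir, "effective_config.yaml")
  emit_config(config, cfg_path)
  cfg_md5 <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(odir, "pipeline.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  state <- new.env(parent = emptyenv())
  artifacts <- list()

  load_state_cohort <- function() {
    if (!is.null(state$cohort)) return(state$cohort)
    idir <- config$paths$input_dir
    pref <- if (file.exists(file.path(idir, "processed_baseline.csv")))
      "processed" else "cohort"
    state$cohort <- load_cohort(file.path(idir, paste0(pref, "_baseline.csv")),
                                file.path(idir, paste0(pref, "_observations.csv")),
                                file.path(idir, paste0(pref, "_outcomes.csv")),
                                quiet = TRUE)
    state$cohort
  }

  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    seed <- stage_seed(config$seed, stage)
    res <- tryCatch(fun(seed), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      marker <- file.path(odir, paste0("FAILED_", stage))
      writeLines(conditionMessage(res), marker)
      logline("[%s] FAILED after %.2fs: %s", stage, elapsed,
              conditionMessage(res))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(res)),
           call. = FALSE)
    }
    for (pth in res$paths) {
      write_sidecar(pth, stage, cfg_md5, seed, res$records, elapsed)
    }
    logline("[%s] ok in %.2fs (%d records)", stage, elapsed,
            res$records %||% NA_integer_)
    artifacts[[stage]] <<- res$paths
  }

  for (stage in stages) {
    switch(stage,
      "simulate" = run_stage(stage, function(seed) {
        sim <- simulate_cohort(config$simulate$n_patients, default_params(),
                               seed = seed)
        state$cohort <- sim$cohort
        paths <- save_cohort(sim$cohort, odir, prefix = "cohort")
        tp <- file.path(odir, "true_params.json")
        p <- sim$params
        jsonlite::write_json(
          list(baseline_prev = as.list(p$baseline_prev),
               gamma = as.list(p$gamma),
               dynamic = lapply(p$dynamic, function(dj)
                 list(beta = dj$beta, beta_tilde = dj$beta_tilde,
                      D = dj$D, sigma = dj$sigma, alpha = dj$alpha)),
               log_h0 = p$log_h0, knots = p$knots,
               intervention_prob = p$intervention_prob,
               intervention_time = p$intervention_time,
               horizon = p$horizon),
          tp, auto_unbox = TRUE, digits = NA)
        list(paths = c(paths, true_params = tp),
             records = n_patients(sim$cohort))
      }),
      "preprocess" = run_stage(stage, function(seed) {
        cohort <- load_state_cohort()
        cohort <- daily_average(cohort)
        rules <- config_rules(config)
        rules <- Filter(function(r)
          r$covariate %in% unique(cohort$observations$covariate), rules)
        if (length(rules)) cohort <- dichotomize(cohort, rules)
        state$cohort <- cohort
        paths <- save_cohort(cohort, odir, prefix = "processed")
        list(paths = paths, records = nrow(cohort$observations))
      }),
      "fit-cox" = run_stage(stage, function(seed) {
        cohort <- load_state_cohort()
        scr <- univariate_screen(cohort, config$model$baseline)
        state$screen <- scr
        pth <- file.path(odir, "cox_screen.csv")
        u <- cbind(scr$univariate, analysis = "univariate")
        m <- if (!is.null(scr$multivariate))
          cbind(scr$multivariate, status = "ok",
                selected = TRUE, analysis = "multivariate")
        write.csv(rbind(u, m), pth, row.names = FALSE)
        list(paths = c(cox = pth), records = nrow(u))
      }),
      "fit-lmm" = run_stage(stage, function(seed) {
        cohort <- load_state_cohort()
        design <- lmm_design(if (config$model$mode == "baseline")
          "baseline" else "nit", include_jump = isTRUE(config$model$include_jump),
          horizon = cohort$horizon_days)
        fits <- lapply(setNames(config$model$dynamic, config$model$dynamic),
                       function(cv) fit_lmm(cohort, cv, design))
        state$lmm <- fits
        pth <- file.path(odir, "lmm_fits.json")
        jsonlite::write_json(lapply(fits, function(f)
          list(covariate = f$covariate, beta = as.list(f$beta_full),
               sigma = f$sigma, D = f$D, loglik = f$loglik,
               converged = f$converged)), pth, auto_unbox = TRUE,
          digits = NA)
        list(paths = c(lmm = pth), records = length(fits))
      }),
      "fit-joint" = run_stage(stage, function(seed) {
        cohort <- load_state_cohort()
        modes <- if (config$model$mode == "both") c("baseline", "nit") else
          config$model$mode
        mc <- config$mcmc
        paths <- character()
        for (md in modes) {
          fit <- nitjm(cohort, dynamic = config$model$dynamic,
                       baseline = config$model$baseline, mode = md,
                       include_jump = isTRUE(config$model$include_jump),
                       knots = config$model$knots, chains = mc$chains,
                       iter = mc$iter, warmup = mc$warmup, thin = mc$thin,
                       b_thin = mc$b_thin, seed = seed,
                       inflation = mc$inflation)
          state[[paste0("fit_", md)]] <- fit
          sm <- summary(fit)
          pth <- file.path(odir, sprintf("joint_%s_summary.csv", md))
          write.csv(rbind(sm$association, sm$baseline), pth,
                    row.names = FALSE)
          dg <- file.path(odir, sprintf("joint_%s_diagnostics.json", md))
          jsonlite::write_json(list(rhat = as.list(fit$draws$rhat),
                                    ess = as.list(fit$draws$ess),
                                    accept = fit$draws$accept,
                                    settings = fit$draws$settings[
                                      c("chains", "iter", "warmup", "seed")]),
                               dg, auto_unbox = TRUE, digits = NA)
          paths <- c(paths, pth, dg)
        }
        list(paths = paths, records = length(modes))
      }),
      "predict" = run_stage(stage, function(seed) {
        fit <- state$fit_nit %||% state$fit_baseline
        if (is.null(fit)) stop("run the fit-joint stage first")
        ev <- config$evaluation
        set.seed(seed)
        pr <- predict(fit, Ts = ev$Ts_list[1], dt = ev$dt_list,
                      n_theta = ev$n_theta, n_b_draws = ev$n_b_draws,
                      n_burn = ev$n_burn)
        pth <- file.path(odir, "predictions.csv")
        write.csv(pr, pth, row.names = FALSE)
        list(paths = c(predictions = pth), records = nrow(pr))
      }),
      "evaluate" = run_stage(stage, function(seed) {
        ev <- config$evaluation
        paths <- character()
        for (md in c("baseline", "nit")) {
          fit <- state[[paste0("fit_", md)]]
          if (is.null(fit)) next
          set.seed(seed)
          g <- auc_grid(fit, Ts_list = ev$Ts_list, dt_list = ev$dt_list,
                        n_theta = ev$n_theta, n_b_draws = ev$n_b_draws,
                        n_burn = ev$n_burn)
          state[[paste0("grid_", md)]] <- g
          pth <- file.path(odir, sprintf("auc_grid_%s.csv", md))
          tab <- rbind(g$auc, Marginal = g$marginal)
          df <- data.frame(row = rownames(tab), tab, check.names = FALSE)
          write.csv(df, pth, row.names = FALSE)
          cat(sprintf("Mean AUC: %.4f +/- %.4f\n", g$mean, g$sd),
              file = pth, append = TRUE)
          paths <- c(paths, pth)
        }
        if (!length(paths)) stop("run the fit-joint stage first")
        list(paths = paths, records = length(paths))
      }),
      "compare" = run_stage(stage, function(seed) {
        if (is.null(state$grid_baseline) || is.null(state$grid_nit)) {
          stop("compare needs both baseline and nit grids from the evaluate stage")
        }
        cmp <- compare_models(state$grid_baseline, state$grid_nit)
        pth <- file.path(odir, "model_comparison.csv")
        mg <- data.frame(Ts = names(cmp$marginal_a),
                         baseline = cmp$marginal_a, nit = cmp$marginal_b,
                         diff = cmp$marginal_diff, row.names = NULL)
        write.csv(mg, pth, row.names = FALSE)
        plt <- file.path(odir, "marginal_auc_comparison.pdf")
        grDevices::pdf(plt, width = 6, height = 4)
        plot(cmp)
        grDevices::dev.off()
        list(paths = c(comparison = pth, plot = plt), records = nrow(mg))
      }))
  }
  invisible(artifacts)
}
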