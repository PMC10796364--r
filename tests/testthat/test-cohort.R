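test_that("save/load round-trips a valid cohort", {
  co <- two_patient_cohort()
  dir <- withr::local_tempdir()
  paths <- save_cohort(co, dir)
  co2 <- load_cohort(paths[["baseline"]], paths[["long"]],
                     paths[["outcome"]], quiet = TRUE)
  expect_equal(co2$baseline, co$baseline)
  expect_equal(co2$outcomes, co$outcomes)
  expect_equal(co2$observations, co$observations)
  expect_equal(co2$horizon_days, co$horizon_days)
})

test_that("cohort validation names the offending record", {
  base <- data.frame(patient_id = c("P1", "P2"), x = c(1, 0))
  out <- data.frame(patient_id = c("P1", "P1"),
                    event_time_days = c(5, 6), good_outcome = c(1, 0))
  obs0 <- data.frame(patient_id = character(), covariate = character(),
                     time_days = numeric(), value = numeric())
  expect_error(sah_cohort(base, out, obs0), "P1")

  out2 <- data.frame(patient_id = c("P1", "P2"),
                     event_time_days = c(5, 14), good_outcome = c(1, 0))
  obs_late <- data.frame(patient_id = "P2", covariate = "gcs",
                         time_days = 15, value = 9)
  expect_error(sah_cohort(base, out2, obs_late), "\\[0, 14\\]")
  obs_unknown <- data.frame(patient_id = "P9", covariate = "gcs",
                            time_days = 1, value = 9)
  expect_error(sah_cohort(base, out2, obs_unknown), "P9")
  obs_after_event <- data.frame(patient_id = "P1", covariate = "gcs",
                                time_days = 6, value = 9)
  expect_error(sah_cohort(base, out2, obs_after_event), "P1")
  expect_error(load_cohort("nope.csv", "nope.csv", "nope.csv"), "not found")
})

test_that("daily averaging bins by calendar day and is idempotent", {
  co <- two_patient_cohort()
  av <- daily_average(co)
  # values {10, 12} at times {0.2, 0.9} -> mean 11 at representative 0.5
  p1 <- av$observations[av$observations$patient_id == "P1" &
                          av$observations$covariate == "gcs", ]
  expect_equal(p1$value, 11)
  expect_equal(p1$time_days, 0.5)
  # single value in a bin is carried over at d - 0.5
  p2 <- av$observations[av$observations$patient_id == "P2" &
                          av$observations$covariate == "gcs", ]
  expect_equal(p2$value, 7)
  expect_equal(p2$time_days, 2.5)
  # idempotence
  expect_equal(daily_average(av)$observations, av$observations)
  # mass conservation: sum of bin means times bin counts = sum of raw values
  raw <- co$observations
  cnt <- aggregate(value ~ patient_id + covariate + day,
                   cbind(raw[c("patient_id", "covariate", "value")],
                         day = pmax(1, ceiling(raw$time_days))), length)
  m <- merge(av$observations, cnt,
             by.x = c("patient_id", "covariate"),
             by.y = c("patient_id", "covariate"))
  expect_equal(sum(m$value.x * m$value.y), sum(raw$value))
  # empty observations: unchanged with a warning
  co0 <- make_cohort("P1", 5, 1)
  expect_warning(out <- daily_average(co0), "no longitudinal")
  expect_identical(out$observations, co0$observations)
})

test_that("dichotomization applies clinical thresholds and keeps originals", {
  obs <- data.frame(
    patient_id = rep("P1", 6),
    covariate = c("glucose", "glucose", "spo2", "spo2", "wbc", "wbc"),
    time_days = c(1, 2, 1, 2, 1, 2),
    value = c(130, 120, 96, 93, 11, 15))
  co <- make_cohort("P1", 10, 1, obs = obs)
  out <- dichotomize(co, default_threshold_rules()[1:3])
  gl <- out$observations[out$observations$covariate == "hyperglycemia", ]
  expect_equal(gl$value, c(1, 0))       # glucose >= 126 mg/dL
  sp <- out$observations[out$observations$covariate == "low_spo2", ]
  expect_equal(sp$value, c(0, 1))       # SpO2 < 95%
  wb <- out$observations[out$observations$covariate == "wbc_abnormal", ]
  expect_equal(wb$value, c(0, 1))       # outside the 4-12 band
  expect_true(all(c("glucose", "spo2", "wbc") %in%
                    out$observations$covariate))
  # record counts per rule equal input record counts; values binary
  expect_equal(nrow(gl), sum(obs$covariate == "glucose"))
  expect_true(all(out$observations$value[
    out$observations$covariate %in%
      c("hyperglycemia", "low_spo2", "wbc_abnormal")] %in% c(0, 1)))
  expect_error(dichotomize(co, list(threshold_rule("creatinine", "at_least",
                                                   cutoff = 1.3,
                                                   output_name = "cr"))),
               "creatinine")
})

test_that("cohort summary counts, stratifies and handles empty strata", {
  ids <- sprintf("P%d", 1:10)
  base <- data.frame(patient_id = ids, age = seq(40, 76, by = 4),
                     hydrocephalus = c(rep(1, 4), rep(0, 6)))
  obs <- data.frame(patient_id = rep(ids[1:3], each = 1),
                    covariate = "gcs", time_days = 1,
                    value = c(10, 12, 14))
  co <- sah_cohort(base, data.frame(patient_id = ids,
                                    event_time_days = rep(10, 10),
                                    good_outcome = rep(c(1, 0), 5)),
                   obs)
  s <- summary(co)
  expect_equal(s$baseline$formatted_all[1], "4 (40.00%)")
  expect_equal(s$dynamic$mean_all, 12)
  expect_equal(s$dynamic$sd_all, 2)   # sample SD of {10, 12, 14}
  # degenerate stratum: all patients in one group
  co1 <- sah_cohort(base, data.frame(patient_id = ids,
                                     event_time_days = rep(10, 10),
                                     good_outcome = rep(1, 10)), obs)
  s1 <- summary(co1)
  expect_equal(s1$n_poor, 0)
  expect_true(is.na(s1$dynamic$mean_poor))
  expect_output(print(s1), "40.00%")
})

test_that("loess curves recover exact trends on clean data", {
  set.seed(1)
  t <- seq(0, 14, length.out = 40)
  # constant series
  cst <- data.frame(time_days = t, value = rep(5, 40))
  cv <- loess_curve(cst, span = 0.75)
  expect_true(all(abs(cv$fit - 5) < 1e-9))
  # noiseless linear data: local linear fit is exact on the interior
  lin <- data.frame(time_days = t, value = 2 * t)
  cl <- loess_curve(lin, span = 0.75)
  interior <- cl$time_days > 1 & cl$time_days < 13
  expect_true(all(abs(cl$fit[interior] - 2 * cl$time_days[interior]) < 1e-6))
  # span 1 on 5 collinear points recovers the straight line
  five <- data.frame(time_days = 1:5, value = 3 * (1:5) - 2)
  c5 <- loess_curve(five, span = 1, n_grid = 9)
  expect_true(all(abs(c5$fit - (3 * c5$time_days - 2)) < 1e-6))
  # grouped curves and the minimum-points guard
  g <- rbind(cbind(lin, grp = "a"), cbind(cst, grp = "b"))
  cg <- loess_curve(g, group = "grp")
  expect_setequal(unique(cg$group), c("a", "b"))
  expect_true(all(cg$upper >= cg$lower))
  expect_error(loess_curve(lin[1:4, ]), "at least 5")
})
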