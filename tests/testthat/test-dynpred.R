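test_that("the risk set conditions on being event-free at Ts", {
  obs <- data.frame(patient_id = c("A", "B", "B", "C"),
                    covariate = "score", time_days = c(1, 2, 9, 0.4),
                    value = c(1, 2, 3, 4))
  co <- make_cohort(c("A", "B", "C"), time = c(2, 14, 13),
                    event = c(1, 0, 1), obs = obs)
  rs <- risk_set(co, 3)
  expect_setequal(rs$outcomes$patient_id, c("B", "C"))
  rs7 <- risk_set(co, 7)
  expect_true(all(rs7$observations$time_days <= 7))
  expect_true("B" %in% rs7$outcomes$patient_id)
  # an early Ts keeps the whole cohort when all events are later
  rs05 <- risk_set(co, 0.5)
  expect_equal(n_patients(rs05), 3)
  co_all_events <- make_cohort(c("A", "B"), time = c(2, 3), event = c(1, 1))
  expect_error(risk_set(co_all_events, 5), "empty")
  expect_error(risk_set(co, 14), "\\(0, 14\\)")
})

const_hazard_fit <- function(h, n = 6, alpha = 0, n_draws = 10) {
  spec <- nitjm_spec("x", "score", mode = "baseline")
  params <- nitjm_params(gamma = c(x = 0), alpha = c(score = alpha),
                         beta = matrix(c(0.5, 0.05), 1),
                         lambda = rep(log(h), 7), sigma = c(score = 0.4),
                         D = list(diag(c(0.4, 0.02))), spec = spec)
  ids <- sprintf("P%d", seq_len(n))
  obs <- data.frame(patient_id = rep(ids, each = 2), covariate = "score",
                    time_days = rep(c(0.5, 1.5), n),
                    value = rnorm(2 * n, 0.5, 0.3))
  co <- make_cohort(ids, time = rep(14, n), event = rep(0, n), obs = obs,
                    baseline = data.frame(patient_id = ids,
                                          x = rep(c(0, 1), length.out = n)))
  degenerate_fit(params, spec, co, n_draws = n_draws)
}

test_that("conditional event probabilities match the exponential closed form", {
  set.seed(55)
  fit <- const_hazard_fit(0.12, n_draws = 200)
  pr <- conditional_event_probability(fit, Ts = 2, dt = 3, n_theta = 200,
                                      n_b_draws = 50, n_burn = 50)
  expect_lt(max(abs(pr$pi - (1 - exp(-0.12 * 3)))), 1e-3)
  # vanishing window
  pr0 <- conditional_event_probability(fit, Ts = 2, dt = 1e-9, n_theta = 5,
                                       n_b_draws = 20, n_burn = 20)
  expect_lt(max(pr0$pi), 1e-6)
  # numerically zero hazard
  set.seed(56)
  fit0 <- const_hazard_fit(exp(-60))
  prz <- conditional_event_probability(fit0, Ts = 2, dt = 5, n_theta = 5,
                                       n_b_draws = 20, n_burn = 20)
  expect_lt(max(prz$pi), 1e-12)
})

test_that("predictions are probabilities, monotone in the interval", {
  set.seed(57)
  sim <- simulate_cohort(40, one_cov_params(), seed = 33)
  s <- sim$params
  spec <- nitjm_spec("x", "score", mode = "nit")
  params <- nitjm:::true_params_to_joint(s)$params
  fit <- degenerate_fit(params, spec, sim$cohort, n_draws = 8)
  pr <- predict(fit, Ts = 2, dt = c(1, 3, 7), n_theta = 8, n_b_draws = 80,
                n_burn = 80)
  expect_true(all(pr$pi >= 0 & pr$pi <= 1))
  w <- reshape(pr, idvar = "patient_id", timevar = "dt", direction = "wide")
  expect_true(all(w$pi.1 <= w$pi.3 + 1e-12))
  expect_true(all(w$pi.3 <= w$pi.7 + 1e-12))
})

test_that("windowed AUC equals exhaustive pair enumeration", {
  # worked example: cases {0.9, 0.6}, controls {0.2, 0.6} -> 3.5/4
  co <- make_cohort(c("c1", "c2", "k1", "k2"), time = c(3, 3.5, 14, 14),
                    event = c(1, 1, 0, 0))
  sc <- c(c1 = 0.9, c2 = 0.6, k1 = 0.2, k2 = 0.6)
  a <- auc_window(sc, co, Ts = 2, dt = 2)
  expect_equal(as.numeric(a), 0.875)
  expect_equal(attr(a, "n_pairs"), 4L)
  # perfect separation and complete ties
  expect_equal(as.numeric(auc_window(c(c1 = 0.9, k1 = 0.2),
                                     make_cohort(c("c1", "k1"),
                                                 time = c(3, 14),
                                                 event = c(1, 0)),
                                     2, 2)), 1.0)
  expect_equal(as.numeric(auc_window(setNames(rep(0.4, 4), names(sc)), co,
                                     2, 2)), 0.5)
  # property: equality with brute-force enumeration on random fixtures
  set.seed(71)
  for (r in 1:20) {
    n <- sample(6:20, 1)
    ids <- sprintf("P%d", seq_len(n))
    time <- round(runif(n, 0.5, 14), 2)
    ev <- rbinom(n, 1, 0.6)
    ev[time >= 14] <- 0
    co <- make_cohort(ids, time = pmin(time, 14), event = ev)
    sc <- setNames(round(runif(n), 2), ids)
    Ts <- 1
    dt <- 5
    a <- auc_window(sc, co, Ts, dt)
    cases <- ids[ev == 1 & time > Ts & time <= Ts + dt]
    ctrls <- ids[time > Ts + dt | (ev == 0 & time >= Ts + dt)]
    if (!length(cases) || !length(ctrls)) {
      expect_true(is.na(a))
      next
    }
    tot <- 0
    for (i in cases) for (j in ctrls) {
      tot <- tot + unname((sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j]))
    }
    expect_equal(as.numeric(a), tot / (length(cases) * length(ctrls)))
  }
  # no cases: reported missing, not fatal
  co_nc <- make_cohort(c("A", "B"), time = c(14, 14), event = c(0, 0))
  expect_true(is.na(auc_window(c(A = 0.5, B = 0.2), co_nc, 1, 2)))
})

test_that("AUC grids aggregate cells into marginal and mean summaries", {
  set.seed(91)
  sim <- simulate_cohort(120, one_cov_params(), seed = 44)
  params <- nitjm:::true_params_to_joint(sim$params)$params
  spec <- nitjm_spec("x", "score", mode = "nit")
  fit <- degenerate_fit(params, spec, sim$cohort, n_draws = 6)
  g <- auc_grid(fit, Ts_list = c(1, 3), dt_list = c(2, 5), n_theta = 6,
                n_b_draws = 60, n_burn = 60)
  expect_true(all(g$auc >= 0 & g$auc <= 1, na.rm = TRUE))
  # marginal = pair-weighted average of the column's cells
  for (s in 1:2) {
    ok <- !is.na(g$auc[, s])
    expect_equal(unname(g$marginal[s]),
                 sum(g$auc[ok, s] * g$pairs[ok, s]) / sum(g$pairs[ok, s]))
  }
  expect_equal(g$mean, mean(g$auc[!is.na(g$auc)]))
  expect_equal(g$sd, sd(g$auc[!is.na(g$auc)]))
  # single-cell grid: the marginal equals the cell
  g1 <- auc_grid(fit, Ts_list = 2, dt_list = 3, n_theta = 6,
                 n_b_draws = 60, n_burn = 60)
  expect_equal(unname(g1$marginal[1]), unname(g1$auc[1, 1]))
  expect_true(is.na(g1$sd))
  expect_output(print(g), "Mean AUC")
})

fake_grid <- function(A, pairs = NULL, Ts = c(1, 2, 3, 5, 7),
                      dt = c(1, 2, 3, 5, 7)) {
  dimnames(A) <- list(paste0("dt=", dt), paste0("Ts=", Ts))
  pairs <- pairs %||% (A * 0 + 10)
  filled <- !is.na(A)
  marginal <- vapply(seq_along(Ts), function(s) {
    ok <- filled[, s]
    sum(A[ok, s] * pairs[ok, s]) / sum(pairs[ok, s])
  }, numeric(1))
  structure(list(auc = A, pairs = pairs, marginal = marginal,
                 mean = mean(A[filled]),
                 sd = sd(A[filled]), Ts_list = Ts, dt_list = dt,
                 horizon = 14),
            class = "nitjm_auc_grid")
}

test_that("pair weighting and phase comparisons are computed as documented", {
  # weighted marginal: cells {1.0 (1 pair), 0.0 (3 pairs)} -> 0.25
  A <- matrix(c(1, 0), 2, 1)
  g <- fake_grid(A, pairs = matrix(c(1, 3), 2, 1), Ts = 1, dt = c(1, 2))
  expect_equal(unname(g$marginal[1]), 0.25)
  # identical grids: zero differences everywhere
  A5 <- matrix(runif(25, 0.6, 0.9), 5, 5)
  A5[5, 5] <- NA
  ga <- fake_grid(A5)
  cmp0 <- compare_models(ga, ga)
  expect_true(all(cmp0$diff == 0, na.rm = TRUE))
  expect_equal(cmp0$overall_diff, 0)
  # constant shift: overall mean difference equals the shift
  gb <- fake_grid(A5 + 0.01)
  cmp <- compare_models(ga, gb)
  expect_equal(cmp$overall_diff, 0.01, tolerance = 1e-12)
  expect_equal(cmp$acute_diff, 0.01, tolerance = 1e-12)
  # acute cells for the standard grid are exactly (1,1), (1,2), (2,1)
  ac <- cmp$acute_cells
  got <- sort(paste(ga$dt_list[ac[, "row"]], ga$Ts_list[ac[, "col"]]))
  expect_equal(got, sort(c("1 1", "2 1", "1 2")))
  # mismatched grids are rejected
  g2 <- fake_grid(matrix(0.7, 2, 2), Ts = c(1, 2), dt = c(1, 2))
  expect_error(compare_models(ga, g2), "different")
})
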