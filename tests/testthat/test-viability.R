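test_that("p50 definitions follow the closed forms", {
  expect_equal(p50_of_initial(0, 10), 6.744898, tolerance = 1e-6)
  expect_equal(p50_of_initial(2.054, 20), 41.581, tolerance = 1e-3)
  # high initial viability converges to the absolute definition
  expect_equal(p50_of_initial(8, 30), p50_absolute(8, 30), tolerance = 1e-8)
  expect_equal(p50_absolute(1, 50), 50)
  expect_equal(p50_absolute(2, 20), 40)
  expect_error(p50_absolute(-0.5, 10), class = "seedspan_invalid_input")
  # monotone in sigma and in Ki; the half-of-initial target (half of a
  # sub-100 % start is below 50 % absolute) is reached at or after the
  # absolute-50 % point, converging from above as Ki grows
  for (Ki in c(-0.5, 0.3, 1, 2.5)) {
    expect_true(all(diff(p50_of_initial(Ki, c(5, 10, 20, 40))) > 0))
  }
  for (s in c(5, 30, 100)) {
    expect_true(all(diff(p50_of_initial(c(-1, 0, 1, 2, 4), s)) > 0))
    for (Ki in c(0.2, 1, 3)) {
      expect_gte(p50_of_initial(Ki, s), p50_absolute(Ki, s))
    }
  }
})

test_that("exact on-curve counts invert the probit model", {
  # pnorm(2) = 0.97725, pnorm(0) = 0.5, pnorm(-2) = 0.02275 at t = 0/40/80
  tc <- exact_probit_tc(2, 20, c(0, 40, 80), 100000)
  f <- fit_probit(tc)
  expect_equal(f$Ki, 2, tolerance = 1e-3)
  expect_equal(f$sigma, 20, tolerance = 1e-3)
  expect_false(f$degenerate)
  expect_false(f$censored)
})

test_that("probit fit recovers generating parameters from rounded counts", {
  tc <- exact_probit_tc(2, 30, c(0, 30, 60, 90, 120), 50)
  f <- fit_probit(tc)
  expect_lt(abs(f$Ki - 2), 0.3)
  expect_lt(abs(f$sigma - 30), 5)
})

test_that("optimizer matches the exhaustive grid-search oracle", {
  set.seed(7)
  cases <- list(
    exact_probit_tc(2, 30, c(0, 30, 60, 90, 120), 50),
    gen_timecourse(1.5, 60, schedule = c(0, 40, 80, 120, 160, 200),
                   n_tested = 50),
    gen_timecourse(2.5, 15, schedule = c(0, 15, 30, 45, 60), n_tested = 25)
  )
  for (tc in cases) {
    f <- fit_probit(tc)
    oracle <- grid_probit_oracle(tc)
    expect_lt(abs(f$log_likelihood - oracle[["ll"]]), 0.005)
    expect_gte(f$log_likelihood, oracle[["ll"]] - 0.005)
  }
})

test_that("degenerate and uninformative time-courses are flagged", {
  flat <- timecourse("flat", c(0, 30, 60), 50, c(25, 25, 25))
  f <- suppressWarnings(fit_probit(flat))
  expect_true(f$degenerate)
  expect_error(fit_probit(timecourse("dead", c(0, 30, 60), 50, c(0, 0, 0))),
               class = "seedspan_invalid_input")
  expect_error(fit_probit(timecourse("alive", c(0, 30, 60), 50, c(50, 50, 50))),
               class = "seedspan_invalid_input")
  expect_error(fit_probit(timecourse("short", c(0, 30), 50, c(50, 10))),
               class = "seedspan_invalid_input")
})

test_that("delta-method SE is calibrated against Monte Carlo", {
  set.seed(11)
  p50s <- ses <- numeric(1000)
  for (i in 1:1000) {
    f <- fit_probit(gen_timecourse(2, 30))
    p50s[i] <- f$p50; ses[i] <- f$p50_se
  }
  expect_lt(abs(sd(p50s) - mean(ses)) / mean(ses), 0.2)
  # information grows with n: SE shrinks towards 0
  big <- fit_probit(exact_probit_tc(2, 30, c(0, 30, 60, 90, 120), 1000000))
  small <- fit_probit(exact_probit_tc(2, 30, c(0, 30, 60, 90, 120), 50))
  expect_lt(big$p50_se, small$p50_se / 50)
  expect_lt(big$p50_se, 0.1)
})

test_that("censored (extrapolated) p50 is flagged but returned", {
  set.seed(3)
  tc <- gen_timecourse(2.054, sigma_for_p50(300), schedule = seq(0, 210, 15))
  f <- fit_probit(tc)
  expect_true(f$censored)
  expect_gt(f$p50, 210)
})

test_that("the logistic model has the documented declining shape", {
  set.seed(5)
  # noiseless data on alpha = 0, beta = 0.1, c = 50
  times <- seq(0, 100, by = 10)
  g <- round(1000 * (100 - 0) / (1 + exp(0.1 * (times - 50))) / 100)
  f <- fit_logistic(timecourse("lg", times, 1000, g))
  expect_equal(predict_survival_curve(f, 50), 50, tolerance = 0.5)
  expect_equal(predict_survival_curve(f, 0), 99.33, tolerance = 0.5)
  expect_equal(f$p50, f$c)
  # parameter recovery on alpha = 10, beta = 0.2, c = 30
  g2 <- round(2000 * (100 - 10) / (1 + exp(0.2 * (times - 30))) / 100)
  f2 <- fit_logistic(timecourse("lg2", times, 2000, g2))
  expect_equal(f2$alpha, 10, tolerance = 0.5)
  expect_equal(f2$beta, 0.2, tolerance = 0.02)
  expect_equal(f2$c, 30, tolerance = 0.5)
})

test_that("model comparison prefers the lower AIC and ties go to probit", {
  tc <- exact_probit_tc(2, 30, c(0, 30, 60, 90, 120), 50)
  fp <- fit_probit(tc)
  fl <- fit_logistic(tc)
  # force known log-likelihoods: AIC_probit = -2ll + 4, AIC_logistic = -2ll + 6
  fp$log_likelihood <- -50      # AIC 104
  fl$log_likelihood <- -52.5    # AIC 111
  expect_equal(compare_fits(fp, fl), "probit")
  fl$log_likelihood <- -45      # AIC 96
  expect_equal(compare_fits(fp, fl), "logistic")
  fl$log_likelihood <- -51      # AIC 108 vs ... set equal
  fp$log_likelihood <- -52      # both AIC 108
  expect_equal(compare_fits(fp, fl), "probit")
})

test_that("predicted survival curves behave like survival curves", {
  tc <- exact_probit_tc(2, 20, c(0, 20, 40, 60, 80), 1000)
  f <- fit_probit(tc)
  expect_equal(predict_survival_curve(f, 0), 97.72, tolerance = 0.1)
  curve <- predict_survival_curve(f, seq(0, 500, 5))
  expect_true(all(diff(curve) <= 0))
  expect_lt(predict_survival_curve(f, 1e6), 1e-8)
  # at p50 the curve is at exactly half its initial value
  expect_equal(predict_survival_curve(f, f$p50),
               predict_survival_curve(f, 0) / 2, tolerance = 1e-8)
})

test_that("NED regression cross-check lands near the ML fit on clean data", {
  tc <- exact_probit_tc(2, 30, c(0, 30, 60, 90, 120), 10000)
  ml <- fit_probit(tc)
  ned <- fit_probit_ned(tc)
  expect_equal(ned$p50, ml$p50, tolerance = 0.05 * ml$p50)
})

test_that("batch fitting returns one row per species with auto choice", {
  set.seed(9)
  tcs <- list(a = gen_timecourse(2, 30, species_id = "a"),
              b = gen_timecourse(1.5, 80, species_id = "b"))
  out <- fit_viability(tcs, model = "auto")
  expect_equal(nrow(out), 2L)
  expect_true(all(out$model %in% c("probit", "logistic")))
  expect_true(all(out$p50 > 0))
})
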