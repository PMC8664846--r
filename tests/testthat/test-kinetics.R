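# Dwell extraction, exponential fits, survival fractions, ensemble decay and
# the Welch group test.

test_that("dwell extraction follows the event-origin rules", {
  ev <- data.frame(time = c(100, 250), frame = c(250, 625),
                   delta = c(178, 178), from_level = c(0, 178),
                   to_level = c(178, 356), direction = "gain",
                   trace_id = "t1")
  dw <- extract_dwells(list(ev), window = 400, kind = "association")
  expect_equal(dw$duration_s, c(100, 150))
  dw_start <- extract_dwells(list(ev), window = 400, kind = "association",
                             origin = "start")
  expect_equal(dw_start$duration_s, c(100, 250))

  # dissociation measured from the preceding gain
  ev2 <- rbind(ev, data.frame(time = 320, frame = 800, delta = -178,
                              from_level = 356, to_level = 178,
                              direction = "loss", trace_id = "t1"))
  dw2 <- extract_dwells(list(ev2), window = 400, kind = "dissociation")
  expect_equal(dw2$duration_s, 70)

  # no qualifying event: one censored dwell at the window
  dw3 <- extract_dwells(list(smtrace:::empty_steps()), window = 400,
                        kind = "rna_release")
  expect_equal(dw3$duration_s, 400)
  expect_true(dw3$censored)
  expect_error(extract_dwells(list(ev), window = -1), "positive")
})

test_that("the CDF fit is exact on exponential quantiles", {
  n <- 500
  d <- qexp((seq_len(n) - 0.5) / n, rate = 1 / 100)
  fit <- fit_exponential(dwell_sample(d))
  expect_lt(abs(fit$tau - 100), 1e-3)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("the censoring-aware MLE has its closed form", {
  fit <- fit_exponential(dwell_sample(c(2, 4, 6)), method = "mle",
                         min_events = 2)
  expect_equal(fit$tau, 4)
  expect_equal(fit$tau_se, 4 / sqrt(3))
  # censored mass enters the numerator only
  dwc <- dwell_sample(c(2, 4, 6, 10), censored = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(fit_exponential(dwc, "mle", min_events = 2)$tau, 22 / 3)
  expect_error(fit_exponential(dwell_sample(5, TRUE), "mle"), "censored")
})

test_that("282-event samples recover the association time constant", {
  cfg <- sim_config("DYNAMICS", seed = 101)
  dw <- simulate_dwell_sample(cfg, "association", 282)
  fit <- fit_exponential(dw)
  expect_lt(abs(fit$tau - 465.3), 2 * 34.4)
})

test_that("survival fractions are monotone with correct endpoints", {
  set.seed(7)
  d <- rexp(200, 1 / 50)
  cens <- d > 100
  d[cens] <- 100
  sample_ <- dwell_sample(d, cens)
  expect_equal(survival_fraction(sample_, 0), 1)
  # at the censoring time only the censored traces still survive
  expect_equal(survival_fraction(sample_, 100), mean(cens))
  s_grid <- sapply(seq(0, 120, by = 5), survival_fraction, sample = sample_)
  expect_true(all(diff(s_grid) <= 0))
  # uncensored sample beyond every duration
  expect_equal(survival_fraction(dwell_sample(c(1, 2, 3)), 10), 0)
  expect_error(survival_fraction(dwell_sample(numeric()), 1), "insufficient")
})

test_that("an exact exponential series is recovered to machine precision", {
  tt <- seq(0, 200, by = 0.4)
  ser <- exp(-tt / 46.5)
  fit <- fit_ensemble_decay(ser, 0.4)
  expect_lt(abs(fit$tau - 46.5), 1e-6)
  expect_lt(abs(fit$baseline), 1e-8)
  expect_error(fit_ensemble_decay(rep(1, 50), 0.4), "fit failure")
  expect_error(fit_ensemble_decay(seq(1, 2, length.out = 50), 0.4),
               "does not decay")
  expect_error(fit_ensemble_decay(seq(2, 1, length.out = 50), 0.4),
               "normalized")
})

test_that("Welch's test matches its closed form and edge cases", {
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_value, 1)
  w <- welch_test(c(0, 0, 0, 1), c(10, 10, 10, 11))
  # means differ by 10, each group has var 0.25 and n 4
  expect_equal(w$t_statistic, -10 / sqrt(0.25 / 4 + 0.25 / 4))
  expect_equal(w$df, 6)
  expect_lt(w$p_value, 0.001)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(welch_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("dwell times are independent of oligomer size", {
  cfg <- sim_config("DYNAMICS")
  set.seed(55)
  ok <- 0
  for (i in 1:100) {
    d <- rexp(120, 1 / 465.3)
    size <- sample(c(2, 4), 120, replace = TRUE)
    p <- welch_test(d[size == 2], d[size == 4])$p_value
    if (p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 90)
})

test_that("MLE and CDF estimates agree on uncensored samples", {
  set.seed(66)
  for (i in 1:10) {
    dw <- dwell_sample(rexp(300, 1 / 100))
    t1 <- fit_exponential(dw, "cdf_lsq")$tau
    t2 <- fit_exponential(dw, "mle")$tau
    expect_lt(abs(t1 - t2) / t2, 0.10)
  }
})

test_that("tau recovery coverage matches the printed uncertainties", {
  cfg <- sim_config("DYNAMICS")
  cfg_rna <- sim_config("RNA_1MM_ATP")
  set.seed(77)
  cover_assoc <- 0
  cover_rna <- 0
  err_dissoc <- numeric(100)
  for (i in 1:100) {
    ta <- fit_exponential(simulate_dwell_sample(cfg, "association", 282))$tau
    if (abs(ta - 465.3) <= 2 * 34.4) cover_assoc <- cover_assoc + 1
    tr <- fit_exponential(simulate_dwell_sample(cfg_rna, "rna_release",
                                                300))$tau
    if (abs(tr - 49.8) <= 2 * 2.9) cover_rna <- cover_rna + 1
    err_dissoc[i] <-
      fit_exponential(simulate_dwell_sample(cfg, "dissociation", 282))$tau
  }
  expect_gte(cover_assoc, 95)
  expect_gte(cover_rna, 90)
  # the dissociation estimator is unbiased at the printed precision
  expect_lt(abs(mean(err_dissoc) - 385.1), 2 * 15.3)
})
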