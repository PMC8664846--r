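# Generators: kinetic, stoichiometric and noise structure of the simulated
# traces, plus reproducibility.

test_that("noise-free bleaching trace is a clean downward staircase", {
  cfg <- sim_config("CALIBRATION", seed = 3, n_frames = 200,
                    unit_sd = 0, read_noise_sd = 0, bleach_rate = 0.2)
  sim <- simulate_bleach_trace(cfg, 2)
  expect_equal(length(sim$truth$event_times), 2)   # distinct bleach frames
  lv <- unique(sim$trace$values)
  expect_equal(sort(lv, decreasing = TRUE), c(2 * 178.2, 178.2, 0))
  # levels appear in strictly decreasing order
  expect_true(!is.unsorted(rev(match(sim$trace$values, sort(lv)))))
  expect_true(all(diff(sim$truth$dye_counts) <= 0))
})

test_that("per-dye emission recovers the configured single-dye intensity", {
  cfg <- sim_config("CALIBRATION", seed = 17, n_frames = 300,
                    read_noise_sd = 0)
  sims <- simulate_calibration_set(cfg, 200)
  per_dye <- unlist(lapply(seq_along(sims$traces), function(i) {
    k <- sims$truths[[i]]$dye_counts
    sims$traces[[i]]$values[k > 0] / k[k > 0]
  }))
  se <- sd(per_dye) / sqrt(length(per_dye))
  expect_lt(abs(mean(per_dye) - 178.2), 3 * se)
})

test_that("zero bleach rate gives no events and a constant dye count", {
  cfg <- sim_config("CALIBRATION", seed = 1, n_frames = 100, bleach_rate = 0)
  sim <- simulate_bleach_trace(cfg, 3)
  expect_length(sim$truth$event_times, 0)
  expect_true(all(sim$truth$dye_counts == 3))
})

test_that("invalid generator arguments are rejected", {
  cfg <- sim_config("CALIBRATION", n_frames = 100)
  expect_error(simulate_bleach_trace(cfg, 0), "positive")
  expect_error(simulate_bleach_trace(sim_config("DYNAMICS"), 1),
               "CALIBRATION")
  expect_error(sim_config("DYNAMICS", kinetics = list(tau_assoc = -5)),
               "positive")
  expect_error(sim_config("TWO_COLOR", pathway_probs = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(simulate_rna_trace(sim_config("CALIBRATION")), "RNA")
  cfgd <- sim_config("DYNAMICS")
  cfgd$kinetics$tau_assoc <- NULL
  expect_error(simulate_oligomer_dynamics_trace(cfgd), "tau_assoc")
})

test_that("dynamics waiting times follow the configured exponentials", {
  cfg <- sim_config("DYNAMICS", seed = 23)
  waits_gain <- numeric()
  waits_loss <- numeric()
  set.seed(23)
  cfg$seed <- NULL
  while (length(waits_gain) < 1000) {
    tr <- simulate_oligomer_dynamics_trace(cfg)
    w <- tr$truth$waits
    waits_gain <- c(waits_gain, w[names(w) == "gain"])
    waits_loss <- c(waits_loss, w[names(w) == "loss"])
  }
  se_g <- sd(waits_gain) / sqrt(length(waits_gain))
  expect_lt(abs(mean(waits_gain) - 465.3), 3 * se_g)
  se_l <- sd(waits_loss) / sqrt(length(waits_loss))
  expect_lt(abs(mean(waits_loss) - 385.1), 3 * se_l)
})

test_that("default event-size mixtures have the configured means", {
  cfg <- sim_config("DYNAMICS")
  amix <- cfg$size_distribution$association
  expect_equal(sum(as.numeric(names(amix)) * amix), 2.13)
  dmix <- cfg$size_distribution$dissociation
  expect_equal(sum(as.numeric(names(dmix)) * dmix), 2.48)
})

test_that("degenerate size mixture yields only size-2 events", {
  cfg <- sim_config("DYNAMICS", seed = 5,
                    kinetics = list(tau_assoc = 20, tau_dissoc = 20),
                    size_distribution = list(association = c(`2` = 1),
                                             dissociation = c(`2` = 1)))
  sim <- simulate_oligomer_dynamics_trace(cfg)
  expect_gt(length(sim$truth$event_sizes), 5)
  expect_true(all(abs(sim$truth$event_sizes) == 2))
})

test_that("RNA censoring matches the closed-form exponential survival", {
  cfg1 <- sim_config("RNA_1MM_ATP", seed = 7)
  dw1 <- simulate_dwell_sample(cfg1, "rna_release", 10000, window = 400)
  p1 <- exp(-400 / 49.8)
  expect_lt(abs(mean(dw1$censored) - p1),
            3 * sqrt(p1 * (1 - p1) / 10000) + 1e-4)

  cfg2 <- sim_config("RNA_10UM_ATP", seed = 8)
  dw2 <- simulate_dwell_sample(cfg2, "rna_release", 10000, window = 400)
  expect_lt(abs(mean(dw2$censored) - 0.716),
            3 * sqrt(0.716 * 0.284 / 10000))

  # zero-length window censors everything
  dw0 <- simulate_dwell_sample(cfg1, "rna_release", 50, window = 0)
  expect_true(all(dw0$censored))
})

test_that("stratified two-colour generation gives exact class counts", {
  cfg <- sim_config("TWO_COLOR", seed = 12, n_frames = 100)
  res <- simulate_two_color_pairs(cfg, 72, stratified = TRUE)
  expect_equal(as.integer(table(factor(res$classes,
                                       c("SIMULTANEOUS", "SEQUENTIAL",
                                         "NO_DISSOCIATION")))),
               c(14, 31, 27))
  for (n in c(1, 5, 57)) {
    res_n <- simulate_two_color_pairs(cfg, n, stratified = TRUE)
    expect_length(res_n$classes, n)
  }
})

test_that("degenerate pathway probabilities force a single class", {
  cfg <- sim_config("TWO_COLOR", seed = 13, n_frames = 100,
                    pathway_probs = c(SIMULTANEOUS = 1, SEQUENTIAL = 0,
                                      NO_DISSOCIATION = 0))
  res <- simulate_two_color_pairs(cfg, 20)
  expect_true(all(res$classes == "SIMULTANEOUS"))
})

test_that("partial channel-A losses are single molecules at the 0.85 rate", {
  cfg <- sim_config("TWO_COLOR", seed = 19, n_frames = 1000)
  res <- simulate_two_color_pairs(cfg, 12000)
  sizes <- unlist(lapply(res$pairs, function(p) {
    s <- p$truth$event_sizes
    if (p$truth$class == "SIMULTANEOUS" && length(s)) s <- s[-length(s)]
    s
  }))
  expect_gte(length(sizes), 10000)
  f <- mean(sizes == -1)
  expect_lt(abs(f - 0.85), 3 * sqrt(0.85 * 0.15 / length(sizes)))
})

test_that("waiting-time samples pass a KS test against the exponential", {
  for (kind in c("association", "dissociation")) {
    cfg <- sim_config("DYNAMICS", seed = 31)
    dw <- simulate_dwell_sample(cfg, kind, 5000)
    tau <- cfg$kinetics[[if (kind == "association") "tau_assoc"
                         else "tau_dissoc"]]
    expect_gt(stats::ks.test(dw$duration_s, "pexp", 1 / tau)$p.value, 0.01)
  }
})

test_that("identical seeds and configs reproduce bit-identical output", {
  for (mk in list(
    function() simulate_bleach_trace(sim_config("CALIBRATION", seed = 42,
                                                n_frames = 150), 3),
    function() simulate_oligomer_dynamics_trace(
      sim_config("DYNAMICS", seed = 42, n_frames = 300)),
    function() simulate_rna_trace(sim_config("RNA_1MM_ATP", seed = 42,
                                             n_frames = 200)),
    function() simulate_two_color_pair(sim_config("TWO_COLOR", seed = 42,
                                                  n_frames = 200)))) {
    a <- mk()
    b <- mk()
    expect_identical(a, b)
  }
})

test_that("ground-truth dye counts are non-negative and change only at events", {
  cfgs <- list(sim_config("DYNAMICS", seed = 55, n_frames = 400),
               sim_config("RNA_1MM_ATP", seed = 56, n_frames = 400))
  sims <- list(simulate_oligomer_dynamics_trace(cfgs[[1]]),
               simulate_rna_trace(cfgs[[2]]))
  for (i in seq_along(sims)) {
    truth <- sims[[i]]$truth
    expect_true(all(truth$dye_counts >= 0))
    change_frames <- which(diff(truth$dye_counts) != 0)  # boundary index
    event_frames <- floor(truth$event_times / cfgs[[i]]$frame_interval)
    expect_true(all(change_frames %in% event_frames))
    expect_true(!is.unsorted(truth$event_times, strictly = TRUE))
  }
})
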