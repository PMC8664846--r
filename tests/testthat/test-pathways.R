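# Channel matching, pathway classification and partial-step statistics.

test_that("identical coordinate lists match perfectly", {
  sp <- data.frame(x = c(10, 40, 80), y = c(12, 42, 82))
  m <- match_channels(sp, sp, radius = 2)
  expect_equal(nrow(m$pairs), 3)
  expect_true(all(m$pairs$distance == 0))
  expect_equal(m$colocalization_fraction, 1)
})

test_that("spots beyond the radius never match", {
  a <- data.frame(x = c(10, 40), y = c(10, 40))
  b <- data.frame(x = c(13, 43), y = c(10, 40))   # offset radius + 1
  m <- match_channels(a, b, radius = 2)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$colocalization_fraction, 0)
  # empty inputs are fine
  m0 <- match_channels(a[0, ], b, radius = 2)
  expect_equal(nrow(m0$pairs), 0)
})

test_that("mutual-nearest matching recovers a known pairing fraction", {
  set.seed(3)
  shared <- data.frame(x = rep(seq(10, 190, by = 20), 10) +
                         runif(100, -0.5, 0.5),
                       y = rep(seq(10, 190, by = 20), each = 10) +
                         runif(100, -0.5, 0.5))
  only_b <- data.frame(x = seq(12, 192, by = 20) + 5, y = rep(200, 10))
  a <- shared
  b <- rbind(shared + matrix(runif(200, -0.8, 0.8), ncol = 2), only_b)
  m <- match_channels(a, b, radius = 2)
  expect_equal(nrow(m$pairs), 100)
  expect_equal(m$colocalization_fraction, 100 / 110)
  expect_equal(length(m$unmatched_b), 10)
})

test_that("classification follows the timing rules", {
  dt <- 0.4
  # B loss at 100.0 s, final A loss at 100.4 s, tolerance 0.8 -> SIMULTANEOUS
  ia <- make_ideal(c(356.4, 178.2, 0), c(100, 151, 1000 - 251), dt)
  ib <- make_ideal(c(178.2, 0), c(250, 750), dt)
  call <- classify_pathway(ia, ib, window = 400, sim_tolerance = 0.8)
  expect_equal(call$class, "SIMULTANEOUS")
  expect_equal(call$rna_step_time, 100)

  # B loss at 50 s, A losses at 120 and 200 s -> SEQUENTIAL
  ia2 <- make_ideal(c(534.6, 356.4, 178.2), c(300, 200, 500), dt)
  ib2 <- make_ideal(c(178.2, 0), c(125, 875), dt)
  call2 <- classify_pathway(ia2, ib2, window = 400, unit = unit178)
  expect_equal(call2$class, "SEQUENTIAL")
  expect_equal(call2$vasa_step_times, c(120, 200))
  expect_equal(call2$vasa_residual_count, 1L)

  # constant B -> NO_DISSOCIATION, and rna_step_time is absent
  ib3 <- idealize_trace(sm_trace(rep(178.2, 1000), dt), max_states = 2)
  call3 <- classify_pathway(ia2, ib3, window = 400)
  expect_equal(call3$class, "NO_DISSOCIATION")
  expect_true(is.na(call3$rna_step_time))

  expect_error(classify_pathway(ia2, ib2, window = 1000), "window")
})

test_that("classification is invariant to channel-wide intensity scaling", {
  dt <- 0.4
  set.seed(9)
  cfg <- sim_config("TWO_COLOR", seed = 9)
  p <- simulate_two_color_pair(cfg, class = "SEQUENTIAL")
  cls <- function(scale_a) {
    tr <- p$trace_a
    tr$values <- tr$values * scale_a
    classify_pathway(idealize_trace(tr, max_states = 8),
                     idealize_trace(p$trace_b, max_states = 3),
                     window = 400)$class
  }
  expect_equal(cls(1), cls(5))
})

test_that("pathway fractions count, round and sum correctly", {
  mk <- function(cls) structure(list(class = cls, rna_step_time = NA,
                                     vasa_step_times = numeric(),
                                     vasa_residual_level = 0,
                                     vasa_residual_count = NA,
                                     pair_id = "x"),
                                class = "pathway_call")
  all_sim <- lapply(1:5, function(i) mk("SIMULTANEOUS"))
  f <- pathway_fractions(all_sim)
  expect_equal(unname(f$percents), c(100, 0, 0))
  one <- pathway_fractions(list(mk("SEQUENTIAL")))
  expect_equal(unname(one$percents["SEQUENTIAL"]), 100)
  mixed <- pathway_fractions(c(lapply(1:14, function(i) mk("SIMULTANEOUS")),
                               lapply(1:31, function(i) mk("SEQUENTIAL")),
                               lapply(1:27, function(i) mk("NO_DISSOCIATION"))))
  expect_equal(unname(mixed$counts), c(14, 31, 27))
  expect_equal(unname(mixed$percents), c(19, 43, 38))
  expect_equal(sum(mixed$fractions), 1)
  expect_lte(abs(sum(mixed$percents) - 100), 1)
  expect_error(pathway_fractions(list()), "insufficient")
})

test_that("partial-step fractions hit their degenerate limits", {
  singles <- data.frame(delta = rep(-178.2, 25), direction = "loss",
                        to_level = 178.2 * 2)
  f1 <- partial_step_fraction(list(singles), unit178)
  expect_equal(f1$fraction_single, 1)
  expect_equal(f1$n_events, 25)
  doubles <- data.frame(delta = rep(-356.4, 25), direction = "loss",
                        to_level = 178.2)
  expect_equal(partial_step_fraction(list(doubles),
                                     unit178)$fraction_single, 0)
  # complete losses (empty spot afterwards) are not partial
  completes <- data.frame(delta = rep(-356.4, 25), direction = "loss",
                          to_level = 0)
  expect_error(partial_step_fraction(list(completes), unit178),
               "insufficient")
})

test_that("the classifier confusion matrix is nearly diagonal", {
  cfg <- sim_config("TWO_COLOR", seed = 37, n_frames = 500)
  res <- simulate_two_color_pairs(cfg, 150, stratified = TRUE)
  pred <- vapply(res$pairs, function(p) {
    classify_pathway(idealize_trace(p$trace_a, max_states = 8),
                     idealize_trace(p$trace_b, max_states = 3),
                     window = 500 * 0.4)$class
  }, character(1))
  expect_lt(mean(pred != res$classes), 0.05)
})
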