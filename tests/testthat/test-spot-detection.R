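# Rendering, spot detection, trace extraction and ensemble intensity.

render_cfg <- function(seed = NULL, read_noise = 20, width = 128,
                       height = 128, background = 100, n_frames = 10) {
  sim_config("RNA_1MM_ATP", seed = seed, n_frames = n_frames,
             read_noise_sd = read_noise,
             image = list(width = width, height = height,
                          background = background))
}

test_that("a rendered spot carries its trace value in the ROI sum", {
  cfg <- render_cfg(read_noise = 0, width = 64, height = 64, background = 50)
  tr <- sm_trace(seq(1000, 100, length.out = 10), 0.4)
  stk <- render_stack(list(tr), data.frame(x = 30, y = 30), cfg)
  ext <- extract_trace(stk, list(x = 30, y = 30), 0.4)
  expect_lt(max(abs(ext$values - tr$values) / tr$values), 0.01)
})

test_that("an empty trace list renders background plus noise only", {
  cfg <- render_cfg(seed = 4, read_noise = 5, width = 32, height = 32,
                    n_frames = 4)
  stk <- render_stack(list(), data.frame(x = numeric(), y = numeric()), cfg)
  expect_equal(dim(stk), c(32, 32, 4))
  expect_lt(abs(mean(stk) - 100), 1)
  expect_lt(abs(sd(stk) - 5), 0.5)
})

test_that("the default field geometry spans 27.648 um", {
  cfg <- sim_config("RNA_1MM_ATP")
  expect_equal(cfg$image$width * cfg$image$pixel_size_nm / 1000, 27.648)
})

test_that("nearby spots trigger the ambiguity warning", {
  cfg <- render_cfg(read_noise = 0, width = 64, height = 64)
  trs <- list(sm_trace(rep(500, 10), 0.4), sm_trace(rep(500, 10), 0.4))
  expect_warning(render_stack(trs, data.frame(x = c(30, 33), y = c(30, 30)),
                              cfg), "ambiguous")
})

test_that("a blank frame yields no detections", {
  set.seed(6)
  frame <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  expect_equal(nrow(detect_spots(frame, tolerance = 100)), 0)
})

test_that("well-separated bright spots are all detected near their truth", {
  cfg <- render_cfg(seed = 9)
  pos <- expand.grid(x = c(20, 45, 70, 95, 115), y = c(30, 90))
  trs <- lapply(1:10, function(i) sm_trace(rep(2400, 10), 0.4))
  stk <- render_stack(trs, pos, cfg)
  # peak prominence ~ 3 x tolerance (2400 * peak fraction ~ 316 counts)
  sp <- detect_spots(stk[, , 1], tolerance = 105)
  expect_equal(nrow(sp), 10)
  d <- sapply(seq_len(nrow(sp)), function(i)
    min(sqrt((sp$x[i] - pos$x)^2 + (sp$y[i] - pos$y)^2)))
  expect_true(all(d <= 1))
  expect_lte(sqrt(mean(d^2)), 1)       # positional RMSE within one pixel
  # deterministic (y, x) ordering
  expect_true(!is.unsorted(order(sp$y, sp$x)))
})

test_that("detection recall stays high across noisy frames", {
  cfg <- render_cfg(seed = 14)
  pos <- expand.grid(x = seq(15, 115, by = 25), y = seq(20, 120, by = 25))
  trs <- lapply(seq_len(nrow(pos)), function(i) sm_trace(rep(2400, 10), 0.4))
  stk <- render_stack(trs, pos, cfg)
  hits <- 0
  for (f in 1:10) {
    sp <- detect_spots(stk[, , f], tolerance = 105)
    for (i in seq_len(nrow(pos))) {
      if (nrow(sp) &&
          min(sqrt((sp$x - pos$x[i])^2 + (sp$y - pos$y[i])^2)) <= 1)
        hits <- hits + 1
    }
  }
  expect_gte(hits / (10 * nrow(pos)), 0.95)
})

test_that("spots closer than the suppression radius merge", {
  cfg <- render_cfg(read_noise = 0, width = 64, height = 64)
  trs <- list(sm_trace(rep(2400, 10), 0.4), sm_trace(rep(2400, 10), 0.4))
  stk <- suppressWarnings(
    render_stack(trs, data.frame(x = c(30, 33), y = c(30, 30)), cfg))
  sp <- detect_spots(stk[, , 1], tolerance = 100)
  expect_equal(nrow(sp), 1)
})

test_that("detection rejects undersized images and bad tolerances", {
  expect_error(detect_spots(matrix(0, 8, 8), tolerance = 10), "smaller")
  expect_error(detect_spots(matrix(0, 64, 64), tolerance = -1), "positive")
  expect_error(extract_trace(array(0, c(32, 32, 2)), list(x = 2, y = 2), 0.4),
               "bounds")
})

test_that("a uniform image extracts an all-zero trace", {
  stk <- array(300, dim = c(32, 32, 5))
  ext <- extract_trace(stk, list(x = 16, y = 16), 0.4)
  expect_equal(ext$values, rep(0, 5))
})

test_that("extraction is invariant to a constant background offset", {
  cfg0 <- render_cfg(read_noise = 0, width = 64, height = 64, background = 0)
  cfg5 <- render_cfg(read_noise = 0, width = 64, height = 64,
                     background = 500)
  tr <- sm_trace(rep(800, 10), 0.4)
  e0 <- extract_trace(render_stack(list(tr), data.frame(x = 30, y = 30),
                                   cfg0), list(x = 30, y = 30), 0.4)
  e5 <- extract_trace(render_stack(list(tr), data.frame(x = 30, y = 30),
                                   cfg5), list(x = 30, y = 30), 0.4)
  expect_equal(e0$values, e5$values, tolerance = 1e-6)
})

test_that("ensemble intensity is flat for static spots and errors when empty", {
  trs <- lapply(1:20, function(i) sm_trace(rep(400, 30), 0.4))
  ser <- ensemble_intensity(trs)
  expect_equal(ser[1], 1)
  expect_true(all(abs(ser - 1) < 1e-12))
  # region containing nothing but flat background: zero after subtraction
  stk <- array(100, dim = c(64, 64, 3))
  expect_error(ensemble_intensity(stk), "normalize")
  expect_error(ensemble_intensity(array(1, c(4, 4, 2)),
                                  region = c(0, 0, 10, 10)), "region")
})

test_that("an ensemble of decaying traces recovers the decay constant", {
  cfg <- sim_config("RNA_1MM_ATP", seed = 77)
  field <- simulate_ensemble_field(cfg, 300)
  ser <- ensemble_intensity(field$traces)
  fit <- fit_ensemble_decay(ser, cfg$frame_interval)
  expect_lt(abs(fit$tau - 46.5) / 46.5, 0.10)
})
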