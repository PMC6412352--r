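test_that("disabling all stochastic terms leaves the pure track sinusoid", {
  cfg <- scenario_config(duration_s = 30, awake_correction_amp = 0,
                         awake_correction_rate = 4,
                         drowsy_correction_rate = 0.25,
                         drowsy_correction_amp = 0.1, noise_sd = 0,
                         kss_profile = data.frame(time = 0, kss = 1),
                         seed = 2)
  tr <- generate_trace(cfg)
  t <- tr$time
  expect_equal(tr$angle,
               cfg$track_curve_amp * sin(2 * pi * t / cfg$track_curve_period_s),
               tolerance = 1e-12)
})

test_that("the same seed regenerates a bit-identical trace", {
  cfg <- scenario_config(duration_s = 60, seed = 42)
  expect_identical(generate_trace(cfg), generate_trace(cfg))
  cfg2 <- scenario_config(duration_s = 60, seed = 43)
  expect_false(identical(generate_trace(cfg)$angle,
                         generate_trace(cfg2)$angle))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(3)
  set.seed(99)
  invisible(generate_trace(scenario_config(duration_s = 10, seed = 1)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("invalid scenario configs are rejected", {
  expect_error(scenario_config(duration_s = -5), "duration")
  expect_error(scenario_config(fs = 0), "fs")
  expect_error(scenario_config(duration_s = 1.007, fs = 60), "integer")
  expect_error(scenario_config(drowsy_correction_rate = 10,
                               awake_correction_rate = 4), "rate")
  expect_error(scenario_config(drowsy_correction_amp = 0.2,
                               awake_correction_amp = 0.5), "amp")
})

test_that("trace length, grid and KSS trace obey the config", {
  cfg <- scenario_config(duration_s = 45, fs = 60, seed = 8)
  tr <- generate_trace(cfg)
  expect_equal(nrow(tr), 45 * 60)
  expect_equal(diff(tr$time), rep(1 / 60, nrow(tr) - 1), tolerance = 1e-12)
  expect_true(all(tr$kss %in% 1:9))
  expect_true(all(diff(tr$kss) >= 0))
})

test_that("drowsy windows have lower zero-crossing rate than awake windows", {
  # planted effect by construction: sparse large corrections vs frequent
  # small ones; pooled over enough windows per regime
  half <- data.frame(time = c(0, 450), kss = c(3, 9))
  cfg <- scenario_config(duration_s = 900, awake_correction_rate = 10,
                         awake_correction_amp = 0.5,
                         drowsy_correction_rate = 0.5,
                         drowsy_correction_amp = 8,
                         kss_profile = half, seed = 31)
  fset <- extract_features(slide_windows(generate_trace(cfg), window_spec()),
                           fs = 60)
  expect_gt(sum(fset$y == 0), 100)
  expect_gt(sum(fset$y == 1), 100)
  zcr <- fset$x[, "I04a"]
  expect_lt(mean(zcr[fset$y == 1]), mean(zcr[fset$y == 0]))
})

test_that("feature bench plants separable informative columns", {
  b <- generate_feature_bench(2000, 36, 5, effect_size = 2, seed = 5)
  expect_equal(dim(b$x), c(2000, 36))
  expect_true(all(b$x >= 0 & b$x <= 1))
  expect_equal(sum(b$y == 0), sum(b$y == 1))
  fish <- apply(b$x, 2, fisher_index, y = b$y)
  expect_setequal(order(fish, decreasing = TRUE)[1:5], b$informative)

  # no planted effect -> all Fisher indexes near the null
  b0 <- generate_feature_bench(2000, 10, 5, effect_size = 0, seed = 5)
  fish0 <- apply(b0$x, 2, fisher_index, y = b0$y)
  expect_lt(max(fish0), 0.02)

  expect_error(generate_feature_bench(100, 10, 11, 1), "n_informative")
})

test_that("planted Fisher separation holds across seeds", {
  hits <- vapply(1:100, function(s) {
    b <- generate_feature_bench(1000, 20, 4, effect_size = 1, seed = s)
    fish <- apply(b$x, 2, fisher_index, y = b$y)
    min(fish[b$informative]) > max(fish[-b$informative])
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("trace CSV round-trips through the time,angle,velocity,kss dialect", {
  tr <- generate_trace(scenario_config(duration_s = 10, seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_identical(readLines(path, n = 1), "time,angle,velocity,kss")
  back <- read_trace_csv(path)
  expect_equal(back$angle, tr$angle, tolerance = 1e-8)
  expect_identical(back$kss, tr$kss)
  expect_equal(attr(back, "fs"), 60, tolerance = 1e-6)

  # a velocity-less file gets the channel by differencing
  df <- utils::read.csv(path)[, c("time", "angle", "kss")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE, quote = FALSE)
  back2 <- read_trace_csv(path2, fs = 60)
  expect_equal(back2$velocity[1:5], diff(back2$angle)[1:5] * 60,
               tolerance = 1e-9)
})
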