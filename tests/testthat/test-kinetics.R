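# ThT preprocessing and lag-phase extraction.

test_that("preprocessing subtracts the control, clips and normalises to 1", {
  tt <- seq(0, 24, by = 0.25)
  ctrl <- tht_curve(tt, rep(2, length(tt)), "c1", "control")
  raw <- tht_curve(tt, 2 + 5 / (1 + exp(-2 * (tt - 6))), "w1", "none")
  pp <- tht_preprocess(raw, ctrl)
  expect_equal(max(pp$signal), 1)
  expect_true(all(pp$signal >= 0))
  expect_true(attr(pp, "normalized"))
  # raw equal to control leaves nothing: an error, not a zero curve
  expect_error(tht_preprocess(ctrl, ctrl), "no signal")
})

test_that("control grids are interpolated when they differ", {
  tt <- seq(0, 24, by = 0.25)
  tc <- seq(0, 24, by = 0.5) + 0.1
  ctrl <- tht_curve(tc, rep(1, length(tc)), "c", "control")
  raw <- tht_curve(tt, 1 + 4 / (1 + exp(-2 * (tt - 6))), "w", "none")
  pp <- tht_preprocess(raw, ctrl)
  expect_equal(max(pp$signal), 1)
  expect_lt(pp$signal[1], 0.05)
})

test_that("triplicate averaging matches the generator expectation", {
  gp <- tht_gen_params(lag_h = 5, rate = 2, plateau = 1)
  reps <- lapply(1:3, function(i) {
    gen_tht_curve(gp, 24, noise_spec("additive-gaussian", 0.02, seed = i),
      replicate_id = paste0("w", i), condition = "none"
    )
  })
  avg <- average_replicates(reps)
  clean <- gen_tht_curve(gp, 24)
  # mean of three 2% replicates stays inside a tight envelope of the truth
  expect_lt(max(abs(avg$signal - clean$signal)), 4 * 0.02 / sqrt(3))
})

test_that("lag time round-trips the generator within one sampling interval", {
  gp <- tht_gen_params(lag_h = 5, rate = 2, plateau = 1)
  ks <- lag_time(gen_tht_curve(gp, 24))
  expect_equal(ks$lag_h, 5, tolerance = 0.25 / 5)
  expect_true(ks$transition)
  expect_lte(ks$lag_h, ks$t50_h)
  # logistic midpoint: t50 = lag + 2/rate
  expect_equal(ks$t50_h, 5 + 2 / 2, tolerance = 0.25)
})

test_that("extracted lags preserve the order of generated lags", {
  lags <- c(5, 8, 12)
  est <- vapply(lags, function(lg) {
    lag_time(gen_tht_curve(
      tht_gen_params(lag_h = lg, rate = 2, plateau = 1), 30
    ))$lag_h
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_equal(est, lags, tolerance = 0.25 / 5)
})

test_that("a step curve gives the step time and the steepest finite slope", {
  tt <- seq(0, 12, by = 0.25)
  ks <- lag_time(tht_curve(tt, as.numeric(tt >= 6)))
  expect_lte(abs(ks$lag_h - 6), 0.25)
  expect_gt(ks$max_slope, 1) # steeper than any smooth 5-point window
})

test_that("lag extraction is shift-equivariant and scale-invariant", {
  gp <- tht_gen_params(lag_h = 4, rate = 1.5, plateau = 1)
  cv <- gen_tht_curve(gp, 20)
  ks <- lag_time(cv)
  shifted <- tht_curve(cv$time_h + 2.5, cv$signal)
  ks_s <- lag_time(shifted)
  expect_equal(ks_s$lag_h - ks$lag_h, 2.5)
  expect_equal(ks_s$t50_h - ks$t50_h, 2.5)
  # positive rescaling before normalisation leaves the lag unchanged
  ctrl <- tht_curve(cv$time_h, rep(0, nrow(cv)), "c", "control")
  for (scale in c(0.2, 7)) {
    scaled <- tht_curve(cv$time_h, cv$signal * scale)
    expect_equal(lag_time(tht_preprocess(scaled, ctrl))$lag_h, ks$lag_h,
      tolerance = 1e-9
    )
  }
})

test_that("mean extracted lag over noisy replicates stays near the truth", {
  gp <- tht_gen_params(lag_h = 5, rate = 2, plateau = 1)
  lags <- vapply(1:100, function(s) {
    lag_time(gen_tht_curve(
      gp, 24, noise_spec("multiplicative-gaussian", 0.02, seed = s)
    ))$lag_h
  }, numeric(1))
  expect_lt(abs(mean(lags) - 5), 0.3)
})

test_that("curves that never transition are reported, not errored", {
  tt <- seq(0, 24, by = 0.25)
  flatish <- tht_curve(tt, 0.02 + 0.01 * sin(tt))
  ks <- lag_time(flatish)
  expect_false(ks$transition)
  expect_true(is.na(ks$lag_h))
})

test_that("kinetics CSV IO round-trips wells and conditions", {
  gp <- tht_gen_params(lag_h = 5, rate = 2, plateau = 5, baseline = 0.5)
  curves <- list(
    a1 = gen_tht_curve(gp, 24, replicate_id = "a1", condition = "none"),
    c1 = tht_curve(seq(0, 24, 0.25), rep(0.5, 97), "c1", "control")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_tht_csv(curves, path)
  back <- read_tht_csv(path)
  expect_setequal(names(back), c("a1", "c1"))
  expect_equal(back$a1$signal, curves$a1$signal)
  expect_identical(attr(back$c1, "condition"), "control")
})
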