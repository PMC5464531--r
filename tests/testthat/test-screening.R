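test_that("basal draws respect range, mean, and determinism", {
  std <- goodwin_standard_params()

  degenerate <- screening_protocol(n_basal = 5, n_speedup = 1,
                                   basal_range = c(1, 1), seed = 3)
  for (p in draw_basal_sets(std, degenerate)) expect_equal(p, std)

  proto <- screening_protocol(n_basal = 400, n_speedup = 1, seed = 11)
  sets <- draw_basal_sets(std, proto)
  mat <- t(vapply(sets, function(p) p$rates / std$rates,
                  numeric(length(std$rates))))
  expect_true(all(mat >= 0.5 & mat <= 2))
  # mean of Uniform(0.5, 2) is 1.25; MC error ~ 0.43/sqrt(400) per rate
  expect_equal(unname(colMeans(mat)), rep(1.25, 6), tolerance = 0.07)
  # structural constants untouched
  for (p in sets) expect_equal(p$structural, std$structural)

  expect_identical(draw_basal_sets(std, proto), sets)
})

test_that("speed-up factors are per-rate uniform with ~2-fold grand mean", {
  proto <- screening_protocol(n_basal = 20, n_speedup = 100, seed = 5)
  f <- draw_speedup_factors(proto, 6)
  expect_equal(dim(f), c(2000, 6))
  expect_true(all(f >= 1.5 & f <= 2.5))
  expect_equal(mean(f), 2, tolerance = 0.02)
  expect_identical(draw_speedup_factors(proto, 6), f)
  proto2 <- screening_protocol(n_basal = 20, n_speedup = 100, seed = 6)
  expect_false(identical(draw_speedup_factors(proto2, 6), f))

  fixed <- screening_protocol(n_basal = 2, n_speedup = 2,
                              speedup_range = c(2, 2), seed = 1)
  expect_true(all(draw_speedup_factors(fixed, 6) == 2))
})

test_that("geometric mean relative amplitude", {
  expect_equal(geometric_mean_relative_amplitude(c(1, 1, 1)), 1)
  expect_equal(geometric_mean_relative_amplitude(c(2, 0.5, 1)), 1)
  expect_equal(geometric_mean_relative_amplitude(c(2, 4, 8)), 4)
  expect_error(geometric_mean_relative_amplitude(c(1, 0)), "positive")
  expect_error(geometric_mean_relative_amplitude(c(1, -2)), "positive")
})

test_that("identity protocol yields relative period 1 and gma 1", {
  proto <- screening_protocol(n_basal = 3, n_speedup = 2,
                              basal_range = c(1, 1),
                              speedup_range = c(1, 1), seed = 8)
  scr <- run_screen(goodwin, goodwin_standard_params(), proto)
  expect_true(all(scr$records$scaled_sustained))
  expect_equal(scr$records$relative_period, rep(1, 6), tolerance = 1e-6)
  expect_equal(scr$records$gma, rep(1, 6), tolerance = 1e-6)
  expect_equal(scr$census$n_scaled_oscillating, 6)
})

test_that("uniform common speed-up gives relative period 1/c and gma 1", {
  # simulate the scaled system with time step dt/c over horizon t_end/c:
  # RK4 increments are then algebraically identical to the basal run, so
  # the rescaling law can be checked to near machine precision without
  # integrator error entering
  p <- twovar_params("low")
  cc <- 2
  base <- simulate_model(twovar, p, t_end = 1200, dt = 0.01)
  fast <- simulate_model(twovar, scale_rates(p, cc), t_end = 1200 / cc,
                         dt = 0.01 / cc)
  expect_equal(max(abs(base$states - fast$states)), 0, tolerance = 1e-9)
  mb <- measure_period_amplitude(base)
  mf <- measure_period_amplitude(fast)
  expect_equal(mf$period / mb$period, 1 / cc, tolerance = 1e-9)
  expect_equal(geometric_mean_relative_amplitude(mf$amplitude /
                                                   mb$amplitude),
               1, tolerance = 1e-12)
})

test_that("screen census and records are reproducible and self-consistent", {
  proto <- screening_protocol(n_basal = 4, n_speedup = 3, seed = 21)
  scr1 <- run_screen(goodwin, goodwin_standard_params(), proto)
  scr2 <- run_screen(goodwin, goodwin_standard_params(), proto)
  expect_identical(scr1$records, scr2$records)
  expect_equal(nrow(scr1$records), 12)
  expect_equal(scr1$census$n_scaled_oscillating,
               sum(scr1$records$scaled_sustained))
  ok <- !is.na(scr1$records$gma)
  expect_true(all(scr1$records$relative_period[ok] > 0))
  # speeding rates 1.5-2.5x shortens the period
  expect_true(all(scr1$records$relative_period[ok] < 1))
})

test_that("screen summary flags constructed counterexamples", {
  records <- data.frame(
    relative_period = c(0.99, 0.97, 0.6, 0.5, 0.96),
    gma = c(1.2, 1.1, 0.8, 0.9, 0.95))
  s <- summarize_screen(records, period_threshold = 0.95, n_bins = 2)
  expect_equal(s$n_maintained, 3)
  expect_equal(s$headline_fraction, 2 / 3)
  expect_equal(s$min_gma_maintained, 0.95)

  none <- summarize_screen(records, period_threshold = 1.5)
  expect_equal(none$headline_fraction, 1)  # vacuous by convention
})

test_that("screen fixtures behave as labelled", {
  fx <- generate_screen_fixture(twovar, n = 2, seed = 9)
  for (f in fx) {
    traj <- simulate_model(twovar, f$scaled, t_end = 1200)
    expect_identical(detect_sustained_oscillation(traj),
                     f$expect_sustained,
                     info = f$category)
    if (f$category == "common_factor") {
      mb <- measure_period_amplitude(
        simulate_model(twovar, f$basal, t_end = 1200))
      ms <- measure_period_amplitude(traj)
      expect_equal(ms$period / mb$period, f$expected_relative_period,
                   tolerance = 1e-3)
    }
  }
})
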