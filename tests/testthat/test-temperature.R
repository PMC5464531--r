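test_that("Arrhenius anchoring and limits are exact", {
  arr <- arrhenius_model(rates_ref = c(a = 2, b = 0.5),
                         energies = c(a = 500, b = 0), T_ref = 298,
                         R = 0.082)
  expect_identical(rates_at_temperature(arr, 298), arr$rates_ref)
  # zero activation energy: temperature-independent
  expect_equal(rates_at_temperature(arr, 350)[["b"]], 0.5)
  # positive energy: strictly increasing in T
  Ts <- seq(280, 320, by = 5)
  va <- vapply(Ts, function(T) rates_at_temperature(arr, T)[["a"]], 0)
  expect_true(all(diff(va) > 0))
  expect_error(rates_at_temperature(arr, -1), "positive")
})

test_that("fitted scale maps the 298 K rates onto the printed 308 K rates
           within 2% per rate", {
  arr <- twovar_arrhenius()
  expect_equal(arr$R, 0.082, tolerance = 0.02)
  predicted <- rates_at_temperature(arr, 308)
  printed <- twovar_params("high")$rates
  for (nm in names(printed))
    expect_equal(predicted[[nm]], printed[[nm]], tolerance = 0.02)
})

test_that("q10 conventions and composition", {
  expect_equal(q10(5, 25, 5, 35, "rate"), 1)
  expect_equal(q10(1, 20, 2, 30, "rate"), 2)
  # longer period at higher temperature -> overcompensation, Q10 < 1
  expect_equal(q10(20, 25, 22, 35, "period"), 20 / 22)
  expect_error(q10(0, 25, 1, 35), "positive")
  expect_error(q10(1, 35, 1, 25), "exceed")

  # composition across a midpoint temperature (geometric, span-weighted)
  q13 <- q10(1.0, 290, 3.1, 310, "rate")
  q12 <- q10(1.0, 290, 1.7, 300, "rate")
  q23 <- q10(1.7, 300, 3.1, 310, "rate")
  expect_equal(q13, (q12^10 * q23^10)^(1 / 20))
})

test_that("equal activation energies reduce the sweep to the exact
           common-scaling closed form", {
  base <- twovar_params("low")
  arr <- arrhenius_model(base$rates,
                         setNames(rep(400, 5), names(base$rates)),
                         T_ref = 298, R = 0.082)
  tab <- temperature_sweep(twovar, base, arr, T_grid = c(298, 304))
  expect_true(all(tab$sustained))
  ratio <- exp(400 / 0.082 * (1 / 298 - 1 / 304))  # common rate factor
  expect_equal(tab$period[2], tab$period[1] / ratio, tolerance = 1e-3)
  # amplitudes are invariant under common scaling
  expect_equal(tab$amplitude_Y[2], tab$amplitude_Y[1], tolerance = 1e-3)

  # 20% inhibition of transcription rates folds straight into the closed
  # form: the orbit changes but the Arrhenius ratio still applies exactly
  tab2 <- inhibition_sweep(twovar, base, arr,
                           inhibited_rates = c("k", "v"), inhibition = 0.2,
                           T_grid = c(298, 304))
  expect_true(all(tab2$sustained))
  expect_equal(tab2$period[2], tab2$period[1] / ratio, tolerance = 1e-3)
})

test_that("printed two-variable Arrhenius model is temperature compensated
           and amplitude-coupled across 298-308 K", {
  arr <- twovar_arrhenius()
  tab <- temperature_sweep(twovar, twovar_params("low"), arr,
                           T_grid = c(298, 308))
  expect_true(all(tab$sustained))
  q <- q10(tab$period[1], 298, tab$period[2], 308, "period")
  expect_gt(q, 0.85); expect_lt(q, 1.15)
  expect_gt(tab$amplitude_Y[2], tab$amplitude_Y[1])
})

test_that("period-maintained energies give a flatter period profile than
           period-shortening energies over 20-30 C", {
  Ts <- 273.15 + c(20, 25, 30)
  flat <- temperature_sweep(goodwin, goodwin_standard_params(),
                            goodwin_arrhenius("maintained"), Ts)
  steep <- temperature_sweep(goodwin, goodwin_standard_params(),
                             goodwin_arrhenius("shortening"), Ts)
  expect_true(all(flat$sustained), all(steep$sustained))
  spread <- function(tab) diff(range(tab$period)) / max(tab$period)
  expect_lt(spread(flat), spread(steep))
})

test_that("20% transcription inhibition preserves oscillation across the
           printed temperature range", {
  tab <- inhibition_sweep(twovar, twovar_params("low"), twovar_arrhenius(),
                          inhibited_rates = c("k", "v"), inhibition = 0.2,
                          T_grid = c(298, 303, 308))
  expect_true(all(tab$sustained))
  # zero inhibition degenerates to the plain sweep
  arr <- twovar_arrhenius()
  expect_equal(
    inhibition_sweep(twovar, twovar_params("low"), arr, "k", 0, 303),
    temperature_sweep(twovar, twovar_params("low"), arr, 303))
  expect_error(
    inhibition_sweep(twovar, twovar_params("low"), twovar_arrhenius(),
                     inhibited_rates = "nope", inhibition = 0.2,
                     T_grid = 298), "unknown rate")
  expect_error(
    inhibition_sweep(twovar, twovar_params("low"), twovar_arrhenius(),
                     inhibited_rates = "k", inhibition = 1.2,
                     T_grid = 298), "inhibition")
})
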