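#' Arrhenius temperature model for rate constants
#'
#' Each rate follows `k_i(T) = A_i exp(-E_i/(R T))`. The prefactors `A_i`
#' are not supplied directly: they are anchored so that `k_i(T_ref)` equals
#' the reference rate exactly, i.e. `k_i(T) = k_i(T_ref) exp((E_i/R)(1/T_ref
#' - 1/T))`. Only the ratio `E_i/R` is identifiable from rate pairs, so the
#' gas-constant-like scale `R` is an explicit field (see
#' [fit_arrhenius_scale()]).
#'
#' @param rates_ref Named vector of reference rates (at `T_ref`).
#' @param energies Named vector of activation energies `E_i >= 0`, same
#'   names as `rates_ref`, in units consistent with `R`.
#' @param T_ref Reference temperature in kelvin.
#' @param R Gas-constant-like scale matching the energy units.
#' @return An object of class `arrhenius_model`.
#' @export
arrhenius_model <- function(rates_ref, energies, T_ref, R) {
  rates_ref <- unlist(rates_ref); energies <- unlist(energies)
  if (is.null(names(rates_ref)) || is.null(names(energies)))
    stop("rates_ref and energies must be named")
  if (!setequal(names(rates_ref), names(energies)))
    stop("rates_ref and energies must name the same rates")
  energies <- energies[names(rates_ref)]
  if (any(energies < 0)) stop("activation energies must be non-negative")
  if (T_ref <= 0 || R <= 0) stop("T_ref and R must be positive")
  structure(list(rates_ref = rates_ref, energies = energies,
                 T_ref = T_ref, R = R),
            class = "arrhenius_model")
}

#' @export
print.arrhenius_model <- function(x, ...) {
  cat("<arrhenius_model> T_ref =", x$T_ref, "K, R =", signif(x$R, 4), "\n")
  cat("  E_i:", paste0(names(x$energies), "=", x$energies, collapse = ", "),
      "\n")
  invisible(x)
}

#' Evaluate Arrhenius-scaled rates at a temperature
#'
#' @param arr An [arrhenius_model()].
#' @param T_K Absolute temperature (kelvin), `> 0`.
#' @return Named vector of rates; at `T_K = T_ref` this reproduces the
#'   reference rates exactly.
#' @export
rates_at_temperature <- function(arr, T_K) {
  stopifnot(inherits(arr, "arrhenius_model"))
  if (T_K <= 0) stop("temperature must be positive (kelvin)")
  arr$rates_ref * exp(arr$energies / arr$R * (1 / arr$T_ref - 1 / T_K))
}

#' Fit the gas-constant-like scale from two printed rate sets
#'
#' Given rates at two temperatures and the activation energies, each rate
#' pair satisfies `log(k_hi/k_lo) = (E_i/R)(1/T_low - 1/T_high)`. A single
#' `R` is estimated by least squares through the origin over all pairs.
#'
#' @param rates_low,rates_high Named rate vectors at `T_low`, `T_high`.
#' @param energies Named activation energies.
#' @param T_low,T_high Temperatures in kelvin, `T_high > T_low`.
#' @return The fitted scalar `R`.
#' @export
fit_arrhenius_scale <- function(rates_low, rates_high, energies,
                                T_low, T_high) {
  nm <- names(unlist(rates_low))
  y <- log(unlist(rates_high)[nm] / unlist(rates_low)[nm])
  x <- unlist(energies)[nm] * (1 / T_low - 1 / T_high)
  1 / (sum(x * y) / sum(x * x))
}

#' Arrhenius model for the two-variable clock
#'
#' Anchors the printed activation energies (335, 1057, 893, 480, 322 for
#' `k, v, a, s, d`) at the 298 K rate set, with the scale `R` fitted at call
#' time from the two printed rate sets via [fit_arrhenius_scale()].
#'
#' @return An `arrhenius_model` with `T_ref = 298` K.
#' @export
twovar_arrhenius <- function() {
  low <- twovar_params("low")$rates
  high <- twovar_params("high")$rates
  energies <- c(k = 335, v = 1057, a = 893, s = 480, d = 322)
  R <- fit_arrhenius_scale(low, high, energies, 298, 308)
  arrhenius_model(low, energies, T_ref = 298, R = R)
}

#' Arrhenius models for the Goodwin clock
#'
#' Two printed activation-energy vectors for the Goodwin rates
#' `vs, vm, ks, vd, k1, k2`, anchored at the standard parameter set at
#' 293 K (20 C): `"maintained"` (637, 328, 327, 663, 311, 601) keeps the
#' period nearly flat across 20-30 C, `"shortening"` (570, 594, 597, 615,
#' 354, 303) does not. Energies share the units of the two-variable model's
#' vectors, so the scale `R` defaults to the one fitted by
#' [twovar_arrhenius()].
#'
#' @param case `"maintained"` or `"shortening"`.
#' @param R Gas-constant-like scale; default: fitted from the two-variable
#'   model's printed rate pairs.
#' @return An `arrhenius_model` with `T_ref = 293` K.
#' @export
goodwin_arrhenius <- function(case = c("maintained", "shortening"),
                              R = NULL) {
  case <- match.arg(case)
  energies <- switch(case,
    maintained = c(vs = 637, vm = 328, ks = 327, vd = 663, k1 = 311,
                   k2 = 601),
    shortening = c(vs = 570, vm = 594, ks = 597, vd = 615, k1 = 354,
                   k2 = 303))
  if (is.null(R)) R <- twovar_arrhenius()$R
  arrhenius_model(goodwin_standard_params()$rates, energies,
                  T_ref = 293, R = R)
}

#' Temperature coefficient Q10
#'
#' Fold change of a quantity per 10 degree temperature rise. For rate-like
#' quantities (amplitudes, reaction speeds) `Q10 =
#' (value_high/value_low)^(10/(T_high - T_low))`. For periods the frequency
#' (reciprocal) convention is used, so a *longer* period at higher
#' temperature gives `Q10 < 1` (temperature overcompensation) and the
#' compensated range is `0.85 < Q10 < 1.15`.
#'
#' @param value_low,value_high Positive measurements at the two
#'   temperatures.
#' @param T_low,T_high Temperatures (any consistent scale), `T_high > T_low`.
#' @param convention `"rate"` or `"period"`.
#' @return The Q10 value.
#' @export
q10 <- function(value_low, T_low, value_high, T_high,
                convention = c("rate", "period")) {
  convention <- match.arg(convention)
  if (value_low <= 0 || value_high <= 0) stop("values must be positive")
  if (T_high <= T_low) stop("T_high must exceed T_low")
  ratio <- switch(convention, rate = value_high / value_low,
                  period = value_low / value_high)
  ratio^(10 / (T_high - T_low))
}

sweep_one <- function(model, params, rates, init, t_end, dt, ...) {
  p <- params
  p$rates[names(rates)] <- rates
  traj <- simulate_model(model, p, init = init, t_end = t_end, dt = dt)
  trajectory_metrics(traj, ...)
}

#' Period and amplitude across a temperature grid
#'
#' Simulates the model at each temperature with Arrhenius-scaled rates and
#' extracts period and per-variable amplitude. Grid points where the model
#' does not oscillate are flagged by `sustained = FALSE`, never dropped.
#'
#' @param model A `clock_model`.
#' @param base_params A `param_set` supplying the structural constants (its
#'   rates are overwritten by the Arrhenius model).
#' @param arr An [arrhenius_model()] covering the model's rates.
#' @param T_grid Temperatures in kelvin.
#' @param t_end,dt Integration control; `t_end = NULL` chooses about 40
#'   cycles of the reference-temperature period.
#' @param init Initial state.
#' @param ... Passed to the oscillation detector
#'   (see [detect_sustained_oscillation()]).
#' @return A data frame with one row per temperature: `T_K`, `sustained`,
#'   `period`, and one `amplitude_<var>` column per state variable.
#' @export
temperature_sweep <- function(model, base_params, arr, T_grid, t_end = NULL,
                              dt = 0.01, init = NULL, ...) {
  stopifnot(inherits(arr, "arrhenius_model"))
  bad <- setdiff(names(arr$rates_ref), model$rate_names)
  if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
  if (is.null(t_end)) {
    m0 <- sweep_one(model, base_params, rates_at_temperature(arr, arr$T_ref),
                    init, 2000, dt, ...)
    t_end <- if (m0$sustained) 40 * m0$period else 2000
  }
  rows <- lapply(T_grid, function(Tk) {
    m <- sweep_one(model, base_params, rates_at_temperature(arr, Tk),
                   init, t_end, dt, ...)
    amp <- as.list(m$amplitude)
    names(amp) <- paste0("amplitude_", names(m$amplitude))
    c(list(T_K = Tk, sustained = m$sustained, period = m$period), amp)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Temperature sweep under partial inhibition of selected reactions
#'
#' Identical to [temperature_sweep()] except that the designated rates are
#' multiplied by `(1 - inhibition)` at every temperature, emulating partial
#' inhibition of e.g. transcription (`k`, `v` in the two-variable model) or
#' translation (`s`).
#'
#' @inheritParams temperature_sweep
#' @param inhibited_rates Character vector of rate names to inhibit.
#' @param inhibition Fraction in `[0, 1)`.
#' @return As [temperature_sweep()].
#' @export
inhibition_sweep <- function(model, base_params, arr, inhibited_rates,
                             inhibition, T_grid, ...) {
  if (inhibition < 0 || inhibition >= 1)
    stop("inhibition must be in [0, 1)")
  bad <- setdiff(inhibited_rates, names(arr$rates_ref))
  if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
  arr2 <- arr
  arr2$rates_ref[inhibited_rates] <-
    arr2$rates_ref[inhibited_rates] * (1 - inhibition)
  temperature_sweep(model, base_params, arr2, T_grid, ...)
}
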