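#' Rate/structural parameter sets for clock models
#'
#' A parameter set separates *rate constants*, which are assumed to increase
#' with temperature, from *structural constants* (Michaelis constants, Hill
#' coefficients, the time-scale separation `eps`), which are held fixed.
#' Temperature scaling and the random-parameterization screen only ever touch
#' the rates.
#'
#' @param model Model name, `"goodwin"` or `"twovar"` (or the name of a model
#'   registered via [define_clock_model()]).
#' @param rates Named numeric vector of positive rate constants.
#' @param structural Named numeric vector of positive structural constants.
#' @return An object of class `param_set`.
#' @seealso [goodwin_standard_params()], [twovar_params()], [scale_rates()]
#' @export
param_set <- function(model, rates, structural) {
  rates <- unlist(rates)
  structural <- unlist(structural)
  if (is.null(names(rates)) || is.null(names(structural)))
    stop("rates and structural must be named")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be positive and finite")
  if (any(!is.finite(structural)) || any(structural <= 0))
    stop("all structural constants must be positive and finite")
  structure(list(model = model, rates = rates, structural = structural),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>", x$model, "\n")
  cat("  rates:     ", paste0(names(x$rates), "=", signif(x$rates, 4),
                              collapse = ", "), "\n")
  cat("  structural:", paste0(names(x$structural), "=",
                              signif(x$structural, 4), collapse = ", "), "\n")
  invisible(x)
}

#' The Goodwin standard parameter set
#'
#' The oscillating reference parameterization of the three-variable Goodwin
#' negative-feedback model: mRNA `M`, cytosolic protein `R`, nuclear repressor
#' `P`. Rates `vs, vm, ks, vd, k1, k2` are temperature-sensitive; the
#' Michaelis constants `KI, KM, KD` and Hill coefficient `n` are structural.
#'
#' @return A `param_set` for the `"goodwin"` model.
#' @export
goodwin_standard_params <- function() {
  param_set("goodwin",
            rates = c(vs = 1.6, vm = 0.505, ks = 0.5, vd = 1.4,
                      k1 = 0.5, k2 = 0.6),
            structural = c(KI = 1, KM = 0.5, KD = 0.13, n = 2))
}

#' Printed parameter sets of the two-variable clock model
#'
#' The two-variable positive-plus-negative feedback model (mRNA `X`,
#' inhibitor protein `Y`) has two reference parameterizations corresponding
#' to a lower (298 K) and a higher (308 K) temperature; the higher set has
#' uniformly faster rates. Structural constants `h, Kv, Ks, alpha, gamma,
#' eps` are shared.
#'
#' @param which `"low"` (298 K) or `"high"` (308 K).
#' @return A `param_set` for the `"twovar"` model.
#' @export
twovar_params <- function(which = c("low", "high")) {
  which <- match.arg(which)
  rates <- switch(which,
    low  = c(k = 0.0625, v = 0.529, a = 0.0923, s = 1.48, d = 0.0507),
    high = c(k = 0.0976, v = 2.15,  a = 0.302,  s = 2.80, d = 0.0778))
  param_set("twovar", rates = rates,
            structural = c(h = 0.5, Kv = 0.5, Ks = 0.5,
                           alpha = 4, gamma = 4, eps = 0.02))
}

#' Define a clock model
#'
#' A clock model bundles the state-variable names, the partition of
#' parameters into temperature-sensitive rates and fixed structural
#' constants, and the right-hand side of the ODE system.
#'
#' @param name Model identifier.
#' @param state_names Character vector of state-variable names.
#' @param rate_names,structural_names The parameter partition.
#' @param rhs Function `(state, params) -> derivatives` returning a numeric
#'   vector of the same length as `state_names`.
#' @return An object of class `clock_model`.
#' @export
define_clock_model <- function(name, state_names, rate_names,
                               structural_names, rhs) {
  stopifnot(is.character(state_names), is.function(rhs))
  structure(list(name = name, state_names = state_names,
                 rate_names = rate_names,
                 structural_names = structural_names, rhs = rhs),
            class = "clock_model")
}

#' Built-in clock models
#'
#' @description
#' `clock_model("goodwin")` is the classical three-variable negative-feedback
#' oscillator: clock mRNA `M` is translated into a cytosolic protein `R`
#' whose nuclear form `P` represses transcription with cooperativity `n`;
#' `M` and `R` are degraded by saturable (Michaelis-Menten) reactions and
#' `P` linearly:
#' \deqn{dM/dt = v_s K_I^n/(K_I^n + P^n) - v_m M/(K_M + M)}
#' \deqn{dR/dt = k_s M - v_d R/(K_D + R)}
#' \deqn{dP/dt = k_1 R - k_2 P}
#'
#' `clock_model("twovar")` is the reduced positive-plus-negative feedback
#' model: mRNA `X` activates its own transcription (Hill coefficient
#' `gamma`) and is repressed by the inhibitor protein `Y`; `eps` sets the
#' time-scale separation between fast mRNA and slow protein:
#' \deqn{\epsilon\, dX/dt = (k + v X^\gamma/(K_v^\gamma + X^\gamma))/(h + Y) - a X}
#' \deqn{dY/dt = s X^\alpha/(K_s^\alpha + X^\alpha) - d Y}
#'
#' @param name `"goodwin"` or `"twovar"`.
#' @return A `clock_model` object.
#' @export
clock_model <- function(name = c("goodwin", "twovar")) {
  name <- match.arg(name)
  switch(name,
    goodwin = define_clock_model(
      "goodwin", state_names = c("M", "R", "P"),
      rate_names = c("vs", "vm", "ks", "vd", "k1", "k2"),
      structural_names = c("KI", "KM", "KD", "n"),
      rhs = goodwin_rhs),
    twovar = define_clock_model(
      "twovar", state_names = c("X", "Y"),
      rate_names = c("k", "v", "a", "s", "d"),
      structural_names = c("h", "Kv", "Ks", "alpha", "gamma", "eps"),
      rhs = twovar_rhs))
}

check_state <- function(state, n) {
  if (length(state) != n || any(!is.finite(state)))
    stop("state must be a finite numeric vector of length ", n)
  if (any(state < 0)) stop("state components must be non-negative")
}

#' Right-hand side of the Goodwin model
#'
#' @param state Numeric vector `(M, R, P)`, all non-negative.
#' @param params A `param_set` for the `"goodwin"` model.
#' @return Named derivative vector `(dM, dR, dP)`. Multiplying every rate by
#'   a common constant `c` multiplies every derivative by exactly `c`.
#' @export
goodwin_rhs <- function(state, params) {
  check_state(state, 3)
  r <- params$rates; s <- params$structural
  M <- state[[1]]; R <- state[[2]]; P <- state[[3]]
  KIn <- s[["KI"]]^s[["n"]]
  c(M = r[["vs"]] * KIn / (KIn + P^s[["n"]]) -
        r[["vm"]] * M / (s[["KM"]] + M),
    R = r[["ks"]] * M - r[["vd"]] * R / (s[["KD"]] + R),
    P = r[["k1"]] * R - r[["k2"]] * P)
}

#' Right-hand side of the two-variable model
#'
#' @param state Numeric vector `(X, Y)`, non-negative.
#' @param params A `param_set` for the `"twovar"` model.
#' @return Named derivative vector `(dX, dY)`.
#' @export
twovar_rhs <- function(state, params) {
  check_state(state, 2)
  r <- params$rates; s <- params$structural
  if (s[["eps"]] <= 0) stop("eps must be positive")
  X <- state[[1]]; Y <- state[[2]]
  Xg <- X^s[["gamma"]]; Kvg <- s[["Kv"]]^s[["gamma"]]
  Xa <- X^s[["alpha"]]; Ksa <- s[["Ks"]]^s[["alpha"]]
  c(X = ((r[["k"]] + r[["v"]] * Xg / (Kvg + Xg)) / (s[["h"]] + Y) -
           r[["a"]] * X) / s[["eps"]],
    Y = r[["s"]] * Xa / (Ksa + Xa) - r[["d"]] * Y)
}

#' Scale the rate constants of a parameter set
#'
#' Multiplies selected rates by positive factors, leaving structural
#' constants untouched. Asking to scale a structural constant is an error:
#' the model's temperature assumption is that only rates respond.
#'
#' @param params A `param_set`.
#' @param factors A single positive number (applied to every rate) or a
#'   named vector of positive factors for a subset of the rates.
#' @return A new `param_set`.
#' @export
scale_rates <- function(params, factors) {
  stopifnot(inherits(params, "param_set"))
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("scaling factors must be positive")
  if (length(factors) == 1L && is.null(names(factors))) {
    params$rates <- params$rates * as.numeric(factors)
    return(params)
  }
  bad <- setdiff(names(factors), names(params$rates))
  if (length(bad)) {
    if (any(bad %in% names(params$structural)))
      stop("structural constants are fixed and cannot be scaled: ",
           paste(intersect(bad, names(params$structural)), collapse = ", "))
    stop("unknown rate name(s): ", paste(bad, collapse = ", "))
  }
  params$rates[names(factors)] <- params$rates[names(factors)] * factors
  params
}
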