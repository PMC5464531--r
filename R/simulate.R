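#' Simulate a clock model with fixed-step RK4
#'
#' Integrates the model ODEs with the classical fourth-order Runge-Kutta
#' method on a uniform grid. The two built-in models run through compiled
#' kernels; any other [define_clock_model()] model is integrated with
#' [deSolve::rk4()].
#'
#' @param model A `clock_model`.
#' @param params A `param_set` matching the model.
#' @param init Initial state (non-negative); default `0.1` for every
#'   variable.
#' @param t_end Final time (model time units; hours for calibrated runs).
#' @param dt Step size; the default `0.01` is the convention used throughout
#'   the package.
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (matrix, one column per state variable), `params`, `dt`, `model`.
#' @export
simulate_model <- function(model, params, init = NULL, t_end = 600,
                           dt = 0.01) {
  stopifnot(inherits(model, "clock_model"), inherits(params, "param_set"))
  if (params$model != model$name)
    stop("parameter set is for model '", params$model, "', not '",
         model$name, "'")
  if (t_end <= 0 || dt <= 0) stop("t_end and dt must be positive")
  nv <- length(model$state_names)
  if (is.null(init)) init <- rep(0.1, nv)
  if (length(init) != nv || any(init < 0))
    stop("init must be a non-negative vector of length ", nv)

  states <- if (model$name == "goodwin") {
    .rk4_goodwin(init, as.list(params$rates), as.list(params$structural),
                 t_end, dt)
  } else if (model$name == "twovar") {
    .rk4_twovar(init, as.list(params$rates), as.list(params$structural),
                t_end, dt)
  } else {
    times <- seq(0, t_end, by = dt)
    func <- function(t, y, parms) list(model$rhs(pmax(y, 0), params))
    out <- deSolve::rk4(init, times, func, parms = NULL)
    unname(as.matrix(out[, -1, drop = FALSE]))
  }
  if (any(!is.finite(states)))
    stop("integration failure: non-finite state encountered")
  if (min(states) < -1e-6)
    stop("integration failure: trajectory left the non-negative orthant")
  colnames(states) <- model$state_names
  n <- nrow(states)
  structure(list(times = seq(0, by = dt, length.out = n), states = states,
                 params = params, dt = dt, model = model$name),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$model, ":", nrow(x$states), "steps, dt =", x$dt,
      ", t in [0,", max(x$times), "]\n")
  invisible(x)
}

# Interior local maxima of x with quadratic (three-point) interpolation.
# Returns interpolated peak times and heights.
find_peaks <- function(times, x) {
  n <- length(x)
  if (n < 3) return(list(t = numeric(0), h = numeric(0)))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  i <- i[i > 1 & i < n]
  if (!length(i)) return(list(t = numeric(0), h = numeric(0)))
  a <- x[i - 1]; b <- x[i]; cc <- x[i + 1]
  den <- a - 2 * b + cc
  off <- ifelse(den != 0, 0.5 * (a - cc) / den, 0)
  dt <- times[2] - times[1]
  list(t = times[i] + off * dt,
       h = b - 0.25 * (a - cc) * off)
}

cv <- function(x) if (length(x) < 2 || mean(x) == 0) Inf else sd(x) / abs(mean(x))

#' Decide whether a trajectory shows sustained oscillations
#'
#' After discarding an initial transient, the reference variable must show
#' at least `min_peaks` interior maxima whose heights and spacings are
#' nearly constant (coefficient of variation below `cv_tol`), with a
#' peak-to-trough excursion that is non-negligible relative to the temporal
#' mean. Damped, divergent, or flat trajectories fail one of these checks.
#'
#' @param traj A `trajectory`.
#' @param transient_fraction Fraction of the run discarded as transient.
#' @param cv_tol Tolerance on the coefficient of variation of peak heights
#'   and inter-peak intervals.
#' @param amp_floor Minimum (max - min) relative to the temporal mean.
#' @param min_peaks Minimum number of interior maxima required.
#' @param ref_var Index or name of the reference variable (default: first).
#' @return `TRUE` or `FALSE`; degenerate inputs return `FALSE`.
#' @export
detect_sustained_oscillation <- function(traj, transient_fraction = 0.5,
                                         cv_tol = 0.05, amp_floor = 1e-3,
                                         min_peaks = 5, ref_var = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  i0 <- max(1L, floor(nrow(traj$states) * transient_fraction))
  x <- traj$states[i0:nrow(traj$states), ref_var]
  t <- traj$times[i0:nrow(traj$states)]
  pk <- find_peaks(t, x)
  if (length(pk$t) < min_peaks) return(FALSE)
  amp <- max(x) - min(x)
  if (amp < amp_floor * abs(mean(x))) return(FALSE)
  if (cv(pk$h) > cv_tol) return(FALSE)
  if (cv(diff(pk$t)) > cv_tol) return(FALSE)
  TRUE
}

# Shared metric computation; returns sustained = FALSE metrics rather than
# erroring, for use inside the screen.
trajectory_metrics <- function(traj, transient_fraction = 0.5, cv_tol = 0.05,
                               amp_floor = 1e-3, min_peaks = 5, ref_var = 1L,
                               k_cycles = 5, half_range = FALSE) {
  sustained <- detect_sustained_oscillation(traj, transient_fraction, cv_tol,
                                            amp_floor, min_peaks, ref_var)
  nv <- ncol(traj$states)
  out <- list(sustained = sustained, period = NA_real_,
              amplitude = rep(NA_real_, nv), vmax = rep(NA_real_, nv),
              vmin = rep(NA_real_, nv), n_cycles_analyzed = 0L)
  names(out$amplitude) <- names(out$vmax) <- names(out$vmin) <-
    colnames(traj$states)
  if (!sustained) return(structure(out, class = "oscillation_metrics"))

  i0 <- max(1L, floor(nrow(traj$states) * transient_fraction))
  t <- traj$times[i0:nrow(traj$states)]
  pk <- find_peaks(t, traj$states[i0:nrow(traj$states), ref_var])
  k <- min(k_cycles, length(pk$t) - 1L)
  tp <- pk$t[(length(pk$t) - k):length(pk$t)]
  out$period <- mean(diff(tp))
  out$n_cycles_analyzed <- k
  win <- traj$times >= tp[1] & traj$times <= tp[length(tp)]
  w <- traj$states[win, , drop = FALSE]
  out$vmax <- apply(w, 2, max)
  out$vmin <- apply(w, 2, min)
  out$amplitude <- (out$vmax - out$vmin) / if (half_range) 2 else 1
  structure(out, class = "oscillation_metrics")
}

#' Measure period and per-variable amplitude of a sustained oscillation
#'
#' The period is the mean inter-peak interval of the reference variable over
#' the last `k_cycles` complete cycles (peak times refined by quadratic
#' interpolation, so accuracy is better than the grid step). Amplitude is
#' peak-to-trough (max - min) per variable over the same window; set
#' `half_range = TRUE` for the sinusoid-amplitude convention.
#'
#' @inheritParams detect_sustained_oscillation
#' @param k_cycles Number of final complete cycles analyzed.
#' @param half_range Report amplitude as (max - min)/2 instead of max - min.
#' @return An `oscillation_metrics` object: `sustained`, `period`,
#'   `amplitude`, `vmax`, `vmin`, `n_cycles_analyzed`.
#' @export
measure_period_amplitude <- function(traj, transient_fraction = 0.5,
                                     cv_tol = 0.05, amp_floor = 1e-3,
                                     min_peaks = 5, ref_var = 1L,
                                     k_cycles = 5, half_range = FALSE) {
  m <- trajectory_metrics(traj, transient_fraction, cv_tol, amp_floor,
                          min_peaks, ref_var, k_cycles, half_range)
  if (!m$sustained)
    stop("trajectory is not a sustained oscillation; ",
         "run detect_sustained_oscillation() first")
  m
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  if (!x$sustained) {
    cat("<oscillation_metrics> not sustained\n")
  } else {
    cat("<oscillation_metrics> period =", signif(x$period, 6),
        "| amplitude:", paste0(names(x$amplitude), "=",
                               signif(x$amplitude, 4), collapse = ", "), "\n")
  }
  invisible(x)
}
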