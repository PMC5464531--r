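#' Harmonic-regression (cosinor) rhythm fit with period scan
#'
#' For each candidate period `P` on a grid, fits
#' `value ~ mesor + b_c cos(2 pi t/P) + b_s sin(2 pi t/P)` by linear least
#' squares and keeps the `P` minimizing the residual sum of squares.
#' Amplitude is the sinusoid amplitude `sqrt(b_c^2 + b_s^2)` (half
#' peak-to-trough); the acrophase is the time of the fitted peak, reduced
#' modulo the period.
#'
#' @param times,values Sample times (h) and measurements; at least 8
#'   samples spanning at least 1.5 of the shortest candidate period.
#' @param period_scan `c(lo, hi)` period range in hours.
#' @param step Scan step (h).
#' @return An object of class `rhythm_fit`: `period`, `amplitude`, `phase`
#'   (acrophase, h), `mesor`, `r_squared`.
#' @export
fit_harmonic <- function(times, values, period_scan = c(20, 28),
                         step = 0.1) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(times) < 8) stop("need at least 8 samples")
  if (diff(range(times)) < 1.5 * period_scan[1])
    stop("samples must span at least 1.5 candidate periods")
  periods <- seq(period_scan[1], period_scan[2], by = step)
  tss <- sum((values - mean(values))^2)
  best <- NULL
  for (P in periods) {
    w <- 2 * pi / P
    X <- cbind(1, cos(w * times), sin(w * times))
    fit <- .lm.fit(X, values)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(P = P, rss = rss, beta = fit$coefficients)
  }
  beta <- best$beta
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  phase <- (best$P / (2 * pi)) * atan2(beta[3], beta[2])
  phase <- phase %% best$P
  structure(list(period = best$P, amplitude = amp, phase = phase,
                 mesor = beta[1],
                 r_squared = if (tss > 0) 1 - best$rss / tss else 0),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("<rhythm_fit> period =", x$period, "h, amplitude =",
      signif(x$amplitude, 4), ", acrophase =", signif(x$phase, 4),
      "h, mesor =", signif(x$mesor, 4), ", R2 =",
      signif(x$r_squared, 3), "\n")
  invisible(x)
}

#' Remove a least-squares linear trend
#'
#' @param times,values The series.
#' @return Detrended values (residuals of a straight-line fit).
#' @export
detrend_linear <- function(times, values) {
  unname(stats::lm.fit(cbind(1, times), values)$residuals)
}

#' Fit an exponentially damped sine curve
#'
#' Nonlinear least squares for
#' `y = y0 + A exp(-x/t0) sin(pi (x - xc)/w)`, the standard model for
#' damped bioluminescence rhythms; the rhythm period is `2 w`. When no
#' initial guess is supplied one is derived from a harmonic fit (optionally
#' after removing a linear trend).
#'
#' @param times,values The trace (at least 10 samples).
#' @param init Optional named list/vector with `y0, A, t0, xc, w`.
#' @param detrend Subtract a least-squares line before fitting (for traces
#'   with a drifting baseline); the reported `y0` then refers to the
#'   detrended trace.
#' @param period_scan Period range handed to [fit_harmonic()] when deriving
#'   the initial guess.
#' @return An object of class `damped_sine_fit`: `y0`, `A`, `t0`, `xc`,
#'   `w`, `period` (= 2w), `rss`.
#' @export
fit_damped_sine <- function(times, values, init = NULL, detrend = FALSE,
                            period_scan = c(20, 28)) {
  if (length(times) < 10) stop("need at least 10 samples")
  if (detrend) values <- detrend_linear(times, values)
  if (is.null(init)) {
    h <- fit_harmonic(times, values, period_scan)
    init <- list(y0 = h$mesor, A = max(h$amplitude, 1e-8),
                 t0 = 2 * diff(range(times)),
                 xc = h$phase - h$period / 4, w = h$period / 2)
  }
  start <- unlist(init)[c("y0", "A", "t0", "xc", "w")]
  model <- function(par, x)
    par[["y0"]] + par[["A"]] * exp(-x / par[["t0"]]) *
      sin(pi * (x - par[["xc"]]) / par[["w"]])
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(par) values - model(par, times),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop("damped-sine fit did not converge (", fit$message,
         "); final residual ", signif(sum(fit$fvec^2), 4),
         ", initial guess ",
         paste0(names(start), "=", signif(start, 4), collapse = ", "))
  p <- as.list(fit$par)
  # canonical form: positive amplitude, w > 0
  if (p$A < 0) { p$A <- -p$A; p$xc <- p$xc + p$w }
  if (p$t0 <= 0 || p$w <= 0)
    stop("damped-sine fit converged to a non-physical solution (t0 = ",
         signif(p$t0, 4), ", w = ", signif(p$w, 4), ")")
  structure(list(y0 = p$y0, A = p$A, t0 = p$t0, xc = p$xc, w = p$w,
                 period = 2 * p$w,
                 rss = sum(fit$fvec^2)),
            class = "damped_sine_fit")
}

#' @export
print.damped_sine_fit <- function(x, ...) {
  cat("<damped_sine_fit> period = 2w =", signif(x$period, 6),
      "h (w =", signif(x$w, 6), "), A =", signif(x$A, 4),
      ", t0 =", signif(x$t0, 4), "\n")
  invisible(x)
}

#' Q10 with replicate-level group comparison
#'
#' Computes the Q10 of a rhythm quantity (period or amplitude) between two
#' temperatures from group means of replicate fits, and tests the
#' temperature effect with a two-sample Student's t-test (equal variances
#' by default; set `var_equal = FALSE` for Welch).
#'
#' @param fits_low,fits_high Lists of [fit_harmonic()] (or compatible)
#'   fits, one per replicate; at least 2 per group.
#' @param T_low,T_high Temperatures (consistent scale, e.g. Celsius).
#' @param quantity `"period"` or `"amplitude"`. Periods use the frequency
#'   (reciprocal) Q10 convention; amplitudes the plain rate convention
#'   (which makes amplitude Q10 invariant to the half- vs full-range
#'   amplitude choice).
#' @param alpha Significance level for the `significant` flag.
#' @param var_equal Classical Student's t-test (TRUE) or Welch.
#' @return An object of class `q10_result`: `q10`, `values_low`,
#'   `values_high`, `T_low`, `T_high`, `p_value`, `significant`,
#'   `quantity`.
#' @export
q10_report <- function(fits_low, fits_high, T_low, T_high,
                       quantity = c("period", "amplitude"), alpha = 0.05,
                       var_equal = TRUE) {
  quantity <- match.arg(quantity)
  pull <- function(fits) vapply(fits, function(f) f[[quantity]], 0)
  v_lo <- pull(fits_low); v_hi <- pull(fits_high)
  if (length(v_lo) < 2 || length(v_hi) < 2)
    stop("need at least 2 replicates per group")
  qv <- q10(mean(v_lo), T_low, mean(v_hi), T_high,
            convention = if (quantity == "period") "period" else "rate")
  p_value <- if (sd(v_lo) == 0 && sd(v_hi) == 0) {
    # degenerate: no within-group variance; identical means are maximally
    # non-significant, different means trivially significant
    if (mean(v_lo) == mean(v_hi)) 1 else 0
  } else {
    t.test(v_lo, v_hi, var.equal = var_equal)$p.value
  }
  structure(list(q10 = qv, values_low = v_lo, values_high = v_hi,
                 T_low = T_low, T_high = T_high, p_value = p_value,
                 significant = p_value < alpha, quantity = quantity),
            class = "q10_result")
}

#' @export
print.q10_result <- function(x, ...) {
  cat("<q10_result>", x$quantity, "Q10 =", signif(x$q10, 4),
      "(", x$T_low, "vs", x$T_high, "deg ), p =", signif(x$p_value, 3),
      if (x$significant) "*" else "", "\n")
  invisible(x)
}
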