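#' Protocol for the random-parameterization screen
#'
#' The screen asks how the oscillation period and amplitudes respond when
#' all reaction speeds increase, as they would with temperature. Basal
#' parameter sets are drawn around a standard set, then each basal set is
#' "sped up" by independent per-rate factors; relative period and
#' geometric-mean relative amplitude summarize each pair of runs.
#'
#' @param n_basal Number of basal sets (reference protocol: 500).
#' @param n_speedup Speed-up sets per basal set (reference protocol: 100).
#' @param basal_range Multiplier range for basal rates around the standard
#'   set (reference: `c(0.5, 2)`).
#' @param speedup_range Per-rate speed-up factor range (reference:
#'   `c(1.5, 2.5)`, mean increase about 2-fold).
#' @param seed Integer seed; every draw is a pure function of it.
#' @param model Model name the protocol applies to.
#' @return An object of class `screening_protocol`.
#' @export
screening_protocol <- function(n_basal = 500, n_speedup = 100,
                               basal_range = c(0.5, 2),
                               speedup_range = c(1.5, 2.5),
                               seed = 1L, model = "goodwin") {
  stopifnot(n_basal >= 1, n_speedup >= 1,
            basal_range[1] > 0, basal_range[1] <= basal_range[2],
            speedup_range[1] > 0, speedup_range[1] <= speedup_range[2])
  structure(list(n_basal = as.integer(n_basal),
                 n_speedup = as.integer(n_speedup),
                 basal_range = basal_range, speedup_range = speedup_range,
                 seed = as.integer(seed), model = model),
            class = "screening_protocol")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Draw basal parameter sets around a standard set
#'
#' Each rate is drawn independently and uniformly on
#' `[low, high] * standard`; structural constants are copied unchanged.
#' Draws are a pure function of `protocol$seed`.
#'
#' @param standard The standard `param_set`.
#' @param protocol A [screening_protocol()].
#' @return List of `n_basal` parameter sets.
#' @export
draw_basal_sets <- function(standard, protocol) {
  stopifnot(inherits(standard, "param_set"),
            inherits(protocol, "screening_protocol"))
  nr <- length(standard$rates)
  with_seed(protocol$seed, {
    lapply(seq_len(protocol$n_basal), function(i) {
      f <- runif(nr, protocol$basal_range[1], protocol$basal_range[2])
      names(f) <- names(standard$rates)
      scale_rates(standard, f)
    })
  })
}

#' Draw per-rate speed-up factor matrix
#'
#' Every rate of every speed-up set gets its own independent
#' `Uniform(low, high)` factor, so e.g. mRNA and protein degradation can
#' speed up by different amounts. Uses `protocol$seed + 1`, independent of
#' the basal draw.
#'
#' @param protocol A [screening_protocol()].
#' @param n_rates Number of rate constants per set.
#' @param n_sets Number of factor rows; default
#'   `n_basal * n_speedup`.
#' @return Matrix `n_sets x n_rates` of factors.
#' @export
draw_speedup_factors <- function(protocol, n_rates,
                                 n_sets = protocol$n_basal *
                                   protocol$n_speedup) {
  stopifnot(inherits(protocol, "screening_protocol"))
  with_seed(protocol$seed + 1L,
    matrix(runif(n_sets * n_rates, protocol$speedup_range[1],
                 protocol$speedup_range[2]),
           nrow = n_sets, ncol = n_rates))
}

#' Geometric-mean relative amplitude
#'
#' `exp(mean(log(x)))` over per-variable amplitude ratios; the screen's
#' summary statistic for simultaneous amplitude increase.
#'
#' @param relative_amplitudes Positive numeric vector.
#' @return The geometric mean.
#' @export
geometric_mean_relative_amplitude <- function(relative_amplitudes) {
  if (any(!is.finite(relative_amplitudes)) || any(relative_amplitudes <= 0))
    stop("relative amplitudes must be positive")
  exp(mean(log(relative_amplitudes)))
}

#' Run the random-parameterization screen
#'
#' For every basal set, and every speed-up set derived from it, simulates
#' the model, classifies sustained oscillation, and (when both members of a
#' pair oscillate) records the relative period (scaled / basal) and the
#' per-variable relative amplitudes with their geometric mean (`gma`).
#' Integration failures are counted as non-oscillating.
#'
#' @param model A `clock_model`.
#' @param standard The standard `param_set` (must itself oscillate).
#' @param protocol A [screening_protocol()].
#' @param dt Integration step.
#' @param cycles Analysis horizon in multiples of the relevant period; runs
#'   last `cycles` expected cycles so slow oscillators are never truncated.
#' @param ... Oscillation-detector settings
#'   (see [detect_sustained_oscillation()]).
#' @return An object of class `screen_result`: `records` (one row per
#'   scaled run), `census` (counts), `protocol`.
#' @export
run_screen <- function(model, standard, protocol, dt = 0.01, cycles = 40,
                       ...) {
  stopifnot(inherits(model, "clock_model"),
            inherits(protocol, "screening_protocol"))
  std_traj <- simulate_model(model, standard, t_end = 2000, dt = dt)
  m_std <- trajectory_metrics(std_traj, ...)
  if (!m_std$sustained) stop("standard parameter set does not oscillate")
  P0 <- m_std$period

  basal_sets <- draw_basal_sets(standard, protocol)
  n_rates <- length(standard$rates)
  factors <- draw_speedup_factors(protocol, n_rates)

  # fallback horizon: slowest basal x slowest speed-up
  t_fallback <- cycles * P0 / (protocol$basal_range[1] *
                                 protocol$speedup_range[1])
  nv <- length(model$state_names)
  rec <- vector("list", protocol$n_basal * protocol$n_speedup)
  n_basal_osc <- 0L
  n_scaled_osc <- 0L

  for (b in seq_len(protocol$n_basal)) {
    bp <- basal_sets[[b]]
    mb <- tryCatch({
      tb <- simulate_model(model, bp,
                           t_end = cycles * P0 / protocol$basal_range[1],
                           dt = dt)
      trajectory_metrics(tb, ...)
    }, error = function(e) list(sustained = FALSE, period = NA_real_,
                                amplitude = rep(NA_real_, nv)))
    if (mb$sustained) n_basal_osc <- n_basal_osc + 1L
    t_end_s <- if (mb$sustained) cycles * mb$period else t_fallback

    for (j in seq_len(protocol$n_speedup)) {
      idx <- (b - 1L) * protocol$n_speedup + j
      f <- factors[idx, ]
      names(f) <- names(standard$rates)
      sp <- scale_rates(bp, f)
      ms <- tryCatch({
        ts <- simulate_model(model, sp, t_end = t_end_s, dt = dt)
        trajectory_metrics(ts, ...)
      }, error = function(e) list(sustained = FALSE, period = NA_real_,
                                  amplitude = rep(NA_real_, nv)))
      if (ms$sustained) n_scaled_osc <- n_scaled_osc + 1L
      both <- mb$sustained && ms$sustained
      rel_amp <- if (both) ms$amplitude / mb$amplitude else rep(NA_real_, nv)
      row <- data.frame(basal_id = b, speedup_id = j,
                        basal_sustained = mb$sustained,
                        scaled_sustained = ms$sustained,
                        basal_period = mb$period, scaled_period = ms$period,
                        relative_period = if (both) ms$period / mb$period
                                          else NA_real_)
      for (v in seq_len(nv))
        row[[paste0("relative_amplitude_", model$state_names[v])]] <-
          rel_amp[v]
      row$gma <- if (both) geometric_mean_relative_amplitude(rel_amp)
                 else NA_real_
      rec[[idx]] <- row
    }
  }
  records <- do.call(rbind, rec)
  census <- list(n_basal = protocol$n_basal,
                 n_speedup = protocol$n_speedup,
                 n_scaled_total = protocol$n_basal * protocol$n_speedup,
                 n_basal_oscillating = n_basal_osc,
                 n_scaled_oscillating = n_scaled_osc,
                 fraction_scaled_oscillating =
                   n_scaled_osc / (protocol$n_basal * protocol$n_speedup))
  structure(list(records = records, census = census, protocol = protocol,
                 standard_period = P0),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", x$census$n_scaled_total, "scaled runs;",
      x$census$n_scaled_oscillating, "sustained (",
      round(100 * x$census$fraction_scaled_oscillating, 1), "%)\n")
  invisible(x)
}

#' Summarize a screen: amplitude coupling vs period maintenance
#'
#' Bins the geometric-mean relative amplitude (`gma`) against relative
#' period and computes the headline statistic: among records whose period
#' is nearly unchanged by the speed-up (`relative_period >= threshold`),
#' the fraction with `gma > 1`. The temperature-amplitude coupling claim is
#' that this fraction is 1 (by convention, 1 when no record qualifies).
#'
#' @param x A `screen_result` or its `records` data frame.
#' @param period_threshold Relative-period cut for "nearly unchanged"
#'   (default 0.95).
#' @param n_bins Number of relative-period bins.
#' @return List with `binned` (per-bin summaries), `n_maintained`,
#'   `headline_fraction`, `min_gma_maintained`.
#' @export
summarize_screen <- function(x, period_threshold = 0.95, n_bins = 20) {
  records <- if (inherits(x, "screen_result")) x$records else x
  ok <- records[!is.na(records$relative_period), , drop = FALSE]
  if (!nrow(ok)) stop("no records with both runs sustained")
  br <- seq(min(ok$relative_period), max(ok$relative_period),
            length.out = n_bins + 1)
  bin <- cut(ok$relative_period, breaks = unique(br), include.lowest = TRUE)
  binned <- do.call(rbind, lapply(split(ok, bin), function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(relative_period = mean(d$relative_period),
               n = nrow(d), mean_gma = mean(d$gma), min_gma = min(d$gma),
               max_gma = max(d$gma))
  }))
  maint <- ok[ok$relative_period >= period_threshold, , drop = FALSE]
  list(binned = binned,
       n_maintained = nrow(maint),
       headline_fraction = if (nrow(maint)) mean(maint$gma > 1) else 1,
       min_gma_maintained = if (nrow(maint)) min(maint$gma) else NA_real_)
}
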