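#' Design for a synthetic circadian expression dataset
#'
#' Emulates a dexamethasone-synchronized culture experiment: mRNA sampled
#' every `dt_sample` hours from `t_start` to `t_end` post-stimulation, a
#' few independent replicates per condition, two incubation temperatures,
#' values optionally expressed relative to the first sampled time point
#' (percent). Each gene has its own period, amplitude, acrophase and mesor
#' per temperature, so temperature-dependent amplitude (coupling) can be
#' designed in directly.
#'
#' @param genes Data frame with columns `gene`, `temperature`, `period`,
#'   `amplitude`, `acrophase`, `mesor` (one row per gene x temperature).
#' @param t_start,t_end,dt_sample Sampling scheme in hours (default: every
#'   4 h from 32 to 96 h, i.e. 17 time points).
#' @param n_replicates Independent replicates per condition (default 3).
#' @param noise_sd Gaussian noise SD as a fraction of each gene's
#'   amplitude.
#' @param normalize Express values relative to the first time point (x100).
#' @param seed Integer seed.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(genes, t_start = 32, t_end = 96,
                             dt_sample = 4, n_replicates = 3,
                             noise_sd = 0.1, normalize = TRUE, seed = 1L) {
  need <- c("gene", "temperature", "period", "amplitude", "acrophase",
            "mesor")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes is missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(t_end > t_start, dt_sample > 0, n_replicates >= 1,
            noise_sd >= 0)
  structure(list(genes = genes, t_start = t_start, t_end = t_end,
                 dt_sample = dt_sample,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, normalize = normalize,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Two-temperature design with a prescribed amplitude ratio
#'
#' Convenience constructor for the common case: one or more genes with a
#' circadian period at each of two temperatures and an amplitude that is
#' `amplitude_ratio`-fold higher at the warmer one.
#'
#' @param gene_names Character vector.
#' @param temperatures Two temperatures (Celsius).
#' @param period_low,period_high Periods (h) at the two temperatures.
#' @param amplitude Base amplitude at the lower temperature.
#' @param amplitude_ratio Fold increase of amplitude at the higher
#'   temperature.
#' @param acrophase,mesor Peak time (h) and baseline.
#' @param ... Passed to [synthetic_design()].
#' @return A `synthetic_design`.
#' @export
coupling_design <- function(gene_names = "geneA", temperatures = c(35, 38),
                            period_low = 22.5, period_high = 23,
                            amplitude = 20, amplitude_ratio = 2.03,
                            acrophase = 8, mesor = 100, ...) {
  genes <- do.call(rbind, lapply(gene_names, function(g)
    data.frame(gene = g, temperature = temperatures,
               period = c(period_low, period_high),
               amplitude = amplitude * c(1, amplitude_ratio),
               acrophase = acrophase, mesor = mesor)))
  synthetic_design(genes, ...)
}

#' Generate a synthetic expression dataset
#'
#' `value = mesor + amplitude cos(2 pi (t - acrophase)/period) + noise`,
#' per gene, temperature and replicate; deterministic given the design
#' seed.
#'
#' @param design A [synthetic_design()].
#' @return Tidy data frame: `gene`, `temperature`, `replicate`, `time_h`,
#'   `value`.
#' @export
generate_expression_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  times <- seq(design$t_start, design$t_end, by = design$dt_sample)
  g <- design$genes
  with_seed(design$seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      do.call(rbind, lapply(seq_len(design$n_replicates), function(rep) {
        clean <- g$mesor[i] + g$amplitude[i] *
          cos(2 * pi * (times - g$acrophase[i]) / g$period[i])
        noisy <- clean + rnorm(length(times),
                               sd = design$noise_sd * g$amplitude[i])
        data.frame(gene = g$gene[i], temperature = g$temperature[i],
                   replicate = rep, time_h = times, value = noisy)
      }))
    }))
  })
  if (design$normalize) {
    # rows are time-ordered within each (gene, temperature, replicate)
    out$value <- stats::ave(out$value, out$gene, out$temperature,
                            out$replicate,
                            FUN = function(v) 100 * v / v[1])
  }
  rownames(out) <- NULL
  out
}

#' Generate a damped bioluminescence-like trace
#'
#' Exponentially damped sine plus Gaussian noise and an optional linear
#' trend (to exercise detrending), matching the model fitted by
#' [fit_damped_sine()].
#'
#' @param t_grid Sample times (h).
#' @param y0,A,t0,xc,w Damped-sine parameters (`period = 2 w`).
#' @param noise_sd Gaussian noise SD (absolute units).
#' @param trend Linear drift slope added as `trend * t`.
#' @param seed Integer seed (`NULL`: use current RNG state).
#' @return Data frame with `time_h`, `value`.
#' @export
generate_bioluminescence_trace <- function(t_grid, y0 = 5, A = 40,
                                           t0 = 60, xc = 3, w = 11,
                                           noise_sd = 0, trend = 0,
                                           seed = NULL) {
  gen <- function() {
    v <- y0 + A * exp(-t_grid / t0) * sin(pi * (t_grid - xc) / w) +
      trend * t_grid
    if (noise_sd > 0) v <- v + rnorm(length(t_grid), sd = noise_sd)
    v
  }
  value <- if (is.null(seed)) gen() else with_seed(seed, gen())
  data.frame(time_h = t_grid, value = value)
}

#' Parameter-set fixtures with known screening behavior
#'
#' Emits basal/scaled parameter-set pairs whose classification is known in
#' advance, for exercising the screen: identity scalings (relative period
#' exactly 1), common-factor scalings by `c` (relative period exactly
#' `1/c`), and, for the two-variable model, sets just below the Hopf point
#' (no sustained oscillation).
#'
#' @param model A `clock_model`.
#' @param n Sets per category.
#' @param seed Integer seed for the basal jitter.
#' @param common_factor The common scaling factor `c`.
#' @return Data-frame-free list of fixtures: each element has `basal`,
#'   `scaled`, `category`, `expect_sustained`,
#'   `expected_relative_period` (NA when not applicable).
#' @export
generate_screen_fixture <- function(model, n = 3, seed = 1L,
                                    common_factor = 2) {
  standard <- switch(model$name, goodwin = goodwin_standard_params(),
                     twovar = twovar_params("high"),
                     stop("no fixture recipe for model ", model$name))
  jitters <- with_seed(seed,
    matrix(runif(n * length(standard$rates), 0.9, 1.1), nrow = n))
  fx <- list()
  for (i in seq_len(n)) {
    f <- jitters[i, ]; names(f) <- names(standard$rates)
    basal <- scale_rates(standard, f)
    fx[[length(fx) + 1]] <- list(basal = basal, scaled = basal,
                                 category = "identity",
                                 expect_sustained = TRUE,
                                 expected_relative_period = 1)
    fx[[length(fx) + 1]] <- list(basal = basal,
                                 scaled = scale_rates(basal, common_factor),
                                 category = "common_factor",
                                 expect_sustained = TRUE,
                                 expected_relative_period = 1 / common_factor)
  }
  if (model$name == "twovar") {
    vc <- find_hopf(standard)$critical_value
    for (i in seq_len(n)) {
      p <- standard
      p$rates[["v"]] <- vc * (0.98 - 0.05 * (i - 1))
      fx[[length(fx) + 1]] <- list(basal = p, scaled = p,
                                   category = "below_hopf",
                                   expect_sustained = FALSE,
                                   expected_relative_period = NA_real_)
    }
  }
  fx
}
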