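test_that("sampling scheme yields 17 time points per replicate", {
  des <- coupling_design(noise_sd = 0, seed = 1)
  dat <- generate_expression_dataset(des)
  one <- dat[dat$gene == "geneA" & dat$temperature == 35 &
               dat$replicate == 1, ]
  expect_equal(nrow(one), 17)
  expect_equal(one$time_h, seq(32, 96, by = 4))
  expect_equal(nrow(dat), 17 * 3 * 2)
})

test_that("noiseless round trip through the harmonic fitter", {
  des <- coupling_design(period_low = 22, period_high = 23,
                         amplitude = 20, amplitude_ratio = 2,
                         noise_sd = 0, normalize = FALSE, seed = 1)
  dat <- generate_expression_dataset(des)
  for (Tc in c(35, 38)) {
    d <- dat[dat$temperature == Tc & dat$replicate == 1, ]
    f <- fit_harmonic(d$time_h, d$value)
    expect_equal(f$period, ifelse(Tc == 35, 22, 23), tolerance = 0.1 / 22)
    expect_equal(f$amplitude, ifelse(Tc == 35, 20, 40), tolerance = 1e-3)
  }
})

test_that("designed amplitude ratio 2.03 per 3 degrees maps to amplitude
           Q10 near 10.6 in the noiseless limit", {
  des <- coupling_design(amplitude_ratio = 2.03, noise_sd = 0,
                         normalize = FALSE, seed = 1)
  dat <- generate_expression_dataset(des)
  fits <- lapply(split(dat, dat[c("temperature", "replicate")]),
                 function(d) fit_harmonic(d$time_h, d$value))
  grp <- function(Tc) fits[grep(paste0("^", Tc), names(fits))]
  r <- q10_report(grp(35), grp(38), 35, 38, "amplitude")
  expect_equal(r$q10, 2.03^(10 / 3), tolerance = 1e-3)
})

test_that("generation is deterministic given the seed and noise obeys
           the replicate-averaging law", {
  des <- coupling_design(noise_sd = 0.1, seed = 7)
  expect_identical(generate_expression_dataset(des),
                   generate_expression_dataset(des))
  des2 <- coupling_design(noise_sd = 0.1, seed = 8)
  expect_false(identical(generate_expression_dataset(des),
                         generate_expression_dataset(des2)))

  # SEM of replicate means scales as noise_sd/sqrt(n)
  sem_of <- function(n, seed) {
    genes <- data.frame(gene = "g", temperature = 35, period = 22.5,
                        amplitude = 10, acrophase = 8, mesor = 100)
    des <- synthetic_design(genes, n_replicates = n, noise_sd = 0.2,
                            normalize = FALSE, seed = seed)
    dat <- generate_expression_dataset(des)
    resid <- dat$value - ave(dat$value, dat$time_h)
    sd(resid) / sqrt(n)
  }
  sems <- vapply(1:6, function(s) c(sem_of(3, s), sem_of(300, s)), c(0, 0))
  expect_equal(mean(sems[1, ] / sems[2, ]), 10, tolerance = 0.25)
})

test_that("relative-to-first-timepoint normalization rescales values but
           not fitted periods or amplitude Q10", {
  # the first sample sits at a zero crossing of the cosine (acrophase =
  # t_start - period/4), so the normalizer equals the mesor at both
  # temperatures and amplitude ratios survive normalization exactly
  mk <- function(norm) coupling_design(amplitude_ratio = 2.03,
                                       period_low = 22.5,
                                       period_high = 22.5,
                                       acrophase = 32 - 22.5 / 4,
                                       noise_sd = 0, normalize = norm,
                                       seed = 3)
  raw <- generate_expression_dataset(mk(FALSE))
  nrm <- generate_expression_dataset(mk(TRUE))
  expect_equal(nrm$value[nrm$time_h == 32], rep(100, 6))
  fits <- function(dat) lapply(split(dat, dat[c("temperature",
                                                "replicate")]),
                               function(d) fit_harmonic(d$time_h, d$value))
  fr <- fits(raw); fn <- fits(nrm)
  expect_equal(vapply(fn, `[[`, 0, "period"),
               vapply(fr, `[[`, 0, "period"))
  g <- function(f, Tc) f[grep(paste0("^", Tc), names(f))]
  expect_equal(q10_report(g(fn, 35), g(fn, 38), 35, 38, "amplitude")$q10,
               q10_report(g(fr, 35), g(fr, 38), 35, 38, "amplitude")$q10,
               tolerance = 1e-10)
})

test_that("bioluminescence traces round-trip and differ only by seed", {
  t <- seq(0, 120, by = 0.5)
  a <- generate_bioluminescence_trace(t, noise_sd = 1, seed = 4)
  b <- generate_bioluminescence_trace(t, noise_sd = 1, seed = 4)
  c_ <- generate_bioluminescence_trace(t, noise_sd = 1, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  clean <- generate_bioluminescence_trace(t, noise_sd = 0)
  expect_equal(mean(a$value), mean(clean$value), tolerance = 0.05)
})
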