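# Shared fixtures and independent oracles for the test suite.

goodwin <- clock_model("goodwin")
twovar <- clock_model("twovar")

# Independent period oracle: upward zero crossings of the mean-subtracted
# reference variable, linearly interpolated; deliberately shares no code
# with the peak-based measure_period_amplitude().
period_zero_crossing <- function(traj, ref_var = 1L,
                                 transient_fraction = 0.5) {
  n <- nrow(traj$states)
  i0 <- floor(n * transient_fraction)
  x <- traj$states[i0:n, ref_var]
  t <- traj$times[i0:n]
  x <- x - mean(x)
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  tz <- t[up] + (t[2] - t[1]) * (-x[up]) / (x[up + 1] - x[up])
  mean(diff(tz))
}

# Wrap a plain numeric series as a trajectory object so the oscillation
# detector can be exercised on analytically constructed signals.
fake_trajectory <- function(times, x, name = "S") {
  states <- matrix(x, ncol = 1, dimnames = list(NULL, name))
  structure(list(times = times, states = states, params = NULL,
                 dt = times[2] - times[1], model = "synthetic"),
            class = "trajectory")
}

# Single-variable exponential decay, used as a guaranteed non-oscillator.
decay_model <- define_clock_model(
  "decay", state_names = "Z", rate_names = "r", structural_names = "c0",
  rhs = function(state, params) c(Z = -params$rates[["r"]] * state[[1]]))
decay_params <- param_set("decay", rates = c(r = 1), structural = c(c0 = 1))

# Cached expensive objects, computed at most once per test run.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

goodwin_metrics <- function() cached("goodwin_metrics", {
  traj <- simulate_model(goodwin, goodwin_standard_params(), t_end = 600)
  list(traj = traj, metrics = measure_period_amplitude(traj))
})

twovar_metrics <- function(which) cached(paste0("twovar_", which), {
  traj <- simulate_model(twovar, twovar_params(which), t_end = 1500)
  list(traj = traj, metrics = measure_period_amplitude(traj))
})

screen_small <- function() cached("screen_small", {
  proto <- screening_protocol(n_basal = 100, n_speedup = 20, seed = 42)
  run_screen(goodwin, goodwin_standard_params(), proto)
})
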