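# Fixed-point, Hopf, and fast-slow analysis of the two-variable model.
#
# Throughout, F(X, Y) denotes the X right-hand side *without* the 1/eps
# factor: F = (k + v X^g/(Kv^g + X^g))/(h + Y) - a X, and
# G(X, Y) = s X^a/(Ks^a + X^a) - d Y.

hill <- function(X, K, n) X^n / (K^n + X^n)
hill_d1 <- function(X, K, n) n * K^n * X^(n - 1) / (K^n + X^n)^2
hill_d2 <- function(X, K, n) {
  n * K^n * X^(n - 2) * ((n - 1) * (K^n + X^n) - 2 * n * X^n) /
    (K^n + X^n)^3
}

twovar_fun <- function(params) {
  r <- params$rates; s <- params$structural
  list(
    F = function(X, Y) (r[["k"]] + r[["v"]] * hill(X, s[["Kv"]],
                                                   s[["gamma"]])) /
          (s[["h"]] + Y) - r[["a"]] * X,
    G = function(X, Y) r[["s"]] * hill(X, s[["Ks"]], s[["alpha"]]) -
          r[["d"]] * Y,
    # inhibitor nullcline Y*(X) (steady state of Y given X)
    Ystar = function(X) r[["s"]] / r[["d"]] * hill(X, s[["Ks"]],
                                                   s[["alpha"]]),
    # activator nullcline Y(X) solving F = 0
    Ynull = function(X) (r[["k"]] + r[["v"]] * hill(X, s[["Kv"]],
                                                    s[["gamma"]])) /
          (r[["a"]] * X) - s[["h"]],
    dYnull = function(X) {
      num <- r[["k"]] + r[["v"]] * hill(X, s[["Kv"]], s[["gamma"]])
      (r[["v"]] * hill_d1(X, s[["Kv"]], s[["gamma"]]) * X - num) /
        (r[["a"]] * X^2)
    },
    r = r, s = s)
}

#' Jacobian of the two-variable model at a state
#'
#' Analytic partial derivatives of the two right-hand sides (the `X` row
#' carries the `1/eps` factor).
#'
#' @param params A `"twovar"` `param_set`.
#' @param state Numeric `(X, Y)`.
#' @return A 2x2 matrix.
#' @export
twovar_jacobian <- function(params, state) {
  r <- params$rates; s <- params$structural
  X <- state[[1]]; Y <- state[[2]]
  num <- r[["k"]] + r[["v"]] * hill(X, s[["Kv"]], s[["gamma"]])
  fX <- (r[["v"]] * hill_d1(X, s[["Kv"]], s[["gamma"]]) / (s[["h"]] + Y) -
           r[["a"]]) / s[["eps"]]
  fY <- -num / (s[["h"]] + Y)^2 / s[["eps"]]
  gX <- r[["s"]] * hill_d1(X, s[["Ks"]], s[["alpha"]])
  gY <- -r[["d"]]
  matrix(c(fX, gX, fY, gY), 2, 2,
         dimnames = list(c("X", "Y"), c("X", "Y")))
}

#' Fixed point of the two-variable model
#'
#' Substitutes the inhibitor steady state `Y*(X)` into the `X` equation and
#' solves the resulting scalar equation by bracketed root finding (first
#' sign change over a fine grid, refined by [uniroot()]). Eigenvalues come
#' from the analytic Jacobian.
#'
#' @param params A `"twovar"` `param_set`.
#' @param x_bracket Search interval for `X*`.
#' @return An object of class `fixed_point`: `state`, `eigenvalues`,
#'   `stability` (`"stable"`/`"unstable"`, focus or node), `residual`.
#' @export
find_fixed_point <- function(params, x_bracket = c(1e-8, 100)) {
  fn <- twovar_fun(params)
  g <- function(X) fn$F(X, fn$Ystar(X))
  xs <- exp(seq(log(x_bracket[1]), log(x_bracket[2]), length.out = 4000))
  vals <- g(xs)
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx))
    stop("no sign change of the reduced equation in the bracket; ",
         "widen x_bracket")
  root <- uniroot(g, c(xs[idx[1]], xs[idx[1] + 1]), tol = 1e-14)$root
  X <- root; Y <- fn$Ystar(X)
  resid <- max(abs(fn$F(X, Y) / params$structural[["eps"]]),
               abs(fn$G(X, Y)))
  ev <- eigen(twovar_jacobian(params, c(X, Y)), only.values = TRUE)$values
  stab <- paste0(if (max(Re(ev)) < 0) "stable" else "unstable", " ",
                 if (is.complex(ev) && any(Im(ev) != 0)) "focus" else "node")
  structure(list(state = c(X = X, Y = Y), eigenvalues = ev,
                 stability = stab, residual = resid),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("<fixed_point> X* =", signif(x$state[1], 6), ", Y* =",
      signif(x$state[2], 6), "(", x$stability, ")\n")
  cat("  eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  invisible(x)
}

#' Locate a Hopf bifurcation by eigenvalue bisection
#'
#' Bisects on the maximum real part of the fixed point's Jacobian
#' eigenvalues as one rate parameter varies. At the returned critical value
#' the real part changes sign while the imaginary part is nonzero: a pair
#' of complex eigenvalues crosses the imaginary axis and a small-amplitude
#' limit cycle is born.
#'
#' @param params A `"twovar"` `param_set` (values of `bif_param` in it are
#'   ignored).
#' @param bif_param Name of the rate to vary (default `"v"`, the positive
#'   feedback strength).
#' @param interval Search interval; the sign of `max Re(lambda)` must
#'   differ at its ends.
#' @param tol Bisection stops when the bracket is narrower than this.
#' @param x_bracket Passed to [find_fixed_point()].
#' @return An object of class `hopf_result`: `parameter`, `critical_value`,
#'   `bracket`, `max_re`, `eigenvalues` at the critical value.
#' @export
find_hopf <- function(params, bif_param = "v", interval = c(0.3, 2.15),
                      tol = 1e-4, x_bracket = c(1e-8, 100)) {
  if (!bif_param %in% names(params$rates))
    stop("unknown rate name: ", bif_param)
  max_re <- function(val) {
    p <- params
    p$rates[[bif_param]] <- val
    max(Re(find_fixed_point(p, x_bracket)$eigenvalues))
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- max_re(lo); fhi <- max_re(hi)
  if (sign(flo) == sign(fhi))
    stop("max Re(eigenvalue) has the same sign at both interval ends; ",
         "expand the search interval")
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    fm <- max_re(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  crit <- 0.5 * (lo + hi)
  p <- params; p$rates[[bif_param]] <- crit
  fp <- find_fixed_point(p, x_bracket)
  if (all(Im(fp$eigenvalues) == 0))
    warning("eigenvalues are real at the critical value; ",
            "not a Hopf bifurcation")
  structure(list(parameter = bif_param, critical_value = crit,
                 bracket = c(lo, hi), max_re = max(Re(fp$eigenvalues)),
                 eigenvalues = fp$eigenvalues),
            class = "hopf_result")
}

#' @export
print.hopf_result <- function(x, ...) {
  cat("<hopf_result>", x$parameter, "* =", signif(x$critical_value, 6),
      "(bracket width", format(diff(x$bracket), digits = 3), ")\n")
  invisible(x)
}

# First zero of the Airy function Ai(-z); governs the O(eps^{2/3}) delayed
# jump at a generic fold of a fast-slow system.
AIRY_Z0 <- 2.3381074104597674
# Per-fold delay constant in units of (eps^2/(|F_XX| |F_Y G|))^{1/3}; the
# 3/2 factor over the naive Airy blow-up time matches the classical van der
# Pol expansion T = T0 + 3 z0 eps^{2/3} (two symmetric folds).
FOLD_DELAY_C <- 3 * AIRY_Z0 / 2^(2 / 3)

#' Fast-slow (singular perturbation) period approximation
#'
#' In the limit `eps -> 0` the fast mRNA `X` is slaved to a stable branch
#' of its nullcline `F(X, Y) = 0` while the slow inhibitor `Y` drifts; the
#' orbit is a relaxation oscillation jumping between the two stable
#' (decreasing) branches at the nullcline folds. The singular period is the
#' sum over both slow segments of `dY / G(X(Y), Y)`, computed as integrals
#' over `X` with the analytic nullcline slope. With `correction = TRUE`
#' (default) the O(`eps^(2/3)`) Airy fold-delay term is added for each
#' fold, using the `eps` stored in the parameter set.
#'
#' @param params A `"twovar"` `param_set` in the relaxation regime (folded
#'   nullcline); otherwise an error is raised.
#' @param correction Add the fold-delay correction (the singular term
#'   itself is independent of `eps`).
#' @param x_range Interval scanned for nullcline folds.
#' @param detail Return a list with the pieces instead of a single number.
#' @return The approximate period (numeric), or a list when
#'   `detail = TRUE`.
#' @export
fastslow_period <- function(params, correction = TRUE,
                            x_range = c(1e-3, 1e3), detail = FALSE) {
  fn <- twovar_fun(params)
  xs <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = 8000))
  dy <- fn$dYnull(xs)
  sgn <- sign(dy)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) != 2)
    stop("activator nullcline is not folded (found ", length(idx),
         " slope sign changes); fast-slow analysis does not apply")
  folds <- vapply(idx, function(i)
    uniroot(fn$dYnull, c(xs[i], xs[i + 1]), tol = 1e-12)$root, 0)
  Xf1 <- folds[1]; Xf2 <- folds[2]
  Y1 <- fn$Ynull(Xf1); Y2 <- fn$Ynull(Xf2)   # Y1 = local min, Y2 = local max
  if (!(Y2 > Y1)) stop("unexpected fold ordering")

  Gn <- function(X) fn$G(X, fn$Ynull(X))
  # entry points of the two slow segments: Y = Y2 on the left branch,
  # Y = Y1 on the right branch
  X_a <- uniroot(function(X) fn$Ynull(X) - Y2,
                 c(x_range[1], Xf1 * (1 - 1e-9)), tol = 1e-13)$root
  X_b <- uniroot(function(X) fn$Ynull(X) - Y1,
                 c(Xf2 * (1 + 1e-9), x_range[2]), tol = 1e-12)$root
  seg <- function(from, to) {
    val <- integrate(function(X) fn$dYnull(X) / Gn(X), from, to,
                     rel.tol = 1e-9, subdivisions = 500L)$value
    if (val < 0) stop("slow drift reverses along a branch; ",
                      "not in the relaxation regime")
    val
  }
  t_left <- seg(X_a, Xf1)   # Y falls from Y2 to Y1 on the left branch
  t_right <- seg(X_b, Xf2)  # Y rises from Y1 to Y2 on the right branch
  T0 <- t_left + t_right

  delay <- 0
  if (correction) {
    eps <- params$structural[["eps"]]
    for (Xf in folds) {
      Yf <- fn$Ynull(Xf)
      Fxx <- params$rates[["v"]] *
        hill_d2(Xf, params$structural[["Kv"]], params$structural[["gamma"]]) /
        (params$structural[["h"]] + Yf)
      Fy <- -(params$rates[["k"]] + params$rates[["v"]] *
                hill(Xf, params$structural[["Kv"]],
                     params$structural[["gamma"]])) /
        (params$structural[["h"]] + Yf)^2
      Gf <- fn$G(Xf, Yf)
      delay <- delay + FOLD_DELAY_C *
        (eps^2 / (abs(Fxx) * abs(Fy * Gf)))^(1 / 3)
    }
  }
  if (detail)
    return(list(period = T0 + delay, period_singular = T0,
                fold_delay = delay,
                folds = data.frame(X = folds, Y = c(Y1, Y2)),
                segments = c(left = t_left, right = t_right)))
  T0 + delay
}
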