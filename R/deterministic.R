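#' Noise-free cycle maps phi and psi
#'
#' Evaluates the regression structure with all noise terms set to zero,
#' giving the deterministic maps from birth amount to division amount,
#' X2 = phi(X0), and to cycle duration, T = psi(X0) = T1 + T2. This is the
#' reduction of the stochastic model to a classical one-dimensional
#' size-regulation model.
#'
#' `phi_psi()` fails if any grid point yields a non-positive T1 or T2 (the
#' model is outside its meaningful domain there); [cycle_curves()] flags such
#' points instead of failing.
#'
#' @param x0 Numeric vector of birth amounts (> 0).
#' @param params A validated [prc1_params] object.
#' @return A tibble with columns `X0, X1, X2, T1, T2, T, a, b`.
#' @examples
#' phi_psi(1e5, prc1_params(1))
#' @export
phi_psi <- function(x0, params) {
  params <- validate_params(params)
  stopifnot(is.numeric(x0), all(x0 > 0))
  out <- eval_deterministic(x0, params$regression)
  if (any(!out$ok)) {
    bad <- x0[!out$ok][1]
    abort(sprintf(
      "Deterministic model yields non-positive T1 or T2 at X0 = %g (outside the model's domain).",
      bad))
  }
  dplyr::select(out, -"ok")
}

eval_deterministic <- function(x0, reg) {
  lna <- reg$b1 + reg$b10 * x0
  a <- exp(lna)
  t1_lin <- reg$b2 + reg$b21 * lna
  T1 <- if (identical(reg$t1_link, "log")) exp(t1_lin) else t1_lin
  X1 <- x0 * exp(-a * T1)
  b <- exp(reg$b4 + reg$b41 * lna + reg$b43 * X1)
  T2 <- reg$b5 + reg$b52 * T1
  X2 <- X1 * exp(b * T2)
  tibble(X0 = x0, X1 = X1, X2 = X2, T1 = T1, T2 = T2,
         T = T1 + T2, a = a, b = b,
         ok = is.finite(X2) & T1 > 0 & T2 > 0 & X1 > 0 & X2 > 0)
}

#' Deterministic cycle variables over a grid of birth amounts
#'
#' Vectorised [phi_psi()] over an increasing grid; grid points where the
#' deterministic model leaves its domain (non-positive durations or amounts)
#' are flagged in the `ok` column rather than dropped.
#'
#' @param params A validated [prc1_params] object.
#' @param x0_grid Increasing positive birth amounts.
#' @return A tibble of class `prc1_curves` with columns
#'   `X0, X1, X2, T1, T2, T, a, b, ok`.
#' @export
cycle_curves <- function(params, x0_grid) {
  params <- validate_params(params)
  stopifnot(is.numeric(x0_grid), all(x0_grid > 0), !is.unsorted(x0_grid))
  out <- eval_deterministic(x0_grid, params$regression)
  class(out) <- c("prc1_curves", class(out))
  out
}

#' Equilibria of the symmetric-division deterministic model
#'
#' Under exactly symmetric division each daughter starts with phi(X0) / 2, so
#' an equilibrium birth amount satisfies X0 = phi(X0) / 2. The search
#' grid-scans g(x) = phi(x)/2 - x on `n_scan` log-spaced points over
#' `interval`, then refines every sign change by bisection to relative
#' tolerance `tol`. A root is flagged stable when the numerical derivative of
#' phi(x)/2 at the root (central difference, step `1e-4 * x`) has magnitude
#' below 1.
#'
#' @param params A validated [prc1_params] object.
#' @param interval Positive search interval `c(x_lo, x_hi)`.
#' @param n_scan Number of log-spaced scan points (default 512).
#' @param tol Relative tolerance of the bisection (default 1e-8).
#' @return A tibble with columns `X0_star, stable, derivative`. When no sign
#'   change is found the tibble is empty and carries the scanned `g` values in
#'   attribute `scan` as a diagnosis aid.
#' @examples
#' find_equilibria(prc1_params(1))
#' @export
find_equilibria <- function(params, interval = c(1e3, 1e6), n_scan = 512,
                            tol = 1e-8) {
  params <- validate_params(params)
  stopifnot(length(interval) == 2, interval[1] > 0, interval[1] < interval[2])
  g_fun <- function(x) {
    ev <- eval_deterministic(x, params$regression)
    ifelse(ev$ok, ev$X2 / 2 - x, NA_real_)
  }
  xs <- exp(seq(log(interval[1]), log(interval[2]), length.out = n_scan))
  gs <- g_fun(xs)

  roots <- numeric()
  for (i in seq_len(n_scan - 1)) {
    g1 <- gs[i]; g2 <- gs[i + 1]
    if (is.na(g1) || is.na(g2)) next
    if (g1 == 0) { roots <- c(roots, xs[i]); next }
    if (sign(g1) * sign(g2) < 0) {
      roots <- c(roots, bisect(g_fun, xs[i], xs[i + 1], tol))
    }
  }
  if (gs[n_scan] == 0 && !is.na(gs[n_scan])) roots <- c(roots, xs[n_scan])
  roots <- unique(roots)

  if (length(roots) == 0) {
    out <- tibble(X0_star = numeric(), stable = logical(),
                  derivative = numeric())
    attr(out, "scan") <- tibble(X0 = xs, g = gs)
    return(out)
  }
  deriv <- vapply(roots, function(r) {
    h <- 1e-4 * r
    lo <- eval_deterministic(r - h, params$regression)
    hi <- eval_deterministic(r + h, params$regression)
    if (!lo$ok || !hi$ok) return(NA_real_)
    (hi$X2 / 2 - lo$X2 / 2) / (2 * h)
  }, numeric(1))
  tibble(X0_star = roots, stable = !is.na(deriv) & abs(deriv) < 1,
         derivative = deriv)
}

bisect <- function(f, lo, hi, tol) {
  flo <- f(lo)
  repeat {
    mid <- (lo + hi) / 2
    if ((hi - lo) <= tol * mid) return(mid)
    fm <- f(mid)
    if (is.na(fm) || fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
}

#' Asymmetric-division iteration of the deterministic map
#'
#' Iterates the one-daughter recursion X0' = U phi(X0), where the inherited
#' fraction U is i.i.d. Beta(alpha, alpha): the deterministic cycle model with
#' division asymmetry as the only source of randomness. The birth amounts X0
#' oscillate from generation to generation while the division amounts
#' X2 = phi(X0) are damped by the regulatory feedback.
#'
#' @param params A validated [prc1_params] object.
#' @param n_steps Number of generations to iterate (>= 1).
#' @param x0_init Initial birth amount; default is the symmetric-division
#'   equilibrium (see [find_equilibria()]).
#' @param seed Optional integer seed.
#' @return A tibble of class `prc1_iteration` with columns
#'   `step, X0, X2, U` (`U` is the fraction passed to the next step). If the
#'   deterministic map fails mid-iteration the series is truncated and the
#'   failure index stored in attribute `failure_index`.
#' @export
asymmetric_iteration <- function(params, n_steps, x0_init = NULL, seed = NULL) {
  params <- validate_params(params)
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  x0_init <- x0_init %||% default_ancestor_x0(params)
  alpha <- params$division$alpha

  X0 <- numeric(n_steps); X2 <- numeric(n_steps); U <- numeric(n_steps)
  x <- x0_init
  failure <- NA_integer_
  for (i in seq_len(n_steps)) {
    ev <- eval_deterministic(x, params$regression)
    if (!ev$ok) { failure <- i; break }
    X0[i] <- x
    X2[i] <- ev$X2
    U[i] <- rbeta(1, alpha, alpha)
    x <- U[i] * X2[i]
  }
  n_done <- if (is.na(failure)) n_steps else failure - 1L
  out <- tibble(step = seq_len(n_done), X0 = X0[seq_len(n_done)],
                X2 = X2[seq_len(n_done)], U = U[seq_len(n_done)])
  class(out) <- c("prc1_iteration", class(out))
  if (!is.na(failure)) attr(out, "failure_index") <- failure
  out
}
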