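# shared fixtures built in code

# parameter set k with all four noise dispersions forced to zero
zero_noise_params <- function(k = 1) {
  p <- prc1_params(k)
  p$regression[c("s_a", "s_T1", "s_b", "s_T2")] <- list(0, 0, 0, 0)
  validate_params(p)
}

# hand-evaluated zero-noise cycle for data set 1 at X0 = 1e5: the oracle is
# plain arithmetic on the fixture coefficients, independent of the simulator
oracle_cycle_ds1 <- function(x0 = 1e5) {
  lna <- -1.600 + 3.9e-6 * x0
  a <- exp(lna)
  T1 <- exp(1.110 - 0.514 * lna)
  X1 <- x0 * exp(-a * T1)
  b <- exp(-1.570 - 0.100 * lna - 1.78e-5 * X1)
  T2 <- 19.970 - 0.6564 * T1
  list(a = a, T1 = T1, X1 = X1, b = b, T2 = T2, X2 = X1 * exp(b * T2))
}

# minimal ad-hoc parameter object for structural tests
toy_params <- function(b10 = 0, b43 = 0, alpha = 20) {
  new_prc1_params(
    regression = list(b1 = -1.2, b10 = b10, b2 = 1.5, b21 = 0,
                      b4 = -2, b41 = 0, b43 = b43, b5 = 12, b52 = 0,
                      s_a = 0, s_T1 = 0, s_b = 0, s_T2 = 0,
                      t1_link = "log", noise_convention = "sd"),
    division = list(alpha = alpha)
  )
}

# strictly V-shaped piecewise-exponential trajectory on a fine grid
v_trajectory <- function(x0 = 100, x1 = 10, x2 = 200, t1 = 1, t2 = 2,
                         dt = 0.001, cell_id = 1L) {
  a <- log(x0 / x1) / t1
  b <- log(x2 / x1) / t2
  tt <- seq(0, t1 + t2, by = dt)
  v <- ifelse(tt <= t1, x0 * exp(-a * tt), x1 * exp(b * (tt - t1)))
  tibble::tibble(cell_id = cell_id, parent_id = NA_integer_, time = tt, value = v)
}
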