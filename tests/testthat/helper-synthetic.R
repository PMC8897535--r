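# shared fixtures: a dense sampling grid, a default input function, and an
# independent brute-force ODE oracle for the 2TC forward model

dense_times <- function(end = 63) {
  sort(unique(c(seq(0, 3, by = 1 / 60), seq(3, end, by = 0.05))))
}

make_test_if <- function(params = feng_params(), end = 63) {
  simulate_input_function(params, dense_times(end))
}

# brute-force fixed-step RK4 integration of the compartment ODEs, driven by
# the same piecewise-linear input function; independent of the package's
# analytic convolution solver
ode_2tc_oracle <- function(kp, input_fn, times, dt = 0.001) {
  kp <- unname(unlist(kp))
  K1 <- kp[1]; k2 <- kp[2]; k3 <- kp[3]
  k4 <- if (length(kp) >= 4) kp[4] else 0
  cpf <- stats::approxfun(input_fn$time, input_fn$cp, yleft = 0, rule = 2)
  deriv <- function(t, y, parms) {
    list(c(K1 * cpf(t) - (k2 + k3) * y[1] + k4 * y[2],
           k3 * y[1] - k4 * y[2]))
  }
  grid <- seq(0, max(times), by = dt)
  out <- deSolve::ode(y = c(C1 = 0, C2 = 0), times = grid, func = deriv,
                      parms = NULL, method = "rk4")
  ct <- out[, "C1"] + out[, "C2"]
  stats::approx(grid, ct, xout = times)$y
}

# small TAC helper around a data.frame
tac_df <- function(schedule, activity) {
  data.frame(start = schedule$start, end = schedule$end,
             mid = schedule$mid, activity = activity)
}
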