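# Shared fixtures and independent reference implementations.

# small noiseless synthetic trial with constant injected stiffness
noiseless_trial <- function(n_strides = 10, k = 20000, v = 2.5, seed = 1) {
  proc <- stiffness_process_spec(k, numeric(), 0, n_strides = n_strides,
                                 seed = seed)
  assemble_trial(proc, slip_params(), noise_spec(0, 0, seed), v = v)
}

# a hand-made stance phase with arbitrary channels (for estimator fixtures)
toy_stance <- function(x, y, F_y, stride_index = 0) {
  stance_phase(stride_index, c(0, length(x)), x, y, F_y)
}

# Independent direct-summation sample ACF: literal double loop over the
# defining sums, no vectorisation shared with the package implementation.
ref_acf <- function(x, max_lag) {
  n <- length(x)
  xbar <- sum(x) / n
  g <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    s <- 0
    for (t in 1:(n - k)) s <- s + (x[t] - xbar) * (x[t + k] - xbar)
    g[k + 1] <- s / n
  }
  g[-1] / g[1]
}

# Independent Ljung-Box Q from the reference ACF
ref_ljung_box_Q <- function(x, m) {
  n <- length(x)
  rho <- ref_acf(x, m)
  s <- 0
  for (k in 1:m) s <- s + rho[k]^2 / (n - k)
  n * (n + 2) * s
}
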