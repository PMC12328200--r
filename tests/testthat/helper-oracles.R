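# Independent oracles used to validate the package's closed forms and solver.
# These deliberately avoid the code paths they check.

# Brute-force continuous-time Monte Carlo of the two-state aldehyde chain:
# flip to the other enantiomer at rate k_e (per direction), absorb by
# reduction at rate k_r from either state. Returns the fraction of trials
# absorbed from the enantiomer opposite to the starting one.
ctmc_flip_oracle <- function(k_e, k_r, n_trials) {
  parity <- logical(n_trials)  # TRUE = currently opposite enantiomer
  alive <- rep(TRUE, n_trials)
  while (any(alive)) {
    m <- sum(alive)
    t_flip <- if (k_e > 0) stats::rexp(m, k_e) else rep(Inf, m)
    t_red <- stats::rexp(m, k_r)
    flips <- t_flip < t_red
    idx <- which(alive)
    parity[idx[flips]] <- !parity[idx[flips]]
    alive[idx[!flips]] <- FALSE
  }
  mean(parity)
}

# Fixed-step classical RK4 integrator, independent of deSolve.
rk4_integrate <- function(rhs, y0, times, dt, parms) {
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0),
                dimnames = list(NULL, names(y0)))
  y <- y0
  t <- times[1]
  out[1, ] <- y
  for (i in 2:length(times)) {
    t_target <- times[i]
    while (t < t_target - 1e-12) {
      h <- min(dt, t_target - t)
      k1 <- rhs(t, y, parms)[[1]]
      k2 <- rhs(t + h / 2, y + h / 2 * k1, parms)[[1]]
      k3 <- rhs(t + h / 2, y + h / 2 * k2, parms)[[1]]
      k4 <- rhs(t + h, y + h * k3, parms)[[1]]
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}

# standard operating conditions used across tests
std_params <- function(...) rate_parameters(...)

expect_within <- function(object, expected, tol_frac) {
  expect_lt(abs(object - expected), tol_frac * abs(expected))
}
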