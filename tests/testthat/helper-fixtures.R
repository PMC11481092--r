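# Shared fixtures for the test suite.  Everything is generated in code.

# A tiny 2-variable space for optimizer tests.
toy_space_2d <- function() {
  design_space(
    variable_spec("a", "degC", 0, 10, "temperature"),
    variable_spec("b", "min", 0, 1, "residence_time")
  )
}

# Smooth concave objective on the unit square with a known interior optimum.
toy_concave <- function(opt = c(0.3, 0.7), height = 0.9) {
  function(u) height * exp(-4 * sum((u - opt)^2))
}

# Fixed-step classical RK4 reference integrator for the amidation network;
# independent of the deSolve path used by the package.
rk4_step2 <- function(y0, k2, k_h, k_da, tau, n_steps = 2000) {
  rhs <- function(y) {
    r2 <- k2 * y[1] * y[2]
    rh <- k_h * y[2] * y[5]
    rda <- k_da * y[3] * y[2]
    c(-r2, -r2 - rh - rda, r2 - rda, rda, -rh, r2 + 2 * rh + rda)
  }
  h <- tau / n_steps
  y <- y0
  for (i in seq_len(n_steps)) {
    k1 <- rhs(y); k2v <- rhs(y + h / 2 * k1); k3 <- rhs(y + h / 2 * k2v)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2v + 2 * k3 + k4)
  }
  y
}

# Quick campaign settings used where the campaign mechanics, not the
# optimum, are under test.
quick_config <- function(budget = 12L) {
  campaign_config(budget = budget, monitoring_interval = 4L,
                  plateau_window = 3L, plateau_delta = 0.005)
}
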