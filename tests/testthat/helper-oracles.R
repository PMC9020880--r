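# Independent oracles used across tests.

# fixed-step classical RK4 integration of the radial dynamics, independent
# of the deSolve-based path in the package (only the algebraic RHS is
# shared physics, re-derived here from the equation)
km_rk4_oracle <- function(R0 = 2e-6, t_end = 2.5e-6, n_steps = 200000L,
                          P_a = 130e3, f = 1e6,
                          rho = 1055, c0 = 1500, mu = 0.005, sigma = 0.072,
                          Pinf = 104600, k = 1) {
  pg0 <- Pinf + 2 * sigma / R0
  pdrv <- function(t) -P_a * sin(2 * pi * f * t)
  rhs <- function(t, y) {
    R <- y[1L]; Rd <- y[2L]
    pg <- pg0 * (R0 / R)^(3 * k)
    Pb <- pg - 2 * sigma / R - 4 * mu * Rd / R
    A <- -3 * k * pg * Rd / R + 2 * sigma * Rd / R^2 + 4 * mu * Rd^2 / R^2
    num <- R / (rho * c0) * A +
      (1 + Rd / c0) * (Pb - Pinf - pdrv(t)) / rho -
      1.5 * (1 - Rd / (3 * c0)) * Rd^2
    den <- (1 - Rd / c0) * R + 4 * mu / (rho * c0)
    c(Rd, num / den)
  }
  h <- t_end / n_steps
  y <- c(R0, 0)
  times <- seq(0, t_end, by = h)
  out <- matrix(0, length(times), 2L)
  out[1L, ] <- y
  for (i in seq_len(n_steps)) {
    t <- times[i]
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- y
  }
  list(times = times, R = out[, 1L], Rd = out[, 2L])
}

# literal transcription of the thick-cylinder hoop stress formula,
# written independently of the package implementation
lame_oracle <- function(P_i, r_i, r_o, r) {
  term1 <- (P_i * r_i^2) / (r_o^2 - r_i^2)
  term2 <- (r_i^2 * r_o^2 / r^2) * P_i / (r_o^2 - r_i^2)
  term1 + term2
}

# quick small meshes shared between tests (built once per test session)
.fixture_env <- new.env()

# memoized default-case RK4 oracle (shared by the unit and acceptance tests)
km_rk4_default <- function() {
  if (is.null(.fixture_env$rk4)) {
    .fixture_env$rk4 <- km_rk4_oracle(t_end = 2.5e-6, n_steps = 50000L)
  }
  .fixture_env$rk4
}
fixture_mesh <- function(key = "default_coarse") {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- switch(
      key,
      default_coarse = generate_mesh(geometry_spec(), "coarse"),
      offset_coarse = generate_mesh(geometry_spec(bubble_offset = 4e-6),
                                    "coarse"),
      stop("unknown fixture mesh"))
  }
  .fixture_env[[key]]
}
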