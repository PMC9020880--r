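# Radial (Keller-Miksis) tier: drive waveform, equation terms, integration
# and trace utilities.

test_that("drive waveform is rarefaction-first, periodic and windowed", {
  dr <- ultrasound_drive()
  expect_equal(drive_pressure(0, dr), 0)
  expect_equal(drive_pressure(0.25e-6, dr), -130e3)
  ts <- seq(0, 3e-6, by = 1e-8)
  expect_equal(drive_pressure(ts, dr), drive_pressure(ts + 1e-6, dr),
               tolerance = 1e-12)
  dr2 <- ultrasound_drive(burst_duration = 1e-6)
  expect_equal(drive_pressure(1.5e-6, dr2), 0)
  expect_error(drive_pressure(-1, dr), "t must be")
})

test_that("radial acceleration vanishes at equilibrium and matches the
           impulsive-start closed form", {
  fl <- fluid_properties()
  gs <- gas_model(fluid = fl)
  d0 <- km_derivatives(0, 2e-6, 0, fl, gs, ultrasound_drive(amplitude = 0))
  expect_equal(d0$Rddot, 0, tolerance = 1e-9)
  # quarter period: instantaneous acoustic pressure -130 kPa at R = R0,
  # Rdot = 0; algebraic solution 1.3e5 / (rho R0 + 4 mu / c)
  d1 <- km_derivatives(0.25e-6, 2e-6, 0, fl, gs, ultrasound_drive())
  expect_equal(d1$Rddot, 1.3e5 / (1055 * 2e-6 + 4 * 0.005 / 1500),
               tolerance = 1e-10)
  expect_error(km_derivatives(0, -1e-6, 0, fl, gs), "breakdown")
  expect_error(km_derivatives(0, 2e-6, 2000, fl, gs), "breakdown")
})

test_that("the compressibility correction vanishes in the large-sound-speed
           limit (Rayleigh-Plesset)", {
  fl <- fluid_properties(sound_speed = 1e9)
  gs <- gas_model(fluid = fl)
  dr <- ultrasound_drive()
  R <- 2.5e-6; Rd <- 5
  d <- km_derivatives(1e-7, R, Rd, fl, gs, dr)
  # Rayleigh-Plesset: R Rdd + 1.5 Rd^2 = (Pb - Pinf - p)/rho
  pg <- gs$equilibrium_gas_pressure * (gs$equilibrium_radius / R)^3
  Pb <- pg - 2 * fl$surface_tension / R - 4 * fl$viscosity * Rd / R
  p <- drive_pressure(1e-7, dr)
  rp <- ((Pb - fl$ambient_pressure - p) / fl$density - 1.5 * Rd^2) / R
  expect_equal(d$Rddot, rp, tolerance = 1e-4)
})

test_that("zero drive leaves the radius at equilibrium to 1e-6 relative", {
  tr <- solve_km(drive = ultrasound_drive(amplitude = 0), t_end = 1e-5,
                 n_samples = 500)
  expect_lt(max(abs(tr$radii - 2e-6)) / 2e-6, 1e-6)
})

test_that("default-drive extrema agree with an independent fixed-step
           integration to 0.1%", {
  tr <- solve_km(t_end = 2.5e-6, n_samples = 2000)
  orc <- km_rk4_default()
  expect_lt(abs(max(tr$radii) - max(orc$R)) / max(orc$R), 1e-3)
  expect_lt(abs(min(tr$radii) - min(orc$R)) / min(orc$R), 1e-3)
  # re-substitution residual of the integrated trace
  expect_lt(km_residual(tr), 5e-3)
})

test_that("small-amplitude free oscillation matches the linearized
           resonance frequency within 1%", {
  fl <- fluid_properties()
  gs <- gas_model(fluid = fl)
  f0 <- linear_resonance_frequency(fl, gs)
  # free oscillation from a slightly perturbed radius, no drive
  R0 <- 2e-6
  tr <- solve_km(fl, gas_model(fluid = fl, equilibrium_radius = R0),
                 ultrasound_drive(amplitude = 0), R0 = R0, t_end = 4e-6,
                 n_samples = 8000)
  # kick it: integrate from perturbed initial radius instead
  rhs <- function(t, y, parms) {
    d <- km_derivatives(t, y[1], y[2], fl, gs,
                        ultrasound_drive(amplitude = 0))
    list(c(d$Rdot, d$Rddot))
  }
  sol <- deSolve::ode(c(R = R0 * 1.001, Rdot = 0),
                      seq(0, 4e-6, length.out = 8001), rhs, NULL,
                      rtol = 1e-10, atol = c(1e-14, 1e-8))
  R <- sol[, 2]
  # measure the period from zero crossings of R - R0
  s <- sign(R - R0)
  cross <- which(diff(s) != 0)
  periods <- diff(sol[cross, 1])
  f_meas <- 1 / (2 * mean(periods))
  # the observed frequency is the damped one; remove the viscous damping
  # shift (beta = 2 mu / (rho R0^2)) before comparing with the undamped
  # linearized formula
  beta <- 2 * fl$viscosity / (fl$density * R0^2)
  f_undamped <- sqrt(f_meas^2 + (beta / (2 * pi))^2)
  expect_lt(abs(f_undamped - f0) / f0, 0.01)
})

test_that("resonance frequency has the Minnaert limit and the stated
           default value, and decreases with radius", {
  fl0 <- fluid_properties(surface_tension = 1e-12)
  f_minn <- 1 / (2 * pi * 2e-6) * sqrt(3 * fl0$ambient_pressure / fl0$density)
  expect_equal(linear_resonance_frequency(fl0, gas_model(fluid = fl0)),
               f_minn, tolerance = 1e-6)
  # defaults: ~1.66 MHz (direct arithmetic on the linearized formula)
  f0 <- linear_resonance_frequency()
  expect_equal(f0, sqrt((3 * (104600 + 72000) - 72000) /
                          (1055 * (2e-6)^2)) / (2 * pi), tolerance = 1e-12)
  expect_equal(round(f0 / 1e6, 2), 1.66)
  f_big <- linear_resonance_frequency(R0 = 4e-6)
  expect_lt(f_big, f0)
})

test_that("small-amplitude driven response matches the linear harmonic
           amplitude within 5%", {
  fl <- fluid_properties()
  gs <- gas_model(fluid = fl)
  dr <- ultrasound_drive(amplitude = 1e3)
  tr <- solve_km(fl, gs, dr, t_end = 2e-5, n_samples = 20000)
  # steady-state amplitude over the last quarter of the run
  tail_idx <- tr$times > 1.5e-5
  amp <- (max(tr$radii[tail_idx]) - min(tr$radii[tail_idx])) / 2
  # linear oscillator response: x'' + 2 b x' + w0^2 x = (Pa/(rho R0)) sin(wt)
  w0 <- 2 * pi * linear_resonance_frequency(fl, gs)
  w <- 2 * pi * dr$frequency
  b <- 2 * fl$viscosity / (fl$density * (2e-6)^2)
  amp_lin <- (dr$amplitude / (fl$density * 2e-6)) /
    sqrt((w0^2 - w^2)^2 + (2 * b * w)^2)
  expect_lt(abs(amp - amp_lin) / amp_lin, 0.05)
})

test_that("with the drive off, oscillation amplitude decays cycle to
           cycle", {
  fl <- fluid_properties()
  gs <- gas_model(fluid = fl)
  rhs <- function(t, y, parms) {
    d <- km_derivatives(t, y[1], y[2], fl, gs,
                        ultrasound_drive(amplitude = 0))
    list(c(d$Rdot, d$Rddot))
  }
  sol <- deSolve::ode(c(R = 2.2e-6, Rdot = 0),
                      seq(0, 6e-6, length.out = 6001), rhs, NULL,
                      rtol = 1e-10, atol = c(1e-14, 1e-8))
  R <- sol[, 2]
  pk <- which(diff(sign(diff(R))) == -2) + 1L
  expect_gt(length(pk), 3)
  expect_true(all(diff(R[pk]) < 1e-15))
})

test_that("rms deviation handles normalizations, resampling and disjoint
           ranges", {
  t <- seq(0, 1e-6, length.out = 101)
  a <- radius_trace(t, rep(2e-6, 101), rep(0, 101),
                    params = list(R0 = 2e-6))
  expect_equal(rms_deviation(a, a), 0)
  b <- radius_trace(t, rep(2e-6, 101) * 1.02, rep(0, 101))
  expect_equal(rms_deviation(a, b, R0 = 2e-6), 2, tolerance = 1e-10)
  # scaled trace with reference normalization: 10% exactly
  t3 <- c(0, 0.5e-6, 1e-6)
  a3 <- radius_trace(t3, c(1.8e-6, 2.2e-6, 2.0e-6), rep(0, 3))
  b3 <- radius_trace(t3, 1.1 * c(1.8e-6, 2.2e-6, 2.0e-6), rep(0, 3))
  expect_equal(rms_deviation(a3, b3, normalization = "reference_trace"),
               10, tolerance = 1e-10)
  c3 <- radius_trace(t3 + 5e-6, c(1.8e-6, 2.2e-6, 2.0e-6), rep(0, 3))
  expect_error(rms_deviation(a3, c3), "disjoint")
})

test_that("radius traces round-trip through CSV with JSON metadata", {
  tr <- solve_km(t_end = 5e-7, n_samples = 100)
  path <- tempfile(fileext = ".csv")
  write_radius_trace(tr, path)
  back <- read_radius_trace(path)
  expect_equal(back$radii, tr$radii, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(meta$drive$frequency, 1e6)
})

test_that("collapse beyond the guard radius raises with a diagnostic", {
  # at 170 kPa the collapse dips to ~0.29 R0 (still subsonic walls), so a
  # guard at 0.4 R0 must trip
  expect_error(
    solve_km(drive = ultrasound_drive(amplitude = 170e3),
             t_end = 2.5e-6, collapse_eps = 0.4),
    "collapsed")
})
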