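# Wall stress formulas and extraction.

test_that("hoop stress matches the closed-form examples", {
  expect_equal(lame_hoop_stress(0, 10e-6, 11e-6), 0)
  # P_i = 100 kPa, r = r_i: 100 * (r_o^2 + r_i^2) / (r_o^2 - r_i^2) kPa
  expect_equal(lame_hoop_stress(100e3, 10e-6, 11e-6, 10e-6),
               100e3 * 221 / 21, tolerance = 1e-12)
  # infinitely thick wall: sigma -> P_i at the inner surface
  expect_equal(lame_hoop_stress(5e4, 10e-6, 1e-2, 10e-6) / 5e4, 1,
               tolerance = 1e-5)
  expect_error(lame_hoop_stress(1e5, 10e-6, 9e-6), "exceed")
  expect_error(lame_hoop_stress(1e5, 10e-6, 11e-6, 12e-6), "outside")
})

test_that("hoop stress equals an independent transcription on random
           parameter tuples and is linear in the pressure", {
  set.seed(42)
  for (i in 1:100) {
    r_i <- runif(1, 1e-6, 50e-6)
    r_o <- r_i * runif(1, 1.01, 3)
    r <- runif(1, r_i, r_o)
    P <- runif(1, -5e5, 5e5)
    expect_equal(lame_hoop_stress(P, r_i, r_o, r), lame_oracle(P, r_i, r_o, r),
                 tolerance = 1e-12)
    expect_equal(lame_hoop_stress(2 * P, r_i, r_o, r),
                 2 * lame_hoop_stress(P, r_i, r_o, r), tolerance = 1e-12)
  }
})

test_that("wall shear recovers a linear shear flow and vanishes for rigid
           motion", {
  mu <- 0.005
  G <- matrix(0, 3, 3); G[2, 3] <- 7       # v_y = 7 z
  expect_equal(wall_shear(G, c(0, 1, 0), mu), mu * 7, tolerance = 1e-14)
  # rigid rotation: antisymmetric gradient -> zero viscous traction
  W <- matrix(c(0, -3, 1, 3, 0, -2, -1, 2, 0), 3, 3)
  expect_equal(wall_shear(W, c(0, 1, 0), mu), 0, tolerance = 1e-14)
  expect_equal(wall_shear(W, c(0.6, 0.8, 0), mu, "tangential_magnitude"), 0,
               tolerance = 1e-12)
})

test_that("wall shear matches the manufactured quadratic field", {
  # v_y = a z^2, v_z = b y^2 at (y, z) = (r_i, 0):
  # tau_yz = mu (dv_y/dz + dv_z/dy) = mu (0 + 2 b r_i)
  a <- 3; b <- 5; r_i <- 10e-6; mu <- 0.005
  G <- matrix(0, 3, 3)
  G[2, 3] <- 2 * a * 0       # dv_y/dz at z = 0
  G[3, 2] <- 2 * b * r_i     # dv_z/dy at y = r_i
  expect_equal(wall_shear(G, c(0, 1, 0), mu), 2 * mu * b * r_i,
               tolerance = 1e-14)
  # linearity in viscosity for the fixed kinematic field
  expect_equal(wall_shear(G, c(0, 1, 0), 2 * mu),
               2 * wall_shear(G, c(0, 1, 0), mu), tolerance = 1e-14)
})

test_that("stress summaries locate extrema of synthetic traces", {
  t <- seq(0, 1e-6, length.out = 401)
  mk <- function(th, amp) {
    df <- data.frame(times = t, P_i = 0,
                     sigma_cr = amp * sin(2 * pi * 1e6 * t),
                     tau = -amp / 10 * sin(2 * pi * 1e6 * t))
    attr(df, "theta_deg") <- th
    class(df) <- c("wall_stress_trace", "data.frame")
    df
  }
  traces <- list(mk(0, 2e5), mk(90, 1e5))
  s <- summarize_stresses(traces)
  expect_equal(s$global$max_sigma_cr, 2e5, tolerance = 1e-3)
  expect_equal(s$global$sigma_angle, 0)
  expect_equal(s$per_angle$t_max_sigma[1], 0.25e-6, tolerance = 1e-8)
  expect_equal(s$per_angle$min_sigma_cr[2], -1e5, tolerance = 1e-3)
  # constant trace: max == min == constant
  cst <- mk(45, 0); cst$sigma_cr <- 7; cst$tau <- 7
  sc <- summarize_stresses(list(cst))
  expect_equal(sc$per_angle$max_sigma_cr, sc$per_angle$min_sigma_cr)
})
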