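test_that("womersley_number matches the laboratory operating points", {
  geo <- lab_geometry()
  # inverse check of the tabulated design frequencies at the scaled geometry
  expect_equal(womersley_number(geo, fluid_properties(1225.6, 1.05e-4),
                                bpm_to_omega(24)), 2, tolerance = 0.01)
  expect_equal(womersley_number(geo, fluid_properties(1202.2, 3.83e-5),
                                bpm_to_omega(35)), 4, tolerance = 0.01)
  # identity case and exact sqrt scaling in omega
  g1 <- canal_geometry(2, 1)
  f1 <- fluid_properties(1, 1)
  expect_identical(womersley_number(g1, f1, 1), 1)
  for (om in c(0.3, 1, 4.7)) {
    expect_identical(womersley_number(g1, f1, 2 * om),
                     sqrt(2) * womersley_number(g1, f1, om))
  }
})

test_that("womersley_number rejects non-positive inputs by field name", {
  expect_error(canal_geometry(-1, 0.01), "length_L")
  expect_error(fluid_properties(1000, 0), "kin_viscosity_nu")
  expect_error(womersley_number(canal_geometry(1, 0.1),
                                fluid_properties(1, 1), -2), "omega")
})

test_that("stroke_metrics recovers stroke volume for harmonic and square waves", {
  geo <- canal_geometry(0.158, 0.013)
  omega <- 2 * pi
  Vs <- 80e-6
  n_per <- 1000L
  rate <- n_per * omega / (2 * pi)
  t <- (0:(4 * n_per)) / rate    # 4 whole cycles, endpoint included
  q <- 0.5 * Vs * omega * sin(omega * t)
  sm <- stroke_metrics(q, geo, omega, rate = rate)
  expect_equal(sm$Vs, Vs, tolerance = 1e-3)
  expect_equal(sm$Ls, Vs / (pi * 0.013^2), tolerance = 1e-3)

  # square wave +-Q0: Vs = Q0 T / 2 = pi Q0 / omega (exact for the
  # trapezoidal rule since |Q| is constant)
  Q0 <- 3e-5
  qs <- Q0 * sign(sin(omega * t + 1e-9))
  expect_equal(stroke_metrics(qs, geo, omega, rate = rate)$Vs,
               pi * Q0 / omega, tolerance = 1e-6)

  # Ls/L = 1 when Vs = pi a^2 L
  Vs1 <- pi * 0.013^2 * 0.158
  q1 <- 0.5 * Vs1 * omega * sin(omega * t)
  expect_equal(stroke_metrics(q1, geo, omega, rate = rate)$Ls_over_L, 1,
               tolerance = 1e-3)
})

test_that("stroke_metrics rejects fractional-cycle and degenerate traces", {
  geo <- canal_geometry(0.1, 0.01)
  t <- seq(0, 1.37 * 2 * pi, by = 2 * pi / 500)
  expect_error(stroke_metrics(sin(t), geo, omega = 1, rate = 500 / (2 * pi)),
               "non-integer")
  expect_error(mean_abs_cycle(numeric(0), 1, rate = 10), "length >= 2")
})

test_that("mean_abs_cycle reproduces analytic and brute-force values", {
  n_per <- 2000L
  rate <- n_per / (2 * pi)
  t <- (0:(2 * n_per)) / rate
  A <- 2.7
  expect_equal(mean_abs_cycle(A * sin(t), 1, rate = rate), 2 * A / pi,
               tolerance = 1e-4)
  expect_equal(mean_abs_cycle(rep(-1.3, length(t)), 1, rate = rate), 1.3)

  # anharmonic case against a 1e6-point trapezoid oracle
  f <- function(tau) sin(tau) + sin(3 * tau) / 3
  tau_fine <- seq(0, 2 * pi, length.out = 1e6 + 1)
  oracle <- pracma::trapz(tau_fine, abs(f(tau_fine))) / (2 * pi)
  expect_equal(mean_abs_cycle(f(t), 1, rate = rate), oracle, tolerance = 1e-4)
})

test_that("mean_abs_cycle is positively homogeneous", {
  n_per <- 512L
  rate <- n_per / (2 * pi)
  t <- (0:(3 * n_per)) / rate
  set.seed(11)
  x <- sin(t) + 0.4 * sin(2 * t + 1) + 0.1 * cos(5 * t)
  m0 <- mean_abs_cycle(x, 1, rate = rate)
  for (c_ in c(-3.2, -1, 0.25, 7)) {
    expect_equal(mean_abs_cycle(c_ * x, 1, rate = rate), abs(c_) * m0,
                 tolerance = 1e-12)
  }
})

test_that("nondimensionalize applies the pressure and flow scales", {
  geo <- canal_geometry(0.158, 0.013)
  fl <- fluid_properties(1225.6, 1.05e-4)
  omega <- bpm_to_omega(24)
  Vs <- pi * 0.013^2 * 0.158            # Ls/L = 1
  Ls <- Vs / (pi * 0.013^2)
  rate <- 80
  t <- (0:1999) / rate
  q <- signal_trace(0.5 * Vs * omega * sin(omega * t), rate, units = "m3/s")
  p <- signal_trace(fl$density_rho * omega^2 * 0.158 * Ls * cos(omega * t),
                    rate, units = "Pa")
  dw <- nondimensionalize(p, q, fl, geo, omega, Ls)
  # harmonic flow maps to Qbar = (1/2) sin(tau)
  expect_equal(max(abs(dw$Qbar)), 0.5, tolerance = 1e-3)
  expect_equal(dw$Qbar, 0.5 * sin(dw$tau), tolerance = 1e-9)
  # unit-scale pressure maps to Pi with amplitude 1
  expect_equal(max(abs(dw$Pi)), 1, tolerance = 1e-3)

  # constant pressure equal to the scale maps to Pi = 1 exactly
  pc <- signal_trace(rep(fl$density_rho * omega^2 * 0.158 * Ls, length(t)),
                     rate, units = "Pa")
  expect_equal(nondimensionalize(pc, q, fl, geo, omega, Ls)$Pi,
               rep(1, length(t)))

  # round trip reproduces the inputs to 1e-12 relative
  back <- redimensionalize(dw)
  expect_equal(back$pressure$values, p$values, tolerance = 1e-12)
  expect_equal(back$flow$values, q$values, tolerance = 1e-12)

  # mismatched channels are rejected
  q_short <- signal_trace(q$values[1:100], rate, units = "m3/s")
  expect_error(nondimensionalize(p, q_short, fl, geo, omega, Ls), "length")
  q_wrong <- signal_trace(q$values, 81, units = "m3/s")
  expect_error(nondimensionalize(p, q_wrong, fl, geo, omega, Ls), "rate")
})

test_that("dimensionless_groups warns outside the physiological envelope", {
  expect_warning(dimensionless_groups(alpha = 8, Ls_over_L = 1, a_over_L = 0.08),
                 "alpha")
  expect_warning(dimensionless_groups(alpha = 3, Ls_over_L = 3, a_over_L = 0.08),
                 "Ls/L")
  expect_silent(dimensionless_groups(alpha = 3, Ls_over_L = 1, a_over_L = 0.08))
})

test_that("trim_cycles keeps whole periods and counts them", {
  rate <- 100
  omega <- 2 * pi          # 1 Hz, 100 samples per cycle
  x <- sin(omega * (0:549) / rate)   # 5.49 cycles
  tr <- trim_cycles(x, omega, rate = rate)
  expect_identical(attr(tr, "n_cycles"), 5)
  expect_equal(length(tr$values), 501L)
  expect_error(trim_cycles(x[1:50], omega, rate = rate), "less than one")
})
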