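test_that("womersley_impedance has the viscous and inertial limits", {
  # alpha -> 0: quasi-steady Poiseuille friction, |Z| -> 8/alpha^2, phase -> 0
  z <- womersley_impedance(0.01)
  expect_equal(Mod(z), 8 / 0.01^2, tolerance = 1e-4)
  expect_lt(Arg(z), 1e-3)
  # alpha -> infinity: pure inertia, Z -> i n
  z100 <- womersley_impedance(100)
  expect_equal(z100, 0 + 1i, tolerance = 0.02)
  z100_3 <- womersley_impedance(100, n = 3)
  expect_equal(z100_3 / 3, 0 + 1i, tolerance = 0.02)
  # asymptotic branch joins the continued fraction smoothly
  expect_lt(Mod(womersley_impedance(199.99) - womersley_impedance(200.01)),
            1e-5)
})

test_that("womersley_impedance agrees with a radial finite-difference solution", {
  for (alpha in c(0.5, 2, 4)) {
    for (n in c(1L, 3L)) {
      z_fd <- fd_womersley_impedance(alpha, n)
      z <- womersley_impedance(alpha, n)
      expect_lt(Mod(z - z_fd) / Mod(z_fd), 1e-3)
    }
  }
})

test_that("womersley_impedance validates its inputs", {
  expect_error(womersley_impedance(-1), "alpha")
  expect_error(womersley_impedance(2, n = 0), "harmonic")
  expect_error(womersley_impedance(1e7), "cap the number of harmonics")
})

test_that("harmonic_decomposition inverts a synthesized waveform", {
  tau <- 2 * pi * (0:255) / 256
  cn_true <- c(-0.5i, 0.2 * exp(1.3i), 0.05 * exp(-0.4i))
  q <- Re(cn_true[1] * exp(1i * tau)) + Re(cn_true[2] * exp(2i * tau)) +
    Re(cn_true[3] * exp(3i * tau))
  hd <- harmonic_decomposition(q, n_harmonics = 3)
  expect_equal(hd$coefficients, cn_true, tolerance = 1e-12)
  # net volume flux is rejected
  expect_error(harmonic_decomposition(q + 0.3), "net volume flux")
  # poor truncation warns about reconstruction error (sin^3 has a 25%
  # third-harmonic component that 2 harmonics cannot represent)
  expect_warning(harmonic_decomposition(sin(tau)^3, n_harmonics = 2),
                 "reconstruction")
})

test_that("harmonic-waveform predictions reach both analytic limits", {
  # Poiseuille: Pi = (4/alpha^2) sin(tau), mean|Pi| = 8/(pi alpha^2)
  p_small <- predict(aqueduct_model(alpha = 0.1, Ls_over_L = 1,
                                    entrance_loss_K = 0, warn = FALSE))
  expect_equal(p_small$mean_abs_Pi, (2 / pi) * 4 / 0.1^2, tolerance = 0.01)
  expect_lt(abs(p_small$phase_lag), 0.01)
  # inviscid: Pi -> (1/2) cos(tau), mean|Pi| -> 1/pi, phi -> pi/2; at
  # alpha = 100 the exact solution still carries a sqrt(2)/alpha viscous
  # correction (~1.4%)
  p_big <- predict(aqueduct_model(alpha = 100, Ls_over_L = 1,
                                  entrance_loss_K = 0, warn = FALSE))
  expect_equal(p_big$mean_abs_Pi, 1 / pi, tolerance = 0.02)
  expect_equal(p_big$phase_lag, pi / 2, tolerance = 0.02)
})

test_that("predictions are linear in the waveform when K = 0", {
  tau <- 2 * pi * (0:127) / 128
  q1 <- sin(tau)
  q2 <- 0.4 * sin(2 * tau + 0.7)
  mdl <- aqueduct_model(alpha = 3, Ls_over_L = 1, entrance_loss_K = 0)
  pr1 <- predict(mdl, waveform = q1, normalize = FALSE)
  pr2 <- predict(mdl, waveform = q2, normalize = FALSE)
  pr12 <- predict(mdl, waveform = q1 + q2, normalize = FALSE)
  expect_equal(pr12$Pi, pr1$Pi + pr2$Pi, tolerance = 1e-10)
  # homogeneity in amplitude
  pr_scaled <- predict(mdl, waveform = 3 * q1, normalize = FALSE)
  expect_equal(pr_scaled$Pi, 3 * pr1$Pi, tolerance = 1e-10)
  expect_equal(pr_scaled$mean_abs_Pi, 3 * pr1$mean_abs_Pi, tolerance = 1e-10)
})

test_that("phase lag rises monotonically from 0 to pi/2 with alpha", {
  alphas <- c(0.5, 1, 2, 3, 4, 6, 8, 10)
  phis <- vapply(alphas, function(a) {
    predict(aqueduct_model(alpha = a, Ls_over_L = 1, warn = FALSE))$phase_lag
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
  expect_true(all(phis > 0 & phis < pi / 2))
  # limit behavior
  expect_lt(predict(aqueduct_model(alpha = 0.05, Ls_over_L = 1,
                                   entrance_loss_K = 0, warn = FALSE))$phase_lag,
            0.01)
})

test_that("mean|Pi| decreases with alpha and is Ls/L-free when K = 0", {
  m <- vapply(c(1, 2, 3, 4, 6), function(a) {
    predict(aqueduct_model(alpha = a, Ls_over_L = 1, warn = FALSE))$mean_abs_Pi
  }, numeric(1))
  expect_true(all(diff(m) < 0))
  # without the entrance loss the linear model has no stroke-length dependence
  m_low <- predict(aqueduct_model(alpha = 3, Ls_over_L = 0.5,
                                  entrance_loss_K = 0))$mean_abs_Pi
  m_high <- predict(aqueduct_model(alpha = 3, Ls_over_L = 1.5,
                                   entrance_loss_K = 0))$mean_abs_Pi
  expect_equal(m_low, m_high, tolerance = 1e-12)
  # with the default K the dependence exists but is weak
  k_low <- predict(aqueduct_model(alpha = 3, Ls_over_L = 0.5))$mean_abs_Pi
  k_high <- predict(aqueduct_model(alpha = 3, Ls_over_L = 1.5))$mean_abs_Pi
  expect_gt(k_high, k_low)
  expect_lt(k_high / k_low - 1, 0.10)
})

test_that("the physiologic stand-in waveform has the documented structure", {
  pr <- predict(aqueduct_model(alpha = 3, Ls_over_L = 1), waveform = "physiologic")
  q <- pr$Qbar
  # unit dimensionless stroke: mean|Qbar| = 1/pi, as for (1/2) sin(tau)
  expect_equal(mean_abs_cycle(c(q, q[1]), 1, rate = length(q) / (2 * pi)),
               1 / pi, tolerance = 1e-3)
  # three peaks and three troughs per cycle
  dq <- diff(c(q, q[1]))
  sgn <- sign(dq)
  sgn <- sgn[sgn != 0]
  expect_identical(sum(sgn != c(sgn[-1], sgn[1])), 6L)
  # systolic dominance
  expect_gt(max(q) / abs(min(q)), 1.3)
  # the induced pressure waveform is anharmonic with secondary extrema
  dp <- diff(c(pr$Pi, pr$Pi[1]))
  sgp <- sign(dp)
  sgp <- sgp[sgp != 0]
  expect_gte(sum(sgp != c(sgp[-1], sgp[1])), 6L)
})

test_that("quasi-1D area profile reduces to the uniform tube and raises losses", {
  a <- 0.013
  L <- 0.158
  prof_uniform <- cbind(x = seq(0, L, length.out = 11),
                        area = rep(pi * a^2, 11))
  geo_u <- canal_geometry(L, a, area_profile = prof_uniform)
  mdl_u <- aqueduct_model(alpha = 2, Ls_over_L = 1, geometry = geo_u,
                          use_area_profile = TRUE)
  mdl_ref <- aqueduct_model(alpha = 2, Ls_over_L = 1, a_over_L = a / L)
  expect_equal(predict(mdl_u)$mean_abs_Pi, predict(mdl_ref)$mean_abs_Pi,
               tolerance = 1e-6)
  # a waisted canal (narrower mid-section) has a larger pressure drop
  x <- seq(0, L, length.out = 41)
  waist <- a * (1 - 0.3 * sin(pi * x / L))
  geo_w <- canal_geometry(L, a, area_profile = cbind(x = x, area = pi * waist^2))
  mdl_w <- aqueduct_model(alpha = 2, Ls_over_L = 1, geometry = geo_w,
                          use_area_profile = TRUE)
  expect_gt(predict(mdl_w)$mean_abs_Pi, predict(mdl_ref)$mean_abs_Pi)
})

test_that("model constructor enforces its configuration contract", {
  expect_error(aqueduct_model(alpha = 2, Ls_over_L = 1, entrance_loss_K = -1),
               "entrance_loss_K")
  expect_error(aqueduct_model(alpha = 2, Ls_over_L = 1, n_harmonics = 0.5),
               "n_harmonics")
  mdl4 <- aqueduct_model(alpha = 2, Ls_over_L = 1, n_harmonics = 4)
  expect_error(predict(mdl4, waveform = "physiologic"), "n_harmonics >= 8")
})
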