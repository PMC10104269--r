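test_that("design_frequency reproduces the tabulated experiment frequencies", {
  geo <- lab_geometry()
  # real-geometry rows: (alpha, nu) -> BPM
  expect_identical(design_frequency(2, geo, fluid_properties(1225.6, 1.05e-4))$bpm_rounded, 24)
  expect_identical(design_frequency(3, geo, fluid_properties(1216.4, 6.82e-5))$bpm_rounded, 35)
  expect_identical(design_frequency(4, geo, fluid_properties(1202.2, 3.83e-5))$bpm_rounded, 35)
  # trivial identity
  d <- design_frequency(1, canal_geometry(2, 1), fluid_properties(1, 1))
  expect_equal(d$omega, 1)
  expect_equal(d$bpm, 60 / (2 * pi))
  # inverse of womersley_number to machine precision
  fl <- glycerol_water_properties(0.80)
  for (om in c(0.9, 2.49, 7.4)) {
    al <- womersley_number(geo, fl, om)
    expect_equal(design_frequency(al, geo, fl)$omega, om, tolerance = 1e-12)
  }
})

test_that("design_frequency flags frequencies outside the pump range", {
  geo <- canal_geometry(0.158, 0.013)
  slow <- fluid_properties(1000, 1e-6)        # alpha = 2 needs < 3 BPM
  expect_warning(d <- design_frequency(2, geo, slow), "pump range")
  expect_false(d$pump_ok)
  expect_true(design_frequency(2, geo, fluid_properties(1225.6, 1.05e-4))$pump_ok)
})

test_that("similarity_check reports residuals of the three conditions", {
  geoH <- canal_geometry(0.0158, 0.0013)
  flH <- csf_properties()
  omH <- design_frequency(2, geoH, flH)$omega
  VsH <- pi * 0.0013^2 * 0.0158
  human <- list(geometry = geoH, fluid = flH,
                oscillation = oscillation_spec(omH, VsH))

  # identical configurations: residuals all zero
  m0 <- scaling_map(human, human)
  chk0 <- similarity_check(m0)
  expect_equal(chk0$residual, rep(0, 3))
  expect_true(attr(chk0, "pass"))
  expect_equal(m0$chi, 1)

  # the scaled-by-10 experiment at 24 BPM with the 84/16 mixture
  geoE <- canal_geometry(0.158, 0.013)
  flE <- glycerol_water_properties(0.84)
  expt <- list(geometry = geoE, fluid = flE,
               oscillation = oscillation_spec(bpm = 24,
                                              stroke_volume_Vs = pi * 0.013^2 * 0.158))
  mp <- scaling_map(human, expt)
  expect_equal(mp$chi, 10)
  chk <- similarity_check(mp)
  expect_true(all(chk$residual < 0.02))
  expect_true(attr(chk, "pass"))

  # halving the experimental viscosity breaks only the Womersley condition,
  # by exactly sqrt(2) - 1 (drive the experiment at the exact matching
  # frequency, not the integer-BPM setting, to isolate the viscosity effect)
  flE2 <- fluid_properties(flE$density_rho, flE$kin_viscosity_nu / 2)
  expt2 <- expt
  expt2$fluid <- flE2
  expt2$oscillation <- oscillation_spec(design_frequency(2, geoE, flE)$omega,
                                        expt$oscillation$stroke_volume_Vs)
  chk2 <- similarity_check(scaling_map(human, expt2))
  expect_equal(chk2$residual[chk2$condition == "womersley"], sqrt(2) - 1,
               tolerance = 1e-10)
  expect_equal(chk2$residual[chk2$condition != "womersley"], rep(0, 2))
})

test_that("pressure_ratio follows the density-viscosity-scale law", {
  geoH <- canal_geometry(0.0158, 0.0013)
  human <- list(geometry = geoH, fluid = csf_properties(),
                oscillation = oscillation_spec(design_frequency(2, geoH, csf_properties())$omega,
                                               pi * 0.0013^2 * 0.0158))
  geoE <- canal_geometry(0.158, 0.013)
  expt <- list(geometry = geoE, fluid = glycerol_water_properties(0.84),
               oscillation = oscillation_spec(bpm = 24,
                                              stroke_volume_Vs = pi * 0.013^2 * 0.158))
  mp <- scaling_map(human, expt)
  ratio <- pressure_ratio(mp)
  expect_equal(as.numeric(ratio),
               (1225.6 / 1000) * (1.05e-4 / 0.71e-6)^2 / 100,
               tolerance = 1e-10)
  expect_equal(as.numeric(ratio), 268, tolerance = 0.01)

  # a 5 Pa human-scale target maps into the sensor design window
  dp_E <- 5 * as.numeric(ratio)
  expect_gt(dp_E, 100)
  expect_lt(dp_E, 1500)
  expect_equal(map_pressure(dp_E, mp), 5, tolerance = 1e-12)

  # identical fluids at chi = 1: ratio is exactly 1
  expect_equal(as.numeric(pressure_ratio(scaling_map(human, human))), 1)

  # invariant under simultaneous rescaling of both configurations
  scale_cfg <- function(cfg, s) {
    list(geometry = canal_geometry(cfg$geometry$length_L * s,
                                   cfg$geometry$mean_radius_a * s),
         fluid = cfg$fluid,
         oscillation = oscillation_spec(cfg$oscillation$omega / s^2,
                                        cfg$oscillation$stroke_volume_Vs * s^3))
  }
  mp2 <- scaling_map(scale_cfg(human, 3), scale_cfg(expt, 3))
  expect_equal(as.numeric(pressure_ratio(mp2)), as.numeric(ratio),
               tolerance = 1e-12)
})

test_that("glycerol_water_properties reproduces the lab mixtures", {
  # exact lookup for the three mixtures measured at 21.5 degC
  for (i in seq_along(c(0.84, 0.80, 0.74))) {
    phi <- c(0.84, 0.80, 0.74)[i]
    fl <- glycerol_water_properties(phi, 21.5)
    expect_identical(fl$kin_viscosity_nu, c(10.5e-5, 6.82e-5, 3.83e-5)[i])
    expect_identical(fl$density_rho, c(1225.6, 1216.4, 1202.2)[i])
    expect_identical(attr(fl, "source"), "lookup")
  }
  # the correlation itself stays close to the measured values
  c84 <- glycerol_water_properties(0.84, 21.5, exact_mixtures = FALSE)
  expect_equal(c84$kin_viscosity_nu, 1.05e-4, tolerance = 0.10)
  expect_equal(c84$density_rho, 1225.6, tolerance = 0.01)
  c80 <- glycerol_water_properties(0.80, 21.5, exact_mixtures = FALSE)
  expect_equal(c80$kin_viscosity_nu, 6.82e-5, tolerance = 0.10)
  # pure water at body temperature is essentially CSF
  w37 <- glycerol_water_properties(0, 37)
  expect_equal(w37$kin_viscosity_nu, 0.7e-6, tolerance = 0.05)
  # out-of-range temperature is a domain error
  expect_error(glycerol_water_properties(0.5, 150), "temperature")
})

test_that("glycerol_water_properties is monotone in glycerol fraction", {
  phis <- seq(0, 1, by = 0.1)
  props <- lapply(phis, glycerol_water_properties,
                  temperature_C = 21.5, exact_mixtures = FALSE)
  rho <- vapply(props, `[[`, numeric(1), "density_rho")
  nu <- vapply(props, `[[`, numeric(1), "kin_viscosity_nu")
  expect_true(all(diff(rho) > 0))
  expect_true(all(diff(nu) > 0))
})

test_that("design_experiment emits a consistent design block", {
  geo <- lab_geometry()
  fl <- glycerol_water_properties(0.84)
  des <- design_experiment(2, geo, fl)
  expect_identical(des$bpm_rounded, 24)
  expect_true(des$pump_frequency_ok)
  expect_true(des$pump_stroke_ok)
  expect_equal(des$Vs_min_ml / des$Vs_max_ml, 0.5 / 1.5, tolerance = 1e-12)
  # expected pressure window sits inside the sensor's comfortable range
  expect_gt(des$expected_mean_abs_dp_min_Pa, 50)
  expect_lt(des$expected_mean_abs_dp_max_Pa, inh2o_to_pa(10))
  df <- as.data.frame(des)
  expect_identical(nrow(df), 1L)
})
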