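#' Frequency needed to reach a target Womersley number
#'
#' Inverts `alpha = sqrt(omega a^2 / nu)` to `omega = alpha^2 nu / a^2` for a
#' given canal and working fluid.  The result is reported both as an angular
#' frequency and in beats per minute (raw and rounded to the nearest integer,
#' ties away from zero, matching how pump settings are tabulated).
#'
#' Frequencies outside the pulsatile-pump operating range 3-200 BPM are
#' flagged with a warning (`pump_ok = FALSE`) but not rejected, so the
#' designer remains usable for other hardware.
#'
#' @param alpha_target target Womersley number.
#' @param geometry a [canal_geometry()].
#' @param fluid a [fluid_properties()].
#' @return List with `omega` \[rad/s\], `bpm`, `bpm_rounded` and `pump_ok`.
#' @examples
#' geo <- canal_geometry(0.158, 0.013)
#' design_frequency(2, geo, fluid_properties(1225.6, 1.05e-4))$bpm_rounded  # 24
#' @export
design_frequency <- function(alpha_target, geometry, fluid) {
  check_positive(alpha_target, "alpha_target")
  stopifnot(inherits(geometry, "canal_geometry"), inherits(fluid, "fluid_properties"))
  omega <- alpha_target^2 * fluid$kin_viscosity_nu / geometry$mean_radius_a^2
  bpm <- omega_to_bpm(omega)
  pump_ok <- bpm >= 3 && bpm <= 200
  if (!pump_ok) {
    warning(sprintf("designed frequency %.3g BPM outside pump range 3-200 BPM", bpm),
            call. = FALSE)
  }
  list(omega = omega, bpm = bpm, bpm_rounded = round_half_away(bpm),
       pump_ok = pump_ok)
}

# round to nearest integer, ties away from zero (unlike IEEE round())
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Scaling map between human and experimental configurations
#'
#' Pairs a human-scale and an experimental-scale flow configuration, each a
#' list with elements `geometry` ([canal_geometry()]), `fluid`
#' ([fluid_properties()]) and `oscillation` ([oscillation_spec()]).  The
#' geometric scale factor is `chi = L_E / L_H`.
#'
#' @param human,experiment configuration lists (see Details).
#' @return Object of class `scaling_map` with elements `human`, `experiment`
#'   and `chi`.
#' @export
scaling_map <- function(human, experiment) {
  for (cfg in list(human, experiment)) {
    stopifnot(inherits(cfg$geometry, "canal_geometry"),
              inherits(cfg$fluid, "fluid_properties"),
              inherits(cfg$oscillation, "oscillation_spec"))
  }
  chi <- experiment$geometry$length_L / human$geometry$length_L
  structure(list(human = human, experiment = experiment, chi = chi),
            class = "scaling_map")
}

config_groups <- function(cfg) {
  dimensionless_groups(cfg$geometry, cfg$fluid, cfg$oscillation$omega,
                       cfg$oscillation$stroke_volume_Vs, warn = FALSE)
}

#' Check the dynamic-similarity conditions of a scaling map
#'
#' Physical similarity between the experiment (subscript E) and the human
#' aqueduct (subscript H) requires equality of the three governing
#' dimensionless groups: the aspect ratio `a/L`, the Womersley number
#' `alpha = sqrt(omega a^2 / nu)` and the stroke-length ratio `Ls/L`.
#' Each condition is reported with its relative residual
#' `|experiment - human| / human`.
#'
#' @param map a [scaling_map()].
#' @param tol pass tolerance on each relative residual (default 2%).
#' @return Data frame with one row per condition: `condition`, `experiment`,
#'   `human`, `residual`, `pass`; attribute `"pass"` gives the overall verdict.
#' @export
similarity_check <- function(map, tol = 0.02) {
  stopifnot(inherits(map, "scaling_map"))
  gH <- config_groups(map$human)
  gE <- config_groups(map$experiment)
  vals_E <- c(gE$a_over_L, gE$alpha, gE$Ls_over_L)
  vals_H <- c(gH$a_over_L, gH$alpha, gH$Ls_over_L)
  res <- abs(vals_E - vals_H) / vals_H
  out <- data.frame(
    condition = c("aspect_ratio", "womersley", "stroke_length_ratio"),
    experiment = vals_E, human = vals_H, residual = res,
    pass = res <= tol,
    stringsAsFactors = FALSE
  )
  attr(out, "pass") <- all(out$pass)
  out
}

#' Pressure ratio between experimental and human scales
#'
#' When the similarity conditions hold, the measured cycle-averaged pressure
#' magnitudes at the two scales are related by
#' `mean|dp|_E / mean|dp|_H = (rho_E / rho_H) * (nu_E / nu_H)^2 * chi^-2`,
#' with `chi` the geometric scale factor.  `map_pressure()` converts a
#' pressure measured in the experiment to the equivalent human-scale value by
#' dividing by this ratio.
#'
#' @param map a [scaling_map()].
#' @param measured_E pressure measured at the experimental scale \[Pa\].
#' @param tol similarity tolerance forwarded to [similarity_check()].
#' @return `pressure_ratio()`: dimensionless scalar (with a warning attached
#'   when the similarity check fails); `map_pressure()`: pressure \[Pa\] at
#'   human scale.
#' @export
pressure_ratio <- function(map, tol = 0.02) {
  stopifnot(inherits(map, "scaling_map"))
  fE <- map$experiment$fluid
  fH <- map$human$fluid
  ratio <- (fE$density_rho / fH$density_rho) *
    (fE$kin_viscosity_nu / fH$kin_viscosity_nu)^2 / map$chi^2
  chk <- similarity_check(map, tol)
  if (!attr(chk, "pass")) {
    warning("similarity conditions not satisfied; pressure mapping is only valid ",
            "when all dimensionless groups match", call. = FALSE)
    attr(ratio, "similarity") <- chk
  }
  ratio
}

#' @rdname pressure_ratio
#' @export
map_pressure <- function(measured_E, map, tol = 0.02) {
  measured_E / as.numeric(pressure_ratio(map, tol))
}

#' Design a scaled experiment for a target Womersley number
#'
#' Combines [design_frequency()] with the flow model to produce a flat
#' design report for one (geometry, fluid, alpha) operating point: drive
#' frequency, stroke-volume range covering `Ls/L` in `Ls_over_L_range`, and
#' the expected window of cycle-averaged pressure magnitudes at the
#' experimental scale.  Stroke volumes outside the pump limit 0-180 mL are
#' flagged.
#'
#' @param alpha_target target Womersley number.
#' @param geometry experimental [canal_geometry()].
#' @param fluid experimental [fluid_properties()].
#' @param Ls_over_L_range range of dimensionless stroke length to cover.
#' @param entrance_loss_K entrance-loss coefficient passed to [aqueduct_model()].
#' @return Object of class `experiment_design` (a named list); its `print()`
#'   method emits the flat key-value block, and `as.data.frame()` a one-row
#'   table suitable for `write.csv()`.
#' @export
design_experiment <- function(alpha_target, geometry, fluid,
                              Ls_over_L_range = c(0.5, 1.5),
                              entrance_loss_K = 0.7) {
  fr <- design_frequency(alpha_target, geometry, fluid)
  a <- geometry$mean_radius_a
  L <- geometry$length_L
  Vs_range <- pi * a^2 * L * Ls_over_L_range
  # expected pressure window from the harmonic-waveform model at the range ends
  dp <- vapply(Ls_over_L_range, function(lsl) {
    mdl <- aqueduct_model(alpha = alpha_target, Ls_over_L = lsl,
                          a_over_L = geometry$aspect_ratio,
                          entrance_loss_K = entrance_loss_K, warn = FALSE)
    pr <- predict(mdl)
    pr$mean_abs_Pi * fluid$density_rho * fr$omega^2 * L * (lsl * L)
  }, numeric(1))
  structure(
    list(alpha = alpha_target,
         length_L = L, mean_radius_a = a, a_over_L = geometry$aspect_ratio,
         density_rho = fluid$density_rho, kin_viscosity_nu = fluid$kin_viscosity_nu,
         omega = fr$omega, bpm = fr$bpm, bpm_rounded = fr$bpm_rounded,
         pump_frequency_ok = fr$pump_ok,
         Ls_over_L_min = Ls_over_L_range[1L], Ls_over_L_max = Ls_over_L_range[2L],
         Vs_min_ml = Vs_range[1L] * 1e6, Vs_max_ml = Vs_range[2L] * 1e6,
         pump_stroke_ok = Vs_range[2L] * 1e6 <= 180,
         expected_mean_abs_dp_min_Pa = min(dp),
         expected_mean_abs_dp_max_Pa = max(dp)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("%s: %s\n", k,
                if (is.numeric(v)) format(v, digits = 6) else as.character(v)))
  }
  invisible(x)
}

#' @export
as.data.frame.experiment_design <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
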