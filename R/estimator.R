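#' Estimate the mean transmantle pressure fluctuation from MRI measurables
#'
#' The clinical endpoint: the cycle-averaged magnitude of the interventricular
#' pressure difference,
#' \deqn{\langle|\Delta p|\rangle = \langle|\Pi|\rangle\,\rho\,\omega^2 L\,
#'       \frac{V_s}{\pi a^2},}
#' computed from quantities measurable noninvasively: the aqueduct stroke
#' volume `Vs` (cardiac-gated PC-MRI), the heart rate, and the aqueduct
#' anatomy (`L`, `a`, from anatomical MRI).  When `mean_abs_Pi` is not
#' supplied it is predicted by the Womersley flow model at the implied
#' `(alpha, Ls/L, a/L)` using the physiologic waveform (the harmonic
#' waveform gives values within a few percent).
#'
#' At fixed `mean|Pi|` the estimate scales as `a^-2`; with the model in the
#' loop, enlarging the aqueduct reduces the estimate even faster, because
#' `mean|Pi|` itself decreases with the Womersley number
#' `alpha = a sqrt(omega/nu)`.  This is why patients with an enlarged
#' aqueduct can show normal transmantle pressures despite increased stroke
#' volumes.
#'
#' @param stroke_volume_Vs aqueduct stroke volume \[m^3\]
#'   (use [ml_to_m3()] for mL).
#' @param omega cardiac angular frequency \[rad/s\]; alternatively give `bpm`.
#' @param geometry aqueduct [canal_geometry()] (note the effective length
#'   convention for a real aqueduct, including its funnel-shaped openings, is
#'   the user's choice; `L` is taken as supplied).
#' @param fluid a [fluid_properties()]; defaults to CSF
#'   (`rho = 1000 kg/m^3`, `nu = 0.71e-6 m^2/s`).
#' @param mean_abs_Pi optional dimensionless cycle-averaged pressure
#'   magnitude; when `NULL` it is computed by the flow model.
#' @param waveform waveform for the model evaluation (default
#'   `"physiologic"`).
#' @param entrance_loss_K entrance-loss coefficient for the model.
#' @param bpm heart rate in beats per minute, used when `omega` is missing.
#' @return Object of class `transmantle_estimate`: the estimated
#'   `mean|dp|` \[Pa\] with attributes `alpha`, `Ls_over_L`, `mean_abs_Pi`
#'   and `waveform`.  A warning is attached when the implied `alpha` falls
#'   outside `[0.5, 10]`, where the model is untested.
#' @examples
#' geo <- canal_geometry(length_L = 0.0158, mean_radius_a = 0.0013)
#' estimate_transmantle(ml_to_m3(0.05), bpm = 60, geometry = geo)
#' @export
estimate_transmantle <- function(stroke_volume_Vs, omega = NULL, geometry,
                                 fluid = csf_properties(), mean_abs_Pi = NULL,
                                 waveform = c("physiologic", "harmonic"),
                                 entrance_loss_K = 0.7, bpm = NULL) {
  waveform <- match.arg(waveform)
  if (is.null(omega)) {
    if (is.null(bpm)) stop("give 'omega' or 'bpm'", call. = FALSE)
    omega <- bpm_to_omega(bpm)
  }
  if (!is.numeric(stroke_volume_Vs) || length(stroke_volume_Vs) != 1L ||
      stroke_volume_Vs < 0) {
    stop("'stroke_volume_Vs' must be a non-negative scalar [m^3]", call. = FALSE)
  }
  stopifnot(inherits(geometry, "canal_geometry"),
            inherits(fluid, "fluid_properties"))
  check_positive(omega, "omega")

  a <- geometry$mean_radius_a
  L <- geometry$length_L
  alpha <- womersley_number(geometry, fluid, omega)
  Ls <- stroke_volume_Vs / (pi * a^2)
  Ls_over_L <- Ls / L
  if (alpha < 0.5 || alpha > 10) {
    warning(sprintf("implied Womersley number alpha = %.3g outside [0.5, 10]; ",
                    alpha), "model extrapolation", call. = FALSE)
  }

  if (is.null(mean_abs_Pi)) {
    mdl <- aqueduct_model(alpha = alpha,
                          Ls_over_L = max(Ls_over_L, .Machine$double.eps),
                          a_over_L = geometry$aspect_ratio,
                          entrance_loss_K = entrance_loss_K, warn = FALSE)
    mean_abs_Pi <- predict(mdl, waveform = waveform)$mean_abs_Pi
  } else if (mean_abs_Pi < 0) {
    stop("'mean_abs_Pi' must be >= 0", call. = FALSE)
  }

  dp <- mean_abs_Pi * fluid$density_rho * omega^2 * L *
    stroke_volume_Vs / (pi * a^2)
  structure(dp, class = "transmantle_estimate",
            alpha = alpha, Ls_over_L = Ls_over_L,
            mean_abs_Pi = mean_abs_Pi, waveform = waveform)
}

#' @export
print.transmantle_estimate <- function(x, ...) {
  cat(sprintf("Mean transmantle pressure fluctuation: %.3g Pa\n", unclass(x)))
  cat(sprintf("  alpha = %.3g, Ls/L = %.3g, mean|Pi| = %.3g (%s waveform)\n",
              attr(x, "alpha"), attr(x, "Ls_over_L"),
              attr(x, "mean_abs_Pi"), attr(x, "waveform")))
  invisible(x)
}
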