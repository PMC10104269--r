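#' Cerebral-aqueduct canal geometry
#'
#' Describes the canal connecting the third and fourth ventricles by its
#' length `L`, mean radius `a` and, optionally, an axial cross-section area
#' profile for anatomically realistic shapes.  In the human brain
#' `L ~ 10-15 mm` and `a ~ 1-1.5 mm`; scaled laboratory models share the
#' aspect ratio `a/L` but may be larger.
#'
#' @param length_L canal length \[m\].
#' @param mean_radius_a mean canal radius \[m\].
#' @param area_profile optional two-column matrix or data.frame
#'   `(axial position [m], cross-section area [m^2])`; positions must increase
#'   strictly from 0 to `length_L` and areas must be positive.
#' @return An object of class `canal_geometry` with fields `length_L`,
#'   `mean_radius_a`, `aspect_ratio` (= a/L) and `area_profile`.
#' @examples
#' # anatomically correct model scaled up by 10: a = 1.3 cm, L = 15.8 cm
#' geo <- canal_geometry(length_L = 0.158, mean_radius_a = 0.013)
#' geo$aspect_ratio   # 0.082
#' @export
canal_geometry <- function(length_L, mean_radius_a, area_profile = NULL) {
  check_positive(length_L, "length_L")
  check_positive(mean_radius_a, "mean_radius_a")
  ar <- mean_radius_a / length_L
  if (ar >= 1) {
    stop("aspect ratio a/L must lie in (0, 1): radius exceeds length",
         call. = FALSE)
  }
  if (!is.null(area_profile)) {
    area_profile <- as.matrix(area_profile)
    if (ncol(area_profile) != 2L || nrow(area_profile) < 2L) {
      stop("'area_profile' needs >= 2 rows of (axial position, area)",
           call. = FALSE)
    }
    x <- area_profile[, 1L]
    A <- area_profile[, 2L]
    if (any(A <= 0)) stop("all cross-section areas must be > 0", call. = FALSE)
    if (any(diff(x) <= 0)) {
      stop("axial positions in 'area_profile' must be strictly increasing",
           call. = FALSE)
    }
    if (abs(x[1L]) > 1e-9 * length_L ||
        abs(x[length(x)] - length_L) > 1e-9 * length_L) {
      stop("'area_profile' must span the canal from 0 to length_L",
           call. = FALSE)
    }
    colnames(area_profile) <- c("x", "area")
  }
  structure(
    list(length_L = length_L, mean_radius_a = mean_radius_a,
         aspect_ratio = ar, area_profile = area_profile),
    class = "canal_geometry"
  )
}

#' @export
print.canal_geometry <- function(x, ...) {
  cat("Canal geometry\n")
  cat(sprintf("  length L       : %.4g m\n", x$length_L))
  cat(sprintf("  mean radius a  : %.4g m\n", x$mean_radius_a))
  cat(sprintf("  aspect ratio   : a/L = %.4g\n", x$aspect_ratio))
  if (!is.null(x$area_profile)) {
    cat(sprintf("  area profile   : %d axial stations\n", nrow(x$area_profile)))
  }
  invisible(x)
}

#' Working-fluid properties
#'
#' Density and kinematic viscosity of the fluid in the canal.  Cerebrospinal
#' fluid is essentially water at body temperature
#' (`rho = 1000 kg/m^3`, `nu = 0.71e-6 m^2/s`); scaled experiments use more
#' viscous glycerol-water mixtures (see [glycerol_water_properties()]).
#'
#' @param density_rho fluid density \[kg/m^3\].
#' @param kin_viscosity_nu kinematic viscosity \[m^2/s\].
#' @return Object of class `fluid_properties`.
#' @seealso [csf_properties()] for the CSF default.
#' @export
fluid_properties <- function(density_rho, kin_viscosity_nu) {
  check_positive(density_rho, "density_rho")
  check_positive(kin_viscosity_nu, "kin_viscosity_nu")
  structure(list(density_rho = density_rho, kin_viscosity_nu = kin_viscosity_nu),
            class = "fluid_properties")
}

#' @rdname fluid_properties
#' @export
csf_properties <- function() fluid_properties(1000, 0.71e-6)

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: rho = %.4g kg/m^3, nu = %.4g m^2/s\n",
              x$density_rho, x$kin_viscosity_nu))
  invisible(x)
}

#' Oscillation specification
#'
#' The periodic drive of the canal flow: angular frequency `omega`, stroke
#' volume `Vs` (the volume displaced back and forth per cycle,
#' `Vs = (1/2) * integral of |Q| dt` over one period) and the waveform
#' identity.  A tabulated waveform supplies one period of flow-rate samples
#' and must carry no net volume per cycle.
#'
#' @param omega angular frequency \[rad/s\]; alternatively give `bpm`.
#' @param stroke_volume_Vs stroke volume \[m^3\].
#' @param waveform `"harmonic"`, `"physiologic"` or `"tabulated"`.
#' @param flow_samples for `waveform = "tabulated"`, numeric vector of
#'   uniformly spaced flow-rate samples \[m^3/s\] covering exactly one period
#'   (endpoint excluded).
#' @param bpm frequency in beats per minute, used when `omega` is missing.
#' @return Object of class `oscillation_spec`.
#' @export
oscillation_spec <- function(omega = NULL, stroke_volume_Vs, waveform = "harmonic",
                             flow_samples = NULL, bpm = NULL) {
  if (is.null(omega)) {
    if (is.null(bpm)) stop("give 'omega' or 'bpm'", call. = FALSE)
    omega <- bpm_to_omega(bpm)
  }
  check_positive(omega, "omega")
  check_positive(stroke_volume_Vs, "stroke_volume_Vs")
  waveform <- match.arg(waveform, c("harmonic", "physiologic", "tabulated"))
  if (waveform == "tabulated") {
    if (is.null(flow_samples) || length(flow_samples) < 8L) {
      stop("tabulated waveform needs >= 8 'flow_samples' over one period",
           call. = FALSE)
    }
    if (abs(mean(flow_samples)) > 1e-6 * max(abs(flow_samples))) {
      stop("tabulated waveform must integrate to zero net volume over one period",
           call. = FALSE)
    }
  }
  structure(
    list(omega = omega, period_T = 2 * pi / omega,
         stroke_volume_Vs = stroke_volume_Vs,
         waveform = waveform, flow_samples = flow_samples),
    class = "oscillation_spec"
  )
}

#' @export
print.oscillation_spec <- function(x, ...) {
  cat(sprintf("Oscillation: omega = %.4g rad/s (%.3g BPM), Vs = %.4g mL, %s waveform\n",
              x$omega, omega_to_bpm(x$omega), x$stroke_volume_Vs * 1e6, x$waveform))
  invisible(x)
}

#' Womersley number
#'
#' `alpha = sqrt(omega * a^2 / nu)`, the ratio of oscillatory-inertial to
#' viscous effects in pulsatile duct flow.  It controls the shape of the
#' velocity profile and the phase relation between pressure gradient and flow
#' rate; aqueduct flow in healthy adults typically has `alpha` between 2 and 4.
#'
#' @param geometry a [canal_geometry()].
#' @param fluid a [fluid_properties()].
#' @param omega angular frequency \[rad/s\].
#' @return Dimensionless Womersley number (scalar).
#' @examples
#' geo <- canal_geometry(0.158, 0.013)
#' womersley_number(geo, fluid_properties(1225.6, 1.05e-4), bpm_to_omega(24))
#' @export
womersley_number <- function(geometry, fluid, omega) {
  stopifnot(inherits(geometry, "canal_geometry"), inherits(fluid, "fluid_properties"))
  check_positive(omega, "omega")
  sqrt(omega * geometry$mean_radius_a^2 / fluid$kin_viscosity_nu)
}

#' Dimensionless groups governing the oscillatory canal flow
#'
#' Buckingham-Pi reduction of the six governing dimensional parameters
#' `(L, a, rho, nu, Ls, omega)` to three dimensionless groups: the Womersley
#' number `alpha`, the stroke-length ratio `Ls/L` and the aspect ratio `a/L`.
#' The cycle-averaged dimensionless pressure obeys
#' `mean|Pi| = f(a/L, Ls/L, alpha)`.
#'
#' Either pass the dimensional description (`geometry`, `fluid`, `omega`,
#' `stroke_volume`) or the three groups directly.
#'
#' @param geometry a [canal_geometry()].
#' @param fluid a [fluid_properties()].
#' @param omega angular frequency \[rad/s\].
#' @param stroke_volume stroke volume \[m^3\].
#' @param alpha,Ls_over_L,a_over_L directly specified groups (all positive).
#' @param warn warn when the groups fall outside the ranges typical of healthy
#'   subjects (`1/20 <= a/L <= 1/10`, `0.5 <= Ls/L <= 1.5`, `2 <= alpha <= 4`).
#'   These are typical-value ranges, not hard validity bounds, so violations
#'   warn rather than error.
#' @return Object of class `dimensionless_groups` with fields `alpha`,
#'   `Ls_over_L`, `a_over_L` and, when derived dimensionally, `Ls` \[m\].
#' @export
dimensionless_groups <- function(geometry = NULL, fluid = NULL, omega = NULL,
                                 stroke_volume = NULL, alpha = NULL,
                                 Ls_over_L = NULL, a_over_L = NULL,
                                 warn = TRUE) {
  Ls <- NA_real_
  if (is.null(alpha)) {
    alpha <- womersley_number(geometry, fluid, omega)
    check_positive(stroke_volume, "stroke_volume")
    Ls <- stroke_volume / (pi * geometry$mean_radius_a^2)
    Ls_over_L <- Ls / geometry$length_L
    a_over_L <- geometry$aspect_ratio
  } else {
    check_positive(alpha, "alpha")
    check_positive(Ls_over_L, "Ls_over_L")
    check_positive(a_over_L, "a_over_L")
  }
  g <- structure(list(alpha = alpha, Ls_over_L = Ls_over_L,
                      a_over_L = a_over_L, Ls = Ls),
                 class = "dimensionless_groups")
  if (warn) warn_outside_typical(g)
  g
}

warn_outside_typical <- function(g) {
  msgs <- character(0)
  if (g$a_over_L < 1 / 20 || g$a_over_L > 1 / 10) {
    msgs <- c(msgs, sprintf("a/L = %.3g outside typical range [1/20, 1/10]", g$a_over_L))
  }
  if (g$Ls_over_L < 0.5 || g$Ls_over_L > 1.5) {
    msgs <- c(msgs, sprintf("Ls/L = %.3g outside typical range [0.5, 1.5]", g$Ls_over_L))
  }
  if (g$alpha < 2 || g$alpha > 4) {
    msgs <- c(msgs, sprintf("alpha = %.3g outside typical range [2, 4]", g$alpha))
  }
  if (length(msgs)) {
    warning(paste(msgs, collapse = "; "),
            " (typical healthy-subject ranges, results remain valid)",
            call. = FALSE)
  }
  invisible(g)
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat(sprintf("Dimensionless groups: alpha = %.4g, Ls/L = %.4g, a/L = %.4g\n",
              x$alpha, x$Ls_over_L, x$a_over_L))
  invisible(x)
}
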