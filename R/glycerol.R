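#' Glycerol-water mixture properties
#'
#' Density and kinematic viscosity of a glycerol-water mixture at a given
#' temperature, for selecting the working fluid of a scaled experiment.
#' Viscosity follows the Cheng (2008) exponent-blending correlation for the
#' dynamic viscosity of glycerol-water mixtures (stated accuracy within a few
#' percent, here documented as about +/-5% on `nu`); density is the
#' volume-fraction-weighted average of temperature-dependent component
#' densities (ideal mixing).
#'
#' Three laboratory mixtures with glycerol volume fractions 0.84, 0.80 and
#' 0.74 at 21.5 degC are shipped as exact lookup overrides, so that their
#' measured properties
#' `nu = (10.5, 6.82, 3.83) x 10^-5 m^2/s`, `rho = (1225.6, 1216.4, 1202.2) kg/m^3`
#' are reproduced exactly; set `exact_mixtures = FALSE` to force the
#' correlation everywhere.
#'
#' @param glycerol_volume_fraction glycerol volume fraction in \[0, 1\].
#' @param temperature_C temperature \[degC\], within the correlation validity
#'   range 0-100 degC.
#' @param exact_mixtures use the tabulated laboratory mixtures when the inputs
#'   match one (default TRUE).
#' @return A [fluid_properties()] object with attributes
#'   `glycerol_volume_fraction`, `temperature_C` and `source`
#'   (`"correlation"` or `"lookup"`).
#' @references Cheng, N.-S. (2008) Formula for the viscosity of a
#'   glycerol-water mixture. Industrial & Engineering Chemistry Research 47,
#'   3285-3288.
#' @examples
#' glycerol_water_properties(0.84, 21.5)                        # lab mixture
#' glycerol_water_properties(0.84, 21.5, exact_mixtures = FALSE) # correlation
#' @export
glycerol_water_properties <- function(glycerol_volume_fraction,
                                      temperature_C = 21.5,
                                      exact_mixtures = TRUE) {
  phi <- glycerol_volume_fraction
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0 || phi > 1) {
    stop("'glycerol_volume_fraction' must be a scalar in [0, 1]", call. = FALSE)
  }
  Tc <- temperature_C
  if (!is.numeric(Tc) || length(Tc) != 1L || Tc < 0 || Tc > 100) {
    stop("'temperature_C' outside correlation validity range [0, 100] degC",
         call. = FALSE)
  }

  if (exact_mixtures && abs(Tc - 21.5) < 0.05) {
    lk <- .lab_mixtures
    hit <- which(abs(lk$phi - phi) < 1e-6)
    if (length(hit) == 1L) {
      fl <- fluid_properties(lk$rho[hit], lk$nu[hit])
      attr(fl, "glycerol_volume_fraction") <- phi
      attr(fl, "temperature_C") <- Tc
      attr(fl, "source") <- "lookup"
      return(fl)
    }
  }

  # component densities [kg/m^3] (Cheng 2008)
  rho_g <- 1277 - 0.654 * Tc
  rho_w <- 1000 * (1 - abs((Tc - 4) / 622)^1.394)
  rho <- phi * rho_g + (1 - phi) * rho_w

  # glycerol mass fraction from ideal volume mixing
  Cm <- phi * rho_g / rho

  # Cheng (2008) dynamic viscosities [Pa s]
  mu_w <- 1.790e-3 * exp((-1230 - Tc) * Tc / (36100 + 360 * Tc))
  mu_g <- 12.100 * exp((-1233 + Tc) * Tc / (9900 + 70 * Tc))
  a <- 0.705 - 0.0017 * Tc
  b <- (4.9 + 0.036 * Tc) * a^2.5
  alpha_blend <- 1 - Cm + a * b * Cm * (1 - Cm) / (a * Cm + b * (1 - Cm))
  mu <- mu_w^alpha_blend * mu_g^(1 - alpha_blend)

  fl <- fluid_properties(rho, mu / rho)
  attr(fl, "glycerol_volume_fraction") <- phi
  attr(fl, "temperature_C") <- Tc
  attr(fl, "source") <- "correlation"
  fl
}

# laboratory mixtures measured at 21.5 degC
.lab_mixtures <- list(
  phi = c(0.84, 0.80, 0.74),
  nu  = c(10.5e-5, 6.82e-5, 3.83e-5),
  rho = c(1225.6, 1216.4, 1202.2)
)
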