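# Synthetic pump/transducer recordings with the statistical structure the
# processing pipeline assumes: ADC-quantized piston position with rare large
# logging spikes, and a noisy pressure channel consistent with the flow model.

#' Noise specification for simulated recordings
#'
#' @param pressure_noise_sd Gaussian pressure noise, as a fraction of the
#'   clean pressure peak.
#' @param position_noise_sd Gaussian position noise, as a fraction of the
#'   piston stroke.
#' @param spike_rate expected logging spikes per 1000 piston samples.
#' @param spike_magnitude spike amplitude as a multiple of the signal peak
#'   (default 100, the scale of serial-logging glitches).
#' @param adc_bits ADC resolution of the piston channel (default 10).
#' @param seed integer seed; a given seed yields a bit-identical recording.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(pressure_noise_sd = 0.02, position_noise_sd = 0.001,
                       spike_rate = 0.2, spike_magnitude = 100,
                       adc_bits = 10L, seed = NULL) {
  stopifnot(pressure_noise_sd >= 0, position_noise_sd >= 0,
            spike_rate >= 0, spike_magnitude >= 0, adc_bits >= 1)
  structure(list(pressure_noise_sd = pressure_noise_sd,
                 position_noise_sd = position_noise_sd,
                 spike_rate = spike_rate, spike_magnitude = spike_magnitude,
                 adc_bits = as.integer(adc_bits), seed = seed),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
noiseless_spec <- function() {
  noise_spec(pressure_noise_sd = 0, position_noise_sd = 0, spike_rate = 0,
             spike_magnitude = 0, adc_bits = 24L)
}

#' Simulate a raw pump/transducer recording
#'
#' Generates the inverse of the measurement chain.  The piston position is
#' the cumulative trapezoidal integral of the commanded flow rate divided by
#' the piston area, sampled at `piston_rate`, zero-averaged (the pump input
#' must start and end at the same value), quantized to `adc_bits` over a
#' full-scale range of 1.2x the stroke, with Gaussian position noise added
#' before quantization and Poisson-placed logging spikes injected after it.
#' The pressure channel is the flow model's dimensionless prediction
#' redimensionalized to `Pa`, sampled at `pressure_rate`, plus Gaussian
#' noise.  Both channels start at `t = 0`.
#'
#' @param geometry a [canal_geometry()].
#' @param fluid a [fluid_properties()].
#' @param omega drive angular frequency \[rad/s\].
#' @param Ls_over_L commanded dimensionless stroke length (sets the stroke
#'   volume `Vs = pi a^2 L * Ls/L`).
#' @param waveform `"harmonic"` or `"physiologic"`.
#' @param model optional [aqueduct_model()] generating the pressure channel;
#'   defaults to the model implied by the configuration.
#' @param noise a [noise_spec()].
#' @param n_cycles number of cycles to record (>= 5).
#' @param piston_area piston cross-section area \[m^2\].
#' @param pressure_rate,piston_rate channel sampling rates \[Hz\].
#' @return A [raw_recording()]; attribute `"truth"` carries the generating
#'   model's `mean_abs_Pi` and `phase_lag` for closure testing.
#' @examples
#' geo <- canal_geometry(0.158, 0.013)
#' rec <- simulate_recording(geo, glycerol_water_properties(0.84),
#'                           bpm_to_omega(24), Ls_over_L = 1,
#'                           noise = noise_spec(seed = 7), n_cycles = 6)
#' @export
simulate_recording <- function(geometry, fluid, omega, Ls_over_L,
                               waveform = c("harmonic", "physiologic"),
                               model = NULL, noise = noise_spec(),
                               n_cycles = 12L, piston_area = 2.5e-3,
                               pressure_rate = 80, piston_rate = 2500) {
  waveform <- match.arg(waveform)
  stopifnot(inherits(geometry, "canal_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(noise, "noise_spec"))
  check_positive(omega, "omega")
  check_positive(Ls_over_L, "Ls_over_L")
  if (n_cycles < 5) stop("'n_cycles' must be >= 5", call. = FALSE)

  if (is.null(model)) {
    model <- aqueduct_model(alpha = womersley_number(geometry, fluid, omega),
                            Ls_over_L = Ls_over_L,
                            a_over_L = geometry$aspect_ratio, warn = FALSE)
  }
  pr <- predict(model, waveform = waveform)
  cn <- pr$coefficients
  a <- geometry$mean_radius_a
  L <- geometry$length_L
  Ls <- Ls_over_L * L
  T_ <- 2 * pi / omega

  # deterministic given the seed: draws use a local RNG state
  if (!is.null(noise$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(noise$seed)
  }

  # piston channel at piston_rate
  tx <- seq(0, by = 1 / piston_rate,
            length.out = floor(n_cycles * T_ * piston_rate) + 1L)
  qx <- omega * pi * a^2 * Ls * harmonic_eval(cn, omega * tx)
  x <- as.numeric(pracma::cumtrapz(tx, qx)) / piston_area
  x <- x - mean(x)
  stroke <- diff(range(x))
  if (noise$position_noise_sd > 0) {
    x <- x + stats::rnorm(length(x), sd = noise$position_noise_sd * stroke)
  }
  # ADC quantization over full scale 1.2x stroke, mid-rise about the mean
  full_scale <- 1.2 * stroke
  step <- full_scale / 2^noise$adc_bits
  x <- pmin(pmax(round(x / step) * step, -full_scale / 2), full_scale / 2)
  # logging spikes, injected downstream of the ADC
  n_spikes <- stats::rpois(1L, noise$spike_rate * length(x) / 1000)
  if (n_spikes > 0 && noise$spike_magnitude > 0) {
    at <- sample.int(length(x), min(n_spikes, length(x)))
    x[at] <- sample(c(-1, 1), length(at), replace = TRUE) *
      noise$spike_magnitude * max(abs(x))
  }

  # pressure channel at pressure_rate
  tp <- seq(0, by = 1 / pressure_rate,
            length.out = floor(n_cycles * T_ * pressure_rate) + 1L)
  Pi_t <- eval_model_pressure(model, cn, omega * tp)
  dp <- Pi_t * fluid$density_rho * omega^2 * L * Ls
  if (noise$pressure_noise_sd > 0) {
    dp <- dp + stats::rnorm(length(dp),
                            sd = noise$pressure_noise_sd * max(abs(dp)))
  }

  rec <- raw_recording(
    pressure = signal_trace(dp, rate = pressure_rate, t0 = 0, units = "Pa"),
    piston_position = signal_trace(x, rate = piston_rate, t0 = 0, units = "m"),
    piston_area = piston_area, geometry = geometry, fluid = fluid,
    omega = omega, waveform = waveform, Ls_over_L_nominal = Ls_over_L
  )
  attr(rec, "truth") <- list(mean_abs_Pi = pr$mean_abs_Pi,
                             phase_lag = pr$phase_lag, model = model)
  rec
}

# model pressure Pi at arbitrary phases tau (same terms as the predict method)
eval_model_pressure <- function(model, cn, tau) {
  Zn <- model_impedances(model, seq_along(cn))
  Pi_lin <- numeric(length(tau))
  for (k in seq_along(cn)) {
    Pi_lin <- Pi_lin + Re(Zn[k] * cn[k] * exp(1i * k * tau))
  }
  ubar <- harmonic_eval(cn, tau) / end_area_dimensionless(model)
  Pi_lin + 0.5 * model$entrance_loss_K * model$groups$Ls_over_L * ubar * abs(ubar)
}

#' @describeIn simulate_recording `simulate()` method: draw `nsim` synthetic
#'   recordings from a fitted/configured model at a given dimensional
#'   operating point.
#' @param object an [aqueduct_model()].
#' @param nsim number of recordings.
#' @param seed base seed; recording `i` uses `seed + i - 1`.
#' @param ... arguments passed on to `simulate_recording()` (at minimum
#'   `geometry`, `fluid` and `omega`).
#' @export
simulate.aqueduct_model <- function(object, nsim = 1, seed = NULL, ...) {
  args <- list(...)
  out <- lapply(seq_len(nsim), function(i) {
    ns <- args$noise %||% noise_spec()
    if (!is.null(seed)) ns$seed <- seed + i - 1L
    args$noise <- ns
    args$model <- object
    args$Ls_over_L <- args$Ls_over_L %||% object$groups$Ls_over_L
    do.call(simulate_recording, args)
  })
  if (nsim == 1L) out[[1L]] else out
}
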