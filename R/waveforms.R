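# Flow-rate waveforms driving the canal: a pure sine and a frozen
# three-peaked "physiologic" stand-in for a cardiac-gated PC-MRI measurement.

# Frozen 8-harmonic stand-in: Qraw(tau) = sum_n A_n sin(n tau + theta_n).
# Chosen once, by a constrained design: exactly three maxima and three minima
# per cycle (the percussion / tidal / dicrotic pattern of intracranial
# waveforms), systolic-dominant (max Q / |min Q| ~ 1.6), smoothly decaying
# harmonic amplitudes, and cycle-averaged pressure magnitude staying within a
# few percent of the pure-sine prediction at equal stroke volume.
.physio_amplitudes <- c(1, 0.4097, 0.1692, 0.1084, 0.0037, 0.0055, 0.0059, 0.0031)
.physio_phases     <- c(0, -1.5526, -0.9910, -2.6806, -1.0997, 1.2806, -2.5735, -2.4730)

#' The frozen physiologic flow waveform
#'
#' Harmonic table of the synthetic cardiac-like aqueduct flow waveform used
#' for `waveform = "physiologic"` throughout the package:
#' `Qbar(tau) = s * sum_n A_n sin(n tau + theta_n)` with the scale `s` fixed
#' so the waveform carries unit dimensionless stroke volume
#' (`mean|Qbar| = 1/pi`, as for `Qbar = (1/2) sin tau`).  It exhibits three
#' peaks and three troughs per cycle with a dominant systolic peak.
#'
#' This is a documented stand-in constructed from qualitative features of
#' cardiac-gated PC-MRI aqueduct waveforms, not a subject measurement.
#'
#' @return Data frame with columns `n`, `amplitude` (before stroke
#'   normalization) and `phase` \[rad\].
#' @export
physiologic_harmonics <- function() {
  data.frame(n = seq_along(.physio_amplitudes),
             amplitude = .physio_amplitudes,
             phase = .physio_phases)
}

# complex coefficients of the stroke-normalized physiologic Qbar
physiologic_coefficients <- function() {
  cn <- complex(real = 0, imaginary = -1) * .physio_amplitudes *
    exp(1i * .physio_phases)
  tau <- 2 * pi * (0:16383) / 16384
  q <- harmonic_eval(cn, tau)
  m <- pracma::trapz(c(tau, 2 * pi), c(abs(q), abs(q[1L]))) / (2 * pi)
  cn / (pi * m)
}

#' Generate one period of a flow-rate waveform
#'
#' Builds the volumetric flow rate `Q(t)` delivered by the pump over one
#' period: the harmonic waveform `Q = (1/2) Vs omega sin(omega t)`, or the
#' frozen physiologic stand-in of [physiologic_harmonics()], both scaled so
#' that the stroke volume `(1/2) * integral(|Q| dt)` equals `Vs`.
#'
#' @param kind `"harmonic"` or `"physiologic"`.
#' @param stroke_volume_Vs stroke volume \[m^3\].
#' @param omega angular frequency \[rad/s\].
#' @param n_samples_per_cycle samples over the period (endpoint excluded).
#' @return A [signal_trace()] of `Q` \[m^3/s\] at rate
#'   `n_samples_per_cycle * omega / (2*pi)` Hz.
#' @examples
#' q <- make_waveform("physiologic", stroke_volume_Vs = 80e-6,
#'                    omega = bpm_to_omega(24))
#' @export
make_waveform <- function(kind = c("harmonic", "physiologic"),
                          stroke_volume_Vs, omega,
                          n_samples_per_cycle = 256L) {
  kind <- match.arg(kind)
  check_positive(stroke_volume_Vs, "stroke_volume_Vs")
  check_positive(omega, "omega")
  tau <- 2 * pi * (seq_len(n_samples_per_cycle) - 1L) / n_samples_per_cycle
  cn <- if (kind == "harmonic") {
    complex(real = 0, imaginary = -0.5)
  } else {
    physiologic_coefficients()
  }
  # Qbar carries unit dimensionless stroke, so Q = Vs * omega * Qbar(omega t)
  q <- stroke_volume_Vs * omega * harmonic_eval(cn, tau)
  signal_trace(q, rate = n_samples_per_cycle * omega / (2 * pi),
               t0 = 0, units = "m3/s")
}
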