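# Processing chain from raw pump/transducer recordings to the cycle-averaged
# dimensionless pressure magnitude and flow/pressure phase lag.

#' Raw experimental recording
#'
#' Bundles the two measured channels — differential pressure (sampled at
#' 80 Hz by the transducer) and piston position (2500 Hz from the pump's
#' analog output) — with the configuration needed to process them.
#'
#' @param pressure [signal_trace()] of differential pressure \[Pa\].
#' @param piston_position [signal_trace()] of piston position \[m\].
#' @param piston_area piston cross-section area \[m^2\].
#' @param geometry a [canal_geometry()].
#' @param fluid a [fluid_properties()].
#' @param omega drive angular frequency \[rad/s\].
#' @param waveform waveform tag: `"harmonic"` or `"physiologic"`; controls the
#'   low-pass cutoff used in processing (5x vs 8x the fundamental).
#' @param Ls_over_L_nominal commanded dimensionless stroke length (optional,
#'   for bookkeeping).
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(pressure, piston_position, piston_area,
                          geometry, fluid, omega,
                          waveform = c("harmonic", "physiologic"),
                          Ls_over_L_nominal = NA_real_) {
  stopifnot(inherits(pressure, "signal_trace"),
            inherits(piston_position, "signal_trace"),
            inherits(geometry, "canal_geometry"),
            inherits(fluid, "fluid_properties"))
  waveform <- match.arg(waveform)
  check_positive(piston_area, "piston_area")
  check_positive(omega, "omega")
  t_start <- max(pressure$t0, piston_position$t0)
  t_end <- min(pressure$t0 + (length(pressure$values) - 1L) / pressure$rate,
               piston_position$t0 +
                 (length(piston_position$values) - 1L) / piston_position$rate)
  if (t_end <= t_start) stop("pressure and piston traces do not overlap in time",
                             call. = FALSE)
  n_common <- (t_end - t_start) / (2 * pi / omega)
  if (n_common < 5 - 0.01) {
    warning(sprintf("traces share only %.2g cycles; at least 5 are recommended",
                    n_common), call. = FALSE)
  }
  structure(
    list(pressure = pressure, piston_position = piston_position,
         piston_area = piston_area, geometry = geometry, fluid = fluid,
         omega = omega, waveform = waveform,
         Ls_over_L_nominal = Ls_over_L_nominal),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("Raw recording\n")
  cat(sprintf("  omega = %.4g rad/s (%.3g BPM), %s waveform\n",
              x$omega, omega_to_bpm(x$omega), x$waveform))
  cat("  pressure: "); print(x$pressure)
  cat("  piston  : "); print(x$piston_position)
  invisible(x)
}

#' Hampel despiking filter
#'
#' Replaces outlier samples by the local median: sample `i` is replaced by the
#' median of the window `x[i-k .. i+k]` whenever it deviates from that median
#' by more than `n_sigmas * 1.4826 * MAD` of the window (the MAD scaled to a
#' Gaussian sigma).  All other samples pass through unchanged.  Windows are
#' clamped at the trace ends so edge spikes are also caught.
#'
#' Serial logging of the pump's piston-position output occasionally produces
#' isolated spikes far larger (100x and more) than the signal peak; this
#' filter removes them without smearing genuine waveform features.
#'
#' @param trace a [signal_trace()] or numeric vector.
#' @param window_halfwidth half-window `k` in samples (window length `2k+1`).
#' @param n_sigmas rejection threshold in robust standard deviations.
#' @param rate sampling rate \[Hz\] for plain numeric input.
#' @return Despiked trace of the same class as the input.
#' @export
hampel_despike <- function(trace, window_halfwidth, n_sigmas = 5, rate = NULL) {
  was_trace <- inherits(trace, "signal_trace")
  tr <- if (was_trace) trace else as_trace(trace, rate %||% 1)
  x <- tr$values
  n <- length(x)
  k <- as.integer(window_halfwidth)
  if (k < 1L) stop("'window_halfwidth' must be >= 1 sample", call. = FALSE)
  if (2L * k + 1L > n) stop("Hampel window longer than the trace", call. = FALSE)

  # fast prefilter with a running median (C code), then the exact windowed
  # decision only for candidate samples; spikes are rare so this is cheap
  m_run <- stats::runmed(x, 2L * k + 1L, endrule = "median")
  d <- abs(x - m_run)
  s_run <- stats::runmed(d, 2L * k + 1L, endrule = "median")
  cand <- which(d > 0 & d >= 0.5 * n_sigmas * 1.4826 * s_run)

  y <- x
  for (i in cand) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    w <- x[lo:hi]
    m0 <- stats::median(w)
    S0 <- 1.4826 * stats::median(abs(w - m0))
    if (abs(x[i] - m0) > n_sigmas * S0) y[i] <- m0
  }
  if (was_trace) {
    signal_trace(y, rate = tr$rate, t0 = tr$t0, units = tr$units)
  } else {
    y
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward (zero phase),
#' with odd-reflection padding at both ends to suppress start-up transients.
#' Zero phase is essential here: a causal filter would bias the measured
#' flow/pressure phase lag.  At the conventional cutoffs of 5x or 8x the
#' drive frequency the passband gain at the fundamental is within 1% of unity
#' with no phase shift.
#'
#' @param trace a [signal_trace()] or numeric vector.
#' @param cutoff cutoff frequency \[Hz\], must be below the Nyquist frequency.
#' @param rate sampling rate \[Hz\] for plain numeric input.
#' @param order filter order (default 4).
#' @return Filtered trace of the same class as the input.
#' @export
lowpass <- function(trace, cutoff, rate = NULL, order = 4L) {
  was_trace <- inherits(trace, "signal_trace")
  tr <- if (was_trace) trace else as_trace(trace, rate)
  fs <- tr$rate
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff %.4g Hz is at or above the Nyquist frequency %.4g Hz",
                 cutoff, fs / 2), call. = FALSE)
  }
  check_positive(cutoff, "cutoff")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  bf$b <- bf$b * sum(bf$a) / sum(bf$b)   # pin the DC gain to exactly 1
  x <- tr$values
  n <- length(x)
  padlen <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff)))
  xp <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - padlen)])
  # filter about the first sample's level so a constant excites no transient
  run <- function(v) {
    as.numeric(signal::filter(bf, v - v[1L])) + v[1L]
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y <- y[(padlen + 1L):(padlen + n)]
  if (was_trace) {
    signal_trace(as.numeric(y), rate = fs, t0 = tr$t0, units = tr$units)
  } else {
    as.numeric(y)
  }
}

# Align the two channels of a recording on the pressure-channel grid inside
# the common time window, converting piston position to flow rate:
# despike (2500 Hz) -> anti-alias low-pass -> linear interpolation onto the
# 80 Hz grid -> central-difference -> Q = area * dx/dt.
align_and_convert <- function(recording, hampel_width_frac = 0.1,
                              hampel_nsigmas = 5) {
  p <- recording$pressure
  xtr <- recording$piston_position
  T_ <- 2 * pi / recording$omega

  k <- max(1L, round(hampel_width_frac * T_ * xtr$rate))
  xd <- with_stage("hampel_despike",
                   hampel_despike(xtr, window_halfwidth = k,
                                  n_sigmas = hampel_nsigmas))
  xf <- with_stage("anti_alias",
                   lowpass(xd, cutoff = 0.4 * p$rate))

  tx <- trace_times(xf)
  tp <- trace_times(p)
  keep <- which(tp >= tx[1L] & tp <= tx[length(tx)])
  if (length(keep) < 3L) {
    stop("[align] fewer than 3 pressure samples inside the common time window",
         call. = FALSE)
  }
  tg <- tp[keep]
  x80 <- stats::approx(tx, xf$values, xout = tg)$y

  dt <- 1 / p$rate
  nq <- length(x80)
  dx <- numeric(nq)
  dx[2:(nq - 1L)] <- (x80[3:nq] - x80[1:(nq - 2L)]) / (2 * dt)
  dx[1L] <- (x80[2L] - x80[1L]) / dt
  dx[nq] <- (x80[nq] - x80[nq - 1L]) / dt
  q <- recording$piston_area * dx

  list(flow = signal_trace(q, rate = p$rate, t0 = tg[1L], units = "m3/s"),
       pressure = signal_trace(p$values[keep], rate = p$rate, t0 = tg[1L],
                               units = "Pa"))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Flow rate from the piston-position channel
#'
#' Converts the raw piston-position recording to a volumetric flow-rate trace
#' on the pressure-channel 80 Hz grid: Hampel despiking at the native rate,
#' anti-alias low-pass, linear interpolation onto the common grid, then
#' central differences (one-sided at the endpoints) times the piston area.
#'
#' @param recording a [raw_recording()].
#' @param hampel_width_frac Hampel half-window as a fraction of the
#'   oscillation period (default 0.1).
#' @param hampel_nsigmas Hampel rejection threshold.
#' @return [signal_trace()] of `Q` \[m^3/s\].
#' @export
position_to_flowrate <- function(recording, hampel_width_frac = 0.1,
                                 hampel_nsigmas = 5) {
  stopifnot(inherits(recording, "raw_recording"))
  if (is.null(recording$piston_area) || !is.numeric(recording$piston_area)) {
    stop("recording is missing 'piston_area'", call. = FALSE)
  }
  align_and_convert(recording, hampel_width_frac, hampel_nsigmas)$flow
}

#' Phase lag between pressure and flow fundamentals
#'
#' `phi = arg(P_1) - arg(Q_1)`, the phase of the pressure fundamental minus
#' the phase of the flow fundamental, estimated from the FFT bin nearest the
#' drive frequency and wrapped to `(-pi, pi]`.  Positive `phi` means the
#' pressure difference peaks before the flow rate.  The spectral definition
#' is robust to waveform shape and jitter, unlike peak-to-peak timing.
#'
#' @param Qbar flow channel ([signal_trace()] or numeric), any units.
#' @param Pi pressure channel, synchronized with `Qbar` (same rate, length).
#' @param omega drive angular frequency \[rad/s\].
#' @param rate sampling rate \[Hz\] for plain numeric inputs.
#' @return Phase lag in radians, in `(-pi, pi]`.
#' @examples
#' tau <- 2 * pi * (0:799) / 200
#' phase_lag(sin(tau), cos(tau), omega = 1, rate = 200 / (2 * pi))  # +pi/2
#' @export
phase_lag <- function(Qbar, Pi, omega, rate = NULL) {
  q <- as_trace(Qbar, rate)
  p <- as_trace(Pi, rate)
  if (length(q$values) != length(p$values) ||
      abs(q$rate - p$rate) > 1e-9 * q$rate) {
    stop("flow and pressure channels must be synchronized ",
         "(same length and sampling rate)", call. = FALSE)
  }
  q <- trim_cycles(q, omega)
  n_c <- attr(q, "n_cycles")
  if (n_c < 2L) {
    stop("insufficient cycles for phase estimation: ",
         "need >= 2 for adequate frequency resolution", call. = FALSE)
  }
  p$values <- p$values[seq_along(q$values)]
  N <- length(q$values)
  bin <- round((omega / (2 * pi)) * N / q$rate) + 1L
  wrap_phase(Arg(stats::fft(p$values)[bin]) - Arg(stats::fft(q$values)[bin]))
}

#' Process a raw recording into a cycle-averaged pressure summary
#'
#' Runs the full measurement chain: align channels by timestamps; despike the
#' piston signal; convert position to flow rate; low-pass both channels at
#' `cutoff_multiple` times the drive frequency (5x for the harmonic waveform,
#' 8x for the physiologic one, which needs more high-frequency content);
#' discard one settling cycle at each end (when at least 4 are available);
#' trim to whole cycles; zero-average the pressure; nondimensionalize; and
#' compute the cycle-averaged `mean|Pi|`, the phase lag `phi` and the
#' dimensional `mean|dp|`.
#'
#' @param recording a [raw_recording()].
#' @param cutoff_multiple low-pass cutoff as a multiple of the drive
#'   frequency; default 5 (harmonic) or 8 (physiologic) per the waveform tag.
#' @param hampel_width_frac,hampel_nsigmas despiking parameters, see
#'   [hampel_despike()].
#' @param drop_guard_cycles discard the first and last cycle (filter settling)
#'   when at least 4 whole cycles are available.
#' @return Object of class `pressure_summary` with fields `mean_abs_Pi`,
#'   `phase_lag_phi`, `mean_abs_dp` \[Pa\], `groups`
#'   ([dimensionless_groups()] with the measured stroke length),
#'   `n_cycles_used`, and the trimmed dimensionless waveforms.
#' @examples
#' geo <- canal_geometry(0.158, 0.013)
#' fl <- glycerol_water_properties(0.84)
#' rec <- simulate_recording(geo, fl, bpm_to_omega(24), Ls_over_L = 1,
#'                           noise = noise_spec(seed = 1), n_cycles = 6)
#' process_experiment(rec)
#' @export
process_experiment <- function(recording, cutoff_multiple = NULL,
                               hampel_width_frac = 0.1, hampel_nsigmas = 5,
                               drop_guard_cycles = TRUE) {
  stopifnot(inherits(recording, "raw_recording"))
  omega <- recording$omega
  f0 <- omega / (2 * pi)
  if (is.null(cutoff_multiple)) {
    cutoff_multiple <- if (recording$waveform == "physiologic") 8 else 5
  }

  ch <- align_and_convert(recording, hampel_width_frac, hampel_nsigmas)
  qf <- with_stage("lowpass_flow", lowpass(ch$flow, cutoff_multiple * f0))
  pf <- with_stage("lowpass_pressure", lowpass(ch$pressure, cutoff_multiple * f0))

  # settling guard: drop first and last cycle when enough are available
  T_ <- 2 * pi / omega
  n_avail <- floor(((length(qf$values) - 1L) / qf$rate) / T_ + 0.01)
  if (drop_guard_cycles && n_avail >= 4L) {
    drop_n <- round(T_ * qf$rate)
    idx <- (drop_n + 1L):(length(qf$values) - drop_n)
    qf <- signal_trace(qf$values[idx], qf$rate, t0 = qf$t0 + drop_n / qf$rate,
                       units = qf$units)
    pf <- signal_trace(pf$values[idx], pf$rate, t0 = pf$t0 + drop_n / pf$rate,
                       units = pf$units)
  }

  qt <- with_stage("trim_cycles", trim_cycles(qf, omega))
  n_c <- attr(qt, "n_cycles")
  if (n_c < 2L) {
    stop("[trim_cycles] insufficient cycles: need >= 2 whole cycles after ",
         "alignment and settling guard", call. = FALSE)
  }
  pv <- pf$values[seq_along(qt$values)]
  pt <- signal_trace(pv - mean(pv), pf$rate, t0 = qt$t0, units = "Pa")

  sm <- with_stage("stroke_metrics",
                   stroke_metrics(qt, recording$geometry, omega))
  dw <- with_stage("nondimensionalize",
                   nondimensionalize(pt, qt, recording$fluid,
                                     recording$geometry, omega, sm$Ls))
  mean_abs_Pi <- with_stage("mean_abs_cycle",
                            mean_abs_cycle(dw$Pi, omega, rate = dw$rate))
  phi <- with_stage("phase_lag",
                    phase_lag(dw$Qbar, dw$Pi, omega, rate = dw$rate))
  groups <- dimensionless_groups(recording$geometry, recording$fluid, omega,
                                 stroke_volume = sm$Vs, warn = FALSE)

  structure(
    list(mean_abs_Pi = mean_abs_Pi, phase_lag_phi = phi,
         mean_abs_dp = mean_abs_Pi * dw$pressure_scale,
         groups = groups, n_cycles_used = n_c,
         waveform = recording$waveform, stroke = sm,
         dimensionless = dw),
    class = "pressure_summary"
  )
}

#' @export
print.pressure_summary <- function(x, ...) {
  cat("Cycle-averaged pressure summary\n")
  cat(sprintf("  alpha = %.4g, Ls/L = %.4g, a/L = %.4g (%s waveform, %d cycles)\n",
              x$groups$alpha, x$groups$Ls_over_L, x$groups$a_over_L,
              x$waveform, x$n_cycles_used))
  cat(sprintf("  mean|Pi|  = %.4g\n", x$mean_abs_Pi))
  cat(sprintf("  phase lag = %.4g rad\n", x$phase_lag_phi))
  cat(sprintf("  mean|dp|  = %.4g Pa\n", x$mean_abs_dp))
  invisible(x)
}

#' @export
coef.pressure_summary <- function(object, ...) {
  c(mean_abs_Pi = object$mean_abs_Pi,
    phase_lag_phi = object$phase_lag_phi,
    mean_abs_dp = object$mean_abs_dp)
}

#' @export
plot.pressure_summary <- function(x, n_bins = 128L, ...) {
  fd <- fold_cycles(x$dimensionless, n_bins)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(fd$tau, fd$Qbar, type = "l", xlab = expression(tau),
                 ylab = expression(bar(Q)), ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::plot(fd$tau, fd$Pi, type = "l", xlab = expression(tau),
                 ylab = expression(Pi), ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' @export
as.data.frame.pressure_summary <- function(x, ...) {
  data.frame(alpha = x$groups$alpha, Ls_over_L = x$groups$Ls_over_L,
             a_over_L = x$groups$a_over_L, waveform = x$waveform,
             mean_abs_Pi = x$mean_abs_Pi, phase_lag_phi = x$phase_lag_phi,
             mean_abs_dp_Pa = x$mean_abs_dp, n_cycles = x$n_cycles_used)
}
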