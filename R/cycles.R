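#' Trim a trace to an integer number of oscillation cycles
#'
#' Keeps the largest whole number of periods `T = 2*pi/omega` from the start
#' of the trace.  Cycle-averaged quantities are only meaningful over whole
#' cycles; a fractional trailing cycle would bias them.
#'
#' @param trace a [signal_trace()] (or numeric vector with `rate`).
#' @param omega angular frequency \[rad/s\].
#' @param rate sampling rate \[Hz\] when `trace` is a plain vector.
#' @param tol tolerated fractional shortfall of a period when counting whole
#'   cycles (default 1%).
#' @return The trimmed `signal_trace` with attribute `"n_cycles"`.
#' @export
trim_cycles <- function(trace, omega, rate = NULL, tol = 0.01) {
  trace <- as_trace(trace, rate)
  check_positive(omega, "omega")
  T_ <- 2 * pi / omega
  duration <- (length(trace$values) - 1L) / trace$rate
  n_c <- floor(duration / T_ + tol)
  if (n_c < 1L) {
    stop(sprintf("trace covers %.3g cycles: less than one full cycle", duration / T_),
         call. = FALSE)
  }
  n_keep <- min(length(trace$values), round(n_c * T_ * trace$rate) + 1L)
  out <- signal_trace(trace$values[seq_len(n_keep)], rate = trace$rate,
                      t0 = trace$t0, units = trace$units)
  attr(out, "n_cycles") <- n_c
  out
}

# internal: assert the trace spans an integer number of cycles within tol*T
check_integer_cycles <- function(trace, omega, tol = 0.01, min_cycles = 1L) {
  T_ <- 2 * pi / omega
  duration <- (length(trace$values) - 1L) / trace$rate
  n_c <- round(duration / T_)
  if (n_c < min_cycles) {
    stop(sprintf("insufficient cycles: trace covers %.3g, need >= %d",
                 duration / T_, min_cycles), call. = FALSE)
  }
  if (abs(duration - n_c * T_) > tol * T_) {
    stop(sprintf("trace covers a non-integer number of cycles (%.4g)", duration / T_),
         call. = FALSE)
  }
  n_c
}

#' Cycle-averaged magnitude of a periodic signal
#'
#' Computes `(omega / 2*pi) * integral(|x| dt)` per cycle by the trapezoidal
#' rule on the sampled grid, averaged over the whole cycles the trace covers.
#' This is the averaging operator behind the mean transmantle pressure
#' magnitude `mean|dp|` and its dimensionless counterpart `mean|Pi|`.
#'
#' @inheritParams trim_cycles
#' @param tol tolerance on the integer-cycle requirement, as a fraction of a
#'   period; a trace whose duration is further than this from a whole number
#'   of cycles is rejected.
#' @return Scalar cycle-averaged magnitude, in the units of `trace`.
#' @examples
#' tau <- seq(0, 2 * pi, length.out = 2001)
#' mean_abs_cycle(sin(tau), omega = 1, rate = 2000 / (2 * pi))  # 2/pi
#' @export
mean_abs_cycle <- function(trace, omega, rate = NULL, tol = 0.01) {
  trace <- as_trace(trace, rate)
  check_positive(omega, "omega")
  check_integer_cycles(trace, omega, tol)
  t <- trace_times(trace)
  pracma::trapz(t, abs(trace$values)) / (t[length(t)] - t[1L])
}

#' Stroke volume and stroke length from a flow-rate trace
#'
#' The stroke volume is the fluid volume displaced back and forth per cycle,
#' `Vs = (1/2) * integral(|Q| dt)` over one period (trapezoidal rule, averaged
#' over the available whole cycles).  The stroke length `Ls = Vs / (pi a^2)`
#' is the equivalent axial excursion of the fluid column in the canal.
#'
#' @param flow_trace flow-rate trace \[m^3/s\]; [signal_trace()] or numeric.
#' @param geometry a [canal_geometry()].
#' @inheritParams mean_abs_cycle
#' @return List with `Vs` \[m^3\], `Ls` \[m\] and `Ls_over_L`.
#' @export
stroke_metrics <- function(flow_trace, geometry, omega, rate = NULL, tol = 0.01) {
  stopifnot(inherits(geometry, "canal_geometry"))
  flow_trace <- as_trace(flow_trace, rate)
  m <- mean_abs_cycle(flow_trace, omega, tol = tol)
  T_ <- 2 * pi / omega
  Vs <- m * T_ / 2
  Ls <- Vs / (pi * geometry$mean_radius_a^2)
  list(Vs = Vs, Ls = Ls, Ls_over_L = Ls / geometry$length_L)
}

#' Nondimensionalize synchronized pressure and flow traces
#'
#' Maps the measured interventricular pressure difference and flow rate to
#' their dimensionless forms
#' `Pi = dp / (rho * omega^2 * L * Ls)` and `Qbar = Q / (omega * pi * a^2 * Ls)`
#' on the phase variable `tau = omega * (t - t0)`.  The pressure scale follows
#' from balancing the local fluid acceleration `~ Ls * omega^2` against the
#' pressure force per unit mass.
#'
#' @param pressure_trace differential pressure \[Pa\], a [signal_trace()].
#' @param flow_trace flow rate \[m^3/s\], a [signal_trace()] with the same
#'   sampling rate and length.
#' @param fluid a [fluid_properties()].
#' @param geometry a [canal_geometry()].
#' @param omega angular frequency \[rad/s\].
#' @param Ls stroke length \[m\] (from [stroke_metrics()] or commanded).
#' @return Object of class `dimensionless_waveforms`: `tau` (phase, radians,
#'   increasing from 0), `Pi`, `Qbar`, plus the scales needed by
#'   [redimensionalize()].
#' @export
nondimensionalize <- function(pressure_trace, flow_trace, fluid, geometry,
                              omega, Ls) {
  stopifnot(inherits(pressure_trace, "signal_trace"),
            inherits(flow_trace, "signal_trace"),
            inherits(fluid, "fluid_properties"),
            inherits(geometry, "canal_geometry"))
  check_positive(omega, "omega")
  check_positive(Ls, "Ls")
  if (length(pressure_trace$values) != length(flow_trace$values)) {
    stop("pressure and flow traces have mismatched lengths", call. = FALSE)
  }
  if (abs(pressure_trace$rate - flow_trace$rate) >
      1e-9 * flow_trace$rate) {
    stop("pressure and flow traces have mismatched sampling rates", call. = FALSE)
  }
  p_scale <- fluid$density_rho * omega^2 * geometry$length_L * Ls
  q_scale <- omega * pi * geometry$mean_radius_a^2 * Ls
  tau <- omega * (trace_times(pressure_trace) - pressure_trace$t0)
  structure(
    list(tau = tau,
         Pi = pressure_trace$values / p_scale,
         Qbar = flow_trace$values / q_scale,
         rate = pressure_trace$rate, omega = omega,
         pressure_scale = p_scale, flow_scale = q_scale,
         t0 = pressure_trace$t0),
    class = "dimensionless_waveforms"
  )
}

#' @rdname nondimensionalize
#' @param dw a `dimensionless_waveforms` object.
#' @return `redimensionalize()` returns a list of two [signal_trace()]s,
#'   `pressure` \[Pa\] and `flow` \[m^3/s\].
#' @export
redimensionalize <- function(dw) {
  stopifnot(inherits(dw, "dimensionless_waveforms"))
  list(
    pressure = signal_trace(dw$Pi * dw$pressure_scale, rate = dw$rate,
                            t0 = dw$t0, units = "Pa"),
    flow = signal_trace(dw$Qbar * dw$flow_scale, rate = dw$rate,
                        t0 = dw$t0, units = "m3/s")
  )
}

#' Fold a multi-cycle dimensionless record onto one cycle
#'
#' Phase-averages `Pi` and `Qbar` onto a uniform grid of `n_bins` phases in
#' `[0, 2*pi)`, pooling all recorded cycles.  Useful for plotting measured
#' waveforms against model predictions.
#'
#' @param dw a `dimensionless_waveforms` object.
#' @param n_bins number of phase bins per cycle.
#' @return A `dimensionless_waveforms` object covering a single cycle.
#' @export
fold_cycles <- function(dw, n_bins = 128L) {
  stopifnot(inherits(dw, "dimensionless_waveforms"))
  ph <- dw$tau %% (2 * pi)
  bin <- floor(ph / (2 * pi) * n_bins) + 1L
  bin[bin > n_bins] <- n_bins
  out <- dw
  out$tau <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  out$Pi <- as.numeric(tapply(dw$Pi, factor(bin, levels = seq_len(n_bins)), mean))
  out$Qbar <- as.numeric(tapply(dw$Qbar, factor(bin, levels = seq_len(n_bins)), mean))
  out$rate <- NA_real_
  out
}

#' @export
print.dimensionless_waveforms <- function(x, ...) {
  cat(sprintf("Dimensionless waveforms: %d samples, %.3g cycles\n",
              length(x$Pi), (x$tau[length(x$tau)] - x$tau[1L]) / (2 * pi)))
  cat(sprintf("  max|Pi| = %.4g, max|Qbar| = %.4g\n",
              max(abs(x$Pi)), max(abs(x$Qbar))))
  invisible(x)
}
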