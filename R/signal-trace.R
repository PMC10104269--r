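#' Uniformly sampled time series
#'
#' Light container for the recorded channels: a start time, a sampling rate
#' and a vector of finite sample values with a units tag.
#'
#' @param values numeric vector of samples (length >= 2, all finite).
#' @param rate sampling frequency \[Hz\].
#' @param t0 time of the first sample \[s\].
#' @param units units tag, one of `"Pa"`, `"m"`, `"m3/s"`, `"dimensionless"`.
#' @return Object of class `signal_trace`.
#' @export
signal_trace <- function(values, rate, t0 = 0,
                         units = c("dimensionless", "Pa", "m", "m3/s")) {
  units <- match.arg(units)
  check_positive(rate, "rate")
  values <- as.numeric(values)
  if (length(values) < 2L) stop("'values' must have length >= 2", call. = FALSE)
  if (!all(is.finite(values))) stop("'values' must all be finite", call. = FALSE)
  structure(list(t0 = t0, rate = rate, values = values, units = units),
            class = "signal_trace")
}

#' @rdname signal_trace
#' @param x a `signal_trace`.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "signal_trace"))
  x$t0 + (seq_along(x$values) - 1) / x$rate
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("Signal trace [%s]: %d samples at %.5g Hz, t = [%.4g, %.4g] s\n",
              x$units, length(x$values), x$rate, x$t0,
              x$t0 + (length(x$values) - 1) / x$rate))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$values)

# internal: coerce numeric/trace inputs to a trace
as_trace <- function(x, rate = NULL, units = "dimensionless") {
  if (inherits(x, "signal_trace")) return(x)
  if (is.null(rate)) stop("'rate' is required for plain numeric input", call. = FALSE)
  signal_trace(x, rate = rate, units = units)
}
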