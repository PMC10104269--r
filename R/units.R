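#' Unit conversions at the I/O boundary
#'
#' All internal computations use strict SI units (m, s, kg, Pa, rad/s).
#' Clinical and pump-facing quantities are usually quoted in beats per minute
#' (BPM), millilitres and inches of water; these helpers convert them once,
#' at the boundary.
#'
#' `inh2o_to_pa()` uses the conventional 4 degC water column
#' (1 inH2O = 249.082 Pa), the reference condition quoted by differential
#' pressure transducer data sheets.
#'
#' @param bpm cycles per minute.
#' @param omega angular frequency \[rad/s\].
#' @param x value to convert (vectorized).
#' @return Converted numeric vector.
#' @examples
#' bpm_to_omega(60)        # 2*pi rad/s
#' omega_to_bpm(2 * pi)    # 60 BPM
#' inh2o_to_pa(10)         # sensor full scale, about 2490 Pa
#' @name units
NULL

#' @rdname units
#' @export
bpm_to_omega <- function(bpm) bpm / 60 * 2 * pi

#' @rdname units
#' @export
omega_to_bpm <- function(omega) omega * 60 / (2 * pi)

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname units
#' @export
inh2o_to_pa <- function(x) x * 249.082

# internal: positive scalar check with informative field name
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
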