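# Plain-text I/O for recordings: two CSV channel files plus a YAML config.

#' Read and write raw recordings as CSV + YAML
#'
#' A recording on disk is a directory with `pressure.csv` (`t_s, dp_Pa`, the
#' 80 Hz transducer channel), `piston.csv` (`t_s, x_m`, the 2500 Hz pump
#' channel) and `config.yaml` (geometry, fluid, drive frequency, waveform tag
#' and piston area).  Sampling rates are inferred from the time stamps, which
#' must be uniform.
#'
#' @param path directory containing (for `read_recording`) or receiving (for
#'   `write_recording`) the three files.
#' @param recording a [raw_recording()].
#' @return `read_recording()` returns a [raw_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path) {
  pfile <- file.path(path, "pressure.csv")
  xfile <- file.path(path, "piston.csv")
  cfile <- file.path(path, "config.yaml")
  for (f in c(pfile, xfile, cfile)) {
    if (!file.exists(f)) stop("missing recording file: ", f, call. = FALSE)
  }
  cfg <- yaml::read_yaml(cfile)
  p <- utils::read.csv(pfile)
  x <- utils::read.csv(xfile)
  raw_recording(
    pressure = trace_from_columns(p[[1L]], p[[2L]], "Pa"),
    piston_position = trace_from_columns(x[[1L]], x[[2L]], "m"),
    piston_area = cfg$piston_area,
    geometry = canal_geometry(cfg$length_L, cfg$mean_radius_a),
    fluid = fluid_properties(cfg$density_rho, cfg$kin_viscosity_nu),
    omega = cfg$omega, waveform = cfg$waveform,
    Ls_over_L_nominal = cfg$Ls_over_L_nominal %||% NA_real_
  )
}

trace_from_columns <- function(t, v, units) {
  dt <- diff(t)
  if (length(dt) < 1L || any(dt <= 0)) {
    stop("time stamps must be strictly increasing", call. = FALSE)
  }
  if ((max(dt) - min(dt)) > 1e-3 * stats::median(dt)) {
    stop("time stamps must be uniformly spaced", call. = FALSE)
  }
  signal_trace(v, rate = 1 / stats::median(dt), t0 = t[1L], units = units)
}

#' @rdname read_recording
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(t_s = trace_times(recording$pressure),
               dp_Pa = recording$pressure$values),
    file.path(path, "pressure.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(t_s = trace_times(recording$piston_position),
               x_m = recording$piston_position$values),
    file.path(path, "piston.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(length_L = recording$geometry$length_L,
         mean_radius_a = recording$geometry$mean_radius_a,
         density_rho = recording$fluid$density_rho,
         kin_viscosity_nu = recording$fluid$kin_viscosity_nu,
         omega = recording$omega, waveform = recording$waveform,
         piston_area = recording$piston_area,
         Ls_over_L_nominal = recording$Ls_over_L_nominal),
    file.path(path, "config.yaml"))
  invisible(path)
}
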