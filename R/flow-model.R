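# Womersley rigid-tube impedance and the harmonic-superposition pressure model.
#
# The linear part of the model is the exact oscillatory Poiseuille (Womersley)
# solution for a rigid circular tube, applied per harmonic; a sign-preserving
# quadratic entrance-loss term accounts for the nearly inviscid pressure losses
# at the canal openings.

# J1(z)/J0(z) for complex z by continued fraction (modified Lentz).
# The recurrence J_{nu-1} + J_{nu+1} = (2 nu / z) J_nu gives
# J1/J0 = 1/(b1 - 1/(b2 - 1/(b3 - ...))), b_k = 2k/z.
# Stable for all |z| used here; iteration count grows ~ |z|.
bessel_j1_over_j0 <- function(z) {
  tiny <- 1e-300
  f <- tiny
  C <- f
  D <- 0
  for (k in 1:5000) {
    b <- 2 * k / z
    a <- if (k == 1L) 1 else -1
    D <- b + a * D
    if (abs(D) < tiny) D <- tiny
    C <- b + a / C
    if (abs(C) < tiny) C <- tiny
    D <- 1 / D
    delta <- C * D
    f <- f * delta
    if (abs(delta - 1) < 1e-15) return(f)
  }
  stop("Bessel continued fraction failed to converge; ",
       "cap the number of harmonics or reduce alpha", call. = FALSE)
}

# Womersley function F(alpha) = 1 - 2 J1(Lambda) / (Lambda J0(Lambda)),
# Lambda = i^{3/2} alpha.  Asymptotic branch for very large alpha where the
# continued fraction would need excessive iterations.
womersley_F <- function(alpha) {
  Lambda <- alpha * exp(3i * pi / 4)
  if (alpha > 200) {
    # J1/J0 -> i + 1/(2 Lambda) for Im(Lambda) large
    return(1 - 2i / Lambda - 1 / Lambda^2)
  }
  1 - 2 * bessel_j1_over_j0(Lambda) / Lambda
}

#' Dimensionless Womersley impedance of a rigid tube
#'
#' Per-harmonic complex impedance `Z_n` relating the dimensionless pressure
#' and flow-rate harmonics, `Pi_n = Z_n * Qbar_n`, for fully developed
#' oscillatory flow in a rigid circular tube:
#' `Z_n = i n / F(alpha_n)` with `F(alpha) = 1 - 2 J1(Lambda)/(Lambda J0(Lambda))`,
#' `Lambda = i^{3/2} alpha` and `alpha_n = alpha * sqrt(n)` the Womersley
#' number of harmonic `n`.
#'
#' Limits: `|Z| -> 8/alpha^2` as `alpha -> 0` (quasi-steady Poiseuille
#' friction, pressure in phase with flow) and `Z -> i n` as `alpha -> Inf`
#' (pure fluid inertia, pressure leading flow by 90 degrees).
#'
#' @param alpha Womersley number of the fundamental (positive scalar).
#' @param n harmonic index (vectorized, integers >= 1).
#' @return Complex vector of impedances, one per element of `n`.
#' @examples
#' Mod(womersley_impedance(0.1))   # ~ 8 / 0.1^2
#' womersley_impedance(100)        # ~ 0 + 1i
#' @export
womersley_impedance <- function(alpha, n = 1L) {
  check_positive(alpha, "alpha")
  if (any(n < 1) || any(n != round(n))) {
    stop("'n' must contain integer harmonic indices >= 1", call. = FALSE)
  }
  if (alpha * sqrt(max(n)) > 1e6) {
    stop("per-harmonic Womersley number exceeds 1e6; ",
         "cap the number of harmonics", call. = FALSE)
  }
  vapply(n, function(k) 1i * k / womersley_F(alpha * sqrt(k)), complex(1))
}

#' Fourier decomposition of a periodic flow waveform
#'
#' Represents one period of a zero-mean flow waveform as complex harmonic
#' amplitudes `c_n` such that `q(tau) = sum_n Re(c_n exp(i n tau))`.
#' A waveform with net volume flux (non-zero mean) is rejected, and a
#' truncation whose reconstruction error exceeds 0.5% RMS triggers a warning.
#'
#' @param q numeric vector: one period of uniformly spaced samples, endpoint
#'   excluded.
#' @param n_harmonics number of harmonics retained.
#' @param fundamental optional fundamental angular frequency \[rad/s\] carried
#'   along as metadata.
#' @return Object of class `harmonic_decomposition` with fields
#'   `coefficients` (complex, length `n_harmonics`), `n_harmonics` and
#'   `fundamental`.
#' @export
harmonic_decomposition <- function(q, n_harmonics = 8L, fundamental = NA_real_) {
  q <- as.numeric(q)
  N <- length(q)
  if (N < 2L * (n_harmonics + 1L)) {
    stop("need more than 2*(n_harmonics + 1) samples per period", call. = FALSE)
  }
  if (abs(mean(q)) > 1e-6 * max(abs(q))) {
    stop("waveform has net volume flux (non-zero mean over the period)",
         call. = FALSE)
  }
  X <- stats::fft(q)
  cn <- 2 * X[seq_len(n_harmonics) + 1L] / N
  recon <- harmonic_eval(cn, 2 * pi * (seq_len(N) - 1L) / N)
  rms_err <- sqrt(mean((q - mean(q) - recon)^2)) / sqrt(mean((q - mean(q))^2))
  if (rms_err > 0.005) {
    warning(sprintf("reconstruction error %.2g%% RMS at %d harmonics exceeds 0.5%%",
                    100 * rms_err, n_harmonics), call. = FALSE)
  }
  structure(list(coefficients = cn, n_harmonics = n_harmonics,
                 fundamental = fundamental),
            class = "harmonic_decomposition")
}

# evaluate sum_n Re(c_n exp(i n tau)) on a vector of phases
harmonic_eval <- function(cn, tau) {
  out <- numeric(length(tau))
  for (k in seq_along(cn)) {
    out <- out + Re(cn[k] * exp(1i * k * tau))
  }
  out
}

#' Womersley pressure model for oscillatory canal flow
#'
#' Builds the dimensionless flow model that predicts the interventricular
#' pressure waveform `Pi(tau)` generated by a prescribed periodic flow rate
#' `Qbar(tau)`:
#' \deqn{\Pi(\tau) = \sum_n Re[Z_n \hat{Q}_n e^{i n \tau}]
#'       + (K/2)(L_s/L)\,\bar{u}|\bar{u}|,}
#' where `Z_n` is the per-harmonic Womersley rigid-tube impedance
#' ([womersley_impedance()]), `ubar` the dimensionless section-mean velocity
#' and `K` a quadratic entrance-loss coefficient for the nearly inviscid
#' openings at the two ends of the canal.  With an axial area profile the
#' linear term series-sums per-slice uniform-tube impedances
#' (quasi-one-dimensional approximation).
#'
#' The default `entrance_loss_K = 0.7` is the sum of typical rounded-entry
#' and sudden-expansion minor-loss coefficients; it is a calibration knob.
#'
#' @param alpha Womersley number of the fundamental.
#' @param Ls_over_L dimensionless stroke length.
#' @param a_over_L canal aspect ratio (default 0.08, a generic aqueduct value).
#' @param entrance_loss_K dimensionless quadratic loss coefficient, >= 0.
#' @param n_harmonics harmonic truncation; `NULL` resolves per waveform at
#'   predict time (1 for harmonic, 8 for physiologic/tabulated, mirroring
#'   low-pass cutoffs of 5x and 8x the fundamental used when processing
#'   measurements).
#' @param geometry optional [canal_geometry()]; supplies `a_over_L` and, with
#'   `use_area_profile = TRUE`, the axial area profile.
#' @param use_area_profile use the geometry's area profile in the linear term.
#' @param warn warn when the groups leave the typical physiological ranges.
#' @return Object of class `aqueduct_model`.
#' @seealso [predict.aqueduct_model()], [simulate_recording()]
#' @examples
#' mdl <- aqueduct_model(alpha = 2, Ls_over_L = 1)
#' pr <- predict(mdl)
#' c(pr$mean_abs_Pi, pr$phase_lag)
#' @export
aqueduct_model <- function(alpha, Ls_over_L = 1, a_over_L = 0.08,
                           entrance_loss_K = 0.7, n_harmonics = NULL,
                           geometry = NULL, use_area_profile = FALSE,
                           warn = TRUE) {
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "canal_geometry"))
    a_over_L <- geometry$aspect_ratio
  }
  if (use_area_profile && (is.null(geometry) || is.null(geometry$area_profile))) {
    stop("'use_area_profile = TRUE' requires a geometry with an area profile",
         call. = FALSE)
  }
  if (entrance_loss_K < 0) stop("'entrance_loss_K' must be >= 0", call. = FALSE)
  if (!is.null(n_harmonics)) {
    if (n_harmonics < 1 || n_harmonics != round(n_harmonics)) {
      stop("'n_harmonics' must be an integer >= 1", call. = FALSE)
    }
  }
  groups <- dimensionless_groups(alpha = alpha, Ls_over_L = Ls_over_L,
                                 a_over_L = a_over_L, warn = warn)
  structure(
    list(groups = groups, entrance_loss_K = entrance_loss_K,
         n_harmonics = n_harmonics, geometry = geometry,
         use_area_profile = use_area_profile),
    class = "aqueduct_model"
  )
}

#' @export
print.aqueduct_model <- function(x, ...) {
  cat("Womersley pressure model for oscillatory canal flow\n")
  cat(sprintf("  alpha = %.4g, Ls/L = %.4g, a/L = %.4g\n",
              x$groups$alpha, x$groups$Ls_over_L, x$groups$a_over_L))
  cat(sprintf("  entrance loss K = %.3g, area profile: %s\n",
              x$entrance_loss_K,
              if (x$use_area_profile) "quasi-1D" else "uniform tube"))
  invisible(x)
}

# per-harmonic impedance, optionally integrating per-slice uniform-tube
# impedance along a variable-area profile:
# Z_n = (i n / L) * integral( (abar/a(x))^2 / F(alpha_n a(x)/abar) dx )
model_impedances <- function(model, n_vec) {
  alpha <- model$groups$alpha
  if (!model$use_area_profile) {
    return(womersley_impedance(alpha, n_vec))
  }
  prof <- model$geometry$area_profile
  abar <- model$geometry$mean_radius_a
  L <- model$geometry$length_L
  xs <- seq(prof[1L, "x"], prof[nrow(prof), "x"], length.out = 201L)
  Ax <- stats::approx(prof[, "x"], prof[, "area"], xout = xs)$y
  ax <- sqrt(Ax / pi)
  vapply(n_vec, function(k) {
    alpha_k <- alpha * sqrt(k)
    integrand <- vapply(ax, function(ai) {
      (abar / ai)^2 / womersley_F(alpha_k * ai / abar)
    }, complex(1))
    (1i * k / L) * pracma::trapz(xs, integrand)
  }, complex(1))
}

# dimensionless end-opening area for the quadratic loss term (mean of the two
# end slices; 1 for a uniform tube)
end_area_dimensionless <- function(model) {
  if (!model$use_area_profile) return(1)
  prof <- model$geometry$area_profile
  A0 <- pi * model$geometry$mean_radius_a^2
  mean(c(prof[1L, "area"], prof[nrow(prof), "area"])) / A0
}

#' Predict the dimensionless pressure waveform for a periodic flow rate
#'
#' Evaluates the model of [aqueduct_model()] for a given flow waveform and
#' returns the dimensionless pressure `Pi(tau)` on one cycle together with its
#' cycle-averaged magnitude `mean|Pi|` (trapezoidal rule) and the phase lag
#' `phi` of the pressure fundamental relative to the flow fundamental
#' (positive when pressure leads).
#'
#' @param object an [aqueduct_model()].
#' @param waveform `"harmonic"` (`Qbar = (1/2) sin(tau)`), `"physiologic"`
#'   (the frozen three-peaked stand-in of [physiologic_harmonics()]), a numeric
#'   vector of one-period flow samples, or a [harmonic_decomposition()].
#' @param n_out number of phase samples on the output cycle.
#' @param normalize rescale a tabulated waveform to unit dimensionless stroke
#'   (`mean|Qbar| = 1/pi`), so that predictions are comparable across
#'   waveforms at equal stroke volume.
#' @param ... unused.
#' @return Object of class `aqueduct_prediction`: `tau` (uniform on
#'   `[0, 2*pi)`), `Pi`, `Qbar`, `mean_abs_Pi`, `phase_lag`, `groups` and the
#'   resolved harmonic coefficients.
#' @examples
#' pr <- predict(aqueduct_model(alpha = 4, Ls_over_L = 1), waveform = "physiologic")
#' pr
#' @export
predict.aqueduct_model <- function(object, waveform = "harmonic",
                                   n_out = 2048L, normalize = TRUE, ...) {
  cn <- resolve_waveform(waveform, object$n_harmonics, normalize)
  n_vec <- seq_along(cn)
  Zn <- model_impedances(object, n_vec)

  tau <- 2 * pi * (seq_len(n_out) - 1L) / n_out
  Qbar <- harmonic_eval(cn, tau)
  Pi_lin <- numeric(n_out)
  for (k in n_vec) {
    Pi_lin <- Pi_lin + Re(Zn[k] * cn[k] * exp(1i * k * tau))
  }
  ubar <- Qbar / end_area_dimensionless(object)
  Pi <- Pi_lin + 0.5 * object$entrance_loss_K * object$groups$Ls_over_L *
    ubar * abs(ubar)

  mean_abs_Pi <- pracma::trapz(c(tau, 2 * pi), c(abs(Pi), abs(Pi[1L]))) / (2 * pi)
  phi <- phase_from_fft(Qbar, Pi, bin = 2L)

  structure(
    list(tau = tau, Pi = Pi, Qbar = Qbar,
         mean_abs_Pi = mean_abs_Pi, phase_lag = phi,
         groups = object$groups, entrance_loss_K = object$entrance_loss_K,
         coefficients = cn),
    class = "aqueduct_prediction"
  )
}

# phase of channel-2's fundamental minus channel-1's, wrapped to (-pi, pi]
phase_from_fft <- function(q, p, bin = 2L) {
  phi <- Arg(stats::fft(p)[bin]) - Arg(stats::fft(q)[bin])
  wrap_phase(phi)
}

wrap_phase <- function(phi) {
  phi <- (phi + pi) %% (2 * pi) - pi
  if (phi <= -pi + 1e-12) phi <- phi + 2 * pi  # convention: (-pi, pi]
  phi
}

# turn the user-facing waveform argument into complex harmonic coefficients
resolve_waveform <- function(waveform, n_harmonics, normalize) {
  if (inherits(waveform, "harmonic_decomposition")) {
    cn <- waveform$coefficients
  } else if (is.character(waveform)) {
    kind <- match.arg(waveform, c("harmonic", "physiologic"))
    if (kind == "harmonic") {
      cn <- complex(real = 0, imaginary = -0.5)
      if (!is.null(n_harmonics) && n_harmonics > 1L) {
        cn <- c(cn, rep(0 + 0i, n_harmonics - 1L))
      }
    } else {
      if (!is.null(n_harmonics) && n_harmonics < 8L) {
        stop("the physiologic waveform requires n_harmonics >= 8", call. = FALSE)
      }
      cn <- physiologic_coefficients()
    }
    return(cn)
  } else if (is.numeric(waveform)) {
    nh <- if (is.null(n_harmonics)) 8L else n_harmonics
    cn <- harmonic_decomposition(waveform, nh)$coefficients
  } else {
    stop("unknown waveform specification", call. = FALSE)
  }
  if (normalize) {
    tau <- 2 * pi * (0:8191) / 8192
    q <- harmonic_eval(cn, tau)
    m <- pracma::trapz(c(tau, 2 * pi), c(abs(q), abs(q[1L]))) / (2 * pi)
    cn <- cn / (pi * m)
  }
  cn
}

#' @export
print.aqueduct_prediction <- function(x, ...) {
  cat("Dimensionless pressure prediction\n")
  cat(sprintf("  alpha = %.4g, Ls/L = %.4g, a/L = %.4g, K = %.3g\n",
              x$groups$alpha, x$groups$Ls_over_L, x$groups$a_over_L,
              x$entrance_loss_K))
  cat(sprintf("  mean|Pi| = %.4g\n", x$mean_abs_Pi))
  cat(sprintf("  phase lag phi = %.4g rad (pressure %s flow)\n",
              x$phase_lag, if (x$phase_lag >= 0) "leads" else "lags"))
  invisible(x)
}

#' @export
as.data.frame.aqueduct_prediction <- function(x, ...) {
  data.frame(tau = x$tau, Pi = x$Pi, Qbar = x$Qbar)
}

#' @export
plot.aqueduct_prediction <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$tau, x$Qbar, type = "l", xlab = expression(tau),
                 ylab = expression(bar(Q)), ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::plot(x$tau, x$Pi, type = "l", xlab = expression(tau),
                 ylab = expression(Pi), ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
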