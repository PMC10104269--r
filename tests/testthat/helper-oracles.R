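# Independent oracles used across the test files.  Each solves the same
# physics (or definition) by a different route than the package code.

# Per-harmonic Womersley impedance by radial finite differences: solve the
# unsteady axisymmetric momentum equation
#   i n alpha^2 w = 1 + w'' + w'/y,  w(1) = 0,  w'(0) = 0
# on y in [0, 1] (second-order central differences, complex Thomas solver),
# integrate the dimensionless flux q = int_0^1 2 y w dy, and recover
# Z = 1 / (alpha^2 q).  Entirely independent of the Bessel continued fraction.
fd_womersley_impedance <- function(alpha, n = 1L, M = 3000L) {
  h <- 1 / M
  m <- M            # unknowns w_0 .. w_{M-1}; w_M = 0 (no-slip)
  ialn <- 1i * n * alpha^2
  A <- complex(m); B <- complex(m); C <- complex(m)
  B[1] <- ialn + 4 / h^2
  C[1] <- -4 / h^2
  j <- 2:m
  y <- (j - 1) * h
  A[j] <- -(1 / h^2 - 1 / (2 * y * h))
  B[j] <- ialn + 2 / h^2
  C[j] <- -(1 / h^2 + 1 / (2 * y * h))
  d <- rep(1 + 0i, m)
  # Thomas forward sweep
  for (i in 2:m) {
    f <- A[i] / B[i - 1]
    B[i] <- B[i] - f * C[i - 1]
    d[i] <- d[i] - f * d[i - 1]
  }
  w <- complex(m)
  w[m] <- d[m] / B[m]
  for (i in (m - 1):1) w[i] <- (d[i] - C[i] * w[i + 1]) / B[i]
  yfull <- (0:M) * h
  wfull <- c(w, 0 + 0i)
  q <- pracma::trapz(yfull, 2 * yfull * wfull)
  1 / (alpha^2 * q)
}

# Literal sample-by-sample Hampel decision (rolling median / rolling MAD with
# edge-clamped windows), written as the plain definition.
hampel_oracle <- function(x, k, n_sigmas = 5) {
  n <- length(x)
  y <- x
  for (i in seq_len(n)) {
    w <- x[max(1, i - k):min(n, i + k)]
    m0 <- median(w)
    S0 <- 1.4826 * median(abs(w - m0))
    if (abs(x[i] - m0) > n_sigmas * S0) y[i] <- m0
  }
  y
}

# Laboratory-style operating points: the anatomically realistic scaled canal
# (a = 1.3 cm, L = 15.8 cm) driven at the frequencies that give alpha = 2, 3, 4
# with the three glycerol-water mixtures.
lab_geometry <- function() canal_geometry(length_L = 0.158, mean_radius_a = 0.013)

lab_point <- function(alpha) {
  fl <- switch(as.character(alpha),
               "2" = glycerol_water_properties(0.84),
               "3" = glycerol_water_properties(0.80),
               "4" = glycerol_water_properties(0.74),
               stop("no lab point for alpha = ", alpha))
  geo <- lab_geometry()
  list(geometry = geo, fluid = fl,
       omega = design_frequency(alpha, geo, fl)$omega)
}

# amplitude and phase of the fundamental of a uniformly sampled record
# covering exactly n_cycles cycles (direct FFT-bin readout)
fundamental <- function(x, n_cycles) {
  X <- fft(x)[n_cycles + 1L]
  c(amplitude = 2 * Mod(X) / length(x), phase = Arg(X))
}
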