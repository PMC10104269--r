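---
title: "Methods: oscillatory aqueduct flow, similarity scaling and transmantle pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory aqueduct flow, similarity scaling and transmantle pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(aqueductflow)
```

## The physical problem

Cerebrospinal fluid oscillates through the cerebral aqueduct — the narrow
canal (length $L \sim 10\text{–}15$ mm, mean radius $a \sim 1\text{–}1.5$ mm)
connecting the third and fourth ventricles — driven by the cardiac cycle.  The
driving interventricular pressure difference $\Delta p(t)$, a proxy for the
transmantle pressure, is only a few Pascals and cannot be measured routinely
in vivo; it must be inferred from the flow rate $Q(t)$, which *is* measurable
by cardiac-gated phase-contrast MRI.  This package implements the chain of
tools needed for that inference and for designing scaled bench experiments
that validate it.

## Dimensionless framework

With $\omega$ the angular frequency, $V_s = \tfrac12 \oint |Q|\,dt$ the stroke
volume and $L_s = V_s/(\pi a^2)$ the stroke length, the cycle-averaged
pressure magnitude
$$\langle|\Delta p|\rangle = \frac{\omega}{2\pi}\oint |\Delta p|\,dt$$
depends on six dimensional parameters $(L, a, \rho, \nu, L_s, \omega)$.
Buckingham-$\Pi$ reduction leaves three groups,
$$\langle|\Pi|\rangle \equiv
  \frac{\langle|\Delta p|\rangle}{\rho\,\omega^2 L\,L_s}
  = f\!\left(\frac{a}{L},\ \frac{L_s}{L},\ \alpha\right),
  \qquad \alpha = \sqrt{\frac{\omega a^2}{\nu}},$$
with $\alpha$ the Womersley number.  The pressure scale $\rho\,\omega^2 L L_s$
comes from balancing the oscillatory acceleration $L_s\omega^2$ against the
pressure force per unit mass.  Healthy adults typically have
$1/20 \lesssim a/L \lesssim 1/10$, $0.5 \lesssim L_s/L \lesssim 1.5$ and
$2 \lesssim \alpha \lesssim 4$; `dimensionless_groups()` warns (but does not
error) outside these ranges because they are typical values, not hard
validity limits of the framework.

All internal computation is in strict SI units; BPM, mL and inH$_2$O are
converted only at the I/O boundary (`bpm_to_omega()`, `ml_to_m3()`,
`inh2o_to_pa()`).  This avoids the silent unit errors that mixed clinical
units invite.

## Similarity design of scaled experiments

A laboratory model of scale $\chi = L_E/L_H$ reproduces the dimensionless
response exactly when the three groups match:
$$\frac{a_E}{L_E} = \frac{a_H}{L_H},\qquad
  \frac{\omega_E a_E^2}{\nu_E} = \frac{\omega_H a_H^2}{\nu_H},\qquad
  \frac{L_{s,E}}{L_E} = \frac{L_{s,H}}{L_H},$$
and then measured pressures map between scales by
$$\frac{\langle|\Delta p|\rangle_E}{\langle|\Delta p|\rangle_H}
  = \frac{\rho_E}{\rho_H}\left(\frac{\nu_E}{\nu_H}\right)^2 \chi^{-2}.$$
A ten-fold scale-up with water would *reduce* the measurable pressure by
$\chi^{-2}$; matching $\alpha$ at practical pump frequencies therefore forces
a much more viscous working fluid, which is why glycerol–water mixtures are
used.  `glycerol_water_properties()` implements the Cheng (2008) viscosity
correlation with volume-fraction-weighted temperature-dependent densities
(ideal mixing).  Three laboratory mixtures (84/16, 80/20, 74/26 by volume at
21.5&nbsp;°C) are shipped as exact lookup overrides so their measured
properties are reproduced verbatim; the correlation fills the continuum with
roughly ±5 % accuracy on $\nu$ (and reproduces those mixtures within ~2 %).
`design_frequency()` inverts $\alpha$ for the drive frequency, reporting BPM
raw and rounded (ties away from zero); pump limits (3–200 BPM, 0–180 mL) are
warnings rather than errors so the designer remains useful for other
hardware.

```{r design}
geo <- canal_geometry(length_L = 0.158, mean_radius_a = 0.013)  # 10x anatomy
design_experiment(2, geo, glycerol_water_properties(0.84))
```

## The flow model

The pressure model is the exact Womersley solution for fully developed
oscillatory flow in a rigid circular tube, applied per harmonic of the flow
waveform, plus a quadratic entrance-loss term:
$$\Pi(\tau) = \sum_n \mathrm{Re}\!\left[\hat Z_n \hat Q_n e^{in\tau}\right]
  + \frac{K}{2}\,\frac{L_s}{L}\,\bar u |\bar u|,
  \qquad \hat Z_n = \frac{i\,n}{F(\alpha\sqrt n)},\qquad
  F(\alpha) = 1 - \frac{2 J_1(\Lambda)}{\Lambda J_0(\Lambda)},\
  \Lambda = i^{3/2}\alpha,$$
with $\bar u$ the dimensionless section-mean velocity.  The linear term has
the correct limits: quasi-steady Poiseuille friction
$|\hat Z| \to 8/\alpha^2$ (pressure in phase with flow) as $\alpha \to 0$,
and pure inertia $\hat Z \to in$ (pressure leading by $\pi/2$) as
$\alpha \to \infty$.  Note the approach to the inertial limit is slow:
$|\hat Z_1| = 1 + \sqrt2/\alpha + O(\alpha^{-2})$, still 1.4 % above the
ideal limit at $\alpha = 100$.

The complex-argument Bessel ratio $J_1/J_0$ is evaluated by a modified-Lentz
continued fraction (stable at all magnitudes used; an asymptotic branch takes
over above $|\Lambda| = 200$), and is cross-checked in the test suite against
an independent radial finite-difference solution of the per-harmonic
momentum equation.

Design choices where the formulation was genuinely open:

* **Entrance loss `K = 0.7`** — the sum of typical rounded-entry and
  sudden-expansion minor-loss coefficients, applied with sign-preserving
  quadratic velocity.  It is a documented calibration knob: it reproduces the
  observation that an anatomically realistic canal (with its funnel-like
  openings into the ventricles) shows a noticeably larger $\langle|\Pi|\rangle$
  than a smooth cylinder, while keeping the stroke-length dependence of both
  $\langle|\Pi|\rangle$ and $\varphi$ below ~10 % across
  $0.5 \le L_s/L \le 1.5$.  All stroke-length dependence of the model enters
  through this term; at `K = 0` the linear model is exactly $L_s/L$-free.
* **Harmonic truncation** — 1 harmonic for the sine waveform, 8 for the
  physiologic one, mirroring the 5× / 8× low-pass cutoffs used when
  processing measurements.
* **Variable-area treatment** — optional and quasi-one-dimensional: the
  linear term series-sums per-slice uniform-tube impedances with the local
  radius; the quadratic term uses the mean of the two end-slice areas, since
  the loss is localized at the openings.  This is an approximation (no
  radial redistribution between slices), adequate for the gentle area
  variations of an aqueduct lumen.

```{r model}
pr2 <- predict(aqueduct_model(alpha = 2, Ls_over_L = 1))
pr4 <- predict(aqueduct_model(alpha = 4, Ls_over_L = 1))
c(mean_abs_Pi_alpha2 = pr2$mean_abs_Pi, mean_abs_Pi_alpha4 = pr4$mean_abs_Pi,
  decrease_pct = 100 * (1 - pr4$mean_abs_Pi / pr2$mean_abs_Pi))
plot(pr2)
```

## Signal-processing pipeline

`process_experiment()` reproduces a laboratory processing chain from the two
recorded channels (differential pressure at 80 Hz; piston position at
2500 Hz) to $(\langle|\Pi|\rangle, \varphi)$:

1. **Despike** the piston channel with a Hampel filter: replace a sample by
   its rolling median when it deviates by more than `n_sigmas` × 1.4826 ×
   rolling MAD.  Defaults — half-window 0.1 period, `n_sigmas = 5` — are
   wide enough to bridge the >100× single-sample logging spikes seen in
   practice and conservative for anharmonic waveforms.  Windows are clamped
   at the trace ends so edge spikes are caught too (an unfiltered 100× spike
   would otherwise contaminate the anti-alias filter downstream).
2. **Anti-alias and align**: low-pass the despiked position at 0.4× the
   pressure rate, then linearly interpolate it onto the pressure channel's
   80 Hz grid inside the common time window.  Interpolating the (smooth,
   filtered) position channel rather than the noisy pressure channel
   introduces the smaller alignment error.
3. **Differentiate** by central differences (one-sided endpoints) and
   multiply by the piston area to get $Q(t)$.
4. **Low-pass both channels** with a 4th-order Butterworth applied
   forward–backward (zero phase — a causal filter would bias $\varphi$) with
   odd-reflection end padding and exact unit DC gain; cutoff 5× the drive
   frequency for the sine waveform, 8× for the physiologic one.
5. **Trim and zero-average**: drop one settling cycle at each end when at
   least 4 whole cycles are available, trim to the largest whole number of
   periods (tolerance 1 % of a period), and subtract the per-recording mean
   from the pressure.  Per-recording (rather than per-cycle) zero-averaging
   is used; with integer-cycle trimming the two coincide for periodic
   signals.
6. **Summaries**: stroke metrics by the trapezoidal rule on the sampled grid
   (no resampling), nondimensionalization by the measured stroke length, and
   the phase lag from the FFT bin nearest the drive frequency,
   $\varphi = \arg\hat\Pi_1 - \arg\hat{\bar Q}_1 \in (-\pi, \pi]$ (positive
   when pressure leads).  The spectral phase definition is robust to jitter
   and waveform shape, unlike peak-to-peak timing; because both channels
   share the same record window, the residual spectral-leakage phase shift
   cancels between them to first order.

At least 2 whole cycles are required for the phase estimate; recordings are
expected to carry 5 or more.

## Synthetic recordings

`simulate_recording()` inverts the measurement chain so the pipeline is
testable end to end without laboratory data: piston position as the
cumulative trapezoidal integral of the commanded $Q(t)$ (zero-averaged, as a
pump input must start and end at the same value), Gaussian position noise,
10-bit ADC quantization over a full scale of 1.2× the stroke, Poisson-placed
±100× logging spikes injected *after* quantization (they are modelled as
serial-logging artifacts, which is why they can exceed the ADC range), and a
pressure channel generated by the flow model plus Gaussian noise.  A single
integer seed drives all draws through a local RNG state, so a given seed is
bit-reproducible and the global RNG stream is untouched.

The **physiologic waveform** is a frozen 8-harmonic synthesis
(`physiologic_harmonics()`), a documented stand-in for a subject's PC-MRI
waveform chosen once against fixed criteria: exactly three peaks and three
troughs per cycle (echoing the percussion, tidal and dicrotic features of
intracranial waveforms), a dominant systolic peak
($\max Q / |\min Q| \approx 1.6$), a smoothly decaying spectrum (amplitudes
$\lesssim 0.3/n^2$ beyond the fourth harmonic, comfortably inside the 8×
low-pass), and a cycle-averaged pressure within a few percent of the
pure-sine prediction at equal stroke volume.  All waveforms are normalized
to unit dimensionless stroke ($\overline{|\bar Q|} = 1/\pi$, as for
$\bar Q = \tfrac12\sin\tau$) so comparisons are at matched stroke volume.

What the generator deliberately does **not** emulate: reservoir sloshing,
balloon-compliance dynamics, trapped-air compressibility (a known
error source in wet benches), or ADC-voltage-to-position calibration.
Passing closure tests therefore demonstrates the correctness of the
processing chain under the stated noise model, not robustness to every
artifact of a physical rig.

## Clinical estimator

Rearranging the dimensionless relation gives the transmantle estimate from
MRI measurables:
$$\langle|\Delta p|\rangle = \langle|\Pi|\rangle\,\rho\,\omega^2 L\,
  \frac{V_s}{\pi a^2}.$$
`estimate_transmantle()` computes $\langle|\Pi|\rangle$ with the flow model
at the implied $(\alpha, L_s/L, a/L)$ using the physiologic waveform by
default (the harmonic option agrees within a few percent).  At fixed
$\langle|\Pi|\rangle$ the estimate scales as $a^{-2}$; with the model in the
loop it falls faster still, because $\langle|\Pi|\rangle$ decreases with
$\alpha = a\sqrt{\omega/\nu}$ — the quantitative form of the argument that
aqueduct enlargement can normalize transmantle pressure even when the stroke
volume rises.  The effective canal length of a real aqueduct (how much of
the funnel-shaped openings to include) is ambiguous; $L$ is taken exactly as
supplied and that choice is the user's.

```{r estimate}
human <- canal_geometry(length_L = 0.0158, mean_radius_a = 0.0013)
estimate_transmantle(ml_to_m3(0.05), bpm = 60, geometry = human)
```

## Numerical choices and problem sizes

* Cycle averaging uses the trapezoidal rule on the sampled grid; predictions
  are evaluated on 2048 phase points per cycle.
* Degenerate inputs error early with the offending field named; traces whose
  duration is further than 1 % of a period from a whole number of cycles are
  rejected by the averaging operators.
* Closure testing uses 8-cycle recordings at the three laboratory operating
  points ($\alpha = 2, 3, 4$ with the matching mixtures), both waveforms and
  $L_s/L \in \{0.5, 1, 1.5\}$; the noiseless chain recovers the generating
  model within ~1 % on $\langle|\Pi|\rangle$ and ~0.001 rad on $\varphi$,
  and stays within 5 % / 0.05 rad at 2 % pressure noise across 20 seeds.
  These sizes keep the full suite fast while leaving wide margins.

## Known limitations

* Rigid walls: no compliance or elastic-wave dynamics; the reservoir balloon
  of a physical rig is treated as ideal pressure relief.
* The entrance-loss coefficient is a single scalar calibrated to reproduce
  qualitative observations, not derived from the opening geometry.
* The quasi-1D variable-area option ignores radial flow redistribution.
* The physiologic waveform is a synthetic stand-in; subject-specific
  waveforms should be supplied as tabulated samples when available.
* The Cheng correlation degrades near the pure-glycerol limit and outside
  0–100 °C; the three laboratory mixtures are exact lookups.
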