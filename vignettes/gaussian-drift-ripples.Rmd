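---
title: "Ripple oscillations in a delayed inhibitory network: model, theory, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ripple oscillations in a delayed inhibitory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplenet)
```

## The model

`ripplenet` studies the feedback-based, inhibition-first account of
hippocampal ripple oscillations (140--220 Hz). A homogeneous population of
`N` interneurons is modeled as leaky integrate-and-fire (LIF) units,

$$\tau_m \dot v_i = -(v_i - E_{leak}) + \frac{\tau_m}{C} I_{ext}(t)
  - \frac{\tau_m J}{N} \sum_{j,k}\delta(t - t_j^k - \Delta)
  + \sqrt{2\tau_m}\,\sigma_V\,\xi_i(t),$$

with instantaneous reset at threshold, no refractory period, all-to-all
inhibitory pulse coupling with synaptic delay $\Delta$, and independent
Gaussian white noise per unit. Sharp wave-associated input from upstream is
modeled as a common excitatory drive $I_{ext}(t)$. The delayed negative
feedback loop turns transient excitation into a fast coherent oscillation of
the population rate, while individual units fire sparsely and irregularly
("sparse synchrony": unit rate below network frequency, saturation
$s = f_{unit}/f_{net} < 1$).

All internal computation uses dimensionless voltage (threshold $V_T = 1$,
rest 0): `to_dimensionless()` maps the physical defaults
($\tau_m = 10$ ms, $C = 100$ pF, $V_{thr}-E_{leak} = 13$ mV, $J = 65$ mV,
$\Delta = 1.2$ ms, $\sigma_V = 2.62$ mV, $N = 10^4$) to $K = 5$,
$V_R = 0$, $D = (2.62/13)^2 \approx 0.0406$. The tabulated dimensionless
default is the rounded $D = 0.04$; `dimensionless_params()` uses the rounded
value and the conversion keeps the exact one, so both representations are
available and neither drifts silently into the other.

## Gaussian-drift approximation

In the mean-field limit the membrane-potential density obeys a
Fokker--Planck equation with an absorbing boundary at threshold and a
reinjection at reset. Between population spikes, strong feedback pushes the
density far below threshold, where the boundary is irrelevant and the
density relaxes to a Gaussian of variance $D$. The package's mean-field
layer therefore approximates the density as a Gaussian with fixed variance
$D$ whose mean $\mu(t)$ obeys the delay differential equation (DDE)

$$\tau_m\dot\mu = I_E(t) - K\tau_m r(t-\Delta) - \mu,\qquad
  r = [\dot\mu]_+\,\frac{1}{\sqrt{2\pi D}} e^{-(V_T-\mu)^2/2D},$$

i.e. the rate is the drift current across threshold, clipped at zero for
downward drift. `integrate_dde()` integrates this by forward Euler
(default `dt` = 0.005 ms, the delay stored as an integer number of steps).
Increasing constant drive produces four regimes (`classify_regime()`):
stable fixed point, a pathological fast oscillation at
$(2\Delta)^{-1} \approx 417$ Hz (an artifact of the rate clipping in which
the Gaussian never leaves the threshold), period-2, and the regular period-1
oscillations the analytical theory describes.

### The phenomenological reset

Single-unit resets are absent from the drift equation. At the end of each
population spike ($\dot\mu$ crossing zero downward), the fired fraction of
the Gaussian equals its suprathreshold mass, the saturation
$s = \tfrac12(1 - \mathrm{erf}[(V_T-\mu_{max})/\sqrt{2D}])$, and the
population-level account of the reset shifts the whole Gaussian down by
$(V_T - V_R)\,s$ to $\mu_{reset} = \mu_{max} - (V_T-V_R)s$.

Two numerical choices deserve explanation:

* **Reset magnitude** (`reset_saturation`). The forward-Euler peak
  $\mu_{max}$ settles a few percent below the closed-form one, so computing
  $s$ from the detected peak systematically under-resets and shortens the
  period (at $I_E = 3.6$: 3.94 ms instead of $\approx 4.2$ ms). The default
  therefore evaluates the saturation from the closed-form cycle peak at the
  instantaneous drive, which is self-consistent with the analytical cycle
  and reproduces the analytical with-reset period to a few percent across
  the whole applicability range. The detected-peak variant remains available.
* **Post-reset clipping.** Immediately after the shift, $\dot\mu$ becomes
  transiently positive again, which would register as a spurious population
  spike; the rate is clipped to zero for exactly one delay window after each
  reset. The window length is a modeling choice; one delay is the shortest
  window that removes the artifact without touching the next genuine
  upstroke, and it reproduces the integrated with-reset period above.

## Closed-form constant-drive cycle theory

For constant drive in the period-1 regime the cycle splits into an upstroke
of duration $t_{off}$ (relaxation from $\mu_{min}$ towards $I_E$ until the
delayed self-inhibition stops it at $\mu_{max}$) and a downstroke of exactly
one delay. `gd_constant_solution()` assembles:

* $\mu_{max} = I_E - e^{-\Delta/\tau_m}[I_E - V_T + \sqrt{2D\ln L}]$ with
  $L = K e^{\Delta/\tau_m}/\sqrt{2\pi D}$, independent of the cycle's
  starting point; oscillations exist only for $L \ge 1$ and
  $I_E \ge V_T - \sqrt{2D\ln L}$ (`gd_existence_bounds()`, the analytical
  estimate of the DDE bifurcation, 0.56 at defaults vs 0.62 numerically);
* the saturation, the reset level, and $\mu_{min}$ from the erf-expressed
  downstroke integral of the delayed feedback;
* $t_{off} = \tau_m\ln[(I_E-\mu_{min})/(I_E-\mu_{max})]$, the period
  $T = t_{off}+\Delta$, $f_{net} = 1/T$ and $f_{unit} = s f_{net}$.

At $I_E = 3.6$ this gives 290.3 Hz without and 235.8 Hz with the reset.
A subtlety worth recording: the downstroke integral mixes two
approximations of the recent trajectory — the single-$K$ term linearises
the upstroke, while the $K^2$ term completes the square on the exponential
form before linearising. The linear-drive quadrature (below) mirrors these
conventions term by term, so its zero-slope limit reproduces the closed
form to quadrature accuracy rather than to a looser analytical tolerance.

The theory applies where units spike at most once per cycle
($I_E \le I_E^{full}$, with the closed-form full-synchrony drive defined by
$\mu_{max} - 3\sqrt D \ge V_T$, i.e. $s \ge 0.9987$) and where the Gaussian
is sufficiently subthreshold between spikes
($\mu_{min} + 3\sqrt D \le V_T$), giving the range
$[I_E^{min}, I_E^{max}]$ of `gd_applicability_range()` (2.84 to 9.76 at
defaults; the closed-form $I_E^{full}$ slightly overestimates the simulated
full-synchrony point near 8.9, as expected from its construction).
`gd_performance_scores()` quantifies theory-vs-simulation agreement by the
mean relative frequency error on a 0.1-spaced drive grid, the covered
fraction of the relevant range, and their product.

## Transient cycles under linearly changing drive, and IFA

Intra-ripple frequency accommodation (IFA) — the decay of the instantaneous
ripple frequency over the event — is quantified by the regression slope
$\chi_{IFA} = \mathrm{Cov}(\hat f,\hat t)/\mathrm{Var}(\hat t)$ over pooled
per-cycle frequency estimates. The mechanism is a hysteresis: each cycle
starts at the minimum set by the *previous* cycle's drive, so under rising
drive cycles start high and run fast, and under falling drive they start
low and run slow, relative to the asymptotic reference.

For drive changing linearly with slope $m$ around the reference
$\hat I_E = I_E(t_{off})$, `gd_cycle_map()` computes one cycle:

* the peak from the slope-corrected transcendental condition, solved
  numerically seeded at $\mu_{max}^\infty$, with a first-order perturbative
  fallback (the sensitivity coefficient is obtained by differentiating the
  peak condition at $m = 0$);
* the upstroke by Lambert W. The argument is evaluated in log space (it
  overflows double precision as $m \to 0$), and the branch is selected by
  the drive direction: the physical solution $u = (P - t_{off})/\tau_m$
  stays in $(-1, 0)$ for rising drive (principal branch) but diverges to
  $-\infty$ as $m \to 0^-$, which lies on the lower branch. Only this
  pairing recovers the constant-drive rise time from both sides; selecting
  the principal branch throughout would be wrong for falling drive. For
  rising drive at low reference drive the argument can fall below $-1/e$:
  no transient solution exists and the cycle is rejected.
* the end-of-cycle mean by composite Simpson quadrature (200 panels over
  one delay) of the downstroke integral, split into the stationary feedback
  part and the slope-proportional correction.

`gd_chain_cycles()` chains cycles over the sharp wave-like double ramp
(`make_spw_drive()`): 200 ms of baseline at half the critical drive, ramps
of slope $\pm m$ between baseline 0.74 and plateau 8.9 (the simulated
full-synchrony drive), and a 20 ms plateau. Per cycle, the reference drive
is found by fixed-point iteration ($\hat I_E = d_{start} + m\,t_{off}$,
tolerance $10^{-6}$ ms); consecutive cycles are matched so the drive is
continuous. Three conventions complete the construction:

* **Entry state.** The rising chain starts at the lowest applicable drive;
  its first cycle begins in the asymptotic state of its start drive — the
  hysteresis assumption applied to the pre-event history. Starting instead
  from the marginal subthreshold state was tested and produces chains that
  terminate immediately at low drive (the following cycle's entry rebounds
  above the subthreshold bound), so it is not used.
* **Plateau anchoring.** The chain family is parametrised by the start
  drive within one cycle of the earliest entry; the chain whose final
  rising cycle ends closest to the moment the drive reaches the plateau is
  selected (an exact alignment generally does not exist in the discrete
  family). The falling chain starts from the asymptotic plateau state when
  the drive begins to fall and runs until no valid cycle remains.
* **Regression inclusion.** A cycle enters the $\chi_{IFA}$ regression only
  if the drive stays inside the applicability range for its whole span
  (`has_ref`). Outside that range there is no asymptotic reference and the
  instantaneous-vs-asymptotic comparison that defines IFA is unavailable;
  the final falling cycle typically survives below the range where cycles
  can start (the event is asymmetric in drive) and is chained but flagged.
  Including such cycles roughly halves the fitted slope, which is
  inconsistent with the regression the cycle theory is meant to summarize.

With these conventions the theoretical slopes at $m = \pm0.4, \pm0.2,
\pm0.1$ per ms are $\approx -2.7$, $-1.6$, $-0.54$ Hz/ms: IFA is
speed-dependent and vanishes for slow drive. The spiking network pooled
over 50 noise realizations gives $\approx -3$ Hz/ms at $m = \pm 0.4$/ms.
`theory_sim_error()` scores theory cycles against simulated
instantaneous-frequency points within $\pm1.5$ ms.

## Linear stability of the stationary state

Away from the oscillatory regime the network sits in an asynchronous
stationary state, solved self-consistently from the LIF f-I curve
(`lif_rate()`, Siegert integral evaluated through the scaled complementary
error function; `stationary_state()` bisects on the total drive). The
stability of this state against periodic rate perturbations is governed by
the LIF susceptibility $\tilde G(\omega)$, evaluated exactly with
parabolic cylinder functions of complex order $-i\omega\tau_m$
(`susceptibility()`, via the confluent hypergeometric representation with a
Lanczos complex log-gamma, validated against closed forms and frozen
arbitrary-precision reference values). The Hopf point solves

$$1 = K\tau_m|\tilde G(\omega)|,\qquad 0 = \pi + \arg\tilde G(\omega)
  - \omega\Delta$$

by a frequency scan plus bisection inside a drive bisection
(`hopf_point()`). The sign convention of the susceptibility (the
complex-conjugate of the classical result, matching an $e^{i\omega t}$
perturbation with time in ms) was fixed by two checks: the static limit
must equal the slope of the f-I curve, and the phase condition must then
locate the oscillation on the physical branch. At the physical defaults
this yields a critical drive of 0.19 nA (dimensionless 1.49) with a 305 Hz
network frequency and a 16 Hz stationary unit rate — sparse synchrony from
the onset. The drift theory's own lower bound (0.56) lies well below this
Hopf point (1.49), consistent with its construction: near the bifurcation
the dynamics is fluctuation-driven and the purely drift-based cycle theory
does not apply there.

## Simulator and estimator conventions

* Euler--Maruyama with `dt` = 0.01 ms; per step the noise increment is
  $\sqrt{2D\,dt/\tau_m}$ times a standard normal per unit, the delayed
  inhibitory kick $K/N$ per presynaptic spike is applied before the
  threshold test, and a unit above threshold at the end of the step is
  reset within the step without crossing-time interpolation. Initial
  voltages are uniform on $[V_R, V_T]$; constant-drive analyses discard the
  first 50 ms. All randomness flows through R's RNG, so a seed fully
  determines a run; a step-by-step R reference implementation consuming
  the same stream is kept in the test suite as an oracle.
* The population rate is the per-bin spike count over $N\,dt$ (spike count
  is conserved exactly); display and peak detection use a Gaussian-smoothed
  rate ($\sigma_t = 0.3$ ms, kernel truncated at $5\sigma$ and normalized).
* The discrete instantaneous-frequency estimator inverts peak-to-peak
  distances of the smoothed rate, keeping peaks exceeding the baseline mean
  rate plus four baseline standard deviations; each pair's frequency is
  timestamped at the pair midpoint, the only convention symmetric under
  time reversal, which the IFA analysis requires. The continuous estimator
  is a complex-Morlet spectrogram ($\omega_0 = 6$, resolving a 200 Hz burst
  with about 5 ms of smearing; implemented in-package since no installed R
  package provides a CWT), taking the maximal-power frequency above 70 Hz;
  validity requires the power to exceed the baseline near-zero-frequency
  power (a DC-centred low-pass with the width and gain of the 70 Hz
  wavelet) plus four baseline standard deviations, with the baseline edges
  trimmed by three low-pass widths against circular leakage. Both
  estimators accept an explicit threshold for sustained oscillations that
  have no quiescent baseline.
* The average oscillation cycle is extracted by segmenting at a fixed phase
  of the analytic signal (FFT Hilbert transform) of the population mean
  membrane potential and averaging 21 equally spaced samples per cycle;
  at least 10 complete cycles are required.

## What the bundled experiments emulate — and what they do not

The package's experiment layer (`run_experiment()`, `make_fixture()`)
generates every input it analyses: constant-drive runs for the frequency
and saturation curves, the symmetric double-ramp events for IFA, synthetic
chirps and flat traces for estimator calibration. The default conditions
are the model's standard parameter set; reduced sizes used in the test
suite ($N = 1000$ for the IFA and full-synchrony simulations, 5 s of
constant drive, 50 noise repetitions of the ramp events, and $N$ down to
a few hundred for estimator unit tests) rely on the model's demonstrated
insensitivity of the population rhythm to network size, which the suite
itself checks across an order of magnitude in $N$.

Passing tests therefore show internal consistency of simulator, theory and
estimators under the model's own assumptions: homogeneous all-to-all
coupling, current-based pulses, white uncorrelated noise, no refractory
period, no pyramidal population, and a stylised piecewise-linear drive.
They do not show that real CA1 ripples obey the model: conductance-based
synapses bound the hyperpolarization that is unbounded here, refractoriness
can split the voltage distribution into alternating clusters, structured
connectivity and correlated noise change the finite-size fluctuations, and
the local field potential is only proxied by the interneuron population
rate. Within the model, the drift-based theory itself excludes the
fluctuation-driven neighbourhood of the Hopf point and drives beyond full
synchrony.

## Known limitations

* The closed-form cycle theory inherits its mixed trajectory
  approximations; near $I_E^{min}$ the integrated DDE is period-2 while the
  closed form still returns a period-1 cycle, and agreement there degrades.
* The numerical DDE bifurcation (0.623 at defaults) is robust to step
  size, history and duration in this implementation but is an
  implementation-sensitive quantity: the clipped drift rate makes the
  transition nonlinear, and different integrators place it within a few
  percent of each other.
* Chain anchoring admits no exact plateau alignment; the selected chain can
  end up to half a cycle short of the plateau, a sub-percent effect on
  $\chi_{IFA}$ for the default geometry.
* The spectrogram estimator's wavelet parameters are a calibration choice;
  the discrete peak-to-peak estimator is the primary, fully specified one,
  and the two are cross-validated against the spectral network frequency
  on sustained oscillations.
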