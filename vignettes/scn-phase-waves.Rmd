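---
title: "Phase waves in the SCN: extraction, statistics, and a lattice model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase waves in the SCN: extraction, statistics, and a lattice model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnwave)
```

## The problem

The suprachiasmatic nucleus (SCN) is a network of thousands of neuronal
circadian oscillators that, in organotypic slices, display a striking
spatiotemporal pattern: once per ~24 h cycle, a gradient of clock-gene
expression phase sweeps across the tissue from the dorsomedial toward
the ventrolateral region at roughly 0.2 mm/h.  This "phase wave" is
highly reproducible, yet its front is visibly ragged: the phase of
individual cells scatters around the smooth wave.  Three quantitative
questions organize this package:

1. How do we turn a bioluminescence movie into per-pixel phase
   $\theta(t)$ and amplitude $A(t)$?
2. How synchronized is the tissue, and how large is the cell-scale
   phase scatter riding on the wave?
3. What intercellular coupling strength is needed to produce such a
   wave, and how robust is it to cellular heterogeneity, dead cells,
   and noise?

## Phase and amplitude from intensity traces

Each pixel's intensity trace is first smoothed with a centred moving
average spanning 6 h (ends handled by a shrinking one-sided window so
the trace keeps its length).  Peaks and troughs are the strict local
extrema of the smoothed trace, with plateaus resolved to their midpoint
and alternation enforced by keeping the more extreme of two same-type
neighbours.  Linear interpolation through the peaks gives the upper
envelope $h(t)$, through the troughs the lower envelope $l(t)$; each is
defined only between its first and last anchor, never extrapolated.
Amplitude and phase are then

$$A(t) = \frac{h(t) - l(t)}{2}, \qquad
  y(t) = \frac{2 x_s(t) - h(t) - l(t)}{h(t) - l(t)},$$

with $y$ clipped to $[-1, 1]$ (interpolation chord error can push it
marginally outside near extrema) and

$$\theta(t) = \arccos y \ \ \text{(descending segments)}, \qquad
  \theta(t) = 2\pi k - \arccos y \ \ \text{(ascending segments)},$$

accumulated so that $\theta$ is continuous, increases by exactly $2\pi$
per cycle, and equals $0 \pmod{2\pi}$ at every detected peak and $\pi$
at every trough.  The functional forms of $A$ and $\theta$ are design
choices of this package; their justification is empirical: on every
oscillatory fixture the envelope phase agrees with the
Hilbert-transform (analytic-signal) phase to better than 0.05 rad/2$\pi$
RMS, and the amplitudes to a few percent, which is the same consistency
check used in the experimental literature.  `hilbert_phase()` remains
available for QC.

A pixel is flagged *non-oscillatory* and excluded from all statistics
(never imputed) when it has fewer than two peaks or troughs, when its
amplitude vanishes anywhere on the envelope domain, or when its median
amplitude is less than `min_snr = 3` times the residual noise level
(the trace minus its smoothed version).  The last criterion is what
rejects rhythmless, trending, or dead pixels that would otherwise
produce spurious tiny extrema from smoothed noise.

## Synchronization index and spatial fluctuation

For a single-frame phase field $\{\theta_j\}$ over $N$ valid pixels the
Kuramoto order parameter is

$$R e^{i\Phi} = \frac{1}{N} \sum_{j=1}^{N} e^{i\theta_j},$$

with $R = 1$ at perfect synchrony and $R \to 0$ for incoherent phases.

The *spatial phase fluctuation* $\Delta$ measures the cell-scale
raggedness of the wave after the wave itself is removed: each pixel's
locally averaged phase (a 7×7-pixel window, about 3×3 cells, for
imaging data; 3×3 for model fields whose cells are single oscillators)
is subtracted, and $\Delta$ is the standard deviation of the residual,
reported in rad/2$\pi$ (fractions of a cycle; multiply by the period
for clock time — `phase_to_time(0.017, 24)` is about 25 min).  The
window mean uses the circular (resultant-vector) mean and a wrapped
difference; for the tightly synchronized fields of interest this is
numerically indistinguishable from the arithmetic mean (verified to
$10^{-6}$ rad in the tests) but remains well defined for rough fields.
Edge pixels without a full window are excluded rather than padded, so
the standard deviation is not biased by asymmetric windows.  Because a
symmetric window mean reproduces any linear field exactly, $\Delta$ is
invariant under adding a phase ramp — it sees the jitter, not the wave.

Wave velocity is estimated from the space–time structure of the phase:
along a chosen pixel line, each frame's spatially unwrapped phase is
regressed on position, and $v = \text{pixel size} / (|s| \cdot T)$ with
$s$ the mean slope in cycles/pixel and $T$ the period.  The line should
run through the wave origin (a radial line); an oblique line sees a
foreshortened gradient and overestimates $v$.  Slopes below `grad_tol`
flag the velocity as undefined rather than returning a huge number.

## The synthetic-movie generator

No real SCN recording ships with this package, so every pipeline stage
is validated against synthetic movies with known ground truth
(`synthetic_movie_spec()`, `generate_movie()`).  The generator emulates
the features that matter statistically:

* damped cosine oscillations per pixel (default period 24 h, damping
  time 100 h) on a baseline with a slow linear trend;
* a phase wave radiating from an origin at 0.2 mm/h;
* cell-scale phase jitter, constant in time, drawn once per cell block
  (default 2×2 pixels) with sd 0.017 rad/2$\pi$ — the jitter is
  assigned per cell, not per pixel, so a 7×7-pixel window covers a
  known number of independent cells;
* a smooth Gaussian amplitude bump (bright centre, amplitude 30–60
  counts) away from the wave origin;
* Gaussian measurement noise (sd 0.5 counts by default) and optional
  dead cells carrying baseline and noise only.

Defaults are chosen once to represent the *analyzed regions* of a good
recording: sampling every 0.5 h for 120 h (neither is reported for the
original experiments; 0.5 h keeps the 6 h smoothing window at 13
samples, and 120 h provides the ≥3 peaks the envelopes need), and an
amplitude-to-noise ratio around 60–120, matching the regime where phase
extraction error (~0.005 cycles, dominated by envelope anchor noise) is
well below the cell jitter being measured.  With a noisier spec the
pipeline still runs, but the measured $\Delta$ then reflects shot noise
as much as biology — as it would for a real dim recording.  The
generator makes no attempt at anatomical realism (no dm/vl geometry,
no VIP/AVP structure); `true_delta` is defined as the realized
detrended sd of the generated phase map itself, so parameter-recovery
tests compare like with like.  Gaussian rather than Poisson noise is a
deliberate simplification of the camera model.

## The lattice model

The tissue is modelled as $N_1 \times N_2 \times N_L$ phase oscillators
(default $20 \times 20 \times 10$) on a cubic lattice with open
boundaries, each coupled to its six von-Neumann neighbours:

$$\dot\theta_i = \omega_i + K \sum_{j \in \langle i \rangle}
    \sin(\theta_j - \theta_i) + \xi_i(t),$$

with natural frequencies $\omega_i \sim \mathcal N(1, \sigma_\omega)$
(one model cycle $2\pi/\langle\omega\rangle$ corresponds to 24 h), a
*pacemaker plane* at $x = 1$ whose drawn frequencies are multiplied by
1.04 (the 4% advantage that initiates the wave), and dead-cell
*defects* on the displayed surface layer $z = 1$, each site deleted
independently with probability $\gamma$ and removed from the dynamics
entirely.  A defect pixel displays the phase of the live oscillator
directly beneath it, as interior neurons shine through a dead surface
cell in the real preparation.  The initial condition is completely
synchronized ($\theta_i = 0$) and integration is fourth-order
Runge–Kutta with $dt = 0.02$.

Two conventions deserve comment because the model definition leaves
them open:

* **Coupling normalization.**  The interaction is the plain sum over
  live neighbours (`normalize_coupling = FALSE`).  The per-neighbour
  normalized variant $K/n_i$ is available, but it makes the lattice
  roughly six times harder to synchronize and puts every critical
  coupling far outside the published range for this system; the plain
  sum reproduces it, which is how the choice was settled.
* **Noise integration.**  The nominal covariance is
  $\langle \xi_i(t)\xi_j(s)\rangle = 2D\,\delta_{ij}\delta(t-s)$.  The
  default scheme (`noise_scheme = "forcing"`) draws one Gaussian per
  step with variance $2D$ and integrates it as a constant forcing, so
  each step adds sd $\sqrt{2D}\,dt$ and the effective diffusion is
  $D\,dt$.  This per-step-forcing convention is what "Runge–Kutta with
  noise" almost always means in practice in this literature, and it is
  the only convention under which noise intensities of order 1–10 are
  compatible with a synchronized lattice at couplings of order 0.1 —
  under the mathematically consistent Itô convention
  (`noise_scheme = "ito"`, step sd $\sqrt{2D\,dt}$, variance growing
  exactly as $2Dt$) the same intensities inject a per-cycle phase
  diffusion of several radians and destroy synchrony outright.  Both
  schemes are implemented; they coincide at $D = 0$, which covers every
  experiment except the noise-robustness sweep.  The $2Dt$
  variance-growth property is asserted in the tests under the Itô
  scheme, where it belongs.

The compiled core exploits the lattice regularity (zero-padded arrays,
neighbour sums as shifted adds, one polynomial sincos per site per
stage) and integrates the full default lattice to $t = 500$ in a few
seconds, which is what makes the replicated sweeps below affordable on
one CPU.

## When is a run "synchronized"?

The published criterion is visual: below the critical coupling the
fluctuation $\Delta(t)$ "grows", above it it stays flat.  Making that
operational needs care, because three distinct failure modes occur:

1. **Late growth** — $\Delta(t)$ still rising in the second half of the
   run.  Caught by a least-squares slope test (`slope_tol`, default
   $2\times10^{-5}$ cycles per time unit) combined with a material-rise
   requirement (final value above twice the post-transient median, or a
   fitted rise exceeding half the median).
2. **Saturation** — a fully disordered field is *stationary* at
   $\Delta \approx 0.23$, so a pure growth test would absurdly call it
   synchronized.  Any run whose post-transient median exceeds
   `delta_max = 0.15` (two thirds of the disordered plateau, far above
   any locked state observed anywhere in the sweeps) is growing.
3. **Partial locking** — a handful of cells slip phase forever while
   the field statistic stays flat.  This is detected directly from the
   definition of synchronization: every cell's mean frequency over the
   post-transient half (by linear regression of its phase on time) must
   agree with the ensemble median to better than half a cycle of
   relative drift over the window ($\pi / T_{\text{post}}$).  One
   drifting *straggler* cell is tolerated (`straggler_max = 1`):
   a single extreme-frequency cell with few live bonds — typically in a
   corner, or isolated by surface defects — can be unlockable at any
   reasonable coupling, and one wrapped pixel cannot move $\Delta$;
   two or more drifting cells count as loss of network synchrony.

A run is *bounded* (synchronized) only if it passes all three.  The
thresholds were fixed from the clear empirical gap between locked runs
(frequency spread $\le 0.01$ per time unit) and slipping runs
($\ge 0.015$) across the whole parameter range, and are not tuned per
experiment.  Critical values are then grid statistics: $K_c$ is the
smallest coupling bounded in a majority of 5 seeded replicates (with
the grid refined to step 0.005 around the transition); the critical
$\sigma_\omega$ and $D$ are the largest grid values bounded in a
majority.

## Study design of the sweeps

All sweeps run at the study conditions — $20\times20\times10$,
$\sigma_\omega = 0.05$ (the observed few-percent period dispersion of
SCN neurons), boost 1.04, $dt = 0.02$ — to a horizon of $t = 500$
(about 80 cycles), discarding a transient of 250.  These horizons are
the package defaults: doubling $t_{\text{end}}$ leaves every
classification in the K-sweeps unchanged (checked during development on
the transition neighbourhoods), while halving it makes near-critical
slopes unmeasurable.  Each grid point uses 5 independently seeded
replicates, and every seed derives from one base seed, so sweeps are
reproducible bit for bit.

The coupling interval for the real tissue is obtained by interpolating
where the steady-state $\Delta(K)$ curves (defect-free and
$\gamma = 0.5$) cross the experimental fluctuation level of
0.02 rad/2$\pi$; interpolation is linear in $\log K$ vs $\log \Delta$
because the synchronized branch decays nearly as a power law
($\Delta \propto \sigma_\omega / K$ over the whole grid), making the
log-log interpolant exact in the limit; a plain linear variant is
available (`interp = "linear"`).

## Degenerate inputs and numerical corner cases

* Movies shorter than three periods, sampling coarser than 1 h, and
  non-positive wave velocities are rejected at spec construction.
* A $1 \times 1 \times T$ movie is a legal single-trace analysis.
* $\gamma = 1$ deletes the whole surface; the displayed field then
  falls back entirely to the second layer.  A column dead through all
  layers would display as NA (masked); with surface-only defects this
  cannot happen.
* Oscillators that lose every neighbour are integrated as free
  rotators ($\dot\theta = \omega_i$), not dropped.
* $y$ clipping before $\arccos$ caps chord-error excursions; envelope
  phase is exact at every anchor by construction.
* With fewer than 3×3 surface sites $\Delta$ is undefined and reported
  NA rather than being computed on a degenerate window.

## What the synthetic validations do and do not show

Passing the recovery tests shows the pipeline is *internally*
consistent: known jitter, velocity and synchrony are recovered within
stated tolerances from data with the assumed structure (stationary cell
jitter, smooth amplitude field, Gaussian noise, a single radial wave).
Real recordings violate these assumptions in ways the generator does
not emulate — anatomical heterogeneity between dm and vl regions,
non-stationary damping, correlated camera artefacts, slice-edge optics
— so agreement on synthetic data bounds the method error, not the
biological measurement error.  Likewise the lattice model is a
deliberately minimal local-coupling caricature: no long-range or
diffusible coupling, no frequency gradients beyond the pacemaker plane,
sinusoidal interaction.  Its role is to show that local coupling at a
few times the critical strength *suffices* to reproduce the wave and
its fluctuation statistics, not that the SCN is such a lattice.

## Known limitations

* The envelope phase is only defined between the first and last
  detected extremum of each pixel; the first and last half-cycle of a
  recording are always lost.
* $K_c$ at the default lattice size is a finite-size crossover, not a
  sharp transition: near the threshold, individual frequency
  realizations differ in their smallest locking coupling by one or two
  grid steps, which is why majorities over replicates (and, for
  headline numbers, several seeds) are essential.
* The straggler tolerance is a judgement call at exactly one cell;
  sweeps report the raw slip counts (`n_slip`) so any other convention
  can be applied post hoc.
* Under the forcing noise convention the injected diffusion scales with
  $dt$; noise intensities are therefore only comparable between runs
  sharing the integration step (all study runs use $dt = 0.02$).
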