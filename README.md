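# scnwave

Quantitative analysis of circadian **phase waves** in the suprachiasmatic
nucleus (SCN), and a lattice model of the oscillator network that
produces them.

In cultured SCN slices expressing a clock-gene bioluminescence reporter,
a gradient of oscillation phase sweeps across the tissue once per
circadian cycle, travelling at about 0.2 mm/h from the dorsomedial to
the ventrolateral region. The wave is reproducible but ragged: the phase
of individual cells scatters around it. This package provides, for
anyone analyzing such recordings or modelling them:

- **Phase/amplitude extraction** from per-pixel intensity traces via
  peak/trough envelopes: the smoothed signal is normalized between its
  piecewise-linear envelopes *h(t)*, *l(t)* and mapped through
  arccos, giving A(t) = (h − l)/2 and an unwrapped θ(t) that is 0 at
  every peak and π at every trough, cross-checked against the
  Hilbert-transform phase (`extract_phase_amplitude()`,
  `hilbert_phase()`).
- **Synchronization statistics**: the Kuramoto order parameter
  R e^{iΦ} = (1/N) Σ_j e^{iθ_j}; the spatial phase fluctuation
  **Δ** = sd of the locally detrended phase (7×7-pixel window),
  in rad/2π; and wave-velocity estimation from space–time phase plots
  (`order_parameter()`, `spatial_detrend()`, `spatial_fluctuation()`,
  `wave_velocity()`).
- **A synthetic-movie generator** with exact ground truth (known
  jitter, velocity, amplitude field, defects), so the whole pipeline is
  testable without any real recording (`synthetic_movie_spec()`,
  `generate_movie()`).
- **The lattice model**: N1×N2×NL phase oscillators with
  nearest-neighbour sine coupling K, normally distributed natural
  frequencies (σ_ω), a 4%-faster pacemaker plane that launches the
  wave, dead-cell defects on the imaged surface (probability γ, each
  displaying the live cell beneath), and dynamical noise D — integrated
  by RK4 (dt = 0.02) in a fast compiled core (`sim_config()`,
  `simulate_lattice()`).
- **Simulation experiments**: critical coupling K_c (smallest K whose
  runs stay synchronized — bounded Δ(t) and full frequency
  entrainment — in a majority of replicates), bracketing of the
  biological coupling strength from the measured Δ ≈ 0.02 rad/2π, and
  robustness maps against σ_ω, γ, layer count and D (`estimate_kc()`,
  `estimate_coupling_interval()`, `robustness_sigma()`,
  `robustness_noise()`).

## Worked example

Generate a synthetic recording with known cell jitter (0.017 rad/2π)
and wave velocity (0.2 mm/h), and push it through the pipeline:

```r
library(scnwave)

mv <- generate_movie(synthetic_movie_spec(seed = 1))
pf <- extract_phase_amplitude(mv$movie)     # envelope phase per pixel
st <- movie_sync_stats(pf)                  # R(t), Delta(t) over frames
wv <- wave_velocity(pf, line = list(type = "row", index = 1))

c(delta = st$delta_mean, truth = mv$truth$true_delta,
  velocity = wv$velocity, R = st$R_mean)
#>      delta      truth   velocity          R
#> 0.01643047 0.01602883 0.19414013 0.98363115
```

The recovered Δ (0.0164) matches the generated cell-scale jitter within
a few percent — `phase_to_time(0.0164, 24) * 60` ≈ 24 min of a 24 h
cycle — the 0.2 mm/h wave is recovered within 3%, and the field is
strongly synchronized (R ≈ 0.98).

On the modelling side, one run of the default 20×20×10 lattice:

```r
tr <- simulate_lattice(sim_config(K = 0.12, seed = 1))
classify_run(tr)[c("class", "steady_delta", "n_slip")]
#> $class
#> [1] "bounded"
#> $steady_delta
#> [1] 0.01374523
#> $n_slip
#> [1] 0
```

At K = 0.12 the lattice holds a synchronized travelling wave whose
surface fluctuation (Δ ≈ 0.014 rad/2π) is of the same order as the
experimental measurement.

## Analysis workflow

The `analysis/` directory contains the numbered study scripts, each a
thin driver over the package that prints what it finds and writes its
tables under `results/`:

| script | what it does |
|---|---|
| `01_synthetic_imaging_pipeline.R` | pipeline recovery of jitter, velocity, R on synthetic movies |
| `02_critical_coupling.R` | Δ(K) sweeps and K_c for γ = 0 and γ = 0.5 |
| `03_coupling_bracket.R` | coupling interval where Δ(K) crosses the measured 0.02 rad/2π |
| `04_robustness.R` | Δ over σ_ω × γ, layer-number dependence, critical σ_ω and D per K |
| `05_pacemaker_variant.R` | wave steepness and Δ(K) for 4% vs 2.7% pacemaker advantage |

Run them in order with `Rscript analysis/01_... .R` etc.; stages are
independent except that 03 reuses 02's tables when present.

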