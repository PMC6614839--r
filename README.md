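# slimfieldr

Quantitative single-molecule analysis of millisecond **Slimfield**
fluorescence microscopy of live bacteria, built for experiments that track
replisome-associated proteins (an accessory helicase such as Rep against a
DnaQ fork marker in *E. coli*) with two interleaved colour channels at
80 nm/pixel and 5 ms/frame.

The package implements the full analysis chain as pipe-friendly functions
over tibbles:

* **Detection & localization** — band-pass candidate finding, iterative
  Gaussian-mask centroids, circular-ROI photometry (radius 5 px, 17 × 17
  background square), SNR > 0.4 acceptance.
* **Tracking** — greedy nearest-neighbour linking within 5 px, 4-frame
  acceptance (2-frame relaxed variant), overtracking through the bleach
  tail.
* **Stoichiometry** — Chung–Kennedy edge-preserving filtering, the
  characteristic single-fluorophore intensity from bleach tails and step
  differences, molecules per focus from the 3-point initial-intensity
  intercept, Gaussian peak fitting of KDE distributions with
  duplicate-peak merging, adjacent-peak periodicity, whole-cell copy
  number by pixel integration, and nearest-neighbour pool-stoichiometry
  expectations.
* **Colocalization** — brightfield cross-correlation registration, the
  Gaussian overlap integral
  `O = (2 σA σB / (σA² + σB²)) · exp(−d² / 2(σA² + σB²))` with greedy
  matching at O ≥ 0.75, a Monte-Carlo random-overlap baseline with an
  analytic single-pair check, origin-constrained stoichiometry gradients,
  and two-proportion tests between strains.
* **Mobility & kinetics** — microscopic D from 3-point MSD fits with the
  intercept fixed at 4σ² (σ = 40 nm), gamma-mixture decomposition into
  immobile/slow/fast modes (KDE least squares with kernel-matched
  convolution, or EM maximum likelihood), immobile fractions by
  colocalization status, fork dwell times and discretized-exponential
  dwell constants, and Stokes–Einstein conversions.
* **Simulation** — a forward generator of two-colour TIFF stacks of
  rod-shaped cells with known stoichiometries, mobility modes, bleach
  times, pool, and EMCCD noise, so every estimator is validated by
  parameter recovery (`study_*()` functions).

Fitted objects ship broom-style `tidy()`/`glance()` methods and
`autoplot()` figures.

## Worked example

Simulate a two-colour dataset of immobile hexameric green foci with a
trimeric red fork marker, then run the whole pipeline:

```r
library(slimfieldr)

cfg <- slim_config(
  field_px = c(256, 256), n_frames = 22, n_cells = 15,
  species = list(
    sim_species("rep",  "green", n_per_cell = 2, S = 6,
                modes = data.frame(mode = "immobile", D = 0, weight = 1)),
    sim_species("dnaq", "red",   n_per_cell = 1, S = 3,
                modes = data.frame(mode = "immobile", D = 0, weight = 1))),
  substeps = 1, seed = 17)

d   <- simulate_dataset(cfg)
res <- run_pipeline(d$stack, slim_pipeline_config(n_rand = 50, seed = 5),
                    brightfield = d$brightfield, cells = d$cells)

res$i_single$green
#> Characteristic intensity: 2029.7 counts/molecule (95% CI 1965.7-3914.6, 26 tracks)
res$summary$n_tracks
#> [1] 45
round(kde_peak(res$stoich$S[res$stoich$channel == "green"], bw = 0.7), 2)
#> [1] 5.62
```

The calibrated single-fluorophore intensity lands within ~2% of the
simulated 2000 counts/molecule, and the modal green stoichiometry recovers
the simulated hexamer (6 ± 1 molecules). `write_results(res, "out/")`
writes the foci/track/stoichiometry tables (CSV) plus `summary.json` and a
provenance-stamped `config.json`.

Individual stages compose with pipes if you prefer:

```r
tracks <- detect_foci(get_channel(d$stack, "green")) |>
  link_foci(max_disp = 5) |>
  accept_tracks(min_frames = 4)
```

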