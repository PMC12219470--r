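# duoscope

Analysis toolkit for **dual-channel miniscope** experiments: single-photon
calcium imaging in which a dynamic activity indicator (GCaMP) is recorded
alongside a constitutively expressed static nuclear marker (dTomato) in the
same field of view. The static channel provides landmarks that let every
cell be registered across recording sessions *even when it is not active*,
separating instability of the imaging field of view from genuine
representational drift of, e.g., hippocampal CA1 place codes.

The package is aimed at systems neuroscientists running longitudinal
linear-track experiments, and at methodologists who want a fully synthetic,
ground-truth-controlled test bed for longitudinal registration and
place-cell statistics.

## What it computes

* **Static-channel cell detection** — local maxima of a smoothed summary
  image, footprints grown as round above-half-max regions
  (`detect_cells()`).
* **Registration** — mutual-nearest-neighbour centroid matching within and
  across sessions, and propagation of the static-channel cross-session map
  to the dynamic channel (`match_centroids()`, `register_cross_session()`,
  `propagate_gcamp_map()`).
* **Cross-talk** — per-cell OLS coefficient of the static trace on the
  dynamic trace, a circular-shuffle null, and the expected ratio from
  emission spectra and filter curves (`fit_crosstalk()`, `shuffled_null()`,
  `expected_crosstalk_ratio()`).
* **Longitudinal tracking statistics** — per-session tracking probability

  `p_m = (1/k) * sum_i N_mi / N_i`

  over `m = 1..k` sessions, and the pairwise reactivation rate
  `p_AB = (N_2/N_A + N_2/N_B)/2` (`tracking_probability()`,
  `reactivation_rate()`).
* **Spatial coding** — behaviour segmentation at 3 cm/s, direction-split
  linearization to `[0, 200)` cm, cosine-kernel (5 cm bandwidth) rate maps
  over 200 bins, Skaggs spatial information

  `I = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)`,

  split-half stability, 500-shuffle place-cell classification, and
  population-vector (PV) correlation between session pairs
  (`place_cell_test()`, `pv_correlation()`).
* **Synthetic data generator** — multi-session two-channel experiments with
  known ground truth: planted direction-specific place fields, Markov
  activity schedules, field-of-view jitter, planted cross-talk
  (`simulate_experiment()`).

## Worked example

```r
library(duoscope)

cfg <- duo_config_demo(seed = 1L)   # 7 sessions, 150 cells, 5 min @ 15 fps
run_full_analysis(cfg, "demo_out")
res <- jsonlite::read_json("demo_out/results.json", simplifyVector = TRUE)

res$crosstalk$observed_mean   # 0.0503   (planted cross-talk alpha = 0.05)
res$crosstalk$null_mean       # -0.00018 (shuffle null centred at zero)
res$slopes$reactivation_gcamp$slope  # -0.0172 per day (p = 0.0008)
res$slopes$pv_gcamp$slope            # -0.0165 per day (p = 0.0019)

tr <- read.csv("demo_out/tracking_probability.csv")
subset(tr, criterion == "gcamp" & m == 7)$p   # 0.348: per-session probability
                                              # of a cell tracked in all 7
```

Numbers above are what the demo configuration actually prints (seed 1).
They show the three headline behaviours: the fitted cross-talk coefficient
recovers the planted 5% leak while its circular-shuffle null centres at
zero; and both the place-cell reactivation rate and the PV correlation
decline with the time interval between sessions (negative OLS slopes),
with the decline visible even for cells whose static landmark guarantees
they stayed in the field of view.

`make_report("demo_out")` aggregates per-figure tables under
`demo_out/report/`.

## Command line

A small CLI wrapper ships in `inst/cli/duoscope.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/duoscope.R", package="duoscope"))')" run-all --out out --seed 1
```

## Notes

The bundled spectra under `inst/extdata/` are *synthetic* stand-ins (a
tabulated GCaMP-like emission curve and idealized 525/50 and 630/75
band-pass filters), not measured vendor curves; see the methods vignette
(`vignettes/duoscope-methods.Rmd`) for what they can and cannot validate.
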