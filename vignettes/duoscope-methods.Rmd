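---
title: "duoscope: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duoscope: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

duoscope analyses two-channel miniscope recordings in which a dynamic
calcium indicator (GCaMP) is imaged together with a constitutive static
nuclear marker (dTomato). This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken where
the procedure was genuinely open.

## 1. The scientific problem

Calcium imaging can only register a cell across days when the cell is
*active* on both days, and the field of view (FOV) itself shifts slightly
between sessions. Longitudinal statistics computed from the dynamic channel
alone therefore confound three things: genuine changes in which cells are
active, genuine changes in spatial tuning (representational drift), and
apparent changes caused by FOV instability. A static marker expressed in
every cell gives a landmark per cell per session, so presence in the FOV
can be established independently of activity. The analyses in this package
quantify (i) how well cells are tracked, (ii) how much signal leaks between
the two fluorescence channels, and (iii) how the place code evolves with
the time interval between sessions, under three inclusion criteria: all
dynamic-channel cells, the "stable" subset whose static landmark is present
in every session, and cells active in both sessions of a pair.

## 2. Cell detection on the static channel

`detect_cells()` works on a summary image (mean projection by default; for
a static signal the mean and max projections give the same detections, and
the mean is more noise-robust). The image is smoothed with a Gaussian
(`smoothing_sigma`, default 2 px), local maxima above an intensity
threshold are collected (default: the 95th percentile of the smoothed
image; plateau ties keep the lexicographically smallest pixel), and a
minimum pairwise peak distance (default 8 px) is enforced greedily in
descending intensity order. Around each peak, `grow_round_footprint()`
takes the connected above-half-max region, where "half max" is relative to
a local background estimated as the median of an annulus placed at
1.5 x the maximum admissible radius — far enough out that an oversized blob
cannot serve as its own background and masquerade as a small cell. The
region is accepted when its equivalent radius `sqrt(area/pi)` lies in
`radius_bounds` (default 1–8 px) and its roundness `4*pi*area/perimeter^2`
is at least `roundness_min` (default 0.6). Perimeter is the Manhattan
boundary length scaled by `pi/4`, which is exact for digital disks; a thin
line scores roundness `~pi/n` and is rejected. None of these numbers is
prescribed by the source procedure (it states only "local maxima" and
"round features"), so all are exposed in `detection_params()`.

## 3. Registration through static landmarks

`match_centroids()` pairs two centroid sets by mutual nearest neighbours
with a distance ceiling (`max_dist`, default 5 px — half the synthetic
minimum cell separation; no threshold is stated by the source). Mutual-NN
pairs are one-to-one by construction; pairs are reported in ascending
distance order with ties broken by the lower index pair, which makes the
operation deterministic and permutation-invariant.

Across sessions, `register_cross_session()` matches each new session
against a *running reference*: the first session seeds the reference, and a
matched reference centroid is updated to the running mean of its members.
Unmatched session cells open new identities; unmatched reference cells are
simply absent from that session. A sequential reference was chosen over
all-pairs clustering because it is simpler, deterministic, and adequate for
rigid FOV jitter of a few pixels (the only jitter model simulated —
rotation and non-rigid deformation are out of scope).

`propagate_gcamp_map()` then assigns each dynamic-channel cell the global
identity of its cross-channel static partner. Dynamic cells without a
static partner are excluded. The "stable" subset is the set of identities
whose static landmark appears in **all** sessions: for these cells absence
of activity cannot be an artifact of the cell leaving the FOV.

## 4. Cross-talk between channels

For each cell registered across both channels, the observed cross-talk
coefficient is the OLS slope `beta` of the static trace on the dynamic
trace. An intercept is included because the channels have unrelated
baselines (the source does not state whether its fit had one; the slope of
a centred fit is unchanged by shifts either way). Traces are never z-scored
for fitting — `beta` must remain a ratio of raw fluorescence dynamics.

The null distribution circularly shifts the static trace by a uniform
random offset in `[min_shift, T - min_shift]` and refits; the default
minimum shift of 30 s far exceeds the indicator transient width, so the
shuffle destroys temporal alignment while preserving both marginal
distributions exactly. For stationary independent traces the null centres
at zero.

The *expected* ratio integrates the dynamic indicator's emission spectrum
against the two emission filters:
`ratio = integral(emission * T_red) / integral(emission * T_green)`
(trapezoidal rule on the union wavelength grid, so sub-nanometre filter
edges are not smeared). The package bundles a **synthetic** stand-in
spectra set (`synthetic_spectra_path()`): a tabulated GCaMP-like emission
curve written from the well-known shape of that spectrum (peak near 510 nm
with a long red tail) and idealized flat-top 525/50 and 630/75 band-pass
filters. These are constructed approximations, not measured vendor curves;
with them the ratio evaluates to 0.069, close to but not exactly the
published 0.075 for the real filter set. The operation itself is verified
exactly on boxcar spectra where the integrals are analytic. Quantitative
agreement with a published ratio requires the actual measured curves, which
are not redistributable here.

## 5. Behaviour and spatial statistics

*Speed* is the absolute central-difference gradient of the track-axis
position, scaled from pixels to cm via the track length and multiplied by
the frame rate; the session "running speed" is its 95th percentile, robust
to acceleration/deceleration. *Behaviour* is idle at or below 3 cm/s
(closed boundary: exactly 3 cm/s is idle; the speed is smoothed with a
5-frame moving average first to avoid label flicker), otherwise left/right
by the sign of the gradient. *Linearization* maps the track to
`[0, 100)` cm and offsets rightward-running frames by +100, so each
direction occupies its own half of `[0, 200)`; idle frames are undefined.
*Trials* complete each time the animal enters the end zone (outer 10 cm)
opposite the previously visited end.

Occupancy and spatial firing activity are cosine-kernel densities,
`K(u) = (pi/4) cos(pi u / 2)` for `|u| <= 1` with `u = (x - x_s)/5 cm`,
evaluated at 200 bin centres (1 cm/bin over both directions) and
normalized to sum to one. Firing samples are the positions of frames with
non-zero deconvolved signal, weighted by its amplitude.

Spatial information is
`I = sum_i p_i (lambda_i/lambda_bar) log2(lambda_i/lambda_bar)`. The mean
`lambda_bar` is the **occupancy-weighted** mean `sum_i p_i lambda_i`
(Skaggs convention). The source says "mean firing activity across the whole
recording session", which is ambiguous between a temporal and an
occupancy-weighted mean; the occupancy-weighted choice guarantees `I >= 0`
(Jensen) and makes `I` invariant to rescaling the firing map. A caller can
pass any other value through `mean_mode`. Bins with occupancy below 1e-4
are masked from normalized maps and statistics.

### Stability and the direction-split caveat

Within-session stability is the mean Pearson correlation of normalized
maps across two splits: odd vs even *round trips* and first vs second half
of trials. The source splits by odd/even trials, but on a shuttle task
consecutive trials alternate running direction, and with direction-split
maps a raw odd/even-trial split compares disjoint halves of the spatial
axis — in the idealized generator (each trial is a pure one-direction run)
the correlation would be computed on essentially empty overlap. Pairing
consecutive trials into round trips puts both directions on both sides of
the split and recovers the intended statistic. Real trajectories mix
directions within trials, which is why the original description works on
real data.

### Place-cell classification

`place_cell_test()` circularly shifts the deconvolved trace 500 times
(offsets uniform in `[30 s, T - 30 s]`), recomputes spatial information and
stability per shuffle, and classifies a cell as a place cell when **both**
observed statistics exceed the 95th percentile of their null
distributions. The conjunction of two 5% tests keeps the family false-
positive rate at or below 5%; the calibration test measures 3.5% on 200
untuned cells, and power 100% for planted fields with an in/out rate ratio
of 10 in a 15-minute session. Internally the 500 shuffles are a single
sparse-matrix product against precomputed kernel matrices
(`spatial_design()`), which makes the full-experiment classification run
in seconds.

### Population-vector correlation

For a session pair, the PV at each spatial bin is the across-cell vector of
normalized firing; the PV correlation is the mean over bins of the Pearson
correlation between the sessions. Cells inactive in one session either
enter as zeros (`zero-fill`) or are dropped (`intersect`). Zero-filled
correlations are systematically lower — dropping inactive cells removes the
zero terms — which is exactly the comparison the three inclusion criteria
are designed to expose. The cell set for a pair is the union of cells
classified as place cells in either session; the source says "all place
cells" without fixing the pair semantics, and the union keeps the set
symmetric in the pair.

## 6. Tracking statistics

`p_m = (1/k) sum_i N_mi / N_i` is the per-session probability that a cell
found in a session is tracked across exactly `m` sessions; the vector over
`m` sums to one for any activity matrix. The pairwise reactivation rate
`p_AB = (N_2/N_A + N_2/N_B)/2` is its `k = m = 2` special case, verified
in the tests by exhaustive enumeration of every activity matrix up to
3 cells x 3 sessions. Cells never seen anywhere are excluded from activity
matrices (they are undetectable); for the stable-subset analysis the
static channel defines row existence. Metric-vs-interval slopes are plain
OLS with exact-t p-values and no multiple-testing correction.

## 7. The synthetic world

The generator emulates the reference experiment: 7 sessions at 2-day
intervals (day indices 0..12, spanning 13 calendar days), 15-minute
sessions at 30 fps, ~150 cells per channel on a 1-m linear track.
Defaults the source does not state were chosen once, from field-typical
values, and are not tuned:

* **Trajectory**: back-and-forth runs at `N(45, 1)` cm/s (the published
  running speeds are ~45 cm/s) with exponential pauses (mean 2 s) at the
  ends.
* **Indicator kernel**: exponential rise 50 ms, decay 400 ms (typical
  GCaMP6f literature values); events are per-frame Poisson counts with
  uniform amplitudes in [0.5, 1.5].
* **Tuning**: 40% of cells get a Gaussian field (sigma 8 cm, centre
  uniform in the central 80% of the track, preferred direction random);
  in-field peak rate 2 Hz against a 0.02 Hz floor; untuned active cells
  fire homogeneously at 0.2 Hz.
* **Footprints**: isotropic Gaussians truncated at 3 sigma; sigma 3 px
  (dynamic) and 2 px (static, nuclear); minimum centroid separation 10 px.
* **Channels**: dynamic baseline 1.0; static baseline `N(2, 0.2)` per cell
  with a slow sinusoidal drift of 2% amplitude (one cycle per session —
  enough structure to make the shuffle null non-degenerate); planted
  cross-talk `alpha = 0.05`; white noise SD 0.1 on both channels (SNR 10
  against unit transients).
* **Longitudinal structure**: per-session activity is a stationary Markov
  chain with marginal `activity_prob = 0.7` and one-step autocorrelation
  0.5, so reactivation decays with session separation; field centres
  random-walk with SD 2 cm per session (representational drift); the FOV
  jitters rigidly by up to 2 px per session.

Seed streams are split per (cell, session), so enlarging the population
does not reshuffle existing cells. Every stage is bit-reproducible given
the config and seed.

**What the generator does not emulate** — and hence what a green test does
not establish: optical PSFs and focal-plane effects, within-session motion,
photobleaching, neuropil background, static-channel expression loss, cells
entering/leaving the FOV (the jitter never exceeds the registration
threshold), and irregular real-world behaviour (mid-track pauses, partial
runs). In particular, the static channel tracks all cells in all sessions
by construction, so the synthetic "stable subset" is the whole population —
the published divergence between all-GCaMP and stable-GCaMP curves arises
from FOV instability that is deliberately outside this model.

## 8. Numerical choices and degenerate inputs

* Quantile thresholds use R's default type-7 quantiles.
* The speed smoother sums unit weights then divides, so a constant speed
  stays exactly constant (the closed idle boundary is testable).
* Silent cells (no events) are classified "not a place cell" with a
  `silent` flag rather than raising; zero-variance dynamic traces are an
  error for cross-talk fits (`beta` undefined).
* Empty detection inputs return empty lists; empty densities, zero-session
  activity matrices, rank-deficient slope fits and degenerate spectra
  raise typed errors (`empty-density`, `zero-session`, `rank-deficient`,
  `degenerate-spectra`).
* KDE normalization is over the realized bins, so edge truncation of the
  kernel does not leak mass.

## 9. Known limitations

The footprint detector assumes roughly isotropic somata and will reject
genuinely elongated cells. The sequential reference registration can, in
principle, drift if jitter is large relative to cell separation; it is
validated only for the rigid-jitter regime. The PV correlation ignores
bins masked in either session rather than imputing. The cross-talk
expected ratio depends entirely on externally supplied spectra, and the
bundled stand-ins are approximations suitable for validating the
integration, not the optical system.
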