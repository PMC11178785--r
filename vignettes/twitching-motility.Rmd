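---
title: "Quantifying pilus-driven twitching motility: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pilus-driven twitching motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilitrack)
```

## The problem

Thermoacidophilic archaea such as *Sulfolobus acidocaldarius* move over
surfaces by *twitching*: cycles in which an adhesion (type IV) pilus extends,
its tip sticks to the substrate, and retraction of the filament drags the
cell body forward. In time-lapse movies (1 frame/s for 5 min) this produces
saltatory, low-persistence tracks; cells without functional adhesion pili
instead wobble around a fixed point, and cells that cannot attach at all may
detach and be carried by convection flow in long, straight "roller" tracks.
`pilitrack` implements the track statistics used to quantify these
phenotypes, the kinetic analysis of single-pilus retraction events, the
replicate-aware statistics used to compare strains, and a mechanistic
simulator that generates all of these data with known ground truth.

## Track statistics

For a track of positions $\mathbf{r}_1,\dots,\mathbf{r}_n$ (µm) sampled on a
fixed frame grid:

* **Net displacement** $D = \lVert \mathbf{r}_n - \mathbf{r}_1 \rVert$. This
  is the "track displacement" of standard tracking software — start-to-end
  distance, *not* the length of the path. Tracks with $D < 2$ µm are
  classified non-motile; 2 µm is roughly one cell diameter (1.6 µm) over the
  5-minute window and is a configuration value
  (`analysis_config(non_motile_threshold = )`), so histograms and
  classification always share the same cutoff.
* **Path length** $L = \sum_i \lVert \mathbf{r}_{i+1}-\mathbf{r}_i \rVert$
  over observed points. Gaps are never interpolated — missing frames simply
  contribute the straight segment between the flanking observations.
* **Persistence ratio** $P = D/L \in [0,1]$ (defined as 0 when $L = 0$).
  The literature does not fix this term algebraically; we use the
  *confinement ratio* reading (net over total path), which matches the
  feature of the tracking software that popularized it and the published
  benchmark values (about 0.12 for twitching archaea versus 0.75 for
  migrating astrocytes in a wound-healing assay). Directionality-ratio
  variants exist; if you need one, compute it from the track table — the
  package deliberately implements only the documented definition.
* **All-pairs MSD**. For lag $\tau = k\,\Delta t$,
  $\mathrm{MSD}(\tau) = \langle \lVert \mathbf{r}_j - \mathbf{r}_i
  \rVert^2 \rangle$ over *all* ordered pairs with $t_j - t_i = \tau$, not
  just consecutive windows. With gaps, pairs are formed only between
  observed points and lags with no pairs are dropped (`n_pairs` records the
  evidence per lag). Translating a track (e.g. aligning starting points)
  provably leaves the MSD unchanged, and the test suite asserts the
  invariance of the fitted slope under translation, rotation and uniform
  rescaling.
* **Anomalous-diffusion exponent $\alpha$**: the unweighted ordinary
  least-squares slope of $\log \mathrm{MSD}$ versus $\log \tau$. A random
  walk gives $\alpha \approx 1$, ballistic motion exactly 2, tethered
  wobbling a plateau ($\alpha \to 0$ at long lags). The fit uses lags up to
  `msd_max_lag_fraction` (default 25%) of the track duration: long-lag MSD
  values average very few pairs and are dominated by noise. The source
  experiments did not state their fit range, which is why $\alpha$
  comparisons carry a tolerance throughout. Lags with $\mathrm{MSD}=0$ are
  dropped (their log is undefined); fewer than two usable lags yields
  `NA` ("undefined"), never a fabricated value.
* **Classification**: `non_motile` if $D$ is under the threshold; `roller`
  if $D \ge 10$ µm *and* $P \ge 0.5$ (long and straight); otherwise
  `motile`. Diffusion classes cut $\alpha$ at 0.5 and 1.2 — the upper value
  is the edge above which observed wild-type slope distributions have
  essentially no mass.

Single-point and zero-length tracks are rejected with an error rather than
silently scored.

## Retraction kinetics

Pilus length traces $(t_i, L_i)$ (sampled every 0.5 s in the source
imaging) are smoothed with a centered moving average (default window 3,
partial windows at the ends). Maximal runs of strictly *decreasing* smoothed
length are candidate events; a plateau breaks a run, so two drops separated
by a constant stretch yield two events. Event boundaries are then read from
the unsmoothed trace: the end is the first sample attaining the run minimum
and the start is the last sample attaining the preceding maximum — this
undoes the one-sample spill-over that smoothing introduces at plateau edges,
and makes the estimator exact on noiseless traces whose retraction time is a
multiple of the frame interval (off-grid retractions incur at most one
frame-interval of boundary error). Runs with total drop below `min_drop`
(default 0.5 µm) are discarded; with the default 0.05 µm length noise, a
0.5 µm drop is ten noise standard deviations, which is why the noiseless
single-drop case is recovered exactly.

The **retraction speed** of an event is
$(L_\mathrm{ini}-L_\mathrm{final})/(t_\mathrm{final}-t_\mathrm{ini})$,
reported as a positive magnitude (the raw final-minus-initial difference is
negative for a retraction). Mean speeds follow the SuperPlot convention
(below); the speed–length relation is a Pearson correlation by default
(the analysis the published figure implies is a linear one; Spearman is
available via `speed_length_method = "spearman"`).

## Replicate-aware statistics (SuperPlots)

The statistical unit is the *biological replicate*, never the cell: cell
values are averaged within each replicate, and group means, SEMs and all
significance tests operate on those replicate means. Cell-level testing
with hundreds of pseudo-replicated observations would produce absurdly
small p-values; the package does not offer it. `anova_tukey()` fits a
one-way fixed-effects ANOVA on the replicate means and adjusts all pairwise
contrasts with Tukey's HSD using the single pooled within-group variance
(studentized-range distribution); the tests cross-check both against a
from-first-principles implementation. With a single replicate the SEM is
reported as `NA` and flagged, mirroring how such groups are shown without
error bars. Zero pooled variance is signalled explicitly rather than
returning a spurious p-value.

## The simulator

`simulate_track()` integrates a point-cell on a 0.1 s sub-frame grid
(10 sub-steps per 1 s frame):

* **Twitchers.** Pili nucleate as a Poisson process (rate
  `pilus_nucleation_rate`), each with a uniform random direction, a
  truncated-normal length on $(0, 14]$ µm (the longest observed fibers are
  about 14 µm) and a truncated-normal retraction speed supported on the
  observed 0.3–2 µm/s range. The tip anchors where it lands; while one
  pilus is attached the cell moves toward its anchor at the pilus's
  retraction speed, and with several attached it moves toward the
  *equal-weight centroid* of the anchors (cells end up "in the middle" of
  the remaining adhered pili — an equal-weight rule, not force-weighted) at
  the mean of the active speeds. A pilus detaches when its remaining length
  is exhausted; with probability `recoil_prob` the cell then takes a single
  instantaneous `recoil_step` backward along that pilus axis — the backward
  slip seen when a cell loses surface attachment, which the source imaging
  describes only qualitatively, hence the simplest one-parameter form.
* **Tethered** cells are iid isotropic Gaussian wobble about a fixed
  anchor. * **Rollers** dwell for a uniform random time, then move at
  constant velocity in a fixed random direction.

Sampled positions receive isotropic Gaussian localization noise. One root
seed drives everything; per-track streams are derived by a fixed counter
scheme (`derive_seed`), so a cohort is bit-reproducible and a given track
keeps its trajectory when the cohort grows.

### Calibration of the strain presets

Live imaging does not measure pilus nucleation rates, per-cell pilus
counts, tether amplitudes or localization noise, so these are free
parameters. They were fixed *once* by a coarse grid search (a few hundred
tracks per candidate, finalists confirmed at a few thousand) against the
published cohort statistics, then frozen verbatim in
`inst/extdata/presets.yaml`; `builtin_presets()` reads that file. The
frozen `WT` preset (nucleation 0.085 /s, pilus length 1.5 ± 0.5 µm, 4.5%
tethered, 0.04 µm noise) reproduces, at large $n$, a mean displacement of
5.71 µm, mean persistence 0.123 and a 12.6% non-motile fraction — against
published values of 5.7 ± 0.44 µm, 0.12 ± 0.03 and 12.4%.

The `daapF` (adhesion-pilin deletion) preset deserves an honest note. Its
published statistics — mean displacement 1.49 µm yet only 46.2% of tracks
under 2 µm — jointly constrain the displacement distribution more tightly
than a Gaussian-wobble population can satisfy: for iid wobble the net
displacement is exactly Rayleigh, and any Rayleigh scale putting half the
cells above 2 µm forces a mean near 2.1 µm. A cohort dominated by large
tethered wobblers therefore cannot reproduce both numbers. The frozen
preset instead models the mutant's residual motility as *rare, short
displacement events* (nucleation 0.00317 /s, so roughly a third of cells
experience no event in 5 min and simply wobble at the noise floor) plus a
small explicitly tethered fraction. This sits at the model family's joint
feasibility optimum (about 1.67 µm and 47%, versus 1.49 µm and 46.2%
printed) and is centered between the two constraints rather than on either
one. Mechanistically the "events" need not be pili at all — detachment and
reattachment under flow produces the same signature — and the preset should
be read as phenomenological for this strain.

`darlJ` is WT-like with almost no tethered cells; `daapB` is mostly
tethered with a 20% roller fraction whose long straight tracks dominate its
displacement distribution. Both are qualitative presets: their published
statistics were not calibration targets. A floor of the twitcher model
worth knowing: even motile twitchers have an ~8% chance of a sub-2 µm
excursion in 5 min at WT-like rates, so the model cannot reach the 4.2%
non-motile fraction reported for the archaellum mutant without raising its
nucleation rate — `darlJ` uses 0.1 /s for this reason.

### What the simulator does and does not emulate

It reproduces the *statistical* structure of the published cohorts:
saltatory low-persistence walks, wobbling non-motile cells, ballistic
rollers, displacement and persistence distributions, MSD slope clusters,
and single-pilus retraction traces with endpoint-recoverable speeds. It
does **not** model hydrodynamics, cell shape or division, pilus bending,
force-dependent speeds, 3-D motion, or DIC image formation — the rendered
movies are Gaussian blobs with additive noise, meant to stress the
detection/linking stage, not to mimic microscope physics. Passing tests on
synthetic data therefore validate the *estimators and pipeline*, not any
biological claim about real movies.

## Imaging and tracking stage

`render_movie()` draws each cell as an isotropic Gaussian blob
(sd = radius/2, default radius 0.8 µm) on a pixel grid where the µm origin
is the center of pixel (0, 0); background noise is set by the peak SNR.
`detect_cells()` smooths, thresholds at mean + 3 sd, takes connected
components of at least 4 px and returns intensity-weighted centroids
(touching cells may merge — a documented limitation of the deliberately
simple detector). `link_tracks()` is greedy nearest-neighbor linking
(closest pairs first, links capped at `max_disp` = 2 µm/frame, gaps bridged
up to 2 frames): global assignment is unnecessary at the cell densities
simulated here, and the greedy rule is trivially auditable. The end-to-end
check (simulate → render at SNR 10 → detect → link → metrics) recovers the
group mean displacement within a few percent of ground truth
(`analysis/05_imaging_closure.R` prints the number for its run).

## Problem sizes and reproducibility

The packaged analyses use the published cohort sizes (200 WT, 222 daapF,
284 darlJ, 302 daapB tracks; 300 s at 1 frame/s; three replicates; 19
single-pilus traces), which run in seconds to a couple of minutes on one
CPU. The imaging-closure analysis uses a 12-cell, 2-minute field so the
rendered stack stays around 100 MB. Every pipeline stage writes a
`manifest.yaml` with the package version, seed, configuration/preset
snapshot and MD5 digests of its outputs; re-running a stage with the same
manifest inputs reproduces the tables byte-identically.

## Known limitations

* The persistence-ratio definition is a documented choice (confinement
  ratio); other definitions exist and will give different absolute values.
* The MSD fit range (25% of duration) is a convention; $\alpha$ values
  shift by a few hundredths under reasonable alternatives.
* Event detection boundaries are exact only on-grid; off-grid retraction
  endpoints incur up to one frame of bias (a percent-level speed effect at
  the default sampling).
* The daapF preset is phenomenological (see above); its tethered fraction
  should not be interpreted as a measured wobbling fraction.
* Greedy linking fails at high density or displacement per frame larger
  than the inter-cell spacing; the renderer's grid layout avoids this by
  construction.
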