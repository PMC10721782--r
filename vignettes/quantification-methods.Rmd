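---
title: "Quantification methods: vessel morphometry, regional plaque density, and study statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphomorph)
```

# Scope

`lymphomorph` implements the measurement layer of a photobiomodulation (PBM)
study in 5xFAD mice: how much a course of transcranial 1267-nm light changes
(i) the diameter of meningeal lymphatic vessels (MLVs) seen in
immunofluorescence, (ii) the density of amyloid-beta plaques per brain
region in cleared light-sheet volumes, (iii) behavioral readouts
(novel-object recognition, water-maze escape latency), and (iv)
cortical-surface temperature and tracer drainage kinetics — together with
the group statistics (mean ± SD, Welch t-test, one-way ANOVA) that tie the
arms of such a study together. Atlas registration is out of scope: the
package consumes a label volume already deformed onto the image grid.

No raw data accompany the study, so every stage is validated by **parameter
recovery**: a synthetic-data module generates each input with a known truth
sidecar, and the tests require the pipeline to recover that truth. The
analysis scripts under `analysis/` run the whole workflow on simulated
studies at the study's stated group sizes.

# Vessel diameter pipeline

The pipeline realizes the classic profile-curve measurement: binarize,
clean, extract the centerline, estimate tangents, and read off the
perpendicular chord at each sampling point.

**Otsu threshold.** `compute_otsu_threshold()` histograms the intensity
range (one level per integer for 8/16-bit data up to 256 levels, otherwise
256 equal bins) and exhaustively maximizes the inter-class variance.
Foreground is *strictly greater* than the threshold. On a plateau of
maximizers the midpoint is returned — symmetric and deterministic, so a
half-0/half-255 image thresholds at 127.

**Cleanup.** `clean_mask()` applies closing (disk, default radius 2 px),
removal of 8-connected components below 64 px, and hole filling. All three
steps are idempotent; defaults suit immunofluorescence masks at roughly
0.5–2 µm/px.

**Centerline.** `extract_centerline()` thins the mask (Zhang–Suen),
prunes spurs shorter than 5 px, splits the skeleton into branches between
endpoints and junctions, and smooths each branch with a 5-point moving
average. The smoothing matters quantitatively: the raw 8-connected pixel
chain overestimates Euclidean arclength by up to ~8% at oblique
orientations, which would bias any quantity indexed by arclength (for a
linearly tapering vessel, the recovered taper slope was 14% low before
smoothing and within 1% after).

**Tangents.** The tangent at a point is the principal component of the
centered centerline points within ±5 px of arclength, sign-oriented along
the branch. Endpoints use one-sided windows.

**Chords.** `measure_diameter_at()` casts rays along ±normal, sampling the
mask by bilinear interpolation at 0.1-px steps; each boundary is the first
0.5-crossing of the interpolated mask. Treating the binary mask as a
continuous field makes the measurement continuous under rotation, but it
quantizes *axis-aligned* chords to odd pixel counts (the crossing always
sits half-way between the last foreground and first background row). Single
chords therefore carry ±0.5–0.7 px of raster phase noise; averages over a
profile, which is what the study reports, do not.

**Which mask is measured.** Topology (centerline, tangents) comes from the
cleaned Otsu mask, but chords are measured on a *half-height mask*: the
image re-binarized at the midpoint between the median intensity at the
centerline points (interior foreground by construction) and the median
off-mask intensity. The reason is a small but systematic property of Otsu's
method: its threshold satisfies t = (µ0 + µ1)/2 over class *means*, and the
partial-intensity pixels of the blurred vessel edge drag µ1 well below the
plateau level — on synthetic tubes the threshold lands near 42% of contrast
instead of 50%, dilating the mask by ≈ 0.35 px. That alone exceeds the 5%
error budget for a 5-px vessel. Class *medians* are insensitive to the edge
ramp, and at the half-height level the 0.5-crossing coincides with the true
half-maximum of a Gaussian-blurred edge.

**Sampling.** `diameter_profile()` samples every 1 px of arclength,
skipping points within 3 px of a branch end, and additionally discards any
sample whose distance to the branch end is less than *half its own measured
diameter*: closer than that, the perpendicular chord cuts the vessel end
cap (or the joining branch at a junction) and underestimates the width.
This self-scaling exclusion is what keeps wide vessels (30 px) as accurate
as narrow ones.

With all of the above, synthetic straight tubes of true width 5–30 px at
0–45° under noise at 10% of contrast are recovered within ~2% (tests assert
5%), with ≤ 0.4 px spread across rotations.

# Plaque detection and regional density

`detect_plaques()` thresholds the volume, groups voxels at 26-connectivity
(via the voxel adjacency graph), drops components below `min_voxels`
(default 5), and records intensity-weighted centroids and volumes. Three
thresholding modes are exposed:

* `"otsu"` — global Otsu, the default for balanced foregrounds;
* `"fixed"` — a user value, as an Imaris-style surface threshold;
* `"background"` — median + 6·MAD of the whole volume.

The third mode exists because global Otsu has a failure mode directly
relevant here: when plaques occupy well under ~1% of the volume (the
*treated* group at realistic burdens), the inter-class variance of
splitting the background noise in half exceeds that of the true gap split,
and the threshold collapses into the noise. Robust background statistics
are the standard remedy for sparse spot detection; at Gaussian noise,
median + 6·MAD sits at ≈ 4 noise SDs, giving a ~3-voxel false-positive load
per 10^6 voxels, removed by the size filter. `quantify_study()` uses it by
default.

`assign_regions()` maps each plaque to the label at its rounded centroid
(deterministic, cheap; boundary-straddling plaques go wholly to their
centroid region). `region_density()` reports, per named region, the plaque
count, summed plaque volume, region volume, count density per mm³, and the
volume fraction. Both density flavors are always computed because "plaque
density" is used both ways in the literature; volume fraction is the
headline metric here, as plaque burden is conventionally a volume (or area)
fraction. `merge_region_groups()` pools counts and volumes over subregions
and recomputes densities from the sums — never by averaging densities — so
a merged row equals what a merged label volume would have produced.

`reduction_rate()` scores a two-group comparison as
`100 × (1 − mean(treated)/mean(control))` on per-animal densities, with a
two-sided Welch t-test. Groups are unpaired, so the alternative summary
reported alongside is the median-based reduction; a per-animal ratio mean
would be undefined.

# Behavioral and physiological readouts

The recognition index is `T_novel / (T_novel + T_familiar)`; chance is 0.5.
Escape latency is the time to the first tracked sample *strictly inside*
the platform ROI (no interpolation between samples — tracking at ≥ 10 Hz
makes sub-sample interpolation immaterial), capped at the 60-s trial
length; in a probe trial the ROI is the former platform location. Path
length sums Euclidean steps, and speed divides by elapsed time, so a closed
loop has nonzero speed. No trajectory smoothing is applied.

Temperature traces are summarized against a baseline: the mean over the
60 s preceding the first irradiation segment. `max_temperature_rise()`
reports the maximum of (T − baseline) over the session — negative if the
trace only cools — and flags rises above +0.5 °C, the conventional
threshold for irreversible cortical thermal damage (a flag only; data are
never modified). The raw maximum of a long sampled trace carries an
extreme-value bias of several noise SDs, so an optional centered smoothing
window (recommended 10–30 s) is available and used in the analysis
scripts. `mean_temperature_rise()` averages irradiation segments and also
reports the whole-session mean, since either averaging convention is
defensible. The default session schedule is 17 min irradiation, 5 min
pause, 17, 5, 17 — 61 min in total.

`roi_timecourse()` quantifies tracer series as mean ROI intensity minus
mean background-ROI intensity, clamped at zero (hence invariant to adding a
constant to the image), with optional normalization to the series maximum
for cross-animal comparison at fixed timepoints.

# Statistics

`mean_sd()` (sample SD, n−1), `t_test()` (Welch by default, pooled
available), `one_way_anova()` (fixed-effects omnibus; no post-hoc test is
attached because none is part of the study design), and `star_flags()`
(strict `*`/`**`/`***` at 0.05/0.01/0.001). P values are reported
uncorrected and labelled as such; a Holm correction across regions can be
applied downstream via `stats::p.adjust()` but is off by default to match
the study's reporting. For two groups the pooled-variance F equals t², and
the suite checks both tests hold their nominal size (type-I error within
[0.040, 0.060] at α = 0.05 over 10⁴ null replicates).

# The synthetic-data module

Every generator is a pure function of (parameters, seed) and attaches a
`synthetic_truth` sidecar; recovery tests read truth only from the sidecar.

* **Vessels** — a tube of prescribed width profile rasterized along a
  midline, with the Gaussian PSF realized as the exact blurred-edge profile
  and additive Gaussian noise. Study conditions used in tests: contrast
  100, noise 10, PSF σ = 0.8 px.
* **Labels/plaques** — disjoint boxes/spheres of integer labels;
  non-overlapping bright spheres (radius uniform in 2–5 voxels by default)
  placed uniformly in each region. A proposed sphere is added only while it
  moves the realized volume fraction *closer* to the target, so the
  realized fraction ends within one sphere volume of the target without
  systematic overshoot; the truth records the realized value.
* **Group studies** — per-animal volume fractions drawn lognormal
  (positive support, CV-parameterized; the study gives only mean ± SD bars,
  no distributional claim) with the treated mean scaled by (1 − effect).
* **Trajectories** — a correlated random walk whose heading is pulled
  toward the platform at a per-second rate `goal_bias` (compounded over
  `dt`, so drift strength does not depend on the sampling rate), with
  wall reflection.
* **Explorations** — the novel-object share drawn from a Beta with mean
  `preference`.
* **Temperature** — first-order exponential approach to baseline + rise
  during irradiation, decay during pauses, plus observation noise.

What the generators deliberately do **not** emulate: optical sectioning,
vignetting, scattering, depth-dependent attenuation, plaque morphology
beyond spheres, vessel branching hierarchies, thigmotaxis, or
pharmacokinetics of the tracer. Passing recovery tests therefore shows the
*measurement* layer is unbiased under idealized image formation, not that
real microscopy is this clean.

# Problem sizes and numerical choices

Simulated study volumes are 40×48×48 voxels with a single 32×40×40 region
and plaque radii 2–4 voxels (defaults elsewhere: 64×128×128, radii 2–5),
chosen so a 200-replicate Monte-Carlo of the full
simulate → detect → assign → density → compare chain runs in about a minute
on one CPU while each animal still carries ~10–25 plaques. Vessel recovery
uses 120-px tubes. Degenerate inputs fail loudly: constant images have no
Otsu threshold, empty masks and single-pixel skeletons are rejected,
vessels shorter than twice the end exclusion are "not measurable", a
control group with zero mean has no defined reduction rate, and
zero-voxel regions cannot be tabulated. Ray casting steps at 0.1 px with a
100-px chord cap; bilinear interpolation treats outside-image as
background.

# Known limitations

* Diameters are defined by the half-height boundary of a single channel;
  no colocalization (LYVE-1 × PROX-1) logic is included.
* Centroid-based region assignment can misattribute plaques straddling a
  boundary; a per-voxel majority rule would cost more and is not
  implemented.
* The ANOVA layer is omnibus-only; training-day curves would need
  repeated-measures modeling, which is out of scope.
* 2D morphometry only; 3D vessel morphometry is a non-goal.
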