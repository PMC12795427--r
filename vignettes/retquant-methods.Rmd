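---
title: "Methods: retinal OCT/OCTA quantification and water-maze correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal OCT/OCTA quantification and water-maze correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retquant)
```

retquant implements the quantification pipeline of a longitudinal retinal
imaging study in a transgenic mouse model of Alzheimer-like amyloidosis:
OCT layer-thickness zonation around the optic nerve head (ONH), SNR-gated
vessel density in the three retinal vascular plexuses from OCT
angiography (OCTA), Morris water maze (MWM) trajectory metrics, and the
longitudinal and structure-function statistics that tie the imaging
parameters to spatial memory. Because raw study data (OCT volumes, swim
videos) are not public, the package ships a synthetic-data module that
generates all three kinds of input with known ground truth; every claim
the pipeline makes is validated against that truth in the test suite.

## The synthetic retina phantom

`phantom_config()` / `generate_phantom()` render a layered reflectivity
volume over a 1 × 1 mm field centered on the ONH:

* Six layers (RNFL/GCL complex, IPL, INL, OPL, photoreceptor complex,
  RPE) stacked below a smoothly undulating inner limiting membrane.
  Boundary surfaces are sums of low-order random-phase cosine modes;
  layer thickness defaults (42/26/27/18/80/28 µm) are plausible murine
  values summing to a ~221 µm retina. Reflectivities alternate
  (plexiform bright, nuclear dark, RPE brightest), which gives the
  gradient-sign sequence the boundary search relies on.
* An ONH pit: all layer thicknesses taper smoothly to 2% of their mean
  inside the ONH radius (default 100 µm), and the depolarization channel
  has a gap there, as the real nerve head interrupts the RPE.
* Vessels drawn as smoothed random-walk tube segments (radius 5–8 µm,
  segment length ≤ 150 µm — plausible murine inter-branch distances)
  within a band at the anatomical depth of each plexus, stamped until the
  target area density is reached; the final stamp is truncated
  pixel-by-pixel so the realized density lands within one pixel of the
  target. Segment starts are uniform over a domain padded by the segment
  length and walks are length-limited rather than clipped at a boundary,
  so coverage is spatially homogeneous out to the field border — without
  this, border-avoiding walks make the analysis region ~1–2 percentage
  points denser than the full field and bias every measured-vs-realized
  comparison. Only the density and the en-face masks are ground truth;
  the tube geometry is a modelling convenience.
* Fully developed speckle: multiplicative exponential intensity noise
  shared across the five repeated B-scans outside vessels and mixed with
  an independent draw (default level 0.9) inside them, plus an additive
  exponential noise floor. An optional radially decreasing signal
  multiplier (`snr_edge`) creates low-SNR zones for gating tests.

The default grid is 256 × 200 × 384 voxels (fast × slow × depth) at
1.5 µm axial sampling — a desk-scale stand-in for the full 512 × 400
acquisition; all distances are physical micrometres so anisotropic pixels
are handled throughout. The axial sampling of the reconstructed volumes
is not stated by the imaging protocol (only the ~3.8 µm optical axial
resolution); 1.5 µm/px is our choice and is configurable.

What the phantom does *not* emulate: eye motion between B-scans,
vignetting, projection (tail) artifacts from superficial onto deep
plexuses, pathology, or realistic capillary network topology. Passing
tests therefore demonstrate correctness of the measurement chain, not
robustness to every artifact of in vivo imaging.

## Layer analysis

`flatten_volume()` locates the RPE per A-scan as the depolarization-
weighted centroid depth, median/box smooths the depth map laterally,
in-paints A-scans without depolarizing signal (ONH) from their
neighbours — more than 30% invalid A-scans raises an error, mirroring
the quality screening that excluded unusable scans — and shifts every
A-scan axially to a common reference depth. Shifts are sub-pixel (linear
interpolation): integer shifting leaves ±half-pixel steps between
neighbouring A-scans that lateral smoothing later turns into boundary
errors above one pixel.

`segment_layers()` is a reimplementation in the spirit of established
gradient-based OCT boundary searches: on the repeat-averaged, lightly
smoothed volume (5 × 5 lateral box, [1,2,1] axial kernel), the ILM is the
first strong positive axial gradient peak above the RPE reference, and
each subsequent boundary is the sign-matched gradient extremum within an
anatomically bounded offset from the previous one (lower offsets clear
the smeared edge of the previous boundary; upper offsets cap each
layer's thickness). Sub-pixel position comes from the centroid of the
gradient lobe around the peak. A lateral 15 px median filter is then
used for outlier *rejection*: the raw estimate is kept where it agrees
with the median within 2 px and replaced by it otherwise. Replacing all
estimates by the median (plain smoothing) biases curved surfaces by up
to ~1.3 px at coarse grids; the rejection variant keeps the noise-free
accuracy at ≤ 0.6 px while still suppressing vessel-shadow outliers.
Ordering is enforced by projection and violations of it raise an error
naming the boundary.

`thickness_maps()` derives the nine standard maps (TOTAL, IRL, ORL and
the six sublayers) as boundary differences, so the composition
identities TOTAL = IRL + ORL, IRL = RNFL/GCL + IPL + INL and
ORL = OPL + PRC + RPE hold *exactly* by construction. The IRL/ORL split
follows the explicit sublayer memberships (OPL belongs to the ORL); the
alternative grouping is computable from the six sublayer maps if wanted.
RPE thickness is the thickness of the segmented depolarizing band.

`annulus_sector_average()` averages a map over the 200–600 µm annulus
around the annotated ONH center and within four sectors formed by the
diagonals of the square field. Pixel membership uses pixel centres in
physical µm with a half-open radial test `[r_in, r_out)` and half-open
angular bins, so membership is deterministic and matches exhaustive
enumeration exactly. Sector names (superior/nasal/inferior/temporal) are
image-frame labels (top/right/bottom/left); true anatomical orientation
depends on eye laterality and is reported as such. The ONH centre is
always an explicit annotation; `detect_onh()` (depolarization-gap
centroid) is provided as a convenience but never called silently.

## OCT angiography

`compute_octa()` computes motion contrast between adjacent repeat pairs
as one minus the amplitude correlation over a local axial window,
averaged over the four pairs and clipped to [0, 1]. A windowed
*correlation* (rather than a pointwise amplitude-similarity ratio) is
used deliberately: for independent speckle the expectation of the
pointwise ratio 2·A₁A₂/(A₁²+A₂²) is π/4, so a pointwise operator cannot
separate flow from static tissue by more than ~0.2 on average, whereas
the windowed correlation gives ≈ 0 for shared speckle and ≈ 1 for
independent amplitudes. The pipeline default window is 5 px: a short
window keeps flow contrast localized in depth so vessels in one plexus
do not smear across the slab boundary into a neighbour (with a 9 px
window the deep-plexus band ghosts into the intermediate slab and biases
its density by up to +3 percentage points).

`project_slabs()` max-projects the decorrelation volume within the three
slabs defined by the segmentation — SVP in [ILM, RNFL/GCL–IPL), ICP in
[RNFL/GCL–IPL, INL–OPL), DCP in [INL–OPL, OPL–PRC) — and mean-projects
the structural intensity over the same slabs for SNR. The DCP slab's
lower bound is the OPL–PRC boundary since the outer nuclear layer sits
inside the photoreceptor complex in this segmentation scheme. The noise
floor is the mean + 2 SD of the structural intensity in the signal-free
vitreous band above the shallowest ILM (the protocol never defines
"noise floor"; this estimator is configurable).

`binarize_vessels()` marks a pixel as vessel when (1) the structural
slab signal is ≥ 10× the noise floor, (2) the decorrelation is at or
above Otsu's threshold on the quality-gated decorrelation histogram,
and (3) the pixel lies within the Frangi vesselness support of the
decorrelation map — hysteresis thresholding (strong = Otsu on the
vesselness histogram, weak = a quarter of it, weak regions kept only
when 8-connected to a strong pixel), dilated by one pixel. The design
rationale: a ridge filter thresholded at a single cutoff recovers only
~2/3 of true vessel area because tube interiors and junctions have
near-zero principal curvature, which makes an area-density measurement
biased by several percentage points. Letting the sharp decorrelation
transition carry the vessel *shape* while the Frangi support verifies
curvilinear *structure* (and rejects isolated speckle) recovers phantom
densities to within ±2 percentage points. The Frangi filter itself is
the standard two-parameter multiscale Hessian vesselness (scales 1–4 px,
blobness β = 0.5, structureness cutoff at half the per-scale maximum,
γ = 2 scale normalization), implemented in the package.

A 10 px border frame is zeroed, the ONH disc is cut out (default 100 µm
radius, matching the 200 µm diameter removed in the thickness analysis;
the protocol does not state the OCTA cutout radius), and
`snr_sector_map()` assigns every pixel to a zone: diagonal quadrant ×
100 µm ring (half-open, ring = floor(dist/width)). Zone SNR is the mean
structural slab signal over the zone divided by the noise floor — the
structural signal, not the flow signal, since an SNR of flow contrast
would be self-referential; this choice is configurable.
`gated_vessel_density()` removes zones below the plexus gate (20× for
SVP and ICP, 15× for DCP), counts vessel and non-vessel pixels in the
remaining zones (excluding border and ONH cutout) and reports
100·positive/(positive+negative). If no zone passes the gate the result
is flagged missing, not zero, mirroring the exclusion of unusable
measurements. Pixel counts are unweighted even though pixels are
anisotropic, matching a count-based area density.

## Morris water maze

`pool_geometry()` fixes the assay geometry: a 1 m diameter pool with
compass quadrants (N = +y, E = +x; half-open angular bins), an 8 cm
hidden platform at half the pool radius in the NW quadrant, and a 10 cm
wall (thigmotaxis) zone. The protocol's schedule table places the
platform in NW for all trials with the probe trial starting from SE, and
the generator follows that table (the accompanying text mentions the
north-east quadrant once; the table is taken as authoritative and the
position is configurable).

`generate_trajectory()` simulates one trial as a persistent random walk
inside the pool disc: each frame (14 Hz) the heading is a renormalized
mix of the previous heading (weight 8), a drift toward the platform, an
outward wall attraction (thigmotaxis, default weight 0.15), and
isotropic noise (SD 0.45); the position advances at the trial's swim
speed (drawn once, mean 0.20 m/s, SD 0.04 — typical murine swim speeds)
and reflects off the wall. The platform drift weight is logistic in
(ability × training day), rescaled so that zero or negative drive gives
exactly zero drift: zero-ability animals are then unbiased, which is
what the probe-day chance level (25% per quadrant, tested over 1000
seeds) requires. The release heading is uniform over the inward-facing
half circle; together with the persistence/turn-noise defaults this was
calibrated once so that a zero-drift walk occupies each quadrant at
25 ± 0.6% despite the fixed SE start (a too-diffusive walk retains the
start bias; a too-ballistic one retains its release axis). Floating is
generated as explicit low-speed episodes (0.005 m/s, episode starts at
0.3/min, exponential mean 2 s), so the floating metric has ground
truth. Training trials end at platform contact (first sample inside the
disc, no dwell requirement) or at the 60 s cap; probe trials last
exactly 60 s with the platform absent while the remembered drift still
applies — which is what probe-day abidance measures.

The metric functions weight each sample by the interval to the next
sample (the last carries the mean interval), so irregular frame times
are handled. Latency is the time of the first sample inside the platform
disc (cap if never); distance is the polygonal path length, truncated at
the latency on training days (whether the tracked distance stops at
contact is not stated by the protocol; truncation is the default and
configurable); floating is the time share of maximal episodes with
speed < 0.02 m/s sustained ≥ 1 s (central-difference speeds); thigmotaxis
is the time share beyond pool radius minus wall width; abidance is the
time share per quadrant (sums to 100 by construction); and target-zone
crossings count outside-to-inside transitions of the former platform
footprint, a start inside counting as one. The floating and wall-zone
parameters are defaults of the tracking software used by such studies
and are not printed in protocols; 0.02 m/s, 1 s and 10 cm are our
choices, all configurable. `trial_table()` validates trial labels
against the schedule and assembles the per-trial table (training days:
latency/distance/floating/thigmotaxis; probe day:
abidance/crossings).

## Cohort generator

`generate_cohort()` draws a long-format longitudinal table (animal ×
eye × week × layer) from a random-intercepts model: group baseline +
group slope·(week − first week) + animal intercept + eye offset +
residual. Defaults mirror the study structure: 16 animals per genotype ×
sex cell (64 total), imaging at 12/20/24/36 weeks, staged removals (16
animals after week 12, 21 after week 24) leaving 27 animals — 14
transgenic, 13 control — at the final week. Baselines are plausible
murine layer thicknesses with males a few µm thicker in the inner
retina and a mild thickening over time. Each animal carries a latent
memory ability (standard normal); for the correlation-carrying layer
(INL by default) the animal intercept is built from that ability with a
loading chosen so the *eye-averaged final-week* thickness has exactly
the configured population correlation (default 0.87 in transgenic
females, the study's headline association). The loading must not exceed
the intercept SD — infeasible combinations raise a validation error
rather than silently attenuating the correlation. Negative generated
thicknesses are clipped at zero and flagged.

## Statistics

`fit_mixed_intercepts()` fits value ~ genotype × sex × week with a
random intercept per animal by REML (lme4), week categorical by default
(the study compares discrete timepoints; a linear-in-week variant is a
flag). Repeated eyes enter as within-animal observations. Factors with
one observed level are dropped; when every animal contributes exactly
one observation the per-animal intercept is unidentifiable and the
model reduces — exactly — to OLS, which the function uses and flags.
`pairwise_emmeans()` computes marginal means per group cell (within
week) and pairwise contrasts via emmeans, with p-values from the
t-distribution on residual degrees of freedom (observations minus
fixed-effect parameters; Satterthwaite-style approximations are
deliberately not used) and *no* multiplicity correction by default,
matching the exploratory design (`adjust = "BH"` is available). In the
balanced single-week two-group case with zero intercept variance the
contrast p equals the classical pooled t-test p to numerical precision,
which the tests assert.

`day5_tests()` (unpaired pooled-variance t-tests; Welch behind a flag),
`chance_level_test()` (one-sample t against 25% abidance or 1.5
crossings), `cohens_d()` (n−1 pooled SD), and `pearson_corr()`
(Pearson r with t-distributed p on n−2 df, plus slope, intercept,
R² = r² and MSE = mean squared residual from the least-squares line on
the same pairs) cover the probe-day and correlation layer.
`correlate_retina_behavior()` averages the two eyes of each mouse first
— one mouse, one statistical unit — joins to per-animal behavioral
metrics, and emits one correlation row per (group, retinal parameter,
behavioral parameter) for the six standard groupings (all/female/male ×
transgenic/control), skipping groups below three complete pairs with a
reason. Body weight can be passed as just another retinal-table
parameter.

`pearson_power()` is the two-sided power of the correlation test under
the Fisher z approximation: with effect atanh(ρ)·√(n−3), power =
Φ(effect − z₁₋α/₂) + Φ(−effect − z₁₋α/₂). At ρ = 0.87, n = 8 it gives
0.846, i.e. the 0.85 reported for the study's headline correlation, and
at ρ = 0 it equals α exactly.

### Known limitations

* The plain Fisher z power approximation is biased low at moderate n
  because it omits the finite-sample mean shift ρ/(2(n−1)) of atanh(r):
  at (ρ = 0.5, n = 30, α = 0.05) it gives 0.814 while the exact power of
  the two-sided t-test (by integrating the exact sample-correlation
  density; Monte-Carlo agrees to 3 decimals) is 0.828. The discrepancy
  of 0.013 is real and documented rather than hidden; the bias-corrected
  or exact variants were not adopted because they no longer reproduce
  0.85 at (0.87, 8) — the exact power there is 0.896. One formula cannot
  do both; the package implements the approximation the study's number
  is consistent with.
* No projection-artifact removal between plexuses: strong superficial
  flow can still shadow into deeper slabs in real data; the phantom only
  probes the axial-window leakage component of this.
* Segmentation assumes the alternating bright/dark layer contrast of a
  healthy rodent retina; severe pathology would require different
  priors.
* Mixed-model contrasts use residual df, which is mildly anticonservative
  for small unbalanced designs relative to Satterthwaite.

### Problem sizes used by the tests

Unit tests run on 96 × 80 phantoms; the acceptance suite uses
256 × 200 × 224 phantoms (ILM placed at 60 µm — the same retina with
less empty depth) for the 20-phantom density-recovery sweep, the full
256 × 200 × 384 default for noise-free thickness recovery, 1000 seeds
for the probe-day chance level, 100 simulated cohorts of 200 animals for
variance recovery, and a 100,000-replicate Monte-Carlo for the power
check. These sizes are the package's own choices for a reproducible
desk-scale validation of the full-scale method.
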