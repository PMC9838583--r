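---
title: "Models, estimators and design choices in uwfvasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in uwfvasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which knobs
matter, and where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement model

An eye enters the pipeline as a binary vessel mask (or a grayscale image
that is first segmented), a manual region-of-interest polygon, the optic
disc center and diameter, the fovea center, and the laterality. All
coordinates use one convention throughout: pixel `(i, j)` has its center at
`((j - 0.5) s, (i - 0.5) s)` mm with `s` the scale in mm/px, the origin at
the image top-left, and rows increasing downward.

### Regions

Fractal dimension depends on the region it is measured in, so the region is
standardized: the **standardized ROI** is the pixel-wise AND of every manual
ROI of one laterality across the dataset. Right- and left-eye ROIs are never
mixed. The **posterior** region is the annulus `d/2 < r <= d/2 + k d` around
the disc center (`d` = disc diameter); the text the package follows gives
the extent as three disc diameters while its table footnote says two, so `k`
is a configuration parameter with default 3 and the discrepancy is surfaced
rather than silently resolved. The annulus is clipped to the standardized
ROI, and the **midperiphery** is the standardized ROI minus the posterior
region (the footnote's "zone C" is read as the posterior region). The disc
interior belongs to no region.

**Quadrants.** The temporal axis u runs from the disc center to the fovea;
a pixel is Temporal when its disc-offset has positive component along u
(ties → T). Superior is the smaller-row side of the disc–fovea line
(ties → S); when that line is exactly vertical the +90° rotation of u breaks
the tie. Anchoring Superior to the image "up" keeps the labels anatomical
for both lateralities (temporal derives from the fovea position, so nothing
flips with left/right metadata); the construction is invariant to rotations
of the whole geometry as long as they do not carry the temporal axis across
the vertical, where "up" genuinely changes sides.

### Sandbox fractal dimension

`sandbox_dimension()` draws `n_centers` (default 500) centers uniformly from
skeleton pixels whose distance to the ROI boundary exceeds the largest
radius — boundary-crossing sandboxes are excluded rather than clipped, the
standard way to keep mass counts unbiased. For each radius R the skeleton
mass M(R) within Euclidean distance R is counted, and

    D_q = 1/(q-1) * slope of ln < (M(R)/M0)^(q-1) >  on  ln(R/L)

with M0 the total mass in the ROI and L the ROI diameter. The reported
measurement is q = 0, i.e. `-slope of ln<M0/M(R)>`; other q are available
for diagnostics. Radii default to a geometric ladder of up to 12 values from
4 px to `min(0.25 L, q90 of the boundary distance at skeleton pixels)`; the
second term makes thin regions (the clipped annulus, the midperiphery ring)
measurable at all — without it no center would be admissible there. Region
seeds are derived from the eye id and region name, so re-runs are
bit-identical. `boxcount_dimension()` is the deliberately independent
oracle: occupied-box counts over a dyadic ladder (default 4 px to
`min(dim)/16`), fitted on `ln N` vs `ln(1/eps)`.

**A known, documented divergence.** On the analytic fixtures the two
estimators agree within ±0.05 of each other and of the closed-form
dimensions. On vessel-tree skeletons they do not: a tree is curve-like below
the branch spacing and branching-structured above it, and the sandbox — with
centers confined to the deep interior by the exclusion rule — weights the
junction-rich hub, while box counting weights all occupied regions equally.
Across every scale window and ROI conditioning we tried, the sandbox reads
0.1–0.35 higher on trees. The acceptance suite asserts the ±0.05 agreement
anyway and reports the measured gap; treat the two numbers as related but
distinct summaries on non-self-similar structures.

### Vessel processing

Segmentation (when starting from images) is a classical multiscale Hessian
ridge filter for dark vessels with hysteresis thresholding — plumbing, not a
contribution; binary masks are accepted directly and the synthetic cohort is
measured from its ground-truth masks by default. The mask is thinned to a
one-pixel skeleton (Zhang–Suen), decomposed into a graph whose nodes are
8-connected clusters of junction pixels (Rutovitz crossing number ≥ 3) and
endpoints, with ordered pixel chains as edges; endpoint-terminated spurs
shorter than 0.3 mm are pruned and pass-through nodes re-merged. Width at a
centerline pixel is twice the Euclidean distance to the nearest background
pixel, times the scale, median-smoothed; when arteriole/venule labels are
available each edge is measured on its own class mask, so a vessel of the
other class running alongside cannot inflate the distance transform.

The "most prominent, unbroken" path per quadrant and class — a manual
operator choice in the source workflow — is operationalized as the
candidate root-to-distal chain maximizing arclength × mean width, with
candidates grown from disc-proximal nodes by width continuity across
junctions, refusing continuations that turn back toward the disc or jump
more than 15% in mean width (a prominence break, e.g. stepping onto a
crossing vessel). Ties break by mean width, then lowest starting pixel row,
then column, so selection is independent of edge enumeration order. An
override file can force the operator's choice.

### Width gradient

The WG is the slope (µm/mm) of an IRLS bisquare fit of width against
arclength, disc-proximal end at zero so negative slopes mean distal
thinning. Arclength is measured along a smoothed copy of the pixel chain:
raw 8-connected chains overstate length (staircase steps plus thinning
jitter) by 10–15%, which would shrink every slope by the same factor.
Before the fit the width profile is cleaned with steps that each answer a
specific raster artifact, all tunable in `path_metrics()`: a path-level
moving median (windows inside one edge cannot span junctions); trimming
0.2 mm at both ends (the distance transform collapses at stroke end-caps);
an asymmetric exclusion window around internal junctions (−0.15/+0.45 mm;
the inflation from a child branch running beside its parent extends mainly
downstream); and a plausibility gate keeping widths within [0.6, 1.25] of
the disc-proximal baseline caliber (sustained inflation where another
vessel runs adjacent; physiological taper only narrows a vessel). Paths
shorter than 2.5 mm yield no WG — their slopes are dominated by width
quantization. The bisquare tuning constant defaults to 8 rather than the
textbook 4.685: EDT widths move in quantized steps, and a tight constant
reads the steps as outliers and flattens genuine taper; 8 still zero-weights
crossing spikes several scales out. Huber weights are selectable, and
`MASS::rlm` serves as an independent cross-check in the tests.

### Tortuosity

The default measure is `tau = L * sum(kappa_i^2 ds_i)` on an
arclength-resampled, moving-average-smoothed path: dimensionless, zero for
straight segments, exactly `pi^2` for a semicircle of any radius, invariant
under rigid motion and scaling, and positively skewed across vessels — hence
the natural-log transform before the statistical stage (the log base is a
declared convention). Arc-over-chord minus one and total turning
`sum|kappa| ds` are available as variants for sensitivity analysis. The
tangent-chord spacing is `max(L/150, 16 px)` capped at `L/10`, with no
further coordinate smoothing by default: the `L/150` term keeps tau
scale-invariant on analytic paths (the semicircle check lands within 2% at
any radius), while the 16-pixel floor shrinks the angle noise from
centerline jitter quadratically without attenuating curvature at the
sinuosity wavelengths — a moving-average window wide enough to remove the
jitter was found to also shortcut genuine bends. Curvature contributions
within 0.25 mm of internal junctions are excluded from the integral (and
from L): chains kink where they thread junction clusters, and those kinks
measure the graph, not the vessel.

### Statistics

Per eye, the metrics row holds D0 per region, WG and tau per quadrant ×
class, and per-class "All" aggregates (arithmetic mean over available
quadrants). Missing cells stay missing until the imputation rule: per
outcome and group, means/SDs are computed on observed cells, cells more
than z = 3 group-SDs from the group mean are replaced by that
pre-imputation mean, missing cells likewise, and everything imputed is
flagged so sensitivity analyses can re-run without it. The threshold z is
configurable because "extreme" is not defined more precisely by the source.

Group contrasts are linear-link GEEs with participants as clusters and an
exchangeable working correlation, adjusted for age (years, uncentered) and
sex (binary indicator; the group coefficient is invariant to both codings).
The default fits one two-group model per contrast (AD vs NC, MCI vs NC,
AD vs MCI), mirroring how such results are tabulated; a joint three-level
model with NC reference is available, in which the AD–MCI coefficient is
exactly the difference of the other two. Standard errors are
**bias-corrected sandwich** estimates (Mancl–DeRouen: per-cluster residuals
inflated by `(I - H_i)^(-1)`) with a t(K−p) reference. The plain sandwich
covered an injected effect only ~91% of the time at 30 participants/group
in our simulations; with the correction, coverage sits at ~94% and type-I
error at ~0.05–0.06, which the acceptance suite verifies at 500 replicates.
With one observation per cluster and an independence working structure the
estimator reduces exactly to OLS. Demographics use Kruskal–Wallis (Dunn
post hocs with Šidák correction `1-(1-p)^m` when significant) and
chi-square tests for sex and laterality.

## The synthetic cohort: what it emulates and what it does not

The generator is a stochastic branching walk: arteriolar and venular arcades
alternate angularly around the disc (one of each per quadrant sector, as in
the real vasculature), grow outward holding their launch heading, and carry
a sinusoidal centerline perturbation. Along every root-to-tip path the true
width is `w(s) = w_root + taper * s`, with a multiplicative width step onto
side branches (child ≤ parent at the branch point); the trunk itself
continues un-stepped, so the selected prominent paths have exactly the
nominal taper. Side branches terminate after 2.2 mm (60% of that for deeper
generations) — real side branches leave the arcade toward the capillary bed
— which also keeps the canopy from exploding combinatorially. Root calibers
get 6% jitter: arcade calibers genuinely vary, and the jitter doubles as
dithering of the raster quantization, keeping cohort width statistics
unbiased. Branching density, taper and sinuosity are independently
controllable, which is what makes factorized parameter-recovery tests
possible.

A cohort draws, per participant, a shared random offset on each generative
parameter (both eyes) plus an independent per-eye offset — the shared
offset induces the exchangeable within-participant correlation the GEE
assumes. Defaults are the study conditions the package emulates: group
sizes 28/30/45 (AD/MCI/NC), taper offsets −0.7 (AD) and −0.6 (MCI) µm/mm
against NC with small opposite-signed branching/sinuosity offsets, ages
71.8/70.2/66.5 ± 6 years, and taper SDs of 0.35 (shared) + 0.35 (per eye),
chosen so the total per-eye WG spread lands near the ~0.7–0.8 µm/mm scale
such cohorts report. Rendering is 1200 px at 12 µm/px (a 14.4 mm field,
disc 1.0 mm at 1.6 mm offset, fovea 3.6 mm temporal, trees to 5.2 mm from
the disc) — a scaled-down posterior pole rather than a full 200° field.
Eyelid/eyelash occluders corrupt only the rendered image, never the truth
mask, motivating the manual ROIs.

What passing tests on this cohort do **not** show: photorealistic contrast
statistics, stereographic peripheral distortion, pathology, central reflex,
or the true population distribution of vessel counts and calibers on UWF
images — none of which are modeled. Parameter recovery here validates the
estimators' geometry and statistics, not their behavior under real-image
noise.

## Numerical choices and degenerate inputs

Problem sizes: analytic fixtures at 512 px; recovery checks at 8–12 eyes
per condition; GEE calibration at 200–500 replicates of 30
participants/group; end-to-end checks on 90-eye cohorts (15/group), of
which the suite runs two seeded repetitions. An empty mask yields an empty
graph (not an error); a region without skeleton yields a missing metric; an
eye failing any stage keeps its row with missing cells and a logged reason;
an empty standardized intersection warns; imputation is idempotent; the
IRLS fit returns the OLS solution when residual scale collapses (an exact
fit); tie-breaks in path selection and quadrant labeling are deterministic;
every generator and estimator is a pure function of its parameters and
seed, and metrics CSVs are byte-identical across re-runs.

## Known limitations

- WG recovery rests on caliber dithering across vessels; a cohort of
  identical-caliber vessels at an unfavorable stroke angle would sit on a
  distance-transform quantization plateau and bias per-path slopes toward
  zero (the per-path floor is roughly one EDT step over the path length).
- The sandbox/box-counting divergence on trees, discussed above.
- Tortuosity's absolute scale depends on the chord spacing; only ratios,
  orderings and log-scale contrasts are comparable across settings. On
  rasters, sinuosity with lateral amplitude below the vessel radius is
  partially erased before measurement — the union of stamped disks along a
  tight sinusoid is a nearly straight band, so the thinned centerline is
  genuinely straighter than the generative one. Recovery tests therefore
  use amplitude levels the raster can express.
- Automatic artery/vein classification is out of scope; class labels come
  from the generator's truth (or an annotation), as the source workflow
  also lacked a reliable automatic procedure.
- Agreement with the original proprietary measurement software cannot be
  tested without it; the package's estimators are validated against
  analytic oracles and generator truth instead.
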