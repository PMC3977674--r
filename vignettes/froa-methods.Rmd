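---
title: "Methods: shape-feature ROI models and the FROA/MMC statistic"
author: "froa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-feature ROI models and the FROA/MMC statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical decisions taken where the design
was genuinely open. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The question and the statistic

Observers fixating a shape may preferentially sample particular shape
features — concave regions of the bounding contour, convex regions, or
the internal boundaries between parts. The package quantifies such
preferences with *Fixation Region Overlap Analysis* (FROA):

1. retained fixations are dilated into a **fixation-region map** `F`
   (union of disks of radius `region_radius_deg`, default 1°, roughly
   the foveal extent, clipped to the frame);
2. the **observed overlap** with an ROI model `R` is
   `O = 100 |F ∩ R| / |F|` over pixels;
3. a **Monte-Carlo chance distribution** re-draws the same number of
   fixations i.i.d. from a null density, rebuilds the region map each
   time, and records its overlap; `C95` is the 95th percentile
   (type-7 linear interpolation) of that distribution;
4. the **model matching correspondence** is `MMC = O − C95`
   (percentage points). `MMC > 0` means overlap above the one-sided
   95% chance bound.

Open choices and how they were fixed:

* **Sidedness.** The chance bound is operationalised as the one-sided
  95th percentile, because a negative MMC is interpreted as overlap
  *below the amount expected at the 95% bound* — a single bound. A
  two-sided variant (97.5th percentile) is exposed via `ci =
  "two_sided"`.
* **Area vs count.** Overlap is pixel-area based ("fixation regions"),
  not fixation-count based. Setting `region_radius_deg = 0` reduces
  each fixation to its pixel, which is the (deduplicated) count-based
  analogue.
* **Null density.** Defaults to uniform over the object silhouette,
  which controls object-versus-background bias; uniform over the frame
  and arbitrary density matrices (e.g. the saliency map below) are
  accepted anywhere a null is needed. Null draws land on pixel
  centres, matching how observed fixation maps are rasterised.
* **Aggregation.** Per participant, MMC is computed per stimulus (with
  the fixation count matched per stimulus in the null) and then
  averaged over stimuli. Chance distributions are shared across the
  ROI models of one stimulus (same draws scored against each model),
  and cached per stimulus × fixation count.
* **Iterations.** Default `n_iterations = 1000`; the package refuses
  fewer than 100.

The defining calibration property — under data drawn from the null
itself, `P(MMC > 0)` equals the nominal exceedance level of the
interpolated 95th percentile (≈ 0.05) — is verified by the test suite on
a 200 × 200 px grid with 15 point-like fixations of 0.3° radius, 1000
Monte-Carlo iterations per replicate and 1000 replicates. The modest
radius keeps the overlap statistic effectively continuous (heavily tied
overlap values would make the exceedance rate lattice-bound).

## Curvature-polarity ROI models

The bounding contour is extracted from the binary mask as the iso-level
curve of the mask blurred with a Gaussian of 0.6 px, at the level a
blurred straight edge attains half a pixel inside its boundary — so
straight runs are traced through boundary pixel centres with subpixel
interpolation elsewhere. The curve is resampled to uniform ~1 px
arc-length spacing and canonically oriented (interior on the left in a
y-up frame), after which signed curvature is

κ = (x′y″ − y′x″) / (x′² + y′²)^{3/2},

from periodic central differences of Gaussian-smoothed coordinates,
with κ > 0 convex. For a disc of radius r this reads +1/r.

**Why the smoothing scale adapts.** A contour traced from a binary mask
carries a digitisation band of about half a pixel. Two arcs whose
curvatures differ by δκ diverge by only δκ·L²/8 over a window of length
L, so curvature differences below ≈ 8·band/L² are invisible at window
L: resolving κ = 0.01 px⁻¹ to 10% requires an effective window near 90
px no matter the estimator. A single small smoothing scale therefore
cannot both localise sharp junction corners and read shallow arcs
accurately. `computeCurvature` uses a scale ladder starting at
`smoothing_sigma` (default 5 samples; ratio 1.6, five rungs, capped at
an eighth of the contour length): each sample reports the smallest
scale whose measured |κ| clears that scale's noise floor (2/σ²). Sharp
corners — strong |κ| — keep base-scale localisation; broad arcs
escalate until their curvature is resolvable. A fixed-scale mode
(`adaptive = FALSE`) remains available.

Polarity masks stamp a filled disk at every contour sample with
|κ| ≥ `kappa_min`, radius

r = r_min + (r_max − r_min) · min(|κ| / kappa_sat, 1),

into the mask matching sign(κ). The radius law is "proportionally
sized" with saturation; the constants are not dictated by theory and
are all config-exposed. Defaults on an 800 px frame: disks 2–20 px,
`kappa_min` 0.005 px⁻¹ (curvature radius 200 px: gentler boundary is
treated as straight), `kappa_sat` 0.1 px⁻¹ (a corner sharper than a
10 px curvature radius earns the full disk). The concave and convex
masks are built independently and may overlap; they are reported
separately.

## Part boundaries: minima/short-cut rule

Concavity extrema are local minima of κ with κ < 0 whose topographic
prominence (computed on the circular curvature profile) exceeds
`prominence` (default 0.005 px⁻¹). Because the multi-scale κ map
spreads a sharp corner into a basin with shallow flanking minima, a
non-maximum-suppression window (`minSeparation`, default 25 samples)
keeps only the deepest minimum in any neighbourhood.

Cuts pair extrema with straight chords under three conditions: the
chord lies entirely inside the silhouette (sampled at 0.5 px along its
open interior), the chord is shorter than both contour arcs it
separates (the short-cut condition), and each extremum is used at most
once. Admissible chords are accepted greedily in order of increasing
length, ties broken by lower contour index — the rule as usually stated
admits other tie-breaks; shortest-first is the canonical reading. The
part-boundary ROI is the union of rectangular bands of half-width
`band_px` (default 10 px ≈ 0.22°) around the accepted cuts, clipped to
the silhouette.

## Viewing geometry and scanpath metrics

The standard frame is 800 px subtending 18° (44.4 px/°). A single
linear px↔degree factor is used; at this field size the tangent
correction is under 2%, smaller than measurement noise. Preprocessing
discards the first fixation of every trial (it reflects the pre-trial
fixation cross, and the synthetic generator pins it to the frame centre
so the rule has a deterministic effect), drops out-of-frame fixations
(they cannot overlap any ROI and would bias the null if clamped), and
flags trials left empty. Saccade amplitudes are Euclidean distances
between consecutive retained fixations within a trial — never across
trials — converted to degrees; dwell time is the per-participant mean
fixation duration.

## Group-level inference

MMC tables go into a balanced split-plot ANOVA (between: task group;
within: ROI model), decomposed with the group effect tested against
subjects-within-groups and the within effects against model ×
subjects-within-groups; partial η² = SS_effect / (SS_effect +
SS_error-of-stratum). Unbalanced or incomplete input is an error — no
silent sums-of-squares choice. No sphericity correction is applied by
default (three within levels, planned contrasts); Greenhouse–Geisser
is available. Zero-variance conventions: a zero-SS effect reports F = 0,
p = 1; a positive effect over a zero error stratum reports F = ∞, p = 0.
Planned comparisons are paired t-tests within groups and independent
t-tests between groups (two-sided, uncorrected by default, Bonferroni
optional), with degenerate constant-difference inputs flagged rather
than mangled. Accuracy scores use an exact-permutation Mann–Whitney U
when both groups have n ≤ 12 and no ties, and the normal approximation
otherwise. Degrees of freedom are always computed from the data
provided.

## The synthetic generators

`generateShape` builds silhouettes as unions of overlapping convex
primitives (ellipses, capsules, rectangles) in chains; the ground-truth
junction chord of each adjacent pair is the segment joining the two
boundary-intersection points, found by walking one boundary and
bisecting the inside/outside transitions of the other. Six built-in
families (2–4 parts) emulate object classes defined by part structure,
with within-family metric variants produced by log-uniform size jitter
(factors confined to (0.5, 2)). Assembly retries on disconnection,
frame escape, or junctions that are not clean two-point crossings, and
fails loudly rather than returning a defective mask. Convex-part unions
put junction concavities exactly where the minima rule predicts cuts,
which is what makes the recovery testable; the generator does not
attempt rendered 3D objects, surface shading, or holes.

`generateScanpath` has two location models. The mixture model places
each non-initial fixation uniformly in the target ROI with probability
π and otherwise samples the null density — so the expected ROI hit rate
is π + (1 − π)·(ROI share under the null), the closed form the tests
check. The step model is a random walk with gamma step lengths
(mean `step_mean` degrees, shape `step_shape`) and uniform directions,
resampling directions that would leave the frame (projection toward the
centre as a last resort), which preserves the step-length distribution
up to boundary effects of order 1%. Durations are always gamma
(mean 198 ms, shape 18 by default, giving the ~46 ms spread typical of
object viewing).

For two-group amplitude experiments the reported group means and SDs
are interpreted as moments of the *saccade-level* amplitude
distribution (shape = (M/SD)²), with an optional participant-level
normal jitter of the mean (`participantSdDeg`, default 0.6° in the
demo designs). That decomposition was chosen because a between-group
t-statistic near 5 with 12 participants per group implies a
between-participant dispersion near 0.65° — far smaller than the
saccade-level SDs — so the saccade-level reading is the only one
consistent with the inferential statistics the design mirrors. A
consequence worth keeping in mind: the realised group mean of 12
jittered participants has an SE of ~0.17°, so individual synthetic
studies legitimately land a few tenths of a degree off the commanded
means.

Every dataset flows from one master seed through per-stream derived
seeds (stimuli, participants, trials, Monte-Carlo draws), so whole
experiments are bit-reproducible and independent of evaluation order.

## Saliency stand-in

`saliencyMap` is a deliberately lightweight conspicuity map: multiscale
centre-surround intensity contrast (difference of Gaussians, surround
at twice the centre scale) plus gradient orientation energy at four
orientations, channel-normalised, combined, and mixed with a 5% uniform
floor so the density has full support (a Monte-Carlo null with
zero-mass regions would make overlap there formally impossible). It is
a pluggable baseline, not a reimplementation of any published saliency
model; any user-supplied density matrix of matching size is accepted in
its place.

## Problem sizes used by the checks

The test suite and acceptance script run at deliberately modest scales,
chosen as the smallest sizes at which the statistical properties are
sharp: curvature calibration on a 256 px disc of radius 100; part-cut
recovery over 50 shapes (families cycled, 12% metric jitter); null
calibration at 1000 replicates × 1000 iterations on a 200 × 200 grid
(500 replicates in the acceptance script); a π sweep over
{0, 0.25, 0.5, 0.75, 1} with 4 participants × 2 stimuli × 3 trials and
300 Monte-Carlo iterations; the demo pipeline with 2 × 6 participants,
3 stimuli, 4 trials and 300 iterations; and the amplitude power check
over 100 replicates of a 12 + 12 participant design.

## Known limitations

* Operates on 2D silhouettes; no 3D surface curvature, self-occlusion
  or shading cues.
* Curvature below the digitisation resolution of a window is reported
  at a coarser scale, not recovered; absolute κ on near-straight
  boundary is only bounded, not measured.
* No raw gaze-sample event detection (fixation parsing, blinks,
  binocular fusion) — input is already-parsed fixation tables.
* The ANOVA path requires balanced complete designs by construction.
* The saliency stand-in is a baseline density, not a validated model of
  human salience.
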