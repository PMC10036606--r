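---
title: "Models and methods: quantifying T-cell close contacts in TIRF microscopy"
author: "closecontacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying T-cell close contacts in TIRF microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

T cells survey antigen-presenting surfaces through microvilli. Where a
microvillus displaces the glycocalyx, the two membranes approach within
the reach of a T-cell receptor, forming a *close contact* of a few
hundred nanometres. On a supported lipid bilayer carrying fluorescent
glycocalyx proteins, close contacts are visible under total internal
reflection fluorescence (TIRF) microscopy as dark, sub-diffraction holes
in a bright uniform background, while a genetically encoded calcium
indicator reports receptor triggering in a second channel and a membrane
dye shows the cell footprint in a third.

Quantifying these data requires (i) segmenting objects at or below the
diffraction limit in noisy EMCCD images, (ii) tracking cells and their
calcium responses, (iii) converting label maps into per-contact and
per-cell features, and (iv) supporting statistics (survival curves for
stage transitions, dose-response fits, molecular densities from
fluorescence correlation spectroscopy). Because segmentation performance
at this scale cannot be judged by eye, the package includes a
first-class synthetic-video generator whose ground truth is known
exactly; every stage of the pipeline is tested against it.

## The synthetic scene and renderer

A `GroundTruthScene` specifies a physical field (um), a uniform
glycocalyx background (100 arbitrary units by convention), circular
contacts (centre, diameter, exclusion depth in [0, 1], birth and death
times), cell footprints with calcium traces, and point emitters. The
renderer rasterises the scene at a fine sub-pixel resolution (default
10.7 nm, one tenth of a camera pixel), blurs with an isotropic Gaussian
PSF (sigma = 131 nm, a bead-calibrated value for a NA 1.49 TIRF
objective) and mean-bins to the 107 nm camera grid.

Numerical choices:

* **Sub-pixel resolution.** The idealised ground truth lives on an
  arbitrarily fine grid; 10.7 nm (an exact tenth of the camera pixel so
  binning is an integer mean) reproduces an independent dense-convolution
  oracle of the blurred disc profile to better than 1% at the central
  pixel, at a small fraction of the cost of a 1 nm grid. The oracle in
  the test suite evaluates the radial convolution integral of a Gaussian
  with a disc by quadrature (a Rice-distribution integral), a completely
  different numerical route from the renderer's separable blur.
* **Boundary handling.** The blur operator is a doubly stochastic matrix
  built with whole-sample reflection, so constant fields pass through
  exactly and total intensity is conserved to machine precision - no
  dark rims on small fields.
* **EMCCD model.** The chain is Poisson photon shot noise, then
  Gamma-distributed electron multiplication (shape = photon count,
  scale = gain), then Gaussian read noise plus a fixed offset. This is
  the standard published EMCCD cascade; its defining property, an
  excess-noise factor of 2 (`Var = 2*gain^2*mu + readNoise^2`), is
  verified by a photon-transfer-curve test. Defaults: gain 250
  ADU/photoelectron, read noise 20 ADU, offset 100 ADU, QE 0.9.
* **Brightness.** Real acquisitions set exposure so the bright
  glycocalyx channel uses the camera's dynamic range. The generator maps
  scene intensity to photons with `photonScale` (default 2.5), so the
  100 a.u. background becomes ~225 photoelectrons/pixel/frame, i.e.
  ~56,000 ADU at gain 250 - near-full 16-bit range. This is the
  simulation's operating point; sensitivity results below are quoted at
  it.

The generator does **not** model TIRF evanescent-depth effects, optical
aberrations, or photobleaching; discs are perfectly circular and the
background perfectly uniform. Passing tests therefore demonstrate
correctness of the measurement chain under idealised optics, not
robustness to bilayer defects or uneven illumination (flat-field
correction is tested separately with synthetic vignetting).

## Close-contact segmentation

The glycocalyx stack is flat-field corrected, smoothed with a temporal
running mean (5 frames) and a spatial Gaussian, and a discrete Laplacian
is applied - a Laplacian-of-Gaussian (LoG) filter overall, positive
inside dark holes. Thresholds are expressed in units of the SD of the
filtered image computed over pixels *outside* segmented cell areas
("notCZ"), recomputed per frame so drifting illumination cannot bias
them. Two detectors are combined:

1. **Hysteresis on the LoG volume.** Weak (`h_low` = 3 SD) components,
   connected 8-wise in-plane and by temporal overlap across frames, are
   kept if they contain at least one strong (`h_high` = 5.5 SD) voxel
   anywhere in their lifetime. Applying hysteresis over the whole
   (t, y, x) stack rather than frame by frame is what makes
   sub-diffraction detection possible at realistic noise: a persistent
   contact needs only one high-confidence voxel over its lifetime,
   whereas transient noise blobs (which the temporal running mean
   stretches over ~5 frames) essentially never produce one.
2. **Late-contact threshold.** Large, fully formed contacts have flat
   dark interiors with little LoG response, so the edge-enhanced image
   (Gaussian + LoG) is additionally thresholded at `mean - h2*SD`
   (`h2` = 3) and eroded (disc radius 2 px).

Components smaller than `min_contact_area_px` (4 px) are removed;
remaining detections are labelled in 3-d with the temporal-overlap rule
("tracked" contacts share a label) and each contact is assigned to the
cell label it overlaps most. With restriction enabled, contact voxels
outside the owning cell's mask are discarded.

The thresholds are user-set by design; the defaults above were
calibrated once on rendered fixtures to meet two simultaneous targets -
zero false-positive contacts on contact-free noise videos and majority
detection of 250 nm contacts at 40% exclusion - and are exposed in
`segmentationConfig()`. The spatial Gaussian (sigma = 2 px) roughly
matches the PSF-blurred width of a sub-diffraction hole, which is what
an optimal linear detector would use. Determinism: ties in all labelling
steps resolve to the lowest label, so segmenting the same video twice
gives identical output.

The smallest reportable contact is one camera pixel
(`minContactArea(107)` = 0.011 um^2); reported areas are pixel counts
times pixel area, with no sub-pixel edge localisation. Diffraction makes
small contacts appear larger and less excluded than their ground truth;
the sensitivity sweep in `scripts/acceptance.R` quantifies the resulting
detection limit (majority detection of 250 nm contacts from 40%
exclusion at the default operating point, with the full
detection-versus-depth curve printed as it runs).

## Cell footprints and the spatiotemporal watershed

The membrane channel first loses its linearly increasing background
(dye binding to the bilayer): each frame's background level is estimated
from its dimmest 20% of pixels, a line is fitted over frames and the
fitted increase subtracted. Frames are then DoG-filtered and thresholded
by the union of a custom global threshold and a per-frame Otsu
threshold. Because Otsu assumes bimodality and would split pure noise,
it is floored at median + 5 sigma, with sigma estimated from the
temporal frame difference (static structure cancels there); this keeps
cell-free frames empty without a hand-set threshold. Components below
`min_cell_area` (20 um^2 by default; small fixtures use less) are
removed.

Cell labels are grown through the 3-d (t, y, x) mask from seeds detected
on the last frame (local maxima of the large-sigma DoG, thinned to a
minimum separation of one cell radius, optionally overridden from a seed
table) - adhered cells overlap frame-to-frame, so a label propagates
back through the cell's whole history. Mask components unreachable from
any seed are attached to the nearest labelled voxel within twice the
cell radius in (x, y, t), else dropped.

## Calcium traces, triggering and populations

The trigger rule operates on the baseline-normalised trace: baseline =
mean of the lowest decile of intensities in the first 60 s of the track
(deterministic reading of "lowest 10%, typically from the first
30-60 s"), trigger = first sustained rise to >= 3x baseline lasting
>= 10 s, measured by default on a 3-sample running mean (a flag switches
to the raw trace; the smoothed reading can delay the reported onset by
one sample). Cells triggering within 40 s of track start are flagged as
settling artefacts and excluded from population denominators.

Population curves are cumulative fractions of all cells versus time.
Following the constraint that signalling saturates at ~80% of cells
(adhesion at 100%), curves are fitted with the lower asymptote fixed at
0 and the upper fixed at the plateau. The exact sigmoid family is not
prescribed by the underlying methodology, so two natural families are
fitted - a logistic in time and a delayed saturating exponential (the
shape produced by Poisson-like triggering after settling) - and the one
with the smaller residual sum of squares supplies the time at which 50%
of all cells have responded; degenerate inputs fall back to the
empirical crossing. A pure logistic alone misestimates exponential-like
cohorts by ~15-20%, which is why the second family exists.

## Features, events and stages

`exclusion_10 = 1 - perc10(I_inside) / mean(I_outside)` uses the 10th
percentile of flat-field-corrected intensities inside the contact
(percentile convention: linear interpolation between order statistics,
R type 7, pinned for reproducibility) over the mean on the 1-px outline
of the owning cell's membrane mask. The separate CD45-exclusion analysis
uses the same formula with the dilated ring regions instead of the cell
outline; both region conventions are implemented
(`contactFeatures` vs `buildRegionPairs` + `cd45Exclusion`).

Per-cell events anchor the four interaction stages - searching (first
membrane signal), scanning (first close contact), spreading (calcium
trigger), synapsing (maximum footprint, from a 5-frame mean-filtered
area trace) - assigned to frames with half-open `[event, next_event)`
intervals; stages III/IV require a trigger, and out-of-order events are
clipped with a warning. The edge QC rule excludes cells touching the
field border before triggering (or, for non-triggering cells, within
300 s of their first contact - the window is configurable since only
"a given time period" is specified). The calcium measurement circle
radius defaults to 5 um (a circle of unspecified size in the source
methodology).

## Enrichment, CD45 exclusion and ligand counting

Inside regions are the contact masks; outside regions are 10-px dilated
rings minus every contact's inside, restricted to the cell mask when the
protein of interest is cell-borne (avoiding fake depletion at the
membrane edge). Enrichment is `mean(inside)/mean(outside)`.

Single bound ligands are counted after a 5-frame temporal running mean
("rolling-ball average" read as a running mean; the radius is
configurable) and a 1-px Gaussian blur. The detection threshold is the
smallest value at which fewer than 2 local maxima appear in a pre-cell
stack - since that stack contains only *unbound, diffusing* molecules,
whose long-exposure motion blur spreads their photons, the calibrated
threshold naturally sits above the diffuser level and below the sharp
peaks of immobile (bound) molecules. Local maxima are 8-connected with
plateaus collapsed to centroids; the signalling timepoint is the
central-difference gradient maximum of the smoothed calcium trace. The
simulator approximates motion blur by averaging 10 sub-frame emitter
positions per exposure; no claim is made that this matches the real
optical blur in detail.

## Statistical models

* **Kaplan-Meier / log-rank** delegate to the survival package
  (`conf.type = "log-log"` is the exponential Greenwood interval); the
  test suite checks them against a hand-rolled product-limit computation
  and a permutation oracle built on an independently coded
  observed-minus-expected statistic.
* **Dose-response**: 4PL
  `response = bottom + (top - bottom)/(1 + (EC50/dose)^hill)` fitted by
  unweighted least squares on log10 dose; either asymptote can be fixed
  (e.g. bottom pinned to the null-ligand response) and is then honoured
  exactly; zero-dose points evaluate to the bottom asymptote.
* **FCS**: `G(tau) = G0*GD(tau)*GT(tau) + Off` with the 2-d diffusion
  form `GD = 1/(1 + tau/tauD)` for membrane measurements (3-d form
  available for solution calibration) and an optional triplet term.
  `N = 1/G0`, `d = sqrt(8 ln2 D tauD)` with a literature diffusion
  coefficient supplied by the caller (it is a config input, not a
  constant), density = `N / (pi (d/2)^2)`.
* **Standard curves**: least-squares slope through the origin of density
  versus concentration, used to extrapolate densities below the ~1
  molecule/um^2 FCS floor.
* **Surface area**: per z-slice, the largest thresholded component is
  hole-filled and its outer contour measured with the
  Vossepoel-Smeulders corrected chain length (0.980 per axial step,
  1.406 per diagonal, -0.091 per corner); plain 1/sqrt(2) chain length
  overestimates smooth contours by ~5%, the corrected weights are
  accurate to ~1% on digitised circles. Summing perimeter x slice depth
  is exact for prismatic shapes (a digitised cylinder reproduces
  2*pi*r*h to ~1%) but systematically underestimates sloped surfaces:
  for a sphere the procedure converges to pi^2*r^2, 21.5% below
  4*pi*r^2, because the slice perimeter ignores the surface tilt. The
  tests pin this documented bias.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
30-80 px fields, 6-15 frame stacks, 20 noise realisations per condition
in the sensitivity sweep, 100-trace trigger cohorts, n = 200 population
cohorts and 2000-4000-draw permutation oracles - sizes at which every
result is stable under the fixed seeds yet the full suite completes in
about a minute. All stochastic steps accept explicit seeds and restore
the caller's RNG state; relabelling and watershed ties resolve to the
lowest label, so repeated runs are bit-identical.

## Known limitations

* Reported contact areas are pixel-based and diffraction-inflated; no
  sub-pixel edge model is attempted.
* The simulator's idealised optics (pure Gaussian PSF, uniform
  background, no bleaching) bound what the validation can claim about
  real data.
* Contact genealogy is temporal overlap only - splits and merges are not
  resolved into lineages.
* The sigmoid families for population curves and the EMCCD cascade are
  documented choices where the underlying methodology names only the
  construct, not the form.
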