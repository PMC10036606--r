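# closecontacts

Quantitative image analysis of the small, microvillus-scale "close
contacts" that T cells form when they engage an antigen-presenting
surface through a glycocalyx. On a supported lipid bilayer carrying a
fluorescent glycocalyx (CD43/CD45 ectodomains), a close contact appears
in TIRF microscopy as a sub-micron dark hole in an otherwise uniform
fluorescent background; T-cell receptor triggering is read out in
parallel as calcium release. This package provides the full measurement
chain for such experiments, plus a synthetic-video generator so every
stage can be validated against known ground truth without any raw data.

It is written for microscopists and quantitative immunologists analysing
multi-channel TIRF time lapses (membrane / glycocalyx / calcium
channels), and for anyone who needs a tested, reusable implementation of
the underlying algorithms.

## What it computes

**Synthetic TIRFM videos** (`simulateVideo`): a ground-truth field with
uniform background intensity 100 and circular exclusion discs of chosen
diameter and depth is rasterised at sub-pixel resolution, convolved with
a Gaussian PSF (sigma = 131 nm), mean-binned to 107 nm camera pixels and
passed through an EMCCD noise model (Poisson shot noise, Gamma-distributed
electron multiplication with excess-noise factor 2, Gaussian read noise):
for expectation mu photoelectrons the output has mean `gain*mu + offset`
and variance `2*gain^2*mu + readNoise^2`.

**Close-contact segmentation** (`segmentCloseContacts`): temporal
running mean, spatial Gaussian, Laplacian (a LoG filter overall), then a
hysteresis threshold at `h_low`/`h_high` SD of the filtered image
outside cell areas, combined with a late-contact threshold
`mean - h2*SD` on the edge-enhanced image, small-component removal, and
labelling of contacts by temporal overlap with assignment to owning
cells. Cell footprints are segmented by DoG + Otsu/global thresholds and
labelled with a spatiotemporal (x, y, t) watershed
(`segmentMembrane`, `labelCells`).

**Calcium analysis** (`trackCells`, `detectTrigger`,
`summarizePopulation`): nearest-neighbour tracking of hundreds of cells,
adhesion when speed stays below 0.2 um/s, triggering when the
baseline-normalised trace rises 3-fold for at least 10 s (responses in
the first 40 s are excluded as settling artefacts), and population
curves with constrained fits giving the time to 50% signalling/adhesion.

**Contact features and events** (`contactFeatures`, `detectEvents`,
`assignStages`): per-contact area (pixel count x pixel area), glycocalyx
exclusion `exclusion_10 = 1 - perc10(I_inside)/mean(I_outside)`,
accumulated contact time, and the four interaction stages (searching,
scanning, spreading, synapsing) anchored on five per-cell event times.

**Local metrics** (`enrichment`, `cd45Exclusion`,
`countBoundMolecules`): protein enrichment/exclusion in dilated
inside/outside region pairs around each contact, and single bound-ligand
counting with a threshold calibrated so that fewer than 2 molecules are
detected in a pre-cell stack (diffusing molecules are motion-blurred
below threshold).

**Statistics** (`kmEstimate`, `logrankTest`, `fitDoseResponse`,
`fcsDensity`, `standardCurve`, `surfaceAreaFromZstack`): Kaplan-Meier
stage-transition curves with exponential Greenwood intervals and
log-rank comparison; constrained four-parameter logistic dose-response
fits; FCS density via `G(tau) = G0*GD(tau)*GT(tau) + Off`,
`d = sqrt(8 ln2 D tauD)`, `N = 1/G0`, density `N / (pi (d/2)^2)`;
density-versus-concentration standard curves through the origin; and
cell surface area as the sum of slice perimeter x slice depth over a
membrane z-stack.

## Worked example

Simulate a 400 nm contact with 60% glycocalyx exclusion, segment it and
measure its features:

```r
library(closecontacts)

scene <- groundTruthScene(
    fieldSize = c(3.21, 3.21),            # um
    contacts  = contactTruth(1.605, 1.605, diameter = 0.4,
                             exclusion_depth = 0.6),
    nFrames   = 10)
vid <- simulateVideo(scene, seed = 1)
vid$glycocalyx
#> TirfVideo [glycocalyx]: 10 frame(s), 30 x 30 px @ 107 nm, dt = 1 s
#>   intensity range: [28830, 78800]

contacts <- segmentCloseContacts(vid$glycocalyx, restrict = FALSE)
contacts
#> LabelVolume [close_contact]: 10 frame(s), 30 x 30 px, 1 label(s)

cellArr <- array(0L, c(10, 30, 30)); cellArr[, 4:27, 4:27] <- 1L
cells <- LabelVolume(cellArr, "cell", 107, 1)
contacts@owners <- c("1" = 1L)
rec <- contactFeatures(contacts, vid$glycocalyx, cells)
round(colMeans(rec[, c("area_um2", "exclusion_10")]), 3)
#>     area_um2 exclusion_10
#>        0.203        0.403

minContactArea(107)
#> [1] 0.011449
```

The contact is found in every frame. Its reported area (0.20 um^2)
exceeds the true disc area (0.13 um^2) because diffraction spreads the
dark hole over neighbouring pixels, and the measured exclusion (0.40) is
below the ground-truth depth (0.6) because the PSF partially fills the
hole back in -- both effects are expected at this size and are why the
resolution floor (one 107 nm pixel, 0.011 um^2) matters when interpreting
small contacts.

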