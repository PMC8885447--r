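---
title: "Profiling protein-inclusion phenotypes from two-channel plate images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protein-inclusion phenotypes from two-channel plate images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inclusionprofiler)
library(dplyr)
```

## The problem

Cells transfected with a GFP-tagged aggregation-prone protein (the
motivating system is mutant SOD1-EGFP in NSC-34 motor-neuron-like cells)
show two phenotypes: diffuse cytoplasmic fluorescence, or bright compact
inclusions superimposed on the diffuse signal. The fraction of
transfected cells bearing inclusions is the screening readout: it
differs strongly between wild-type and ALS-associated mutants and
responds to small-molecule treatment. Counting those cells by eye does
not scale to checkerboard drug-combination plates, so the package
implements an automated chain:

1. **Illumination correction** per channel across an imaging session.
2. **Segmentation** of transfected cells from nuclear seeds, gated to
   equivalent diameters of 17--50 px.
3. **Cytoprofiles**: per-cell intensity, size/shape, Haralick texture,
   granulometry and radial-distribution features.
4. **User-assisted random-forest classification** into inclusion /
   no-inclusion bins, with a review protocol that measures accuracy as a
   function of training effort.
5. **Per-well enumeration** of the percentage of cells with inclusions.
6. Downstream analytics: **HSA checkerboard synergy**, **relative
   survival with trapezoid AUC**, and **4PL dose--response fits**.

Because no imaging data ship with the package, a **simulator**
(`scene_spec()`, `generate_field()`, `generate_plate()`) renders
ground-truthed synthetic plates; every stage is validated against the
truth it emits.

## The simulator and what it does (not) emulate

`generate_field()` renders cells as smoothed random ellipses with
elliptical nuclei; inclusion-phenotype cells receive 1--4 2-D Gaussian
puncta whose peak sits at `puncta_contrast` (default 3) times the cell's
diffuse level. Puncta centres are drawn from the cell interior at least
one punctum radius from the rim, matching the intracellular nature of
inclusion bodies and keeping the rendered contrast exact. Diffuse
expression is lognormal (`meanlog = log(8000)`, `sdlog = 0.35` camera
units), emulating the wide expression range of transient transfection. A
radial Gaussian vignette (depth 0.25 of full illumination, scale 0.8 of
the short image side) is applied multiplicatively, then Poisson shot
noise (gain 0.5) and Gaussian read noise (sd 60), then saturation at the
16-bit ceiling. Defaults place 40 cells of diameter 30 ± 6 px in a
512 × 512 field: the diameter distribution deliberately straddles the
17--50 px analysis gate so the gate is exercised from both sides.

These choices make the two phenotypes *cleanly* discriminable: real
micrographs add debris, apoptotic blebs, focus drift, and cells whose
inclusions sit atop very dim diffuse signal. Passing the synthetic bars
therefore demonstrates that the chain is implemented correctly and is
internally consistent — not that the same accuracy would be reached on
any particular microscope's data. Photorealism, 3-D stacks and
brightfield autofocus artefacts are out of scope.

Determinism contract: one integer seed per scene or plate; identical
seeds give bit-identical images. A plate derives one sub-seed per field
from its master seed, so fields are reproducible but uncorrelated.

## Illumination correction

`estimate_illumination()` averages the fields of a session pixelwise
(mean by default; median by flag for robustness to sparse bright
objects) and smooths with a wide Gaussian. The "500 pixel" smoothing
scale is interpreted as an artifact *diameter* (FWHM), the convention of
high-content tools for that phrase, giving `sigma = scale / 2.355`; the
scale is a parameter because the sigma-vs-width convention is not
universal. Correction is subtractive with a minimum-preserving offset:
`corrected = max(image - surface + min(surface), 0)`. Pure subtraction
of a background estimate can null genuine signal in dim images; the
offset removes the spatial trend while preserving the dimmest region's
level, and the clamp guarantees nonnegative intensities. The simulator
applies its bias multiplicatively (vignetting physics); at the smoothing
scales involved, subtractive correction of a multiplicative bias agrees
to first order, and the residual is what the segmentation-recall bar
absorbs. One scale caveat: Gaussian smoothing at a scale comparable to
the illumination variation itself attenuates the estimated amplitude
(convolving a Gaussian bias of scale `s_b` with a smoothing Gaussian of
sigma `s` shrinks its peak by `s_b^2 / (s_b^2 + s^2)`), leaving a
residual trend after correction. Choose the smoothing scale well below
the scale on which illumination varies and above the scale of cells —
on a 512 px simulated field with a 205 px vignette, a 60--100 px scale
corrects to near-idempotence while 300 px leaves a visible residual.

## Segmentation

Nuclei: Otsu threshold after a 2 px Gaussian presmooth, then watershed
on the distance transform to split touching nuclei. Cells: the
GFP-positive mask is thresholded with a **three-class Otsu**, keeping
the lower split. A two-class Otsu fails here for a structural reason:
transfected-cell brightness is heavy-tailed (lognormal), so the bimodal
criterion places its threshold *inside* the foreground range and drops
dim transfected cells wholesale. The three-class variant models
background / dim cells / bright cells and its lower threshold tracks
the background--foreground boundary. Cell regions grow from nuclear
seeds (`propagate`); a GFP-only mode (no nuclear stain, used for
live-cell counting) falls back to watershed splitting. Objects outside
the 17--50 px equivalent-diameter gate are discarded (hard assertion),
as are border-touching objects — tile scans are acquired without
overlap, so border objects are truncated and would double-count.
"17 to 50 pixel units" is read as typical object diameter, the source
convention for that phrasing; both bounds are parameters.

Coordinates are 0-based with x = column, y = row; bounding boxes are
half-open. Focus QC (`qc_focus()`) reports a normalised
variance-of-Laplacian score and never drops images itself.

## Cytoprofiles

The exact feature menus are fixed choices where only the families are
prescribed: 13 Haralick co-occurrence statistics at offsets {3, 8} px
(angle-averaged, via EBImage), a 16-element granulometry spectrum (disk
openings of radius 1--16 px on the masked cell, background set to the
cell minimum, entries are fractions of above-baseline intensity removed
per scale; the patch is lightly denoised first — Gaussian sigma 0.75,
well under the ~5 px punctum width — because single-pixel shot noise
otherwise contributes small-scale mass that mimics puncta in small
cells), and a 4-bin radial intensity distribution (fraction,
mean-fraction and 8-wedge CV per bin, bin 1 innermost). They mirror
common high-content defaults and are arguments of `compute_profiles()`.
EBImage's grayscale morphology operates on [0, 1] images, so the
granulometry patch is rescaled by its maximum — the spectrum is
ratio-based and unaffected. Undefined ratios on degenerate patches
(e.g. texture correlation of a constant cell) are coerced to 0 so all
features are finite; masks under 9 px are rejected outright.

Normalisation is per-batch z-scoring (`normalize_profiles()`; a robust
variant was considered and left out — the z-score is the simplest
reading and random forests are insensitive to monotone scaling anyway).
Zero-variance features are dropped with a warning. The classifier
stores its training batch's statistics and re-applies them at scoring
time (`apply_normalization()`): re-standardising each scored plate
would shift features between plates of different composition and make
calls depend on what else was on the plate.

## Classification and the review protocol

`train_inclusion_classifier()` fits a seeded 100-tree random forest
with sqrt-features per split — the algorithm family is prescribed, the
hyperparameters are the field's defaults. Ties at the 0.5 probability
threshold resolve to *no inclusion*: conservative for a readout that is
a prevalence. The "user" is an oracle interface: tests and the
simulator supply truth labels programmatically; an interactive reviewer
can supply them the same way. `review_protocol()` reproduces the
training-review loop: at each training size it draws `batch = 100`
cells *predicted* as each bin, scores them against the oracle, repeats
three times, and stops at a mean inclusion-bin accuracy of 0.97. This
per-bin (precision-like) accuracy is what a reviewer inspecting
requested cells actually measures; held-out per-class recall is
reported alongside in the `"recall"` attribute because the two can
differ.

`summarize_wells()` turns per-cell calls into per-well percentages and
flags wells under 50 scored cells. `correct_prevalence()` implements
the Rogan–Gladen estimator for when measured sensitivity/specificity
should be divided out; the headline chain reports the raw percentage.

## Synergy, survival, dose-response

Checkerboards are normalised per replicate to that replicate's (0, 0)
well (exactly 100 at the control; values above 100 — worsening — are
retained so antagonism stays visible), then averaged *after*
normalisation. Effects are reductions, `E = 100 - %control`, so
positive synergy means fewer inclusions than the best monotherapy:
`S = E - max(E(a,0), E(0,b))`, with the margins defined as exactly 0
(they *are* the reference; with noisy margins the raw difference could
otherwise go negative there, which would misreport monotherapy as
antagonism). Calls use the strict `S > 10` threshold, `S < -10` for
antagonism. Raw differences are used rather than smoothed surfaces;
tools that fit before differencing will disagree slightly on real data.

Relative survival divides a GFP+ count series by its own start, then by
the matched control arm at the same timepoint (same-treatment control;
a vehicle-control variant is a matter of passing a different control
series). AUC is the trapezoid rule on the raw timepoints — no
resampling, so the statistic is exactly reproducible from the table.
The 4PL fit places zero doses at (min nonzero dose)/100 on the log
axis, the standard convention for "log(inhibitor)" fits, seeds from
data quantiles, and flags rather than errors on non-convergence; an
IC50 outside the dosed range is flagged extrapolated.

## Numerical choices and problem sizes

Granulometry and texture are the expensive features (~15 ms per cell);
the validation suite therefore works at 40-cell 512 × 512 fields and
pools of a few hundred to a few thousand cells, sizes at which the
binomial error of a recovered prevalence is well inside the tolerances
being checked. The acceptance script (`scripts/acceptance.R`)
regenerates everything from scratch at ~3000 scored cells for the
high-prevalence condition and ~6000 for the 0.8% condition, where the
binomial standard error of the recovered percentage
(`sqrt(p(1-p)/n)` ≈ 0.11 points at n = 6000) must sit well inside the
±0.3-point check. Segmentation-recall and classification bars are
means over independently seeded fields/splits. All randomness flows
from one integer seed per run.

## Known limitations

* The simulator's phenotype margin is generous; accuracy bars
  transfer to real data only as an upper bound.
* Subtractive correction of a multiplicative vignette is a first-order
  approximation; divisive flat-fielding is deliberately not the default.
* No cell tracking: live-cell "survival" is per-timepoint counting.
* Statistical inference on per-well tables (t tests, ANOVA) is left to
  external tools by design; the package emits per-replicate tables.
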