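---
title: "Entropy-based scratch-assay quantification: model, parameters and validation"
author: "WoundEntropy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based scratch-assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WoundEntropy)
```

## The measurement problem

In a scratch (wound-healing) assay a gap is scraped into a confluent cell
monolayer and its re-population by migrating cells is photographed over
time, typically by phase-contrast microscopy at low magnification. The
quantity of interest is how much of the initial wound is still open at each
timepoint. Manual outlining is slow and subjective; intensity thresholding
fails because phase-contrast renders both cells and background at similar
mean brightness. What reliably distinguishes the two regions is *texture*:
a monolayer is optically busy, a cell-free scratch is flat.

WoundEntropy quantifies that distinction with local Shannon entropy. For a
pixel $i$ with a disk-shaped neighborhood $D_r(i)$ of radius $r$, the
entropy of the 8-bit intensity histogram within the disk is

$$H_i = -\sum_{v=0}^{255} p_{iv} \log_2 p_{iv},
\qquad p_{iv} = \frac{\#\{j \in D_r(i) : I_j = v\}}{|D_r(i)|},$$

in bits, with $0 \le H_i \le \min(8, \log_2 |D_r(i)|)$. Cell-covered
regions score near the ceiling; a flat wound scores near zero; a single
threshold on the rescaled entropy map separates them.

## The segmentation pipeline

`segmentWound()` applies, in order:

1. **Local entropy** over the disk of radius $r$ (`localEntropy()`),
   with *reflect* padding at the frame border. Reflect padding matters:
   zero padding would depress border entropies and create a spurious
   low-entropy rim that the threshold would misread as wound.
2. **8-bit rescale** (`rescaleEntropy()`). Two modes are provided because
   an integer threshold (the published value is 92) only makes sense on a
   0–255 scale: `per_image_max` maps $v \mapsto
   \mathrm{round}(255\,v/\max H)$ (default), `fixed_8bit` maps $v \mapsto
   \mathrm{round}(255\,v/8)$. The normalization actually used by the
   original program is not documented, so both are exposed;
   `per_image_max` is the default because a threshold of 92 is then a
   *relative* cut at ~36 % of each image's entropy range, robust to
   illumination and confluency differences between images.
3. **Threshold**: wound candidate = rescaled entropy **strictly below** the
   threshold (the texture-poor side).
4. **Morphological cleanup**: binary closing then opening with a disk of
   radius `cleanupRadius` (default $\lceil r/4 \rceil$, tying the cleanup
   scale to the texture scale). Closing first bridges debris speckle inside
   the wound; opening then removes monolayer-side noise. Erosion treats
   out-of-frame pixels as foreground so wounds touching the frame edge are
   not eaten.
5. **Component filter**: connected components (8-connectivity by default)
   smaller than `minComponentFrac` (default 0.005) of the frame are
   discarded; **all** survivors are kept. Near closure a wound fragments
   into islands, so keeping only the largest component would bias late
   timepoints low. No positional prior (e.g. a central-band assumption) is
   used: a hand-made scratch is not guaranteed central.

Degenerate input: a constant image has zero entropy everywhere, the
per-image-max rescale maps it to all zeros, and the whole frame is
classified as wound — the correct cell-free-field limit.

### Parameters and presets

| parameter | meaning | default |
|---|---|---|
| `discSize` | disk size (px) of the entropy neighborhood | 20 |
| `discIsDiameter` | interpret `discSize` as diameter instead of radius | `FALSE` |
| `threshold` | 8-bit cut on the rescaled entropy | 92 |
| `entropyScale` | rescale mode | `per_image_max` |
| `cleanupRadius` | disk radius of closing/opening (px) | $\lceil r/4\rceil$ |
| `minComponentFrac` | minimum component size, fraction of frame | 0.005 |
| `connectivity` | component connectivity | 8 |

`cellLinePreset()` carries the calibrated pairs for the two ovarian
carcinoma lines the method was developed on: TOV-21G (disc 20, threshold
92) and SK-OV-3 (disc 50, threshold 92); the lines differ in cell size and
morphology, hence the different texture scale. The disc size is interpreted
as the disk *radius* — the dominant convention for rank-filter footprints —
but since the original description does not say, `discIsDiameter = TRUE` is
available.

### Manual supervision

The method was designed to run with a human in the loop. `applyOverride()`
replaces, intersects or unions a mask with a supervisor-supplied region
(raster or polygon), recomputes areas, and sets an `overridden` flag that
is carried into reports.

## Closure kinetics

All evaluations are relative to the initial wound at T0:
$\mathrm{open}(t) = 100 \cdot A(t)/A(T_0)$ and
$\mathrm{closure}(t) = 100 - \mathrm{open}(t)$ (`openWoundPercent()`).
Values above 100 are reported uncapped with an `EXPANDED` flag —
clipping would hide detachment artifacts the supervisor should see. Frames
of one well are treated as re-located fields of the same dish; no
registration is applied and a frame-dimension mismatch is a hard error.
`compareConditions()` aggregates replicate wells into mean, sd, n per
condition and timepoint.

## Companion microplate calculations

* **MTT viability**: $100\,(T - T_c)/(C - C_c)$ from 570 nm signal and
  630 nm background absorbances of treated and control wells; growth
  inhibition is its complement. The quantity is invariant to a common
  absorbance offset.
* **GI50/GI25/GI10** (`giLevel()`): the concentration where viability
  crosses $100 - \mathrm{level}$, found by scanning the dose–response
  curve along increasing concentration for the first bracketing pair on a
  decreasing segment and interpolating linearly in
  $\log_{10}(\text{concentration})$. Log-linear interpolation rather than a
  4PL fit is a deliberate choice: it is assumption-free, deterministic,
  exact at nodes, and the assay description prescribes level definitions,
  not a fitting procedure. Out-of-range or non-monotone situations return
  explicit statuses (`above_range`, `below_range`,
  `non_monotone_ambiguous`) instead of extrapolated numbers.
* **Fluorescence ratios** (`fluorescenceRatio()`): AO/PI viability =
  green/orange; JC-1 membrane potential = orange/green; NAO mitochondrial
  mass = mean green passed through. A zero denominator yields an
  `undefined_ratio` status, not an error.
* **∆∆Cq** (`ddcqFoldChange()`): replicate Cq values are averaged
  arithmetically (the standard practice; averaging $2^{-Cq}$ is *not*
  done), $\Delta Cq = Cq_\mathrm{target} - Cq_\mathrm{reference}$ per
  sample, fold change $= 2^{-\Delta\Delta Cq}$ with HPRT1 as the default
  reference and 100 % amplification efficiency assumed (no efficiency
  correction is described for the assay).

## What the synthetic generator emulates — and what it does not

`simulateScratchImage()` builds frames from the two ingredients the
segmentation actually senses: a high-entropy cell region (iid uniform
intensities on [0, 255] by default — the maximal-contrast texture — or a
speckle model) and a flat wound band (`woundLevel` 140, `woundNoiseSd` 0 by
default) whose edges are roughened by a clipped ±1 random walk
(`edgeRoughness` 3 px), mimicking the ragged edge of a pipette-tip scratch.
The realized mask is returned as exact ground truth.
`simulateScratchSeries()` reuses the same texture field and edge walks and
scales the band width by the programmed closure fractions, so the truth
series is exact by construction. Default series geometry mirrors the
physical assay: a ~0.7 mm scratch from a 100 µL tip imaged at 4×
(~1.3 µm/px) is a band of roughly 560 px, emulated as `woundFrac = 0.35`
of a 1600 × 480 px field.

The generator does **not** emulate phase-contrast optics (halos, lensing at
the wound edge), debris inside the wound, illumination gradients, or the
gradual texture of lamellipodia at the migration front. Passing the
synthetic-recovery tests therefore demonstrates that the pipeline correctly
measures texture-defined wounds of known geometry — not that the presets
are optimal for any particular microscope.

`simulatePlate()` produces four-parameter-logistic dose–response plates,
$v(c) = \text{bottom} + (\text{top}-\text{bottom})/(1 + (c/GI_{50})^{h})$,
with nine 2-fold dilutions from 200 µM by default (matching the assay's
200–1.076 µM serial-dilution range), and `simulateCqTable()` produces Cq
tables whose ∆∆Cq inversion recovers programmed fold changes exactly in the
noiseless case.

## Numerical choices

* Entropy uses base-2 logarithms (bits), fixing the 0–8 range the
  `fixed_8bit` rescale relies on; the histogram uses the 256 native 8-bit
  levels with no re-binning.
* The kernel computes $H$ from the full 256-bin histogram at every pixel in
  a fixed bin order (with a precomputed $c \log_2 c$ table), so results are
  bitwise identical under image flips; a sub-$10^{-12}$ float residue is
  snapped to exactly 0 (the smallest attainable non-zero entropy, counts
  $(n-1,1)$, is orders of magnitude larger).
* Reflect padding is half-sample symmetric (the edge pixel is duplicated).
* Rounding follows R's `round()` (half-to-even) in the rescale step.
* 16-bit inputs default to min–max stretching (microscope exports rarely
  fill the 16-bit range); `fixed_shift` (value >> 8) is available when
  cross-image comparability matters more.
* RGB inputs collapse by integer-rounded Rec.601 luminance.

## Known limitations

**The fixed threshold sits low in the entropy transition, which biases
absolute areas.** Crossing from wound into monolayer, the disk gradually
picks up texture, and entropy rises from the wound floor to the texture
ceiling over a transition of width $\approx 2r$. With `per_image_max`
rescaling, threshold 92 cuts this transition at ~36 % of the ceiling — a
point reached when only a small fraction of the disk holds texture — so the
detected boundary sits a roughly constant offset $\delta \approx 0.36\,r$
*inside* the true wound on each side (measured on noise-free flat wounds;
a noisy wound floor pushes the offset larger). The signed area error is
therefore $\approx -2\delta \cdot \mathrm{frac} / \text{band width}$:
negligible when the band is much wider than the disc (the intended imaging
regime — published micrograph scratches are 20–30 disc radii wide) but
material for narrow bands. At the narrowest geometry we validate (band =
5 × disc, frame height 3 × disc), measured errors are ≈ −0.15 × wound
fraction for both presets: within ±0.03 at fraction 0.1, beyond it at 0.3
and 0.5. Two practical consequences: (i) absolute wound fractions from
narrow-band images carry a systematic low bias; (ii) T0-relative
percentages — the quantity the assay actually reports — largely cancel the
offset, since numerator and denominator are biased by the same
$2\delta \times$ height. The validation suite checks closure percentages to
±3 points end to end at the realistic default geometry.

Other limitations: no image registration between timepoints; no single-cell
resolution inside the wound; the `precision adjustment` by which the preset
pairs were originally chosen is not documented, so no auto-tuning is
attempted — presets are data, not a fitted model.

## Validation problem sizes

The test suite validates the entropy kernel against a brute-force per-pixel
oracle on 20 random 9–32 px images (radii 1–3, agreement to 1e-9), disk
footprints against exhaustive lattice enumeration for radii 1–50,
ground-truth recovery across 20 seeds × 4 wound fractions × both presets at
the minimal band-width geometry above, closure kinetics end to end on the
default 1600 × 480 px series, GI recovery on noiseless plates with GI50 at
5, 25 and 100 µM, and ∆∆Cq recovery over 100 noisy replicate tables
(0.2-cycle noise, median within ±10 %).

```{r example}
sim <- simulateScratchSeries(closureFracs = c(1, 0.6, 0.1),
                             times = c(0, 24, 48), seed = 7)
masks <- lapply(sim$images, segmentWound, params = cellLinePreset("tov21g"))
openWoundPercent(scratchSeries("well-A1", sim$times, masks))
```
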