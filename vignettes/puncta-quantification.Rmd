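---
title: "Simulating and quantifying smFISH puncta in DRG neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying smFISH puncta in DRG neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctasim)
```

## The problem

Single-molecule in situ hybridization (RNAscope and kin) renders individual
mRNA transcripts as diffraction-limited fluorescent puncta. Quantifying
expression per neuron then rests on two operations whose failure modes are
easy to underestimate: counting puncta (which saturates once spots are
closer than the point-spread function allows them to be resolved) and
measuring mean fluorescence intensity (which requires careful background
subtraction but stays linear in transcript number). `punctasim` rebuilds
this quantification machinery — for dorsal-root-ganglion (DRG) sensory
neurons labelled with the standard NF200 / CGRP / IB4 marker panel and
probed for acid-sensing ion channel (ASIC) subunit transcripts — on fully
synthetic data, so that every stage can be validated by parameter recovery:
the simulator knows each neuron's ground truth, the pipeline must get it
back.

## The image model

A punctum is a point emitter. An image is generated in four steps:

1. **Placement.** Emitters are placed uniformly in a circular region of
   interest (ROI) of diameter 25 µm — the scale of an average mouse DRG
   soma. Their number is Poisson with mean $\rho \cdot \pi r^2$ for puncta
   density $\rho$. A Poisson draw (rather than rounding $\rho \pi r^2$)
   keeps the model well-defined at the low end of the density sweep, where
   the expected count is below one. Emitters may coincide.
2. **Binning.** Positions are binned into the pixel grid (200 nm pitch by
   default); a pixel's value is the number of emitters it contains. There
   is no sub-pixel PSF shifting: the renderer works on this integer
   matrix.
3. **PSF convolution.** The grid is scaled by
   $\varepsilon \, \pi (\omega_0 / \mathrm{px})^2$ and convolved with a
   2-D Gaussian kernel of $e^{-2}$ radius $\omega_0$ (300 nm = 1.5 px by
   default), truncated at $4\omega_0$ (< 1e-6 of the mass) and normalized
   to unit sum. $\varepsilon$ (default 100 intensity units) is the mean
   intensity contributed by one particle. With the unit-sum normalization,
   one isolated emitter integrates to exactly
   $\varepsilon \pi (\omega_0/\mathrm{px})^2 \approx 706.9$ i.u. and peaks
   at $2\varepsilon$ — both are locked by tests against a
   dense-grid numerical integration oracle. The rendered image is padded
   by the kernel radius so no emitter mass is ever clipped at the border;
   total image intensity is therefore *exactly* linear in emitter count.
   Whether the "area of a disk of radius $\omega_0$" prefactor is taken in
   pixel or micrometre units only rescales the intensity axis; pixel units
   are used throughout.
4. **Noise.** Independent zero-mean Gaussian noise (default sd 1 i.u.) is
   added per pixel. The simulation assumes detector linearity — no
   saturation, shot noise, gain or photobleaching model.

## Spot detection

Detection follows the thresholded local-maxima family of particle
finders: a peak is a pixel above the amplitude threshold (default 6 i.u.)
that is a strict maximum over its 8-neighborhood, and no two kept peaks
may be closer than the minimum separation, which defaults to $\omega_0$
in pixels. Suppression is greedy in order of decreasing amplitude. Two
semantics were fixed where the maxima-finder family is ambiguous, and are
locked by a brute-force oracle test (exhaustive scan plus naive
suppression on random images):

* **Plateaus.** Equal-valued neighboring maxima are resolved by keeping
  the lexicographically smallest pixel of the (8-connected) plateau, and a
  plateau counts as a maximum only if every pixel bordering it is strictly
  lower — hence a constant image contains no peaks.
* **Ties in suppression.** Equal amplitudes are ordered by (row, column).

**Noise envelope.** The default noise (sd 1 i.u.) puts the 6 i.u.
threshold at six sigma, where false maxima are vanishingly rare. Because a
noise pixel above the threshold is almost automatically a local maximum,
the false-peak rate per pixel is roughly the Gaussian upper-tail
probability at `threshold / noise_sd`: at sd 2 (three sigma) that is
~1.4e-3 per pixel — tens of false puncta in a soma-sized mask, enough to
flip truly negative cells past the 3-puncta rule. Per-neuron recovery is
therefore validated at the default noise, and users raising `noise_sd`
above roughly `threshold / 4.5` should raise the threshold with it.

## The ground-truth population

`sample_population()` draws neurons with marker class (NF200 — myelinated,
larger somata; CGRP — peptidergic nociceptors; IB4 — non-peptidergic
nociceptors; plus an unlabeled remainder), soma area, and true expression
state per probe. Two generation modes mirror the two assay designs:
independent Bernoulli per probe (single-probe assays, parameterized by the
reported per-marker percentages) and a joint 8-category multinomial over
ASIC1a/ASIC2b/ASIC3 combinations (the three-probe multiplex assay,
parameterized by the reported co-expression fractions, 2038 neurons).

Choices where the source data are silent, made once and kept:

* **Per-cell puncta counts.** Positive cells draw uniform 5–20 puncta,
  negative cells 0 (p = 0.8) or 1–2. These are stand-ins, not estimates —
  no per-cell transcript counts are reported — chosen so the ≥ 3-puncta
  rule is nearly noiseless while still exercising the negative branch.
* **Soma areas** are marker-specific Gaussians truncated at zero
  (NF200 900 ± 250 µm², CGRP 420 ± 120, IB4 380 ± 100, unlabeled
  500 ± 150), consistent with the small/medium/large class boundaries at
  650 and 900 µm² and with NF200 cells being the large ones. A neuron has
  a single soma area independent of probe state; the per-(probe, marker)
  size distributions analysed downstream arise by conditioning on calls,
  not by construction.
* **Marker proportions** default to 30/25/25/20 % — a plausible lumbar DRG
  composition; recovery results do not depend on it.
* **Condition effects.** Nerve-injury (cuff) effects are declarative
  rows (segment, marker, probe → new probability or intensity
  multiplier); sham keeps naive parameters. Probability effects redraw
  the targeted cells' truth; intensity effects scale their emitter
  brightness $\varepsilon$-multiplier, which propagates linearly to
  measured intensity.

Every stochastic stage derives a child seed from the master seed and a
stage label, so stages are independently reproducible.

## Per-neuron quantification

`quantify_population()` runs the full loop for each neuron and probe: the
soma is rendered as an isolated field (emitters uniform in the soma disk),
noise is added, peaks are detected, counted inside the soma mask (dilated
by one pixel to keep rim puncta), and the ≥ 3 rule produces the call.
Optionally the mean intensity is measured in a centered circular ROI
(physical radius 6.3 µm, the 10-pixel ROI of the reference protocol at
0.63 µm/px, converted to the rendering grid) and corrected by the average
of 3–5 puncta-free background regions; background regions are taken from
the field corners and verified puncta-free, mimicking the manual
selection. Adding a constant offset to the whole image leaves corrected
intensities unchanged (tested to 1e-9). Neurons whose ROI would exit the
image are excluded and logged rather than measured. A merged cluster of
puncta yields at least one detected peak; no cluster-splitting is
attempted — counting each detected peak once is the adopted convention.

## Statistics

* **Size histograms** (100 µm² bins) are fit with a scaled Gaussian
  $A e^{-(x-\mu)^2/2\sigma^2}$ by Levenberg–Marquardt least squares.
* The **extra sum-of-squares F-test** compares "one curve for both
  datasets" against "separate curves":
  $F = \frac{(SS_c - SS_s)/(df_c - df_s)}{SS_s/df_s}$, upper-tail p from
  $F(df_c - df_s,\; df_s)$. The separate model sums the two individual
  fits' SS with $df = n_1 + n_2 - 2k$; the combined fit pools all
  histogram points with $df = n_1 + n_2 - k$ ($k = 3$ parameters). Its
  type-I error is nominal under the test's own null — two point sets from
  a shared curve with iid Gaussian errors (calibration verified by
  simulation: rejection rate 0.05 ± 0.02, p-values uniform). Applied to
  histogram *counts*, residuals are Poisson-heteroscedastic and the test
  is anticonservative; treat those p-values as approximate, as the
  original curve-comparison workflow does.
* **Proportion comparisons** (sham vs cuff percent positive) use the
  classical pooled-variance unpaired t-test, with the DRG
  section/ganglion — not the neuron — as the experimental unit; a Welch
  variant is available by flag.
* **Per-cell intensity comparisons** use one-way ANOVA followed by
  Tukey's HSD (delegated to `aov()` / `TukeyHSD()`); an all-constant
  input is flagged as a no-variance case instead of being given a
  p-value.

## What passing tests do and do not show

The simulator emulates the statistical structure the analysis assumes:
uniform puncta in circular somata, Gaussian PSF, iid Gaussian noise,
homogeneous marker disks. Real tissue departs from all of these —
clustered transcripts, out-of-focus light, autofluorescence, touching and
sectioned somata, irregular shapes. Parameter recovery here therefore
validates the *quantification machinery* (detection, counting, ROI
statistics, combinatorics, tests), not the biological accuracy of any
particular staining; the known counting failure (saturation at high
density) is reproduced, not repaired — it is the reason the intensity
path exists.

## Problem sizes and defaults used in validation

Validation runs use the study-scale sizes: 2038 neurons for the multiplex
recovery, 500 per class for the marginal recovery, the printed density
sweep 0.0001–3.1 puncta/µm² at 100 replicates per density, 1000-replicate
null simulations for the test calibrations, and 1000 random 32×32 images
for the detector oracle.

## A worked example

```{r example, eval = FALSE}
params <- population_params(mode = "multinomial")
pop <- sample_population(params, 200, seed = 1)
q <- quantify_population(pop, sim_config(seed = 1), quant_config(), seed = 1)
coexpression_table(q)
marker_percentage_table(q, "ASIC3")
sat <- saturation_experiment(sim_config(), reps = 20, seed = 1)
```

## Known limitations

* 2-D only; no 3-D PSF or axial sectioning.
* No automated soma segmentation: masks come from the simulator (or, in
  principle, from manual ROIs) — the fully automated random-forest route
  was rejected in the source workflow and is out of scope.
* The detector performs no smoothing before maxima detection, so the
  threshold must dominate the noise (see the noise envelope above).
* Puncta-count distributions per cell are configurable stand-ins; absolute
  intensity scales are arbitrary (i.u.), only ratios and comparisons are
  meaningful.
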