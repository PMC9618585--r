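---
title: "Classifying potato processing aptitude from NIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying potato processing aptitude from NIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuberspec)
```

## The problem

Potato cultivars destined for crisping need high dry matter (roughly 20--24%)
and very low reducing sugars (below about 0.2% of fresh weight, to limit
browning and acrylamide formation during frying), while cultivars for cooking
sit around 17--19% dry matter. These compositional differences leave a small
but systematic imprint on the near-infrared reflectance of cut tuber flesh.
`tuberspec` implements a complete chemometric workflow that exploits this: a
push-broom NIR camera (900--1,700 nm, 256 bands, 320-pixel lines) images
fresh-cut slices, and a PLS-DA classifier assigns each tuber — or each pixel —
to the *cooking* or *frying as crisps* aptitude class.

The package covers every stage: reflectance calibration, slice segmentation,
spectral pre-processing, mean-spectrum and pixel-wise PLS-DA with
venetian-blinds cross-validation, forward interval PLS (iPLS) wavelength
selection, and classification maps. Because no public hyperspectral dataset
of this design exists, a synthetic generator reproduces the statistical
structure of the measurement so the entire pipeline is exercised end to end
from code alone.

## Models and procedures

### Reflectance calibration

Raw counts are normalized per column $x$ and band $\lambda$ against a white
ceramic tile (nominal reflectance 0.99) and a dark (shutter-closed) scan:

$$R(x,\lambda) = \frac{I(x,\lambda) - I_D(x,\lambda)}{I_W(x,\lambda) - I_D(x,\lambda)}.$$

References recorded as short line scans are averaged along the scan direction
first; a guard rejects any position where $|I_W - I_D| \le 10^{-6}$ with an
error naming the (column, band) rather than propagating NaN. Reflectance may
optionally be clipped to $[0, 2]$, but the default keeps out-of-range values:
slice reflectance mostly lies between 0 and 0.6, and extreme pixels are
informative noise. The first 30 of 256 bands are discarded for their poor
signal-to-noise ratio, leaving 226 bands from about 994 nm. Coordinates
throughout the package are 1-based (row, col), row-major, origin top-left —
the R convention; only consistency matters for fold/unfold round trips.

### Segmentation

The slice is separated from the dark sample holder by projecting the cube to
its per-pixel mean reflectance, thresholding with Otsu's criterion over a
256-bin histogram of the image range, then closing with a disc (radius 2 px),
filling holes and keeping the single largest 8-connected component (discarding
components under 50 px first). A more elaborate superpixel/local-contrast
front end exists in the literature for this task; it is a separate algorithm
in its own right and is intentionally not reproduced — on a dark background
the mean-band projection plus Otsu is already near-exact, and the
morphological defaults above are stated, configurable choices.

### Spectral pre-processing

Ten named chains are compared, built from six operators: Savitzky-Golay
smoothing (`SM`, 15-point window, 2nd-order polynomial), standard normal
variate (`SNV`), multiplicative scatter correction (`MSC`), first and second
SG derivatives (`1D`, `2D`, same window/order), and mean centering (`MC`).
Conventions that matter for reproducibility:

* SNV uses the sample standard deviation ($n-1$).
* The MSC reference is the mean spectrum of the calibration set (for
  pixel-wise models, the mean of all calibration pixels).
* SG filters handle band edges by the polynomial fit within the terminal
  window, so no bands are lost and the 226-band grid is preserved; smoothing
  is exact on polynomials up to degree 2.
* Derivatives are scaled by $1/\Delta\lambda^{\text{order}}$, i.e. reported
  per nm; the spacing is read from the wavelengths attached to the spectra.
* `1D`/`2D` are self-contained SG derivative filters (an SG derivative
  implies its own smoothing), so derivative chains do not additionally apply
  `SM`.
* Chains separate fitting from application: MSC references and MC means are
  learned on calibration data only (inside each CV fold, on the training
  portion only) and then applied unchanged to validation data.

### PLS-DA

Classification is PLS2 regression of a two-column 0/1 class dummy matrix on
the spectra, using the SIMPLS algorithm; a NIPALS implementation is kept
internally as a cross-check (for a binary dummy coding the centered response
has rank 1, so the two algorithms agree to numerical precision, and at full
rank both reduce to ordinary least squares — both facts are exploited as test
oracles). The decision rule is the argmax of the predicted class responses,
equivalent to a 0.5 threshold on their difference; exact ties go to the first
(positive) class. The probabilistic Bayes-threshold variant found in some
commercial toolboxes is deliberately not replicated. Cross-validation is
venetian blinds with 10 splits of width 1 over sample order (over pixels, for
pixel-wise models; a grouped-by-tuber option would be a natural extension but
interleaved pixel folds replicate the emulated design). The latent-variable
count is the smallest one minimizing the unweighted mean of calibration and
cross-validated class error, scanned up to `max_lv` (default 10).

Reported metrics follow the standard confusion-matrix arithmetic:
sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, class error
$1-(\text{sens}+\text{spec})/2$, accuracy $100\,(TP+TN)/n$. In the binary
case the two class rows mirror sensitivity/specificity and share the error —
the comparison tables print both rows. Tables round errors to 3 decimals and
accuracies to 2 (round-half-even); raw values are always retained.

### Forward iPLS

The spectrum is divided into equidistant intervals of 1 or 5 variables (a
non-multiple band count leaves a final short remainder interval rather than
dropping bands, preserving full coverage). Greedy forward selection adds, at
each step, the interval whose inclusion minimizes RMSECV — the
root-mean-squared cross-validated error of the continuous dummy response —
with the LV count re-optimized per candidate (capped at 10). "Automatic"
selection size means the grid is fixed by the interval width and the
*number selected* is decided by the stopping rule: stop when the best
candidate improves RMSECV by less than a relative `1e-3`. Selection operates
on the already pre-processed calibration matrix (chains are applied once,
upstream), which matches the operator signatures and standard iPLS practice;
the headline model metrics, by contrast, re-fit chain state inside every CV
fold.

### Classification maps

Pixel-wise predictions are folded back to image geometry and coded TP/FN on
cooking slices and TN/FP on frying slices (cooking is the positive class).
Map counts aggregated over validation slices reproduce the validation
confusion matrix exactly — a structural identity that is tested. Rendered
PNGs use TP dark green, TN dark blue, FP light green, FN yellow, with a
deterministic legend strip, so identical inputs give byte-identical files.

## The synthetic generator

`generate_slice()` and `generate_dataset()` emulate the acquisition campaign:
10 cultivars × 8 tubers = 80 slices (40 per class), 256 bands over 900--1,700
nm, 320-column frames with 112 rows, written as uint16 ENVI cubes with a
shared white/dark reference pair, truth masks, a manifest and a per-cultivar
chemistry table (dry matter, starch, reducing sugars, and the DNSA absorbance
consistent with the RS calibration line). Ellipse semi-axes are drawn from
U(30, 40) px, giving roughly 4,500--5,000 foreground pixels per slice — the
same order as the emulated campaign's ~4,800 pixels per slice. The pixel-wise
design selects 3 tubers per cultivar and splits them 2/1 into
calibration/validation (20/10 tubers); the mean-spectrum design splits all 80
tubers 75/25 stratified by class (60/20).

A foreground pixel's reflectance is built as

$$s(\lambda) = r(u)\,b(\lambda) + \delta\,g(\lambda)\,a(u) + \text{texture} ,$$

where $u$ is the normalized elliptical radius, $b$ a smooth baseline (0.55
falling to 0.35) carved by three Gaussian absorption valleys at 1,015, 1,200
and 1,450 nm (depths 0.05/0.07/0.25, widths 20/35/45 nm — the 1,450 nm valley
being the strong O–H water band), $r(u)$ darkens the pith (factor 0.75 at the
centre, Gaussian profile of scale 0.35), and the class offset $\delta = +0.02$
reflectance acts over 1,200--1,400 nm for the frying class with its own pith
attenuation $a(u)$ (factor 0.4 at the centre — pith tissue, low in starch,
carries a weaker class signal). On top come per-tuber valley-depth jitter
(relative sd 0.04), per-pixel compositional texture (valley-depth jitter with
relative sd 0.3 and a class-marker amplitude spread of sd 0.01 over the
marker window), per-pixel scatter $a\,s+b$ with $a \sim N(1, 0.05)$,
$b \sim N(0, 0.01)$, band-independent noise $N(0, 0.005)$, and per-column
stripes $N(0, 0.003)$ mimicking line-scan column noise. Raw counts are
obtained by inverting the calibration equation against the generated
references, so with all stochastic terms at zero the calibrated cube
reproduces the construction exactly.

Choices worth making explicit:

* **Pixel texture is what separates the two experiments.** Per-pixel terms
  are independent across pixels, so they average out of mean spectra: the
  mean-spectrum experiment achieves external accuracies in the high 90s
  under the defaults, while pixel-wise accuracy lands around 80% with false
  positives concentrated in the pith, where the class signal is attenuated
  but the within-class marker variation is not. Both patterns are the point
  of the emulation, not tuning targets of individual tests.
* **The chemistry table is not spectrally coupled.** Dry matter and sugars
  are drawn per cultivar for the chemistry CSV, but the spectral class
  signal is controlled solely by $\delta$. This keeps the control experiment
  clean — setting $\delta = 0$ removes *all* class information and
  end-to-end accuracy drops to chance — at the cost of not modelling
  DM-to-spectrum correlations within a class. Per-cultivar spectral effects
  likewise default to zero: each cultivar belongs to exactly one class, so
  any cultivar-specific spectral signature would act as a hidden class
  signal and break the $\delta = 0$ null.
* **What passing tests do not show.** The generator is a statistical
  emulation, not a radiative-transfer model: no specular highlights, no
  partial-volume mixing at slice edges (the emulated campaign reported
  false negatives concentrated there; our edges behave like cortex), no
  acrylamide chemistry, no between-session instrument drift. Accuracies on
  synthetic data therefore say that the *pipeline* recovers planted
  structure at realistic noise levels — not that a particular accuracy will
  be met on a real instrument.

## Numerical conventions

* Wavelengths are written to ENVI headers at full double precision (`%.17g`)
  so the axis round-trips bit-exactly; the axis validator requires uniform
  spacing within $10^{-9}$ nm.
* Degenerate inputs error early with typed conditions: flat spectra under
  SNV, near-zero MSC slopes, constant images under Otsu, empty masks, folds
  whose training portion holds a single class (skipped with a warning).
* Ties: LV selection picks the smallest count within $10^{-12}$ of the
  minimum score; class-response ties go to the positive class; equal-size
  largest components keep the first label in scan order.
* Every stochastic step (generator, splits) is driven by explicit integer
  seeds; per-slice substreams are derived by counter so a slice's content
  does not depend on generation order.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full 80-tuber mean-spectrum
experiment and the 30-tuber pixel-wise experiment at the default cube
geometry, plus reduced-size campaigns (64 × 96 frames, 4 cultivars) for the
structural and property checks. These sizes are the package's own choice of
a thorough-but-routine desk-scale validation; all of them are plain function
arguments, so larger campaigns are one call away.

## Known limitations

* Binary classification only; the multiclass extension of PLS-DA is out of
  scope.
* The venetian-blinds plan for pixel-wise models interleaves pixels, so
  pixels of one tuber appear in both training and held-out folds; external
  validation (whole held-out tubers) is the honest generalization figure,
  and the gap between the two is visible in the reported tables.
* iPLS explores contiguous equal-width intervals with greedy forward
  selection; backward elimination, synergy variants and stochastic searches
  are not implemented.
* The segmentation stand-in assumes a dark, uncluttered background.
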