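---
title: "Methods: channel-optimized LFIA readout and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel-optimized LFIA readout and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfiaQuant)
```

## The measurement model

A lateral flow immunoassay strip develops a coloured **test line** where
labelled antigen–antibody complexes accumulate, and a **control line**
downstream that catches any labelled particle — its presence certifies that
the sample flowed. As analyte concentration rises the test line darkens.

The readout statistic is the ratio of mean pixel intensities

$$\frac{I(b)}{I(t)},$$

with $I(t)$ taken over a region of interest on the test line and $I(b)$
over an equal-sized background region of bare membrane. Since a change of
illumination multiplies every pixel by the same factor, the factor cancels
in the ratio; this drift cancellation is exact before quantization and is
verified as a property test.

The package reads the ratio not from the full-spectrum image but from a
single Bayer colour channel, chosen to overlap the label's absorption
band. The chain is: spectral channel selection → channel-plane extraction
→ line localisation → ROI means → ratio → calibration statistics.

## Spectral channel selection

Label absorption is modelled as a Lorentzian band with unit peak,

$$\mathrm{ext}(\lambda) = \frac{1}{1 + \left(\frac{\lambda - \lambda_0}{w/2}\right)^2},$$

with centre $\lambda_0$ and FWHM $w$. Defaults: colloidal gold
$\lambda_0 = 546$ nm, $w = 80$ nm; iron oxide $\lambda_0 = 487$ nm,
$w = 120$ nm. Only the peak positions are physically anchored; the
Lorentzian shape is a smoothness assumption, and real gold extinction is
asymmetric (steeper on the red side). A consequence worth knowing: with
symmetric bands the red channel picks up more of the gold tail than the
blue channel does, so the full between-channel ordering of a real gold
strip (red weakest) is not reproduced — only the dominance of the matched
channel is, which is what channel selection needs.

A test line at concentration $c$ reflects
$R(\lambda) = R_\mathrm{mem}(\lambda)\, e^{-k\,c\,\mathrm{ext}(\lambda)}$
(Beer–Lambert attenuation of the membrane baseline; absorptivity scale
$k = 0.02$ per ng/mL by default). The **difference spectrum**
$\Delta(\lambda) = R_\mathrm{mem}(\lambda) - R(\lambda)$ peaks where the
label absorbs.

Channel sensitivities are Gaussians ($\sigma = 25$ nm) at the sensor's
centre wavelengths 613/537/456 nm, clipped to zero outside 400–700 nm
(the on-chip infrared cut-off); manufacturer curves are not public, so a
synthetic preset with exactly these curves ships in
`inst/extdata/bayer_channels_synthetic.csv`. The selected channel
maximises the response-weighted integral
$s(\mathrm{ch}) = \int \Delta(\lambda)\, C_\mathrm{ch}(\lambda)\,
d\lambda$ (trapezoid rule on the 380–780 nm, 1 nm grid). The integral
generalises to wide or asymmetric bands; a nearest-centre rule is
available as a fast fallback (`method = "nearest"`). Ties break in the
fixed order red → green → blue, and `peakWavelength()` breaks value ties
toward the smallest wavelength; a constant spectrum yields a warning and
the first grid point.

## The strip simulator

`makeStripScene()` + `makeSensorModel()` + `generateCalibrationSet()`
produce images with *known* ground truth, so every downstream stage is
testable without hardware. What is emulated:

* geometry — 400 × 120 px, test line at column 150, control at 300, 12 px
  wide, flow left → right (no pixel geometry is physically anchored; these
  are declared defaults);
* concentration response — linear `a + b·c` (defaults `a = 1.0449`,
  `b = 0.0156` per ng/mL) or Langmuir
  `1 + (a − 1 + b·c)/(1 + c/K)` with `K = 100` ng/mL, which departs from
  its initial line by the relative deficit `c/(c+K)`: ≈ 9 % at 10 ng/mL,
  33 % at 50 ng/mL — hence a linear range that ends at 10 ng/mL under the
  10 % criterion below;
* rendering — per channel, the responsivity-normalised integral of
  reflectance against the channel curve; the test line is attenuated so
  that in the most label-sensitive channel the noise-free ratio equals
  the target response *exactly*, other channels scaled by their relative
  spectral score. This makes recovery of the generating coefficients
  well-posed rather than approximate;
* camera — RGGB mosaic sampling (red at site (1,1)), scalar or spatial
  illumination gain, Gaussian shot noise (SD ∝ √signal, scale 0.002) plus
  read noise (SD 0.002) on the [0, 1] scale, clip and round to 8 bits;
* replicate variability — each strip's target ratio is perturbed by
  N(0, `ratioNoiseSd`²), representing strip-to-strip fabrication and
  development variability, which dominates pixel noise after ROI
  averaging. The default 0.002 keeps the default conditions low-noise;
  a blank-ratio SD of 0.0104 — the value consistent with a 2 ng/mL
  detection limit at slope 0.0156 — is used where detection-limit
  behaviour is exercised.

Not emulated: optics blur, JPEG artifacts, flow kinetics and incubation,
membrane texture, the edge-aggregation lines that sprayed iron-oxide
suspensions leave on drying, perspective or rotation of hand-held photos.
Passing tests therefore demonstrate the *analysis chain* is correct and
self-consistent under the declared image model; they do not certify
performance on real strips, where line shapes, background texture and
lighting are less kind.

All randomness flows from one master seed through a documented integer
derivation (`master → per-image sub-seed`), so a calibration set is
bit-reproducible.

## Readout

Channel planes come from **native CFA sites** by default: per 2 × 2 RGGB
cell, red from its one site, blue from its site, green as the mean of its
two — half-resolution planes with no interpolation, matching a sensor
that stores each band directly. Bilinear full-resolution demosaicing is
available behind a flag for real photographs. The `"original"` (total
colour) readout is the unweighted mean of the three planes; a Rec.601
luma weighting is available but not default, since the unseparated
readout it stands in for has no defined weighting.

Lines are found on the column-mean profile of the central 60 % of rows.
The detector thresholds depth below the median baseline (minimum
prominence 0.01 on the [0, 1] scale), groups columns into dips, takes
each dip's extent as its full width at half prominence and its centre as
the depth-weighted centroid over that width. The upstream dip is the test
line, the downstream one the control line. Assay logic: **no control
line ⇒ invalid strip** (flow failure), never "negative"; control line
but no test dip ⇒ valid negative, with the test ROI falling back to its
configured expected position. The background ROI is placed midway
between the two lines with the same width as the test ROI; a saturation
flag is raised if more than 0.5 % of ROI pixels sit at full code value.
ROI geometry is not physically anchored and is fully config-exposed.

## Calibration statistics

* **Fit** — OLS of replicate-level ratios on concentration
  (`fitCalibration()`), R² reported on replicates, not level means (the
  choice is ambiguous in practice; replicate-level is the conservative
  one and is declared here).
* **Linear range** (`linearRange()`) — the largest grid prefix
  $\{0, \dots, c_k\}$, $k \ge 3$ levels, whose per-level means satisfy
  $|{\rm mean}_i - \hat y_i| / (\hat y_i - \hat a) \le 0.10$ at every
  positive level, where $\hat y$ is the prefix OLS fit and $\hat a$ its
  intercept. The denominator is the fitted signal *above baseline*, so
  the criterion measures relative response distortion; the blank level
  anchors the fit but is not itself tested (its above-baseline signal is
  zero). Levels whose fitted signal is non-positive fail outright.
* **Detection limit** (`detectionLimit()`) — the IUPAC-style
  `3·SD(blank)/slope` from ≥ 3 blank replicates; an empirical
  alternative ("lowest level whose mean exceeds blank + 3 SD") sits
  behind `method = "empirical"`. No formula is anchored for this
  quantity; `3σ/slope` is the declared design choice.
* **Channel comparison** (`compareChannels()`) — per concentration
  level, a one-way ANOVA across the four readout methods, then pairwise
  pooled-variance t-tests of each colour channel against the original
  readout with Bonferroni adjustment `p_adj = min(1, 3p)`. This is the
  standard reading of "Bonferroni one-way ANOVA" as a post-hoc family of
  three comparisons per level. Differences of means are reported signed
  (channel − reference).
* **Inversion** (`predictConcentration()`) — `(ratio − a)/b`, negative
  estimates clamped to 0 and flagged, below-LOD and above-range
  estimates flagged.

## Numerical choices and degenerate inputs

1 nm wavelength grid, trapezoid integration everywhere; dense Riemann
summation serves as the independent oracle in tests. Internal image
computation is floating point on [0, 1]; quantization to 8 bits happens
once, at the sensor stage. Per-ROI means over ~200+ pixels make the
residual quantization bias negligible relative to replicate noise.
Degenerate cases error loudly rather than guess: empty row bands,
odd-sized mosaics, zero test-line intensity, overlapping ROIs,
all-zero channel scores, rank-deficient calibration designs, non-positive
slopes for LOD/inversion.

## Problem sizes

The test suite and the acceptance script run the simulator at the study
grid (six levels × 10 replicates, 400 × 120 px, ~60 images per run;
coefficient-recovery runs use four levels × 10 replicates, and the
detection-limit condition averages five sub-seeded runs). These sizes
keep a full run in seconds on one core while leaving per-level standard
errors well below the effects being measured.

## Known limitations

* Band shapes, membrane reflectance (flat 0.95) and the illuminant
  (flat) are idealised; only band centres and the channel centres are
  anchored to the modelled instrument.
* Native-site extraction halves resolution; expected line positions are
  scaled accordingly, and detection accuracy is specified in full-
  resolution pixels.
* The comparison report's t and p values depend on replicate noise that
  real instruments generate differently; the report's *structure* and
  the Bonferroni arithmetic are the tested contract, not any particular
  significance pattern.
* Strips are assumed axis-aligned (a reader fixture, not hand-held
  photography).
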