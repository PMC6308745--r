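# lfiaQuant

Channel-optimized colorimetric readout for lateral flow immunoassays
(LFIA).

Quantitative LFIA readers photograph the strip and estimate analyte
concentration from how dark the test line is. Most readers use monochrome
intensity over the sensor's whole 400–700 nm response, although the label's
colour information is confined to a narrow band — colloidal gold's plasmon
absorption peaks near 546 nm, brown iron-oxide particles near 487 nm.
Everything outside that band contributes noise (membrane colour, sample
colour, ambient light). Because a colour camera's Bayer filter already
splits the image into red/green/blue bands (centres 613/537/456 nm for the
sensor modelled here), picking the single channel that overlaps the label's
absorption band gives a narrowband readout with no extra optics.

`lfiaQuant` is for assay and reader developers who want to prototype and
validate that readout without instrument hardware. It implements:

* **Spectral channel selection** — label absorption models, test-line
  minus background difference spectra, and the response-weighted score
  `s(ch) = ∫ Δ(λ) C_ch(λ) dλ` that picks the most sensitive Bayer channel
  (gold → green, iron oxide → blue).
* **A synthetic strip simulator** — scene geometry (test line upstream,
  control line downstream), Beer–Lambert line attenuation, RGGB
  colour-filter-array sampling, illumination gain, shot + read noise,
  8-bit quantization — with a known ground-truth concentration response,
  either linear or saturating (Langmuir).
* **I(b)/I(t) densitometry** — native-site channel-plane extraction,
  column-profile dip detection with control-line QC, and the statistic
  `I(b)/I(t)` (mean background ROI intensity over mean test-line ROI
  intensity), which rises with concentration and cancels global
  illumination drift.
* **Calibration statistics** — OLS calibration `ratio = a + b·c`,
  linear-range determination by prefix lack-of-fit, limit of detection
  `LOD = 3·SD(blank)/b`, ratio-to-concentration inversion, and one-way
  ANOVA with Bonferroni-adjusted pairwise comparison of the channel
  readout methods against the original (unseparated) colour readout.

The simulator's defaults encode the CK-MB (creatine kinase–MB, a cardiac
biomarker) study conditions: concentration grid 0/2/4/10/50/100 ng/mL, 10
replicates per level, green-channel response `ratio = 1.0449 + 0.0156·c`.

## Worked example

```r
library(lfiaQuant)

## which channel should read a gold-labelled strip?
gold <- makeLabelModel("gold")
d <- differenceSpectrum(flatSpectrum(), reflectanceSpectrum(gold, 100))
peakWavelength(d)
#> [1] 546
selectChannel(d)$scores
#>      red    green     blue
#> 25.96970 45.64004 18.21110

## simulate, analyse and calibrate a full run
cfg <- defaultPipelineConfig(seed = 42)
res <- runPipeline(cfg, "runs/demo")
res$calibration
#> CalibrationModel: ratio = 1.0450 + 0.0156 * c, R^2 = 1.0000
#>   linear range 0-100 ng/mL, 6 levels, 60 points

## one strip, green channel
m <- analyzeImage("runs/demo/images/strip_L04_R01.png", "green")
m
#> RatioMeasurement [green]: I(b)=0.8740, I(t)=0.7280, I(b)/I(t)=1.2004 (flags: none)
predictConcentration(res$calibration, intensityRatio(m), lod = res$lod)
#>      ratio concentration flag
#> 1 1.200434      9.964776
```

The channel scores say the green channel integrates the most of the gold
difference signal, so it is the quantification channel. The fitted line
recovers the generating coefficients, and the strip simulated at 10 ng/mL
reads back at 9.96 ng/mL. `runs/demo/` also contains `results.csv` (all
channels, all strips), `comparison.csv` (Bonferroni-adjusted channel
comparisons) and `run.log`.

A thin CLI wraps the same functions
(`inst/scripts/lfia.R {pipeline|simulate|analyze|calibrate|compare}`).

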