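#' Construct a synthetic strip scene
#'
#' Defaults describe the study conditions this package targets: a 400 x 120
#' px image of a pale membrane with a 12 px wide test line at column 150 and
#' control line at column 300 (flow left to right), a colloidal-gold label,
#' and the linear concentration response ratio = 1.0449 + 0.0156 c (ng/mL)
#' of the CK-MB green-channel calibration. The `langmuir` mode,
#' ratio = 1 + (a - 1 + b c) / (1 + c / K), bends the same initial slope onto
#' a saturating binding curve (default K = 100 ng/mL), which confines the
#' usable linear range to low concentrations.
#'
#' @param widthPx,heightPx image dimensions (even numbers).
#' @param testLineCenterPx,controlLineCenterPx line centre columns, 1-based;
#'   the test line must be strictly upstream (smaller column).
#' @param lineWidthPx line width in pixels.
#' @param membraneReflectance [Spectrum-class]; default flat 0.95.
#' @param label a [LabelModel-class]; default colloidal gold.
#' @param concentration analyte concentration, ng/mL.
#' @param controlStrength fractional attenuation of the control line.
#' @param response list with `mode` ("linear"/"langmuir"), `a`, `b`, `K`.
#' @return a [StripScene-class].
#' @export
makeStripScene <- function(widthPx = 400L, heightPx = 120L,
                           testLineCenterPx = 150L,
                           controlLineCenterPx = 300L, lineWidthPx = 12L,
                           membraneReflectance = flatSpectrum(),
                           label = makeLabelModel("gold"),
                           concentration = 0,
                           controlStrength = 0.3,
                           response = list(mode = "linear", a = 1.0449,
                                           b = 0.0156, K = 100)) {
  methods::new("StripScene", widthPx = as.integer(widthPx),
               heightPx = as.integer(heightPx),
               testLineCenterPx = as.integer(testLineCenterPx),
               controlLineCenterPx = as.integer(controlLineCenterPx),
               lineWidthPx = as.integer(lineWidthPx),
               membraneReflectance = membraneReflectance, label = label,
               concentration = concentration,
               controlStrength = controlStrength, response = response)
}

#' Construct a camera / sensor model
#'
#' @param channels list of three [ChannelResponse-class]; default
#'   [bayerChannels()] (centres 613 / 537 / 456 nm).
#' @param cfaPattern CFA phase; `"RGGB"` (red at row 1, column 1).
#' @param bitDepth output bit depth (8).
#' @param illuminationGain positive scalar or matrix; default 0.92.
#' @param shotNoise shot-noise scale (SD contribution `shotNoise *
#'   sqrt(signal)` on the [0, 1] scale); default 0.002.
#' @param readNoise additive read-noise SD; default 0.002.
#' @param seed integer seed for the noise stage.
#' @return a [SensorModel-class].
#' @export
makeSensorModel <- function(channels = bayerChannels(), cfaPattern = "RGGB",
                            bitDepth = 8L, illuminationGain = 0.92,
                            shotNoise = 0.002, readNoise = 0.002,
                            seed = 1L) {
  methods::new("SensorModel", channels = channels, cfaPattern = cfaPattern,
               bitDepth = as.integer(bitDepth),
               illuminationGain = illuminationGain, shotNoise = shotNoise,
               readNoise = readNoise, seed = as.integer(seed))
}

#' @describeIn groundTruthRatio noise-free I(b)/I(t) implied by the scene's
#'   concentration response.
#' @export
setMethod("groundTruthRatio", "StripScene", function(scene, ...) {
  r <- scene@response
  cc <- scene@concentration
  if (r$mode == "linear") r$a + r$b * cc
  else 1 + (r$a - 1 + r$b * cc) / (1 + cc / r$K)
})

## per-channel background level: responsivity-normalised integral of the
## membrane reflectance against the channel sensitivity
.channelBackground <- function(scene, sensor) {
  grid <- scene@membraneReflectance@wavelength
  vapply(sensor@channels, function(ch) {
    cv <- .onGrid(ch@curve, grid)
    .trapz(grid, scene@membraneReflectance@value * cv) / .trapz(grid, cv)
  }, numeric(1))
}

## relative spectral sensitivity of each channel to this label, from the
## difference spectrum at a reference concentration; normalised to max 1
.channelSensitivity <- function(scene, sensor, labelK, refConcentration) {
  d <- differenceSpectrum(
    scene@membraneReflectance,
    reflectanceSpectrum(scene@label, refConcentration,
                        scene@membraneReflectance, k = labelK))
  sc <- selectChannel(d, sensor@channels)$scores
  sc / max(sc)
}

#' Render a strip scene to a continuous three-plane colour image
#'
#' Each pixel's channel value is the illumination gain times the
#' responsivity-normalised integral of the local reflectance against the
#' channel sensitivity curve. Test-line columns are attenuated such that, in
#' the channel most sensitive to the label, the noise-free background /
#' test-line mean ratio equals `targetRatio` exactly; the other channels are
#' attenuated in proportion to their relative spectral sensitivity to the
#' label. The control line is attenuated by the scene's `controlStrength` in
#' every channel (labelled particles of any kind accumulate there, rendered
#' neutrally). Output values are not clipped: pre-quantization rendering is
#' linear in the illumination gain.
#'
#' @param scene a [StripScene-class].
#' @param sensor a [SensorModel-class].
#' @param targetRatio the I(b)/I(t) the rendered strip should encode;
#'   defaults to [groundTruthRatio()] of the scene. Override to inject
#'   strip-to-strip variability.
#' @param labelK absorptivity scale passed to [reflectanceSpectrum()].
#' @param refConcentration reference concentration for the per-channel
#'   sensitivity weights.
#' @return numeric array `heightPx x widthPx x 3` (red, green, blue planes).
#' @export
renderScene <- function(scene, sensor, targetRatio = groundTruthRatio(scene),
                        labelK = 0.02, refConcentration = 100) {
  stopifnot(methods::is(scene, "StripScene"),
            methods::is(sensor, "SensorModel"))
  h <- scene@heightPx; w <- scene@widthPx
  g <- sensor@illuminationGain
  if (is.matrix(g) && !identical(dim(g), c(h, w)))
    .stopf("illumination gain field is %dx%d but the scene is %dx%d",
           nrow(g), ncol(g), h, w)
  bg <- .channelBackground(scene, sensor)
  sens <- .channelSensitivity(scene, sensor, labelK, refConcentration)
  aSel <- 1 - 1 / targetRatio
  att <- aSel * sens                       # per-channel fractional attenuation
  half <- scene@lineWidthPx %/% 2L
  tCols <- (scene@testLineCenterPx - half + 1L):(scene@testLineCenterPx + half)
  cCols <- (scene@controlLineCenterPx - half + 1L):
    (scene@controlLineCenterPx + half)
  img <- array(0, dim = c(h, w, 3L))
  for (i in 1:3) {
    plane <- matrix(bg[i], h, w)
    plane[, tCols] <- bg[i] * (1 - att[i])
    plane[, cCols] <- bg[i] * (1 - scene@controlStrength)
    img[, , i] <- plane * g                # scalar or full gain field
  }
  dimnames(img) <- list(NULL, NULL,
                        vapply(sensor@channels, function(ch) ch@name,
                               character(1)))
  img
}

#' Sample a colour image through an RGGB colour filter array
#'
#' Keeps, at every pixel, only the channel its Bayer site records: red at
#' odd (row, column) sites, blue at even ones, green at the two mixed sites
#' (RGGB phase, red at position (1, 1)).
#'
#' @param colorImage numeric array `h x w x 3` (red, green, blue).
#' @param pattern CFA phase; only `"RGGB"`.
#' @return a [MosaicImage-class] (continuous; quantize with
#'   [addNoiseAndQuantize()]).
#' @export
mosaicImage <- function(colorImage, pattern = "RGGB") {
  d <- dim(colorImage)
  if (length(d) != 3L || d[3] != 3L) .stopf("expected an h x w x 3 array")
  if (any(d[1:2] %% 2L != 0L))
    .stopf("mosaic dimensions must be even, got %dx%d", d[1], d[2])
  if (pattern != "RGGB") .stopf("only the RGGB pattern is supported")
  h <- d[1]; w <- d[2]
  oddR <- seq(1L, h, 2L); evenR <- seq(2L, h, 2L)
  oddC <- seq(1L, w, 2L); evenC <- seq(2L, w, 2L)
  m <- matrix(0, h, w)
  m[oddR, oddC]  <- colorImage[oddR, oddC, 1L]    # R
  m[oddR, evenC] <- colorImage[oddR, evenC, 2L]   # G
  m[evenR, oddC] <- colorImage[evenR, oddC, 2L]   # G
  m[evenR, evenC] <- colorImage[evenR, evenC, 3L] # B
  methods::new("MosaicImage", data = m, pattern = pattern,
               bitDepth = NA_integer_)
}

## 3x3 correlation with edge replication, used by the bilinear demosaic
.conv3 <- function(m, kern) {
  h <- nrow(m); w <- ncol(m)
  p <- m[c(1, 1:h, h), c(1, 1:w, w)]      # replicate-pad by one
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    kv <- kern[dr + 2, dc + 2]
    if (kv != 0)
      out <- out + kv * p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out
}

#' Extract per-channel planes from a CFA mosaic
#'
#' Default `"native"` mode performs no interpolation: per 2 x 2 RGGB cell it
#' takes red from its single site, blue from its site, and green as the mean
#' of the two green sites, yielding half-resolution planes — the direct
#' "store each band individually" reading of Bayer data. `"bilinear"` mode
#' interpolates each channel to full resolution (for real photographs).
#'
#' @param m a [MosaicImage-class], or a numeric matrix of CFA samples.
#' @param mode `"native"` or `"bilinear"`.
#' @param pattern CFA phase when `m` is a bare matrix.
#' @return named list of three [ChannelPlane-class] objects
#'   (`red`, `green`, `blue`), values normalised to [0, 1].
#' @export
demosaicPlanes <- function(m, mode = c("native", "bilinear"),
                           pattern = "RGGB") {
  mode <- match.arg(mode)
  if (is.matrix(m)) m <- methods::new("MosaicImage", data = m,
                                      pattern = pattern,
                                      bitDepth = NA_integer_)
  stopifnot(methods::is(m, "MosaicImage"))
  d <- m@data
  if (!is.na(m@bitDepth)) d <- d / (2^m@bitDepth - 1)
  d <- pmin(pmax(d, 0), 1)
  h <- nrow(d); w <- ncol(d)
  oddR <- seq(1L, h, 2L); evenR <- seq(2L, h, 2L)
  oddC <- seq(1L, w, 2L); evenC <- seq(2L, w, 2L)
  if (mode == "native") {
    planes <- list(red = d[oddR, oddC],
                   green = (d[oddR, evenC] + d[evenR, oddC]) / 2,
                   blue = d[evenR, evenC])
    prov <- "native"
  } else {
    kern <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3)
    mk <- function(mask) {
      num <- .conv3(d * mask, kern)
      den <- .conv3(mask, kern)
      num / den
    }
    mR <- matrix(0, h, w); mR[oddR, oddC] <- 1
    mG <- matrix(0, h, w); mG[oddR, evenC] <- 1; mG[evenR, oddC] <- 1
    mB <- matrix(0, h, w); mB[evenR, evenC] <- 1
    planes <- list(red = mk(mR), green = mk(mG), blue = mk(mB))
    prov <- "bilinear"
  }
  mapply(function(p, nm) {
    methods::new("ChannelPlane", data = pmin(pmax(p, 0), 1), channel = nm,
                 provenance = prov)
  }, planes, names(planes), SIMPLIFY = FALSE)
}

#' Add sensor noise and quantize to 8-bit code values
#'
#' Applies a Gaussian approximation of shot noise (SD `shotNoise *
#' sqrt(signal)`) plus additive read noise on the [0, 1] scale, clips to
#' [0, 1] and rounds to integer code values. With both noise parameters zero
#' this is pure quantization. The same seed always produces a bit-identical
#' image.
#'
#' @param image a continuous [MosaicImage-class], or a numeric matrix/array
#'   of values on the [0, 1] scale (values above 1 are clipped).
#' @param sensor a [SensorModel-class] supplying noise parameters, bit depth
#'   and the default seed.
#' @param seed integer seed; `NA` draws from the current RNG stream (for
#'   callers managing their own seed).
#' @return a quantized [MosaicImage-class] when given a mosaic/matrix, or an
#'   integer array for array input.
#' @export
addNoiseAndQuantize <- function(image, sensor, seed = sensor@seed) {
  stopifnot(methods::is(sensor, "SensorModel"))
  wasMosaic <- methods::is(image, "MosaicImage")
  v <- if (wasMosaic) image@data else image
  if (any(v < 0)) .stopf("negative pre-noise values")
  run <- function() {
    n <- length(v)
    noisy <- v
    if (sensor@shotNoise > 0)
      noisy <- noisy + stats::rnorm(n, 0, sensor@shotNoise * sqrt(pmax(v, 0)))
    if (sensor@readNoise > 0)
      noisy <- noisy + stats::rnorm(n, 0, sensor@readNoise)
    mx <- 2^sensor@bitDepth - 1
    codes <- round(pmin(pmax(noisy, 0), 1) * mx)
    dim(codes) <- dim(v)
    codes
  }
  codes <- if (is.na(seed)) run() else .withSeed(seed, run())
  if (wasMosaic || is.matrix(codes))
    methods::new("MosaicImage",
                 data = if (is.matrix(codes)) codes else as.matrix(codes),
                 pattern = if (wasMosaic) image@pattern else "RGGB",
                 bitDepth = sensor@bitDepth)
  else codes
}

#' Generate a calibration set of synthetic strip images
#'
#' Renders `replicates` strips at every concentration of the grid, each with
#' its own deterministic sub-seed derived from the master seed. Per strip,
#' the target ratio is the scene's ground truth plus a Gaussian
#' strip-to-strip perturbation (`ratioNoiseSd`) emulating fabrication and
#' development variability; the image then passes through CFA sampling,
#' sensor noise and 8-bit quantization. Images are written as single-plane
#' grayscale PNG mosaics (or full RGB PNGs), together with a manifest CSV
#' mapping each file to its concentration, replicate, seed and ground-truth
#' ratio.
#'
#' @param outDir output directory (created if needed).
#' @param concentrations concentration grid in ng/mL; default the CK-MB
#'   study grid 0, 2, 4, 10, 50, 100.
#' @param replicates strips per concentration; default 10.
#' @param scene a template [StripScene-class]; its concentration is replaced
#'   level by level.
#' @param sensor a [SensorModel-class].
#' @param seed master seed (integer, mandatory).
#' @param ratioNoiseSd SD of the per-strip target-ratio perturbation;
#'   default 0.002.
#' @param format `"mosaic-png"` (raw CFA plane, default) or `"rgb-png"`.
#' @param labelK,refConcentration passed to [renderScene()].
#' @return invisibly, a list with `dir` and the manifest `data.frame`
#'   (columns filename, concentration_ng_per_ml, replicate, seed,
#'   truth_ratio).
#' @export
generateCalibrationSet <- function(outDir,
                                   concentrations = c(0, 2, 4, 10, 50, 100),
                                   replicates = 10,
                                   scene = makeStripScene(),
                                   sensor = makeSensorModel(),
                                   seed,
                                   ratioNoiseSd = 0.002,
                                   format = c("mosaic-png", "rgb-png"),
                                   labelK = 0.02, refConcentration = 100) {
  if (missing(seed)) .stopf("a master seed is mandatory")
  if (replicates < 1) .stopf("replicates must be >= 1")
  format <- match.arg(format)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(concentrations) * replicates)
  idx <- 0L
  for (li in seq_along(concentrations)) {
    sc <- scene
    sc@concentration <- concentrations[li]
    truth <- groundTruthRatio(sc)
    for (ri in seq_len(replicates)) {
      idx <- idx + 1L
      s <- .deriveSeed(seed, idx)
      fname <- sprintf("strip_L%02d_R%02d.png", li, ri)
      .withSeed(s, {
        target <- truth + stats::rnorm(1, 0, ratioNoiseSd)
        img <- renderScene(sc, sensor, targetRatio = target,
                           labelK = labelK,
                           refConcentration = refConcentration)
        if (format == "mosaic-png") {
          mq <- addNoiseAndQuantize(mosaicImage(img, sensor@cfaPattern),
                                    sensor, seed = NA)
          png::writePNG(mq@data / (2^sensor@bitDepth - 1),
                        file.path(outDir, fname))
        } else {
          codes <- addNoiseAndQuantize(img, sensor, seed = NA)
          png::writePNG(codes / (2^sensor@bitDepth - 1),
                        file.path(outDir, fname))
        }
      })
      rows[[idx]] <- data.frame(filename = fname,
                                concentration_ng_per_ml = concentrations[li],
                                replicate = ri, seed = s,
                                truth_ratio = truth)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(dir = outDir, manifest = manifest))
}
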