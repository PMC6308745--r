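#' Sampled optical spectrum
#'
#' A spectrum sampled on a strictly increasing wavelength grid. Used for
#' membrane reflectance, label extinction, channel sensitivity and
#' test-line-minus-background difference curves. The default working grid in
#' this package is 380--780 nm at 1 nm steps.
#'
#' @slot wavelength numeric, strictly increasing wavelength grid in nm.
#' @slot value numeric, one sample per grid point (unitless).
#'
#' @seealso [makeSpectrum()], [flatSpectrum()], [differenceSpectrum()],
#'   [peakWavelength()]
#' @export
setClass("Spectrum",
  representation(wavelength = "numeric", value = "numeric"),
  validity = function(object) {
    w <- object@wavelength; v <- object@value
    if (length(w) == 0L) return("empty wavelength grid")
    if (length(w) != length(v)) return("wavelength and value lengths differ")
    if (anyNA(w) || anyNA(v) || any(!is.finite(v)))
      return("missing or non-finite values")
    if (any(diff(w) <= 0)) return("wavelength grid must be strictly increasing")
    TRUE
  })

#' Spectral sensitivity of one Bayer colour channel
#'
#' The colour camera's red, green and blue Bayer filters pass bands centred
#' (for the sensor modelled here) at 613, 537 and 456 nm; an on-chip infrared
#' cut-off restricts the response to 400--700 nm. The sensitivity curve is
#' identically zero outside that window.
#'
#' @slot name one of `"red"`, `"green"`, `"blue"`.
#' @slot centerNm centre wavelength in nm.
#' @slot curve a [Spectrum-class] with the non-negative sensitivity.
#'
#' @seealso [bayerChannels()], [selectChannel()]
#' @export
setClass("ChannelResponse",
  representation(name = "character", centerNm = "numeric", curve = "Spectrum"),
  validity = function(object) {
    if (!object@name %in% c("red", "green", "blue"))
      return("channel name must be red, green or blue")
    v <- object@curve@value
    w <- object@curve@wavelength
    if (any(v < 0)) return("sensitivity curve must be non-negative")
    if (sum(v) <= 0) return("sensitivity curve integrates to zero")
    if (any(v[w < 400 | w > 700] != 0))
      return("sensitivity must be zero outside 400-700 nm")
    TRUE
  })

#' Optical model of a labelling particle
#'
#' Absorption band of the labelling nanoparticle, normalised to unit peak.
#' Colloidal gold has its plasmon band near 546 nm on the assay membrane;
#' brown iron-oxide particles absorb maximally near 487 nm.
#'
#' @slot name label identifier, e.g. `"gold"` or `"iron_oxide"`.
#' @slot bandCenterNm absorption-band centre in nm.
#' @slot bandWidthNm full width at half maximum of the band in nm.
#' @slot extinction a [Spectrum-class]; relative absorption per unit
#'   concentration-thickness, unique maximum 1 at `bandCenterNm`.
#'
#' @seealso [makeLabelModel()], [reflectanceSpectrum()]
#' @export
setClass("LabelModel",
  representation(name = "character", bandCenterNm = "numeric",
                 bandWidthNm = "numeric", extinction = "Spectrum"),
  validity = function(object) {
    e <- object@extinction@value
    if (any(e < 0)) return("extinction must be non-negative")
    w <- object@extinction@wavelength
    if (sum(e == max(e)) != 1L)
      return("extinction must have a unique global maximum")
    if (abs(w[which.max(e)] - object@bandCenterNm) > .Machine$double.eps^0.5 +
          max(diff(w)))
      return("extinction maximum must sit at bandCenterNm")
    if (object@bandWidthNm <= 0) return("bandWidthNm must be positive")
    TRUE
  })

#' Ground-truth description of a synthetic LFIA strip
#'
#' Geometry and optics of a simulated strip: a pale membrane carrying a darker
#' test line upstream and a control line downstream (flow runs left to right
#' along image columns), a labelling particle, and the concentration response
#' that maps analyte concentration to the noise-free I(b)/I(t) ratio.
#'
#' The response is either `linear`, ratio = a + b*c, or `langmuir`,
#' ratio = 1 + (a - 1 + b*c) / (1 + c/K), which reduces to the linear form as
#' the saturation constant K grows.
#'
#' @slot widthPx,heightPx image dimensions in pixels (even, for RGGB).
#' @slot testLineCenterPx,controlLineCenterPx line centre columns (1-based).
#' @slot lineWidthPx nominal line width in pixels.
#' @slot membraneReflectance a [Spectrum-class], baseline membrane reflectance.
#' @slot label a [LabelModel-class].
#' @slot concentration analyte concentration in ng/mL.
#' @slot controlStrength fractional attenuation of the control line in (0, 1).
#' @slot response named list: `mode` ("linear" or "langmuir"), `a`, `b`, `K`.
#'
#' @seealso [makeStripScene()], [groundTruthRatio()], [renderScene()]
#' @export
setClass("StripScene",
  representation(widthPx = "integer", heightPx = "integer",
                 testLineCenterPx = "integer", controlLineCenterPx = "integer",
                 lineWidthPx = "integer", membraneReflectance = "Spectrum",
                 label = "LabelModel", concentration = "numeric",
                 controlStrength = "numeric", response = "list"),
  validity = function(object) {
    if (object@widthPx < 4L || object@heightPx < 2L)
      return("image too small")
    if (object@testLineCenterPx >= object@controlLineCenterPx)
      return("test line must lie strictly upstream of the control line")
    if (object@lineWidthPx <= 0L) return("line width must be positive")
    if (object@concentration < 0) return("concentration must be >= 0")
    if (object@controlStrength <= 0 || object@controlStrength >= 1)
      return("controlStrength must be in (0, 1)")
    r <- object@response
    if (!all(c("mode", "a", "b", "K") %in% names(r)))
      return("response needs fields mode, a, b, K")
    if (!r$mode %in% c("linear", "langmuir"))
      return("response mode must be 'linear' or 'langmuir'")
    half <- object@lineWidthPx %/% 2L
    if (object@testLineCenterPx - half < 1L ||
        object@controlLineCenterPx + half > object@widthPx)
      return("lines fall outside the image")
    TRUE
  })

#' Camera / sensor model for strip simulation
#'
#' Bayer colour sensor: three channel responses, the RGGB mosaic phase, bit
#' depth, an illumination gain (scalar, or a matrix field for vignetting) and
#' a two-component noise model (shot noise with SD proportional to the square
#' root of the signal, plus additive read noise), on the internal [0, 1]
#' intensity scale.
#'
#' @slot channels list of three [ChannelResponse-class] objects (red, green,
#'   blue).
#' @slot cfaPattern CFA phase string; only `"RGGB"` (red at row 1, column 1)
#'   is implemented.
#' @slot bitDepth output bit depth; 8 gives code values 0--255.
#' @slot illuminationGain positive scalar, or positive matrix matched to the
#'   scene dimensions.
#' @slot shotNoise shot-noise scale s: SD contribution s*sqrt(signal).
#' @slot readNoise additive read-noise SD.
#' @slot seed integer RNG seed used by the noise stage.
#'
#' @seealso [makeSensorModel()], [addNoiseAndQuantize()]
#' @export
setClass("SensorModel",
  representation(channels = "list", cfaPattern = "character",
                 bitDepth = "integer", illuminationGain = "ANY",
                 shotNoise = "numeric", readNoise = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@channels) != 3L ||
        !all(vapply(object@channels, is, logical(1), "ChannelResponse")))
      return("channels must be a list of three ChannelResponse objects")
    nm <- vapply(object@channels, function(ch) ch@name, character(1))
    if (!identical(sort(nm), c("blue", "green", "red")))
      return("channels must cover red, green and blue")
    if (object@cfaPattern != "RGGB") return("only the RGGB pattern is supported")
    g <- object@illuminationGain
    if (!(is.numeric(g) && all(g > 0)))
      return("illuminationGain must be positive everywhere")
    if (object@shotNoise < 0 || object@readNoise < 0)
      return("noise parameters must be >= 0")
    TRUE
  })

#' Raw colour-filter-array image
#'
#' A single plane of CFA samples: each pixel carries the code value of the one
#' Bayer site (R, G or B) at that position. Values are integer code values in
#' [0, 2^bitDepth - 1] after [addNoiseAndQuantize()], or floats in [0, 1]
#' pre-quantization.
#'
#' @slot data numeric matrix (rows x columns), dimensions even in both axes.
#' @slot pattern CFA phase, `"RGGB"`.
#' @slot bitDepth bit depth of quantized data; `NA` while still continuous.
#'
#' @seealso [mosaicImage()], [demosaicPlanes()]
#' @export
setClass("MosaicImage",
  representation(data = "matrix", pattern = "character", bitDepth = "integer"),
  validity = function(object) {
    d <- dim(object@data)
    if (any(d %% 2L != 0L)) return("mosaic dimensions must be even for RGGB")
    if (object@pattern != "RGGB") return("only the RGGB pattern is supported")
    if (!is.na(object@bitDepth)) {
      mx <- 2^object@bitDepth - 1
      if (any(object@data < 0) || any(object@data > mx))
        return("code values outside [0, 2^bitDepth - 1]")
    }
    TRUE
  })

#' Single-channel intensity plane
#'
#' One colour channel of a strip image, normalised to [0, 1]. Provenance
#' records whether the plane came from native CFA sites (half resolution, no
#' interpolation), from bilinear demosaicing, or directly from an RGB file.
#'
#' @slot data numeric matrix in [0, 1].
#' @slot channel `"red"`, `"green"`, `"blue"` or `"original"` (channel mean).
#' @slot provenance `"native"`, `"bilinear"` or `"rgb"`.
#'
#' @seealso [demosaicPlanes()], [columnProfile()], [measureRatio()]
#' @export
setClass("ChannelPlane",
  representation(data = "matrix", channel = "character",
                 provenance = "character"),
  validity = function(object) {
    if (!all(is.finite(object@data))) return("plane contains non-finite values")
    if (any(object@data < 0) || any(object@data > 1))
      return("plane values must lie in [0, 1]")
    if (!object@channel %in% c("red", "green", "blue", "original"))
      return("unknown channel")
    TRUE
  })

#' Located test and control lines on a strip
#'
#' Result of dip detection on a column-mean intensity profile. The upstream
#' (smaller-column) dip is the test line, the downstream dip the control line.
#' A strip whose control line is missing is invalid (failed flow), not
#' negative; a strip with a control line but no visible test line is a valid
#' negative and the test-line extent falls back to its expected position.
#'
#' @slot testCenter,controlCenter line centre columns (NA if absent).
#' @slot testExtent,controlExtent integer `c(left, right)` column extents.
#' @slot profile numeric column-mean intensity profile the detection ran on.
#' @slot valid logical, control line present.
#' @slot testDetected logical, test line found (FALSE = fallback extent).
#'
#' @seealso [detectLines()], [measureRatio()]
#' @export
setClass("LineDetection",
  representation(testCenter = "numeric", testExtent = "integer",
                 controlCenter = "numeric", controlExtent = "integer",
                 profile = "numeric", valid = "logical",
                 testDetected = "logical"),
  validity = function(object) {
    if (length(object@testExtent) != 2L || length(object@controlExtent) != 2L)
      return("extents must be length-2 (left, right)")
    if (isTRUE(object@valid) && !is.na(object@testCenter) &&
        !is.na(object@controlCenter) &&
        object@testCenter >= object@controlCenter)
      return("test line centre must precede the control line centre")
    TRUE
  })

#' One strip's I(b)/I(t) measurement
#'
#' The quantification statistic: mean background intensity I(b) over mean
#' test-line intensity I(t), both taken over rectangular regions of interest
#' in a single channel plane. Because an illumination change scales both
#' means equally, the ratio cancels global illumination drift.
#'
#' @slot iT mean test-line ROI intensity (normalised [0, 1] scale).
#' @slot iB mean background ROI intensity.
#' @slot ratio iB / iT; >= 1 expected for non-negative concentrations.
#' @slot channel channel the plane came from.
#' @slot testCenter,controlCenter detected line centres (plane coordinates).
#' @slot flags character vector of QC flags (e.g. `"saturated"`,
#'   `"no_test_line"`).
#'
#' @seealso [measureRatio()], [analyzeImage()]
#' @export
setClass("RatioMeasurement",
  representation(iT = "numeric", iB = "numeric", ratio = "numeric",
                 channel = "character", testCenter = "numeric",
                 controlCenter = "numeric", flags = "character"),
  validity = function(object) {
    if (object@iT <= 0) return("I(t) must be positive")
    if (object@ratio < 0) return("ratio must be non-negative")
    TRUE
  })

#' Fitted concentration-response calibration
#'
#' Ordinary-least-squares line ratio = intercept + slope * concentration,
#' fitted on replicate-level data restricted to the linear range, with
#' per-level summary statistics and the R-squared of the fit.
#'
#' @slot intercept,slope OLS coefficients (ratio units; ratio per ng/mL).
#' @slot rSquared coefficient of determination on replicate-level points.
#' @slot linearRange numeric `c(0, upper)` in ng/mL.
#' @slot levelStats data.frame: concentration, n, mean, sd per level used.
#' @slot residualSd residual standard deviation of the fit.
#' @slot coefSe standard errors of `c(intercept, slope)`.
#'
#' @seealso [fitCalibration()], [detectionLimit()], [predictConcentration()]
#' @export
setClass("CalibrationModel",
  representation(intercept = "numeric", slope = "numeric",
                 rSquared = "numeric", linearRange = "numeric",
                 levelStats = "data.frame", residualSd = "numeric",
                 coefSe = "numeric"),
  validity = function(object) {
    if (nrow(object@levelStats) < 3L)
      return("calibration needs at least 3 concentration levels")
    if (object@rSquared < 0 || object@rSquared > 1)
      return("R-squared must lie in [0, 1]")
    TRUE
  })

## ---- accessors ----

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "ChannelResponse", function(x) x@curve@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "LabelModel", function(x) x@extinction@wavelength)

#' @rdname intensities
#' @export
setMethod("intensities", "Spectrum", function(x) x@value)
#' @rdname intensities
#' @export
setMethod("intensities", "ChannelResponse", function(x) x@curve@value)
#' @rdname intensities
#' @export
setMethod("intensities", "LabelModel", function(x) x@extinction@value)

#' @rdname channelName
#' @export
setMethod("channelName", "ChannelResponse", function(x) x@name)
#' @rdname channelName
#' @export
setMethod("channelName", "ChannelPlane", function(x) x@channel)
#' @rdname channelName
#' @export
setMethod("channelName", "RatioMeasurement", function(x) x@channel)

#' @rdname pixelData
#' @export
setMethod("pixelData", "MosaicImage", function(x) x@data)
#' @rdname pixelData
#' @export
setMethod("pixelData", "ChannelPlane", function(x) x@data)

#' @rdname intensityRatio
#' @export
setMethod("intensityRatio", "RatioMeasurement", function(x) x@ratio)

#' @rdname calibrationCoef
#' @export
setMethod("calibrationCoef", "CalibrationModel", function(object)
  c(intercept = object@intercept, slope = object@slope))

## ---- show methods ----

setMethod("show", "Spectrum", function(object) {
  w <- object@wavelength
  cat(sprintf("Spectrum: %d points, %g-%g nm, value range [%.4g, %.4g]\n",
              length(w), min(w), max(w), min(object@value), max(object@value)))
})

setMethod("show", "ChannelResponse", function(object) {
  cat(sprintf("ChannelResponse '%s': centre %g nm, window 400-700 nm\n",
              object@name, object@centerNm))
})

setMethod("show", "LabelModel", function(object) {
  cat(sprintf("LabelModel '%s': band centre %g nm, FWHM %g nm\n",
              object@name, object@bandCenterNm, object@bandWidthNm))
})

setMethod("show", "StripScene", function(object) {
  cat(sprintf(
    "StripScene %dx%d px: test line @%d, control @%d (width %d px)\n",
    object@widthPx, object@heightPx, object@testLineCenterPx,
    object@controlLineCenterPx, object@lineWidthPx))
  cat(sprintf("  label '%s', concentration %g ng/mL, %s response (truth ratio %.4f)\n",
              object@label@name, object@concentration, object@response$mode,
              groundTruthRatio(object)))
})

setMethod("show", "SensorModel", function(object) {
  ctr <- vapply(object@channels, function(ch) ch@centerNm, numeric(1))
  cat(sprintf(
    "SensorModel: %s CFA, %d-bit, channel centres %s nm, shot %.3g, read %.3g\n",
    object@cfaPattern, object@bitDepth, paste(ctr, collapse = "/"),
    object@shotNoise, object@readNoise))
})

setMethod("show", "MosaicImage", function(object) {
  q <- if (is.na(object@bitDepth)) "continuous" else
    sprintf("%d-bit", object@bitDepth)
  cat(sprintf("MosaicImage %dx%d (%s, %s)\n", nrow(object@data),
              ncol(object@data), object@pattern, q))
})

setMethod("show", "ChannelPlane", function(object) {
  cat(sprintf("ChannelPlane '%s' (%s): %dx%d, mean %.4f\n", object@channel,
              object@provenance, nrow(object@data), ncol(object@data),
              mean(object@data)))
})

setMethod("show", "LineDetection", function(object) {
  cat(sprintf(
    "LineDetection: test @%s [%s], control @%s [%s], valid=%s\n",
    format(object@testCenter), paste(object@testExtent, collapse = "-"),
    format(object@controlCenter), paste(object@controlExtent, collapse = "-"),
    object@valid))
})

setMethod("show", "RatioMeasurement", function(object) {
  fl <- if (length(object@flags)) paste(object@flags, collapse = ",") else "none"
  cat(sprintf(
    "RatioMeasurement [%s]: I(b)=%.4f, I(t)=%.4f, I(b)/I(t)=%.4f (flags: %s)\n",
    object@channel, object@iB, object@iT, object@ratio, fl))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: ratio = %.4f + %.4f * c, R^2 = %.4f\n",
              object@intercept, object@slope, object@rSquared))
  cat(sprintf("  linear range 0-%g ng/mL, %d levels, %d points\n",
              object@linearRange[2], nrow(object@levelStats),
              sum(object@levelStats$n)))
})
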