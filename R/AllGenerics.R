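#' @title Generics for lfiaQuant containers
#' @name lfiaQuant-generics
#' @keywords internal
NULL

#' Wavelength grid of a spectrum-like object
#'
#' @param x a \linkS4class{Spectrum}, \linkS4class{ChannelResponse} or
#'   \linkS4class{LabelModel}.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Sampled values of a spectrum-like object
#'
#' @param x a \linkS4class{Spectrum}, \linkS4class{ChannelResponse} or
#'   \linkS4class{LabelModel}.
#' @return numeric vector of intensities / sensitivities / extinctions.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Name of the colour channel carried by an object
#'
#' @param x a \linkS4class{ChannelResponse}, \linkS4class{ChannelPlane} or
#'   \linkS4class{RatioMeasurement}.
#' @return single character string.
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' Pixel data of an image-like object
#'
#' @param x a \linkS4class{MosaicImage} or \linkS4class{ChannelPlane}.
#' @return numeric or integer matrix.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' Ground-truth background/test-line intensity ratio of a synthetic scene
#'
#' @param scene a \linkS4class{StripScene}.
#' @param ... further arguments for methods.
#' @return numeric scalar, the noise-free I(b)/I(t) the scene encodes.
#' @export
setGeneric("groundTruthRatio", function(scene, ...)
  standardGeneric("groundTruthRatio"))

#' I(b)/I(t) ratio stored in a measurement
#'
#' @param x a \linkS4class{RatioMeasurement}.
#' @return numeric scalar.
#' @export
setGeneric("intensityRatio", function(x) standardGeneric("intensityRatio"))

#' Calibration coefficients
#'
#' @param object a \linkS4class{CalibrationModel}.
#' @return named numeric vector \code{c(intercept, slope)}.
#' @export
setGeneric("calibrationCoef", function(object)
  standardGeneric("calibrationCoef"))
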