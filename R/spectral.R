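#' Default wavelength grid
#'
#' The working grid for all spectra in this package: 380--780 nm in 1 nm
#' steps, covering the visible band with margin around the 400--700 nm sensor
#' window.
#'
#' @return numeric vector of wavelengths in nm.
#' @export
defaultWavelengthGrid <- function() seq(380, 780, by = 1)

#' Construct a Spectrum
#'
#' @param wavelength strictly increasing wavelength grid in nm.
#' @param value sampled values, same length.
#' @return a [Spectrum-class].
#' @examples
#' s <- makeSpectrum(400:700, rep(1, 301))
#' @export
makeSpectrum <- function(wavelength, value) {
  methods::new("Spectrum", wavelength = as.numeric(wavelength),
               value = as.numeric(value))
}

#' Spectrally flat spectrum
#'
#' Convenience constructor for a constant spectrum, e.g. an idealised white
#' membrane reflectance or a flat illuminant.
#'
#' @param value constant value (default 0.95, a pale nitrocellulose membrane).
#' @param wavelength wavelength grid (default [defaultWavelengthGrid()]).
#' @return a [Spectrum-class].
#' @export
flatSpectrum <- function(value = 0.95, wavelength = defaultWavelengthGrid()) {
  makeSpectrum(wavelength, rep(value, length(wavelength)))
}

#' Read / write spectra as two-column CSV
#'
#' The on-disk exchange format is a CSV with one header row and two columns,
#' `wavelength_nm` and `value`.
#'
#' @param path file path.
#' @return `readSpectrum` returns a [Spectrum-class]; `writeSpectrum`
#'   invisibly returns `path`.
#' @export
readSpectrum <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L)
    .stopf("spectrum CSV '%s' needs two columns (wavelength_nm, value)", path)
  makeSpectrum(df[[1]], df[[2]])
}

#' @rdname readSpectrum
#' @param s a [Spectrum-class] to write.
#' @export
writeSpectrum <- function(s, path) {
  stopifnot(methods::is(s, "Spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = s@wavelength, value = s@value),
    path, row.names = FALSE)
  invisible(path)
}

#' Build a labelling-particle absorption model
#'
#' Models the particle's absorption band as a Lorentzian with unit peak:
#' ext(lambda) = 1 / (1 + ((lambda - center) / (w/2))^2) with `w` the full
#' width at half maximum. Colloidal gold on the membrane absorbs maximally
#' near 546 nm; iron-oxide particles near 487 nm.
#'
#' @param name label identifier (`"gold"`, `"iron_oxide"`, or any string).
#' @param bandCenterNm band centre in nm; must lie inside the grid.
#' @param bandWidthNm FWHM in nm, > 0. Defaults: 80 for gold, 120 for iron
#'   oxide, 100 otherwise.
#' @param wavelength wavelength grid (default [defaultWavelengthGrid()]).
#' @return a [LabelModel-class].
#' @examples
#' gold <- makeLabelModel("gold")
#' peakWavelength(gold@extinction)  # 546
#' @export
makeLabelModel <- function(name, bandCenterNm = NULL, bandWidthNm = NULL,
                           wavelength = defaultWavelengthGrid()) {
  if (is.null(bandCenterNm))
    bandCenterNm <- switch(name, gold = 546, iron_oxide = 487,
      .stopf("no default band centre for label '%s'; supply bandCenterNm", name))
  if (is.null(bandWidthNm))
    bandWidthNm <- switch(name, gold = 80, iron_oxide = 120, 100)
  if (bandCenterNm < min(wavelength) || bandCenterNm > max(wavelength))
    .stopf("band centre %g nm lies outside the wavelength grid [%g, %g]",
           bandCenterNm, min(wavelength), max(wavelength))
  if (bandWidthNm <= 0) .stopf("bandWidthNm must be > 0")
  gamma <- bandWidthNm / 2
  ext <- 1 / (1 + ((wavelength - bandCenterNm) / gamma)^2)
  methods::new("LabelModel", name = name, bandCenterNm = bandCenterNm,
               bandWidthNm = bandWidthNm,
               extinction = makeSpectrum(wavelength, ext))
}

#' Reflectance of a test line under Beer-Lambert-style attenuation
#'
#' The line's reflectance is the membrane baseline attenuated exponentially by
#' the accumulated label: R(lambda) = R_mem(lambda) * exp(-k * c *
#' ext(lambda)). At zero concentration the membrane reflectance is returned
#' unchanged; the log-attenuation is linear in concentration.
#'
#' @param label a [LabelModel-class].
#' @param concentration analyte concentration (>= 0), ng/mL.
#' @param membraneReflectance a [Spectrum-class]; default flat 0.95.
#' @param k absorptivity scale per (ng/mL) of label accumulated in the line;
#'   default 0.02 gives roughly 7x peak attenuation at 100 ng/mL.
#' @return a [Spectrum-class] on the membrane's grid.
#' @export
reflectanceSpectrum <- function(label, concentration,
                                membraneReflectance = flatSpectrum(),
                                k = 0.02) {
  stopifnot(methods::is(label, "LabelModel"),
            methods::is(membraneReflectance, "Spectrum"))
  if (concentration < 0) .stopf("concentration must be >= 0")
  grid <- membraneReflectance@wavelength
  ext <- .onGrid(label@extinction, grid)
  makeSpectrum(grid,
               membraneReflectance@value * exp(-k * concentration * ext))
}

#' Test-line-minus-background difference spectrum
#'
#' Pointwise `background - test`; positive wherever the line absorbs more
#' light than the bare membrane. The wavelength of its maximum identifies the
#' band where the label's signal is strongest.
#'
#' @param background a [Spectrum-class] (membrane background).
#' @param test a [Spectrum-class] (test-line reflectance), same grid.
#' @return a [Spectrum-class].
#' @export
differenceSpectrum <- function(background, test) {
  stopifnot(methods::is(background, "Spectrum"), methods::is(test, "Spectrum"))
  if (!identical(background@wavelength, test@wavelength))
    .stopf("difference spectrum requires identical wavelength grids")
  makeSpectrum(background@wavelength, background@value - test@value)
}

#' Wavelength of the spectral maximum
#'
#' Returns the wavelength of the global maximum; ties are broken towards the
#' smallest wavelength. A constant spectrum has no meaningful peak: a warning
#' is emitted and the first grid wavelength returned.
#'
#' @param s a [Spectrum-class].
#' @return wavelength in nm.
#' @export
peakWavelength <- function(s) {
  stopifnot(methods::is(s, "Spectrum"))
  v <- s@value
  if (max(v) == min(v)) {
    warning("degenerate (constant) spectrum; returning the first grid value",
            call. = FALSE)
    return(s@wavelength[1L])
  }
  s@wavelength[which.max(v)]
}

#' Bayer channel responses of the reader camera
#'
#' Channel sensitivities modelled as Gaussians (default sigma 25 nm) at the
#' sensor's centre wavelengths -- red 613, green 537, blue 456 nm -- clipped
#' to zero outside the 400--700 nm window imposed by the on-chip infrared
#' cut-off filter.
#'
#' @param centers named numeric vector of centre wavelengths in nm.
#' @param sigma Gaussian width in nm.
#' @param wavelength wavelength grid.
#' @return list of three [ChannelResponse-class] objects (red, green, blue).
#' @export
bayerChannels <- function(centers = c(red = 613, green = 537, blue = 456),
                          sigma = 25,
                          wavelength = defaultWavelengthGrid()) {
  stopifnot(all(c("red", "green", "blue") %in% names(centers)))
  lapply(c("red", "green", "blue"), function(nm) {
    ctr <- centers[[nm]]
    v <- exp(-0.5 * ((wavelength - ctr) / sigma)^2)
    v[wavelength < 400 | wavelength > 700] <- 0
    methods::new("ChannelResponse", name = nm, centerNm = ctr,
                 curve = makeSpectrum(wavelength, v))
  })
}

#' Load channel responses from a CSV table
#'
#' Reads a four-column CSV (`wavelength_nm`, `red`, `green`, `blue`) into a
#' list of [ChannelResponse-class] objects, the same format as the packaged
#' preset `system.file("extdata", "bayer_channels_synthetic.csv", package =
#' "lfiaQuant")` (a synthetic stand-in for manufacturer curves, generated by
#' [bayerChannels()]). Channel centres are taken as the per-channel argmax.
#'
#' @param path CSV file path.
#' @return list of three [ChannelResponse-class] objects (red, green, blue).
#' @export
readChannelResponses <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "red", "green", "blue")
  if (!all(need %in% names(df)))
    .stopf("channel CSV '%s' needs columns %s", path,
           paste(need, collapse = ", "))
  lapply(c("red", "green", "blue"), function(nm) {
    v <- df[[nm]]
    methods::new("ChannelResponse", name = nm,
                 centerNm = df$wavelength_nm[which.max(v)],
                 curve = makeSpectrum(df$wavelength_nm, v))
  })
}

#' Select the most sensitive colour channel for a difference spectrum
#'
#' Scores each channel by the response-weighted integral
#' score = integral of diff(lambda) * curve(lambda) d lambda (trapezoid rule)
#' and returns the channel with the largest score. Ties are broken in the
#' order red, green, blue. With `method = "nearest"` the channel whose centre
#' wavelength is closest to the difference spectrum's peak is chosen instead
#' (a fast fallback; ties again by channel order).
#'
#' @param diff a [Spectrum-class], typically from [differenceSpectrum()].
#' @param channels list of [ChannelResponse-class]; default [bayerChannels()].
#' @param method `"integral"` (default) or `"nearest"`.
#' @return list with elements `channel` (name) and `scores` (named numeric).
#' @examples
#' gold <- makeLabelModel("gold")
#' d <- differenceSpectrum(flatSpectrum(),
#'                         reflectanceSpectrum(gold, 100))
#' selectChannel(d)$channel  # "green"
#' @export
selectChannel <- function(diff, channels = bayerChannels(),
                          method = c("integral", "nearest")) {
  stopifnot(methods::is(diff, "Spectrum"), length(channels) >= 1L)
  method <- match.arg(method)
  nm <- vapply(channels, function(ch) ch@name, character(1))
  ord <- order(match(nm, c("red", "green", "blue")))
  channels <- channels[ord]; nm <- nm[ord]
  if (method == "nearest") {
    pk <- peakWavelength(diff)
    ctr <- vapply(channels, function(ch) ch@centerNm, numeric(1))
    scores <- -abs(ctr - pk)
    names(scores) <- nm
    return(list(channel = nm[which.max(scores)], scores = scores))
  }
  grid <- diff@wavelength
  scores <- vapply(channels, function(ch)
    .trapz(grid, diff@value * .onGrid(ch@curve, grid)), numeric(1))
  names(scores) <- nm
  if (all(scores == 0))
    .stopf("no signal: every channel score is zero")
  list(channel = nm[which.max(scores)], scores = scores)
}
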