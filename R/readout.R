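#' Column-mean intensity profile
#'
#' Averages a channel plane over a band of rows, producing the 1-D profile
#' along the flow axis in which the test and control lines appear as dips.
#'
#' @param plane a [ChannelPlane-class] or numeric matrix.
#' @param rowBand integer `c(first, last)` rows; default the central 60% of
#'   rows, away from strip edges.
#' @return numeric vector, one mean per column.
#' @export
columnProfile <- function(plane, rowBand = NULL) {
  d <- if (methods::is(plane, "ChannelPlane")) plane@data else plane
  h <- nrow(d)
  if (is.null(rowBand)) rowBand <- .centralRowBand(h)
  if (rowBand[1] < 1 || rowBand[2] > h || rowBand[1] > rowBand[2])
    .stopf("row band [%d, %d] invalid for a %d-row plane",
           rowBand[1], rowBand[2], h)
  colMeans(d[rowBand[1]:rowBand[2], , drop = FALSE])
}

.centralRowBand <- function(h, frac = 0.6) {
  lo <- max(1L, floor(h * (1 - frac) / 2) + 1L)
  hi <- min(h, ceiling(h * (1 + frac) / 2))
  c(lo, hi)
}

## dip finder: columns deeper than minProminence below the median baseline,
## grouped into runs; each dip's extent is its full width at half prominence
## and its centre the depth-weighted centroid over that width
.findDips <- function(profile, minProminence, minSeparation) {
  baseline <- stats::median(profile)
  depth <- baseline - profile
  cand <- which(depth > minProminence)
  if (length(cand) == 0L) return(list())
  breaks <- which(diff(cand) > max(2L, minSeparation %/% 2L))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(cand))
  dips <- lapply(seq_along(starts), function(i) {
    cols <- cand[starts[i]:ends[i]]
    dmax <- max(depth[cols])
    half <- cols[depth[cols] >= dmax / 2]
    list(center = sum(half * depth[half]) / sum(depth[half]),
         extent = c(min(half), max(half)), depth = dmax)
  })
  dips[order(vapply(dips, `[[`, numeric(1), "center"))]
}

#' Locate the test and control lines in an intensity profile
#'
#' Detects intensity dips by their prominence below the median baseline. The
#' upstream dip is assigned to the test line and the downstream dip to the
#' control line. Assay logic: a missing control line means the strip is
#' invalid (flow failure), not negative; a control line without a test line
#' is a valid negative, and the test-line extent falls back to the expected
#' position supplied in the configuration.
#'
#' @param profile numeric column-mean profile (from [columnProfile()]).
#' @param minProminence minimum dip depth below baseline (default 0.01 on
#'   the [0, 1] intensity scale).
#' @param minSeparation minimum column separation between lines.
#' @param expectedTest,expectedControl expected line centre columns (in the
#'   profile's own coordinates); used to classify a lone dip and as the
#'   test-line fallback.
#' @param fallbackHalfWidth half width of the fallback test ROI, columns.
#' @return a [LineDetection-class].
#' @export
detectLines <- function(profile, minProminence = 0.01, minSeparation = 10,
                        expectedTest = NULL, expectedControl = NULL,
                        fallbackHalfWidth = 3L) {
  if (length(profile) <= 2 * minSeparation)
    .stopf("profile too short (%d columns) for minSeparation %d",
           length(profile), minSeparation)
  dips <- .findDips(profile, minProminence, minSeparation)
  mkDet <- function(tc, te, td, cc, ce) {
    methods::new("LineDetection", testCenter = tc,
                 testExtent = as.integer(te), controlCenter = cc,
                 controlExtent = as.integer(ce), profile = profile,
                 valid = TRUE, testDetected = td)
  }
  fallbackTest <- function(cc, ce) {
    if (is.null(expectedTest))
      .stopf("no test line detected and no expected position configured")
    mkDet(as.numeric(expectedTest),
          c(expectedTest - fallbackHalfWidth,
            expectedTest + fallbackHalfWidth), FALSE, cc, ce)
  }
  if (length(dips) == 0L)
    .stopf("invalid assay: no control line detected")
  if (length(dips) == 1L) {
    d <- dips[[1L]]
    if (!is.null(expectedTest) && !is.null(expectedControl) &&
        abs(d$center - expectedTest) < abs(d$center - expectedControl))
      .stopf("invalid assay: test line present but no control line")
    return(fallbackTest(d$center, d$extent))
  }
  if (length(dips) > 2L) {      # keep the two deepest, restore flow order
    keep <- order(vapply(dips, `[[`, numeric(1), "depth"),
                  decreasing = TRUE)[1:2]
    dips <- dips[sort(keep)]
  }
  mkDet(dips[[1L]]$center, dips[[1L]]$extent, TRUE,
        dips[[2L]]$center, dips[[2L]]$extent)
}

#' Measure the I(b)/I(t) intensity ratio
#'
#' I(t) is the mean intensity over the test-line region of interest (the
#' detected extent across the row band); I(b) is the mean over an
#' equal-width background region centred midway between the test and
#' control lines. Their ratio I(b)/I(t) rises as the test line darkens with
#' analyte concentration, and is invariant to global illumination scaling
#' since both means scale equally.
#'
#' @param plane a [ChannelPlane-class] or numeric matrix.
#' @param detection a [LineDetection-class] from [detectLines()].
#' @param rowBand integer `c(first, last)`; default central 60% of rows.
#' @param saturationFrac fraction of ROI pixels at full code value above
#'   which the `"saturated"` QC flag is raised.
#' @return a [RatioMeasurement-class].
#' @export
measureRatio <- function(plane, detection, rowBand = NULL,
                         saturationFrac = 0.005) {
  d <- if (methods::is(plane, "ChannelPlane")) plane@data else plane
  chan <- if (methods::is(plane, "ChannelPlane")) plane@channel else "unknown"
  stopifnot(methods::is(detection, "LineDetection"))
  h <- nrow(d); w <- ncol(d)
  if (is.null(rowBand)) rowBand <- .centralRowBand(h)
  rows <- rowBand[1]:rowBand[2]
  te <- detection@testExtent
  if (any(is.na(te)) || te[1] < 1L || te[2] > w)
    .stopf("test ROI [%s] outside the %d-column plane",
           paste(te, collapse = ", "), w)
  roiT <- d[rows, te[1]:te[2], drop = FALSE]
  width <- te[2] - te[1] + 1L
  bgCenter <- (detection@testCenter + detection@controlCenter) / 2
  bgStart <- as.integer(round(bgCenter - width / 2 + 0.5))
  bgEnd <- bgStart + width - 1L
  if (bgStart <= te[2] || bgEnd >= detection@controlExtent[1])
    .stopf("background ROI [%d, %d] overlaps a line", bgStart, bgEnd)
  roiB <- d[rows, bgStart:bgEnd, drop = FALSE]
  iT <- mean(roiT); iB <- mean(roiB)
  if (iT == 0) .stopf("degenerate image: test ROI intensity is zero")
  flags <- character(0)
  if (mean(roiT >= 1) > saturationFrac || mean(roiB >= 1) > saturationFrac)
    flags <- c(flags, "saturated")
  if (!detection@testDetected) flags <- c(flags, "no_test_line")
  methods::new("RatioMeasurement", iT = iT, iB = iB, ratio = iB / iT,
               channel = chan, testCenter = detection@testCenter,
               controlCenter = detection@controlCenter, flags = flags)
}

#' Default readout configuration
#'
#' ROI and detection settings used by [analyzeImage()]. Expected line
#' positions are given in full-resolution image coordinates and are scaled
#' automatically when native half-resolution planes are analysed.
#'
#' @param expectedTest,expectedControl expected line centre columns
#'   (full-resolution coordinates); defaults match [makeStripScene()].
#' @param minProminence,minSeparation dip-detection settings (see
#'   [detectLines()]); `minSeparation` in full-resolution columns.
#' @param rowBandFrac central fraction of rows averaged into the profile.
#' @param demosaic `"native"` or `"bilinear"` (see [demosaicPlanes()]).
#' @param pattern CFA phase for raw mosaic input.
#' @param luma if `TRUE`, the `"original"` channel is the Rec.601
#'   luma-weighted mean instead of the unweighted channel mean.
#' @return named list of settings.
#' @export
readoutConfig <- function(expectedTest = 150, expectedControl = 300,
                          minProminence = 0.01, minSeparation = 20,
                          rowBandFrac = 0.6, demosaic = "native",
                          pattern = "RGGB", luma = FALSE) {
  list(expectedTest = expectedTest, expectedControl = expectedControl,
       minProminence = minProminence, minSeparation = minSeparation,
       rowBandFrac = rowBandFrac, demosaic = demosaic, pattern = pattern,
       luma = luma)
}

.readImageFile <- function(path) {
  if (!file.exists(path)) .stopf("cannot read image '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      .stopf("the 'tiff' package is required to read TIFF input")
    tiff::readTIFF(path)
  } else .stopf("unsupported image format '%s'", ext)
}

## planes (list of ChannelPlane) + coordinate scale from file or in-memory
## input; grayscale input is treated as a raw CFA mosaic
.extractPlanes <- function(img, config) {
  if (is.matrix(img)) {
    if (any(dim(img) %% 2L != 0L))
      .stopf("raw mosaic dimensions must be even, got %dx%d",
             nrow(img), ncol(img))
    planes <- demosaicPlanes(img, mode = config$demosaic,
                             pattern = config$pattern)
    scale <- if (config$demosaic == "native") 0.5 else 1
  } else if (length(dim(img)) == 3L) {
    img <- img[, , 1:3, drop = FALSE]     # drop alpha if present
    planes <- mapply(function(i, nm)
      methods::new("ChannelPlane", data = pmin(pmax(img[, , i], 0), 1),
                   channel = nm, provenance = "rgb"),
      1:3, c("red", "green", "blue"), SIMPLIFY = FALSE)
    names(planes) <- c("red", "green", "blue")
    scale <- 1
  } else .stopf("unsupported image data (need a matrix or h x w x 3 array)")
  list(planes = planes, scale = scale)
}

.originalPlane <- function(planes, luma = FALSE) {
  wts <- if (luma) c(0.299, 0.587, 0.114) else rep(1 / 3, 3)
  d <- wts[1] * planes$red@data + wts[2] * planes$green@data +
    wts[3] * planes$blue@data
  methods::new("ChannelPlane", data = d, channel = "original",
               provenance = planes$red@provenance)
}

#' Analyse one strip image into a ratio measurement
#'
#' Loads an image (8-bit RGB PNG/TIFF, or a single-plane raw CFA mosaic),
#' extracts the requested channel plane, computes the column profile,
#' locates the test and control lines, and measures I(b)/I(t). The
#' `"original"` channel is the unweighted mean of the three colour planes
#' (the no-channel-separation readout).
#'
#' @param image file path, numeric matrix (raw mosaic) or `h x w x 3` array.
#' @param channel `"green"`, `"red"`, `"blue"` or `"original"`.
#' @param config settings list from [readoutConfig()].
#' @return a [RatioMeasurement-class].
#' @export
analyzeImage <- function(image, channel = c("green", "red", "blue",
                                            "original"),
                         config = readoutConfig()) {
  channel <- match.arg(channel)
  img <- if (is.character(image)) .readImageFile(image) else image
  ex <- .extractPlanes(img, config)
  plane <- if (channel == "original") .originalPlane(ex$planes, config$luma)
           else ex$planes[[channel]]
  h <- nrow(plane@data)
  band <- .centralRowBand(h, config$rowBandFrac)
  profile <- columnProfile(plane, band)
  det <- detectLines(profile,
                     minProminence = config$minProminence,
                     minSeparation = max(4L,
                       as.integer(config$minSeparation * ex$scale)),
                     expectedTest = round(config$expectedTest * ex$scale),
                     expectedControl = round(config$expectedControl *
                                               ex$scale))
  measureRatio(plane, det, rowBand = band)
}

#' Batch strip analysis
#'
#' Runs [analyzeImage()] over a set of files and channels, returning one row
#' per (image, channel).
#'
#' @param paths character vector of image files.
#' @param channels channels to extract for every image.
#' @param config settings list from [readoutConfig()].
#' @return data.frame with columns image, channel, I_t, I_b, ratio,
#'   test_center, control_center, flags.
#' @export
analyzeStrips <- function(paths,
                          channels = c("red", "green", "blue", "original"),
                          config = readoutConfig()) {
  rows <- list()
  for (p in paths) for (ch in channels) {
    m <- analyzeImage(p, channel = ch, config = config)
    rows[[length(rows) + 1L]] <- data.frame(
      image = basename(p), channel = ch, I_t = m@iT, I_b = m@iB,
      ratio = m@ratio, test_center = m@testCenter,
      control_center = m@controlCenter,
      flags = paste(m@flags, collapse = ";"))
  }
  do.call(rbind, rows)
}

#' Analyse a simulated calibration set
#'
#' Convenience wrapper: reads the manifest written by
#' [generateCalibrationSet()], analyses every image in the requested
#' channels, and joins the per-image metadata (concentration, replicate,
#' ground-truth ratio) onto the measurements.
#'
#' @param dir directory containing images and `manifest.csv`.
#' @param channels channels to extract.
#' @param config settings list from [readoutConfig()].
#' @return data.frame: manifest columns plus channel, I_t, I_b, ratio,
#'   test_center, control_center, flags.
#' @export
analyzeCalibrationSet <- function(dir,
                                  channels = c("red", "green", "blue",
                                               "original"),
                                  config = readoutConfig()) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) .stopf("no manifest.csv in '%s'", dir)
  manifest <- utils::read.csv(mpath)
  res <- analyzeStrips(file.path(dir, manifest$filename), channels, config)
  merge(manifest, res, by.x = "filename", by.y = "image", sort = FALSE)
}
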