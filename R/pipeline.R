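#' Default end-to-end pipeline configuration
#'
#' A nested list describing every stage: scene geometry and response, sensor
#' model, simulation grid and replicates, readout settings, calibration and
#' comparison settings. Serialisable to YAML via [writePipelineConfig()].
#' The master seed drives all randomness through documented per-image
#' sub-seeds and is mandatory.
#'
#' @param seed master seed (integer).
#' @return named configuration list.
#' @export
defaultPipelineConfig <- function(seed) {
  if (missing(seed)) .stopf("a master seed is mandatory")
  list(
    seed = as.integer(seed),
    scene = list(widthPx = 400L, heightPx = 120L, testLineCenterPx = 150L,
                 controlLineCenterPx = 300L, lineWidthPx = 12L,
                 membraneReflectance = 0.95, label = "gold",
                 controlStrength = 0.3,
                 response = list(mode = "linear", a = 1.0449, b = 0.0156,
                                 K = 100)),
    sensor = list(bitDepth = 8L, illuminationGain = 0.92, shotNoise = 0.002,
                  readNoise = 0.002),
    simulate = list(concentrations = c(0, 2, 4, 10, 50, 100),
                    replicates = 10L, ratioNoiseSd = 0.002,
                    format = "mosaic-png"),
    analyze = list(channels = c("red", "green", "blue", "original"),
                   demosaic = "native", minProminence = 0.01,
                   minSeparation = 20L, rowBandFrac = 0.6),
    calibrate = list(channel = "green", rangeTolerance = 0.10,
                     rangeLimit = NULL, lodMethod = "three_sigma"),
    compare = list(reference = "original", m = 3L)
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure and invariants (mandatory master seed, test line
#' strictly upstream of the control line, positive dimensions, known channel
#' and response mode) before any work is done.
#'
#' @param config configuration list.
#' @return the config, invisibly; errors on the first violation.
#' @export
validatePipelineConfig <- function(config) {
  need <- c("seed", "scene", "sensor", "simulate", "analyze", "calibrate",
            "compare")
  miss <- setdiff(need, names(config))
  if (length(miss)) .stopf("config missing sections: %s",
                           paste(miss, collapse = ", "))
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    .stopf("config requires an integer master seed")
  sc <- config$scene
  if (sc$testLineCenterPx >= sc$controlLineCenterPx)
    .stopf("invalid config: test line must be upstream of the control line")
  if (sc$widthPx <= 0 || sc$heightPx <= 0 || sc$lineWidthPx <= 0)
    .stopf("invalid config: non-positive scene dimensions")
  if (!sc$response$mode %in% c("linear", "langmuir"))
    .stopf("invalid config: unknown response mode '%s'", sc$response$mode)
  if (!config$calibrate$channel %in% c("red", "green", "blue", "original"))
    .stopf("invalid config: unknown calibration channel '%s'",
           config$calibrate$channel)
  if (any(config$simulate$concentrations < 0) ||
      config$simulate$replicates < 1)
    .stopf("invalid config: bad simulation grid")
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `readPipelineConfig` returns the validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  validatePipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.sceneFromConfig <- function(cf, concentration = 0) {
  makeStripScene(widthPx = cf$widthPx, heightPx = cf$heightPx,
                 testLineCenterPx = cf$testLineCenterPx,
                 controlLineCenterPx = cf$controlLineCenterPx,
                 lineWidthPx = cf$lineWidthPx,
                 membraneReflectance = flatSpectrum(cf$membraneReflectance),
                 label = makeLabelModel(cf$label),
                 concentration = concentration,
                 controlStrength = cf$controlStrength,
                 response = cf$response)
}

.sensorFromConfig <- function(cf, seed) {
  makeSensorModel(bitDepth = cf$bitDepth,
                  illuminationGain = cf$illuminationGain,
                  shotNoise = cf$shotNoise, readNoise = cf$readNoise,
                  seed = seed)
}

#' Run the full simulate - analyze - calibrate - compare pipeline
#'
#' Given a validated configuration, generates the synthetic calibration set,
#' analyses every image in every requested channel, fits the calibration for
#' the configured channel (linear range, OLS coefficients, R-squared, limit
#' of detection), compares the channel methods against the reference by
#' Bonferroni-adjusted pairwise tests, and writes all artifacts into the run
#' directory: `images/` + `manifest.csv`, `results.csv`,
#' `calibration.json`, `comparison.csv`, `run.log`, and `run_manifest.csv`
#' with an MD5 checksum per output file. Deterministic given the master
#' seed.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or path
#'   to a YAML file.
#' @param outDir run directory, created if needed.
#' @return invisibly, a list with `dir`, `results` (data.frame),
#'   `calibration` ([CalibrationModel-class]), `lod`, `linearRange`, and
#'   `comparison` (data.frame).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(fmt, ...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = logPath, append = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    logLine("stage simulate: grid {%s} x %d replicates",
            paste(config$simulate$concentrations, collapse = ", "),
            config$simulate$replicates)
    scene <- .sceneFromConfig(config$scene)
    sensor <- .sensorFromConfig(config$sensor, config$seed)
    sim <- generateCalibrationSet(
      file.path(outDir, "images"),
      concentrations = config$simulate$concentrations,
      replicates = config$simulate$replicates,
      scene = scene, sensor = sensor, seed = config$seed,
      ratioNoiseSd = config$simulate$ratioNoiseSd,
      format = config$simulate$format)
    file.copy(file.path(sim$dir, "manifest.csv"),
              file.path(outDir, "manifest.csv"), overwrite = TRUE)

    stage <- "analyze"
    rc <- readoutConfig(expectedTest = config$scene$testLineCenterPx,
                        expectedControl = config$scene$controlLineCenterPx,
                        minProminence = config$analyze$minProminence,
                        minSeparation = config$analyze$minSeparation,
                        rowBandFrac = config$analyze$rowBandFrac,
                        demosaic = config$analyze$demosaic)
    results <- analyzeCalibrationSet(sim$dir,
                                     channels = config$analyze$channels,
                                     config = rc)
    for (i in seq_len(nrow(results)))
      logLine("analyzed %s [%s]: ratio=%.4f flags=%s",
              results$filename[i], results$channel[i], results$ratio[i],
              ifelse(results$flags[i] == "", "none", results$flags[i]))
    utils::write.csv(results, file.path(outDir, "results.csv"),
                     row.names = FALSE)

    stage <- "calibrate"
    chan <- config$calibrate$channel
    dch <- results[results$channel == chan, ]
    agg <- stats::aggregate(ratio ~ concentration_ng_per_ml, dch, mean)
    upper <- if (!is.null(config$calibrate$rangeLimit))
      config$calibrate$rangeLimit
    else linearRange(agg$concentration_ng_per_ml, agg$ratio,
                     tolerance = config$calibrate$rangeTolerance)
    model <- fitCalibration(dch$concentration_ng_per_ml, dch$ratio,
                            rangeLimit = upper)
    blanks <- dch$ratio[dch$concentration_ng_per_ml == 0]
    lod <- detectionLimit(model, blanks,
                          method = config$calibrate$lodMethod)
    calib <- list(channel = chan, intercept = model@intercept,
                  slope = model@slope, r_squared = model@rSquared,
                  linear_range_ng_per_ml = c(0, upper),
                  lod_ng_per_ml = lod,
                  n_levels = nrow(model@levelStats),
                  n_points = sum(model@levelStats$n))
    jsonlite::write_json(calib, file.path(outDir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    logLine("calibration [%s]: ratio = %.4f + %.4f c, R2 = %.4f, range 0-%g, LOD %.3g",
            chan, model@intercept, model@slope, model@rSquared, upper, lod)

    stage <- "compare"
    cmpData <- data.frame(channel = results$channel,
                          concentration = results$concentration_ng_per_ml,
                          ratio = results$ratio)
    cmp <- compareChannels(cmpData[cmpData$concentration > 0, ],
                           reference = config$compare$reference,
                           m = config$compare$m)
    utils::write.csv(cmp, file.path(outDir, "comparison.csv"),
                     row.names = FALSE)

    stage <- "manifest"
    outs <- c("manifest.csv", "results.csv", "calibration.json",
              "comparison.csv")
    sums <- tools::md5sum(file.path(outDir, outs))
    utils::write.csv(data.frame(file = outs, md5 = unname(sums)),
                     file.path(outDir, "run_manifest.csv"),
                     row.names = FALSE)
    logLine("pipeline complete")
    list(dir = outDir, results = results, calibration = model,
         lod = lod, linearRange = c(0, upper), comparison = cmp)
  }, error = function(e) {
    logLine("FAILED at stage %s: %s", stage, conditionMessage(e))
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}
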