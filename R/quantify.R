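#' Fit a linear calibration of ratio on concentration
#'
#' Ordinary least squares of the I(b)/I(t) ratio on analyte concentration,
#' restricted to levels at or below `rangeLimit`. R-squared is computed on
#' the replicate-level points.
#'
#' @param concentrations numeric, one per measurement (ng/mL).
#' @param ratios numeric, the I(b)/I(t) measurements.
#' @param rangeLimit upper concentration bound of the fit (default
#'   unlimited); typically the output of [linearRange()].
#' @return a [CalibrationModel-class].
#' @examples
#' cc <- c(0, 2, 4, 10)
#' fitCalibration(cc, 1.0449 + 0.0156 * cc)
#' @export
fitCalibration <- function(concentrations, ratios, rangeLimit = Inf) {
  stopifnot(length(concentrations) == length(ratios))
  keep <- concentrations <= rangeLimit & !is.na(ratios)
  cc <- concentrations[keep]; rr <- ratios[keep]
  if (length(unique(cc)) < 3L)
    .stopf("calibration needs >= 3 distinct concentration levels within the range limit")
  fit <- stats::lm(rr ~ cc)
  if (any(is.na(stats::coef(fit)))) .stopf("rank-deficient calibration design")
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  r2 <- if (is.nan(sm$r.squared)) 1 else min(max(sm$r.squared, 0), 1)
  stats <- do.call(rbind, lapply(split(rr, cc), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)))
  stats <- data.frame(concentration = as.numeric(rownames(stats)), stats,
                      row.names = NULL)
  methods::new("CalibrationModel",
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               rSquared = r2,
               linearRange = c(0, max(cc)),
               levelStats = stats[order(stats$concentration), ],
               residualSd = sm$sigma,
               coefSe = unname(sm$coefficients[, "Std. Error"]))
}

#' Upper bound of the linear range
#'
#' Finds the largest prefix {0, ..., c_k} of the concentration grid on which
#' a straight line still describes the per-level mean ratios: the prefix OLS
#' fit must leave every positive level's relative lack of fit
#' |mean - fit| / (fit - intercept) at or below `tolerance`. The denominator
#' is the fitted signal above baseline, so the criterion measures relative
#' departure of the response, not of the raw ratio; the blank level anchors
#' the fit but is not itself tested (its above-baseline signal is zero).
#'
#' @param concentrations sorted concentration grid starting at 0 (ng/mL).
#' @param levelMeans mean ratio per level, same length.
#' @param tolerance maximum relative lack of fit (default 0.10).
#' @return upper bound of the linear range, ng/mL.
#' @export
linearRange <- function(concentrations, levelMeans, tolerance = 0.10) {
  stopifnot(length(concentrations) == length(levelMeans))
  if (is.unsorted(concentrations, strictly = TRUE))
    .stopf("concentration grid must be sorted strictly ascending")
  if (concentrations[1] != 0) .stopf("concentration grid must start at 0")
  n <- length(concentrations)
  for (k in n:3) {
    cc <- concentrations[1:k]; mm <- levelMeans[1:k]
    fit <- stats::lm(mm ~ cc)
    b0 <- stats::coef(fit)[1]
    fitted <- stats::fitted(fit)
    pos <- cc > 0
    signal <- fitted[pos] - b0
    rel <- ifelse(signal > 0, abs(mm[pos] - fitted[pos]) / signal, Inf)
    if (all(rel <= tolerance)) return(concentrations[k])
  }
  .stopf("linear range undetermined: no prefix of >= 3 levels is linear within tolerance %g",
         tolerance)
}

#' Limit of detection from blank replicates
#'
#' Default `"three_sigma"` criterion: LOD = 3 * SD(blank ratios) / slope,
#' the concentration whose expected response rises three blank standard
#' deviations above the blank. The `"empirical"` alternative returns the
#' lowest tested concentration whose mean ratio exceeds the blank mean plus
#' three blank SDs.
#'
#' @param model a [CalibrationModel-class] with positive slope.
#' @param blankRatios numeric, >= 3 replicate ratios at concentration 0.
#' @param method `"three_sigma"` (default) or `"empirical"`.
#' @return limit of detection in ng/mL.
#' @examples
#' m <- fitCalibration(c(0, 2, 4, 10), 1.0449 + 0.0156 * c(0, 2, 4, 10))
#' detectionLimit(m, c(1.04, 1.05, 1.06))
#' @export
detectionLimit <- function(model, blankRatios,
                           method = c("three_sigma", "empirical")) {
  method <- match.arg(method)
  stopifnot(methods::is(model, "CalibrationModel"))
  if (length(blankRatios) < 3L) .stopf("need >= 3 blank replicates")
  if (model@slope <= 0) .stopf("LOD undefined for non-positive slope")
  if (method == "three_sigma")
    return(3 * stats::sd(blankRatios) / model@slope)
  thr <- mean(blankRatios) + 3 * stats::sd(blankRatios)
  ls <- model@levelStats
  above <- ls$concentration > 0 & ls$mean > thr
  if (!any(above)) .stopf("no tested level exceeds blank + 3 SD")
  min(ls$concentration[above])
}

#' Invert a calibration: ratio to concentration
#'
#' Applies c = (ratio - intercept) / slope. Estimates below zero are clamped
#' to 0 and flagged; estimates below the LOD (when supplied) or above the
#' model's linear range are flagged.
#'
#' @param model a [CalibrationModel-class].
#' @param ratio numeric vector of measured I(b)/I(t) values.
#' @param lod optional limit of detection, ng/mL.
#' @return data.frame with columns ratio, concentration, flag (`""`,
#'   `"clamped"`, `"below_lod"`, `"above_linear_range"`).
#' @export
predictConcentration <- function(model, ratio, lod = NULL) {
  stopifnot(methods::is(model, "CalibrationModel"))
  if (model@slope <= 0) .stopf("cannot invert a non-positive slope")
  conc <- (ratio - model@intercept) / model@slope
  flag <- rep("", length(conc))
  flag[conc < 0] <- "clamped"
  conc <- pmax(conc, 0)
  if (!is.null(lod)) flag[flag == "" & conc < lod] <- "below_lod"
  tol <- 1e-8 * max(1, model@linearRange[2])
  flag[flag == "" & conc > model@linearRange[2] + tol] <- "above_linear_range"
  data.frame(ratio = ratio, concentration = conc, flag = flag)
}

#' Compare channel readout methods by one-way ANOVA with Bonferroni
#' correction
#'
#' At each concentration level, fits a one-way ANOVA of the replicate ratios
#' across the readout methods (red, green, blue, original), then tests each
#' colour channel against the reference method with a pooled-variance
#' pairwise t-test whose p-value is Bonferroni-adjusted for the `m`
#' comparisons per level (adjusted p = min(1, m * p)).
#'
#' @param data data.frame with columns `channel`, `concentration`, `ratio`
#'   (one row per replicate measurement), e.g. from
#'   [analyzeCalibrationSet()].
#' @param reference reference method; default `"original"`.
#' @param m number of comparisons per level for the Bonferroni factor;
#'   default the 3 colour channels.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per (concentration, comparison):
#'   concentration, comparison, difference_of_means, t, p, p_adjusted,
#'   significant.
#' @export
compareChannels <- function(data, reference = "original", m = 3,
                            alpha = 0.05) {
  stopifnot(all(c("channel", "concentration", "ratio") %in% names(data)))
  if (!reference %in% data$channel)
    .stopf("reference method '%s' absent from the data", reference)
  allCh <- unique(as.character(data$channel))
  rows <- list()
  for (conc in sort(unique(data$concentration))) {
    d <- data[data$concentration == conc, ]
    ns <- table(factor(as.character(d$channel), levels = allCh))
    if (any(ns < 2L)) {
      warning(sprintf(
        "concentration %g: groups with < 2 replicates, level omitted", conc),
        call. = FALSE)
      next
    }
    d$channel <- factor(d$channel)
    av <- stats::aov(ratio ~ channel, data = d)
    mse <- sum(stats::residuals(av)^2) / av$df.residual
    means <- tapply(d$ratio, d$channel, mean)
    others <- setdiff(levels(d$channel), reference)
    for (ch in others) {
      diffm <- means[[ch]] - means[[reference]]
      se <- sqrt(mse * (1 / ns[[ch]] + 1 / ns[[reference]]))
      tstat <- diffm / se
      p <- 2 * stats::pt(-abs(tstat), av$df.residual)
      padj <- min(1, m * p)
      rows[[length(rows) + 1L]] <- data.frame(
        concentration = conc,
        comparison = sprintf("%s vs. %s", reference, ch),
        difference_of_means = diffm, t = tstat, p = p, p_adjusted = padj,
        significant = padj < alpha)
    }
  }
  if (length(rows) == 0L) .stopf("no level had enough replicates to compare")
  do.call(rbind, rows)
}
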