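## Per-species d-to-h calibration: OLS fit, parallel upper-boundary line,
## underestimation evaluation, and the packaged published coefficients.

#' Fit the per-species h(d) linear model
#'
#' Ordinary least squares of total flower height \code{h} on diameter
#' \code{d} (both mm) for one species, on a seeded random train split
#' (default 80/20). Test indices are retained for later underestimation
#' evaluation.
#'
#' @param data measurements data.frame (\code{species, d_mm, h_mm}).
#' @param species which species to fit.
#' @param trainFrac fraction of measurements used for fitting, in (0, 1).
#' @param seed integer seed for the split (the caller's RNG state is left
#'   untouched).
#' @return a [CalibrationModel-class].
#' @export
fitSpeciesModel <- function(data, species, trainFrac = 0.8, seed = 1L) {
  stopifnot(trainFrac > 0, trainFrac < 1)
  df <- data[data$species == species, , drop = FALSE]
  n <- nrow(df)
  if (n < 5L)
    pvStop("insufficient_data",
           "insufficient data: %d measurement(s) of '%s' (need >= 5)",
           n, species)
  nTrain <- round(trainFrac * n)
  trainIdx <- withSeed(seed, sort(sample.int(n, nTrain)))
  if (length(trainIdx) < 3L)
    pvStop("insufficient_data",
           "insufficient data: %d training point(s) after split (need >= 3)",
           length(trainIdx))
  testIdx <- setdiff(seq_len(n), trainIdx)
  fit <- stats::lm(h_mm ~ d_mm, data = df[trainIdx, ])
  new("CalibrationModel", species = species,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      residuals = unname(stats::residuals(fit)),
      trainIdx = as.integer(trainIdx), testIdx = as.integer(testIdx),
      nTrain = length(trainIdx), nTest = length(testIdx))
}

#' Derive the parallel upper-boundary line
#'
#' The regression line is unsafe for cutting: points on or above it mean
#' the cut would land inside the calyx. The boundary keeps the regression
#' slope and translates the intercept up by \code{c}, where \code{c} is the
#' one-sided empirical \code{coverage}-quantile of the training residuals
#' (default), or \code{qnorm(coverage) * sd(residuals)} under
#' \code{"normal_theory"}. With the empirical method at least a
#' \code{coverage} fraction of training points lies at or below the
#' boundary, by construction.
#'
#' @param model a [CalibrationModel-class].
#' @param coverage target fraction in \code{[0.5, 1)}; 0.85 balances
#'   overestimating the cut depth against damaging the flower.
#' @param method \code{"empirical_quantile"} or \code{"normal_theory"}.
#' @return a [BoundaryLine-class].
#' @export
upperBoundary <- function(model, coverage = 0.85,
                          method = c("empirical_quantile", "normal_theory")) {
  method <- match.arg(method)
  if (!isScalarNumber(coverage) || coverage < 0.5 || coverage >= 1)
    pvStop("contract", "coverage must be in [0.5, 1), got %s",
           format(coverage))
  r <- model@residuals
  offset <- if (method == "empirical_quantile") {
    sort(r)[ceiling(coverage * length(r))]
  } else {
    stats::qnorm(coverage) * stats::sd(r)
  }
  new("BoundaryLine", species = model@species, slope = model@slope,
      interceptUpper = model@intercept + offset, coverage = coverage,
      method = method)
}

#' Predict plucking height h from diameter d
#'
#' @param line a [BoundaryLine-class] or [CalibrationModel-class].
#' @param d diameter(s), mm, non-negative.
#' @return predicted h, mm.
#' @export
predictH <- function(line, d) {
  if (any(d < 0)) pvStop("contract", "diameter must be non-negative")
  if (is(line, "BoundaryLine")) line@slope * d + line@interceptUpper
  else if (is(line, "CalibrationModel")) line@slope * d + line@intercept
  else if (is.list(line) && !is.null(line$slope))  # packaged regression line
    line$slope * d + line$intercept
  else pvStop("contract", "predictH needs a BoundaryLine or CalibrationModel")
}

#' Count underestimated flowers
#'
#' A flower is underestimated when its true \code{h} is strictly above the
#' line's prediction — the cut would land inside the calyx. Typically
#' applied to the held-out test split.
#'
#' @param line the [BoundaryLine-class] (or a model, for the raw line).
#' @param data measurements data.frame with \code{d_mm, h_mm}.
#' @return list with \code{countUnder} and \code{n}.
#' @export
evaluateUnderestimation <- function(line, data) {
  if (nrow(data) == 0L) pvStop("contract", "no measurements to evaluate")
  pred <- predictH(line, data$d_mm)
  list(countUnder = sum(data$h_mm > pred), n = nrow(data))
}

#' Test-split measurements of a fitted model
#'
#' @param model a [CalibrationModel-class].
#' @param data the full measurements data.frame the model was fitted from.
#' @return the held-out rows for the model's species.
#' @export
testMeasurements <- function(model, data) {
  df <- data[data$species == model@species, , drop = FALSE]
  df[model@testIdx, , drop = FALSE]
}

#' Published per-species calibration coefficients
#'
#' Loads the packaged coefficient table (species, slope, regression
#' intercept, upper-boundary intercept, coverage; pansy 0.36/26.33/43.20,
#' snapdragon 0.38/5.33/34.57, marigold 0.66/7.10/37.91, coverage 0.85).
#' The two pansy varieties are pooled as one species. A user table with
#' the same columns can be supplied to extend or override.
#'
#' @param species species name.
#' @param configPath optional CSV with columns \code{species, slope,
#'   intercept_regression, intercept_upper, coverage}; defaults to the
#'   packaged table.
#' @return list with \code{model} (a residual-free
#'   [CalibrationModel-class] surrogate as a plain list with \code{slope},
#'   \code{intercept}) and \code{boundary} (a [BoundaryLine-class]).
#' @examples
#' loadPackagedCoefficients("marigold")$boundary
#' @export
loadPackagedCoefficients <- function(species, configPath = NULL) {
  if (is.null(configPath))
    configPath <- system.file("extdata", "calibration_coefficients.csv",
                              package = "pluckvision", mustWork = TRUE)
  tab <- utils::read.csv(configPath, stringsAsFactors = FALSE)
  row <- tab[tab$species == species, , drop = FALSE]
  if (nrow(row) == 0L)
    pvStop("no_calibration",
           "no calibration for species '%s' (known: %s)",
           species, paste(tab$species, collapse = ", "))
  list(
    model = list(species = species, slope = row$slope[1],
                 intercept = row$intercept_regression[1]),
    boundary = new("BoundaryLine", species = species, slope = row$slope[1],
                   interceptUpper = row$intercept_upper[1],
                   coverage = row$coverage[1], method = "packaged"))
}

#' All packaged calibrations, keyed by species
#'
#' @inheritParams loadPackagedCoefficients
#' @return named list of [loadPackagedCoefficients()] results.
#' @export
packagedCalibrations <- function(configPath = NULL) {
  if (is.null(configPath))
    configPath <- system.file("extdata", "calibration_coefficients.csv",
                              package = "pluckvision", mustWork = TRUE)
  tab <- utils::read.csv(configPath, stringsAsFactors = FALSE)
  out <- lapply(tab$species, loadPackagedCoefficients, configPath = configPath)
  names(out) <- tab$species
  out
}

#' Write a calibration config from fitted models
#'
#' @param models list of [CalibrationModel-class].
#' @param boundaries matching list of [BoundaryLine-class].
#' @param path output CSV path.
#' @return path, invisibly.
#' @export
writeCalibrationConfig <- function(models, boundaries, path) {
  df <- do.call(rbind, Map(function(m, b) {
    data.frame(species = m@species, slope = m@slope,
               intercept_regression = m@intercept,
               intercept_upper = b@interceptUpper, coverage = b@coverage)
  }, models, boundaries))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
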