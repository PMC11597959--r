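## End-to-end orchestration: detection -> segmentation cleaning -> point
## isolation -> PCA pose -> morphometry -> h prediction -> plucking point.
## Failures are contained per flower (status fields), never raised, so one
## bad flower cannot abort a frame.

#' Translate the flower centre to the 3D plucking point
#'
#' \code{center3d + (hMm / 1000) * mainAxis}: the centre is moved down
#' along the main pose axis by the predicted height.
#'
#' @param center3d flower centre, metres.
#' @param mainAxis unit 3-vector.
#' @param hMm predicted plucking height, mm (>= 0).
#' @return 3D point, metres.
#' @examples
#' computePluckPoint(c(0, 0, 0.5), c(0, 0, 1), 40)  # (0, 0, 0.54)
#' @export
computePluckPoint <- function(center3d, mainAxis, hMm) {
  if (abs(vnorm(mainAxis) - 1) > 1e-6)
    pvStop("contract", "mainAxis must be unit length")
  if (!isScalarNumber(hMm) || hMm < 0)
    pvStop("contract", "hMm must be a non-negative number")
  as.numeric(center3d) + (hMm / 1000) * as.numeric(mainAxis)
}

#' Pipeline configuration
#'
#' @param calibrations named list (species -> list with a
#'   \code{boundary} [BoundaryLine-class]), e.g. [packagedCalibrations()].
#' @param defaultSpecies species whose calibration is used for labels with
#'   no entry of their own; \code{NULL} makes an unknown label a
#'   configuration error.
#' @param mainAxisRule passed to [pcaPose()].
#' @param diameterMethod passed to [flowerDiameterMm()].
#' @param minGapPx passed to [flagOcclusions()].
#' @param topFraction passed to [centerPoint3D()].
#' @return config list.
#' @export
pipelineConfig <- function(calibrations = packagedCalibrations(),
                           defaultSpecies = NULL,
                           mainAxisRule = "min_variance",
                           diameterMethod = "calipers",
                           minGapPx = 3L,
                           topFraction = 0.1) {
  list(calibrations = calibrations, defaultSpecies = defaultSpecies,
       mainAxisRule = mainAxisRule, diameterMethod = diameterMethod,
       minGapPx = minGapPx, topFraction = topFraction)
}

boundaryFor <- function(config, label) {
  cal <- config$calibrations[[label]]
  if (is.null(cal) && !is.null(config$defaultSpecies))
    cal <- config$calibrations[[config$defaultSpecies]]
  if (is.null(cal))
    pvStop("configuration",
           "no calibration for species '%s' and no default configured", label)
  cal$boundary
}

naResult <- function(det, status, pose = NULL) {
  new("FlowerResult", detection = det, centerPx = rep(NaN, 2),
      center3d = rep(NaN, 3), diameterMm = NaN, hMm = NaN,
      pluckPoint3d = rep(NaN, 3), pose = pose, status = status)
}

#' Process one frame end to end
#'
#' Runs the cascade on every detection: clean the mask (nearest-centroid
#' component), flag occlusions (only flowers with a complete point cloud
#' are processed), isolate 3D points, estimate pose by PCA, measure the
#' diameter on the flower plane, locate the centre, predict \code{h} from
#' the species' upper-boundary line, and translate to the plucking point.
#' Per-flower failures become statuses (\code{occluded_skipped},
#' \code{no_depth}, \code{degenerate}); a missing calibration for any
#' detection label is a configuration error raised before any processing.
#'
#' @param frame a [Frame-class].
#' @param detections detections data.frame.
#' @param masks list of raw [BinaryMask-class], one per detection.
#' @param config from [pipelineConfig()].
#' @param verbose log per-stage timings via [message()].
#' @return list of [FlowerResult-class], one per detection.
#' @export
processFrame <- function(frame, detections, masks,
                         config = pipelineConfig(), verbose = FALSE) {
  n <- nrow(detections)
  if (length(masks) != n)
    pvStop("configuration", "%d detections but %d masks", n, length(masks))
  ## fail fast on missing calibration, before touching any geometry
  for (lab in unique(detections$label)) boundaryFor(config, lab)
  if (n == 0L) return(list())
  t0 <- proc.time()[["elapsed"]]
  cleaned <- vector("list", n)
  for (i in seq_len(n)) {
    cleaned[[i]] <- tryCatch(cleanMask(masks[[i]], detections[i, ]),
                             pluckvision_no_component = function(e) NULL)
  }
  tClean <- proc.time()[["elapsed"]]
  occ <- flagOcclusions(Filter(Negate(is.null), cleaned), frame,
                        minGapPx = config$minGapPx)
  occAll <- rep("complete", n)
  occAll[!vapply(cleaned, is.null, logical(1))] <- occ
  tOcc <- proc.time()[["elapsed"]]
  results <- vector("list", n)
  for (i in seq_len(n)) {
    det <- detections[i, , drop = FALSE]
    if (is.null(cleaned[[i]])) { results[[i]] <- naResult(det, "degenerate"); next }
    if (occAll[i] == "occluded") {
      results[[i]] <- naResult(det, "occluded_skipped"); next
    }
    results[[i]] <- tryCatch({
      cloud <- isolatePoints(frame, cleaned[[i]])
      pose <- pcaPose(cloud, mainAxisRule = config$mainAxisRule)
      dMm <- flowerDiameterMm(cloud, pose, method = config$diameterMethod)
      ctr <- centerPoint3D(cloud, cleaned[[i]], axis = pose@mainAxis,
                           topFraction = config$topFraction)
      hMm <- predictH(boundaryFor(config, det$label), dMm)
      pluck <- computePluckPoint(ctr$center3d, pose@mainAxis, hMm)
      new("FlowerResult", detection = det, centerPx = ctr$centerPx,
          center3d = ctr$center3d, diameterMm = dMm, hMm = hMm,
          pluckPoint3d = pluck, pose = pose, status = "ok")
    },
    pluckvision_insufficient_depth = function(e) naResult(det, "no_depth"),
    pluckvision_no_depth = function(e) naResult(det, "no_depth"),
    pluckvision_degenerate_geometry = function(e) naResult(det, "degenerate"),
    pluckvision_degenerate_hull = function(e) naResult(det, "degenerate"))
  }
  if (verbose) {
    tEnd <- proc.time()[["elapsed"]]
    message(sprintf(
      "processFrame '%s': clean %.3fs, occlusion %.3fs, geometry %.3fs (%d flowers)",
      frame@frameId, tClean - t0, tOcc - tClean, tEnd - tOcc, n))
  }
  results
}

## ---- command-line interface -----------------------------------------

parseArgs <- function(args) {
  out <- list(`_positional` = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else {
      out$`_positional` <- c(out$`_positional`, a); i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: \code{run} (process a frame:
#' \code{--image --cloud --detections [--masks DIR] [--calib CSV]
#' [--species S] [--main-axis-rule R] [--out results.json] [--csv out.csv]
#' [--seed N]}), \code{simulate} (write a synthetic fixture directory:
#' \code{--n-flowers K --seed N --out DIR [--noise-sd-mm S]}) and
#' \code{calibrate} (fit models from measurements:
#' \code{--measurements M.csv [--train-frac 0.8] [--coverage 0.85]
#' [--seed N] --out calib.csv}).
#'
#' @param args character vector, e.g. \code{commandArgs(TRUE)}.
#' @return integer exit code: 0 success, 1 I/O error, 2 configuration
#'   error.
#' @export
cliRun <- function(args) {
  opts <- parseArgs(args)
  cmd <- opts$`_positional`[1]
  code <- tryCatch({
    if (is.na(cmd) || is.null(cmd)) {
      message("usage: pluckvision <run|simulate|calibrate> [options]")
      return(2L)
    }
    switch(cmd,
      run = cliRunFrame(opts),
      simulate = cliSimulate(opts),
      calibrate = cliCalibrate(opts),
      { message("unknown command: ", cmd); 2L })
  },
  pluckvision_configuration = function(e) { message(conditionMessage(e)); 2L },
  pluckvision_no_calibration = function(e) { message(conditionMessage(e)); 2L },
  pluckvision_io = function(e) { message(conditionMessage(e)); 1L },
  pluckvision_error = function(e) { message(conditionMessage(e)); 1L },
  error = function(e) { message(conditionMessage(e)); 1L })
  code
}

cliRunFrame <- function(opts) {
  need <- c("image", "cloud", "detections")
  miss <- need[!need %in% names(opts)]
  if (length(miss) > 0) {
    message("missing required options: ", paste0("--", miss, collapse = " "))
    return(2L)
  }
  frame <- loadFrame(opts$image, opts$cloud)
  W <- dim(frame@image)[2]; H <- dim(frame@image)[1]
  classMap <- strsplit(opts$`class-map` %||% "pansy,snapdragon,marigold",
                       ",")[[1]]
  det <- loadDetections(opts$detections, dialect = "yolo_txt",
                        imageSize = c(W, H), classMap = classMap)
  if (!is.null(opts$species)) det$label <- opts$species
  pairs <- if (!is.null(opts$masks))
    attachMasks(frame, det, maskSource = "files", maskDir = opts$masks)
  else attachMasks(frame, det, maskSource = "fallback_threshold")
  config <- pipelineConfig(
    calibrations = packagedCalibrations(configPath = opts$calib),
    mainAxisRule = opts$`main-axis-rule` %||% "min_variance")
  results <- processFrame(frame, det, lapply(pairs, `[[`, "mask"), config)
  outPath <- opts$out %||% "results.json"
  writeResults(results, outPath)
  if (!is.null(opts$csv))
    utils::write.csv(resultsToDataFrame(results), opts$csv, row.names = FALSE)
  message(sprintf("processed %d detection(s) -> %s", length(results), outPath))
  0L
}

cliSimulate <- function(opts) {
  if (is.null(opts$out)) { message("simulate needs --out DIR"); return(2L) }
  nFlowers <- as.integer(opts$`n-flowers` %||% 3L)
  seed <- as.integer(opts$seed %||% 1L)
  noise <- as.numeric(opts$`noise-sd-mm` %||% 0)
  flowers <- sampleFlowers(nFlowers, seed = seed)
  scene <- renderScene(flowers, noiseSdMm = noise, seed = seed + 1L,
                       frameId = sprintf("sim%04d", seed))
  paths <- writeScene(scene, opts$out)
  message("wrote scene to ", opts$out)
  0L
}

cliCalibrate <- function(opts) {
  if (is.null(opts$measurements)) {
    message("calibrate needs --measurements CSV"); return(2L)
  }
  meas <- readMeasurements(opts$measurements)
  trainFrac <- as.numeric(opts$`train-frac` %||% 0.8)
  coverage <- as.numeric(opts$coverage %||% 0.85)
  seed <- as.integer(opts$seed %||% 1L)
  specs <- unique(meas$species)
  models <- lapply(specs, function(s)
    fitSpeciesModel(meas, s, trainFrac = trainFrac, seed = seed))
  bounds <- lapply(models, upperBoundary, coverage = coverage)
  outPath <- opts$out %||% "calibration.csv"
  writeCalibrationConfig(models, bounds, outPath)
  for (i in seq_along(models)) {
    m <- models[[i]]
    ev <- evaluateUnderestimation(bounds[[i]], testMeasurements(m, meas))
    message(sprintf(
      "%s: h = %.3f d %+.3f, boundary %+.3f; %d/%d test flowers underestimated",
      m@species, m@slope, m@intercept, bounds[[i]]@interceptUpper,
      ev$countUnder, ev$n))
  }
  0L
}

#' Place well-separated random flowers on the synthetic bench
#'
#' Helper for simulation and end-to-end tests: draws species, sizes and
#' modest tilts (up to ~20 degrees, upright posture) on a grid of
#' non-overlapping bench positions, with the true plucking height taken
#' from the species' packaged upper-boundary line so pipeline output is
#' directly comparable to ground truth.
#'
#' @param n number of flowers.
#' @param seed integer seed.
#' @param depthM bench-top flower depth, metres.
#' @param domeFraction dome height as a fraction of diameter (default
#'   1/8; 0 gives flat disks, the exact-recovery limit of the geometry).
#' @param calibrations boundary lines keyed by species; defaults to the
#'   packaged ones.
#' @return list of [SyntheticFlower-class].
#' @export
sampleFlowers <- function(n, seed = 1L, depthM = 0.5, domeFraction = 1 / 8,
                          calibrations = packagedCalibrations()) {
  species <- c("pansy", "snapdragon", "marigold")
  meanD <- c(pansy = 48, snapdragon = 28, marigold = 36)
  withSeed(seed, {
    ## spread flowers over a grid so footprints cannot overlap
    cells <- expand.grid(gx = -2:2, gy = -1:1)
    cells <- cells[sample.int(nrow(cells), n), , drop = FALSE]
    lapply(seq_len(n), function(i) {
      sp <- sample(species, 1)
      d <- meanD[[sp]] * stats::runif(1, 0.85, 1.15)
      tilt <- stats::runif(1, 0, 20) * pi / 180
      azim <- stats::runif(1, 0, 2 * pi)
      ax <- c(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt))
      ctr <- c(cells$gx[i] * 0.09 + stats::runif(1, -0.01, 0.01),
               cells$gy[i] * 0.09 + stats::runif(1, -0.01, 0.01),
               depthM + stats::runif(1, -0.01, 0.01))
      h <- predictH(calibrations[[sp]]$boundary, d)
      SyntheticFlower(species = sp, center3d = ctr, mainAxis = ax,
                      diameterMm = d, domeHeightMm = d * domeFraction,
                      trueHMm = h)
    })
  })
}
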