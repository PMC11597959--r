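#' @import methods
NULL

#' Frame: an RGB image with a pixel-aligned organized point cloud
#'
#' A \code{Frame} couples an 8-bit colour raster with an organized point
#' cloud on the same pixel grid: element \code{cloud[v+1, u+1, ]} is the 3D
#' point (metres, camera frame) seen at 0-based pixel \code{(u, v)}.
#' Invalid depth is encoded as an all-\code{NaN} point. The camera frame is
#' +X right, +Y down, +Z forward, so all finite \code{z} are strictly
#' positive.
#'
#' @slot image numeric array \code{H x W x 3}, values in \code{[0, 1]}.
#' @slot cloud numeric array \code{H x W x 3}, metres; \code{NaN} rows mark
#'   invalid depth.
#' @slot frameId single character identifier.
#'
#' @seealso [loadFrame()], [isolatePoints()]
#' @exportClass Frame
setClass("Frame", representation(
  image = "array",
  cloud = "array",
  frameId = "character"
))

setValidity("Frame", function(object) {
  di <- dim(object@image); dc <- dim(object@cloud)
  if (length(di) != 3L || di[3] != 3L) return("image must be H x W x 3")
  if (length(dc) != 3L || dc[3] != 3L) return("cloud must be H x W x 3")
  if (!all(di[1:2] == dc[1:2])) return("image and cloud grids differ")
  if (length(object@frameId) != 1L) return("frameId must be a single string")
  fin <- is.finite(object@cloud)
  nfin <- fin[, , 1] + fin[, , 2] + fin[, , 3]
  if (any(nfin != 0L & nfin != 3L))
    return("cloud points must be all-finite or all-NaN")
  z <- object@cloud[, , 3]
  if (any(z[is.finite(z)] <= 0))
    return("finite z must be strictly positive (in front of the camera)")
  TRUE
})

#' Construct a Frame
#'
#' @param image numeric array \code{H x W x 3} in \code{[0, 1]}.
#' @param cloud numeric array \code{H x W x 3}, metres, \code{NaN} = invalid.
#' @param frameId identifier string.
#' @return A validated [Frame-class] object.
#' @export
Frame <- function(image, cloud, frameId = "frame") {
  new("Frame", image = image, cloud = cloud, frameId = frameId)
}

#' BinaryMask: a per-flower segmentation mask
#'
#' @slot grid logical \code{H x W} matrix, \code{TRUE} = flower pixel.
#' @slot provenance where the mask came from: \code{"external"} (files from
#'   a deep segmenter) or \code{"fallback"} (colour threshold).
#' @exportClass BinaryMask
setClass("BinaryMask", representation(
  grid = "matrix",
  provenance = "character"
))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@grid)) return("grid must be logical")
  if (length(object@provenance) != 1L) return("provenance must be length 1")
  TRUE
})

#' Construct a BinaryMask
#' @param grid logical H x W matrix.
#' @param provenance \code{"external"} or \code{"fallback"}.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(grid, provenance = "external") {
  storage.mode(grid) <- "logical"
  new("BinaryMask", grid = grid, provenance = provenance)
}

#' FlowerPointCloud: the 3D points of one flower
#'
#' Points isolated from an organized cloud through a segmentation mask,
#' or sampled synthetically. Coordinates are metres in the camera frame.
#'
#' @slot points numeric \code{N x 3} matrix, all finite.
#' @slot sourcePixels integer \code{N x 2} matrix of 0-based \code{(u, v)}
#'   pixels, or a 0-row matrix for synthetic clouds.
#' @slot nDropped number of mask pixels discarded for invalid depth.
#' @exportClass FlowerPointCloud
setClass("FlowerPointCloud", representation(
  points = "matrix",
  sourcePixels = "matrix",
  nDropped = "integer"
))

setValidity("FlowerPointCloud", function(object) {
  if (ncol(object@points) != 3L) return("points must be N x 3")
  if (!all(is.finite(object@points))) return("points must be finite")
  if (nrow(object@sourcePixels) > 0 &&
      nrow(object@sourcePixels) != nrow(object@points))
    return("sourcePixels must match points")
  TRUE
})

#' Construct a FlowerPointCloud
#' @param points numeric N x 3 matrix, metres.
#' @param sourcePixels integer N x 2 matrix of 0-based (u, v), optional.
#' @param nDropped count of invalid-depth pixels dropped during isolation.
#' @return A [FlowerPointCloud-class].
#' @export
FlowerPointCloud <- function(points,
                             sourcePixels = matrix(0L, 0L, 2L),
                             nDropped = 0L) {
  new("FlowerPointCloud", points = points,
      sourcePixels = sourcePixels, nDropped = as.integer(nDropped))
}

#' PoseEstimate: PCA axes of a flower point cloud
#'
#' The three principal axes of the flower's points, eigenvalue-ordered, plus
#' the oriented main axis used for plucking-point translation. The main axis
#' is sign-fixed to have a non-negative Z component, i.e. it points away
#' from the downward-looking camera, into the canopy.
#'
#' @slot axes 3 x 3 matrix whose columns are e1, e2, e3 (decreasing
#'   variance), orthonormal.
#' @slot eigenvalues numeric length 3, non-increasing, non-negative.
#' @slot mainAxis unit 3-vector with \code{mainAxis[3] >= 0}.
#' @slot centroid numeric length 3, metres.
#' @exportClass PoseEstimate
setClass("PoseEstimate", representation(
  axes = "matrix",
  eigenvalues = "numeric",
  mainAxis = "numeric",
  centroid = "numeric"
))

setValidity("PoseEstimate", function(object) {
  A <- object@axes
  if (!all(dim(A) == c(3L, 3L))) return("axes must be 3 x 3")
  G <- crossprod(A)
  if (max(abs(G - diag(3))) > 1e-6) return("axes must be orthonormal")
  ev <- object@eigenvalues
  if (length(ev) != 3L || any(diff(ev) > 1e-9) || any(ev < -1e-12))
    return("eigenvalues must be non-increasing and non-negative")
  u <- object@mainAxis
  if (abs(vnorm(u) - 1) > 1e-6) return("mainAxis must be unit length")
  if (u[3] < -1e-9) return("mainAxis must have non-negative Z component")
  if (length(object@centroid) != 3L) return("centroid must be length 3")
  TRUE
})

#' CalibrationModel: per-species linear d-to-h regression
#'
#' Ordinary least squares fit of total flower height \code{h} (top of the
#' corolla down to the plucking point, mm) on flower diameter \code{d} (mm)
#' for one species, on a seeded train split.
#'
#' @slot species species name.
#' @slot slope mm of height per mm of diameter.
#' @slot intercept mm.
#' @slot residuals training residuals, mm (length \code{nTrain}).
#' @slot trainIdx,testIdx integer indices into the fitting data.
#' @slot nTrain,nTest split sizes.
#' @exportClass CalibrationModel
setClass("CalibrationModel", representation(
  species = "character",
  slope = "numeric",
  intercept = "numeric",
  residuals = "numeric",
  trainIdx = "integer",
  testIdx = "integer",
  nTrain = "integer",
  nTest = "integer"
))

setValidity("CalibrationModel", function(object) {
  if (object@nTrain < 3L) return("nTrain must be >= 3")
  if (length(object@residuals) != object@nTrain)
    return("residuals length must equal nTrain")
  if (abs(mean(object@residuals)) > 1e-9 * max(1, stats::sd(object@residuals)))
    return("OLS training residuals must have mean ~ 0")
  TRUE
})

#' BoundaryLine: the parallel upper-boundary cut line
#'
#' The regression line translated upward so that a target fraction
#' (\code{coverage}) of flowers fall at or below it; predicting \code{h}
#' from this line places the cut below the calyx rather than through it.
#' Slope is identical to the parent regression (parallel translation).
#'
#' @slot species species name.
#' @slot slope mm/mm, equal to the parent model's slope.
#' @slot interceptUpper mm.
#' @slot coverage target fraction in \code{[0.5, 1)}.
#' @slot method \code{"empirical_quantile"}, \code{"normal_theory"} or
#'   \code{"packaged"}.
#' @exportClass BoundaryLine
setClass("BoundaryLine", representation(
  species = "character",
  slope = "numeric",
  interceptUpper = "numeric",
  coverage = "numeric",
  method = "character"
))

setValidity("BoundaryLine", function(object) {
  if (object@coverage <= 0 || object@coverage >= 1)
    return("coverage must be in (0, 1)")
  TRUE
})

#' FlowerResult: the full per-flower pipeline output
#'
#' One record per detection. When \code{status != "ok"} the geometric slots
#' hold \code{NA}/\code{NaN} and are serialized as \code{null}. For
#' \code{status == "ok"}, \code{pluckPoint3d == center3d +
#' (hMm/1000) * pose main axis} by construction.
#'
#' @slot detection one-row data.frame (xmin, ymin, xmax, ymax, label,
#'   confidence).
#' @slot centerPx numeric (u, v), 0-based pixels.
#' @slot center3d numeric length 3, metres.
#' @slot diameterMm flower diameter, mm.
#' @slot hMm predicted top-to-plucking-point height, mm.
#' @slot pluckPoint3d numeric length 3, metres.
#' @slot pose a [PoseEstimate-class], or NULL.
#' @slot status one of \code{"ok"}, \code{"occluded_skipped"},
#'   \code{"no_depth"}, \code{"degenerate"}.
#' @exportClass FlowerResult
setClass("FlowerResult", representation(
  detection = "data.frame",
  centerPx = "numeric",
  center3d = "numeric",
  diameterMm = "numeric",
  hMm = "numeric",
  pluckPoint3d = "numeric",
  pose = "ANY",
  status = "character"
))

setValidity("FlowerResult", function(object) {
  st <- object@status
  if (!st %in% c("ok", "occluded_skipped", "no_depth", "degenerate"))
    return("unknown status")
  if (st == "ok") {
    geo <- c(object@centerPx, object@center3d, object@diameterMm,
             object@hMm, object@pluckPoint3d)
    if (!all(is.finite(geo))) return("ok result must have finite geometry")
    expect <- object@center3d + (object@hMm / 1000) * object@pose@mainAxis
    if (max(abs(expect - object@pluckPoint3d)) > 1e-9)
      return("pluckPoint3d must equal center + (h/1000) * main axis")
  }
  TRUE
})

#' SyntheticFlower: ground-truth description of a simulated flower
#'
#' @slot species species name.
#' @slot center3d apex of the corolla (the flower's top point), metres.
#' @slot mainAxis unit 3-vector, +Z-leaning (stem-ward).
#' @slot diameterMm corolla diameter.
#' @slot domeHeightMm sagitta of the spherical-cap corolla (0 = flat disk).
#' @slot trueHMm true top-to-plucking-point height.
#' @slot truePluckPoint \code{center3d + (trueHMm/1000) * mainAxis}, metres.
#' @exportClass SyntheticFlower
setClass("SyntheticFlower", representation(
  species = "character",
  center3d = "numeric",
  mainAxis = "numeric",
  diameterMm = "numeric",
  domeHeightMm = "numeric",
  trueHMm = "numeric",
  truePluckPoint = "numeric"
))

setValidity("SyntheticFlower", function(object) {
  if (abs(vnorm(object@mainAxis) - 1) > 1e-9) return("mainAxis must be unit")
  if (object@mainAxis[3] < 0) return("mainAxis must lean toward +Z")
  if (object@diameterMm <= 0) return("diameterMm must be positive")
  if (object@domeHeightMm < 0) return("domeHeightMm must be >= 0")
  expect <- object@center3d + (object@trueHMm / 1000) * object@mainAxis
  if (max(abs(expect - object@truePluckPoint)) > 0)
    return("truePluckPoint must equal center + (h/1000) * axis exactly")
  TRUE
})

#' Construct a SyntheticFlower
#'
#' @param species species name (must have a calibration when run through
#'   the pipeline).
#' @param center3d apex position, metres, camera frame.
#' @param mainAxis direction from the apex toward the stem; normalised, and
#'   must lean toward +Z (away from the camera).
#' @param diameterMm,domeHeightMm corolla geometry, mm.
#' @param trueHMm true plucking height, mm.
#' @return A [SyntheticFlower-class].
#' @export
SyntheticFlower <- function(species, center3d, mainAxis, diameterMm,
                            domeHeightMm = 0, trueHMm = 0) {
  u <- unitVector(mainAxis, "mainAxis")
  new("SyntheticFlower", species = species, center3d = as.numeric(center3d),
      mainAxis = u, diameterMm = diameterMm, domeHeightMm = domeHeightMm,
      trueHMm = trueHMm,
      truePluckPoint = as.numeric(center3d) + (trueHMm / 1000) * u)
}

#' CameraModel: pinhole camera for the synthetic scene renderer
#'
#' @slot width,height image size, pixels.
#' @slot focalPx focal length, pixels (square pixels assumed).
#' @slot cx,cy principal point, 0-based pixel coordinates.
#' @exportClass CameraModel
setClass("CameraModel", representation(
  width = "integer", height = "integer",
  focalPx = "numeric", cx = "numeric", cy = "numeric"
))

setValidity("CameraModel", function(object) {
  if (object@focalPx <= 0) return("focal length must be positive")
  if (object@cx < 0 || object@cx > object@width - 1 ||
      object@cy < 0 || object@cy > object@height - 1)
    return("principal point must lie inside the image")
  TRUE
})

#' Construct a CameraModel
#'
#' Defaults match a bench-top RGB-D rig: 1280 x 720 grid (921,600 pixels),
#' 700 px focal length, principal point at the image centre.
#'
#' @param width,height image size in pixels.
#' @param focalPx focal length in pixels.
#' @param cx,cy principal point (0-based); defaults to the image centre.
#' @return A [CameraModel-class].
#' @export
CameraModel <- function(width = 1280L, height = 720L, focalPx = 700,
                        cx = (width - 1) / 2, cy = (height - 1) / 2) {
  new("CameraModel", width = as.integer(width), height = as.integer(height),
      focalPx = focalPx, cx = cx, cy = cy)
}
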