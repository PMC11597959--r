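#' @include AllClasses.R
NULL

#' Accessors for pluckvision classes
#'
#' Slot access for the package's S4 objects. \code{frameImage} and
#' \code{frameCloud} return the H x W x 3 arrays of a [Frame-class];
#' \code{maskGrid} the logical matrix of a [BinaryMask-class];
#' \code{cloudPoints} the N x 3 point matrix of a [FlowerPointCloud-class];
#' \code{mainAxis}, \code{poseAxes} and \code{poseCentroid} the components
#' of a [PoseEstimate-class]; \code{resultStatus} the status string of a
#' [FlowerResult-class].
#'
#' @param x an object of the class named above.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameImage", function(x) standardGeneric("frameImage"))
#' @rdname accessors
#' @export
setGeneric("frameCloud", function(x) standardGeneric("frameCloud"))
#' @rdname accessors
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))
#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))
#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))
#' @rdname accessors
#' @export
setGeneric("mainAxis", function(x) standardGeneric("mainAxis"))
#' @rdname accessors
#' @export
setGeneric("poseAxes", function(x) standardGeneric("poseAxes"))
#' @rdname accessors
#' @export
setGeneric("poseEigenvalues", function(x) standardGeneric("poseEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("poseCentroid", function(x) standardGeneric("poseCentroid"))
#' @rdname accessors
#' @export
setGeneric("resultStatus", function(x) standardGeneric("resultStatus"))

#' @rdname accessors
setMethod("frameImage", "Frame", function(x) x@image)
#' @rdname accessors
setMethod("frameCloud", "Frame", function(x) x@cloud)
#' @rdname accessors
setMethod("frameId", "Frame", function(x) x@frameId)
#' @rdname accessors
setMethod("maskGrid", "BinaryMask", function(x) x@grid)
#' @rdname accessors
setMethod("cloudPoints", "FlowerPointCloud", function(x) x@points)
#' @rdname accessors
setMethod("mainAxis", "PoseEstimate", function(x) x@mainAxis)
#' @rdname accessors
setMethod("mainAxis", "SyntheticFlower", function(x) x@mainAxis)
#' @rdname accessors
setMethod("poseAxes", "PoseEstimate", function(x) x@axes)
#' @rdname accessors
setMethod("poseEigenvalues", "PoseEstimate", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("poseCentroid", "PoseEstimate", function(x) x@centroid)
#' @rdname accessors
setMethod("resultStatus", "FlowerResult", function(x) x@status)

setMethod("show", "Frame", function(object) {
  d <- dim(object@cloud)
  z <- object@cloud[, , 3]
  cat(sprintf("Frame '%s': %d x %d grid, %d/%d finite points\n",
              object@frameId, d[2], d[1], sum(is.finite(z)), d[1] * d[2]))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask (%s): %d x %d, %d flower pixels\n",
              object@provenance, ncol(object@grid), nrow(object@grid),
              sum(object@grid)))
})

setMethod("show", "FlowerPointCloud", function(object) {
  cat(sprintf("FlowerPointCloud: %d points (%d dropped for invalid depth)\n",
              nrow(object@points), object@nDropped))
})

setMethod("show", "PoseEstimate", function(object) {
  cat("PoseEstimate\n")
  cat(sprintf("  eigenvalues: %s\n",
              paste(signif(object@eigenvalues, 4), collapse = ", ")))
  cat(sprintf("  main axis:   (%s)\n",
              paste(sprintf("%.4f", object@mainAxis), collapse = ", ")))
  cat(sprintf("  centroid:    (%s) m\n",
              paste(sprintf("%.4f", object@centroid), collapse = ", ")))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel [%s]: h = %.4f d %+.4f (mm), n = %d/%d\n",
              object@species, object@slope, object@intercept,
              object@nTrain, object@nTest))
})

setMethod("show", "BoundaryLine", function(object) {
  cat(sprintf("BoundaryLine [%s, %s]: h = %.4f d %+.4f (mm), coverage %.2f\n",
              object@species, object@method, object@slope,
              object@interceptUpper, object@coverage))
})

setMethod("show", "FlowerResult", function(object) {
  cat(sprintf("FlowerResult [%s] status=%s", object@detection$label[1],
              object@status))
  if (object@status == "ok")
    cat(sprintf(": d=%.1f mm, h=%.1f mm, pluck=(%s) m",
                object@diameterMm, object@hMm,
                paste(sprintf("%.3f", object@pluckPoint3d), collapse = ", ")))
  cat("\n")
})

setMethod("show", "SyntheticFlower", function(object) {
  cat(sprintf("SyntheticFlower [%s]: d=%.1f mm, dome=%.1f mm, h=%.1f mm\n",
              object@species, object@diameterMm, object@domeHeightMm,
              object@trueHMm))
})

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel: %d x %d px, f=%.1f px, pp=(%.1f, %.1f)\n",
              object@width, object@height, object@focalPx,
              object@cx, object@cy))
})
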