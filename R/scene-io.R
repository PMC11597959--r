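## Readers and writers for frames, detections, masks, measurement tables
## and per-flower result records.

#' Load an RGB-D frame from an image and an organized PLY cloud
#'
#' The image and the cloud must share one pixel grid (the depth sensor's
#' cloud is registered to the left camera image). Missing depth is kept as
#' NaN; no interpolation is performed.
#'
#' @param imagePath PNG or JPEG image.
#' @param cloudPath organized PLY (see [readOrganizedPLY()]).
#' @param frameId identifier; defaults to the image file stem.
#' @return A [Frame-class].
#' @examples
#' \dontrun{
#' fr <- loadFrame("bench.png", "bench.ply")
#' }
#' @export
loadFrame <- function(imagePath, cloudPath,
                      frameId = tools::file_path_sans_ext(basename(imagePath))) {
  if (!file.exists(imagePath)) pvStop("io", "image not found: %s", imagePath)
  if (!file.exists(cloudPath)) pvStop("io", "cloud not found: %s", cloudPath)
  img <- EBImage::readImage(imagePath)
  dat <- EBImage::imageData(img)       # W x H (x channels)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3]
  image <- aperm(dat, c(2L, 1L, 3L))   # H x W x 3
  ply <- readOrganizedPLY(cloudPath)
  if (ply$height != dim(image)[1] || ply$width != dim(image)[2])
    pvStop("grid_mismatch",
           "grid mismatch: image %d x %d vs cloud %d x %d",
           dim(image)[2], dim(image)[1], ply$width, ply$height)
  Frame(image = image, cloud = ply$cloud, frameId = frameId)
}

#' Load per-flower detections from YOLO txt or COCO JSON
#'
#' YOLO lines are \code{class cx cy w h} with coordinates normalised to
#' \code{[0, 1]}; COCO annotations carry \code{bbox = [x, y, w, h]} in
#' pixels. Both are converted to 0-based half-open pixel corners
#' \code{(xmin, ymin, xmax, ymax)}, clipped to the image bounds, input
#' order preserved.
#'
#' @param path detections file.
#' @param dialect \code{"yolo_txt"} or \code{"coco_json"}.
#' @param imageSize integer \code{c(W, H)}.
#' @param classMap character vector mapping 0-based class index + 1 to a
#'   species label (YOLO) or category id names (COCO). Unknown indices are
#'   a format error.
#' @param confidence default confidence for dialects without one.
#' @return data.frame with columns \code{xmin, ymin, xmax, ymax, label,
#'   confidence} (one row per detection).
#' @export
loadDetections <- function(path, dialect = c("yolo_txt", "coco_json"),
                           imageSize, classMap = NULL, confidence = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) pvStop("io", "detections not found: %s", path)
  W <- imageSize[1]; H <- imageSize[2]
  if (dialect == "yolo_txt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(emptyDetections())
    rows <- lapply(lines, function(ln) {
      tok <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(tok) < 5L || anyNA(tok))
        pvStop("format", "bad yolo_txt line: '%s'", ln)
      cls <- as.integer(tok[1]); v <- tok[2:5]
      conf <- if (length(tok) >= 6L) tok[6] else confidence
      if (any(v < 0) || any(v > 1))
        pvStop("format", "yolo_txt coordinates outside [0,1]: '%s'", ln)
      label <- if (is.null(classMap)) as.character(cls) else {
        if (cls + 1L > length(classMap))
          pvStop("format", "unknown class index %d (class map has %d entries)",
                 cls, length(classMap))
        classMap[cls + 1L]
      }
      data.frame(xmin = (v[1] - v[3] / 2) * W, ymin = (v[2] - v[4] / 2) * H,
                 xmax = (v[1] + v[3] / 2) * W, ymax = (v[2] + v[4] / 2) * H,
                 label = label, confidence = conf)
    })
    det <- do.call(rbind, rows)
  } else {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) pvStop("format", "bad COCO JSON: %s",
                                               conditionMessage(e)))
    anns <- doc$annotations
    if (is.null(anns)) anns <- list()
    catNames <- NULL
    if (!is.null(doc$categories)) {
      catNames <- vapply(doc$categories, function(cc) as.character(cc$name),
                         character(1))
      names(catNames) <- vapply(doc$categories, function(cc)
        as.character(cc$id), character(1))
    }
    if (length(anns) == 0L) return(emptyDetections())
    rows <- lapply(anns, function(a) {
      bb <- as.numeric(a$bbox)
      if (length(bb) != 4L) pvStop("format", "COCO bbox must have 4 numbers")
      label <- if (!is.null(catNames) && !is.null(a$category_id)) {
        nm <- catNames[as.character(a$category_id)]
        if (is.na(nm)) pvStop("format", "unknown COCO category id %s",
                              a$category_id)
        nm
      } else if (!is.null(classMap) && !is.null(a$category_id)) {
        classMap[as.integer(a$category_id) + 1L]
      } else as.character(a$category_id %||% "flower")
      conf <- if (!is.null(a$score)) as.numeric(a$score) else confidence
      data.frame(xmin = bb[1], ymin = bb[2],
                 xmax = bb[1] + bb[3], ymax = bb[2] + bb[4],
                 label = label, confidence = conf)
    })
    det <- do.call(rbind, rows)
  }
  clipDetections(det, W, H)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

emptyDetections <- function() {
  data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
             ymax = numeric(), label = character(), confidence = numeric())
}

clipDetections <- function(det, W, H) {
  det$xmin <- pmax(0, pmin(det$xmin, W)); det$xmax <- pmax(0, pmin(det$xmax, W))
  det$ymin <- pmax(0, pmin(det$ymin, H)); det$ymax <- pmax(0, pmin(det$ymax, H))
  bad <- det$xmin >= det$xmax | det$ymin >= det$ymax
  if (any(bad)) pvStop("format", "degenerate bounding box after clipping")
  rownames(det) <- NULL
  det
}

bboxCenter <- function(bbox) {
  c((bbox[["xmin"]] + bbox[["xmax"]]) / 2, (bbox[["ymin"]] + bbox[["ymax"]]) / 2)
}

## ---- masks -----------------------------------------------------------

#' Read / write a binary mask as 8-bit PNG
#'
#' Single-channel PNG, 0 = background, 255 = flower.
#'
#' @param path PNG path.
#' @param provenance provenance tag for the returned [BinaryMask-class].
#' @return \code{readMaskPNG}: a [BinaryMask-class]; \code{writeMaskPNG}:
#'   the path, invisibly.
#' @export
readMaskPNG <- function(path, provenance = "external") {
  if (!file.exists(path)) pvStop("io", "mask not found: %s", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  BinaryMask(m > 0.5, provenance = provenance)
}

#' @rdname readMaskPNG
#' @param mask a [BinaryMask-class] or logical matrix.
#' @export
writeMaskPNG <- function(mask, path) {
  g <- if (is(mask, "BinaryMask")) mask@grid else mask
  png::writePNG(matrix(as.numeric(g), nrow(g), ncol(g)), path)
  invisible(path)
}

## ---- measurements ----------------------------------------------------

#' Read / write caliper measurement tables
#'
#' CSV with header \code{species,d_mm,h_mm}: per-flower diameter \code{d}
#' and total height \code{h} (corolla top down to the plucking point),
#' both in millimetres.
#'
#' @param path CSV path.
#' @return \code{readMeasurements}: data.frame with columns
#'   \code{species, d_mm, h_mm}.
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path)) pvStop("io", "measurements not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "d_mm", "h_mm")
  if (!all(need %in% names(df)))
    pvStop("format", "measurements CSV must have columns %s",
           paste(need, collapse = ","))
  if (any(df$d_mm <= 0) || any(df$h_mm <= 0))
    pvStop("format", "measurements must have d_mm > 0 and h_mm > 0")
  df[need]
}

#' @rdname readMeasurements
#' @param measurements data.frame with \code{species, d_mm, h_mm}.
#' @export
writeMeasurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- results ---------------------------------------------------------

resultToList <- function(r) {
  nul3 <- function(v) if (all(is.finite(v))) as.numeric(v) else NULL
  nul1 <- function(v) if (isTRUE(is.finite(v))) as.numeric(v) else NULL
  pose <- NULL
  if (is(r@pose, "PoseEstimate"))
    pose <- list(e1 = as.numeric(r@pose@axes[, 1]),
                 e2 = as.numeric(r@pose@axes[, 2]),
                 e3 = as.numeric(r@pose@axes[, 3]),
                 eigenvalues = as.numeric(r@pose@eigenvalues),
                 main_axis = as.numeric(r@pose@mainAxis),
                 centroid = as.numeric(r@pose@centroid))
  list(
    detection = list(bbox = as.numeric(r@detection[1, c("xmin", "ymin",
                                                        "xmax", "ymax")]),
                     label = r@detection$label[1],
                     confidence = r@detection$confidence[1]),
    center_px = nul3(r@centerPx),
    center_3d = nul3(r@center3d),
    diameter_mm = nul1(r@diameterMm),
    h_mm = nul1(r@hMm),
    pluck_point_3d = nul3(r@pluckPoint3d),
    axes = pose,
    status = r@status)
}

listToResult <- function(x) {
  num <- function(v, n) if (is.null(v)) rep(NaN, n) else as.numeric(v)
  pose <- NULL
  if (!is.null(x$axes))
    pose <- new("PoseEstimate",
                axes = cbind(as.numeric(x$axes$e1), as.numeric(x$axes$e2),
                             as.numeric(x$axes$e3)),
                eigenvalues = as.numeric(x$axes$eigenvalues),
                mainAxis = as.numeric(x$axes$main_axis),
                centroid = as.numeric(x$axes$centroid))
  bb <- as.numeric(x$detection$bbox)
  det <- data.frame(xmin = bb[1], ymin = bb[2], xmax = bb[3], ymax = bb[4],
                    label = x$detection$label,
                    confidence = as.numeric(x$detection$confidence))
  new("FlowerResult", detection = det,
      centerPx = num(x$center_px, 2), center3d = num(x$center_3d, 3),
      diameterMm = num(x$diameter_mm, 1)[1], hMm = num(x$h_mm, 1)[1],
      pluckPoint3d = num(x$pluck_point_3d, 3),
      pose = pose, status = x$status)
}

#' Write / read per-flower pipeline results
#'
#' JSON document with one record per flower; geometric fields of records
#' whose status is not \code{"ok"} are serialized as \code{null}. The pair
#' round-trips losslessly (floats to full double precision). A flat CSV
#' export is available via [resultsToDataFrame()].
#'
#' @param results list of [FlowerResult-class].
#' @param path output path.
#' @return \code{writeResults}: path invisibly; \code{readResults}: list of
#'   [FlowerResult-class].
#' @export
writeResults <- function(results, path) {
  recs <- lapply(results, resultToList)
  txt <- jsonlite::toJSON(list(flowers = recs), auto_unbox = TRUE,
                          digits = NA, null = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) pvStop("io", "cannot write results to %s", path)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  if (!file.exists(path)) pvStop("io", "results not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc$flowers, listToResult)
}

#' Flatten results to a data.frame
#'
#' One row per flower with bbox, label, status, centre, diameter, height
#' and plucking point columns; suitable for CSV export.
#'
#' @param results list of [FlowerResult-class].
#' @return data.frame.
#' @export
resultsToDataFrame <- function(results) {
  if (length(results) == 0L)
    return(data.frame(label = character(), status = character()))
  do.call(rbind, lapply(results, function(r) {
    data.frame(label = r@detection$label[1],
               confidence = r@detection$confidence[1],
               xmin = r@detection$xmin[1], ymin = r@detection$ymin[1],
               xmax = r@detection$xmax[1], ymax = r@detection$ymax[1],
               status = r@status,
               center_u = r@centerPx[1], center_v = r@centerPx[2],
               center_x = r@center3d[1], center_y = r@center3d[2],
               center_z = r@center3d[3],
               diameter_mm = r@diameterMm, h_mm = r@hMm,
               pluck_x = r@pluckPoint3d[1], pluck_y = r@pluckPoint3d[2],
               pluck_z = r@pluckPoint3d[3])
  }))
}
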