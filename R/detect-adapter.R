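## Pluggable detection and mask sources.
##
## Deep detectors and segmenters (YOLO-family boxes, promptable foundation
## segmenters) are reached only through files written by external tools;
## a classical HSV colour-blob detector provides a GPU-free fallback so the
## geometry pipeline runs end-to-end on synthetic or bench scenes.

## 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
## touch diagonally are merged with a union-find pass.
labelComponents8 <- function(grid) {
  lab <- EBImage::bwlabel(matrix(as.numeric(grid), nrow(grid), ncol(grid)))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right diagonal pairs
  a2 <- lab[-1, -W]; b2 <- lab[-H, -1]   # up-right diagonal pairs
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(nl)
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- pairs[r, 1]; rb <- pairs[r, 2]
      while (parent[ra] != ra) ra <- parent[ra]
      while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- integer(nl)
  for (i in seq_len(nl)) { r <- i; while (parent[r] != r) r <- parent[r]; root[i] <- r }
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

## Hue in degrees [0, 360); s, v in [0, 1]. Returns logical H x W.
hsvInRange <- function(image, low, high) {
  H <- dim(image)[1]; W <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  inHue <- if (low[1] <= high[1]) hue >= low[1] & hue <= high[1]
           else hue >= low[1] | hue <= high[1]   # wrap across 0
  ok <- inHue & hsv[2, ] >= low[2] & hsv[2, ] <= high[2] &
    hsv[3, ] >= low[3] & hsv[3, ] <= high[3]
  matrix(ok, H, W)
}

#' Classical colour-blob fallback detector
#'
#' Thresholds the image in HSV space (hue may wrap across 0) and returns
#' one detection per 8-connected component of in-range pixels with at least
#' \code{minAreaPx} pixels. Confidence is the component's fill ratio
#' (area / bbox area). A stand-in detection source for scenes where no
#' external deep detector output is available; it is not a substitute for
#' one on real field imagery.
#'
#' @param image H x W x 3 numeric array in \code{[0, 1]} (or a
#'   [Frame-class]).
#' @param colorLow,colorHigh HSV triples \code{c(h, s, v)}: hue in degrees
#'   \code{[0, 360)}, saturation/value in \code{[0, 1]}. If
#'   \code{colorLow[1] > colorHigh[1]} the hue interval wraps.
#' @param minAreaPx minimum component area, pixels.
#' @param label species label assigned to every detection.
#' @return detections data.frame (see [loadDetections()]).
#' @export
colorBlobDetect <- function(image, colorLow = c(20, 0.4, 0.3),
                            colorHigh = c(50, 1, 1),
                            minAreaPx = 50L, label = "flower") {
  if (is(image, "Frame")) image <- image@image
  stopifnot(minAreaPx >= 1L)
  sel <- hsvInRange(image, colorLow, colorHigh)
  if (!any(sel)) return(emptyDetections())
  lab <- labelComponents8(sel)
  rows <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)   # (row = v+1, col = u+1)
    if (nrow(idx) < minAreaPx) next
    u <- idx[, 2] - 1L; v <- idx[, 1] - 1L
    xmin <- min(u); xmax <- max(u) + 1L; ymin <- min(v); ymax <- max(v) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax, label = label,
      confidence = nrow(idx) / ((xmax - xmin) * (ymax - ymin)))
  }
  if (length(rows) == 0L) return(emptyDetections())
  det <- do.call(rbind, rows)
  rownames(det) <- NULL
  det
}

#' Pair detections with raw segmentation masks
#'
#' Masks come either from files written by an external segmenter (one PNG
#' per detection, named \code{<frame_id>_det<k>.png}, k 0-based) or from a
#' fallback HSV threshold applied inside each bounding box. Either way the
#' returned mask is restricted to pixels inside its detection's box and is
#' raw: component selection happens later in [cleanMask()].
#'
#' @param frame a [Frame-class].
#' @param detections detections data.frame.
#' @param maskSource \code{"files"} or \code{"fallback_threshold"}.
#' @param maskDir directory containing the mask PNGs (files mode).
#' @param colorLow,colorHigh HSV range for the fallback threshold.
#' @return list of \code{list(detection = <one-row data.frame>,
#'   mask = <BinaryMask>)}, one per detection, order preserved.
#' @export
attachMasks <- function(frame, detections,
                        maskSource = c("files", "fallback_threshold"),
                        maskDir = NULL,
                        colorLow = c(20, 0.4, 0.3), colorHigh = c(50, 1, 1)) {
  maskSource <- match.arg(maskSource)
  H <- dim(frame@image)[1]; W <- dim(frame@image)[2]
  out <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    det <- detections[i, , drop = FALSE]
    if (maskSource == "files") {
      fp <- file.path(maskDir %||% ".",
                      sprintf("%s_det%d.png", frame@frameId, i - 1L))
      if (!file.exists(fp))
        pvStop("mask_missing", "mask missing for detection %d: %s", i - 1L, fp)
      mk <- readMaskPNG(fp, provenance = "external")
      if (!all(dim(mk@grid) == c(H, W)))
        pvStop("grid_mismatch", "mask %s does not match frame grid", fp)
      g <- mk@grid
    } else {
      g <- hsvInRange(frame@image, colorLow, colorHigh)
    }
    ## restrict to the half-open bbox
    keep <- matrix(FALSE, H, W)
    rows <- seq.int(floor(det$ymin) + 1L, ceiling(det$ymax))
    cols <- seq.int(floor(det$xmin) + 1L, ceiling(det$xmax))
    rows <- rows[rows >= 1L & rows <= H]; cols <- cols[cols >= 1L & cols <= W]
    keep[rows, cols] <- TRUE
    g <- g & keep
    out[[i]] <- list(detection = det,
                     mask = BinaryMask(g, provenance = if (maskSource == "files")
                       "external" else "fallback"))
  }
  out
}
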