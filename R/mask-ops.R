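## Mask cleaning and occlusion flagging.
##
## A promptable segmenter can return several disjoint polygons for one box
## prompt even though each box contains a single flower; only the component
## whose centroid is closest to the box centre is kept. Overlapping flowers
## are resolved depth-first: only the shallower (complete) flower of a pair
## is processed, the one beneath is left for the next harvesting pass.

#' Split a mask into 8-connected components
#'
#' @param mask a [BinaryMask-class] or logical matrix.
#' @return list of components, sorted by decreasing pixel area; each is a
#'   list with \code{pixels} (n x 2 integer matrix of 0-based (u, v)),
#'   \code{areaPx} and \code{centroidPx} (mean (u, v) of member pixels).
#'   An all-false mask yields an empty list.
#' @export
splitComponents <- function(mask) {
  g <- if (is(mask, "BinaryMask")) mask@grid else mask
  if (!any(g)) return(list())
  lab <- labelComponents8(g)
  comps <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    uv <- cbind(u = idx[, 2] - 1L, v = idx[, 1] - 1L)
    list(pixels = uv, areaPx = nrow(uv), centroidPx = colMeans(uv))
  })
  comps[order(vapply(comps, `[[`, numeric(1), "areaPx"), decreasing = TRUE)]
}

#' Select the component nearest the bounding-box centre
#'
#' Of all mask polygons inside one box prompt, only the one whose centroid
#' is closest (Euclidean) to the box centre is the flower; ties are broken
#' by larger area, then by lower index.
#'
#' @param components list from [splitComponents()].
#' @param bbox one-row detections data.frame or named vector with
#'   \code{xmin, ymin, xmax, ymax}.
#' @return the selected component.
#' @export
selectComponent <- function(components, bbox) {
  if (length(components) == 0L)
    pvStop("no_component", "no component to select (empty mask)")
  ctr <- bboxCenter(bbox)
  d <- vapply(components, function(cp) vnorm(cp$centroidPx - ctr), numeric(1))
  area <- vapply(components, `[[`, numeric(1), "areaPx")
  ord <- order(d, -area, seq_along(components))
  components[[ord[1]]]
}

#' Clean a raw mask down to its selected component
#'
#' Idempotent: a mask that is already a single component is unchanged.
#'
#' @param mask a [BinaryMask-class].
#' @param bbox the paired detection's box.
#' @return a [BinaryMask-class] containing exactly the selected component.
#' @export
cleanMask <- function(mask, bbox) {
  comp <- selectComponent(splitComponents(mask), bbox)
  g <- matrix(FALSE, nrow(mask@grid), ncol(mask@grid))
  g[cbind(comp$pixels[, "v"] + 1L, comp$pixels[, "u"] + 1L)] <- TRUE
  BinaryMask(g, provenance = mask@provenance)
}

#' Flag occluded flowers among a set of cleaned masks
#'
#' Two flowers are considered to overlap when one mask, dilated by
#' \code{minGapPx}, intersects the other; the deeper one (greater mean
#' depth over its mask pixels) is flagged \code{"occluded"} and skipped by
#' the pipeline, so that only flowers with a complete point cloud are
#' processed. At most one of each overlapping pair is flagged.
#'
#' @param masks list of [BinaryMask-class] sharing the frame grid.
#' @param frame the [Frame-class] supplying per-pixel depth.
#' @param minGapPx dilation radius, pixels (default 3): masks closer than
#'   this are treated as touching.
#' @return character vector, \code{"complete"} or \code{"occluded"}, one
#'   per mask.
#' @export
flagOcclusions <- function(masks, frame, minGapPx = 3L) {
  n <- length(masks)
  if (n == 0L) return(character())
  z <- frame@cloud[, , 3]
  grids <- lapply(masks, function(m) m@grid)
  meanZ <- vapply(grids, function(g) {
    zz <- z[g]; zz <- zz[is.finite(zz)]
    if (length(zz) == 0L) Inf else mean(zz)
  }, numeric(1))
  size <- 2L * as.integer(minGapPx) + 1L
  brush <- EBImage::makeBrush(size, shape = "box")
  dil <- lapply(grids, function(g) {
    EBImage::dilate(matrix(as.numeric(g), nrow(g), ncol(g)), brush) > 0.5
  })
  status <- rep("complete", n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (any(dil[[i]] & grids[[j]]) || any(dil[[j]] & grids[[i]])) {
      deeper <- if (meanZ[i] > meanZ[j]) i else j
      status[deeper] <- "occluded"
    }
  }
  status
}
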