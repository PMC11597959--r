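## Convex-polygon morphometry: hull, Chebyshev centre, flower diameter,
## and the 3D centre point.

#' Exact 2D convex hull
#'
#' Counter-clockwise vertex list of the smallest convex polygon enclosing
#' the points, with duplicate and collinear vertices pruned.
#'
#' @param points n x 2 numeric matrix.
#' @return m x 2 matrix of hull vertices, CCW, m >= 3.
#' @export
convexHull2D <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    pvStop("degenerate_hull", "degenerate hull: need >= 3 points, got %d",
           nrow(points))
  idx <- grDevices::chull(points[, 1], points[, 2])   # clockwise order
  V <- points[rev(idx), , drop = FALSE]               # -> counter-clockwise
  V <- unique(V)
  if (nrow(V) >= 3L) {
    ## prune vertices collinear with their neighbours
    keep <- rep(TRUE, nrow(V))
    m <- nrow(V)
    scale2 <- max(1, max(abs(V))^2)
    for (i in seq_len(m)) {
      a <- V[if (i == 1L) m else i - 1L, ]; b <- V[i, ]
      cc <- V[if (i == m) 1L else i + 1L, ]
      cross <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
      if (abs(cross) <= 1e-12 * scale2) keep[i] <- FALSE
    }
    V <- V[keep, , drop = FALSE]
  }
  if (nrow(V) < 3L)
    pvStop("degenerate_hull", "degenerate hull: points are collinear")
  unname(V)
}

#' Chebyshev centre of a convex polygon
#'
#' The in-polygon point with maximum distance to the boundary — the centre
#' of the maximum inscribed circle — found by solving the linear program
#' max r subject to n_i . p + r <= n_i . v_i over the polygon's edge
#' half-planes (unit outward normals n_i).
#'
#' @param poly m x 2 CCW convex polygon (e.g. from [convexHull2D()]).
#' @return list with \code{center} (length-2 numeric) and \code{radius}.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' chebyshevCenter(sq)  # center (0.5, 0.5), radius 0.5
#' @export
chebyshevCenter <- function(poly) {
  poly <- as.matrix(poly)
  m <- nrow(poly)
  if (m < 3L) pvStop("degenerate_hull", "polygon needs >= 3 vertices")
  ## pracma's simplex assumes non-negative variables: shift the polygon
  ## into the positive quadrant first, shift the solution back after.
  off <- apply(poly, 2, min) - 1
  P <- sweep(poly, 2, off)
  nxt <- c(seq_len(m)[-1], 1L)
  ex <- P[nxt, 1] - P[, 1]; ey <- P[nxt, 2] - P[, 2]
  len <- sqrt(ex^2 + ey^2)
  ok <- len > 1e-12
  nx <- ey[ok] / len[ok]; ny <- -ex[ok] / len[ok]   # outward normal (CCW)
  b <- nx * P[ok, 1] + ny * P[ok, 2]
  A <- cbind(nx, ny, 1)
  sol <- tryCatch(
    pracma::linprog(c(0, 0, 1), A = A, b = b, maximize = TRUE,
                    maxiter = 100 + 20 * nrow(A)),
    error = function(e) NULL)
  if (!is.null(sol) && !is.null(sol$x) && !anyNA(sol$x) &&
      all(A %*% sol$x <= b + 1e-7))
    return(list(center = as.numeric(sol$x[1:2] + off),
                radius = as.numeric(sol$x[3])))
  ## simplex failed: the LP optimum is defined by 3 active half-planes
  ## (or 2 parallel ones); enumerate edge triples analytically
  best <- NULL
  mm <- nrow(A)
  for (i in seq_len(mm - 2)) for (j in seq.int(i + 1, mm - 1))
    for (k in seq.int(j + 1, mm)) {
      M <- A[c(i, j, k), , drop = FALSE]
      x <- tryCatch(solve(M, b[c(i, j, k)]), error = function(e) NULL)
      if (is.null(x) || x[3] < 0) next
      if (all(A %*% x <= b + 1e-9 * max(1, abs(b)))) {
        if (is.null(best) || x[3] > best[3]) best <- x
      }
    }
  if (is.null(best))
    pvStop("degenerate_hull", "Chebyshev centre could not be computed")
  list(center = as.numeric(best[1:2] + off), radius = as.numeric(best[3]))
}

## Project cloud points onto the plane orthogonal to the pose main axis.
projectToFlowerPlane <- function(cloud, pose) {
  Q <- sweep(cloud@points, 2, pose@centroid)
  B <- orthobasis(pose@mainAxis)
  Q %*% B
}

#' Flower diameter from the flower-plane convex hull
#'
#' Projects the flower's points onto the plane orthogonal to the pose main
#' axis through the centroid, takes the convex hull of the projection, and
#' reports the maximum pairwise distance between hull vertices (the
#' antipodal caliper width), converted to millimetres. With
#' \code{method = "inscribed"} the inscribed-circle diameter (twice the
#' Chebyshev radius) is reported instead.
#'
#' @param cloud a [FlowerPointCloud-class].
#' @param pose its [PoseEstimate-class].
#' @param method \code{"calipers"} (default) or \code{"inscribed"}.
#' @return diameter in mm.
#' @export
flowerDiameterMm <- function(cloud, pose, method = c("calipers", "inscribed")) {
  method <- match.arg(method)
  XY <- projectToFlowerPlane(cloud, pose)
  if (nrow(unique(round(XY, 12))) == 2L) {
    ## exactly two distinct projected locations: the diameter is their gap
    U <- unique(round(XY, 12))
    return(1000 * vnorm(U[1, ] - U[2, ]))
  }
  hull <- convexHull2D(XY)
  if (method == "calipers") {
    1000 * max(stats::dist(hull))
  } else {
    2000 * chebyshevCenter(hull)$radius
  }
}

#' Flower centre: Chebyshev centre pixel and its 3D point
#'
#' The pixel centre is the Chebyshev centre of the convex hull of the
#' mask's true pixels. Its 3D position lies on that pixel's viewing ray,
#' at the depth of the top of the flower: the mean of the top decile of
#' the flower's points, where "top" is measured along the main pose axis
#' (the direction \code{h} is defined along). For an upright flower this
#' is the smallest-z decile; for a tilted one it stays the corolla apex
#' rather than the rim leaning toward the camera.
#'
#' @param cloud the flower's [FlowerPointCloud-class].
#' @param mask its cleaned [BinaryMask-class].
#' @param axis unit 3-vector along which "top" is measured; the pose main
#'   axis (default: the camera axis, for strictly face-on use).
#' @param topFraction fraction of top points averaged (default 0.1).
#' @return list with \code{centerPx} (u, v), \code{center3d} (metres) and
#'   \code{radiusPx}.
#' @export
centerPoint3D <- function(cloud, mask, axis = c(0, 0, 1), topFraction = 0.1) {
  idx <- which(mask@grid, arr.ind = TRUE)
  if (nrow(idx) < 3L) pvStop("degenerate_hull", "mask has < 3 pixels")
  uv <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  hull <- convexHull2D(uv)
  cc <- chebyshevCenter(hull)
  ## top-of-flower axial depth: mean of the smallest decile of the axial
  ## coordinate (axis points stem-ward, so small = top of the corolla)
  s <- sort(cloud@points %*% axis)
  sTop <- mean(s[seq_len(max(1L, ceiling(topFraction * length(s))))])
  ## viewing ray through the centre pixel: borrow the direction of the
  ## nearest valid-depth source pixel
  if (nrow(cloud@sourcePixels) == 0L)
    pvStop("no_depth", "no depth: cloud carries no source pixels")
  d2 <- (cloud@sourcePixels[, 1] - cc$center[1])^2 +
    (cloud@sourcePixels[, 2] - cc$center[2])^2
  if (min(d2) > 9)  # nearest valid-depth pixel further than 3 px away
    pvStop("no_depth", "no depth: no finite point within 3 px of the centre")
  p <- cloud@points[which.min(d2), ]
  dir <- p / p[3]                       # ray at unit depth
  proj <- sum(dir * axis)
  if (abs(proj) < 0.1) {                # extreme tilt: fall back to depth
    zTop <- mean(sort(cloud@points[, 3])[
      seq_len(max(1L, ceiling(topFraction * nrow(cloud@points))))])
    center3d <- dir * zTop
  } else {
    center3d <- dir * (sTop / proj)
  }
  list(centerPx = as.numeric(cc$center), center3d = as.numeric(center3d),
       radiusPx = cc$radius)
}
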