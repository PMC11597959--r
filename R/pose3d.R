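## Mask-to-cloud isolation and PCA pose estimation.

#' Isolate a flower's 3D points through its cleaned mask
#'
#' Picks exactly the organized-cloud points at the mask's true pixels;
#' invalid-depth (NaN) points are dropped and counted, never interpolated.
#'
#' @param frame a [Frame-class].
#' @param mask a [BinaryMask-class] on the same grid.
#' @return a [FlowerPointCloud-class] with per-point source pixels.
#' @export
isolatePoints <- function(frame, mask) {
  g <- mask@grid
  if (!all(dim(g) == dim(frame@cloud)[1:2]))
    pvStop("grid_mismatch", "mask grid does not match frame grid")
  idx <- which(g, arr.ind = TRUE)           # (v+1, u+1)
  n <- nrow(idx)
  pts <- cbind(frame@cloud[, , 1][idx], frame@cloud[, , 2][idx],
               frame@cloud[, , 3][idx])
  fin <- rowSums(is.finite(pts)) == 3L
  nFin <- sum(fin)
  if (nFin < 3L)
    pvStop("insufficient_depth",
           "insufficient depth: %d finite point(s) under the mask (need >= 3)",
           nFin)
  FlowerPointCloud(points = pts[fin, , drop = FALSE],
                   sourcePixels = cbind(u = idx[fin, 2] - 1L,
                                        v = idx[fin, 1] - 1L),
                   nDropped = n - nFin)
}

#' Estimate flower pose by principal component analysis
#'
#' Eigen-decomposes the covariance of the mean-centred points. The axes are
#' the eigenvectors in decreasing-eigenvalue order. For disk-like flower
#' faces the surface normal — the direction the stem extends — is the
#' minimum-variance eigenvector, so \code{mainAxisRule = "min_variance"}
#' (the default) takes e3 as the main axis; \code{"max_variance"} takes e1
#' for elongated targets. The main axis sign is fixed so its Z component is
#' non-negative: with a downward-looking camera (+Z into the canopy) it
#' points stem-ward, the direction along which the centre is translated
#' "down" to the plucking point.
#'
#' @param cloud a [FlowerPointCloud-class] (N >= 3).
#' @param mainAxisRule \code{"min_variance"} or \code{"max_variance"}.
#' @return a [PoseEstimate-class].
#' @export
pcaPose <- function(cloud, mainAxisRule = c("min_variance", "max_variance")) {
  mainAxisRule <- match.arg(mainAxisRule)
  P <- cloud@points
  if (nrow(P) < 3L)
    pvStop("insufficient_depth", "need >= 3 points for pose, got %d", nrow(P))
  ctr <- colMeans(P)
  C <- stats::cov(P)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (ev[2] <= 1e-10 * max(ev[1], .Machine$double.eps))
    pvStop("degenerate_geometry",
           "degenerate geometry: points are (numerically) collinear")
  A <- eg$vectors
  ## deterministic eigenvector signs: largest-|.| entry positive
  for (k in 1:3) {
    m <- which.max(abs(A[, k]))
    if (A[m, k] < 0) A[, k] <- -A[, k]
  }
  u <- if (mainAxisRule == "min_variance") A[, 3] else A[, 1]
  if (u[3] < 0) u <- -u
  new("PoseEstimate", axes = A, eigenvalues = ev, mainAxis = u,
      centroid = ctr)
}

#' Sign-agnostic angle between two 3D directions
#'
#' \code{acos(|u . v|)} in degrees: the angle between the lines spanned by
#' the two unit vectors, in \code{[0, 90]}.
#'
#' @param u,v unit 3-vectors.
#' @return angle in degrees.
#' @examples
#' angularError(c(0, 0, 1), c(0, 1, 1) / sqrt(2))  # 45
#' @export
angularError <- function(u, v) {
  if (abs(vnorm(u) - 1) > 1e-6 || abs(vnorm(v) - 1) > 1e-6)
    pvStop("contract", "angularError expects unit vectors")
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
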