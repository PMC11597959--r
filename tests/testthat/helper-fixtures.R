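## Shared fixture builders: tiny frames, disk masks, rotations.

## H x W x 3 cloud with constant depth z0 (plus optional NaN pixels given
## as a 2-column (v+1, u+1) index matrix), pinhole-consistent x,y.
flatCloud <- function(H, W, z0 = 0.5, f = 700,
                      cx = (W - 1) / 2, cy = (H - 1) / 2, naIdx = NULL) {
  u <- matrix(rep(0:(W - 1), each = H), H, W)
  v <- matrix(rep(0:(H - 1), W), H, W)
  cloud <- array(0, c(H, W, 3))
  cloud[, , 1] <- (u - cx) / f * z0
  cloud[, , 2] <- (v - cy) / f * z0
  cloud[, , 3] <- z0
  if (!is.null(naIdx)) for (k in 1:3) {
    p <- cloud[, , k]; p[naIdx] <- NaN; cloud[, , k] <- p
  }
  cloud
}

tinyFrame <- function(H = 8, W = 8, z0 = 0.5, naIdx = NULL, id = "tiny") {
  img <- array(0.5, c(H, W, 3))
  Frame(image = img, cloud = flatCloud(H, W, z0, naIdx = naIdx), frameId = id)
}

## logical H x W mask with a filled disk (0-based centre, radius in px)
diskMask <- function(H, W, cu, cv, r) {
  u <- matrix(rep(0:(W - 1), each = H), H, W)
  v <- matrix(rep(0:(H - 1), W), H, W)
  (u - cu)^2 + (v - cv)^2 <= r^2
}

## random 3D rotation matrix (uniform via QR of a Gaussian matrix)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotationX <- function(deg) {
  th <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
}

## points on a disk of given radius (m) in the z = z0 plane, optional rim
diskPoints <- function(n, radius, z0 = 0.5, rim = 0.05) {
  nr <- round(rim * n)
  r <- c(radius * sqrt(runif(n - nr)), rep(radius, nr))
  phi <- runif(n) * 2 * pi
  P <- cbind(r * cos(phi), r * sin(phi), z0)
  dimnames(P) <- NULL
  P
}

## brute-force Chebyshev oracle: dense grid over the polygon's bounding
## box; distance of an interior point to a convex CCW polygon's boundary
## is the min over edges of (b_i - n_i . p)
gridChebyshev <- function(poly, pitch = 1e-3) {
  m <- nrow(poly)
  nxt <- c(2:m, 1)
  ex <- poly[nxt, 1] - poly[, 1]; ey <- poly[nxt, 2] - poly[, 2]
  len <- sqrt(ex^2 + ey^2)
  nx <- ey / len; ny <- -ex / len
  b <- nx * poly[, 1] + ny * poly[, 2]
  xs <- seq(min(poly[, 1]), max(poly[, 1]), by = pitch)
  ys <- seq(min(poly[, 2]), max(poly[, 2]), by = pitch)
  best <- -Inf; bestPt <- c(NA, NA)
  for (x in xs) {
    d <- b - nx * x - outer(ny, ys)      # m x |ys| signed distances
    dmin <- apply(d, 2, min)
    j <- which.max(dmin)
    if (dmin[j] > best) { best <- dmin[j]; bestPt <- c(x, ys[j]) }
  }
  list(center = bestPt, radius = best)
}

## random convex polygon: hull of uniform points in the unit square
randomConvexPolygon <- function(nPts = 12) {
  convexHull2D(cbind(runif(nPts), runif(nPts)))
}

## independent OLS oracle: closed-form normal equations
olsOracle <- function(d, h) {
  n <- length(d)
  sxx <- sum(d^2) - sum(d)^2 / n
  sxy <- sum(d * h) - sum(d) * sum(h) / n
  a <- sxy / sxx
  b <- mean(h) - a * mean(d)
  c(a = a, b = b)
}

pluckErrorsMm <- function(results, gt) {
  df <- resultsToDataFrame(results)
  sqrt((df$pluck_x - gt$pluck_x)^2 + (df$pluck_y - gt$pluck_y)^2 +
         (df$pluck_z - gt$pluck_z)^2) * 1000
}

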