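test_that("convex hull is exact, CCW, and prunes collinear vertices", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  hull <- convexHull2D(pts)
  expect_identical(nrow(hull), 4L)
  ## CCW: shoelace area positive, equal to 1
  m <- nrow(hull); nxt <- c(2:m, 1)
  area <- sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2]) / 2
  expect_equal(area, 1)
  ## collinear midpoints are pruned
  hull2 <- convexHull2D(rbind(pts, c(0.5, 0), c(1, 0.5)))
  expect_identical(nrow(hull2), 4L)
  ## all input points inside or on the hull (brute-force half-plane check)
  set.seed(61)
  th <- runif(100) * 2 * pi; r <- sqrt(runif(100))
  P <- cbind(r * cos(th), r * sin(th))
  h <- convexHull2D(P)
  mh <- nrow(h); nxt <- c(2:mh, 1)
  for (i in seq_len(mh)) {
    cross <- (h[nxt[i], 1] - h[i, 1]) * (P[, 2] - h[i, 2]) -
      (h[nxt[i], 2] - h[i, 2]) * (P[, 1] - h[i, 1])
    expect_true(all(cross >= -1e-12))    # every point left of every CCW edge
  }
  expect_error(convexHull2D(cbind(1:5, 2 * (1:5))),
               class = "pluckvision_degenerate_hull")
  expect_error(convexHull2D(rbind(c(0, 0), c(1, 1))),
               class = "pluckvision_degenerate_hull")
})

test_that("Chebyshev centre matches closed forms on square and right triangle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  cc <- chebyshevCenter(sq)
  expect_equal(cc$center, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(cc$radius, 0.5, tolerance = 1e-9)
  ## 3-4-5 right triangle: incircle r = (3 + 4 - 5)/2 = 1 at (1, 1)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  ci <- chebyshevCenter(convexHull2D(rbind(tri, c(1, 0.5))))
  expect_equal(ci$center, c(1, 1), tolerance = 1e-9)
  expect_equal(ci$radius, 1, tolerance = 1e-9)
})

test_that("Chebyshev centre agrees with a dense-grid brute-force maximizer", {
  set.seed(71)
  pitch <- 1e-3
  for (k in 1:8) {
    poly <- randomConvexPolygon(10)
    cc <- chebyshevCenter(poly)
    oracle <- gridChebyshev(poly, pitch)
    expect_equal(cc$radius, oracle$radius, tolerance = 2 * pitch)
    ## radius <= circumradius; centre strictly inside
    ctr <- colMeans(poly)
    circum <- max(sqrt(rowSums(sweep(poly, 2, ctr)^2)))
    expect_lt(cc$radius, circum + 1e-12)
    m <- nrow(poly); nxt <- c(2:m, 1)
    cross <- (poly[nxt, 1] - poly[, 1]) * (cc$center[2] - poly[, 2]) -
      (poly[nxt, 2] - poly[, 2]) * (cc$center[1] - poly[, 1])
    expect_true(all(cross > 0))
  }
})

test_that("caliper diameter recovers a circle and is rigid-motion invariant", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circle <- cbind(0.018 * cos(th), 0.018 * sin(th), 0.5)   # r = 18 mm
  cl <- FlowerPointCloud(circle)
  pose <- pcaPose(cl)
  expect_equal(flowerDiameterMm(cl, pose), 36, tolerance = 1e-6)
  ## rigid motion: rotate 30 deg about X and translate
  R <- rotationX(30)
  moved <- sweep(circle %*% t(R), 2, c(0.05, -0.02, 0.2), "+")
  cl2 <- FlowerPointCloud(moved)
  d2 <- flowerDiameterMm(cl2, pcaPose(cl2))
  expect_equal(d2, 36, tolerance = 36 * 1e-6)
  set.seed(81)
  P0 <- diskPoints(200, 0.014, 0)        # local flower frame
  cl0 <- FlowerPointCloud(sweep(P0, 2, c(0, 0, 0.6), "+"))
  d0 <- flowerDiameterMm(cl0, pcaPose(cl0))
  for (k in 1:5) {
    Rr <- randomRotation()
    P <- sweep(P0 %*% t(Rr), 2, c(0, 0, 0.6), "+")
    clr <- FlowerPointCloud(P)
    dr <- flowerDiameterMm(clr, pcaPose(clr))
    expect_equal(dr, d0, tolerance = 1e-6)
  }
})

test_that("two distinct projected points define the diameter directly", {
  P <- rbind(c(0, 0, 0.5), c(0.01, 0, 0.5), c(0, 0, 0.5))
  cl <- FlowerPointCloud(P)
  pose <- new("PoseEstimate", axes = diag(3), eigenvalues = c(1, 1, 0) * 1e-5,
              mainAxis = c(0, 0, 1), centroid = colMeans(P))
  expect_equal(flowerDiameterMm(cl, pose), 10, tolerance = 1e-9)
})

test_that("diameter is at least the inscribed-circle diameter on synthetic disks", {
  set.seed(91)
  fl <- SyntheticFlower("marigold", c(0, 0, 0.5), c(0, 0, 1), 36)
  cl <- makeFlowerCloud(fl, 400, noiseSdMm = 0, seed = 7)
  pose <- pcaPose(cl)
  expect_gte(flowerDiameterMm(cl, pose, method = "calipers"),
             flowerDiameterMm(cl, pose, method = "inscribed") - 1e-9)
})

test_that("noisy synthetic flowers at species scales are measured within 2 mm", {
  set.seed(101)
  for (d in c(28, 36, 60)) {
    R <- rotationX(10)              # upright posture, modest tilt
    fl <- SyntheticFlower("x", c(0, 0, 0.5), as.numeric(R %*% c(0, 0, 1)),
                          diameterMm = d, domeHeightMm = d / 10)
    cl <- makeFlowerCloud(fl, 500, noiseSdMm = 1, seed = 200 + d)
    est <- flowerDiameterMm(cl, pcaPose(cl))
    expect_lt(abs(est - d), 2)
  }
})

test_that("centre point sits at the mask centre, at top-decile axial depth", {
  H <- 80; W <- 80
  m <- diskMask(H, W, 40, 40, 18)
  fr <- tinyFrame(H, W, 0.5, id = "ctr")
  cl <- isolatePoints(fr, BinaryMask(m))
  ctr <- centerPoint3D(cl, BinaryMask(m))
  expect_equal(ctr$centerPx, c(40, 40), tolerance = 0.75)
  expect_equal(ctr$center3d[3], 0.5, tolerance = 1e-9)   # constant depth

  ## dome: apex z = 0.48, rim z = 0.50 -> top-decile mean just above apex
  set.seed(111)
  fl <- SyntheticFlower("x", c(0, 0, 0.48), c(0, 0, 1),
                        diameterMm = 40, domeHeightMm = 20)
  cl2 <- makeFlowerCloud(fl, 2000, noiseSdMm = 0, seed = 3)
  ## oracle: recompute the expected top-decile mean from the same points
  z <- sort(cloudPoints(cl2)[, 3])
  zTop <- mean(z[seq_len(ceiling(0.1 * length(z)))])
  expect_gte(zTop, 0.48); expect_lte(zTop, 0.482)
  cl2@sourcePixels <- cbind(u = rep(40L, nrow(cloudPoints(cl2))),
                            v = rep(40L, nrow(cloudPoints(cl2))))
  ctr2 <- centerPoint3D(cl2, BinaryMask(m))
  expect_equal(ctr2$center3d[3], zTop, tolerance = 1e-6)

  ## no finite depth near the centre -> no_depth
  naIdx <- which(diskMask(H, W, 40, 40, 6), arr.ind = TRUE)
  frNA <- tinyFrame(H, W, 0.5, naIdx = naIdx)
  clNA <- isolatePoints(frNA, BinaryMask(m))
  expect_error(centerPoint3D(clNA, BinaryMask(m)),
               class = "pluckvision_no_depth")
})
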