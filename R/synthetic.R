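## Synthetic RGB-D scene generator with exact ground truth.
##
## Flowers are modelled as spherical caps (dome height 0 = flat disk) seen
## by a pinhole camera above a flat bench. This is deliberately minimal:
## the downstream geometry uses only point statistics, so a cap exercises
## every code path (PCA, hull, Chebyshev centre, boundary translation)
## while keeping ground truth exact.

speciesColor <- function(species) {
  switch(species,
         marigold = c(1.00, 0.55, 0.05),
         snapdragon = c(0.95, 0.90, 0.15),
         pansy = c(0.55, 0.25, 0.75),
         c(0.9, 0.2, 0.2))
}

## Sphere radius of a cap with rim radius a and sagitta hc (hc > 0).
capSphereRadius <- function(a, hc) (a^2 + hc^2) / (2 * hc)

#' Sample a synthetic flower's point cloud
#'
#' Points are drawn on the flower's cap surface: uniform over the projected
#' disk, with a fixed fraction placed exactly on the rim circle so the true
#' diameter is represented in every draw, then rotated so the cap normal is
#' the flower's main axis, translated to its centre, and perturbed by
#' Gaussian noise of \code{noiseSdMm}. The default noise model perturbs
#' depth along the camera ray, the way a stereo RGB-D sensor errs
#' (lateral error is sub-pixel); \code{"isotropic"} perturbs all three
#' coordinates.
#'
#' @param flower a [SyntheticFlower-class].
#' @param nPoints number of points (>= 3).
#' @param noiseSdMm noise standard deviation, mm.
#' @param seed integer seed; same seed, same cloud.
#' @param noiseModel \code{"depth"} (default) or \code{"isotropic"}.
#' @param rimFraction fraction of points placed on the rim (default 0.05).
#' @return a [FlowerPointCloud-class] (no source pixels).
#' @export
makeFlowerCloud <- function(flower, nPoints = 500L, noiseSdMm = 0,
                            seed = 1L, noiseModel = c("depth", "isotropic"),
                            rimFraction = 0.05) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(nPoints >= 3L, noiseSdMm >= 0)
  a <- flower@diameterMm / 2000            # rim radius, metres
  hc <- flower@domeHeightMm / 1000
  withSeed(seed, {
    nRim <- round(rimFraction * nPoints)
    r <- c(a * sqrt(stats::runif(nPoints - nRim)), rep(a, nRim))
    phi <- stats::runif(nPoints) * 2 * pi
    sag <- if (hc > 0) {
      R <- capSphereRadius(a, hc)
      R - sqrt(pmax(0, R^2 - r^2))
    } else rep(0, nPoints)
    B <- orthobasis(flower@mainAxis)
    P <- flower@center3d[col(matrix(0, nPoints, 3))] +
      outer(r * cos(phi), B[, 1]) + outer(r * sin(phi), B[, 2]) +
      outer(sag, flower@mainAxis)
    dim(P) <- c(nPoints, 3)
    if (noiseSdMm > 0) {
      if (noiseModel == "depth") {
        ## perturb along each point's viewing ray (camera at the origin)
        eps <- stats::rnorm(nPoints, 0, noiseSdMm / 1000)
        P <- P * (1 + eps / P[, 3])
      } else {
        P <- P + matrix(stats::rnorm(3 * nPoints, 0, noiseSdMm / 1000),
                        nPoints, 3)
      }
    }
    FlowerPointCloud(points = P)
  })
}

#' Render a synthetic RGB-D scene
#'
#' Ray-casts each flower's cap against a pinhole camera over a flat
#' background bench, filling an organized cloud (one point per pixel),
#' a species-coloured image, per-flower exact masks and tight boxes, and a
#' ground-truth table. Where flowers overlap in the image the nearer one
#' wins the pixel (z-buffer), so the mask of the flower beneath is missing
#' the overlap — exactly the situation the occlusion-skip rule handles.
#'
#' @param flowers list of [SyntheticFlower-class].
#' @param camera a [CameraModel-class].
#' @param backgroundDepthM bench depth, metres.
#' @param noiseSdMm depth noise applied to flower pixels, mm.
#' @param seed integer seed.
#' @param frameId frame identifier.
#' @return list with \code{frame} ([Frame-class]), \code{detections}
#'   (data.frame), \code{masks} (list of [BinaryMask-class]), and
#'   \code{groundTruth} (data.frame: species, centre, axis, diameter,
#'   h, plucking point per flower).
#' @export
renderScene <- function(flowers, camera = CameraModel(),
                        backgroundDepthM = 0.7, noiseSdMm = 0, seed = 1L,
                        frameId = "synthetic") {
  W <- camera@width; H <- camera@height
  f <- camera@focalPx; cx <- camera@cx; cy <- camera@cy
  ## background bench plane
  u <- matrix(rep(0:(W - 1), each = H), H, W)
  v <- matrix(rep(0:(H - 1), W), H, W)
  z <- matrix(backgroundDepthM, H, W)
  cloudX <- (u - cx) / f * z
  cloudY <- (v - cy) / f * z
  cloudZ <- z
  image <- array(0, c(H, W, 3))
  image[, , 2] <- 0.35                     # bench green
  owner <- matrix(0L, H, W)
  withSeed(seed, {
    for (k in seq_along(flowers)) {
      fl <- flowers[[k]]
      if (fl@center3d[3] <= 0)
        pvStop("contract", "flower %d is behind the camera", k)
      a <- fl@diameterMm / 2000; hc <- fl@domeHeightMm / 1000
      apex <- fl@center3d; ax <- fl@mainAxis
      ## candidate pixels: projection of a bounding sphere around the cap
      rad <- sqrt(a^2 + hc^2)
      zNear <- max(1e-3, apex[3] - rad)
      ctrU <- apex[1] / apex[3] * f + cx; ctrV <- apex[2] / apex[3] * f + cy
      rPx <- ceiling(rad / zNear * f) + 2L
      us <- max(0L, floor(ctrU - rPx)):min(W - 1L, ceiling(ctrU + rPx))
      vs <- max(0L, floor(ctrV - rPx)):min(H - 1L, ceiling(ctrV + rPx))
      if (length(us) == 0L || length(vs) == 0L) next
      uu <- rep(us, each = length(vs)); vv <- rep(vs, length(us))
      dx <- (uu - cx) / f; dy <- (vv - cy) / f    # ray = t * (dx, dy, 1)
      if (hc > 0) {
        R <- capSphereRadius(a, hc)
        s <- apex + R * ax                        # sphere centre
        bq <- -2 * (dx * s[1] + dy * s[2] + s[3])
        aq <- dx^2 + dy^2 + 1
        cq <- sum(s^2) - R^2
        disc <- bq^2 - 4 * aq * cq
        hit <- disc >= 0
        t <- rep(NA_real_, length(uu))
        t[hit] <- (-bq[hit] - sqrt(disc[hit])) / (2 * aq[hit])  # near root
        px <- t * dx; py <- t * dy; pz <- t
        axial <- (px - apex[1]) * ax[1] + (py - apex[2]) * ax[2] +
          (pz - apex[3]) * ax[3]
        hit <- hit & !is.na(t) & t > 0 & axial >= -1e-12 & axial <= hc + 1e-12
      } else {
        denom <- dx * ax[1] + dy * ax[2] + ax[3]
        t <- sum(apex * ax) / denom
        px <- t * dx; py <- t * dy; pz <- t
        rr2 <- (px - apex[1])^2 + (py - apex[2])^2 + (pz - apex[3])^2
        hit <- abs(denom) > 1e-9 & t > 0 & rr2 <= a^2 + 1e-15
      }
      if (!any(hit)) next
      uu <- uu[hit]; vv <- vv[hit]; pz <- pz[hit]
      if (noiseSdMm > 0) pz <- pz + stats::rnorm(length(pz), 0, noiseSdMm / 1000)
      lin <- cbind(vv + 1L, uu + 1L)
      nearer <- pz < z[lin]
      lin <- lin[nearer, , drop = FALSE]
      pz <- pz[nearer]; uu <- uu[nearer]; vv <- vv[nearer]
      z[lin] <- pz
      owner[lin] <- k
      cloudX[lin] <- (uu - cx) / f * pz
      cloudY[lin] <- (vv - cy) / f * pz
      cloudZ[lin] <- pz
      col <- speciesColor(fl@species)
      for (ch in 1:3) {
        plane <- image[, , ch]; plane[lin] <- col[ch]; image[, , ch] <- plane
      }
    }
  })
  cloud <- array(c(cloudX, cloudY, cloudZ), c(H, W, 3))
  frame <- Frame(image = image, cloud = cloud, frameId = frameId)
  masks <- list(); rows <- list()
  for (k in seq_along(flowers)) {
    fl <- flowers[[k]]
    g <- owner == k
    masks[[k]] <- BinaryMask(g, provenance = "external")
    idx <- which(g, arr.ind = TRUE)
    bbox <- if (nrow(idx) > 0)
      c(min(idx[, 2]) - 1L, min(idx[, 1]) - 1L, max(idx[, 2]), max(idx[, 1]))
    else c(0, 0, 0, 0)
    rows[[k]] <- data.frame(
      xmin = bbox[1], ymin = bbox[2], xmax = bbox[3], ymax = bbox[4],
      label = fl@species, confidence = 1)
  }
  if (length(flowers) == 0L)
    return(list(frame = frame, detections = emptyDetections(),
                masks = list(), groundTruth = NULL))
  gt <- do.call(rbind, lapply(flowers, function(fl) {
    data.frame(species = fl@species,
               center_x = fl@center3d[1], center_y = fl@center3d[2],
               center_z = fl@center3d[3],
               axis_x = fl@mainAxis[1], axis_y = fl@mainAxis[2],
               axis_z = fl@mainAxis[3],
               diameter_mm = fl@diameterMm, dome_mm = fl@domeHeightMm,
               h_mm = fl@trueHMm,
               pluck_x = fl@truePluckPoint[1], pluck_y = fl@truePluckPoint[2],
               pluck_z = fl@truePluckPoint[3])
  }))
  list(frame = frame, detections = do.call(rbind, rows), masks = masks,
       groundTruth = gt)
}

#' Default per-species measurement-generator parameters
#'
#' Slopes and intercepts are the published calibration values; diameter
#' ranges are centred on the species' typical sizes (snapdragon ~28 mm,
#' marigold ~36 mm, pansy up to 60 mm, with a two-component mixture
#' emulating the two pooled pansy varieties). Residual spread defaults to
#' 8 mm, homoscedastic.
#'
#' @return data.frame with columns \code{species, a, b, sigma_mm, d_min,
#'   d_max, d_min2, d_max2, mix_w}.
#' @export
defaultSpeciesParams <- function() {
  data.frame(
    species = c("pansy", "snapdragon", "marigold"),
    a = c(0.36, 0.38, 0.66),
    b = c(26.33, 5.33, 7.10),
    sigma_mm = c(8, 8, 8),
    d_min = c(30, 20, 28), d_max = c(48, 36, 44),
    d_min2 = c(48, NA, NA), d_max2 = c(60, NA, NA),
    mix_w = c(0.75, 1, 1))
}

#' Generate a synthetic caliper-measurement table
#'
#' Draws diameters uniformly in each species' range (two-component uniform
#' mixture where configured) and heights from \code{h = a d + b +
#' N(0, sigma)}.
#'
#' @param speciesParams parameter table, see [defaultSpeciesParams()].
#' @param nPerSpecies measurements per species (default 100, i.e. 300
#'   flowers over the three default species).
#' @param seed integer seed.
#' @return measurements data.frame (\code{species, d_mm, h_mm}).
#' @export
makeMeasurements <- function(speciesParams = defaultSpeciesParams(),
                             nPerSpecies = 100L, seed = 1L) {
  withSeed(seed, {
    out <- lapply(seq_len(nrow(speciesParams)), function(i) {
      p <- speciesParams[i, ]
      useMain <- stats::runif(nPerSpecies) < p$mix_w
      d <- ifelse(useMain | is.na(p$d_min2),
                  stats::runif(nPerSpecies, p$d_min, p$d_max),
                  stats::runif(nPerSpecies, p$d_min2, p$d_max2))
      h <- p$a * d + p$b + stats::rnorm(nPerSpecies, 0, p$sigma_mm)
      data.frame(species = p$species, d_mm = d, h_mm = pmax(h, 0.1))
    })
    do.call(rbind, out)
  })
}

#' Write a rendered scene to disk in the pipeline's input formats
#'
#' PNG image, organized PLY cloud, YOLO-format detections, per-detection
#' mask PNGs and a ground-truth CSV — the same formats [loadFrame()],
#' [loadDetections()] and [attachMasks()] read back.
#'
#' @param scene output of [renderScene()].
#' @param dir output directory (created if missing).
#' @param classMap species labels, index = YOLO class id + 1.
#' @return named list of written paths.
#' @export
writeScene <- function(scene, dir,
                       classMap = c("pansy", "snapdragon", "marigold")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- scene$frame@frameId
  H <- dim(scene$frame@image)[1]; W <- dim(scene$frame@image)[2]
  imgPath <- file.path(dir, paste0(id, ".png"))
  png::writePNG(scene$frame@image, imgPath)
  plyPath <- file.path(dir, paste0(id, ".ply"))
  writeOrganizedPLY(scene$frame@cloud, plyPath)
  detPath <- file.path(dir, paste0(id, ".txt"))
  det <- scene$detections
  cls <- match(det$label, classMap) - 1L
  if (anyNA(cls)) pvStop("format", "species not in class map: %s",
                         paste(unique(det$label[is.na(cls)]), collapse = ", "))
  lines <- sprintf("%d %.8f %.8f %.8f %.8f", cls,
                   (det$xmin + det$xmax) / 2 / W, (det$ymin + det$ymax) / 2 / H,
                   (det$xmax - det$xmin) / W, (det$ymax - det$ymin) / H)
  writeLines(lines, detPath)
  maskPaths <- character(length(scene$masks))
  for (i in seq_along(scene$masks)) {
    maskPaths[i] <- file.path(dir, sprintf("%s_det%d.png", id, i - 1L))
    writeMaskPNG(scene$masks[[i]], maskPaths[i])
  }
  gtPath <- file.path(dir, paste0(id, "_truth.csv"))
  utils::write.csv(scene$groundTruth, gtPath, row.names = FALSE)
  list(image = imgPath, cloud = plyPath, detections = detPath,
       masks = maskPaths, groundTruth = gtPath)
}
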