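test_that("organized PLY round-trips a cloud with NaN rows, both formats", {
  cloud <- flatCloud(6, 5, 0.5, naIdx = rbind(c(2, 3), c(5, 1), c(6, 5)))
  for (fmt in c("ascii", "binary_little_endian")) {
    path <- tempfile(fileext = ".ply")
    writeOrganizedPLY(cloud, path, format = fmt)
    back <- readOrganizedPLY(path)
    expect_identical(back$width, 5L)
    expect_identical(back$height, 6L)
    finite <- is.finite(back$cloud)
    expect_equal(sum(is.finite(back$cloud[, , 3])), 27)  # 30 - 3 NaN
    expect_equal(back$cloud[finite], cloud[is.finite(cloud)],
                 tolerance = 1e-6)  # float32 storage
    expect_true(all(is.nan(back$cloud[!finite])))
    unlink(path)
  }
})

test_that("loadFrame couples image and cloud, preserving invalid depth", {
  dir <- withr::local_tempdir()
  H <- 4L; W <- 4L
  img <- array(runif(H * W * 3), c(H, W, 3))
  png::writePNG(img, file.path(dir, "f.png"))
  cloud <- flatCloud(H, W, 0.4, naIdx = rbind(c(1, 1), c(2, 2), c(3, 4)))
  writeOrganizedPLY(cloud, file.path(dir, "f.ply"))
  fr <- loadFrame(file.path(dir, "f.png"), file.path(dir, "f.ply"))
  expect_s4_class(fr, "Frame")
  expect_equal(sum(is.finite(frameCloud(fr)[, , 3])), 13)  # 16 - 3
  ## never interpolated: NaN pixels stay NaN
  expect_true(is.nan(frameCloud(fr)[1, 1, 3]))
  ## grid mismatch is a hard error
  writeOrganizedPLY(flatCloud(5, 4, 0.4), file.path(dir, "bad.ply"))
  expect_error(loadFrame(file.path(dir, "f.png"), file.path(dir, "bad.ply")),
               class = "pluckvision_grid_mismatch")
  expect_error(loadFrame(file.path(dir, "nope.png"), file.path(dir, "f.ply")),
               class = "pluckvision_io")
})

test_that("a full 1280x720 frame carries 921,600 cloud entries", {
  dir <- withr::local_tempdir()
  png::writePNG(array(0, c(720, 1280, 3)), file.path(dir, "big.png"))
  writeOrganizedPLY(flatCloud(720, 1280, 0.5), file.path(dir, "big.ply"))
  fr <- loadFrame(file.path(dir, "big.png"), file.path(dir, "big.ply"))
  expect_identical(prod(dim(frameCloud(fr))[1:2]), 921600)
})

test_that("YOLO txt parsing converts normalized centres to pixel corners", {
  p <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.5 0.5", p)
  det <- loadDetections(p, "yolo_txt", imageSize = c(100, 100),
                        classMap = "marigold")
  expect_equal(unlist(det[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 25, ymin = 25, xmax = 75, ymax = 75))
  expect_identical(det$label, "marigold")
  ## empty file -> empty detections
  writeLines(character(), p)
  expect_identical(nrow(loadDetections(p, "yolo_txt", c(100, 100))), 0L)
  ## out-of-range normalized coordinates are a format error
  writeLines("0 1.5 0.5 0.2 0.2", p)
  expect_error(loadDetections(p, "yolo_txt", c(100, 100)),
               class = "pluckvision_format")
  ## unknown class index without a map entry
  writeLines("7 0.5 0.5 0.2 0.2", p)
  expect_error(loadDetections(p, "yolo_txt", c(100, 100),
                              classMap = c("a", "b")),
               class = "pluckvision_format")
})

test_that("COCO JSON parsing converts xywh to corners and keeps order", {
  p <- tempfile(fileext = ".json")
  doc <- list(
    annotations = list(
      list(bbox = c(10, 20, 30, 40), category_id = 1, score = 0.9),
      list(bbox = c(0, 0, 5, 5), category_id = 2)),
    categories = list(list(id = 1, name = "pansy"),
                      list(id = 2, name = "marigold")))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), p)
  det <- loadDetections(p, "coco_json", imageSize = c(200, 200))
  expect_equal(unlist(det[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 10, ymin = 20, xmax = 40, ymax = 60))
  expect_identical(det$label, c("pansy", "marigold"))
  expect_equal(det$confidence[1], 0.9)
})

test_that("results JSON round-trips losslessly, nulling non-ok geometry", {
  expect_identical(length(readResults(writeResults(list(), tempfile()))), 0L)
  det <- data.frame(xmin = 1, ymin = 2, xmax = 30, ymax = 40,
                    label = "pansy", confidence = 0.77)
  pose <- pcaPose(FlowerPointCloud(diskPoints(50, 0.02)))
  h <- 41.3
  ctr <- c(0.011, -0.002, 0.498)
  ok <- new("FlowerResult", detection = det, centerPx = c(15.25, 21.5),
            center3d = ctr, diameterMm = 36.2, hMm = h,
            pluckPoint3d = ctr + h / 1000 * mainAxis(pose),
            pose = pose, status = "ok")
  bad <- new("FlowerResult", detection = det, centerPx = rep(NaN, 2),
             center3d = rep(NaN, 3), diameterMm = NaN, hMm = NaN,
             pluckPoint3d = rep(NaN, 3), pose = NULL, status = "no_depth")
  path <- tempfile(fileext = ".json")
  writeResults(list(ok, bad), path)
  back <- readResults(path)
  expect_equal(back[[1]]@pluckPoint3d, ok@pluckPoint3d, tolerance = 1e-9)
  expect_equal(back[[1]]@diameterMm, 36.2, tolerance = 1e-9)
  expect_equal(poseAxes(back[[1]]@pose), poseAxes(pose), tolerance = 1e-9)
  expect_identical(back[[2]]@status, "no_depth")
  expect_true(all(is.nan(back[[2]]@pluckPoint3d)))
  ## the raw JSON stores nulls for the failed record
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_null(doc$flowers[[2]]$pluck_point_3d)
})

test_that("measurement CSV reader enforces schema and positivity", {
  p <- tempfile(fileext = ".csv")
  writeMeasurements(data.frame(species = "pansy", d_mm = 40, h_mm = 55), p)
  m <- readMeasurements(p)
  expect_identical(names(m), c("species", "d_mm", "h_mm"))
  writeLines("species,d_mm,h_mm\npansy,-3,10", p)
  expect_error(readMeasurements(p), class = "pluckvision_format")
})
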