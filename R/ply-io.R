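## Organized point-cloud PLY input/output.
##
## The organized layout is carried in `obj_info width`/`obj_info height`
## header lines; vertices are stored row-major (row v, column u at index
## v*W + u), per-vertex float32 x,y,z in metres. NaN encodes invalid depth.

#' Read an organized point cloud from PLY
#'
#' Supports ascii and binary_little_endian PLY with per-vertex float
#' \code{x,y,z} properties and \code{obj_info width}/\code{height} grid
#' metadata. Invalid-depth points (\code{NaN}) are preserved, never
#' interpolated or dropped.
#'
#' @param path PLY file path.
#' @return list with \code{cloud} (H x W x 3 numeric array, metres),
#'   \code{width}, \code{height}.
#' @export
readOrganizedPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) pvStop("io", "not a PLY file: %s", path)
  fmt <- NULL; width <- NA_integer_; height <- NA_integer_
  nvert <- NA_integer_; props <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) pvStop("io", "truncated PLY header in %s", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "obj_info" && length(tok) >= 3) {
      if (tok[2] == "width") width <- as.integer(tok[3])
      if (tok[2] == "height") height <- as.integer(tok[3])
    } else if (tok[1] == "element" && tok[2] == "vertex")
      nvert <- as.integer(tok[3])
    else if (tok[1] == "property" && length(tok) == 3) props <- c(props, tok[3])
    else if (tok[1] == "end_header") break
  }
  if (is.na(width) || is.na(height))
    pvStop("io", "PLY %s lacks obj_info width/height grid metadata", path)
  if (is.na(nvert)) pvStop("io", "PLY %s lacks a vertex element", path)
  if (nvert != width * height)
    pvStop("grid_mismatch",
           "PLY %s: %d vertices but %d x %d grid metadata",
           path, nvert, width, height)
  if (!all(c("x", "y", "z") %in% props))
    pvStop("io", "PLY %s lacks x/y/z vertex properties", path)
  np <- length(props)
  if (identical(fmt, "ascii")) {
    vals <- scan(con, what = numeric(), n = nvert * np, quiet = TRUE)
    M <- matrix(vals, ncol = np, byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    vals <- readBin(con, "numeric", n = nvert * np, size = 4L,
                    endian = "little")
    M <- matrix(vals, ncol = np, byrow = TRUE)
  } else pvStop("io", "unsupported PLY format '%s'", fmt)
  ix <- match(c("x", "y", "z"), props)
  cloud <- array(NA_real_, c(height, width, 3L))
  for (k in 1:3) cloud[, , k] <- t(matrix(M[, ix[k]], nrow = width))
  ## normalise: any point with a non-finite coordinate is fully invalid
  bad <- !(is.finite(cloud[, , 1]) & is.finite(cloud[, , 2]) &
             is.finite(cloud[, , 3]))
  for (k in 1:3) { p <- cloud[, , k]; p[bad] <- NaN; cloud[, , k] <- p }
  list(cloud = cloud, width = width, height = height)
}

#' Write an organized point cloud to PLY
#'
#' @param cloud H x W x 3 numeric array, metres; NaN = invalid depth.
#' @param path output path.
#' @param format \code{"binary_little_endian"} (default) or \code{"ascii"}.
#' @return \code{path}, invisibly.
#' @export
writeOrganizedPLY <- function(cloud, path,
                              format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  d <- dim(cloud)
  stopifnot(length(d) == 3L, d[3] == 3L)
  H <- d[1]; W <- d[2]
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    paste("obj_info width", W),
    paste("obj_info height", H),
    paste("element vertex", H * W),
    "property float x", "property float y", "property float z",
    "end_header")
  ## row-major interleave: x,y,z for pixel (u=0,v=0), (u=1,v=0), ...
  M <- cbind(as.vector(t(cloud[, , 1])),
             as.vector(t(cloud[, , 2])),
             as.vector(t(cloud[, , 3])))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) pvStop("io", "cannot write %s", path))
  on.exit(close(con))
  writeLines(header, con)
  if (format == "ascii") {
    writeLines(sprintf("%.9g %.9g %.9g", M[, 1], M[, 2], M[, 3]), con)
  } else {
    writeBin(as.numeric(t(M)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
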