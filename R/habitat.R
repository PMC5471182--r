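#' Construct a habitat reflectance raster
#'
#' Lightweight in-memory raster: three band matrices (rows top-to-bottom),
#' an affine geotransform given by the top-left corner and pixel size, and
#' `NA` for nodata cells. Coordinate units are either projected meters
#' (`units = "m"`) or geographic degrees (`units = "deg"`); with degrees,
#' buffer distances are evaluated with a local cos-latitude metric scaling.
#'
#' @param red,green,blue Numeric matrices of reflectance (0-255 scale), same
#'   shape; `NA` marks nodata.
#' @param origin Numeric `c(x, y)` of the top-left raster corner.
#' @param pixel_size Numeric `c(dx, dy)` (both > 0; y decreases downwards).
#' @param units `"m"` or `"deg"`.
#' @return Object of class `habitat_raster`.
#' @export
habitat_raster <- function(red, green, blue, origin = c(0, 0),
                           pixel_size = c(1, 1), units = c("m", "deg")) {
  units <- match.arg(units)
  stopifnot(is.matrix(red), is.matrix(green), is.matrix(blue))
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue))) {
    stop("all bands must have the same shape", call. = FALSE)
  }
  if (any(pixel_size <= 0)) stop("pixel size must be > 0", call. = FALSE)
  structure(
    list(bands = list(red = red, green = green, blue = blue),
         origin = as.numeric(origin), pixel_size = as.numeric(pixel_size),
         units = units),
    class = "habitat_raster"
  )
}

#' @export
print.habitat_raster <- function(x, ...) {
  d <- dim(x$bands$red)
  cat(sprintf("habitat_raster: %d x %d px, origin (%g, %g), pixel %g x %g %s, %d nodata cells\n",
              d[1], d[2], x$origin[1], x$origin[2],
              x$pixel_size[1], x$pixel_size[2], x$units,
              sum(is.na(x$bands$red))))
  invisible(x)
}

# pixel-center coordinates; row 1 is the top of the raster
.raster_centers <- function(r) {
  d <- dim(r$bands$red)
  list(x = r$origin[1] + (seq_len(d[2]) - 0.5) * r$pixel_size[1],
       y = r$origin[2] - (seq_len(d[1]) - 0.5) * r$pixel_size[2])
}

#' Write / read a habitat raster as TIFF plus world file
#'
#' Bands are stored as 32-bit float TIFF samples scaled to `[0, 1]`
#' (255 = 1.0), with a fourth validity-mask channel (1 = data, 0 = nodata).
#' The geotransform goes into an ESRI world file (`.tfw`) and the units into
#' a small JSON sidecar, so the trio of plain files round-trips exactly.
#'
#' @param r A `habitat_raster`.
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_habitat_raster <- function(r, path) {
  stopifnot(inherits(r, "habitat_raster"))
  d <- dim(r$bands$red)
  a <- array(0, dim = c(d[1], d[2], 4))
  for (k in 1:3) {
    b <- r$bands[[k]] / 255
    b[is.na(b)] <- 0
    a[, , k] <- b
  }
  a[, , 4] <- !is.na(r$bands$red)
  tiff::writeTIFF(a, path, bits.per.sample = 32)
  tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  # world-file convention: pixel sizes, rotations, center of top-left pixel
  writeLines(format(c(r$pixel_size[1], 0, 0, -r$pixel_size[2],
                      r$origin[1] + r$pixel_size[1] / 2,
                      r$origin[2] - r$pixel_size[2] / 2), digits = 17), tfw)
  jsonlite::write_json(list(units = r$units),
                       sub("\\.tiff?$", ".json", path, ignore.case = TRUE),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_habitat_raster
#' @export
read_habitat_raster <- function(path) {
  # libtiff flags the mask channel as an undeclared extra sample; harmless
  a <- suppressWarnings(tiff::readTIFF(path)) * 255
  if (length(dim(a)) != 3 || dim(a)[3] != 4) {
    stop("expected a 4-channel (RGB + mask) raster TIFF", call. = FALSE)
  }
  mask <- a[, , 4] < 127.5
  bands <- lapply(1:3, function(k) { b <- a[, , k]; b[mask] <- NA; b })
  tfw <- as.numeric(readLines(sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)))
  meta_path <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  units <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)$units else "m"
  habitat_raster(bands[[1]], bands[[2]], bands[[3]],
                 origin = c(tfw[5] - tfw[1] / 2, tfw[6] - tfw[4] / 2),
                 pixel_size = c(tfw[1], -tfw[4]), units = units)
}

#' Per-pixel temporal mean of raster layers
#'
#' Mean over a stack of co-registered rasters, ignoring nodata; a cell is
#' nodata in the output only if it is nodata in every layer. This is the
#' multi-year averaging step applied to satellite reflectance scenes before
#' habitat colour extraction.
#'
#' @param rasters List of `habitat_raster` objects on identical grids.
#' @return A `habitat_raster`.
#' @export
temporal_mean <- function(rasters) {
  stopifnot(length(rasters) >= 1)
  r0 <- rasters[[1]]
  for (r in rasters) {
    if (!identical(dim(r$bands$red), dim(r0$bands$red)) ||
        !isTRUE(all.equal(r$origin, r0$origin)) ||
        !isTRUE(all.equal(r$pixel_size, r0$pixel_size))) {
      stop("rasters are not on identical grids", call. = FALSE)
    }
  }
  out <- lapply(c("red", "green", "blue"), function(ch) {
    stack <- lapply(rasters, function(r) r$bands[[ch]])
    sums <- Reduce(`+`, lapply(stack, function(m) ifelse(is.na(m), 0, m)))
    cnts <- Reduce(`+`, lapply(stack, function(m) !is.na(m)))
    res <- sums / cnts
    res[cnts == 0] <- NA
    res
  })
  habitat_raster(out[[1]], out[[2]], out[[3]], origin = r0$origin,
                 pixel_size = r0$pixel_size, units = r0$units)
}

#' Mean habitat colour within a radius of a point
#'
#' Averages all pixels whose center lies within Euclidean distance `radius`
#' of the point (nodata excluded); if no pixel center qualifies, the pixel
#' containing the point is used. For rasters in geographic degrees the
#' offsets are converted to meters with a local cos-latitude scaling
#' (meters per degree longitude = 111320 cos(lat), latitude = 110540), so a
#' metric radius such as 1 km can be used directly.
#'
#' @param raster A `habitat_raster`.
#' @param x,y Point coordinates in raster units.
#' @param radius Buffer radius: map units for projected rasters, meters for
#'   degree rasters.
#' @return One-row colour data.frame (`red`, `green`, `blue`, `L`) with
#'   attribute `n_pixels`.
#' @export
buffer_mean <- function(raster, x, y, radius) {
  stopifnot(inherits(raster, "habitat_raster"), radius > 0)
  d <- dim(raster$bands$red)
  ctr <- .raster_centers(raster)
  xmin <- raster$origin[1]; ymax <- raster$origin[2]
  xmax <- xmin + d[2] * raster$pixel_size[1]
  ymin <- ymax - d[1] * raster$pixel_size[2]
  if (x < xmin || x > xmax || y < ymin || y > ymax) {
    stop("point outside raster extent", call. = FALSE)
  }
  dx <- outer(rep(1, d[1]), ctr$x - x)
  dy <- outer(ctr$y - y, rep(1, d[2]))
  if (raster$units == "deg") {
    dx <- dx * 111320 * cos(y * pi / 180)
    dy <- dy * 110540
  }
  inside <- dx^2 + dy^2 <= radius^2
  if (!any(inside)) {
    row <- min(d[1], max(1, ceiling((ymax - y) / raster$pixel_size[2])))
    col <- min(d[2], max(1, ceiling((x - xmin) / raster$pixel_size[1])))
    inside <- matrix(FALSE, d[1], d[2])
    inside[row, col] <- TRUE
  }
  vals <- vapply(raster$bands, function(b) {
    v <- b[inside]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(vals)) stop("all pixels within the buffer are nodata", call. = FALSE)
  res <- colour_vector(vals[1], vals[2], vals[3])
  attr(res, "n_pixels") <- sum(inside)
  res
}

#' Extract habitat colour for a table of points
#'
#' @param raster A `habitat_raster`.
#' @param points data.frame with columns `id`, `x`, `y` (raster units).
#' @param radius Buffer radius (see [buffer_mean()]).
#' @return data.frame `id`, `red`, `green`, `blue`, `L`.
#' @export
extract_points <- function(raster, points, radius) {
  stopifnot(all(c("id", "x", "y") %in% names(points)))
  out <- do.call(rbind, lapply(seq_len(nrow(points)), function(i) {
    buffer_mean(raster, points$x[i], points$y[i], radius)
  }))
  cbind(id = points$id, out)
}

#' Period-split habitat colour for repeatability
#'
#' Temporal mean then buffer extraction for each of two groups of raster
#' layers (e.g. scenes from two halves of the study period); the paired
#' values per point feed the downstream intraclass-correlation repeatability
#' estimate ([icc()]).
#'
#' @param group1,group2 Lists of `habitat_raster` layers.
#' @param points data.frame with `id`, `x`, `y`.
#' @param radius Buffer radius.
#' @return data.frame with `id` and per-channel `\*_p1` / `\*_p2` columns.
#' @export
split_period_repeatability <- function(group1, group2, points, radius) {
  if (length(group1) == 0 || length(group2) == 0) {
    stop("both period groups must be non-empty", call. = FALSE)
  }
  e1 <- extract_points(temporal_mean(group1), points, radius)
  e2 <- extract_points(temporal_mean(group2), points, radius)
  out <- data.frame(id = e1$id)
  for (ch in c("red", "green", "blue", "L")) {
    out[[paste0(ch, "_p1")]] <- e1[[ch]]
    out[[paste0(ch, "_p2")]] <- e2[[ch]]
  }
  out
}
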