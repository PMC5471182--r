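#' BT.601 total reflectance
#'
#' Weighted average of the red, green and blue reflectances,
#' `L = 0.299 R + 0.587 G + 0.114 B` (ITU-R BT.601 luma coefficients).
#'
#' @param red,green,blue Numeric reflectances (vectorized).
#' @return Numeric total reflectance.
#' @export
total_reflectance <- function(red, green, blue) {
  stopifnot(is.finite(red), is.finite(green), is.finite(blue))
  0.299 * red + 0.587 * green + 0.114 * blue
}

#' Build a colour table with total reflectance
#'
#' @param red,green,blue Channel values on the 8-bit 0-255 scale.
#' @return data.frame with columns `red`, `green`, `blue`, `L`.
#' @export
colour_vector <- function(red, green, blue) {
  data.frame(red = red, green = green, blue = blue,
             L = total_reflectance(red, green, blue))
}

#' Black/white balance correction
#'
#' Per channel, the linear map taking the observed black reference to 0 and
#' the observed white reference to 255, then clipping to `[0, 255]`. This is
#' the standardization applied to photographs taken alongside a colour
#' reference chart so that images from different light conditions are
#' comparable.
#'
#' @param pixel Numeric length-3 RGB vector, or an n x 3 matrix of pixels,
#'   on the 0-255 scale.
#' @param ref List with numeric length-3 elements `white` and `black`: the
#'   observed chart references.
#' @return Corrected colour: data.frame row(s) `red`, `green`, `blue`, `L`,
#'   with attribute `n_clipped` (count of channel values clipped).
#' @export
balance_correct <- function(pixel, ref) {
  stopifnot(is.list(ref), length(ref$white) == 3, length(ref$black) == 3)
  if (any(ref$white <= ref$black)) {
    stop("invalid balance reference: white <= black in some channel", call. = FALSE)
  }
  m <- if (is.matrix(pixel)) pixel else matrix(pixel, nrow = 1)
  if (ncol(m) != 3) stop("pixel must have 3 channels", call. = FALSE)
  out <- sweep(sweep(m, 2, ref$black, "-"), 2,
               ref$white - ref$black, "/") * 255
  n_clipped <- sum(out < 0 | out > 255)
  out <- pmin(pmax(out, 0), 255)
  res <- colour_vector(out[, 1], out[, 2], out[, 3])
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Read an RGB image as a 0-255 array
#'
#' PNG and TIFF are supported (8-, 16- or 32-bit float); values are rescaled
#' to the 0-255 reflectance scale. Greyscale images are replicated across
#' channels; an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return Numeric h x w x 3 array on the 0-255 scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
  if (dim(img)[3] == 1) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Mean colour of a square image patch
#'
#' Arithmetic per-channel mean over the patch region (the sampling area on
#' the back of a specimen's head in the photographic protocol), with BT.601
#' total reflectance. Patch sides outside the 40-150 px protocol range give
#' a warning, not an error.
#'
#' @param image h x w x 3 array on the 0-255 scale (see [read_image()]).
#' @param region Integer vector `c(row0, col0, side)`, 0-based, half-open.
#' @return One-row colour data.frame (`red`, `green`, `blue`, `L`).
#' @export
extract_patch_mean <- function(image, region) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, length(region) == 3)
  row0 <- region[1]; col0 <- region[2]; side <- region[3]
  if (side < 1) stop("empty patch region", call. = FALSE)
  if (row0 < 0 || col0 < 0 || row0 + side > dim(image)[1] || col0 + side > dim(image)[2]) {
    stop("patch region outside image bounds", call. = FALSE)
  }
  if (side < 40 || side > 150) {
    warning("patch side ", side, " px outside the 40-150 px sampling protocol")
  }
  rows <- (row0 + 1):(row0 + side)
  cols <- (col0 + 1):(col0 + side)
  ch <- apply(image[rows, cols, , drop = FALSE], 3, mean)
  colour_vector(ch[1], ch[2], ch[3])
}

#' Log-transform and standardize
#'
#' `log10` followed by a z-score with the sample (n-1) standard deviation;
#' the scale used for all continuous colour variables before modelling.
#'
#' @param values Positive numeric vector.
#' @return Standardized vector (mean 0, sd 1).
#' @export
log_standardize <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0) {
    stop("non-positive or missing values at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  lx <- log10(values)
  s <- stats::sd(lx)
  if (s == 0) stop("zero variance after log transform", call. = FALSE)
  (lx - mean(lx)) / s
}
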