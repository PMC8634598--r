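## Calibrated image model, Otsu thresholding, region algebra and the
## per-region measurement vector shared by both quantification pipelines.
##
## Conventions (fixed so results tables are stable across runs and machines):
##  - images are integer matrices indexed [row, col] = [y, x];
##  - region masks are logical matrices on the same grid, 8-connected;
##  - pixel centers sit at (x - 0.5, y - 0.5) in pixel units;
##  - statistics use population (divide-by-n) moments, mode ties take the
##    smallest value, the median of an even-count region takes the lower
##    middle -- mirroring ImageJ's measurement definitions.

#' Pixel calibration
#'
#' Isotropic spatial calibration plus the nominal bit depth of the source
#' acquisition. The bit depth fixes the intensity range `[0, 2^bit_depth - 1]`
#' used for validation, Otsu histogram binning and 8-bit conversion; typical
#' confocal acquisitions are 12-bit stored in 16-bit containers.
#'
#' @param pixel_size_um Pixel edge length in micrometers (> 0).
#' @param bit_depth Bits per sample of the source image: 8, 12 or 16.
#' @return A `"nmj_calibration"` object.
#' @examples
#' calibration(0.1, 12)
#' @export
calibration <- function(pixel_size_um, bit_depth = 12L) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    stop("bit_depth must be one of 8, 12, 16", call. = FALSE)
  }
  structure(list(pixel_size_um = as.numeric(pixel_size_um),
                 bit_depth = bit_depth),
            class = "nmj_calibration")
}

max_value <- function(cal) 2L^cal$bit_depth - 1L

#' Single-channel calibrated image
#'
#' @param pixels Integer matrix of non-negative intensities, `[row, col]`.
#' @param cal A [calibration()] object; all values must fit its bit depth.
#' @return A `"nmj_channel"` object.
#' @export
channel_image <- function(pixels, cal) {
  stopifnot(inherits(cal, "nmj_calibration"))
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("pixels must be a matrix with positive dimensions", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) stop("pixels must not contain NA", call. = FALSE)
  rng <- range(pixels)
  if (rng[1L] < 0L || rng[2L] > max_value(cal)) {
    stop(sprintf("pixel values must lie in [0, %d] for a %d-bit image",
                 max_value(cal), cal$bit_depth), call. = FALSE)
  }
  structure(list(pixels = pixels, calibration = cal), class = "nmj_channel")
}

#' @export
print.nmj_channel <- function(x, ...) {
  cat(sprintf("<nmj_channel> %d x %d px, %d-bit, %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels),
              x$calibration$bit_depth, x$calibration$pixel_size_um))
  invisible(x)
}

#' Two-channel stack (protein channel + mask channel)
#'
#' Pairs the channel to be quantified (channel 1, e.g. Evi-GFP or
#' Atg8-mCherry) with the channel that defines the region mask (channel 2,
#' e.g. HRP or DLG). Both must share dimensions and calibration.
#'
#' @param protein,mask [channel_image()] objects.
#' @return A `"nmj_stack"` object with elements `protein`, `mask`,
#'   `calibration`.
#' @export
two_channel_stack <- function(protein, mask) {
  stopifnot(inherits(protein, "nmj_channel"), inherits(mask, "nmj_channel"))
  if (!identical(dim(protein$pixels), dim(mask$pixels))) {
    stop("channels must have identical dimensions", call. = FALSE)
  }
  if (!identical(protein$calibration, mask$calibration)) {
    stop("channels must share one calibration", call. = FALSE)
  }
  structure(list(protein = protein, mask = mask,
                 calibration = protein$calibration),
            class = "nmj_stack")
}

#' @export
print.nmj_stack <- function(x, ...) {
  cat(sprintf("<nmj_stack> %d x %d px, %d-bit, %.4g um/px (protein + mask)\n",
              nrow(x$protein$pixels), ncol(x$protein$pixels),
              x$calibration$bit_depth, x$calibration$pixel_size_um))
  invisible(x)
}

empty_mask <- function(img) {
  matrix(FALSE, nrow(img$pixels), ncol(img$pixels))
}

#' Otsu threshold of a channel
#'
#' Automatic threshold maximizing between-class variance over a 256-bin
#' histogram spanning the full nominal bit-depth range (so 12-bit images use
#' bins of width 16, matching auto-thresholding of display-scaled data and
#' keeping thresholds comparable across images acquired with identical
#' settings). The foreground mask keeps pixels strictly above the returned
#' threshold. Ties in the variance criterion resolve to the smallest
#' threshold.
#'
#' @param img A [channel_image()].
#' @return List with `threshold` (intensity value in source units: the
#'   largest intensity still classified as background) and `mask` (logical
#'   matrix of foreground pixels).
#' @examples
#' cal <- calibration(0.1, 8)
#' img <- channel_image(matrix(c(rep(0L, 50), rep(200L, 50)), 10, 10), cal)
#' otsu_threshold(img)$threshold
#' @export
otsu_threshold <- function(img) {
  stopifnot(inherits(img, "nmj_channel"))
  nbins <- 256L
  maxv <- max_value(img$calibration)
  binwidth <- (maxv + 1L) / nbins
  bins <- as.integer(img$pixels %/% binwidth)  # 0 .. 255
  counts <- tabulate(bins + 1L, nbins)
  if (sum(counts > 0L) < 2L) {
    stop("degenerate histogram: image has a single occupied intensity bin",
         call. = FALSE)
  }
  n <- sum(counts)
  lev <- 0:(nbins - 1L)
  w0 <- cumsum(counts)                       # class 0: bins <= t
  s0 <- cumsum(counts * lev)
  stot <- s0[nbins]
  w1 <- n - w0
  valid <- which(w0 > 0L & w1 > 0L)          # thresholds t = lev[valid]
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (stot - s0[valid]) / w1[valid]
  sigma_b <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  t_bin <- lev[valid][which.max(sigma_b)]    # which.max -> smallest on ties
  thr <- as.integer((t_bin + 1L) * binwidth - 1L)
  list(threshold = thr, mask = img$pixels > thr)
}

#' Select one 8-connected component of a mask
#'
#' Headless stand-in for the interactive wand-tool click: either the
#' component containing an explicit seed pixel, or the largest component
#' (ties broken by the component whose topmost-leftmost pixel comes first in
#' reading order).
#'
#' @param mask Logical matrix.
#' @param seed Either the string `"largest"` or an `(x, y)` pixel coordinate
#'   (column, row; 1-based) lying on a foreground pixel.
#' @return Logical matrix keeping the selected component only.
#' @export
select_component <- function(mask, seed = "largest") {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  lab <- cpp_label8(mask)
  if (identical(seed, "largest")) {
    sizes <- tabulate(lab[lab > 0L])
    # labels are assigned in reading order, so which.max lands on the tied
    # component whose first pixel is earliest
    keep <- which.max(sizes)
  } else {
    seed <- as.integer(seed)
    if (length(seed) != 2L) stop("seed must be \"largest\" or c(x, y)", call. = FALSE)
    x <- seed[1L]; y <- seed[2L]
    if (y < 1L || y > nrow(mask) || x < 1L || x > ncol(mask)) {
      stop("seed outside image bounds", call. = FALSE)
    }
    keep <- lab[y, x]
    if (keep == 0L) stop("seed not in foreground", call. = FALSE)
  }
  lab == keep
}

#' Enlarge a region by a calibrated distance
#'
#' Euclidean dilation: adds every pixel whose center lies within
#' `distance_um` of the nearest region pixel center (computed with an exact
#' Euclidean distance transform, not iterated structuring-element dilation).
#' The default 1 um matches the subsynaptic-reticulum shell in which released
#' exosomes travel.
#'
#' @param roi Logical matrix.
#' @param distance_um Non-negative distance in micrometers.
#' @param cal A [calibration()].
#' @return Logical matrix containing `roi` and its shell.
#' @export
enlarge_region <- function(roi, distance_um, cal) {
  stopifnot(is.logical(roi), is.matrix(roi), inherits(cal, "nmj_calibration"))
  if (!is.numeric(distance_um) || length(distance_um) != 1L || distance_um < 0) {
    stop("distance_um must be a single non-negative number", call. = FALSE)
  }
  if (!any(roi) || distance_um == 0) return(roi)
  d2 <- cpp_edt_sq(roi)
  r_px <- distance_um / cal$pixel_size_um
  d2 <= r_px^2
}

#' Zero a region of an image
#'
#' Sets all region pixels to 0 (the "bouton in black" step); pixels outside
#' the region are untouched.
#'
#' @param img A [channel_image()].
#' @param roi Logical matrix on `img`'s grid.
#' @return A new [channel_image()].
#' @export
clear_region <- function(img, roi) {
  stopifnot(inherits(img, "nmj_channel"), is.logical(roi))
  if (!identical(dim(roi), dim(img$pixels))) {
    stop("roi and image dimensions differ", call. = FALSE)
  }
  px <- img$pixels
  px[roi] <- 0L
  channel_image(px, img$calibration)
}

stats_columns <- c("label", "area_um2", "mean", "std_dev", "min", "max",
                   "intden", "rawintden", "median", "mode", "skew", "kurt",
                   "perim_um")

#' Region measurement vector
#'
#' Computes the full per-region measurement row used by both results tables:
#' calibrated area, mean, population standard deviation, min/max, integrated
#' density (area x mean), raw integrated density (exact sum of pixel
#' values), median (lower middle on even counts), mode (smallest value on
#' ties), population skewness, excess kurtosis, and -- when the region is a
#' single 8-connected component -- the outer-boundary chain-code perimeter
#' (edge steps 1 px, diagonal steps sqrt(2) px, calibrated). Skewness and
#' kurtosis of a zero-variance region are reported as 0 by convention.
#'
#' @param img A [channel_image()].
#' @param roi Non-empty logical matrix on `img`'s grid.
#' @param label Row label for the output.
#' @return One-row data.frame with columns
#'   `r paste(nmjquant:::stats_columns, collapse = ", ")`.
#' @export
region_stats <- function(img, roi, label = "") {
  stopifnot(inherits(img, "nmj_channel"), is.logical(roi))
  if (!identical(dim(roi), dim(img$pixels))) {
    stop("roi and image dimensions differ", call. = FALSE)
  }
  v <- as.numeric(img$pixels[roi])
  n <- length(v)
  if (n == 0L) stop("empty region", call. = FALSE)
  ps <- img$calibration$pixel_size_um
  area <- n * ps^2
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  sdev <- sqrt(m2)
  if (sdev > 0) {
    skew <- (sum((v - mu)^3) / n) / sdev^3
    kurt <- (sum((v - mu)^4) / n) / sdev^4 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  sv <- sort(v)
  med <- if (n %% 2L == 1L) sv[(n + 1L) %/% 2L] else sv[n %/% 2L]
  tab <- table(v)
  mode_val <- as.numeric(names(tab)[tab == max(tab)])[1L]  # names sorted ascending
  lab <- cpp_label8(roi)
  perim <- if (max(lab) == 1L) cpp_perimeter(roi) * ps else NA_real_
  data.frame(label = label, area_um2 = area, mean = mu, std_dev = sdev,
             min = min(v), max = max(v), intden = area * mu,
             rawintden = sum(v), median = med, mode = mode_val,
             skew = skew, kurt = kurt, perim_um = perim,
             stringsAsFactors = FALSE)
}

#' Convert an image to 8-bit
#'
#' Linear map of the full nominal range `[0, 2^bit_depth - 1]` onto
#' `[0, 255]`, rounded half-up (so 12-bit 4095 -> 255, 2048 -> 128). The map
#' is fixed by the bit depth, not by the per-image min/max, so absolute
#' intensities stay comparable across images acquired with identical
#' settings. 8-bit input is returned unchanged.
#'
#' @param img A [channel_image()] with bit depth >= 8.
#' @return An 8-bit [channel_image()].
#' @export
convert_to_8bit <- function(img) {
  stopifnot(inherits(img, "nmj_channel"))
  cal <- img$calibration
  if (cal$bit_depth == 8L) return(img)
  scale <- 255 / max_value(cal)
  px <- matrix(as.integer(floor(img$pixels * scale + 0.5)),
               nrow(img$pixels), ncol(img$pixels))
  channel_image(px, calibration(cal$pixel_size_um, 8L))
}
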