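## Autophagosome (fluorescent puncta) quantification: median filtering,
## mean + k*SD thresholding inside an Otsu-segmented region, size and
## circularity filtering, centroid-distance merging, counting.

#' Autophagoquant configuration
#'
#' Defaults reproduce the published parameterization for Atg8-positive
#' autophagosomes at the larval NMJ: detection threshold at the ROI mean
#' plus 4 standard deviations, median filter of radius 1 px, particle size
#' window 0.09-0.5, circularity window [0, 1] (the circularity floor is
#' deliberately 0 because puncta circularity is inconsistent), and a 0.5 um
#' centroid-distance limit below which adjacent clusters are merged into a
#' single object.
#'
#' @param k_sd Threshold multiplier on the ROI standard deviation.
#' @param median_radius_px Radius (pixels) of the Euclidean-disk median
#'   filter; radius 1 uses the pixel plus its 4 edge neighbors.
#' @param size_min_um2,size_max_um2 Particle size window. With
#'   `size_unit = "um2"` these are areas in square micrometers (the particle
#'   analyzer's native unit); with `"um-diameter"` they are diameters in
#'   micrometers, converted to an area window via `pi * (d/2)^2` to match
#'   size calibration done by measuring the base of a fluorescence profile.
#' @param circ_min,circ_max Circularity window in `[0, 1]`, where
#'   circularity is `4 * pi * area / perimeter^2`, capped at 1.
#' @param merge_distance_um Clusters closer than this are merged (0 disables
#'   merging in practice since distinct dots are at least 1 px apart).
#' @param roi `"largest"` or an `(x, y)` seed for [select_component()].
#' @param size_unit `"um2"` or `"um-diameter"` (see above).
#' @param threshold_source `"filtered"` (default): detection threshold uses
#'   the mean/SD of the median-filtered ROI (results row 2);
#'   `"unfiltered"` uses row 3 instead.
#' @param row4_mode `"otsu"` (default): results row 4 measures ROI pixels
#'   above the Otsu threshold of the 8-bit protein channel;
#'   `"detection"` measures the ROI pixels above the mean + k*SD detection
#'   threshold instead.
#' @param merge_metric `"centroid"` (default) or `"edge"`
#'   (minimum pixel-to-pixel distance) for the merge rule.
#' @return An `"autophagoquant_config"` list.
#' @export
autophagoquant_config <- function(k_sd = 4,
                                  median_radius_px = 1L,
                                  size_min_um2 = 0.09,
                                  size_max_um2 = 0.5,
                                  circ_min = 0,
                                  circ_max = 1,
                                  merge_distance_um = 0.5,
                                  roi = "largest",
                                  size_unit = c("um2", "um-diameter"),
                                  threshold_source = c("filtered", "unfiltered"),
                                  row4_mode = c("otsu", "detection"),
                                  merge_metric = c("centroid", "edge")) {
  size_unit <- match.arg(size_unit)
  if (size_unit == "um-diameter") {
    size_min_um2 <- pi * (size_min_um2 / 2)^2
    size_max_um2 <- pi * (size_max_um2 / 2)^2
    size_unit <- "um2"
  }
  stopifnot(k_sd >= 0, median_radius_px >= 0, merge_distance_um >= 0,
            size_min_um2 < size_max_um2,
            circ_min >= 0, circ_min <= circ_max, circ_max <= 1)
  structure(list(k_sd = k_sd,
                 median_radius_px = as.integer(median_radius_px),
                 size_min_um2 = size_min_um2, size_max_um2 = size_max_um2,
                 circ_min = circ_min, circ_max = circ_max,
                 merge_distance_um = merge_distance_um,
                 roi = roi, size_unit = size_unit,
                 threshold_source = match.arg(threshold_source),
                 row4_mode = match.arg(row4_mode),
                 merge_metric = match.arg(merge_metric)),
            class = "autophagoquant_config")
}

#' Disk median filter
#'
#' Replaces each pixel by the median of its Euclidean-disk neighborhood of
#' the given radius (radius 1: the pixel and its 4 edge neighbors); at the
#' image border only the available neighbors are used. Used to suppress
#' single-pixel noise before puncta detection.
#'
#' @param img A [channel_image()].
#' @param radius_px Integer radius >= 0 (0 is the identity).
#' @return A filtered [channel_image()].
#' @export
median_filter <- function(img, radius_px = 1L) {
  stopifnot(inherits(img, "nmj_channel"), radius_px >= 0)
  if (radius_px == 0L) return(img)
  out <- cpp_median_disk(matrix(as.numeric(img$pixels), nrow(img$pixels)),
                         as.integer(radius_px))
  channel_image(matrix(as.integer(out), nrow(out)), img$calibration)
}

#' Puncta detection threshold
#'
#' `mean + k_sd * std_dev` of the reference ROI measurement, not clamped to
#' the intensity range (a threshold above 255 simply yields zero
#' detections). Candidate pixels must exceed it strictly, so a
#' zero-variance ROI yields no detections.
#'
#' @param roi_stats A [region_stats()] row for the reference region.
#' @param k_sd Multiplier (default 4).
#' @return Threshold intensity (numeric).
#' @export
detection_threshold <- function(roi_stats, k_sd = 4) {
  stopifnot(is.data.frame(roi_stats), nrow(roi_stats) == 1L)
  roi_stats$mean + k_sd * roi_stats$std_dev
}

make_dot <- function(idx, img, cal) {
  nr <- nrow(img$pixels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  ps <- cal$pixel_size_um
  n <- length(idx)
  area <- n * ps^2
  comp <- matrix(FALSE, nr, ncol(img$pixels))
  comp[idx] <- TRUE
  perim <- cpp_perimeter(comp) * ps
  circ <- if (perim > 0) min(1, 4 * pi * area / perim^2) else 1
  v <- as.numeric(img$pixels[idx])
  structure(list(idx = idx, dim = dim(img$pixels),
                 centroid_um = c(x = (mean(cols) - 0.5) * ps,
                                 y = (mean(rows) - 0.5) * ps),
                 area_um2 = area, perim_um = perim, circularity = circ,
                 mean = mean(v), min = min(v), max = max(v),
                 intden = area * mean(v), rawintden = sum(v)),
            class = "nmj_dot")
}

#' @export
print.nmj_dot <- function(x, ...) {
  cat(sprintf("<dot> %d px, %.3g um^2, circ %.3g, centroid (%.3g, %.3g) um\n",
              length(x$idx), x$area_um2, x$circularity,
              x$centroid_um[["x"]], x$centroid_um[["y"]]))
  invisible(x)
}

#' Detect candidate puncta in a filtered channel
#'
#' Candidate pixels are ROI pixels whose filtered intensity strictly exceeds
#' the threshold; 8-connected components are kept when their calibrated
#' area falls inside the size window and their circularity inside the
#' circularity window. Perimeters come from the outer-boundary chain code;
#' circularity is `4*pi*area/perimeter^2` capped at 1 (digital perimeters
#' push the raw formula above 1 for tiny particles).
#'
#' @param filtered The (median-filtered, 8-bit) protein [channel_image()].
#' @param roi Non-empty logical matrix.
#' @param threshold Detection threshold (see [detection_threshold()]).
#' @param cfg An [autophagoquant_config()].
#' @return List of dot objects (possibly empty), in reading order of their
#'   first pixel.
#' @export
detect_dots <- function(filtered, roi, threshold, cfg = autophagoquant_config()) {
  stopifnot(inherits(filtered, "nmj_channel"), is.logical(roi))
  if (!any(roi)) stop("empty mask", call. = FALSE)
  cand <- roi & (filtered$pixels > threshold)
  if (!any(cand)) return(list())
  lab <- cpp_label8(cand)
  dots <- lapply(seq_len(max(lab)), function(k) {
    make_dot(which(lab == k), filtered, filtered$calibration)
  })
  keep <- vapply(dots, function(d) {
    d$area_um2 >= cfg$size_min_um2 && d$area_um2 <= cfg$size_max_um2 &&
      d$circularity >= cfg$circ_min && d$circularity <= cfg$circ_max
  }, logical(1L))
  dots[keep]
}

dot_pair_distance <- function(a, b, metric = "centroid") {
  if (metric == "centroid") {
    sqrt(sum((a$centroid_um - b$centroid_um)^2))
  } else {
    nr <- a$dim[1L]
    pa <- cbind(((a$idx - 1L) %% nr), ((a$idx - 1L) %/% nr))
    pb <- cbind(((b$idx - 1L) %% nr), ((b$idx - 1L) %/% nr))
    d2 <- outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2
    sqrt(min(d2))  # px; caller rescales
  }
}

#' Merge nearby dots into single objects
#'
#' Iteratively merges the closest pair of dots whose centroid distance is at
#' or below `merge_distance_um` (ties resolved toward the pair whose
#' centroids come first in reading order), recomputing the merged dot's
#' centroid, area, perimeter and circularity, and repeats -- newly merged
#' dots are re-tested -- until no pair qualifies. Merged dots are not
#' re-filtered on size (filtering precedes merging in the pipeline).
#'
#' @param dots List of dots from [detect_dots()].
#' @param merge_distance_um Distance limit in micrometers.
#' @param cal A [calibration()].
#' @param source The [channel_image()] the dots were detected on, used to
#'   recompute merged-dot intensity statistics.
#' @param metric `"centroid"` (default) or `"edge"`.
#' @return List of merged dots; all pairwise distances exceed the limit.
#' @export
merge_dots <- function(dots, merge_distance_um, cal, source, metric = "centroid") {
  stopifnot(inherits(cal, "nmj_calibration"), inherits(source, "nmj_channel"))
  if (length(dots) < 2L || merge_distance_um < 0) return(dots)
  ps <- cal$pixel_size_um
  repeat {
    n <- length(dots)
    if (n < 2L) break
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- dot_pair_distance(dots[[i]], dots[[j]], metric)
        if (metric == "edge") d <- d * ps
        if (d > merge_distance_um) next
        key <- c(d,
                 dots[[i]]$centroid_um[["y"]], dots[[i]]$centroid_um[["x"]],
                 dots[[j]]$centroid_um[["y"]], dots[[j]]$centroid_um[["x"]])
        if (is.null(best) || lex_lt(key, best$key)) {
          best <- list(key = key, i = i, j = j)
        }
      }
    }
    if (is.null(best)) break
    merged <- make_dot(sort(union(dots[[best$i]]$idx, dots[[best$j]]$idx)),
                       source, cal)
    dots <- c(dots[-c(best$i, best$j)], list(merged))
  }
  # stable output order: by first pixel in reading order
  if (length(dots) > 1L) {
    nr <- dots[[1L]]$dim[1L]
    first_rm <- vapply(dots, function(d) {
      rows <- ((d$idx - 1L) %% nr)
      cols <- ((d$idx - 1L) %/% nr)
      min(rows * dots[[1L]]$dim[2L] + cols)
    }, numeric(1L))
    dots <- dots[order(first_rm)]
  }
  dots
}

lex_lt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Distance from a dot centroid to the ROI boundary
#'
#' Euclidean distance (micrometers) from the dot centroid to the nearest
#' pixel center outside the ROI -- e.g. the distance from an autophagosome
#' to the plasma membrane when the ROI traces the synaptic compartment.
#'
#' @param dot A dot from [detect_dots()] / [merge_dots()].
#' @param roi Logical matrix; must not cover the full grid.
#' @param cal A [calibration()].
#' @return Distance in micrometers.
#' @export
dot_distance_to_boundary <- function(dot, roi, cal) {
  stopifnot(inherits(dot, "nmj_dot"), is.logical(roi),
            inherits(cal, "nmj_calibration"))
  out_idx <- which(!roi)
  if (length(out_idx) == 0L) stop("no boundary: roi covers the full grid",
                                  call. = FALSE)
  nr <- nrow(roi)
  ps <- cal$pixel_size_um
  ox <- (((out_idx - 1L) %/% nr) + 0.5) * ps
  oy <- (((out_idx - 1L) %% nr) + 0.5) * ps
  sqrt(min((ox - dot$centroid_um[["x"]])^2 + (oy - dot$centroid_um[["y"]])^2))
}

#' Run the Autophagoquant pipeline on one two-channel image
#'
#' Pipeline, in macro order: convert the protein channel to 8-bit;
#' Otsu-threshold the mask channel and measure the binarized (0/255) result
#' over the full frame (row 1); select the ROI component; median-filter the
#' 8-bit protein channel and measure the filtered ROI (row 2); measure the
#' unfiltered ROI (row 3); set the detection threshold to the row-2 mean
#' plus `k_sd` standard deviations; detect, size/circularity-filter and
#' merge dots; measure the ROI pixels above the protein channel's own Otsu
#' threshold (row 4); summarize the binarized detection image over the dot
#' pixels (whose mode is 255 by construction whenever a dot exists).
#'
#' @param stack A [two_channel_stack()].
#' @param cfg An [autophagoquant_config()].
#' @return An `"autophagoquant_result"` with `rows` (4-row table), `dots`
#'   (post-merge dot list), `dots_df` (per-dot table: id, centroid,
#'   area, perimeter, circularity, intensities, distance to ROI boundary),
#'   `summary` (count, total/average area, percent area and the
#'   binarized-image statistics), `detection_threshold`, `roi_mask`,
#'   `mask_otsu_threshold`, `protein_otsu_threshold`.
#' @examples
#' fx <- make_auto_stack(seed = 1, n_spots = 5)
#' res <- run_autophagoquant(fx$stack, autophagoquant_config())
#' res$summary$count
#' @export
run_autophagoquant <- function(stack, cfg = autophagoquant_config()) {
  stopifnot(inherits(stack, "nmj_stack"), inherits(cfg, "autophagoquant_config"))
  warn_saturation(stack$protein, "protein")
  cal <- stack$calibration
  cal8 <- calibration(cal$pixel_size_um, 8L)
  protein8 <- convert_to_8bit(stack$protein)

  th_mask <- otsu_threshold(stack$mask)
  bin_mask <- channel_image(matrix(as.integer(th_mask$mask) * 255L,
                                   nrow(th_mask$mask)), cal8)
  full <- matrix(TRUE, nrow(th_mask$mask), ncol(th_mask$mask))
  r1 <- region_stats(bin_mask, full, "mask_otsu_binarized")

  roi <- select_component(th_mask$mask, cfg$roi)
  filtered <- median_filter(protein8, cfg$median_radius_px)
  r2 <- region_stats(filtered, roi, "roi_protein_filtered")
  r3 <- region_stats(protein8, roi, "roi_protein_unfiltered")

  thr <- detection_threshold(if (cfg$threshold_source == "filtered") r2 else r3,
                             cfg$k_sd)
  pre <- detect_dots(filtered, roi, thr, cfg)
  dots <- merge_dots(pre, cfg$merge_distance_um, cal, source = filtered,
                     metric = cfg$merge_metric)

  # a flat protein channel has no Otsu threshold; row 4 is then undefined
  th_protein <- tryCatch(otsu_threshold(protein8), error = function(e) NULL)
  row4_set <- if (cfg$row4_mode == "otsu") {
    if (is.null(th_protein)) roi & FALSE
    else roi & (protein8$pixels > th_protein$threshold)
  } else {
    roi & (filtered$pixels > thr)
  }
  r4 <- if (any(row4_set)) {
    region_stats(protein8, row4_set, "roi_protein_above_threshold")
  } else {
    warning("row 4: no ROI pixel above the protein-channel threshold",
            call. = FALSE)
    na_stats_row("roi_protein_above_threshold")
  }

  rows <- rbind(r1, r2, r3, r4)
  rownames(rows) <- NULL

  # summary over the 0/255 binarized detection image, restricted to dot pixels
  detection_bin <- matrix(0L, nrow(roi), ncol(roi))
  for (d in dots) detection_bin[d$idx] <- 255L
  bin_img <- channel_image(detection_bin, cal8)
  roi_area <- sum(roi) * cal$pixel_size_um^2
  if (length(dots) > 0L) {
    dot_union <- detection_bin > 0L
    bs <- region_stats(bin_img, dot_union, "dots_binarized")
    summary <- data.frame(
      count = length(dots),
      total_area_um2 = sum(vapply(dots, `[[`, numeric(1L), "area_um2")),
      average_size_um2 = mean(vapply(dots, `[[`, numeric(1L), "area_um2")),
      percent_area = 100 * bs$area_um2 / roi_area,
      mean = bs$mean, mode = bs$mode, perim_um = sum(
        vapply(dots, `[[`, numeric(1L), "perim_um")),
      intden = bs$intden, median = bs$median, skew = bs$skew,
      kurt = bs$kurt)
  } else {
    summary <- data.frame(count = 0L, total_area_um2 = 0,
                          average_size_um2 = NA_real_, percent_area = 0,
                          mean = NA_real_, mode = NA_real_, perim_um = 0,
                          intden = 0, median = NA_real_, skew = NA_real_,
                          kurt = NA_real_)
  }

  dots_df <- if (length(dots) > 0L) {
    do.call(rbind, lapply(seq_along(dots), function(i) {
      d <- dots[[i]]
      data.frame(id = i,
                 centroid_x_um = d$centroid_um[["x"]],
                 centroid_y_um = d$centroid_um[["y"]],
                 area_um2 = d$area_um2, perim_um = d$perim_um,
                 circularity = d$circularity, mean = d$mean,
                 intden = d$intden,
                 dist_to_boundary_um =
                   if (all(roi)) NA_real_
                   else dot_distance_to_boundary(d, roi, cal))
    }))
  } else {
    data.frame(id = integer(), centroid_x_um = numeric(),
               centroid_y_um = numeric(), area_um2 = numeric(),
               perim_um = numeric(), circularity = numeric(),
               mean = numeric(), intden = numeric(),
               dist_to_boundary_um = numeric())
  }

  structure(list(rows = rows, dots = dots, dots_df = dots_df,
                 summary = summary, detection_threshold = thr,
                 roi_mask = roi,
                 mask_otsu_threshold = th_mask$threshold,
                 protein_otsu_threshold =
                   if (is.null(th_protein)) NA_integer_ else th_protein$threshold,
                 config = cfg),
            class = "autophagoquant_result")
}

na_stats_row <- function(label) {
  data.frame(label = label, area_um2 = 0, mean = NA_real_, std_dev = NA_real_,
             min = NA_real_, max = NA_real_, intden = NA_real_,
             rawintden = 0, median = NA_real_, mode = NA_real_,
             skew = NA_real_, kurt = NA_real_, perim_um = NA_real_,
             stringsAsFactors = FALSE)
}

#' @export
print.autophagoquant_result <- function(x, ...) {
  cat("Autophagoquant result\n")
  cat(sprintf("  detection threshold: %.4g (mean + %g SD)\n",
              x$detection_threshold, x$config$k_sd))
  cat(sprintf("  dots counted: %d\n", x$summary$count))
  print(x$summary, digits = 6)
  invisible(x)
}
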