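## Synthetic two-channel NMJ-like image generator with exhaustive ground
## truth. Defaults: 256 x 256 px at 0.1 um/px, 12-bit, bouton radius 2 um
## (within the 2-5 um diameter range of larval boutons) -- large enough to
## exercise every pipeline stage, small enough for sub-second tests.
##
## Shell plants are single pixels by default so compartment sums are exact;
## blur > 0 spreads intensity and is only meant for robustness fixtures.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

disk_mask <- function(size, center, radius_px) {
  cx <- center[1L]; cy <- center[2L]
  x <- matrix(rep(seq_len(size) - 0.5, each = size), size)   # col centers
  y <- matrix(rep(seq_len(size) - 0.5, times = size), size)  # row centers
  (x - cx)^2 + (y - cy)^2 <= radius_px^2
}

gaussian_blur <- function(mat, sd_px) {
  if (sd_px <= 0) return(mat)
  r <- ceiling(3 * sd_px)
  k <- exp(-((-r):r)^2 / (2 * sd_px^2))
  k <- k / sum(k)
  pad_conv <- function(m) {  # 1D convolution down columns, zero padding
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (o in (-r):r) {
      src <- seq_len(nr) + o
      ok <- src >= 1L & src <= nr
      out[ok, ] <- out[ok, ] + k[o + r + 1L] * m[src[ok], ]
    }
    out
  }
  t(pad_conv(t(pad_conv(mat))))
}

apply_noise <- function(mat, maxv, noise_sd, poisson) {
  if (poisson) mat <- matrix(rpois(length(mat), lambda = mat), nrow(mat))
  if (noise_sd > 0) mat <- mat + rnorm(length(mat), 0, noise_sd)
  matrix(as.integer(pmin(pmax(round(mat), 0), maxv)), nrow(mat))
}

finalize_channel <- function(clean, cal, noise_sd, poisson, blur_sd) {
  m <- gaussian_blur(clean, blur_sd)
  channel_image(apply_noise(m, max_value(cal), noise_sd, poisson), cal)
}

#' Synthetic bouton image for the exosome-release pipeline
#'
#' Renders a two-channel stack: the mask channel holds a bright filled-disk
#' bouton on top of a dimmer perisynaptic (SSR-like) shell, the protein
#' channel holds a diffuse interior level plus single-pixel "exosome"
#' plants inside the shell annulus. Ground truth records the bouton and
#' shell pixel sets and the exact noise-free protein (`S`) and membrane
#' (`M`) sums over the shell, so noise-free pipeline output can be checked
#' bit-exactly (`release_index == S / M`).
#'
#' @param size Image side in pixels.
#' @param pixel_size_um,bit_depth Calibration (see [calibration()]).
#' @param center Bouton center `(x, y)` in pixel units; default image
#'   center.
#' @param bouton_radius_um Bouton radius (default 2 um, within the 2-5 um
#'   diameter range of larval boutons).
#' @param membrane_level Mask-channel intensity on the bouton disk.
#' @param shell_membrane_level Mask-channel intensity in the shell annulus
#'   (kept well below `membrane_level` so Otsu isolates the bouton).
#' @param interior_protein_level Protein-channel intensity inside the
#'   bouton.
#' @param shell_width_um Annulus width; matches the pipeline's default
#'   enlargement distance.
#' @param shell_plants Either NULL (plant `n_plants` random single pixels
#'   in the annulus with amplitudes drawn from `amp_range`) or a list of
#'   `list(pos = c(x, y), amp = )` entries; a plant outside the annulus is
#'   an error.
#' @param n_plants,amp_range Random-plant count and amplitude range.
#' @param noise_sd Additive Gaussian noise SD (intensity units), applied to
#'   both channels and clipped to the valid range.
#' @param poisson Replace each noise-free value by a Poisson draw first?
#' @param blur_sd Gaussian blur SD in pixels (0 = none; breaks exact
#'   compartment sums).
#' @param background_level Protein-channel level outside the bouton
#'   (default 0 so the planted shell sum is exact).
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output. The caller's RNG state is restored.
#' @return List with `stack` (a [two_channel_stack()]) and `truth`:
#'   `bouton`, `shell` (logical matrices), `plants` (data.frame x, y, amp),
#'   `S`, `M` (noise-free shell sums), `planted_amp_sum`.
#' @export
make_exo_stack <- function(size = 256L, pixel_size_um = 0.1, bit_depth = 12L,
                           center = NULL, bouton_radius_um = 2,
                           membrane_level = 3000L,
                           shell_membrane_level = 200L,
                           interior_protein_level = 500L,
                           shell_width_um = 1,
                           shell_plants = NULL, n_plants = 4L,
                           amp_range = c(300, 1500),
                           noise_sd = 0, poisson = FALSE, blur_sd = 0,
                           background_level = 0L, seed = NULL) {
  cal <- calibration(pixel_size_um, bit_depth)
  maxv <- max_value(cal)
  if (is.null(center)) center <- c(size / 2, size / 2)
  r_px <- bouton_radius_um / pixel_size_um
  bouton <- disk_mask(size, center, r_px)
  if (!any(bouton)) stop("bouton outside image bounds", call. = FALSE)
  d2 <- cpp_edt_sq(bouton)
  shell <- !bouton & d2 <= (shell_width_um / pixel_size_um)^2

  with_seed(seed, {
    if (is.null(shell_plants)) {
      shell_idx <- which(shell)
      n_plants <- min(n_plants, length(shell_idx))
      pick <- sample(shell_idx, n_plants)
      nr <- size
      shell_plants <- lapply(seq_along(pick), function(i) {
        list(pos = c(((pick[i] - 1L) %/% nr) + 1L,   # x = col
                     ((pick[i] - 1L) %% nr) + 1L),   # y = row
             amp = round(runif(1L, amp_range[1L], amp_range[2L])))
      })
    }

    mask_clean <- matrix(0, size, size)
    mask_clean[shell] <- shell_membrane_level
    mask_clean[bouton] <- membrane_level

    protein_clean <- matrix(as.numeric(background_level), size, size)
    protein_clean[bouton] <- interior_protein_level
    plants_df <- data.frame(x = integer(), y = integer(), amp = numeric())
    for (p in shell_plants) {
      x <- as.integer(p$pos[1L]); y <- as.integer(p$pos[2L])
      if (x < 1L || x > size || y < 1L || y > size || !shell[y, x]) {
        stop("plant outside annulus", call. = FALSE)
      }
      protein_clean[y, x] <- protein_clean[y, x] + p$amp
      plants_df <- rbind(plants_df, data.frame(x = x, y = y, amp = p$amp))
    }
    if (max(protein_clean) > maxv || max(mask_clean) > maxv) {
      stop("planted amplitude exceeds the bit-depth maximum", call. = FALSE)
    }

    truth <- list(bouton = bouton, shell = shell, plants = plants_df,
                  S = sum(protein_clean[shell]),
                  M = sum(mask_clean[shell]),
                  planted_amp_sum = sum(plants_df$amp))

    stack <- two_channel_stack(
      finalize_channel(protein_clean, cal, noise_sd, poisson, blur_sd),
      finalize_channel(mask_clean, cal, noise_sd, poisson, blur_sd))
    list(stack = stack, truth = truth)
  })
}

spot_pixels <- function(size, center, rx_px, ry_px, angle) {
  r <- ceiling(max(rx_px, ry_px)) + 1L
  cx <- center[1L]; cy <- center[2L]
  cols <- max(1L, floor(cx - r)):min(size, ceiling(cx + r))
  rows <- max(1L, floor(cy - r)):min(size, ceiling(cy + r))
  ca <- cos(angle); sa <- sin(angle)
  idx <- integer(0)
  for (j in cols) {
    dx <- (j - 0.5) - cx
    for (i in rows) {
      dy <- (i - 0.5) - cy
      u <- (dx * ca + dy * sa) / rx_px
      v <- (-dx * sa + dy * ca) / ry_px
      if (u * u + v * v <= 1) idx <- c(idx, (j - 1L) * size + i)
    }
  }
  idx
}

#' Synthetic puncta image for the autophagosome-counting pipeline
#'
#' Renders a DLG-like surrounding region in the mask channel and, in the
#' protein channel, a flat interior level plus compact high-intensity spots
#' (optionally elliptical). Ground truth records every planted spot's pixel
#' set, center and calibrated area, plus the spot count and the count
#' expected after centroid-distance merging, so noise-free pipeline counts
#' can be compared exactly.
#'
#' @inheritParams make_exo_stack
#' @param region_center,region_radius_um Surrounding-region disk (mask
#'   channel); default radius 8 um.
#' @param region_level Mask-channel intensity on the region.
#' @param protein_interior_level Protein level inside the region (the
#'   diffuse cytosolic signal).
#' @param spots NULL (generate `n_spots` random non-overlapping spots) or a
#'   list of `list(center = c(x, y), radius_um = , amp = , axis_ratio = 1,
#'   angle = 0)` entries. `amp` is added on top of the interior level.
#' @param n_spots,spot_radius_range_um,spot_amp Random-spot parameters.
#' @param min_separation_um Minimum pairwise center distance; violating it
#'   with explicit `spots` (when `check_separation`) is an error.
#' @param margin_um Minimum distance of spot centers from the region
#'   boundary.
#' @param spot_area_window_um2 Expected planted-area window (the detection
#'   size filter); a planted spot outside it is an error when `check_size`.
#' @param check_separation,check_size Enable the two preconditions above.
#' @param merge_distance_um Merge limit used to record
#'   `expected_merged_count` in the ground truth.
#' @return List with `stack` and `truth`: `region` (logical matrix),
#'   `count`, `centers_px` (data.frame x, y), `spot_idx` (list of pixel
#'   index vectors), `areas_um2`, `expected_merged_count`.
#' @export
make_auto_stack <- function(size = 256L, pixel_size_um = 0.1, bit_depth = 12L,
                            region_center = NULL, region_radius_um = 8,
                            region_level = 3000L,
                            protein_interior_level = 480L,
                            spots = NULL, n_spots = 5L,
                            spot_radius_range_um = c(0.18, 0.32),
                            spot_amp = 2400L,
                            min_separation_um = 1.0, margin_um = 1.0,
                            spot_area_window_um2 = c(0.09, 0.5),
                            check_separation = TRUE, check_size = TRUE,
                            merge_distance_um = 0.5,
                            noise_sd = 0, poisson = FALSE, blur_sd = 0,
                            background_level = 0L, seed = NULL) {
  cal <- calibration(pixel_size_um, bit_depth)
  maxv <- max_value(cal)
  if (is.null(region_center)) region_center <- c(size / 2, size / 2)
  region <- disk_mask(size, region_center, region_radius_um / pixel_size_um)
  if (!any(region)) stop("region outside image bounds", call. = FALSE)

  with_seed(seed, {
    if (is.null(spots)) {
      rmax <- region_radius_um / pixel_size_um - margin_um / pixel_size_um
      centers <- matrix(numeric(0), 0L, 2L)
      guard <- 0L
      while (nrow(centers) < n_spots && guard < 10000L) {
        guard <- guard + 1L
        ang <- runif(1L, 0, 2 * pi)
        rad <- sqrt(runif(1L)) * rmax
        cand <- region_center + rad * c(cos(ang), sin(ang))
        if (nrow(centers) > 0L) {
          d <- sqrt((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2)
          if (min(d) * pixel_size_um < min_separation_um) next
        }
        centers <- rbind(centers, cand)
      }
      if (nrow(centers) < n_spots) {
        stop("could not place the requested spots with the given separation",
             call. = FALSE)
      }
      spots <- lapply(seq_len(n_spots), function(i) {
        list(center = centers[i, ],
             radius_um = runif(1L, spot_radius_range_um[1L],
                               spot_radius_range_um[2L]),
             amp = spot_amp, axis_ratio = 1, angle = 0)
      })
    }

    if (check_separation && length(spots) > 1L) {
      for (i in seq_len(length(spots) - 1L)) {
        for (j in (i + 1L):length(spots)) {
          d <- sqrt(sum((spots[[i]]$center - spots[[j]]$center)^2)) *
            pixel_size_um
          if (d < min_separation_um) {
            stop("overlapping spots: pairwise separation below the requested minimum",
                 call. = FALSE)
          }
        }
      }
    }

    protein_clean <- matrix(as.numeric(background_level), size, size)
    protein_clean[region] <- protein_interior_level
    spot_idx <- vector("list", length(spots))
    centers_px <- data.frame(x = numeric(), y = numeric())
    for (i in seq_along(spots)) {
      sp <- spots[[i]]
      ar <- if (is.null(sp$axis_ratio)) 1 else sp$axis_ratio
      an <- if (is.null(sp$angle)) 0 else sp$angle
      rx <- sp$radius_um / pixel_size_um
      idx <- spot_pixels(size, sp$center, rx, rx * ar, an)
      if (length(idx) == 0L) stop("spot renders no pixels", call. = FALSE)
      if (!all(region[idx])) stop("spot extends outside the region", call. = FALSE)
      a_um2 <- length(idx) * pixel_size_um^2
      if (check_size && (a_um2 < spot_area_window_um2[1L] ||
                         a_um2 > spot_area_window_um2[2L])) {
        stop(sprintf("planted spot area %.3g um^2 outside the expected window",
                     a_um2), call. = FALSE)
      }
      protein_clean[idx] <- protein_clean[idx] + sp$amp
      spot_idx[[i]] <- idx
      centers_px <- rbind(centers_px,
                          data.frame(x = sp$center[1L], y = sp$center[2L]))
    }
    if (max(protein_clean) > maxv) {
      stop("planted amplitude exceeds the bit-depth maximum", call. = FALSE)
    }

    mask_clean <- matrix(0, size, size)
    mask_clean[region] <- region_level

    # expected post-merge object count, from the merge rule applied to the
    # planted pixel sets on the noise-free 8-bit rendering
    clean8 <- convert_to_8bit(channel_image(
      matrix(as.integer(round(protein_clean)), size), cal))
    planted_dots <- lapply(spot_idx, make_dot, img = clean8, cal = cal)
    expected_merged <- length(merge_dots(planted_dots, merge_distance_um,
                                         cal, source = clean8))

    truth <- list(region = region, count = length(spots),
                  centers_px = centers_px, spot_idx = spot_idx,
                  areas_um2 = vapply(spot_idx, function(ix)
                    length(ix) * pixel_size_um^2, numeric(1L)),
                  expected_merged_count = expected_merged)

    stack <- two_channel_stack(
      finalize_channel(protein_clean, cal, noise_sd, poisson, blur_sd),
      finalize_channel(mask_clean, cal, noise_sd, poisson, blur_sd))
    list(stack = stack, truth = truth)
  })
}
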