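## Exosome-release quantification: protein fluorescence in a calibrated
## extrasynaptic shell around the Otsu-segmented bouton, as an 8-row results
## table plus a release index.

#' Exoquant configuration
#'
#' @param shell_distance_um Extracellular distance to quantify, in
#'   micrometers; the default 1 um corresponds to the thickness of the
#'   subsynaptic reticulum in which released exosomes travel.
#' @param roi `"largest"` or an `(x, y)` seed pixel for
#'   [select_component()].
#' @param index_mode `"shell-ratio"` (default): release index = shell
#'   protein raw integrated density / shell membrane-marker raw integrated
#'   density. `"inside-outside"`: the alternative outside/inside protein
#'   ratio (row 6 / row 4 raw integrated density).
#' @param annulus Also report shell-only (annulus, bouton excluded)
#'   measurement rows? Off by default; the canonical rows 5-6 measure the
#'   enlarged region with the bouton interior already zeroed, faithful to
#'   the original macro.
#' @return A `"exoquant_config"` list.
#' @export
exoquant_config <- function(shell_distance_um = 1.0,
                            roi = "largest",
                            index_mode = c("shell-ratio", "inside-outside"),
                            annulus = FALSE) {
  if (!is.numeric(shell_distance_um) || shell_distance_um < 0) {
    stop("shell_distance_um must be >= 0", call. = FALSE)
  }
  structure(list(shell_distance_um = shell_distance_um,
                 roi = roi,
                 index_mode = match.arg(index_mode),
                 annulus = isTRUE(annulus)),
            class = "exoquant_config")
}

warn_saturation <- function(img, what) {
  if (any(img$pixels == max_value(img$calibration))) {
    warning(sprintf("saturated pixels in %s channel; quantification proceeds",
                    what), call. = FALSE)
  }
  invisible(NULL)
}

#' Run the Exoquant pipeline on one two-channel image
#'
#' Pipeline, in macro order: measure both full channels (rows 1-2);
#' Otsu-threshold the mask channel and select the bouton component; measure
#' the bouton interior in both channels (rows 3-4); zero the bouton interior
#' in both channels; enlarge the bouton region by `shell_distance_um`;
#' measure the enlarged region in the cleared channels (rows 5-6, so their
#' raw integrated densities are shell-pure while their means are diluted by
#' the zeroed interior); measure the full cleared images (rows 7-8). The
#' release index is the shell protein signal divided by the shell
#' membrane-marker signal (raw integrated densities).
#'
#' @param stack A [two_channel_stack()].
#' @param cfg An [exoquant_config()].
#' @return An `"exoquant_result"` with `rows` (8-row measurement table),
#'   `otsu_threshold`, `bouton_mask`, `enlarged_mask`, `shell_mask`
#'   (annulus), `release_index` and, when `cfg$annulus`, `annulus_rows`.
#' @examples
#' fx <- make_exo_stack(seed = 1)
#' res <- run_exoquant(fx$stack, exoquant_config())
#' res$release_index
#' @export
run_exoquant <- function(stack, cfg = exoquant_config()) {
  stopifnot(inherits(stack, "nmj_stack"), inherits(cfg, "exoquant_config"))
  warn_saturation(stack$mask, "mask")
  warn_saturation(stack$protein, "protein")
  cal <- stack$calibration
  full <- matrix(TRUE, nrow(stack$mask$pixels), ncol(stack$mask$pixels))

  r1 <- region_stats(stack$mask, full, "full_mask")
  r2 <- region_stats(stack$protein, full, "full_protein")

  th <- otsu_threshold(stack$mask)
  bouton <- select_component(th$mask, cfg$roi)
  r3 <- region_stats(stack$mask, bouton, "bouton_mask")
  r4 <- region_stats(stack$protein, bouton, "bouton_protein")

  cl_mask <- clear_region(stack$mask, bouton)
  cl_protein <- clear_region(stack$protein, bouton)
  enlarged <- enlarge_region(bouton, cfg$shell_distance_um, cal)
  r5 <- region_stats(cl_mask, enlarged, "shell_mask")
  r6 <- region_stats(cl_protein, enlarged, "shell_protein")
  r7 <- region_stats(cl_mask, full, "cleared_full_mask")
  r8 <- region_stats(cl_protein, full, "cleared_full_protein")

  rows <- rbind(r1, r2, r3, r4, r5, r6, r7, r8)
  rownames(rows) <- NULL

  res <- structure(list(rows = rows,
                        otsu_threshold = th$threshold,
                        bouton_mask = bouton,
                        enlarged_mask = enlarged,
                        shell_mask = enlarged & !bouton,
                        release_index = NA_real_,
                        config = cfg),
                   class = "exoquant_result")
  if (cfg$annulus) {
    ann <- res$shell_mask
    if (any(ann)) {
      res$annulus_rows <- rbind(
        region_stats(cl_mask, ann, "annulus_mask"),
        region_stats(cl_protein, ann, "annulus_protein"))
      rownames(res$annulus_rows) <- NULL
    }
  }
  res$release_index <- release_index(res)
  res
}

#' Exosome release index
#'
#' Ratio of shell protein signal to shell membrane-marker signal: the
#' protein raw integrated density in the enlarged extracellular area divided
#' by the membrane (HRP) raw integrated density in the same area, allowing
#' direct comparison between genotypes. Undefined (NA, with a warning) when
#' the membrane shell signal is zero. Under `index_mode = "inside-outside"`
#' the ratio is instead shell protein / bouton-interior protein.
#'
#' @param res An `"exoquant_result"`.
#' @return A single ratio, or NA with a warning.
#' @export
release_index <- function(res) {
  stopifnot(inherits(res, "exoquant_result"))
  num <- res$rows$rawintden[6L]
  den <- if (res$config$index_mode == "inside-outside") {
    res$rows$rawintden[4L]
  } else {
    res$rows$rawintden[5L]
  }
  if (den <= 0) {
    warning("release index undefined: zero signal in the denominator region",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Normalize per-image indices to a control group
#'
#' Divides every index by the mean of the control indices, so the control
#' group averages 1 (the convention used when reporting mutant release
#' relative to wild type).
#'
#' @param indices Numeric vector of per-image release indices.
#' @param control_indices Numeric vector for the control condition.
#' @return `indices / mean(control_indices)`.
#' @export
normalize_to_control <- function(indices, control_indices) {
  if (length(control_indices) == 0L || all(is.na(control_indices))) {
    stop("control set is empty", call. = FALSE)
  }
  m <- mean(control_indices, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0", call. = FALSE)
  indices / m
}

#' @export
print.exoquant_result <- function(x, ...) {
  px_area <- x$rows$area_um2[1L] / prod(dim(x$bouton_mask))
  cat("Exoquant result\n")
  cat(sprintf("  Otsu threshold (mask channel): %d\n", x$otsu_threshold))
  cat(sprintf("  bouton area: %.4g um^2; shell area: %.4g um^2\n",
              sum(x$bouton_mask) * px_area, sum(x$shell_mask) * px_area))
  cat(sprintf("  release index: %.6g\n", x$release_index))
  print(x$rows, digits = 6)
  invisible(x)
}
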