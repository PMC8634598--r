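## TIFF ingestion with micrometer calibration, CSV/JSON emission, batch
## driver. 12-bit acquisitions travel in 16-bit TIFF containers with raw
## values preserved; the nominal bit depth comes from configuration, never
## from the container.

#' Load a two-channel TIFF as a calibrated stack
#'
#' Reads a single-plane multichannel grayscale TIFF (two directories, or
#' one directory with two samples per pixel). Pixel size comes from the
#' file's resolution tags when present (equal x/y resolution in cm or inch
#' units); otherwise `pixel_size_um` is required. Anisotropic pixels are
#' rejected. A warning is emitted if any pixel sits at the bit-depth
#' maximum (saturation).
#'
#' @param path TIFF file path.
#' @param channel_order Named integer vector giving which channel is which,
#'   e.g. `c(protein = 1, mask = 2)`.
#' @param pixel_size_um Calibration override in micrometers per pixel.
#' @param bit_depth Nominal bits per sample of the acquisition (default 12;
#'   the container may still be 16-bit).
#' @return A [two_channel_stack()].
#' @export
load_stack <- function(path, channel_order = c(protein = 1L, mask = 2L),
                       pixel_size_um = NULL, bit_depth = 12L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  channels <- list()
  for (el in imgs) {
    if (length(dim(el)) == 3L) {
      for (s in seq_len(dim(el)[3L])) {
        channels[[length(channels) + 1L]] <- el[, , s]
      }
    } else {
      channels[[length(channels) + 1L]] <- el
    }
  }
  if (length(channels) < 2L) stop("requires two channels", call. = FALSE)

  if (is.null(pixel_size_um)) {
    first <- imgs[[1L]]
    xr <- attr(first, "x.resolution")
    yr <- attr(first, "y.resolution")
    unit <- attr(first, "resolution.unit")
    if (is.null(xr) || is.null(yr) || !is.numeric(xr) || xr <= 0) {
      stop("missing calibration: no resolution tags and no pixel_size_um override",
           call. = FALSE)
    }
    if (!isTRUE(all.equal(xr, yr))) {
      stop("anisotropic pixels are not supported", call. = FALSE)
    }
    um_per_unit <- switch(as.character(unit %||% "inch"),
                          cm = 1e4, centimeter = 1e4,
                          inch = 25400, `2` = 25400, `3` = 1e4,
                          stop("unrecognized resolution unit; pass pixel_size_um",
                               call. = FALSE))
    pixel_size_um <- um_per_unit / xr
  }
  cal <- calibration(pixel_size_um, bit_depth)

  to_channel <- function(m) {
    m <- matrix(as.integer(round(m)), nrow(m))
    channel_image(m, cal)
  }
  protein <- to_channel(channels[[channel_order[["protein"]]]])
  mask <- to_channel(channels[[channel_order[["mask"]]]])
  if (any(protein$pixels == max_value(cal)) ||
      any(mask$pixels == max_value(cal))) {
    warning(sprintf("%s: saturated pixels at the %d-bit maximum",
                    basename(path), bit_depth), call. = FALSE)
  }
  two_channel_stack(protein, mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a stack as a two-directory TIFF
#'
#' Raw integer values are preserved exactly (8-bit data in an 8-bit
#' container, 12/16-bit data in a 16-bit container), so a write/read
#' round-trip is bit-identical. Resolution tags are not written; pass the
#' pixel size when re-loading.
#'
#' @param stack A [two_channel_stack()]; directory 1 = protein, 2 = mask.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "nmj_stack"))
  container_bits <- if (stack$calibration$bit_depth == 8L) 8L else 16L
  denom <- 2^container_bits - 1
  tiff::writeTIFF(list(stack$protein$pixels / denom,
                       stack$mask$pixels / denom),
                  path, bits.per.sample = container_bits,
                  compression = "none")
  invisible(path)
}

#' Write ground truth as JSON
#'
#' Versioned schema: scalar fields verbatim, pixel sets as 1-based linear
#' (column-major) index vectors with the grid dimension recorded.
#'
#' @param truth A `truth` list from [make_exo_stack()] or
#'   [make_auto_stack()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  enc <- list(schema_version = 1L)
  for (nm in names(truth)) {
    v <- truth[[nm]]
    if (is.matrix(v) && is.logical(v)) {
      enc[[nm]] <- list(dim = dim(v), idx = which(v))
    } else {
      enc[[nm]] <- v
    }
  }
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' MD5 of the canonical JSON rendering; recorded in every batch report so a
#' changed parameter is visible as a changed hash.
#'
#' @param cfg Any configuration list.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                           digits = NA, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

result_csv_table <- function(res, image = "") {
  if (inherits(res, "exoquant_result")) {
    rows <- res$rows
    rows$otsu_threshold <- NA_real_
    rows$release_index <- NA_real_
    summary_row <- rows[1L, ]
    summary_row[1L, ] <- NA
    summary_row$label <- "summary"
    summary_row$otsu_threshold <- res$otsu_threshold
    summary_row$release_index <- res$release_index
    out <- rbind(rows, summary_row)
  } else if (inherits(res, "autophagoquant_result")) {
    rows <- res$rows
    rows$detection_threshold <- NA_real_
    rows$count <- NA_integer_
    summary_row <- rows[1L, ]
    summary_row[1L, ] <- NA
    summary_row$label <- "summary"
    summary_row$detection_threshold <- res$detection_threshold
    summary_row$count <- res$summary$count
    out <- rbind(rows, summary_row)
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  cbind(data.frame(image = image, stringsAsFactors = FALSE), out)
}

#' Write per-image results as CSV
#'
#' Emits the labeled measurement rows (fixed column order: label, area_um2,
#' mean, std_dev, min, max, intden, rawintden, median, mode, skew, kurt,
#' perim_um) plus one summary row carrying the Otsu threshold and release
#' index (Exoquant) or detection threshold and dot count (Autophagoquant).
#'
#' @param res An `"exoquant_result"` or `"autophagoquant_result"`.
#' @param file Output CSV path.
#' @param image Image label for the first column.
#' @return `file`, invisibly.
#' @export
write_results_csv <- function(res, file, image = "") {
  write.csv(result_csv_table(res, image), file, row.names = FALSE)
  invisible(file)
}

#' Write the per-dot table as CSV
#'
#' One row per post-merge dot: id, centroid (um), area, perimeter,
#' circularity, mean, integrated density, distance to the ROI boundary.
#'
#' @param res An `"autophagoquant_result"`.
#' @param file Output CSV path.
#' @param image Image label column.
#' @return `file`, invisibly.
#' @export
write_dots_csv <- function(res, file, image = "") {
  stopifnot(inherits(res, "autophagoquant_result"))
  df <- cbind(data.frame(image = image, stringsAsFactors = FALSE), res$dots_df)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Process a batch of images with one configuration
#'
#' Resolves globs, sorts paths, processes every image independently (one
#' failure does not abort the batch) and returns per-image result blocks,
#' failure records and run metadata including a configuration hash.
#'
#' @param inputs Character vector of paths and/or globs.
#' @param mode `"exo"` or `"auto"`.
#' @param cfg An [exoquant_config()] or [autophagoquant_config()] matching
#'   `mode`; defaults used when NULL.
#' @param pixel_size_um,bit_depth,channel_order Passed to [load_stack()].
#' @param out_csv Optional combined results CSV (per-file blocks with an
#'   image column).
#' @param dots_csv Optional combined per-dot CSV (`mode = "auto"`).
#' @return A `"nmj_batch_report"` with `blocks`, `failures`, `metadata`.
#' @export
run_batch <- function(inputs, mode = c("exo", "auto"), cfg = NULL,
                      pixel_size_um = NULL, bit_depth = 12L,
                      channel_order = c(protein = 1L, mask = 2L),
                      out_csv = NULL, dots_csv = NULL) {
  mode <- match.arg(mode)
  paths <- unlist(lapply(inputs, function(p) {
    if (grepl("[*?\\[]", p)) Sys.glob(p) else p
  }))
  paths <- sort(unique(paths))
  if (length(paths) == 0L) stop("no inputs resolved", call. = FALSE)
  if (is.null(cfg)) {
    cfg <- if (mode == "exo") exoquant_config() else autophagoquant_config()
  }
  blocks <- list()
  failures <- list()
  for (p in paths) {
    res <- tryCatch({
      stack <- load_stack(p, channel_order = channel_order,
                          pixel_size_um = pixel_size_um,
                          bit_depth = bit_depth)
      if (mode == "exo") run_exoquant(stack, cfg)
      else run_autophagoquant(stack, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(file = p,
                                                reason = conditionMessage(res))
    } else {
      blocks[[length(blocks) + 1L]] <- list(file = p, result = res)
    }
  }
  report <- structure(
    list(blocks = blocks, failures = failures,
         metadata = list(package_version = as.character(packageVersion("nmjquant")),
                         mode = mode, config_hash = config_hash(cfg),
                         n_inputs = length(paths),
                         n_processed = length(blocks))),
    class = "nmj_batch_report")
  if (!is.null(out_csv)) {
    tabs <- lapply(report$blocks, function(b)
      result_csv_table(b$result, image = basename(b$file)))
    write.csv(do.call(rbind, tabs), out_csv, row.names = FALSE)
  }
  if (!is.null(dots_csv) && mode == "auto") {
    tabs <- lapply(report$blocks, function(b)
      cbind(data.frame(image = basename(b$file), stringsAsFactors = FALSE),
            b$result$dots_df))
    write.csv(do.call(rbind, tabs), dots_csv, row.names = FALSE)
  }
  report
}

#' @export
print.nmj_batch_report <- function(x, ...) {
  cat(sprintf("Batch report: %d processed, %d failed (mode %s, config %s)\n",
              length(x$blocks), length(x$failures),
              x$metadata$mode, substr(x$metadata$config_hash, 1L, 8L)))
  for (f in x$failures) cat(sprintf("  FAILED %s: %s\n", f$file, f$reason))
  invisible(x)
}

#' Save a review overlay as PNG
#'
#' Grayscale protein channel with the segmented region outlined (and dot
#' outlines for Autophagoquant results) -- a quick visual check mirroring
#' the advice to inspect images before quantifying. Requires the `png`
#' package.
#'
#' @param stack The [two_channel_stack()] that was quantified.
#' @param res The corresponding result object.
#' @param file Output PNG path.
#' @return `file`, invisibly.
#' @export
save_overlay <- function(stack, res, file) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required for overlays", call. = FALSE)
  }
  px <- stack$protein$pixels
  g <- px / max(1, max(px))
  rgb <- array(rep(g, 3L), c(nrow(g), ncol(g), 3L))
  outline <- function(m) m & !shrink1(m)
  if (inherits(res, "exoquant_result")) {
    b <- outline(res$bouton_mask); s <- outline(res$enlarged_mask)
    rgb[, , 1L][b | s] <- 1; rgb[, , 2L][b | s] <- 1; rgb[, , 3L][b | s] <- 0
  } else if (inherits(res, "autophagoquant_result")) {
    r <- outline(res$roi_mask)
    rgb[, , 1L][r] <- 0; rgb[, , 2L][r] <- 1; rgb[, , 3L][r] <- 1
    for (d in res$dots) {
      m <- matrix(FALSE, nrow(g), ncol(g)); m[d$idx] <- TRUE
      o <- outline(m)
      rgb[, , 1L][o] <- 1; rgb[, , 2L][o] <- 1; rgb[, , 3L][o] <- 0
    }
  }
  png::writePNG(rgb, file)
  invisible(file)
}

shrink1 <- function(m) {
  # 4-neighbor erosion, used only to draw 1-px outlines
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1L, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-nr, , drop = FALSE])
  left <- cbind(m[, -1L, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -nc, drop = FALSE])
  m & up & down & left & right
}
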