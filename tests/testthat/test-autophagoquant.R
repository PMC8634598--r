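test_that("the disk median filter is an identity at radius 0 and rejects impulses", {
  set.seed(21)
  img <- img8(matrix(sample(0:255, 225, TRUE), 15, 15))
  expect_identical(median_filter(img, 0L), img)
  flat <- img8(matrix(40, 9, 9))
  expect_identical(median_filter(flat, 1L)$pixels, flat$pixels)
  hot <- matrix(0L, 9, 9); hot[5, 5] <- 255L
  expect_true(all(median_filter(img8(hot), 1L)$pixels == 0L))
})

test_that("radius-1 median uses the 5-pixel plus neighborhood", {
  m <- matrix(0L, 5, 5)
  m[3, 3] <- 10L; m[2, 3] <- 20L; m[4, 3] <- 30L; m[3, 2] <- 40L; m[3, 4] <- 50L
  out <- median_filter(img8(m), 1L)
  expect_identical(out$pixels[3, 3], 30L)  # median of {10,20,30,40,50}
  # corner uses the 3 available neighbors only (lower middle of 3)
  c3 <- sort(c(m[1, 1], m[1, 2], m[2, 1]))
  expect_identical(out$pixels[1, 1], c3[2])
})

test_that("the detection threshold is mean + k SD, unclamped", {
  st <- data.frame(mean = 10, std_dev = 5)
  expect_equal(detection_threshold(st, 4), 30)
  expect_equal(detection_threshold(st, 0), 10)
  expect_equal(detection_threshold(data.frame(mean = 250, std_dev = 30), 4), 370)
})

test_that("a constant ROI yields no detections (strict inequality)", {
  img <- img8(matrix(40L, 20, 20), pixel_size_um = 0.1)
  roi <- matrix(TRUE, 20, 20)
  st <- region_stats(img, roi)
  thr <- detection_threshold(st, 4)
  expect_identical(thr, 40)  # sd = 0
  expect_length(detect_dots(img, roi, thr), 0L)
})

test_that("detection recovers a planted in-range spot and applies the size filter", {
  cfg <- autophagoquant_config()
  m <- matrix(30L, 40, 40)
  spot <- disk_at(40, 20.5, 20.5, 1.8)      # 9 px = 0.09 um^2 at 0.1 um/px
  m[spot] <- 200L
  img <- img8(m, pixel_size_um = 0.1)
  roi <- matrix(TRUE, 40, 40)
  dots <- detect_dots(img, roi, 100, cfg)
  expect_length(dots, 1L)
  expect_setequal(dots[[1]]$idx, which(spot))
  expect_equal(dots[[1]]$area_um2, 0.09)

  big <- matrix(30L, 40, 40)
  big[disk_at(40, 20, 20, 8)] <- 200L       # ~2 um^2, above size_max
  expect_length(detect_dots(img8(big, 0.1), roi, 100, cfg), 0L)

  expect_length(detect_dots(img, roi, 400, cfg), 0L)  # nothing above threshold
})

test_that("pre-merge dots always satisfy the size window and circularity bounds", {
  fx <- make_auto_stack(seed = 31, n_spots = 8)
  res <- run_autophagoquant(fx$stack)
  cfg <- autophagoquant_config()
  protein8 <- convert_to_8bit(fx$stack$protein)
  filt <- median_filter(protein8, 1L)
  pre <- detect_dots(filt, res$roi_mask, res$detection_threshold, cfg)
  for (d in pre) {
    expect_true(d$area_um2 >= cfg$size_min_um2 && d$area_um2 <= cfg$size_max_um2)
    expect_true(d$circularity >= 0 && d$circularity <= 1)
  }
  # with the recommended circularity floor of 0 nothing is rejected on shape
  wide <- autophagoquant_config(circ_min = 0, circ_max = 1)
  expect_identical(length(detect_dots(filt, res$roi_mask,
                                      res$detection_threshold, wide)),
                   length(pre))
})

make_test_dot <- function(size, rows, cols, level = 200L, ps = 0.1) {
  m <- matrix(30L, size, size)
  m[rows, cols] <- level
  img <- img8(m, pixel_size_um = ps)
  full <- matrix(FALSE, size, size); full[rows, cols] <- TRUE
  nmjquant:::make_dot(which(full), img, img$calibration)
}

test_that("dot merging applies the centroid-distance rule to a fixed point", {
  size <- 40; ps <- 0.1
  cal <- calibration(ps, 8L)
  src <- img8(matrix(200L, size, size), pixel_size_um = ps)

  d1 <- make_test_dot(size, 2:4, 2:4)
  d2 <- make_test_dot(size, 2:4, 5:7)    # centroids 0.3 um apart
  merged <- merge_dots(list(d1, d2), 0.5, cal, source = src)
  expect_length(merged, 1L)
  expect_identical(sort(merged[[1]]$idx), sort(c(d1$idx, d2$idx)))

  d3 <- make_test_dot(size, 2:4, 8:10)   # 0.6 um from d1
  expect_length(merge_dots(list(d1, d3), 0.5, cal, source = src), 2L)

  # equal-mass collinear chain at 0.4/0.4 um: after the first merge the union
  # centroid sits 0.6 um from the third dot, so the fixed point is two dots
  a <- make_test_dot(size, 2:4, 5:7)
  b <- make_test_dot(size, 6:8, 5:7)
  c <- make_test_dot(size, 10:12, 5:7)
  expect_length(merge_dots(list(a, b, c), 0.5, cal, source = src), 2L)

  # a 3x heavier middle dot pulls the union centroid within reach: full collapse
  b_big <- make_test_dot(size, 6:8, 2:11)  # 30 px
  out <- merge_dots(list(a, b_big, c), 0.5, cal, source = src)
  expect_length(out, 1L)
})

test_that("merging is idempotent and leaves all pairs beyond the limit", {
  set.seed(33)
  cal <- calibration(0.1, 8L)
  src <- img8(matrix(200L, 60, 60), pixel_size_um = 0.1)
  for (k in 1:5) {
    dots <- lapply(1:6, function(i) {
      r0 <- sample(2:55, 1); c0 <- sample(2:55, 1)
      make_test_dot(60, r0:(r0 + 2), c0:(c0 + 2))
    })
    m1 <- merge_dots(dots, 0.5, cal, source = src)
    m2 <- merge_dots(m1, 0.5, cal, source = src)
    expect_identical(lapply(m2, `[[`, "idx"), lapply(m1, `[[`, "idx"))
    if (length(m1) > 1L) {
      for (i in seq_len(length(m1) - 1L)) {
        for (j in (i + 1L):length(m1)) {
          d <- sqrt(sum((m1[[i]]$centroid_um - m1[[j]]$centroid_um)^2))
          expect_true(d > 0.5)
        }
      }
    }
  }
})

test_that("the pipeline reproduces the 4-row table and planted counts", {
  fx <- make_auto_stack(seed = 35, n_spots = 5)
  res <- run_autophagoquant(fx$stack)
  expect_identical(nrow(res$rows), 4L)
  expect_identical(res$rows$label,
                   c("mask_otsu_binarized", "roi_protein_filtered",
                     "roi_protein_unfiltered", "roi_protein_above_threshold"))
  expect_identical(res$summary$count, 5L)
  expect_identical(res$summary$count, length(res$dots))
  expect_identical(res$summary$mode, 255)
  expect_identical(res$summary$median, 255)
  # threshold identity
  expect_equal(res$detection_threshold - res$rows$mean[2],
               res$config$k_sd * res$rows$std_dev[2])
  # row 1 measures the binarized mask channel: only 0 and 255 present
  expect_identical(res$rows$min[1], 0)
  expect_identical(res$rows$max[1], 255)
})

test_that("a flat protein channel yields zero dots", {
  fx <- make_auto_stack(seed = 36, n_spots = 0)
  res <- run_autophagoquant(fx$stack)
  expect_identical(res$summary$count, 0L)
  expect_identical(nrow(res$dots_df), 0L)
  expect_identical(res$summary$total_area_um2, 0)
})

test_that("raising k_sd never increases the candidate pixel count", {
  fx <- make_auto_stack(seed = 37, n_spots = 6)
  protein8 <- convert_to_8bit(fx$stack$protein)
  filt <- median_filter(protein8, 1L)
  roi <- select_component(otsu_threshold(fx$stack$mask)$mask)
  st <- region_stats(filt, roi)
  prev <- Inf
  for (k in c(0, 2, 4, 8)) {
    n_cand <- sum(roi & (filt$pixels > detection_threshold(st, k)))
    expect_true(n_cand <= prev)
    prev <- n_cand
  }
})

test_that("centroid-to-boundary distance matches brute force", {
  cal <- calibration(0.1, 8L)
  roi <- disk_at(40, 20, 20, 12)
  img <- img8(matrix(200L, 40, 40), pixel_size_um = 0.1)
  # dot at the disk center: distance ~ radius (within half-pixel discretization)
  center_dot <- nmjquant:::make_dot(which(disk_at(40, 20, 20, 1.8)), img, cal)
  d <- dot_distance_to_boundary(center_dot, roi, cal)
  expect_true(abs(d - 1.2) < 0.1)

  set.seed(39)
  for (k in 1:5) {
    r0 <- sample(14:26, 1); c0 <- sample(14:26, 1)
    spot <- matrix(FALSE, 40, 40); spot[r0, c0] <- TRUE
    dot <- nmjquant:::make_dot(which(spot), img, cal)
    out_pix <- which(!roi, arr.ind = TRUE)
    brute <- sqrt(min(((out_pix[, 2] - 0.5) * 0.1 - dot$centroid_um[["x"]])^2 +
                        ((out_pix[, 1] - 0.5) * 0.1 - dot$centroid_um[["y"]])^2))
    expect_equal(dot_distance_to_boundary(dot, roi, cal), brute)
  }

  expect_error(dot_distance_to_boundary(center_dot, matrix(TRUE, 40, 40), cal),
               "no boundary")
})

test_that("the diameter size-unit flag converts the window to areas", {
  cfg <- autophagoquant_config(size_min_um2 = 0.3, size_max_um2 = 0.8,
                               size_unit = "um-diameter")
  expect_equal(cfg$size_min_um2, pi * 0.15^2)
  expect_equal(cfg$size_max_um2, pi * 0.4^2)
})
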