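test_that("Otsu separates a forced two-class image and rejects constant input", {
  img <- img8(matrix(c(rep(0, 50), rep(200, 50)), 10, 10))
  res <- otsu_threshold(img)
  expect_identical(res$mask, img$pixels == 200L)
  expect_true(res$threshold >= 0 && res$threshold < 200)

  expect_error(otsu_threshold(img8(matrix(7, 5, 5))), "degenerate histogram")
})

test_that("Otsu equals exhaustive within-class-variance minimization", {
  set.seed(42)
  for (k in 1:10) {
    v <- c(rnorm(400, 50, 10), rnorm(624, 180, 10))
    v <- pmin(pmax(round(v), 0), 255)
    img <- img8(matrix(v, 32, 32))
    expect_identical(otsu_threshold(img)$threshold, otsu_brute(v))
  }
})

test_that("Otsu of a 12-bit image thresholds in source units", {
  cal <- calibration(0.1, 12L)
  v <- matrix(c(rep(100L, 60), rep(3000L, 40)), 10, 10)
  img <- channel_image(v, cal)
  res <- otsu_threshold(img)
  expect_identical(res$mask, v == 3000L)
  expect_true(res$threshold >= 100 && res$threshold < 3000)
})

test_that("component selection honors seeds, size ties and 8-connectivity", {
  m <- matrix(FALSE, 12, 12)
  m[2:3, 2:6] <- TRUE                      # 10 px component
  m[6:10, 5:12] <- TRUE                    # 40 px component
  expect_identical(sum(select_component(m, "largest")), 40L)
  small <- select_component(m, c(2, 2))    # seed (x, y) inside the small one
  expect_identical(sum(small), 10L)
  expect_true(all(m[small]))

  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE # touch only diagonally
  expect_identical(sum(select_component(diag2, c(1, 1))), 2L)

  expect_error(select_component(m, c(1, 1)), "seed not in foreground")
  expect_error(select_component(matrix(FALSE, 3, 3)), "empty mask")
})

test_that("selected components are connected subsets of the input mask", {
  set.seed(7)
  for (k in 1:5) {
    m <- random_blob(20, 20, n_seeds = 4L)
    if (!any(m)) next
    comp <- select_component(m, "largest")
    expect_true(all(m[comp]))
    # connectedness: relabeling the component yields a single label
    expect_identical(max(nmjquant:::cpp_label8(comp)), 1L)
  }
})

test_that("enlargement is Euclidean, monotone, and matches brute force", {
  cal <- calibration(1, 8L)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_identical(enlarge_region(one, 0, cal), one)
  plus <- enlarge_region(one, 1, cal)
  expect_identical(sum(plus), 5L)                     # 4 edge neighbors only
  expect_false(plus[2, 2])                            # diagonal at sqrt(2) excluded

  set.seed(11)
  for (k in 1:5) {
    roi <- random_blob(24, 24)
    d <- runif(1, 0.5, 6)
    out <- enlarge_region(roi, d, cal)
    expect_identical(out, enlarge_brute(roi, d, 1))
    expect_true(all(out[roi]))                        # output contains roi
    bigger <- enlarge_region(roi, d + 1, cal)
    expect_true(all(bigger[out]))                     # monotone in distance
  }
})

test_that("clearing zeroes the region and conserves total intensity", {
  set.seed(3)
  img <- img8(matrix(sample(0:255, 400, TRUE), 20, 20))
  full <- matrix(TRUE, 20, 20)
  expect_identical(clear_region(img, matrix(FALSE, 20, 20))$pixels, img$pixels)
  expect_true(all(clear_region(img, full)$pixels == 0L))

  roi <- random_blob(20, 20)
  cleared <- clear_region(img, roi)
  expect_identical(region_stats(cleared, full)$rawintden +
                     region_stats(img, roi)$rawintden,
                   region_stats(img, full)$rawintden)
})

test_that("region statistics match a naive recomputation", {
  img <- img8(matrix(c(1, 2, 3, 9), 2, 2))
  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  st <- region_stats(img, roi)
  expect_equal(st$area_um2, 3)
  expect_equal(st$mean, 2)
  expect_equal(st$median, 2)
  expect_equal(st$rawintden, 6)
  expect_equal(st$skew, 0)

  tie <- img8(matrix(c(0, 0, 255, 255), 2, 2))
  st2 <- region_stats(tie, matrix(TRUE, 2, 2))
  expect_equal(st2$mean, 127.5)
  expect_equal(st2$mode, 0)        # tie resolves to the smaller value
  expect_equal(st2$min, 0)
  expect_equal(st2$max, 255)
  expect_equal(st2$median, 0)      # even count takes the lower middle

  set.seed(5)
  vals <- sample(0:255, 100, TRUE)
  m <- matrix(0L, 10, 20)
  roi <- matrix(FALSE, 10, 20)
  roi[1:10, 1:10] <- TRUE
  m[roi] <- vals
  st3 <- region_stats(img8(m, pixel_size_um = 0.2), roi)
  ref <- stats_naive(vals, 0.2)
  for (f in names(ref)) expect_equal(st3[[f]], ref[[f]], info = f)

  expect_error(region_stats(img, matrix(FALSE, 2, 2)), "empty region")
  flat <- region_stats(img8(matrix(9, 3, 3)), matrix(TRUE, 3, 3))
  expect_equal(flat$skew, 0)
  expect_equal(flat$kurt, 0)
})

test_that("raw integrated density is additive over disjoint regions", {
  set.seed(9)
  img <- img8(matrix(sample(0:255, 900, TRUE), 30, 30))
  a <- matrix(FALSE, 30, 30); a[1:10, ] <- TRUE
  b <- matrix(FALSE, 30, 30); b[11:30, ] <- TRUE
  expect_identical(region_stats(img, a)$rawintden +
                     region_stats(img, b)$rawintden,
                   region_stats(img, a | b)$rawintden)
})

test_that("8-bit conversion maps the full nominal range, monotonically", {
  cal <- calibration(0.1, 12L)
  v <- 0:4095
  img <- channel_image(matrix(v, 64, 64), cal)
  out <- convert_to_8bit(img)
  expect_identical(out$calibration$bit_depth, 8L)
  o <- as.vector(out$pixels)
  expect_identical(o[1], 0L)
  expect_identical(o[4096], 255L)
  expect_identical(o[2049], as.integer(round(2048 * 255 / 4095)))  # 128
  expect_true(all(diff(o) >= 0L))                # monotone over the full sweep
  expect_identical(o, as.integer(floor(v * 255 / 4095 + 0.5)))

  img8bit <- img8(matrix(0:255, 16, 16))
  expect_identical(convert_to_8bit(img8bit), img8bit)
})
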