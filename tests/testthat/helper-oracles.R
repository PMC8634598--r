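# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, all-pairs, sorting) so they exercise none of the
# package's own code paths.

img8 <- function(mat, pixel_size_um = 1) {
  channel_image(matrix(as.integer(mat), nrow(mat)),
                calibration(pixel_size_um, 8L))
}

pop_var <- function(x) mean((x - mean(x))^2)

# exhaustive minimization of within-class variance over all 256 candidate
# thresholds of an 8-bit image; ties resolve to the smallest threshold
otsu_brute <- function(values) {
  v <- as.numeric(values)
  n <- length(v)
  best_t <- NA_integer_
  best_w <- Inf
  for (t in 0:255) {
    a <- v[v <= t]
    b <- v[v > t]
    if (length(a) == 0L || length(b) == 0L) next
    wcv <- (length(a) * pop_var(a) + length(b) * pop_var(b)) / n
    if (wcv < best_w) {
      best_w <- wcv
      best_t <- t
    }
  }
  best_t
}

# all-pairs Euclidean enlargement on small grids
enlarge_brute <- function(roi, distance_um, pixel_size_um) {
  nr <- nrow(roi); nc <- ncol(roi)
  rq <- which(roi, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  lim2 <- (distance_um / pixel_size_um)^2
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d2 <- min((rq[, 1L] - i)^2 + (rq[, 2L] - j)^2)
      out[i, j] <- d2 <= lim2
    }
  }
  out
}

# direct recomputation of every measurement field from the sorted value list
stats_naive <- function(v, pixel_size_um = 1) {
  v <- as.numeric(v)
  n <- length(v)
  s <- sort(v)
  mu <- sum(v) / n
  sdv <- sqrt(sum((v - mu)^2) / n)
  med <- if (n %% 2L == 1L) s[(n + 1L) / 2L] else s[n / 2L]
  uq <- sort(unique(v))
  cnt <- vapply(uq, function(u) sum(v == u), numeric(1L))
  list(area_um2 = n * pixel_size_um^2, mean = mu, std_dev = sdv,
       min = s[1L], max = s[n], intden = n * pixel_size_um^2 * mu,
       rawintden = sum(v), median = med, mode = uq[which.max(cnt)],
       skew = if (sdv > 0) mean((v - mu)^3) / sdv^3 else 0,
       kurt = if (sdv > 0) mean((v - mu)^4) / sdv^4 - 3 else 0)
}

# random blob mask: union of a few disks, for enlargement/selection tests
random_blob <- function(nr, nc, n_seeds = 3L) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_len(n_seeds)) {
    ci <- sample.int(nr, 1L); cj <- sample.int(nc, 1L)
    r <- sample(1:3, 1L)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- TRUE
      }
    }
  }
  m
}

# 8-bit protein + mask stack built directly from matrices (pixel size in um)
stack8 <- function(protein, mask, pixel_size_um = 0.1) {
  cal <- calibration(pixel_size_um, 8L)
  two_channel_stack(channel_image(matrix(as.integer(protein), nrow(protein)), cal),
                    channel_image(matrix(as.integer(mask), nrow(mask)), cal))
}

# disk helper in test space
disk_at <- function(size, cx, cy, r) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      if ((j - 0.5 - cx)^2 + (i - 0.5 - cy)^2 <= r^2) m[i, j] <- TRUE
    }
  }
  m
}
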