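test_that("uniform expression yields a constant matrix and a zero trace", {
  set.seed(5)
  n <- 4000
  ap <- c(0, 1, runif(n - 2))
  dv <- runif(n, 0, 2 * pi - 1e-9)
  emb <- make_flat_embryo(ap, dv, list(lacZ = rep(2.5, n)))
  m <- extract_pattern(emb, "lacZ")
  expect_true(all(abs(m$values - 2.5) < 1e-12))
  tr <- lateral_trace(m)
  expect_equal(tr$value, rep(0, 100))
})

test_that("per-cell means match a brute-force computation on a step pattern", {
  set.seed(17)
  n <- 5000
  ap <- c(0, 1, runif(n - 2))
  dv <- runif(n, 0, 2 * pi - 1e-9)
  v <- ifelse(ap < 0.5, 0, 1)
  emb <- make_flat_embryo(ap, dv, list(lacZ = v))
  m <- extract_pattern(emb, "lacZ")
  # independent per-cell means via tapply on hand-computed assignments
  strip <- pmin(floor(dv / (2 * pi / 16)), 15)
  bin <- pmin(floor(ap * 100), 99)
  ref <- tapply(v, list(factor(strip, 0:15), factor(bin, 0:99)), mean)
  occupied <- !is.na(ref)
  expect_equal(m$values[occupied], ref[occupied], ignore_attr = TRUE)
  expect_equal(sum(m$counts), n)
  tr <- lateral_trace(m)
  expect_true(all(tr$value[1:49] < 0.05))
  expect_true(all(tr$value[52:100] > 0.95))
})

test_that("a 12-nucleus fixture gives hand-computed cell means", {
  strip_of <- function(s) (s + 0.5) * 2 * pi / 16
  bin_of <- function(b) (b + 0.5) / 100
  ap <- bin_of(c(0, 0, 10, 10, 10, 40, 40, 99, 99, 50, 50, 70))
  ap[1] <- 0; ap[8] <- 1   # pin the axis extremes into bins 0 and 99
  dv <- strip_of(c(3, 3, 3, 3, 3, 4, 4, 11, 11, 12, 12, 0))
  vals <- c(1, 3, 4, 6, 8, 10, 20, 5, 7, 2, 4, 9)
  emb <- make_flat_embryo(ap, dv, list(lacZ = vals))
  m <- suppressWarnings(extract_pattern(emb, "lacZ"))
  expect_equal(m$values[4, 1], mean(c(1, 3)))     # strip 3, bin 0
  expect_equal(m$values[4, 11], mean(c(4, 6, 8))) # strip 3, bin 10
  expect_equal(m$values[5, 41], mean(c(10, 20)))  # strip 4, bin 40
  expect_equal(m$values[12, 100], mean(c(5, 7)))  # strip 11, bin 99
  expect_equal(m$values[13, 51], mean(c(2, 4)))   # strip 12, bin 50
  expect_equal(m$values[1, 71], 9)                # strip 0, bin 70
  expect_equal(sum(m$counts), 12)
})

test_that("lateral averaging takes the mean of the two sides", {
  vals <- matrix(1, 16, 100)
  vals[c(4, 5), ] <- 2    # left strips 3-4
  vals[c(12, 13), ] <- 4  # right strips 11-12
  m <- structure(list(values = vals, counts = matrix(1, 16, 100),
                      channel = "lacZ", label = "t"),
                 class = "trace_matrix")
  tr <- lateral_trace(m)
  # pre-subtraction trace is (2+4)/2 = 3 everywhere, so the subtracted
  # background equals 3 and the trace is flat zero
  expect_equal(attr(tr, "background"), 3)
  expect_equal(tr$value, rep(0, 100))
})

test_that("empty cells are interpolated and flagged by zero counts", {
  set.seed(23)
  n <- 3000
  ap <- c(0, 1, runif(n - 2))
  gap <- ap > 0.4 & ap < 0.45
  ap <- ap[!gap]; n <- length(ap)
  dv <- runif(n, 0, 2 * pi - 1e-9)
  emb <- make_flat_embryo(ap, dv, list(lacZ = ap * 10))
  m <- extract_pattern(emb, "lacZ")
  expect_false(anyNA(m$values))
  gap_bins <- 42:44
  expect_true(all(m$counts[, gap_bins] == 0))
  # linear ramp: interpolation reproduces it closely inside the gap
  expect_equal(m$values[4, 43], 10 * (42.5 / 100), tolerance = 0.2)
})

test_that("rotating the embryo about the AP axis permutes the strips", {
  cfg <- reporter_config(n_nuclei = 2000, nucleus_noise_sigma = 0,
                         outlier_rate = 0, embryo_scale_sigma = 0)
  emb <- generate_embryo(cfg, "A", seed = 13)
  th <- 2 * pi / 16
  nuc <- emb$nuclei[c("nucleus_id", "x", "y", "z")]
  nuc$lacZ <- emb$nuclei$lacZ
  rot <- nuc
  rot$y <- nuc$y * cos(th) - nuc$z * sin(th)
  rot$z <- nuc$y * sin(th) + nuc$z * cos(th)
  m0 <- extract_pattern(embryo(nuc, embryo_id = "a"), "lacZ")
  m1 <- extract_pattern(embryo(rot, embryo_id = "b"), "lacZ")
  perm <- c(16, 1:15)   # strip s moves to strip s+1 (mod 16)
  expect_equal(m1$counts, m0$counts[perm, ])
  expect_equal(m1$values, m0$values[perm, ], tolerance = 1e-9)
})

test_that("group averaging is linear and reduces to a single embryo", {
  cfg <- reporter_config(n_nuclei = 1500, nucleus_noise_sigma = 0,
                         outlier_rate = 0, embryo_scale_sigma = 0)
  e1 <- generate_embryo(cfg, "A", seed = 2)
  g1 <- group_average_trace(list(e1), "lacZ")
  expect_equal(g1$value, embryo_trace(e1, "lacZ")$value)
  expect_equal(g1$sem, rep(0, 100))

  e3 <- e1
  e3$nuclei$lacZ <- e3$nuclei$lacZ * 3
  g <- group_average_trace(list(e1, e3), "lacZ")
  expect_equal(g$value, 2 * embryo_trace(e1, "lacZ")$value, tolerance = 1e-9)

  expect_error(group_average_trace(list(), "lacZ"), "empty")
})

test_that("the SEM of the group trace shrinks like one over root n", {
  cfg <- reporter_config(n_nuclei = 1000, nucleus_noise_sigma = 1,
                         outlier_rate = 0)
  mk <- function(n, seed0) {
    lapply(seq_len(n), function(i) generate_embryo(cfg, "A", seed = seed0 + i))
  }
  g10 <- group_average_trace(mk(10, 400), "lacZ")
  g40 <- group_average_trace(mk(40, 500), "lacZ")
  stripe_bins <- 36:45
  ratio <- mean(g10$sem[stripe_bins]) / mean(g40$sem[stripe_bins])
  expect_gt(ratio, 1.4)   # ideal value 2
  expect_lt(ratio, 2.8)
})
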