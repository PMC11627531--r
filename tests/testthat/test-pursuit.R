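# Smooth-pursuit trajectories, offsets, and series comparisons.

test_that("trajectories are deterministic, bounded and centered", {
  t1 <- make_trajectory(seed = 41)
  t2 <- make_trajectory(seed = 41)
  expect_identical(t1, t2)
  rect <- c(0.2, 0.3, 0.8, 0.7)
  expect_true(all(t1$x >= rect[1] & t1$x <= rect[3]))
  expect_true(all(t1$y >= rect[2] & t1$y <= rect[4]))
  expect_equal(max(t1$time_ms), 45000)

  still <- make_trajectory(speed = 0, seed = 42)
  expect_equal(length(unique(still$x)), 1)
  expect_equal(length(unique(still$y)), 1)

  # waypoints are uniform in the rectangle: long-run mean near the center
  set.seed(43)
  long <- make_trajectory(speed = 5, duration_ms = 300000, seed = 43)
  expect_lt(abs(mean(long$x) - 0.5), 0.03)
  expect_lt(abs(mean(long$y) - 0.5), 0.03)
})

test_that("per-bin coordinate means are exact and order-invariant", {
  s <- data.frame(time_ms = c(10, 60, 120), x = c(0.2, 0.4, 0.9),
                  y = c(0.2, 0.4, 0.1), valid = TRUE)
  bm <- bin_mean_coordinates(s)
  expect_equal(bm$x, c(0.3, 0.9))
  expect_equal(bm$y, c(0.3, 0.1))
  bm2 <- bin_mean_coordinates(s[c(3, 1, 2), ])
  expect_equal(bm, bm2)
  const <- data.frame(time_ms = 0:99, x = 0.42, y = 0.17)
  expect_equal(bin_mean_coordinates(const)$x, 0.42)
})

test_that("the Euclidean offset matches hand arithmetic and symmetry", {
  expect_equal(euclidean_offset(0.5, 0.5, 0.5, 0.5), 0)
  expect_equal(euclidean_offset(0.25, 0.25, 0.5, 0.5), 0.3535534,
               tolerance = 1e-6)
  expect_equal(euclidean_offset(0.1, 0.9, 0.7, 0.2),
               euclidean_offset(0.7, 0.2, 0.1, 0.9))
})

test_that("unbiased Gaussian noise gives the Rayleigh mean offset", {
  set.seed(44)
  n <- 10000
  off <- euclidean_offset(0.5 + rnorm(n, 0, 0.05), 0.5 + rnorm(n, 0, 0.05),
                          0.5, 0.5)
  expected <- 0.05 * sqrt(pi / 2)
  expect_lt(abs(mean(off) - expected) / expected, 0.05)
})

test_that("identical series compare with t = 0 and p = 1", {
  set.seed(45)
  a <- runif(30, 0.1, 0.3)
  r <- compare_offset_series(a, a, paired = FALSE)
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_error(compare_offset_series(a, a, paired = TRUE), "zero variance")
})

test_that("the paired comparison matches the textbook formula", {
  a <- c(0.12, 0.15, 0.11, 0.18, 0.14)
  b <- c(0.20, 0.22, 0.19, 0.25, 0.21)
  r <- compare_offset_series(a, b, paired = TRUE)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
})

test_that("a constant true offset gap is detected with many bins", {
  set.seed(46)
  a <- 0.13 + rnorm(200, 0, 0.02)
  b <- 0.23 + rnorm(200, 0, 0.02)
  r <- compare_offset_series(a, b, paired = TRUE)
  expect_lt(r$p, 0.001)
  expect_lt(r$t, 0)
})

test_that("a noisier channel shows a larger offset at every bin", {
  track <- make_trajectory(seed = 47, duration_ms = 20000)
  clean <- method_model("infrared", fps = 60, spatial_sd = 0.02)
  noisy <- method_model("webgazer", fps = 26, spatial_sd = 0.15)
  g1 <- simulate_pursuit_gaze(track, 12, clean, seed = 48)
  g2 <- simulate_pursuit_gaze(track, 12, noisy, seed = 48)
  s1 <- pursuit_offset_series(g1, track)
  s2 <- pursuit_offset_series(g2, track)
  shared <- intersect(s1$bin, s2$bin)
  expect_true(mean(s2$offset[s2$bin %in% shared] >
                     s1$offset[s1$bin %in% shared]) > 0.95)
  r <- compare_offset_series(s1[s1$bin %in% shared, ],
                             s2[s2$bin %in% shared, ], paired = TRUE)
  expect_lt(r$p, 0.001)
})
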