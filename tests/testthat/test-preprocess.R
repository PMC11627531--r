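# Coordinate normalization, ROI assignment, binning, exclusions, agreement.

test_that("pixel coordinates normalize to screen proportions", {
  r <- normalize_coordinates(c(960, 0, 1920), c(540, 0, 1080), 1920, 1080)
  expect_equal(r$x, c(0.5, 0, 1))
  expect_equal(r$y, c(0.5, 0, 1))
  expect_true(all(r$valid))
  off <- normalize_coordinates(-5, 200, 1920, 1080)
  expect_false(off$valid)
  expect_error(normalize_coordinates(1, 1, 0, 1080), "positive")
})

test_that("ROI assignment partitions the screen", {
  geom <- roi_geometry(0.15, 16 / 9)
  expect_equal(assign_roi(0.5, 0.5, geometry = geom), "center")
  expect_equal(assign_roi(0.2, 0.2, geometry = geom), "top_left")
  expect_equal(assign_roi(0.6, 0.4, geometry = geom), "top_right")
  # hand-evaluated boundary cases at aspect 16:9:
  # half-extents are 0.15/2 = 0.075 (y) and 0.075 * 9/16 = 0.0422 (x)
  expect_equal(assign_roi(0.54, 0.52, geometry = geom), "center")
  # (0.55, 0.5): |dx| = 0.05 > 0.0422 so not center; y = 0.5 sits on the
  # half-open bottom side of the horizontal midline
  expect_equal(assign_roi(0.55, 0.5, geometry = geom), "bottom_right")
  expect_equal(assign_roi(0.55, 0.499, geometry = geom), "top_right")
  expect_equal(assign_roi(0.3, 0.3, valid = FALSE, geometry = geom),
               "off_or_unknown")
  # every valid sample maps to exactly one region
  set.seed(1)
  x <- runif(500); y <- runif(500)
  lab <- assign_roi(x, y, geometry = geom)
  expect_true(all(lab %in% c("center", "top_left", "top_right",
                             "bottom_left", "bottom_right")))
})

test_that("binarization thresholds follow the 30%/50% inclusive rules", {
  mk <- function(n_on_target, n_total, n_left = 0) {
    lab <- c(rep("top_left", n_on_target),
             rep("bottom_left", max(n_left - n_on_target, 0)),
             rep("top_right", n_total - max(n_left, n_on_target)))
    data.frame(subject = 1, trial = 1,
               time_ms = seq(0, 99, length.out = n_total), label = lab)
  }
  b1 <- bin_looks(mk(3, 10), window = c(0, 100))
  expect_equal(b1$look_top_left, 1L)   # 3/10 = 30% -> at least 30% -> 1
  b2 <- bin_looks(mk(2, 10), window = c(0, 100))
  expect_equal(b2$look_top_left, 0L)   # 2/10 below threshold
  b3 <- bin_looks(mk(3, 5, n_left = 3), window = c(0, 100))
  expect_equal(b3$look_left, 1L)       # 3/5 = 60% >= 50%
  b4 <- bin_looks(mk(2, 5, n_left = 2), window = c(0, 100))
  expect_equal(b4$look_left, 0L)       # 2/5 = 40% < 50%
})

test_that("raising the ROI threshold never turns a 0 into a 1", {
  set.seed(2)
  s <- data.frame(subject = rep(1:2, each = 150),
                  trial = rep(rep(1:3, each = 50), 2),
                  time_ms = rep(seq(0, 490, by = 10), 6),
                  x = runif(300), y = runif(300), valid = TRUE)
  lo <- bin_looks(s, window = c(0, 500), roi_threshold = 0.3)
  hi <- bin_looks(s, window = c(0, 500), roi_threshold = 0.5)
  for (col in paste0("look_", c("center", "top_left", "bottom_right"))) {
    expect_true(all(hi[[col]] <= lo[[col]], na.rm = TRUE))
  }
})

test_that("binned indicators are invariant to sampling rate", {
  # two streams with identical per-bin ROI proportions, different fps
  mk <- function(per_bin) {
    t <- as.vector(vapply(0:4, function(b) {
      seq(b * 100, b * 100 + 99, length.out = per_bin)
    }, numeric(per_bin)))
    lab <- rep(c(rep("top_left", per_bin * 0.4),
                 rep("center", per_bin * 0.6)), 5)
    data.frame(subject = 1, trial = 1, time_ms = t, label = lab)
  }
  b10 <- bin_looks(mk(10), window = c(0, 500))
  b40 <- bin_looks(mk(40), window = c(0, 500))
  cols <- grep("^look_", names(b10), value = TRUE)
  expect_equal(b10[cols], b40[cols])
})

test_that("empty bins are missing, not zero", {
  s <- data.frame(subject = 1, trial = 1, time_ms = c(20, 250),
                  label = c("center", "top_left"))
  b <- bin_looks(s, window = c(0, 400))
  b <- b[order(b$bin), ]
  expect_equal(b$missing, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(is.na(b$look_center[b$missing])))
  expect_equal(b$n_samples, c(1L, 0L, 1L, 0L))
})

test_that("off-screen samples dilute ROI proportions under the default denominator", {
  s <- data.frame(subject = 1, trial = 1, time_ms = seq(0, 99, 10),
                  label = c(rep("top_left", 3), rep("off_or_unknown", 7)))
  all_den <- bin_looks(s, window = c(0, 100))
  valid_den <- bin_looks(s, window = c(0, 100), denominator = "valid")
  expect_equal(all_den$look_top_left, 1L)   # 3/10 = 30%
  expect_equal(valid_den$look_top_left, 1L) # 3/3 = 100%
  s2 <- s
  s2$label[1] <- "off_or_unknown"
  expect_equal(bin_looks(s2, window = c(0, 100))$look_top_left, 0L) # 2/10
  expect_equal(bin_looks(s2, window = c(0, 100),
                         denominator = "valid")$look_top_left, 1L)  # 2/2
})

test_that("trial exclusion uses a strict 50% off-screen rule", {
  mk <- function(n_off, trial) {
    data.frame(subject = 1, trial = trial, time_ms = seq_len(100),
               label = c(rep("off_or_unknown", n_off),
                         rep("center", 100 - n_off)))
  }
  frames <- rbind(mk(51, 1), mk(50, 2), mk(0, 3))
  ex <- exclude_trials(frames)
  expect_equal(ex$excluded, c(TRUE, FALSE, FALSE))

  # exclusion propagates to a co-recorded dataset by subject x trial
  other <- data.frame(subject = 1, trial = c(1, 2, 3, 4), x = 0.5)
  kept <- apply_trial_exclusions(other, ex)
  expect_equal(kept$trial, c(2, 3, 4))  # missing trial 4 untouched
})

test_that("fully lost trials are excluded downstream", {
  frames <- data.frame(subject = 1, trial = 1, time_ms = seq_len(40),
                       label = "off_or_unknown")
  ex <- exclude_trials(frames)
  expect_true(ex$excluded)
})

test_that("annotation agreement is exact on constructed streams", {
  a <- rep(c("center", "top_left"), 5)
  expect_equal(annotation_agreement(a, a), 100)
  b <- a; b[10] <- "top_right"
  expect_equal(annotation_agreement(a, b), 90)
  expect_error(annotation_agreement(a, a[-1]), "length")
  # random independent labels over 6 classes agree ~1/6 of the time
  set.seed(3)
  labs <- c("center", "top_left", "top_right", "bottom_left",
            "bottom_right", "off_or_unknown")
  x <- sample(labs, 10000, replace = TRUE)
  y <- sample(labs, 10000, replace = TRUE)
  se <- 100 * sqrt(1 / 6 * 5 / 6 / 10000)
  expect_lt(abs(annotation_agreement(x, y) - 100 / 6), 3 * se)
})

test_that("noise-free rendered channels reproduce the latent binned sequence", {
  des <- task_design("fixation", n_trials = 8)
  eff <- effect_spec(latency_sd_ms = 0, subject_sd_ms = 0, item_sd_ms = 0,
                     explore_prob = 0)
  coords <- method_model("clean_xy", fps = 50)
  labs <- method_model("clean_lab", fps = 50, output_mode = "labels")
  ex <- simulate_experiment(2, 4, des, eff, list(coords, labs), seed = 5)
  bx <- bin_looks(ex$samples, window = c(0, 1500))
  bl <- bin_looks(ex$frames, window = c(0, 1500))
  cols <- grep("^look_", names(bx), value = TRUE)
  key <- function(b) order(b$subject, b$trial, b$bin)
  expect_equal(as.data.frame(bx[key(bx), cols]),
               as.data.frame(bl[key(bl), cols]),
               ignore_attr = TRUE)
  # latency 300 exactly: switch at bin 3 of the aligned window
  b1 <- bx[bx$subject == 1 & bx$trial == 1, ]
  b1 <- b1[order(b1$bin), ]
  expect_equal(b1$look_center[1:3], rep(1L, 3))
  expect_equal(b1[["look_top_left"]][4:15], rep(1L, 12))
})
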