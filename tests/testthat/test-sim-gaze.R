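# Synthetic multi-method gaze generator: timelines, channels, determinism.

noise_free <- function() {
  effect_spec(latency_sd_ms = 0, subject_sd_ms = 0, item_sd_ms = 0,
              explore_prob = 0)
}

test_that("noise-free timelines switch exactly at the base latency", {
  des <- task_design("fixation")
  tl <- sample_timeline(des, noise_free(), condition = "target",
                        target_roi = "top_left")
  expect_equal(tl$start_ms, c(0, 750 + 300))
  expect_equal(tl$roi, c("center", "top_left"))
  expect_equal(tl$end_ms[2], des$trial_duration_ms)
  expect_equal(attr(tl, "latency_ms"), 300)
})

test_that("a forced competitor glance lands inside the effect window", {
  des <- task_design("phonemic_cohort")
  eff <- effect_spec(latency_sd_ms = 0, subject_sd_ms = 0, item_sd_ms = 0,
                     explore_prob = 0,
                     competitor_prob = c(cohort = 1, control = 0),
                     competitor_window_ms = c(400, 900))
  set.seed(1)
  for (i in 1:20) {
    tl <- sample_timeline(des, eff, condition = "cohort",
                          target_roi = "top_left",
                          competitor_roi = "bottom_right")
    comp <- tl[tl$roi == "bottom_right", ]
    expect_equal(nrow(comp), 1)
    expect_gte(comp$start_ms, 750 + 400)
    expect_lte(comp$end_ms, 750 + 900)
    # intervals still partition the trial
    expect_equal(tl$start_ms[-1], tl$end_ms[-nrow(tl)])
    expect_equal(tl$start_ms[1], 0)
    expect_equal(tl$end_ms[nrow(tl)], des$trial_duration_ms)
  }
  # control trials never glance
  tlc <- sample_timeline(des, eff, condition = "control",
                         target_roi = "top_left",
                         competitor_roi = "bottom_right")
  expect_false("bottom_right" %in% tlc$roi)
})

test_that("effect windows outside the trial are rejected", {
  des <- task_design("phonemic_cohort")
  eff <- effect_spec(competitor_prob = c(cohort = 1, control = 0),
                     competitor_window_ms = c(1400, 2000))
  set.seed(2)
  expect_error(sample_timeline(des, eff, condition = "cohort",
                               target_roi = "top_left",
                               competitor_roi = "top_right"),
               "outside the trial")
})

test_that("sampled latencies follow the stated truncated-Gaussian model", {
  des <- task_design("fixation")
  eff <- effect_spec(base_latency_ms = 300, latency_sd_ms = 50,
                     subject_sd_ms = 0, item_sd_ms = 0, explore_prob = 0)
  set.seed(3)
  lat <- replicate(10000, attr(sample_timeline(des, eff,
                                               condition = "target",
                                               target_roi = "top_left"),
                               "latency_ms"))
  # truncation at 80 ms is > 4 SD away: the mean stays at base
  expect_lt(abs(mean(lat) - 300), 3 * 50 / sqrt(10000))
  expect_lt(abs(sd(lat) - 50), 2)
  expect_gte(min(lat), 80)
})

test_that("noise-free coordinate rendering sits on the active centroid", {
  des <- task_design("fixation")
  tl <- sample_timeline(des, noise_free(), condition = "target",
                        target_roi = "bottom_right")
  r <- render_coordinates(tl, method_model("clean", fps = 40))
  expect_equal(r$time_ms, seq(0, 2225, by = 25))
  pre <- r[r$time_ms < 1050, ]
  post <- r[r$time_ms >= 1050, ]
  expect_true(all(pre$x == 0.5 & pre$y == 0.5))
  expect_true(all(post$x == 0.75 & post$y == 0.75))
  expect_true(all(r$valid))
})

test_that("channel latency delays the rendered switch by exactly the lag", {
  des <- task_design("fixation")
  tl <- sample_timeline(des, noise_free(), condition = "target",
                        target_roi = "top_right")
  lagged <- render_coordinates(tl, method_model("lag", fps = 100,
                                                latency_ms = 300))
  onset <- min(lagged$time_ms[lagged$x == 0.75])
  expect_equal(onset, 1050 + 300)
})

test_that("spatial noise reproduces the Rayleigh mean offset", {
  des <- task_design("fixation", n_trials = 1, trial_duration_ms = 100000,
                     align_zero_ms = 50)
  tl <- tibble::tibble(start_ms = 0, end_ms = 100000, roi = "center")
  set.seed(4)
  r <- render_coordinates(tl, method_model("noisy", fps = 100,
                                           spatial_sd = 0.05))
  off <- euclidean_offset(r$x, r$y, 0.5, 0.5)
  expect_equal(length(off), 10000)
  expect_lt(abs(mean(off) - 0.05 * sqrt(pi / 2)) / (0.05 * sqrt(pi / 2)),
            0.05)
})

test_that("label rendering honors error and loss rates", {
  des <- task_design("fixation", trial_duration_ms = 100000,
                     align_zero_ms = 50)
  tl <- tibble::tibble(start_ms = 0, end_ms = 100000, roi = "top_left")
  clean <- render_labels(tl, method_model("m", fps = 25,
                                          output_mode = "labels"))
  expect_true(all(clean$label == "top_left"))

  set.seed(5)
  noisy <- render_labels(tl, method_model("m", fps = 100,
                                          output_mode = "labels",
                                          label_error_rate = 0.1))
  err_frac <- mean(noisy$label != "top_left")
  expect_lt(abs(err_frac - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(noisy)))
  expect_false("off_or_unknown" %in% noisy$label)

  lost <- render_labels(tl, method_model("m", fps = 25,
                                         output_mode = "labels",
                                         trackloss_rate = 1))
  expect_true(all(lost$label == "off_or_unknown"))
})

test_that("experiments are byte-identical under the same seed", {
  des <- task_design("phonemic_cohort", n_trials = 8)
  eff <- effect_spec(competitor_prob = c(cohort = 0.5, control = 0.2))
  mth <- list(method_model("xy", fps = 30, spatial_sd = 0.05,
                           trackloss_rate = 0.1),
              method_model("lab", fps = 25, output_mode = "labels",
                           label_error_rate = 0.05))
  e1 <- simulate_experiment(4, 4, des, eff, mth, seed = 99)
  e2 <- simulate_experiment(4, 4, des, eff, mth, seed = 99)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$frames, e2$frames)
  expect_identical(e1$truth, e2$truth)
  e3 <- simulate_experiment(4, 4, des, eff, mth, seed = 100)
  expect_false(identical(e1$samples, e3$samples))
})

test_that("trial loss drops whole trials at the configured rate", {
  des <- task_design("fixation", n_trials = 50, trial_duration_ms = 300,
                     align_zero_ms = 100)
  eff <- noise_free()
  mth <- list(method_model("lossy", fps = 10, trial_loss_rate = 0.5))
  e <- simulate_experiment(20, 4, des, eff, mth, seed = 6)
  n_rendered <- nrow(unique(e$samples[c("subject", "trial")]))
  frac <- 1 - n_rendered / 1000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("all channels share one latent behavior", {
  des <- task_design("fixation", n_trials = 6)
  mth <- list(method_model("a", fps = 20), method_model("b", fps = 20))
  e <- simulate_experiment(3, 3, des, noise_free(), mth, seed = 7)
  a <- e$samples[e$samples$method == "a", c("subject", "trial", "time_ms", "x", "y")]
  b <- e$samples[e$samples$method == "b", c("subject", "trial", "time_ms", "x", "y")]
  # identical parameters and no channel noise: identical renderings
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("cohort excess stays confined to the configured window", {
  des <- task_design("phonemic_cohort")
  eff <- effect_spec(competitor_prob = c(cohort = 0.45, control = 0.15),
                     competitor_window_ms = c(400, 900),
                     explore_prob = 0.3)
  mth <- list(method_model("xy", fps = 40))
  e <- simulate_experiment(24, 12, des, eff, mth, seed = 8)
  b <- bin_looks(e$samples, window = c(0, 1500))
  b <- derive_look_responses(b, e$design)
  rate <- function(cond, bins) {
    x <- b$look_competitor[b$condition == cond & b$bin %in% bins]
    mean(x, na.rm = TRUE)
  }
  n_per_cell <- sum(b$condition == "cohort" & b$bin == 0)
  mc_se <- sqrt(0.25 / n_per_cell)
  in_bins <- 5:7    # bins fully inside the 400-900 ms window
  out_bins <- c(0:2, 11:14)
  expect_gt(rate("cohort", in_bins) - rate("control", in_bins), 6 * mc_se)
  expect_lt(abs(rate("cohort", out_bins) - rate("control", out_bins)),
            2 * mc_se)
})
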