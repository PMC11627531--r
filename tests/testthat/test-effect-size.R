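# Analysis-, cluster- and maximum-window effect sizes in both metrics.

fake_test <- function(start, end, sign = 1L, significant = TRUE) {
  structure(list(clusters = tibble::tibble(
    start_bin = start, end_bin = end, sign = sign, z_sum = 10,
    p = 0.001, p_label = "0.001", significant = significant,
    start_ms = start * 100, end_ms = (end + 1) * 100 - 1)),
    class = "cluster_perm_test")
}

test_that("the cluster window is the overlap of the axis clusters", {
  b <- tibble::tibble(subject = 1, trial = 1, bin = 0:14,
                      look_target = 1L)
  es <- proportion_effect_sizes(b, fake_test(1, 14), fake_test(3, 14))
  expect_equal(es$cluster_bins, 3:14)
  expect_equal(es$cluster, 1.0)
  expect_equal(es$maximum, 1.0)

  # disjoint clusters: no overlap, cluster and maximum absent
  es2 <- proportion_effect_sizes(b, fake_test(0, 3), fake_test(8, 14))
  expect_true(is.na(es2$cluster) && is.na(es2$maximum))
  expect_false(is.na(es2$analysis))

  # negative-sign clusters do not define a positive-effect window
  es3 <- proportion_effect_sizes(b, fake_test(1, 14, sign = -1L),
                                 fake_test(1, 14))
  expect_true(is.na(es3$cluster))
})

test_that("proportion effect sizes equal the generating means", {
  # known per-bin look probabilities: low before bin 5, high after
  set.seed(31)
  n_trials <- 400
  d <- expand.grid(trial = seq_len(n_trials), bin = 0:9)
  p <- ifelse(d$bin >= 5, 0.9, 0.1)
  d$subject <- (d$trial - 1) %/% 20 + 1
  d$look_target <- rbinom(nrow(d), 1, p)
  b <- tibble::as_tibble(d)
  es <- proportion_effect_sizes(b, fake_test(5, 9), fake_test(5, 9))
  mc_se <- sqrt(0.25 / (n_trials * 5))
  expect_lt(abs(es$analysis - 0.5), 3 * mc_se)
  expect_lt(abs(es$cluster - 0.9), 3 * sqrt(0.09 / (n_trials * 5)))
  expect_gte(es$maximum, es$cluster)
  expect_lte(es$analysis, es$cluster)
})

test_that("a null condition difference gives d near zero", {
  d <- simulate_binned_experiment(32, 16, 10, base_logit = 0,
                                  condition_beta = 0, subject_sd = 0.3,
                                  seed = 32)
  spec <- bin_model_spec("look_competitor", fixed = "condition")
  dd <- window_cohens_d(d, 0:9, spec, mode = "analysis")
  expect_true(dd$converged)
  expect_lt(abs(dd$d), 0.05)  # 5120 observations
})

test_that("maximum mode selects the generator's peak bin", {
  hits <- 0
  for (i in 1:20) {
    d <- simulate_binned_experiment(16, 12, 8, base_logit = qlogis(0.2),
                                    condition_beta = 0.9,
                                    effect_bins = 4, subject_sd = 0.4,
                                    seed = 300 + i)
    spec <- bin_model_spec("look_competitor", fixed = "condition")
    dd <- window_cohens_d(d, 0:7, spec, mode = "maximum")
    if (!is.na(dd$bin) && dd$bin == 4) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of runs
})

test_that("window d uses the documented t-to-d conversion", {
  d <- simulate_binned_experiment(12, 8, 6, condition_beta = 0.5,
                                  effect_bins = 0:5, subject_sd = 0.3,
                                  seed = 33)
  spec <- bin_model_spec("look_competitor", fixed = "condition")
  dd <- window_cohens_d(d, 0:5, spec, mode = "analysis")
  expect_equal(dd$d, 2 * dd$z / sqrt(dd$n_obs - 2), tolerance = 1e-10)
  expect_equal(dd$df, dd$n_obs - 2L)
})

test_that("cluster-window d stays below maximum d on effect data", {
  wins <- 0
  for (i in 1:20) {
    d <- simulate_binned_experiment(16, 12, 10, base_logit = qlogis(0.2),
                                    condition_beta = 0.7,
                                    effect_bins = 3:6, subject_sd = 0.4,
                                    seed = 400 + i)
    spec <- bin_model_spec("look_competitor", fixed = "condition")
    dc <- window_cohens_d(d, 3:6, spec, mode = "cluster")
    dm <- window_cohens_d(d, 3:6, spec, mode = "maximum")
    if (dc$converged && dm$converged && abs(dc$d) <= abs(dm$d))
      wins <- wins + 1
  }
  expect_gte(wins, 18)
})
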