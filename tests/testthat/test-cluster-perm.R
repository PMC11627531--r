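# Cluster formation, label shuffling schemes, permutation p-values.

test_that("clusters are maximal same-sign supra-threshold runs", {
  cl <- find_clusters(c(0.5, 2.5, 3.0, 1.9, -2.2))
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start_bin, c(1, 4))
  expect_equal(cl$end_bin, c(2, 4))
  expect_equal(cl$sign, c(1L, -1L))
  expect_equal(cl$z_sum, c(5.5, 2.2))

  expect_equal(nrow(find_clusters(c(1.9, -2, 0, 2))), 0)

  # sign changes split otherwise-adjacent supra-threshold bins
  cl3 <- find_clusters(c(2.1, -2.1, 2.1))
  expect_equal(nrow(cl3), 3)
  expect_true(all(cl3$start_bin == cl3$end_bin))

  # exactly |z| == threshold does not cross the strict threshold
  expect_equal(nrow(find_clusters(c(2, 2, 2))), 0)
})

test_that("condition shuffling preserves per-subject label counts", {
  b <- make_toy_binned(seed = 21)
  set.seed(1)
  for (i in 1:10) {
    p <- permute_labels(b, "condition_within_subject")
    for (s in unique(b$subject)) {
      tab0 <- table(b$condition[b$subject == s & b$bin == 0])
      tab1 <- table(p$condition[p$subject == s & p$bin == 0])
      expect_equal(tab0, tab1)
    }
    # responses untouched
    expect_identical(p$look_competitor, b$look_competitor)
  }
})

test_that("target-side shuffling re-derives looks against the new side", {
  b <- make_toy_binned(seed = 22)
  # trial with 100% left looks: if the new side is right, indicator flips
  b$look_left <- 1L
  b$look_right <- 0L
  b$look_target_hside <- 1L   # observed target side: left
  set.seed(2)
  p <- permute_labels(b, "target_side", axis = "horizontal")
  right <- p$target_hside == "right"
  expect_true(any(right))
  expect_true(all(p$look_target_hside[right] == 0L))
  expect_true(all(p$look_target_hside[!right] == 1L))
})

test_that("experiment shuffling moves whole subjects between experiments", {
  b <- make_toy_binned(seed = 23)
  b$experiment <- ifelse(b$subject == 1, "lab", "web")
  set.seed(3)
  p <- permute_labels(b, "experiment_between_subjects")
  per_subj <- tapply(p$experiment, p$subject, function(x) length(unique(x)))
  expect_true(all(per_subj == 1))
  expect_equal(sort(table(p$experiment[!duplicated(p$subject)])),
               sort(table(b$experiment[!duplicated(b$subject)])))
})

test_that("method shuffling relabels co-recorded datasets within subject", {
  b0 <- make_toy_binned(seed = 24)
  b1 <- b0; b1$method <- "infrared"
  b2 <- b0; b2$method <- "webgazer"; b2$look_competitor <- 1L - b2$look_competitor
  b <- rbind(b1, b2)
  set.seed(4)
  p <- permute_labels(b, "method_within_subject")
  # each subject still has both labels, each covering a full dataset
  for (s in unique(p$subject)) {
    expect_equal(sort(unique(p$method[p$subject == s])),
                 c("infrared", "webgazer"))
  }
  expect_equal(sort(p$look_competitor), sort(b$look_competitor))
})

test_that("permutation p-values count larger-or-equal null statistics", {
  b <- make_toy_binned(seed = 25)
  spec <- bin_model_spec("look_competitor", fixed = "condition")
  ct <- cluster_permutation_test(b, spec, "condition_within_subject",
                                 n_perm = 4, threshold = 1, seed = 5)
  if (nrow(ct$clusters)) {
    for (i in seq_len(nrow(ct$clusters))) {
      expect_equal(ct$clusters$p[i],
                   mean(ct$null_stats >= ct$clusters$z_sum[i] - 0.01))
    }
  }
  expect_true(all(ct$clusters$p >= 0 & ct$clusters$p <= 1))
  # monotone: a larger observed z-sum never gets a larger p
  ord <- order(ct$clusters$z_sum)
  expect_true(all(diff(ct$clusters$p[ord]) <= 0))
})

test_that("zero counts are reported as p below resolution", {
  b <- make_toy_binned(seed = 26)
  spec <- bin_model_spec("look_competitor", fixed = "condition")
  ct <- cluster_permutation_test(b, spec, "condition_within_subject",
                                 n_perm = 50, threshold = 1, seed = 6)
  zero <- ct$clusters$p == 0
  expect_true(all(grepl("^< ", ct$clusters$p_label[zero])))
})

test_that("cluster ms spans follow the bin labeling convention", {
  # bins 1-3 at 100 ms from a 0-start window span 100-399 ms
  b <- make_toy_binned(seed = 27)
  spec <- bin_model_spec("look_competitor", fixed = "condition")
  ct <- cluster_permutation_test(b, spec, "condition_within_subject",
                                 n_perm = 2, threshold = 0.5, seed = 7,
                                 bin_ms = 100, window_start_ms = 0)
  expect_gt(nrow(ct$clusters), 0)
  for (i in seq_len(nrow(ct$clusters))) {
    expect_equal(ct$clusters$start_ms[i], ct$clusters$start_bin[i] * 100)
    expect_equal(ct$clusters$end_ms[i],
                 (ct$clusters$end_bin[i] + 1) * 100 - 1)
  }
})

test_that("permutation results are reproducible from the seed", {
  b <- make_toy_binned(seed = 28)
  spec <- bin_model_spec("look_competitor", fixed = "condition")
  a <- cluster_permutation_test(b, spec, "condition_within_subject",
                                n_perm = 20, threshold = 1, seed = 11)
  b2 <- cluster_permutation_test(b, spec, "condition_within_subject",
                                 n_perm = 20, threshold = 1, seed = 11)
  expect_equal(a$null_stats, b2$null_stats)
  expect_equal(a$clusters, b2$clusters)
})

test_that("the internal fast permutation path matches the public shuffler", {
  # permuting labels on the data frame (public path) and updating the prep
  # structure in place (permutation-loop path) must give the same per-bin
  # z series for the same drawn assignment
  b <- make_toy_binned(seed = 29)
  spec <- bin_model_spec("look_competitor", fixed = "condition")
  bins <- sort(unique(b$bin))
  prep <- gazeperm:::.scan_prep(b, spec, bins)
  pp <- gazeperm:::.perm_prep(b, spec, "condition_within_subject",
                              "horizontal", prep)
  for (i in 1:5) {
    set.seed(gazeperm:::.sub_seed(12, i))
    drawn <- gazeperm:::.perm_draw(pp)
    z_fast <- gazeperm:::.scan_z(pp$update(prep, drawn))
    set.seed(gazeperm:::.sub_seed(12, i))
    pb <- permute_labels(b, "condition_within_subject")
    z_public <- scan_window(pb, spec)$z
    expect_equal(z_fast, z_public, tolerance = 0.01)
  }
})
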