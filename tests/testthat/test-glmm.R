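# Per-bin binomial mixed models: oracle equivalence, recovery, fallbacks.

test_that("pooled fits match ordinary logistic regression when variance collapses", {
  # every subject and every item at exactly 60% success: the ML variance
  # components are zero and the fit must collapse to the pooled logit
  d <- expand.grid(subject = 1:10, item = 1:10)
  d$y <- as.integer((d$subject + d$item) %% 10 < 6)
  fit <- fit_bin_model(d, bin_model_spec("y"))
  ref <- glm(y ~ 1, data = d, family = binomial)
  expect_true(fit$converged)
  expect_true(fit$singular)  # variance components at zero
  expect_equal(fit$estimate, log(0.6 / 0.4), tolerance = 1e-6)
  expect_lt(abs(fit$estimate - unname(coef(ref))), 1e-4)
  expect_lt(abs(fit$se - sqrt(vcov(ref)[1, 1])), 1e-4)

  # with a condition effect and no real random variation
  d2 <- make_logit_data(12, 10, beta0 = 0.2, beta_cond = 0.7, seed = 2)
  spec <- bin_model_spec("y", fixed = "condition")
  fit2 <- fit_bin_model(d2, spec)
  d2$code <- ifelse(d2$condition == "cohort", 1, -1)
  ref2 <- glm(y ~ code, data = d2, family = binomial)
  expect_lt(abs(fit2$estimate - unname(coef(ref2)[2])), 1e-4)
})

test_that("fast Laplace fitter agrees with glmer and the exact fitter", {
  d <- make_logit_data(24, 12, beta0 = 0.3, beta_cond = 0.8,
                       subject_sd = 1, item_sd = 0.5, seed = 3)
  spec <- bin_model_spec("y", fixed = "condition")
  fast <- fit_bin_model(d, spec, engine = "fast")
  ref <- fit_bin_model(d, spec, engine = "glmer")
  expect_true(fast$converged && ref$converged)
  # different Laplace profiling strategies: close, not identical
  expect_lt(abs(fast$estimate - ref$estimate), 0.08)
  expect_lt(abs(fast$z - ref$z), 0.3)
  expect_lt(max(abs(fast$sigma - ref$sigma)), 0.1)

  # single-random-factor case against the exact marginal likelihood
  d1 <- make_logit_data(16, 8, beta0 = 0.2, beta_cond = 0.6,
                        subject_sd = 0.8, seed = 4)
  spec1 <- bin_model_spec("y", fixed = "condition", random = "(1|subject)")
  fast1 <- fit_bin_model(d1, spec1)
  exact1 <- fit_bin_exact(d1, spec1)
  expect_lt(abs(fast1$estimate - exact1$estimate), 0.05)
  expect_lt(abs(fast1$z - exact1$z), 0.25)
})

test_that("condition effects are recovered within 3 SE at realistic sizes", {
  d <- make_logit_data(40, 12, beta0 = -0.5, beta_cond = 0.8,
                       subject_sd = 1, item_sd = 0.3, seed = 5)
  fit <- fit_bin_model(d, bin_model_spec("y", fixed = "condition"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate - 0.8), 3 * fit$se)
})

test_that("z is sign-symmetric under relabeling of sum-coded levels", {
  d <- make_logit_data(16, 8, beta_cond = 0.6, subject_sd = 0.5, seed = 6)
  spec <- bin_model_spec("y", fixed = "condition")
  f1 <- fit_bin_model(d, spec)
  d2 <- d
  d2$condition <- ifelse(d$condition == "cohort", "zcontrol", "acohort")
  f2 <- fit_bin_model(d2, spec)
  expect_equal(abs(f1$z), abs(f2$z), tolerance = 1e-6)
  expect_equal(f1$z, -f2$z, tolerance = 1e-6)
})

test_that("degenerate responses are flagged, not fitted", {
  d <- make_logit_data(6, 6, seed = 7)
  d$y <- 1
  fit <- fit_bin_model(d, bin_model_spec("y", fixed = "condition"))
  expect_false(fit$converged)
  expect_equal(fit$reason, "no_variation")

  d2 <- make_logit_data(6, 6, seed = 8)
  d2$y[d2$condition == "cohort"] <- 1  # one cell constant
  fit2 <- fit_bin_model(d2, bin_model_spec("y", fixed = "condition"))
  expect_false(fit2$converged)
  expect_equal(fit2$reason, "cell_no_variation")
})

test_that("scan_window applies carry-forward and zero-at-first-bin rules", {
  set.seed(9)
  d <- make_logit_data(8, 8, beta0 = 0.4, subject_sd = 0.3, seed = 9)
  full <- d[rep(seq_len(nrow(d)), each = 4), ]
  full$bin <- rep(0:3, times = nrow(d))
  set.seed(10)
  full$y <- rbinom(nrow(full), 1, 0.65)
  full$y[full$bin == 2] <- 1          # bin 2: separation -> carried
  full$y[full$bin == 0] <- 0          # bin 0: no variation -> zero rule
  sc <- scan_window(full, bin_model_spec("y"))
  expect_equal(sc$z[1], 0)            # first-bin failure reports zero
  expect_true(sc$carried[1])
  expect_true(sc$carried[3])
  expect_equal(sc$z[3], sc$z[2])      # inherits previous bin's z
  expect_false(sc$carried[2])
  expect_false(sc$carried[4])
})

test_that("carried bins cannot create excursions absent in their source", {
  # if the source bin is sub-threshold, the carried bin must be too
  set.seed(12)
  for (s in 1:5) {
    d <- make_logit_data(8, 8, seed = 20 + s)
    full <- d[rep(seq_len(nrow(d)), each = 3), ]
    full$bin <- rep(0:2, times = nrow(d))
    set.seed(30 + s)
    full$y <- rbinom(nrow(full), 1, 0.55)
    full$y[full$bin == 2] <- 0  # always carried
    sc <- scan_window(full, bin_model_spec("y"))
    expect_equal(abs(sc$z[3]) > 2, abs(sc$z[2]) > 2)
  }
})
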