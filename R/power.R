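#' Locate the 3-bin peak-effect window
#'
#' Takes the time bin with the largest per-bin effect size together with
#' the previous and the subsequent bins.  When the largest effect sits at
#' a boundary, the window is the three bins nearest that boundary; ties go
#' to the earliest bin.
#'
#' @param d Per-bin effect-size series (e.g. per-bin Cohen's d).
#' @param bins Bin indices aligned with `d` (default `seq_along(d) - 1`).
#' @return Integer vector of 3 consecutive bins.
#' @examples
#' find_peak_window(c(0.1, 0.3, 0.5, 0.2))  # bins 1-3
#' @export
find_peak_window <- function(d, bins = NULL) {
  .assert(length(d) >= 3, "need at least 3 bins")
  if (is.null(bins)) bins <- seq_along(d) - 1L
  i <- which.max(d)  # earliest argmax on ties
  i <- min(max(i, 2L), length(d) - 1L)
  bins[(i - 1L):(i + 1L)]
}

#' Per-bin Cohen's d series
#'
#' Computes the standardized condition effect in each bin by scanning the
#' window with the task's per-bin model and converting each bin's z to
#' Cohen's d via `d = 2 z / sqrt(n_obs - n_fixed)` (carry-forward bins
#' inherit the previous bin's z, matching the cluster-analysis fallback).
#'
#' @param data Binned look data.
#' @param spec The task's [bin_model_spec()].
#' @param bins Bins to scan (default: all).
#' @return A tibble `bin`, `z`, `d`, `n_obs`, `carried`.
#' @export
per_bin_d <- function(data, spec, bins = NULL) {
  sc <- scan_window(data, spec, bins = bins)
  n_fixed <- 1L + length(spec$fixed)
  sc$d <- 2 * sc$z / sqrt(pmax(sc$n_obs - n_fixed, 1))
  sc[, c("bin", "z", "d", "n_obs", "carried")]
}

#' Collapse a window to one binary response per trial
#'
#' Computes, per trial, the proportion of non-missing window bins with a
#' competitor (or other relevant) look, and binarizes it at the threshold
#' (default 30%): the trial is coded 1 when at least 30% of its window
#' shows the look, reflecting the dominant looking behavior in the window.
#' Trials with no non-missing bin in the window are dropped and counted.
#' `proportion_of = "samples"` weights bins by their recorded sample
#' counts instead (a sample-level reading of "recorded looks").
#'
#' @param binned Binned look data.
#' @param window_bins Bins of the (typically 3-bin peak) window.
#' @param response Indicator column (default `"look_competitor"`).
#' @param threshold Binarization threshold (inclusive, default 0.30).
#' @param proportion_of `"bins"` (default) or `"samples"`.
#' @return A tibble with one row per trial (`subject`, `item`, `trial`,
#'   `condition`, `prop`, `response`), attribute `"n_dropped"`.
#' @export
collapse_and_binarize <- function(binned, window_bins,
                                  response = "look_competitor",
                                  threshold = 0.30,
                                  proportion_of = c("bins", "samples")) {
  proportion_of <- match.arg(proportion_of)
  .assert(response %in% names(binned), "column '%s' not found", response)
  d <- binned[binned$bin %in% window_bins, , drop = FALSE]
  key <- paste(d$subject, d$trial, sep = "\r")
  y <- d[[response]]
  w <- if (proportion_of == "bins") rep(1, nrow(d)) else d$n_samples
  ok <- !is.na(y)
  num <- tapply(ifelse(ok, y * w, 0), key, sum)
  den <- tapply(ifelse(ok, w, 0), key, sum)
  uk <- !duplicated(key)
  ord <- match(key[uk], names(num))
  out <- tibble(subject = d$subject[uk], item = d$item[uk],
                trial = d$trial[uk], condition = d$condition[uk],
                prop = as.numeric(num[ord] / den[ord]))
  dropped <- sum(is.na(out$prop) | den[ord] == 0)
  out <- out[!is.na(out$prop), , drop = FALSE]
  out$response <- as.integer(out$prop >= threshold)
  attr(out, "n_dropped") <- dropped
  out
}

#' Fit the observed-effect model for power analysis
#'
#' Fits the trial-level binomial-logit model of the binarized window
#' responses with a sum-coded condition fixed effect and a maximal
#' random-effects structure: by-subject and by-item random intercepts and
#' condition slopes.  On non-convergence the structure is simplified
#' stepwise - slope correlations dropped first, then the slopes - and
#' each step is recorded.
#'
#' @param trials Output of [collapse_and_binarize()] (columns `subject`,
#'   `item`, `condition`, `response`).
#' @param response Response column name.
#' @return An object of class `observed_effect_model`: `beta` (intercept
#'   and condition effect), `se`, `z`, `p`, `varcomp` (SDs:
#'   `subject`, `subject_slope`, `item`, `item_slope`), `formula`,
#'   `simplification`, `n_subjects`, `n_items`, `n_obs`.
#' @export
fit_observed_effect_model <- function(trials, response = "response") {
  .assert(all(c("subject", "item", "condition") %in% names(trials)),
          "`trials` needs subject, item and condition columns")
  .assert(length(unique(trials$subject)) >= 2 &&
            length(unique(trials$item)) >= 2,
          "need at least 2 subjects and 2 items")
  .assert(length(unique(trials[[response]])) >= 2,
          "response shows no variation (separation)")
  df <- as.data.frame(trials)
  df$.y <- as.numeric(df[[response]])
  df$.c <- .sum_code(df$condition)[, 1]
  ladder <- c(
    ".y ~ .c + (1 + .c | subject) + (1 + .c | item)",
    ".y ~ .c + (1 + .c || subject) + (1 + .c || item)",
    ".y ~ .c + (1 | subject) + (1 | item)")
  steps <- c("maximal", "no_correlations", "intercepts_only")
  fit <- NULL; used <- NA_character_
  for (i in seq_along(ladder)) {
    f <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(stats::as.formula(ladder[i]), data = df,
                    family = binomial))),
      error = function(e) NULL)
    if (!is.null(f)) {
      conv <- length(f@optinfo$conv$lme4$messages) == 0
      if (conv || i == length(ladder)) { fit <- f; used <- steps[i]; break }
    }
  }
  .assert(!is.null(fit), "observed-effect model failed at every ladder step")
  co <- summary(fit)$coefficients
  vc <- lme4::VarCorr(fit)
  getsd <- function(grp, term) {
    m <- vc[[grp]]
    if (is.null(m)) {
      # uncorrelated fits name components like "subject" and "subject.1"
      for (nm in names(vc)[startsWith(names(vc), grp)]) {
        if (term %in% rownames(vc[[nm]])) return(sqrt(vc[[nm]][term, term]))
      }
      return(0)
    }
    if (term %in% rownames(m)) sqrt(m[term, term]) else 0
  }
  varcomp <- c(subject = getsd("subject", "(Intercept)"),
               subject_slope = getsd("subject", ".c"),
               item = getsd("item", "(Intercept)"),
               item_slope = getsd("item", ".c"))
  z <- co[".c", "z value"]
  structure(list(
    beta = c(intercept = unname(co["(Intercept)", "Estimate"]),
             condition = unname(co[".c", "Estimate"])),
    se = c(intercept = unname(co["(Intercept)", "Std. Error"]),
           condition = unname(co[".c", "Std. Error"])),
    z = unname(z), p = 2 * stats::pnorm(-abs(z)),
    varcomp = varcomp, formula = ladder[match(used, steps)],
    simplification = used,
    n_subjects = length(unique(df$subject)),
    n_items = length(unique(df$item)),
    n_obs = nrow(df), fit = fit),
    class = "observed_effect_model")
}

#' @export
print.observed_effect_model <- function(x, ...) {
  cat(sprintf(
    "<observed_effect_model> beta = %.3f (SE %.3f), |z| = %.2f, p = %.4g\n",
    x$beta["condition"], x$se["condition"], abs(x$z), x$p))
  cat(sprintf("  structure: %s; SDs: subj %.2f, subj-slope %.2f, item %.2f, item-slope %.2f\n",
              x$simplification, x$varcomp["subject"],
              x$varcomp["subject_slope"], x$varcomp["item"],
              x$varcomp["item_slope"]))
  invisible(x)
}

#' Simulation-based power across sample sizes
#'
#' Estimates, for each candidate number of subjects, the probability of
#' detecting the observed condition effect: datasets are simulated from
#' the fitted observed-effect model (fixed effects as fitted; fresh
#' subject and item random effects drawn from the fitted variance
#' components; the item set kept at its original size), refitted, and the
#' effect is counted as detected when the refit's focal `|z|` exceeds the
#' threshold.  Power at a given n is the fraction of detections among
#' `n_sim` simulations; refit failures are counted and reported, not
#' silently dropped.
#'
#' @param model An [fit_observed_effect_model()] result.
#' @param n_grid Subject sample sizes (default 20, 30, 40, 50, 60).
#' @param n_sim Simulated datasets per sample size (default 1000).
#' @param z_threshold Detection threshold on `|z|` (default 2).
#' @param seed Integer seed; curves are reproducible from it.
#' @param beta Optional override of the condition effect (e.g. 0 for a
#'   null calibration of the procedure).
#' @return A tibble of class `power_curve`: `n`, `power`, `mc_se`,
#'   `n_sim`, `n_failed`, `z_threshold`.
#' @export
simulate_power <- function(model, n_grid = c(20, 30, 40, 50, 60),
                           n_sim = 1000, z_threshold = 2, seed = 1,
                           beta = NULL) {
  .assert(inherits(model, "observed_effect_model"),
          "`model` must be an observed_effect_model")
  b0 <- model$beta[["intercept"]]
  b1 <- if (is.null(beta)) model$beta[["condition"]] else beta
  vc <- model$varcomp
  ni <- model$n_items
  # refit with the same random-effects structure the observed model kept
  with_slopes <- vc["subject_slope"] > 1e-6 || vc["item_slope"] > 1e-6
  spec <- if (with_slopes) {
    bin_model_spec("response", fixed = "condition",
                   random = c("(1+condition|subject)",
                              "(1+condition|item)"))
  } else {
    bin_model_spec("response", fixed = "condition",
                   random = c("(1|subject)", "(1|item)"))
  }
  n_grid <- sort(n_grid)
  out <- tibble(n = n_grid, power = NA_real_, mc_se = NA_real_,
                n_sim = n_sim, n_failed = 0L, z_threshold = z_threshold)
  sigma_init <- if (with_slopes) pmax(unname(vc), 0.1)
                else pmax(unname(vc[c("subject", "item")]), 0.1)
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    hits <- 0L; fails <- 0L
    for (s in seq_len(n_sim)) {
      set.seed(.sub_seed(seed, gi * 1000000 + s))
      us <- rnorm(n, 0, vc["subject"])
      uss <- rnorm(n, 0, vc["subject_slope"])
      ui <- rnorm(ni, 0, vc["item"])
      uis <- rnorm(ni, 0, vc["item_slope"])
      d <- expand.grid(item = seq_len(ni), subject = seq_len(n))
      code <- ifelse((d$subject + d$item) %% 2 == 0, 1, -1)
      d$condition <- ifelse(code > 0, "cohort", "control")
      eta <- b0 + b1 * code + us[d$subject] + ui[d$item] +
        code * (uss[d$subject] + uis[d$item])
      d$response <- rbinom(nrow(d), 1, plogis(eta))
      fit <- fit_bin_model(d, spec, engine = "fast_full",
                           sigma_init = sigma_init)
      if (fit$converged) {
        if (abs(fit$z) > z_threshold) hits <- hits + 1L
      } else {
        fails <- fails + 1L
      }
    }
    p <- hits / n_sim
    out$power[gi] <- p
    out$mc_se[gi] <- sqrt(p * (1 - p) / n_sim)
    out$n_failed[gi] <- fails
  }
  class(out) <- c("power_curve", class(out))
  out
}

#' End-to-end power analysis from binned data
#'
#' Chains the full observed-effect power procedure: per-bin effect sizes,
#' 3-bin peak window, trial-level collapse and 30% binarization,
#' observed-effect model, and simulation across the sample-size grid.
#'
#' @param binned Binned look data with the condition and response columns.
#' @param spec The task's [bin_model_spec()].
#' @inheritParams simulate_power
#' @inheritParams collapse_and_binarize
#' @return A list: `peak_window`, `observed_model`, `power` (the
#'   [simulate_power()] curve).
#' @export
power_analysis <- function(binned, spec, n_grid = c(20, 30, 40, 50, 60),
                           n_sim = 1000, z_threshold = 2, threshold = 0.30,
                           seed = 1) {
  ds <- per_bin_d(binned, spec)
  win <- find_peak_window(ds$d, bins = ds$bin)
  trials <- collapse_and_binarize(binned, win, response = spec$response,
                                  threshold = threshold)
  model <- fit_observed_effect_model(trials)
  pw <- simulate_power(model, n_grid = n_grid, n_sim = n_sim,
                       z_threshold = z_threshold, seed = seed)
  list(peak_window = win, observed_model = model, power = pw)
}
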