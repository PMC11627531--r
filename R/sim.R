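#' Describe an eye-tracking method channel
#'
#' A generative model of one recording channel: its sampling rate, spatial
#' error, temporal lag, per-sample track loss, whole-trial loss, and output
#' mode.  Coordinate channels (infrared trackers, appearance-based
#' estimators) emit x/y screen proportions; label channels (frame-by-frame
#' manual annotation) emit ROI labels directly.
#'
#' The bundled presets mirror the sampling rates typical of the three
#' method families (60 fps infrared, 25 fps annotated webcam video, and a
#' 12-26 fps appearance-based estimator); their spatial error, lag and loss
#' values are illustrative defaults, not estimates of any particular
#' device.
#'
#' @param name Channel label.
#' @param fps Sampling rate, samples per second.
#' @param spatial_sd Per-axis Gaussian error SD in screen-proportion units
#'   (ignored in labels mode).
#' @param latency_ms Constant added lag in ms.
#' @param trackloss_rate Per-sample probability of an invalid observation.
#' @param trial_loss_rate Probability a whole trial yields no data.
#' @param output_mode `"coordinates"` or `"labels"`.
#' @param label_error_rate Labels mode only: probability a rendered label
#'   is replaced by a uniformly random other visible-region label.
#' @param jitter_sd_ms Optional SD of Gaussian jitter on sample times, for
#'   estimator-like irregular sampling (default 0: a regular clock).
#' @return An object of class `method_model`.
#' @examples
#' method_model("infrared", fps = 60, spatial_sd = 0.02)
#' method_model("manual", fps = 25, output_mode = "labels")
#' @export
method_model <- function(name, fps, spatial_sd = 0, latency_ms = 0,
                         trackloss_rate = 0, trial_loss_rate = 0,
                         output_mode = c("coordinates", "labels"),
                         label_error_rate = 0, jitter_sd_ms = 0) {
  output_mode <- match.arg(output_mode)
  .assert(.is_scalar_num(fps) && fps > 0, "`fps` must be positive")
  .assert(.is_scalar_num(spatial_sd) && spatial_sd >= 0,
          "`spatial_sd` must be non-negative")
  .assert(.is_scalar_num(latency_ms) && latency_ms >= 0,
          "`latency_ms` must be non-negative")
  .assert(.is_prob(trackloss_rate), "`trackloss_rate` must be in [0, 1]")
  .assert(.is_prob(trial_loss_rate), "`trial_loss_rate` must be in [0, 1]")
  .assert(.is_prob(label_error_rate), "`label_error_rate` must be in [0, 1]")
  structure(list(name = name, fps = fps, spatial_sd = spatial_sd,
                 latency_ms = latency_ms, trackloss_rate = trackloss_rate,
                 trial_loss_rate = trial_loss_rate, output_mode = output_mode,
                 label_error_rate = label_error_rate,
                 jitter_sd_ms = jitter_sd_ms),
            class = "method_model")
}

#' @export
print.method_model <- function(x, ...) {
  cat(sprintf(
    "<method_model> %s: %g fps, %s, spatial_sd %g, lag %g ms, loss %g/%g\n",
    x$name, x$fps, x$output_mode, x$spatial_sd, x$latency_ms,
    x$trackloss_rate, x$trial_loss_rate))
  invisible(x)
}

#' Describe a task's trial structure
#'
#' Trial counts and durations default to the standard designs of the five
#' tasks: a 32-trial fixation task (1500 ms of target display), a 16-trial
#' cued lexical fixation task, a 36-trial phonemic cohort task with cohort
#' and control conditions, a 16-trial anticipatory looking task with
#' constraining and non-constraining verb conditions, and a single 45 s
#' smooth pursuit trial.  `align_zero_ms` is the within-trial time of the
#' event that defines analysis time zero (target or target-word onset).
#'
#' @param task Task name.
#' @param n_trials Number of trials per subject.
#' @param trial_duration_ms Total trial duration.
#' @param align_zero_ms Time of the alignment event within the trial.
#' @param condition_labels Condition labels (tasks with conditions only).
#' @param geometry A [roi_geometry()].
#' @return An object of class `task_design`.
#' @export
task_design <- function(task = c("fixation", "lexical_fixation",
                                 "phonemic_cohort", "anticipatory",
                                 "pursuit"),
                        n_trials = NULL, trial_duration_ms = NULL,
                        align_zero_ms = NULL, condition_labels = NULL,
                        geometry = roi_geometry()) {
  task <- match.arg(task)
  def <- switch(task,
    fixation = list(n_trials = 32, trial_duration_ms = 2250,
                    align_zero_ms = 750, condition_labels = "target"),
    lexical_fixation = list(n_trials = 16, trial_duration_ms = 3100,
                            align_zero_ms = 1600,
                            condition_labels = "target"),
    phonemic_cohort = list(n_trials = 36, trial_duration_ms = 2250,
                           align_zero_ms = 750,
                           condition_labels = c("cohort", "control")),
    anticipatory = list(n_trials = 16, trial_duration_ms = 2500,
                        align_zero_ms = 1500,
                        condition_labels = c("constraining",
                                             "non_constraining")),
    pursuit = list(n_trials = 1, trial_duration_ms = 45000,
                   align_zero_ms = 0, condition_labels = "pursuit"))
  d <- modifyList(def, Filter(Negate(is.null),
                              list(n_trials = n_trials,
                                   trial_duration_ms = trial_duration_ms,
                                   align_zero_ms = align_zero_ms,
                                   condition_labels = condition_labels)))
  .assert(d$n_trials > 0, "`n_trials` must be positive")
  .assert(d$align_zero_ms >= 0 && d$align_zero_ms < d$trial_duration_ms,
          "`align_zero_ms` must lie within the trial")
  structure(c(list(task = task, geometry = geometry), d),
            class = "task_design")
}

#' Describe the latent looking behavior
#'
#' Generative parameters of the behavior the channels observe: the
#' distribution of saccade latencies from the alignment event to target
#' fixation, subject- and item-level random variation in that latency,
#' per-condition latency shifts (anticipatory-style effects), and
#' per-condition competitor-glance probabilities confined to a time window
#' (cohort-style effects).
#'
#' Latencies are Gaussian, truncated below at `min_latency_ms` (a
#' physiological floor on saccade latency).
#'
#' @param base_latency_ms Mean latency from alignment zero to target
#'   fixation (default 300 ms).
#' @param latency_sd_ms Trial-level latency SD (default 60 ms).
#' @param min_latency_ms Truncation floor (default 80 ms).
#' @param subject_sd_ms,item_sd_ms SDs of subject- and item-level random
#'   latency shifts.
#' @param condition_latency_shift_ms Named vector: per-condition additive
#'   latency shift in ms.
#' @param competitor_prob Named vector: per-condition probability that the
#'   trial contains a glance to the competitor region inside the effect
#'   window.
#' @param competitor_window_ms `c(start, end)` of the effect window in ms
#'   relative to alignment zero.
#' @param competitor_duration_ms Duration of a competitor glance.
#' @param explore_prob Probability that a trial contains one exploratory
#'   glance to a uniformly random non-target quadrant at a uniform time
#'   within the trial (condition-independent baseline looking; real
#'   observers glance at distractors throughout a trial).
#' @param explore_duration_ms Duration of an exploratory glance.
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(competitor_prob = c(cohort = 0.25, control = 0.10),
#'             competitor_window_ms = c(400, 900))
#' @export
effect_spec <- function(base_latency_ms = 300, latency_sd_ms = 60,
                        min_latency_ms = 80, subject_sd_ms = 40,
                        item_sd_ms = 20,
                        condition_latency_shift_ms = NULL,
                        competitor_prob = NULL,
                        competitor_window_ms = c(400, 900),
                        competitor_duration_ms = 250,
                        explore_prob = 0.3, explore_duration_ms = 200) {
  .assert(latency_sd_ms >= 0 && subject_sd_ms >= 0 && item_sd_ms >= 0,
          "latency SDs must be non-negative")
  if (!is.null(competitor_prob)) {
    .assert(all(competitor_prob >= 0 & competitor_prob <= 1),
            "`competitor_prob` entries must be in [0, 1]")
    .assert(competitor_window_ms[2] > competitor_window_ms[1],
            "`competitor_window_ms` must be an increasing interval")
  }
  .assert(.is_prob(explore_prob), "`explore_prob` must be in [0, 1]")
  structure(list(base_latency_ms = base_latency_ms,
                 latency_sd_ms = latency_sd_ms,
                 min_latency_ms = min_latency_ms,
                 subject_sd_ms = subject_sd_ms, item_sd_ms = item_sd_ms,
                 condition_latency_shift_ms = condition_latency_shift_ms,
                 competitor_prob = competitor_prob,
                 competitor_window_ms = competitor_window_ms,
                 competitor_duration_ms = competitor_duration_ms,
                 explore_prob = explore_prob,
                 explore_duration_ms = explore_duration_ms),
            class = "effect_spec")
}

#' Sample a latent gaze timeline for one trial
#'
#' Draws the ground-truth sequence of fixated regions for a trial: the
#' gaze starts on the central fixation region, switches to the target
#' region at a sampled latency after the alignment event
#' (`base + subject_re + item_re + condition shift` plus trial noise,
#' truncated at the minimum saccade latency), and - in cohort-style
#' conditions - may contain a competitor glance inside the configured
#' effect window.
#'
#' @param design A [task_design()].
#' @param effects An [effect_spec()].
#' @param subject_re,item_re Random latency shifts in ms for this trial's
#'   subject and item.
#' @param condition Condition label (must be one of the design's).
#' @param target_roi Target quadrant.
#' @param competitor_roi Competitor quadrant (cohort-style tasks).
#' @return A tibble of ordered non-overlapping intervals `start_ms`,
#'   `end_ms`, `roi` partitioning the trial, with attributes `latency_ms`
#'   (sampled latency), `glance` (logical) and `glance_window_ms`.
#' @export
sample_timeline <- function(design, effects, subject_re = 0, item_re = 0,
                            condition, target_roi,
                            competitor_roi = NULL) {
  .assert(condition %in% design$condition_labels,
          "condition '%s' is not in the design", condition)
  dur <- design$trial_duration_ms
  a0 <- design$align_zero_ms
  lat <- effects$base_latency_ms + subject_re + item_re
  if (!is.null(effects$condition_latency_shift_ms) &&
      condition %in% names(effects$condition_latency_shift_ms))
    lat <- lat + effects$condition_latency_shift_ms[[condition]]
  lat <- max(effects$min_latency_ms,
             lat + rnorm(1, 0, effects$latency_sd_ms))
  switch_ms <- min(a0 + lat, dur)

  tl <- tibble(start_ms = c(0, switch_ms),
               end_ms = c(switch_ms, dur),
               roi = c("center", target_roi))
  tl <- tl[tl$end_ms > tl$start_ms, , drop = FALSE]

  # baseline exploratory glance, independent of condition
  if (!is.null(effects$explore_prob) && effects$explore_prob > 0 &&
      runif(1) < effects$explore_prob) {
    others <- setdiff(.quadrants, target_roi)
    e_roi <- others[sample.int(length(others), 1)]
    edur <- min(effects$explore_duration_ms, dur)
    eon <- runif(1, 0, dur - edur)
    tl <- .timeline_insert(tl, eon, eon + edur, e_roi)
  }

  glance <- FALSE
  gw <- c(NA_real_, NA_real_)
  cp <- effects$competitor_prob
  if (!is.null(cp) && condition %in% names(cp) && !is.null(competitor_roi)) {
    win <- a0 + effects$competitor_window_ms
    .assert(win[1] >= 0 && win[2] <= dur,
            "competitor effect window [%g, %g] lies outside the trial",
            effects$competitor_window_ms[1], effects$competitor_window_ms[2])
    if (runif(1) < cp[[condition]]) {
      glance <- TRUE
      gdur <- min(effects$competitor_duration_ms, win[2] - win[1])
      onset <- runif(1, win[1], win[2] - gdur)
      gw <- c(onset, onset + gdur)
      tl <- .timeline_insert(tl, gw[1], gw[2], competitor_roi)
    }
  }
  attr(tl, "latency_ms") <- lat
  attr(tl, "glance") <- glance
  attr(tl, "glance_window_ms") <- gw
  tl
}

# Overlay an interval on a timeline, splitting overlapped intervals.
.timeline_insert <- function(tl, start, end, roi) {
  pieces <- list()
  for (i in seq_len(nrow(tl))) {
    s <- tl$start_ms[i]; e <- tl$end_ms[i]; r <- tl$roi[i]
    if (e <= start || s >= end) {
      pieces[[length(pieces) + 1]] <- c(s, e, r)
    } else {
      if (s < start) pieces[[length(pieces) + 1]] <- c(s, start, r)
      if (e > end) pieces[[length(pieces) + 1]] <- c(end, e, r)
    }
  }
  pieces[[length(pieces) + 1]] <- c(start, end, roi)
  m <- do.call(rbind, pieces)
  out <- tibble(start_ms = as.numeric(m[, 1]), end_ms = as.numeric(m[, 2]),
                roi = m[, 3])
  out <- out[order(out$start_ms), , drop = FALSE]
  out
}

# ROI active at each time (vectorized); times clamped into the trial.
.timeline_roi_at <- function(tl, t) {
  t <- pmin(pmax(t, tl$start_ms[1]), tl$end_ms[nrow(tl)] - 1e-9)
  tl$roi[findInterval(t, tl$start_ms)]
}

#' Render a latent timeline through a coordinate channel
#'
#' Samples the channel at times `0, 1000/fps, 2000/fps, ...` within the
#' trial.  Each sample reports the centroid of the region active
#' `latency_ms` earlier (times before trial start are clamped), plus
#' per-axis Gaussian error, clipped to the unit square (real estimators
#' return on-screen coordinates); with probability `trackloss_rate` the
#' sample is invalid.
#'
#' @param timeline A [sample_timeline()] result.
#' @param method A [method_model()] with `output_mode = "coordinates"`.
#' @param geometry A [roi_geometry()] (unused by the default centroid
#'   placement but kept for custom layouts).
#' @return A tibble `time_ms`, `x`, `y`, `valid` (trial-clock times).
#' @export
render_coordinates <- function(timeline, method, geometry = roi_geometry()) {
  .assert(method$output_mode == "coordinates",
          "`method` must be a coordinate channel")
  dur <- timeline$end_ms[nrow(timeline)]
  t <- (seq_len(ceiling(dur * method$fps / 1000)) - 1) * 1000 / method$fps
  if (method$jitter_sd_ms > 0)
    t <- sort(pmin(pmax(t + rnorm(length(t), 0, method$jitter_sd_ms), 0),
                   dur - 1e-9))
  roi <- .timeline_roi_at(timeline, t - method$latency_ms)
  pos <- roi_centroid(roi)
  n <- length(t)
  x <- pmin(pmax(pos[, "x"] + rnorm(n, 0, method$spatial_sd), 0), 1)
  y <- pmin(pmax(pos[, "y"] + rnorm(n, 0, method$spatial_sd), 0), 1)
  valid <- runif(n) >= method$trackloss_rate
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  tibble(time_ms = t, x = x, y = y, valid = valid)
}

#' Render a latent timeline through a label (annotation) channel
#'
#' Frames at `1000/fps` ms spacing report the region active `latency_ms`
#' earlier.  With probability `label_error_rate` a frame's label is
#' replaced by a uniformly random *other* visible-region label (annotator
#' error); with probability `trackloss_rate` it is replaced by
#' `"off_or_unknown"` (blinks, looks away, unclear video).
#'
#' @param timeline A [sample_timeline()] result.
#' @param method A [method_model()] with `output_mode = "labels"`.
#' @return A tibble `time_ms`, `label`.
#' @export
render_labels <- function(timeline, method) {
  .assert(method$output_mode == "labels",
          "`method` must be a label channel")
  dur <- timeline$end_ms[nrow(timeline)]
  t <- (seq_len(ceiling(dur * method$fps / 1000)) - 1) * 1000 / method$fps
  lab <- .timeline_roi_at(timeline, t - method$latency_ms)
  n <- length(t)
  if (method$label_error_rate > 0) {
    err <- runif(n) < method$label_error_rate
    if (any(err)) {
      lab[err] <- vapply(lab[err], function(l) {
        sample(setdiff(.roi_levels, l), 1)
      }, character(1))
    }
  }
  lost <- runif(n) < method$trackloss_rate
  lab[lost] <- "off_or_unknown"
  tibble(time_ms = t, label = lab)
}

#' Simulate a complete multi-method gaze experiment
#'
#' Draws one latent timeline per subject x trial and renders it once
#' through *each* method channel, emulating a within-session design in
#' which all methods record the same behavior simultaneously.  Whole
#' trials are dropped independently per method with that method's
#' `trial_loss_rate`.  Items are assigned to trials cyclically;
#' two-condition designs are counterbalanced so each subject sees each
#' condition equally often and each item appears in both conditions across
#' subjects.  Target quadrants rotate across trials; the competitor region
#' is a randomly drawn different quadrant.
#'
#' All sample times in the returned streams are re-expressed relative to
#' the alignment event (`time_ms = 0` at target onset).
#'
#' @param n_subjects,n_items Numbers of subjects and items.
#' @param design A [task_design()].
#' @param effects An [effect_spec()].
#' @param methods List of [method_model()]s.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return An object of class `gaze_experiment`: a list with `design`
#'   (trial table), `samples` (coordinate streams, all methods stacked),
#'   `frames` (label streams), and `truth` (per-trial sampled latencies
#'   and glance windows, plus the subject/item random effects).
#' @export
simulate_experiment <- function(n_subjects, n_items, design, effects,
                                methods, seed = 1) {
  .assert(n_subjects >= 1 && n_items >= 1,
          "need at least one subject and one item")
  .assert(length(methods) >= 1, "`methods` must not be empty")
  .assert(all(vapply(methods, inherits, logical(1), "method_model")),
          "`methods` must be a list of method_model objects")
  set.seed(seed)
  a0 <- design$align_zero_ms
  nc <- length(design$condition_labels)

  subj_re <- rnorm(n_subjects, 0, effects$subject_sd_ms)
  item_re <- rnorm(n_items, 0, effects$item_sd_ms)

  trials <- expand.grid(trial = seq_len(design$n_trials),
                        subject = seq_len(n_subjects))[, c("subject", "trial")]
  trials$item <- (trials$trial - 1L) %% n_items + 1L
  trials$condition <- design$condition_labels[
    ((trials$trial - 1L) + (trials$subject - 1L)) %% nc + 1L]
  trials$target_roi <- .quadrants[(trials$trial - 1L) %% 4L + 1L]
  trials$competitor_roi <- vapply(trials$target_roi, function(tq) {
    sample(setdiff(.quadrants, tq), 1)
  }, character(1))

  nt <- nrow(trials)
  timelines <- vector("list", nt)
  truth <- tibble(subject = trials$subject, trial = trials$trial,
                  item = trials$item, condition = trials$condition,
                  latency_ms = NA_real_, glance = FALSE,
                  glance_start_ms = NA_real_, glance_end_ms = NA_real_)
  for (i in seq_len(nt)) {
    tl <- sample_timeline(design, effects,
                          subject_re = subj_re[trials$subject[i]],
                          item_re = item_re[trials$item[i]],
                          condition = trials$condition[i],
                          target_roi = trials$target_roi[i],
                          competitor_roi = trials$competitor_roi[i])
    timelines[[i]] <- tl
    truth$latency_ms[i] <- attr(tl, "latency_ms")
    truth$glance[i] <- attr(tl, "glance")
    gw <- attr(tl, "glance_window_ms")
    truth$glance_start_ms[i] <- gw[1] - a0
    truth$glance_end_ms[i] <- gw[2] - a0
  }

  samples <- list()
  frames <- list()
  for (m in methods) {
    keep <- runif(nt) >= m$trial_loss_rate
    for (i in which(keep)) {
      if (m$output_mode == "coordinates") {
        r <- render_coordinates(timelines[[i]], m, design$geometry)
      } else {
        r <- render_labels(timelines[[i]], m)
      }
      r$time_ms <- r$time_ms - a0
      r$subject <- trials$subject[i]
      r$trial <- trials$trial[i]
      r$item <- trials$item[i]
      r$condition <- trials$condition[i]
      r$method <- m$name
      if (m$output_mode == "coordinates") {
        samples[[length(samples) + 1]] <- r
      } else {
        frames[[length(frames) + 1]] <- r
      }
    }
  }
  bind <- function(lst) if (length(lst)) dplyr::bind_rows(lst) else NULL

  structure(list(
    design = as_tibble(trials),
    samples = bind(samples),
    frames = bind(frames),
    truth = truth,
    subject_re = subj_re, item_re = item_re,
    task_design = design, effects = effects, methods = methods,
    seed = seed), class = "gaze_experiment")
}

#' @export
print.gaze_experiment <- function(x, ...) {
  cat(sprintf(
    "<gaze_experiment> %s task: %d subjects x %d trials, %d method(s), seed %d\n",
    x$task_design$task, length(unique(x$design$subject)),
    x$task_design$n_trials, length(x$methods), x$seed))
  invisible(x)
}

#' Simulate binned binary look data from a logistic mixed model
#'
#' Generates per-trial, per-bin binary look indicators directly from a
#' binomial-logit mixed model with crossed subject and item random
#' intercepts (and optional uncorrelated condition slopes): the generative
#' structure assumed by the per-bin cluster analyses.  The condition
#' effect (on the logit scale, per unit of the +1/-1 sum-coded contrast)
#' applies only inside `effect_bins`, so null data and time-localized
#' effects are both available.  Used for calibration studies (type-I
#' error, effect-size behavior) where channel-level rendering is not the
#' object of study.
#'
#' @param n_subjects,n_items Crossed design sizes (each subject sees each
#'   item once; conditions counterbalanced).
#' @param n_bins Number of time bins.
#' @param base_logit Baseline log-odds of a look.
#' @param condition_beta Condition effect per contrast unit inside
#'   `effect_bins` (0 for null data).  Either a scalar (a flat effect) or
#'   a vector of per-bin effects aligned with `effect_bins`, for peaked
#'   time courses like a rising-and-falling competitor preference.
#' @param effect_bins Integer bins (0-based) carrying the effect.
#' @param subject_sd,item_sd Random-intercept SDs (logit scale).
#' @param subject_slope_sd,item_slope_sd Random condition-slope SDs.
#' @param response Name of the generated indicator column.
#' @param seed Integer seed.
#' @return A tibble `subject`, `item`, `trial`, `condition`, `bin` and the
#'   response column, with attribute `"truth"` recording the parameters.
#' @export
simulate_binned_experiment <- function(n_subjects, n_items, n_bins,
                                       base_logit = qlogis(0.2),
                                       condition_beta = 0,
                                       effect_bins = integer(0),
                                       subject_sd = 0.5, item_sd = 0.25,
                                       subject_slope_sd = 0,
                                       item_slope_sd = 0,
                                       response = "look_competitor",
                                       seed = 1) {
  set.seed(seed)
  us <- rnorm(n_subjects, 0, subject_sd)
  ui <- rnorm(n_items, 0, item_sd)
  uss <- rnorm(n_subjects, 0, subject_slope_sd)
  uis <- rnorm(n_items, 0, item_slope_sd)
  d <- expand.grid(item = seq_len(n_items), subject = seq_len(n_subjects))
  d$trial <- d$item
  d$condition <- c("cohort", "control")[
    (d$subject + d$item) %% 2 + 1L]
  code <- ifelse(d$condition == "cohort", 1, -1)
  .assert(length(condition_beta) %in% c(1L, length(effect_bins)),
          "`condition_beta` must be scalar or match `effect_bins`")
  full <- d[rep(seq_len(nrow(d)), each = n_bins), ]
  full$bin <- rep(seq_len(n_bins) - 1L, times = nrow(d))
  code_full <- rep(code, each = n_bins)
  beta_by_bin <- rep(0, n_bins)
  beta_by_bin[effect_bins + 1L] <- condition_beta
  beta_bin <- beta_by_bin[full$bin + 1L]
  eta <- base_logit + beta_bin * code_full +
    us[full$subject] + ui[full$item] +
    code_full * (uss[full$subject] + uis[full$item])
  full[[response]] <- rbinom(nrow(full), 1, plogis(eta))
  out <- as_tibble(full[c("subject", "item", "trial", "condition", "bin",
                          response)])
  attr(out, "truth") <- list(base_logit = base_logit,
                             condition_beta = condition_beta,
                             effect_bins = effect_bins,
                             subject_sd = subject_sd, item_sd = item_sd,
                             subject_slope_sd = subject_slope_sd,
                             item_slope_sd = item_slope_sd, seed = seed)
  out
}
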