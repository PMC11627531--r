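#' Generate a smooth-pursuit stimulus trajectory
#'
#' A constant-speed, piecewise-linear path between uniformly random
#' waypoints inside a rectangle, emulating a randomly moving pursuit
#' target.  This waypoint generator is a synthetic stand-in for whatever
#' trajectory a given experiment used; analyses only require the track
#' positions over time.
#'
#' @param rect `c(x0, y0, x1, y1)` bounding rectangle in screen
#'   proportions.
#' @param speed Speed in screen proportions per second.
#' @param duration_ms Track duration (default 45 s).
#' @param seed Integer seed.
#' @param dt_ms Sampling step of the returned track.
#' @return A tibble `time_ms`, `x`, `y` of class `stimulus_track`.
#' @export
make_trajectory <- function(rect = c(0.2, 0.3, 0.8, 0.7), speed = 0.25,
                            duration_ms = 45000, seed = 1, dt_ms = 10) {
  .assert(length(rect) == 4 && rect[3] > rect[1] && rect[4] > rect[2],
          "`rect` must be c(x0, y0, x1, y1) with positive area")
  .assert(all(rect >= 0 & rect <= 1), "`rect` must lie inside [0,1]^2")
  .assert(speed >= 0, "`speed` must be non-negative")
  set.seed(seed)
  t_grid <- seq(0, duration_ms, by = dt_ms)
  start <- c(runif(1, rect[1], rect[3]), runif(1, rect[2], rect[4]))
  if (speed == 0) {
    out <- tibble(time_ms = t_grid, x = start[1], y = start[2])
    class(out) <- c("stimulus_track", class(out))
    return(out)
  }
  pts <- list(start)
  times <- 0
  while (times[length(times)] < duration_ms) {
    nxt <- c(runif(1, rect[1], rect[3]), runif(1, rect[2], rect[4]))
    prev <- pts[[length(pts)]]
    dist <- sqrt(sum((nxt - prev)^2))
    times <- c(times, times[length(times)] + dist / speed * 1000)
    pts[[length(pts) + 1]] <- nxt
  }
  px <- vapply(pts, `[`, numeric(1), 1)
  py <- vapply(pts, `[`, numeric(1), 2)
  out <- tibble(time_ms = t_grid,
                x = approx(times, px, xout = t_grid)$y,
                y = approx(times, py, xout = t_grid)$y)
  class(out) <- c("stimulus_track", class(out))
  out
}

# Track position at arbitrary times (linear interpolation).
.track_at <- function(track, t) {
  cbind(x = approx(track$time_ms, track$x, xout = t, rule = 2)$y,
        y = approx(track$time_ms, track$y, xout = t, rule = 2)$y)
}

#' Per-bin mean gaze coordinates
#'
#' Averages the recorded (valid) coordinates of each time bin; bins with
#' no valid sample are missing.
#'
#' @param samples Data frame with `time_ms`, `x`, `y` and optionally
#'   `valid`.
#' @param bin_ms Bin width (default 100).
#' @return A tibble `bin`, `time_ms` (bin midpoint), `x`, `y`, `n`.
#' @export
bin_mean_coordinates <- function(samples, bin_ms = 100) {
  ok <- if ("valid" %in% names(samples)) samples$valid else TRUE
  ok <- ok & !is.na(samples$x) & !is.na(samples$y)
  s <- samples[ok, , drop = FALSE]
  .assert(nrow(s) > 0, "no valid samples")
  bin <- floor(s$time_ms / bin_ms)
  agg <- aggregate(cbind(x = s$x, y = s$y), by = list(bin = bin), FUN = mean)
  n <- as.integer(table(bin))
  tibble(bin = as.integer(agg$bin),
         time_ms = (agg$bin + 0.5) * bin_ms,
         x = agg$x, y = agg$y, n = n)
}

#' Euclidean gaze-to-target offset
#'
#' Distance in screen-proportion units between an estimated gaze position
#' and the stimulus position:
#' `sqrt((x_target - x)^2 + (y_target - y)^2)`.
#'
#' @param x,y Gaze coordinates (vectors allowed).
#' @param x_target,y_target Stimulus coordinates.
#' @return Numeric vector of distances.
#' @examples
#' euclidean_offset(0.25, 0.25, 0.5, 0.5)  # 0.3536
#' @export
euclidean_offset <- function(x, y, x_target, y_target) {
  sqrt((x_target - x)^2 + (y_target - y)^2)
}

#' Per-bin spatial offset of gaze from a pursuit stimulus
#'
#' For each subject, averages gaze coordinates per 100 ms bin and computes
#' the Euclidean offset to the stimulus position at the bin midpoint; then
#' aggregates over subjects to one mean offset per bin.
#'
#' @param samples Gaze stream with `subject`, `time_ms`, `x`, `y`,
#'   `valid`.
#' @param track A [make_trajectory()] track (or any `time_ms`/`x`/`y`
#'   table).
#' @param bin_ms Bin width (default 100).
#' @return A tibble of class `pursuit_series`: `bin`, `time_ms`, `offset`
#'   (mean over subjects), `n_subjects`; per-subject offsets in attribute
#'   `"by_subject"`, grand mean/SD over all subject x bin offsets in
#'   attribute `"grand"`.
#' @export
pursuit_offset_series <- function(samples, track, bin_ms = 100) {
  .assert("subject" %in% names(samples), "`samples` needs a subject column")
  per_subj <- lapply(split(samples, samples$subject), function(s) {
    bm <- bin_mean_coordinates(s, bin_ms = bin_ms)
    tp <- .track_at(track, bm$time_ms)
    tibble(subject = s$subject[1], bin = bm$bin, time_ms = bm$time_ms,
           offset = euclidean_offset(bm$x, bm$y, tp[, "x"], tp[, "y"]))
  })
  by_subject <- dplyr::bind_rows(per_subj)
  agg <- aggregate(offset ~ bin + time_ms, data = by_subject, FUN = mean)
  agg <- agg[order(agg$bin), ]
  nsub <- as.integer(table(by_subject$bin)[as.character(agg$bin)])
  out <- tibble(bin = as.integer(agg$bin), time_ms = agg$time_ms,
                offset = agg$offset, n_subjects = nsub)
  attr(out, "by_subject") <- by_subject
  attr(out, "grand") <- c(mean = mean(by_subject$offset),
                          sd = sd(by_subject$offset))
  class(out) <- c("pursuit_series", class(out))
  out
}

#' Compare two pursuit offset series
#'
#' Tests whether the mean per-bin offsets differ between two datasets,
#' with one value per time bin per dataset (subject-aggregated): a paired
#' t-test on the bin-aligned differences for within-experiment
#' comparisons, or a two-sample t-test for between-experiment comparisons.
#'
#' @param series_a,series_b [pursuit_offset_series()] results (or numeric
#'   vectors of per-bin offsets).
#' @param paired Use a paired test (requires aligned, equal-length bin
#'   series).
#' @return A list `t`, `df`, `p`, `mean_a`, `mean_b`, `paired`.
#' @export
compare_offset_series <- function(series_a, series_b, paired = TRUE) {
  a <- if (is.numeric(series_a)) series_a else series_a$offset
  b <- if (is.numeric(series_b)) series_b else series_b$offset
  if (paired) {
    .assert(length(a) == length(b),
            "paired comparison requires equal-length aligned bin series")
    if (!is.numeric(series_a) && !is.numeric(series_b))
      .assert(identical(series_a$bin, series_b$bin),
              "paired comparison requires a shared bin grid")
  }
  .assert(length(a) >= 2 && length(b) >= 2, "need at least 2 bins")
  if (paired) .assert(sd(a - b) > 0, "zero variance in paired differences")
  else .assert(sd(a) > 0 || sd(b) > 0, "zero variance in both series")
  tt <- t.test(a, b, paired = paired, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b), paired = paired)
}

#' Simulate pursuit gaze for several subjects through a method channel
#'
#' Each subject's latent gaze follows the stimulus track with that
#' subject's pursuit lag; the channel then adds its own constant lag,
#' spatial error and track loss, and samples at its rate.
#'
#' @param track A [make_trajectory()] track.
#' @param n_subjects Number of subjects.
#' @param method A coordinate [method_model()].
#' @param subject_lag_sd_ms SD of the subject-level pursuit lag
#'   (mean 100 ms).
#' @param seed Integer seed.
#' @return A gaze sample tibble `subject`, `time_ms`, `x`, `y`, `valid`,
#'   `method`.
#' @export
simulate_pursuit_gaze <- function(track, n_subjects, method,
                                  subject_lag_sd_ms = 30, seed = 1) {
  .assert(method$output_mode == "coordinates",
          "pursuit rendering requires a coordinate channel")
  set.seed(seed)
  lag <- pmax(0, rnorm(n_subjects, 100, subject_lag_sd_ms))
  dur <- max(track$time_ms)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    t <- (seq_len(ceiling(dur * method$fps / 1000)) - 1) * 1000 / method$fps
    pos <- .track_at(track, t - lag[s] - method$latency_ms)
    n <- length(t)
    x <- pmin(pmax(pos[, "x"] + rnorm(n, 0, method$spatial_sd), 0), 1)
    y <- pmin(pmax(pos[, "y"] + rnorm(n, 0, method$spatial_sd), 0), 1)
    valid <- runif(n) >= method$trackloss_rate
    x[!valid] <- NA_real_; y[!valid] <- NA_real_
    out[[s]] <- tibble(subject = s, time_ms = t, x = x, y = y,
                       valid = valid, method = method$name)
  }
  dplyr::bind_rows(out)
}
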