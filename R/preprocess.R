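#' Region-of-interest geometry
#'
#' The screen is divided into a central region and four quadrants.  The
#' central region is a square with a side of `center_fraction` of the
#' screen *height* (so its x-extent in screen-proportion units is scaled by
#' `1/aspect_ratio`); the quadrants are the four screen quarters minus any
#' overlap with the central square.  Coordinates are screen proportions
#' with the origin at the top-left and y increasing downward.
#'
#' @param center_fraction Side of the central square as a fraction of
#'   screen height (default 0.15).
#' @param aspect_ratio Screen width/height ratio (default 16/9).
#' @return An object of class `roi_geometry`.
#' @export
roi_geometry <- function(center_fraction = 0.15, aspect_ratio = 16 / 9) {
  .assert(.is_scalar_num(center_fraction) && center_fraction > 0 &&
            center_fraction < 1, "`center_fraction` must be in (0, 1)")
  .assert(.is_scalar_num(aspect_ratio) && aspect_ratio > 0,
          "`aspect_ratio` must be positive")
  structure(list(center_fraction = center_fraction,
                 aspect_ratio = aspect_ratio),
            class = "roi_geometry")
}

#' Centroid of a region of interest
#'
#' Quadrant centroids sit at the centers of the four screen quarters
#' (combinations of 0.25 and 0.75); the central region's centroid is
#' (0.5, 0.5).  This is where the simulator places stimuli, mirroring a
#' display with one image in the middle of each quadrant.
#'
#' @param roi ROI label(s): `"center"`, `"top_left"`, `"top_right"`,
#'   `"bottom_left"`, `"bottom_right"`.
#' @return A two-column matrix of (x, y) screen proportions.
#' @export
roi_centroid <- function(roi) {
  cx <- c(center = 0.5, top_left = 0.25, top_right = 0.75,
          bottom_left = 0.25, bottom_right = 0.75)
  cy <- c(center = 0.5, top_left = 0.25, top_right = 0.25,
          bottom_left = 0.75, bottom_right = 0.75)
  .assert(all(roi %in% names(cx)), "unknown ROI label")
  cbind(x = unname(cx[roi]), y = unname(cy[roi]))
}

#' Convert pixel coordinates to screen proportions
#'
#' Scales pixel coordinates so the screen center maps to (0.5, 0.5) and the
#' bottom-right corner to (1.0, 1.0), making analyses independent of screen
#' size.  Points outside the screen are flagged invalid rather than
#' clipped.
#'
#' @param x_px,y_px Pixel coordinates (origin top-left).
#' @param screen_width_px,screen_height_px Screen size in pixels.
#' @return A data frame with columns `x`, `y` (screen proportion) and
#'   `valid` (`FALSE` where the input is missing or off screen).
#' @examples
#' normalize_coordinates(960, 540, 1920, 1080)  # -> (0.5, 0.5)
#' @export
normalize_coordinates <- function(x_px, y_px, screen_width_px,
                                  screen_height_px) {
  .assert(.is_scalar_num(screen_width_px) && screen_width_px > 0 &&
            .is_scalar_num(screen_height_px) && screen_height_px > 0,
          "screen dimensions must be positive")
  x <- x_px / screen_width_px
  y <- y_px / screen_height_px
  valid <- !is.na(x) & !is.na(y) & x >= 0 & x <= 1 & y >= 0 & y <= 1
  data.frame(x = x, y = y, valid = valid)
}

#' Assign gaze samples to regions of interest
#'
#' A sample falls in the central region when its distance from the screen
#' center is at most half the central square's side along both axes
#' (`|x - 0.5| <= center_fraction / (2 * aspect_ratio)` and
#' `|y - 0.5| <= center_fraction / 2`); otherwise it is assigned to the
#' quadrant given by `x < 0.5` and `y < 0.5` (y increases downward, so
#' `y < 0.5` is the top half).  Every valid sample maps to exactly one of
#' the five regions; invalid samples map to `"off_or_unknown"`.
#'
#' @param x,y Screen-proportion coordinates.
#' @param valid Logical validity flags (default: all valid).
#' @param geometry A [roi_geometry()].
#' @return Character vector of ROI labels.
#' @export
assign_roi <- function(x, y, valid = NULL, geometry = roi_geometry()) {
  if (is.null(valid)) valid <- rep(TRUE, length(x))
  half_y <- geometry$center_fraction / 2
  half_x <- half_y / geometry$aspect_ratio
  out <- rep("off_or_unknown", length(x))
  ok <- valid & !is.na(x) & !is.na(y)
  ctr <- ok & abs(x - 0.5) <= half_x & abs(y - 0.5) <= half_y
  out[ctr] <- "center"
  quad <- ok & !ctr
  out[quad & x < 0.5 & y < 0.5] <- "top_left"
  out[quad & x >= 0.5 & y < 0.5] <- "top_right"
  out[quad & x < 0.5 & y >= 0.5] <- "bottom_left"
  out[quad & x >= 0.5 & y >= 0.5] <- "bottom_right"
  out
}

#' Bin and binarize looks into 100 ms time-bin indicators
#'
#' Divides each trial's observation stream into fixed-width time bins and
#' derives one binary look indicator per region of interest and per screen
#' side.  An ROI indicator is 1 when at least `roi_threshold` (default 30%)
#' of the recorded looks in the bin fall in that region; a side indicator
#' is 1 when at least `side_threshold` (default 50%) fall on that side
#' (sides comprise the two quadrants of the corresponding screen half; the
#' central region belongs to neither side).  By default the denominator
#' counts *all* recorded samples in the bin, including off-screen or
#' unidentifiable ones (`denominator = "valid"` restricts it to on-screen
#' samples).  Bins without any recorded sample get `NA` indicators and are
#' flagged missing.
#'
#' Works on coordinate streams (columns `x`, `y`, `valid`; regions assigned
#' via [assign_roi()]) and on annotation frame streams (a `label` column)
#' alike.
#'
#' @param samples Data frame of observations with `subject`, `trial`,
#'   `time_ms` (relative to the alignment zero) and either `x`/`y`/`valid`
#'   or `label`; additional trial-constant columns (condition, method,
#'   item, ...) are carried through.
#' @param window `c(start_ms, end_ms)` analysis window; must align to the
#'   bin grid.  Bin `k` covers `[start + k*bin_ms, start + (k+1)*bin_ms)`.
#' @param bin_ms Bin width in ms (default 100).
#' @param roi_threshold,side_threshold Binarization thresholds (inclusive).
#' @param geometry A [roi_geometry()] (coordinate streams only).
#' @param denominator `"all"` (default) or `"valid"`, see Details.
#' @return A tibble with one row per trial x bin: trial metadata, `bin`,
#'   `bin_start_ms`, `n_samples`, `missing`, `look_center`,
#'   `look_top_left`, ..., `look_left`, `look_right`, `look_top`,
#'   `look_bottom`.
#' @export
bin_looks <- function(samples, window = c(0, 1500), bin_ms = 100,
                      roi_threshold = 0.30, side_threshold = 0.50,
                      geometry = roi_geometry(),
                      denominator = c("all", "valid")) {
  denominator <- match.arg(denominator)
  .assert(length(window) == 2 && window[2] > window[1],
          "`window` must be c(start_ms, end_ms) with end > start")
  .assert((window[2] - window[1]) %% bin_ms == 0 &&
            window[1] %% bin_ms == 0,
          "`window` must align to the %g ms bin grid", bin_ms)
  .assert(.is_prob(roi_threshold) && .is_prob(side_threshold),
          "thresholds must be in [0, 1]")
  .assert(all(c("subject", "trial", "time_ms") %in% names(samples)),
          "`samples` needs subject, trial and time_ms columns")

  if (!"label" %in% names(samples)) {
    .assert(all(c("x", "y") %in% names(samples)),
            "`samples` needs either a label column or x/y coordinates")
    valid <- if ("valid" %in% names(samples)) samples$valid else TRUE
    samples$label <- assign_roi(samples$x, samples$y, valid, geometry)
  }

  n_bins <- (window[2] - window[1]) / bin_ms
  inw <- samples$time_ms >= window[1] & samples$time_ms < window[2]
  s <- samples[inw, , drop = FALSE]
  s$bin <- as.integer(floor((s$time_ms - window[1]) / bin_ms))

  meta_cols <- setdiff(names(samples),
                       c("time_ms", "x", "y", "valid", "label", "bin"))
  trial_key <- paste(samples$subject, samples$trial, sep = "\r")
  meta <- samples[!duplicated(trial_key), meta_cols, drop = FALSE]
  meta_key <- paste(meta$subject, meta$trial, sep = "\r")

  grid <- meta[rep(seq_len(nrow(meta)), each = n_bins), , drop = FALSE]
  grid$bin <- rep(seq_len(n_bins) - 1L, times = nrow(meta))
  grid$bin_start_ms <- window[1] + grid$bin * bin_ms
  gkey <- paste(paste(grid$subject, grid$trial, sep = "\r"), grid$bin,
                sep = "\v")

  skey <- paste(paste(s$subject, s$trial, sep = "\r"), s$bin, sep = "\v")
  idx <- match(skey, gkey)
  counts <- function(lab) {
    hit <- as.numeric(s$label %in% lab)
    v <- numeric(length(gkey))
    t <- tapply(hit, idx, sum)
    v[as.integer(names(t))] <- t
    v
  }
  n_all <- counts(.roi_all)
  n_den <- if (denominator == "all") n_all else counts(.roi_levels)

  prop <- function(lab) {
    p <- counts(lab) / n_den
    p[n_den == 0] <- NA_real_
    p
  }
  out <- as_tibble(grid)
  out$n_samples <- as.integer(n_all)
  out$missing <- n_all == 0
  for (roi in .roi_levels) {
    p <- prop(roi)
    out[[paste0("look_", roi)]] <-
      ifelse(is.na(p), NA_integer_, as.integer(p >= roi_threshold))
  }
  for (side in names(.side_quadrants)) {
    p <- prop(.side_quadrants[[side]])
    out[[paste0("look_", side)]] <-
      ifelse(is.na(p), NA_integer_, as.integer(p >= side_threshold))
  }
  out
}

#' Derive trial-specific look responses
#'
#' Joins per-trial design information (target and competitor regions) onto
#' binned looks and derives the response indicators used in the analyses:
#' looks to the target quadrant, looks to the competitor quadrant, and
#' looks to the target side of the screen on each axis.
#'
#' @param binned Output of [bin_looks()].
#' @param design Data frame with one row per `subject` x `trial` carrying
#'   `target_roi` and optionally `competitor_roi` (quadrant labels).
#' @return `binned` with added columns `target_roi`, `target_hside`,
#'   `target_vside`, `look_target`, `look_target_hside`,
#'   `look_target_vside` and (when competitor information is present)
#'   `competitor_roi`, `look_competitor`.
#' @export
derive_look_responses <- function(binned, design) {
  .assert(all(c("subject", "trial", "target_roi") %in% names(design)),
          "`design` needs subject, trial and target_roi columns")
  key_b <- paste(binned$subject, binned$trial, sep = "\r")
  key_d <- paste(design$subject, design$trial, sep = "\r")
  m <- match(key_b, key_d)
  .assert(!anyNA(m), "some trials in `binned` are missing from `design`")
  tq <- design$target_roi[m]
  .assert(all(tq %in% .quadrants), "target_roi must be a quadrant label")
  binned$target_roi <- tq
  binned$target_hside <- ifelse(tq %in% .side_quadrants$left, "left", "right")
  binned$target_vside <- ifelse(tq %in% .side_quadrants$top, "top", "bottom")
  look_mat <- as.matrix(binned[paste0("look_", .quadrants)])
  binned$look_target <-
    look_mat[cbind(seq_len(nrow(binned)), match(tq, .quadrants))]
  side_mat_h <- as.matrix(binned[c("look_left", "look_right")])
  binned$look_target_hside <-
    side_mat_h[cbind(seq_len(nrow(binned)),
                     ifelse(binned$target_hside == "left", 1L, 2L))]
  side_mat_v <- as.matrix(binned[c("look_top", "look_bottom")])
  binned$look_target_vside <-
    side_mat_v[cbind(seq_len(nrow(binned)),
                     ifelse(binned$target_vside == "top", 1L, 2L))]
  if ("competitor_roi" %in% names(design)) {
    cq <- design$competitor_roi[m]
    binned$competitor_roi <- cq
    binned$look_competitor <-
      look_mat[cbind(seq_len(nrow(binned)), match(cq, .quadrants))]
  }
  binned
}

#' Attention-based trial exclusion
#'
#' Flags trials in which more than `threshold` (default 50%, strict
#' inequality) of the annotated frames were not directed towards the
#' screen (`"off_or_unknown"`): such trials indicate insufficient
#' attention and are excluded from all co-recorded datasets of the same
#' subject and trial via [apply_trial_exclusions()].
#'
#' @param frames Annotation stream: `subject`, `trial`, `label`.
#' @param threshold Maximum tolerated off-screen fraction (default 0.5).
#' @return A tibble with one row per trial: `subject`, `trial`,
#'   `n_frames`, `off_fraction`, `excluded`.
#' @export
exclude_trials <- function(frames, threshold = 0.5) {
  .assert(all(c("subject", "trial", "label") %in% names(frames)),
          "`frames` needs subject, trial and label columns")
  key <- paste(frames$subject, frames$trial, sep = "\r")
  uk <- !duplicated(key)
  off <- frames$label == "off_or_unknown"
  n <- tapply(rep(1, length(key)), key, sum)
  noff <- tapply(as.numeric(off), key, sum)
  ord <- match(key[uk], names(n))
  out <- tibble(subject = frames$subject[uk], trial = frames$trial[uk],
                n_frames = as.integer(n[ord]),
                off_fraction = as.numeric(noff[ord] / n[ord]))
  out$excluded <- out$off_fraction > threshold
  out
}

#' Propagate trial exclusions to co-recorded datasets
#'
#' Removes the trials flagged by [exclude_trials()] from a dataset recorded
#' simultaneously on the same subjects.  Trials missing from a dataset for
#' other reasons (e.g. estimator trial loss) are left as they are: absence
#' in one method is not back-filled or mirrored in another.
#'
#' @param data Any per-sample or per-bin dataset with `subject` and
#'   `trial` columns.
#' @param exclusions Output of [exclude_trials()].
#' @return `data` without the excluded trials.
#' @export
apply_trial_exclusions <- function(data, exclusions) {
  bad <- exclusions[exclusions$excluded, c("subject", "trial")]
  if (!nrow(bad)) return(data)
  key <- paste(data$subject, data$trial, sep = "\r")
  bad_key <- paste(bad$subject, bad$trial, sep = "\r")
  data[!key %in% bad_key, , drop = FALSE]
}

#' Frame-level agreement between two annotation streams
#'
#' Percentage of time-aligned frames on which two annotators assigned the
#' same region label, the standard reliability check for manually annotated
#' gaze video.
#'
#' @param primary,secondary Equal-length, time-aligned label vectors (or
#'   data frames with a `label` column).
#' @return Percent agreement in `[0, 100]`.
#' @export
annotation_agreement <- function(primary, secondary) {
  if (is.data.frame(primary)) primary <- primary$label
  if (is.data.frame(secondary)) secondary <- secondary$label
  .assert(length(primary) == length(secondary),
          "annotation streams differ in length (%d vs %d)",
          length(primary), length(secondary))
  .assert(length(primary) > 0, "empty annotation streams")
  100 * mean(primary == secondary)
}
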