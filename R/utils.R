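# Internal helpers shared across modules.

# ROI vocabulary.  `y` increases downward (screen convention), so "top"
# quadrants have y < 0.5.
.roi_levels <- c("center", "top_left", "top_right",
                 "bottom_left", "bottom_right")
.roi_all <- c(.roi_levels, "off_or_unknown")

.quadrants <- c("top_left", "top_right", "bottom_left", "bottom_right")

.sides <- list(
  horizontal = c("left", "right"),
  vertical   = c("top", "bottom")
)

# quadrants belonging to each screen side
.side_quadrants <- list(
  left   = c("top_left", "bottom_left"),
  right  = c("top_right", "bottom_right"),
  top    = c("top_left", "top_right"),
  bottom = c("bottom_left", "bottom_right")
)

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.is_prob <- function(x) is.numeric(x) && length(x) == 1 &&
  !is.na(x) && x >= 0 && x <= 1

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)

# sum-coded (+1/-1) numeric codes for a two-or-more level factor; the first
# level of the sorted unique values carries +1 on its own contrast column
.sum_code <- function(x) {
  f <- factor(x)
  .assert(nlevels(f) >= 2, "factor must have at least 2 levels")
  if (nlevels(f) == 2) {
    code <- ifelse(as.integer(f) == 1L, 1, -1)
    m <- matrix(code, ncol = 1,
                dimnames = list(NULL, paste0("sum_", levels(f)[1])))
    return(m)
  }
  contrasts(f) <- stats::contr.sum(nlevels(f))
  m <- model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0("sum_", levels(f)[-nlevels(f)])
  m
}

# Deterministic sub-seed derivation (counter scheme); keeps results
# independent of evaluation order and within 32-bit integer range.
.sub_seed <- function(seed, counter) {
  (as.numeric(seed) * 48271 + as.numeric(counter) * 1117) %% 2147483562 + 1
}

# grand-mean of a binary indicator ignoring missing values
.grand_mean <- function(x) mean(x[!is.na(x)])
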