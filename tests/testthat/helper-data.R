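# Shared generators for small deterministic fixtures.

# Crossed subject x item binary data from a logistic model with known
# parameters (independent of the package's own simulators).
make_logit_data <- function(n_subjects, n_items, beta0 = 0, beta_cond = 0,
                            subject_sd = 0, item_sd = 0, seed = 1) {
  set.seed(seed)
  us <- rnorm(n_subjects, 0, subject_sd)
  ui <- rnorm(n_items, 0, item_sd)
  d <- expand.grid(subject = seq_len(n_subjects), item = seq_len(n_items))
  d$condition <- ifelse((d$subject + d$item) %% 2 == 0, "cohort", "control")
  code <- ifelse(d$condition == "cohort", 1, -1)
  d$y <- rbinom(nrow(d), 1, plogis(beta0 + beta_cond * code +
                                     us[d$subject] + ui[d$item]))
  d
}

# Tiny binned dataset for exhaustive permutation oracles:
# 2 subjects x 4 trials x n_bins, with per-bin response probabilities set
# per condition so that moderate (non-separated) effects exist.
make_toy_binned <- function(n_bins = 6, effect_bins = 2:4,
                            p_cohort = 0.85, p_control = 0.15,
                            p_base = 0.4, seed = 1) {
  set.seed(seed)
  d <- expand.grid(trial = 1:4, subject = 1:2)
  d$item <- d$trial
  d$condition <- ifelse(d$trial %% 2 == 0, "cohort", "control")
  full <- d[rep(seq_len(nrow(d)), each = n_bins), ]
  full$bin <- rep(seq_len(n_bins) - 1L, times = nrow(d))
  p <- ifelse(full$bin %in% effect_bins,
              ifelse(full$condition == "cohort", p_cohort, p_control),
              p_base)
  full$look_competitor <- rbinom(nrow(full), 1, p)
  # side looks for the target-side scheme: left-biased in effect bins
  p_left <- ifelse(full$bin %in% effect_bins, 0.85, 0.5)
  full$look_left <- rbinom(nrow(full), 1, p_left)
  full$look_right <- 1L - full$look_left
  full$target_hside <- "left"
  full$look_target_hside <- full$look_left
  tibble::as_tibble(full)
}

# Exhaustive null distribution of the maximum cluster z-sum under the
# condition-within-subject scheme, by enumerating every distinct
# within-subject label assignment (independent oracle for the Monte-Carlo
# permutation machinery).
exhaustive_condition_null <- function(data, spec, threshold) {
  key <- paste(data$subject, data$trial)
  ut <- !duplicated(key)
  tsub <- data$subject[ut]
  tcond <- data$condition[ut]
  per_subject <- lapply(unique(tsub), function(s) {
    labs <- tcond[tsub == s]
    unique(combinat_perms(labs))
  })
  grids <- expand.grid(lapply(per_subject, seq_along))
  subj_idx <- lapply(unique(tsub), function(s) which(tsub == s))
  vapply(seq_len(nrow(grids)), function(g) {
    newcond <- tcond
    for (j in seq_along(per_subject)) {
      newcond[subj_idx[[j]]] <- per_subject[[j]][[grids[g, j]]]
    }
    d2 <- data
    d2$condition <- newcond[match(key, key[ut])]
    z <- scan_window(d2, spec)$z
    cl <- find_clusters(z, threshold = threshold)
    if (nrow(cl)) max(cl$z_sum) else 0
  }, numeric(1))
}

# all distinct permutations of a small label vector
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    for (r in rest) out[[length(out) + 1]] <- c(x[i], r)
  }
  unique(out)
}

# Exhaustive null of the max cluster z-sum under the target-side scheme
# (every trial's side redrawn): enumerates all 2^n_trials assignments.
exhaustive_side_null <- function(data, spec, threshold) {
  key <- paste(data$subject, data$trial)
  ut <- !duplicated(key)
  n_trials <- sum(ut)
  trial_of_row <- match(key, key[ut])
  vapply(seq_len(2^n_trials) - 1L, function(mask) {
    side1 <- bitwAnd(bitwShiftR(mask, seq_len(n_trials) - 1L), 1L) == 1L
    d2 <- data
    first <- side1[trial_of_row]
    d2$look_target_hside <- ifelse(first, data$look_left, data$look_right)
    z <- scan_window(d2, spec)$z
    cl <- find_clusters(z, threshold = threshold)
    if (nrow(cl)) max(cl$z_sum) else 0
  }, numeric(1))
}
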