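#' Find supra-threshold clusters in a per-bin z series
#'
#' Identifies maximal runs of adjacent time bins whose `z` statistics all
#' exceed the threshold in absolute value and share the same sign, and sums
#' the absolute `z` values over each run into the cluster-mass (z-sum)
#' statistic.  A sign change splits a run even when both bins are
#' supra-threshold.
#'
#' @param z Numeric vector of per-bin z statistics (ordered by bin).
#' @param threshold Absolute z threshold for a bin to count as reliable
#'   (default 2).
#' @param bins Optional bin indices aligned with `z` (default
#'   `seq_along(z) - 1`).
#' @return A tibble with columns `start_bin`, `end_bin` (inclusive), `sign`
#'   (+1/-1) and `z_sum`; zero rows when no bin exceeds the threshold.
#' @examples
#' find_clusters(c(0.5, 2.5, 3.0, 1.9, -2.2))
#' @export
find_clusters <- function(z, threshold = 2, bins = NULL) {
  .assert(is.numeric(z) && all(is.finite(z)), "`z` must be finite numeric")
  if (is.null(bins)) bins <- seq_along(z) - 1L
  state <- ifelse(abs(z) > threshold, sign(z), 0)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  tibble(
    start_bin = bins[starts[keep]],
    end_bin = bins[ends[keep]],
    sign = as.integer(r$values[keep]),
    z_sum = vapply(which(keep), function(i) {
      sum(abs(z[starts[i]:ends[i]]))
    }, numeric(1))
  )
}

#' Permute labels of a binned look dataset
#'
#' Applies one of four shuffling schemes used to build permutation null
#' distributions:
#' \describe{
#'   \item{`condition_within_subject`}{for each subject independently, the
#'     condition labels are randomly reassigned across that subject's
#'     trials (marginal per-subject condition counts are preserved).}
#'   \item{`method_within_subject`}{for each subject, which of the
#'     subject's co-recorded datasets carries which method label is
#'     randomly reassigned.}
#'   \item{`experiment_between_subjects`}{experiment labels are shuffled
#'     across subjects (each subject keeps a single label).}
#'   \item{`target_side`}{for each subject and trial, the designated target
#'     side on the given axis is redrawn uniformly and the target-side look
#'     indicator is recomputed against the new side from the observed side
#'     looks (`look_left`/`look_right` or `look_top`/`look_bottom`).}
#' }
#' Observed responses are never altered except by re-derivation in the
#' target-side scheme.
#'
#' @param data Binned look data (one row per trial x bin).
#' @param scheme Permutation scheme name.
#' @param axis For the target-side scheme: `"horizontal"` or `"vertical"`.
#' @return The dataset with permuted labels (and, for the target-side
#'   scheme, a recomputed `look_target_hside`/`look_target_vside` column).
#' @export
permute_labels <- function(data,
                           scheme = c("condition_within_subject",
                                      "method_within_subject",
                                      "experiment_between_subjects",
                                      "target_side"),
                           axis = c("horizontal", "vertical")) {
  scheme <- match.arg(scheme)
  axis <- match.arg(axis)
  switch(scheme,
    condition_within_subject = {
      .assert(all(c("subject", "trial", "condition") %in% names(data)),
              "condition scheme needs subject, trial, condition columns")
      key <- paste(data$subject, data$trial, sep = "\r")
      ut <- !duplicated(key)
      tsub <- data$subject[ut]
      tcond <- data$condition[ut]
      newcond <- tcond
      for (s in unique(tsub)) {
        i <- which(tsub == s)
        newcond[i] <- tcond[i][sample.int(length(i))]
      }
      data$condition <- newcond[match(key, key[ut])]
      data
    },
    method_within_subject = {
      .assert(all(c("subject", "method") %in% names(data)),
              "method scheme needs subject and method columns")
      key <- paste(data$subject, data$method, sep = "\r")
      uu <- !duplicated(key)
      usub <- data$subject[uu]
      umeth <- data$method[uu]
      newmeth <- umeth
      for (s in unique(usub)) {
        i <- which(usub == s)
        newmeth[i] <- umeth[i][sample.int(length(i))]
      }
      data$method <- newmeth[match(key, key[uu])]
      data
    },
    experiment_between_subjects = {
      .assert(all(c("subject", "experiment") %in% names(data)),
              "experiment scheme needs subject and experiment columns")
      us <- unique(data$subject)
      lab <- data$experiment[match(us, data$subject)]
      newlab <- lab[sample.int(length(lab))]
      data$experiment <- newlab[match(data$subject, us)]
      data
    },
    target_side = {
      sides <- .sides[[axis]]
      look_cols <- paste0("look_", sides)
      resp <- if (axis == "horizontal") "look_target_hside" else "look_target_vside"
      side_col <- if (axis == "horizontal") "target_hside" else "target_vside"
      .assert(all(c("subject", "trial", look_cols) %in% names(data)),
              "target-side scheme needs side look columns")
      key <- paste(data$subject, data$trial, sep = "\r")
      ut <- !duplicated(key)
      new_side <- sides[sample.int(2, sum(ut), replace = TRUE)]
      row_side <- new_side[match(key, key[ut])]
      data[[side_col]] <- row_side
      data[[resp]] <- ifelse(row_side == sides[1],
                             data[[look_cols[1]]], data[[look_cols[2]]])
      data
    })
}

# ---- fast in-place permutation updates on a scan prep object -------------

# Precomputes the structures needed to update a prep object in place for
# each permutation, so that no data-frame work happens inside the loop.
.perm_prep <- function(data, spec, scheme, axis, prep) {
  kept <- prep$kept
  out <- list(scheme = scheme, axis = axis)
  if (scheme %in% c("condition_within_subject", "method_within_subject",
                    "experiment_between_subjects")) {
    shuffle_var <- switch(scheme,
      condition_within_subject = "condition",
      method_within_subject = "method",
      experiment_between_subjects = "experiment")
    .assert(identical(spec$fixed, shuffle_var) ||
              (length(spec$fixed) >= 1 && shuffle_var %in% spec$fixed),
            "fast permutation path requires '%s' among the fixed effects",
            shuffle_var)
    unit_key <- switch(scheme,
      condition_within_subject = paste(data$subject, data$trial, sep = "\r"),
      method_within_subject = paste(data$subject, data$method, sep = "\r"),
      experiment_between_subjects = as.character(data$subject))
    uk <- unit_key[kept]
    uu <- !duplicated(unit_key)
    out$unit_of_row <- match(uk, unit_key[uu])
    out$unit_subject <- data$subject[uu]
    lv <- sort(unique(as.character(data[[shuffle_var]])))
    .assert(length(lv) == 2,
            "fast permutation path requires a two-level '%s'", shuffle_var)
    out$unit_code <- ifelse(as.character(data[[shuffle_var]])[uu] == lv[1],
                            1, -1)
    out$units_by_subject <- split(seq_along(out$unit_subject),
                                  out$unit_subject)
    # column of X carrying the shuffled factor's code
    cn <- colnames(prep$sub[[1]]$X)
    out$xcol <- which(cn == shuffle_var | cn == paste0("sum_", lv[1]) |
                        startsWith(cn, shuffle_var))
    .assert(length(out$xcol) == 1,
            "cannot locate the shuffled factor's design column")
    # interaction columns involving the shuffled variable would need
    # recomputation; the fast path only supports a single-factor design
    .assert(length(spec$fixed) == 1,
            "fast permutation path supports a single fixed factor")
    out$update <- function(prep, perm_codes) {
      for (i in seq_along(prep$sub)) {
        s <- prep$sub[[i]]
        rows <- s$idx
        s$X[, out$xcol] <- perm_codes[out$unit_of_row[rows]]
        s$cell <- ifelse(s$X[, out$xcol] > 0, 1L, 2L)
        s$cell_rows <- split(seq_len(s$n), s$cell)
        prep$sub[[i]] <- s
      }
      prep
    }
  } else if (scheme == "target_side") {
    sides <- .sides[[axis]]
    look_cols <- paste0("look_", sides)
    .assert(all(look_cols %in% names(data)),
            "target-side scheme needs '%s' and '%s'",
            look_cols[1], look_cols[2])
    key <- paste(data$subject, data$trial, sep = "\r")
    uk <- key[kept]
    uu <- !duplicated(key)
    out$trial_of_row <- match(uk, key[uu])
    out$n_trials <- sum(uu)
    out$look1 <- data[[look_cols[1]]][kept]
    out$look2 <- data[[look_cols[2]]][kept]
    out$update <- function(prep, side_draw) {
      first <- side_draw[out$trial_of_row] == 1L
      ynew <- ifelse(first, out$look1, out$look2)
      for (i in seq_along(prep$sub)) {
        s <- prep$sub[[i]]
        s$y <- ynew[s$idx]
        prep$sub[[i]] <- s
      }
      prep
    }
  }
  out
}

.perm_draw <- function(pp) {
  if (pp$scheme == "target_side") {
    sample.int(2, pp$n_trials, replace = TRUE)
  } else {
    codes <- pp$unit_code
    for (i in pp$units_by_subject) codes[i] <- codes[i][sample.int(length(i))]
    if (pp$scheme == "experiment_between_subjects") {
      # one unit per subject: shuffle across, not within, subjects
      codes <- pp$unit_code[sample.int(length(pp$unit_code))]
    }
    codes
  }
}

#' Cluster-mass permutation test on binned look data
#'
#' Runs the full cluster-based permutation analysis: scans the analysis
#' window bin by bin with the specified logit mixed model (carry-forward
#' fallback rules included), thresholds the per-bin `z` series at
#' `|z| > threshold`, forms same-sign clusters with their z-sum statistics,
#' and compares each observed cluster against a permutation null
#' distribution built by re-scanning label-shuffled datasets.
#'
#' Each observed cluster's p-value is the proportion of permutation null
#' statistics greater than or equal to its z-sum.  By default the null
#' statistic of a permutation is its *maximum* cluster z-sum (0 when the
#' permuted scan yields no cluster), which controls the family-wise error
#' rate; `null_statistic = "all"` instead pools every cluster z-sum found
#' across permutations.  A p-value of exactly zero is reported as
#' `< 1/n_perm` (e.g. `"< 0.001"` at 1000 permutations).
#'
#' Permutation random streams are derived from `seed` by a counter scheme,
#' so results are reproducible and independent of evaluation order.
#'
#' @param data Binned look data (one row per trial x bin).
#' @param spec A [bin_model_spec()].
#' @param scheme,axis Shuffling scheme, see [permute_labels()].
#' @param n_perm Number of permutations (default 1000).
#' @param threshold Per-bin |z| threshold (default 2).
#' @param alpha Cluster significance level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @param bins Bins to scan (default: all present).
#' @param null_statistic `"max"` (default) or `"all"`, see Details.
#' @return An object of class `cluster_perm_test`: a list with `clusters`
#'   (tibble with bin and ms spans, sign, z_sum, p, p_label, significant),
#'   `scan` (the observed per-bin results), `null_stats`, and the test
#'   parameters.
#' @export
cluster_permutation_test <- function(data, spec,
                                     scheme = c("condition_within_subject",
                                                "method_within_subject",
                                                "experiment_between_subjects",
                                                "target_side"),
                                     axis = c("horizontal", "vertical"),
                                     n_perm = 1000, threshold = 2,
                                     alpha = 0.05, seed = NULL, bins = NULL,
                                     bin_ms = 100, window_start_ms = 0,
                                     null_statistic = c("max", "all")) {
  scheme <- match.arg(scheme)
  axis <- match.arg(axis)
  null_statistic <- match.arg(null_statistic)
  .assert(n_perm >= 1, "`n_perm` must be at least 1")
  if (is.null(seed)) seed <- sample.int(1e6, 1)

  if (scheme == "target_side") {
    resp <- if (axis == "horizontal") "look_target_hside" else "look_target_vside"
    .assert(spec$response == resp,
            "target-side scheme expects response '%s'", resp)
  }
  if (is.null(bins)) bins <- sort(unique(data$bin))
  prep <- .scan_prep(data, spec, bins)
  scan <- .scan_fit(prep)
  clusters <- find_clusters(scan$z, threshold = threshold, bins = bins)

  pp <- .perm_prep(data, spec, scheme, axis, prep)
  null_max <- numeric(n_perm)
  null_all <- vector("list", n_perm)
  sigma_bins <- attr(scan, "sigmas")
  for (b in seq_len(n_perm)) {
    set.seed(.sub_seed(seed, b))
    drawn <- .perm_draw(pp)
    prep_b <- pp$update(prep, drawn)
    zb <- .scan_z(prep_b, sigma_bins = sigma_bins)
    cl <- find_clusters(zb, threshold = threshold)
    null_max[b] <- if (nrow(cl)) max(cl$z_sum) else 0
    if (null_statistic == "all") null_all[[b]] <- cl$z_sum
  }
  pool <- if (null_statistic == "max") null_max else unlist(null_all)
  denom <- if (null_statistic == "max") n_perm else max(length(pool), 1L)

  if (nrow(clusters)) {
    # numerical tie guard: a permutation whose refit reproduces the observed
    # assignment must count as "greater or equal" despite optimizer noise
    cnt <- vapply(clusters$z_sum,
                  function(zs) sum(pool >= zs - 0.01), numeric(1))
    clusters$p <- cnt / denom
    clusters$p_label <- ifelse(
      cnt == 0, paste0("< ", format(1 / denom, digits = 3)),
      format(round(clusters$p, 4), digits = 4))
    clusters$significant <- clusters$p < alpha
    clusters$start_ms <- window_start_ms + clusters$start_bin * bin_ms
    clusters$end_ms <- window_start_ms + (clusters$end_bin + 1) * bin_ms - 1
  } else {
    clusters$p <- numeric(0)
    clusters$p_label <- character(0)
    clusters$significant <- logical(0)
    clusters$start_ms <- numeric(0)
    clusters$end_ms <- numeric(0)
  }

  structure(list(clusters = clusters, scan = scan, null_stats = null_max,
                 null_pool = pool,
                 params = list(scheme = scheme, axis = axis, n_perm = n_perm,
                               threshold = threshold, alpha = alpha,
                               seed = seed, bin_ms = bin_ms,
                               window_start_ms = window_start_ms,
                               null_statistic = null_statistic,
                               response = spec$response,
                               focal = spec$focal)),
            class = "cluster_perm_test")
}

#' @export
print.cluster_perm_test <- function(x, ...) {
  p <- x$params
  cat(sprintf("Cluster-mass permutation test (%s%s, %d permutations)\n",
              p$scheme,
              if (p$scheme == "target_side") paste0(", ", p$axis) else "",
              p$n_perm))
  cat(sprintf("  response: %s   focal: %s   |z| threshold: %g\n",
              p$response, p$focal, p$threshold))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$clusters))) {
    cl <- x$clusters[i, ]
    cat(sprintf("  cluster %d-%d ms (bins %d-%d, %s): z-sum = %.2f, p %s%s\n",
                cl$start_ms, cl$end_ms, cl$start_bin, cl$end_bin,
                if (cl$sign > 0) "+" else "-", cl$z_sum,
                if (grepl("^<", cl$p_label)) cl$p_label
                else paste0("= ", cl$p_label),
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}
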