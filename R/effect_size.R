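#' Proportion-based effect sizes for target-fixation tasks
#'
#' For tasks whose per-bin models have no fixed effects (target side
#' versus chance), the effect size is the grand average proportion of
#' target-quadrant looks, reported over three windows: the full analysis
#' window (an underestimate, since it includes bins before the effect),
#' the *cluster window* - the temporal overlap of the significant
#' positive clusters from the horizontal and vertical target-side
#' analyses - and the *maximum*: the single bin within the cluster window
#' with the greatest grand-average proportion (an overestimate).
#'
#' @param binned Binned look data with the target-quadrant indicator.
#' @param horizontal,vertical [cluster_permutation_test()] results of the
#'   target-side analyses on the two axes (or tibbles of clusters with
#'   `start_bin`, `end_bin`, `sign`, `significant`).
#' @param analysis_bins Bins of the analysis window (default: all bins in
#'   `binned`).
#' @param response Indicator column (default `"look_target"`).
#' @return A list of class `effect_sizes`: `metric = "proportion"`,
#'   `analysis`, `cluster`, `maximum` (the latter two `NA` when no
#'   overlapping positive clusters exist), `cluster_bins`,
#'   `analysis_bins`.
#' @export
proportion_effect_sizes <- function(binned, horizontal, vertical,
                                    analysis_bins = NULL,
                                    response = "look_target") {
  .assert(response %in% names(binned), "column '%s' not found", response)
  if (is.null(analysis_bins)) analysis_bins <- sort(unique(binned$bin))
  h_bins <- .positive_cluster_bins(horizontal)
  v_bins <- .positive_cluster_bins(vertical)
  cluster_bins <- intersect(h_bins, v_bins)

  y <- binned[[response]]
  win_mean <- function(bins) {
    if (!length(bins)) return(NA_real_)
    .grand_mean(y[binned$bin %in% bins])
  }
  analysis <- win_mean(analysis_bins)
  cluster <- win_mean(cluster_bins)
  maximum <- if (length(cluster_bins)) {
    max(vapply(cluster_bins, function(b) win_mean(b), numeric(1)))
  } else NA_real_

  structure(list(metric = "proportion", analysis = analysis,
                 cluster = cluster, maximum = maximum,
                 cluster_bins = sort(cluster_bins),
                 analysis_bins = analysis_bins),
            class = "effect_sizes")
}

.positive_cluster_bins <- function(test) {
  cl <- if (inherits(test, "cluster_perm_test")) test$clusters else test
  if (!nrow(cl)) return(integer(0))
  keep <- cl$sign > 0
  if ("significant" %in% names(cl)) keep <- keep & cl$significant
  cl <- cl[keep, , drop = FALSE]
  if (!nrow(cl)) return(integer(0))
  sort(unique(unlist(Map(seq, cl$start_bin, cl$end_bin))))
}

#' @export
print.effect_sizes <- function(x, ...) {
  fmt <- function(v) {
    if (is.na(v)) return("NA")
    if (x$metric == "proportion") sprintf("%.1f%%", 100 * v)
    else sprintf("%.3f", v)
  }
  cat(sprintf("<effect_sizes> metric: %s\n", x$metric))
  cat(sprintf("  analysis window: %s\n  cluster window:  %s\n  maximum:         %s\n",
              fmt(x$analysis), fmt(x$cluster), fmt(x$maximum)))
  invisible(x)
}

#' Cohen's d from a window-level logit mixed model
#'
#' For condition-effect tasks, the effect size over a window is obtained
#' by fitting the task's logit mixed model to all bins in the window
#' jointly (analysis- and cluster-window fits add a random intercept for
#' time bin) and converting the focal fixed effect to a standardized
#' Cohen's d via the t-to-d rule `d = 2 z / sqrt(n_obs - n_fixed)`, with
#' the Wald z standing in for t (a binomial-logit fit carries no residual
#' degrees of freedom; the convention is recorded in the result).  In
#' `"maximum"` mode the single bin with the largest observed condition
#' difference in mean response is selected first and fitted alone.
#'
#' @param data Binned look data.
#' @param bins Window bins.
#' @param spec A [bin_model_spec()] with the condition fixed effect.
#' @param mode `"analysis"`, `"cluster"` or `"maximum"`.
#' @param engine Fitting engine, see [fit_bin_model()].
#' @return A list of class `cohens_d`: `d`, `z`, `df`, `n_obs`, `mode`,
#'   `bin` (maximum mode), `converged`, `reason`, `convention`.
#' @export
window_cohens_d <- function(data, bins, spec,
                            mode = c("analysis", "cluster", "maximum"),
                            engine = "fast") {
  mode <- match.arg(mode)
  .assert(length(bins) >= 1, "empty window")
  .assert(!is.null(spec$fixed), "Cohen's d requires a condition fixed effect")
  d <- data[data$bin %in% bins, , drop = FALSE]

  if (mode == "maximum") {
    lv <- sort(unique(as.character(d$condition)))
    diffs <- vapply(sort(unique(d$bin)), function(b) {
      db <- d[d$bin == b, ]
      abs(.grand_mean(db[[spec$response]][db$condition == lv[1]]) -
            .grand_mean(db[[spec$response]][db$condition == lv[2]]))
    }, numeric(1))
    sel <- sort(unique(d$bin))[which.max(diffs)]
    d <- d[d$bin == sel, , drop = FALSE]
    spec_fit <- spec
  } else {
    sel <- NA_integer_
    # window-level model adds a random intercept for time bin
    spec_fit <- bin_model_spec(spec$response, fixed = spec$fixed,
                               random = c(spec$random, "(1|bin)"),
                               focal = spec$focal)
  }
  fit <- fit_bin_model(d, spec_fit, engine = engine)
  if (!fit$converged) {
    return(structure(list(d = NA_real_, z = NA_real_, df = NA_real_,
                          n_obs = fit$n_obs, mode = mode, bin = sel,
                          converged = FALSE, reason = fit$reason,
                          convention = "d = 2z/sqrt(n_obs - n_fixed)"),
                     class = "cohens_d"))
  }
  n_fixed <- 1L + length(spec$fixed)
  df <- fit$n_obs - n_fixed
  structure(list(d = 2 * fit$z / sqrt(df), z = fit$z, df = df,
                 n_obs = fit$n_obs, mode = mode, bin = sel,
                 converged = TRUE, reason = NA_character_,
                 convention = "d = 2z/sqrt(n_obs - n_fixed)"),
            class = "cohens_d")
}

#' @export
print.cohens_d <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<cohens_d> %s window: d = %.3f (z = %.2f, df = %d)\n",
                x$mode, x$d, x$z, x$df))
  } else {
    cat(sprintf("<cohens_d> %s window: not estimable (%s)\n",
                x$mode, x$reason))
  }
  invisible(x)
}

#' All three Cohen's d effect sizes for a condition effect
#'
#' Convenience wrapper computing the analysis-window, cluster-window and
#' maximum Cohen's d for one dataset.  When the cluster test found no
#' significant cluster, only the analysis and maximum measures are
#' computed (the maximum is then searched over the analysis window).
#' With several disjoint significant clusters, one cluster-window d is
#' reported per cluster rather than pooling them.
#'
#' @param data Binned look data.
#' @param test A [cluster_permutation_test()] result for the same data.
#' @param spec The task's [bin_model_spec()].
#' @param analysis_bins Analysis-window bins (default: all in `data`).
#' @return A list of class `effect_sizes`: `metric = "cohens_d"`,
#'   `analysis`, `cluster` (possibly `NA`; vector if several clusters),
#'   `maximum`, `cluster_bins`, and the underlying [window_cohens_d()]
#'   objects in `fits`.
#' @export
cohens_d_effect_sizes <- function(data, test, spec, analysis_bins = NULL) {
  if (is.null(analysis_bins)) analysis_bins <- sort(unique(data$bin))
  cl <- test$clusters
  sig <- cl[cl$significant & cl$sign > 0, , drop = FALSE]
  fits <- list()
  fits$analysis <- window_cohens_d(data, analysis_bins, spec, "analysis")
  if (nrow(sig)) {
    fits$cluster <- lapply(seq_len(nrow(sig)), function(i) {
      window_cohens_d(data, seq(sig$start_bin[i], sig$end_bin[i]), spec,
                      "cluster")
    })
    main <- which.max(sig$z_sum)
    max_bins <- seq(sig$start_bin[main], sig$end_bin[main])
  } else {
    fits$cluster <- NULL
    max_bins <- analysis_bins
  }
  fits$maximum <- window_cohens_d(data, max_bins, spec, "maximum")
  cluster_d <- if (is.null(fits$cluster)) NA_real_
               else vapply(fits$cluster, function(f) f$d, numeric(1))
  structure(list(metric = "cohens_d",
                 analysis = fits$analysis$d,
                 cluster = cluster_d,
                 maximum = fits$maximum$d,
                 cluster_bins = if (nrow(sig)) .positive_cluster_bins(test)
                                else integer(0),
                 analysis_bins = analysis_bins,
                 fits = fits),
            class = "effect_sizes")
}
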