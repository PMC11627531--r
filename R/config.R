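#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration describing a simulation-plus-analysis run:
#' the task, sample sizes, method channels, effect parameters, analysis
#' window and thresholds.  Missing fields are filled with the standard
#' defaults (100 ms bins; 30% ROI and 50% side binarization; 50%
#' off-screen trial exclusion; |z| > 2 bin threshold; cluster p < 0.05;
#' 1000 permutations; task-specific analysis windows: 0-1500 ms for the
#' fixation, lexical fixation and cohort tasks, -700-1000 ms for the
#' anticipatory task).  Invalid values are reported together, naming each
#' offending field.
#'
#' @param path Path to a YAML file (or a list already in memory).
#' @return A validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (is.list(path)) path else {
    .assert(file.exists(path), "config file '%s' not found", path)
    yaml::read_yaml(path)
  }
  def <- list(
    task = "phonemic_cohort",
    n_subjects = 20, n_items = 12,
    seed = 1, n_perm = 1000,
    window_ms = NULL,  # task default filled below
    bin_ms = 100,
    thresholds = list(z = 2.0, roi = 0.30, side = 0.50,
                      exclusion = 0.50, alpha = 0.05),
    geometry = list(center_fraction = 0.15, aspect_ratio = 16 / 9),
    effects = list(),
    methods = list(list(name = "infrared", fps = 60, spatial_sd = 0.02,
                        output_mode = "coordinates"),
                   list(name = "manual", fps = 25, output_mode = "labels",
                        label_error_rate = 0.02, trackloss_rate = 0.05),
                   list(name = "webgazer", fps = 26, spatial_sd = 0.15,
                        latency_ms = 150, trackloss_rate = 0.05,
                        trial_loss_rate = 0.01,
                        output_mode = "coordinates")))
  cfg <- modifyList(def, raw)
  # unnamed lists must replace, not merge element-wise
  if (!is.null(raw$methods)) cfg$methods <- raw$methods
  if (!is.null(raw$effects)) cfg$effects <- raw$effects
  if (is.null(cfg$window_ms)) {
    cfg$window_ms <- switch(cfg$task, anticipatory = c(-700, 1000),
                            c(0, 1500))
  }
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$task %in% c("fixation", "lexical_fixation", "phonemic_cohort",
                      "anticipatory", "pursuit"),
      sprintf("task: unknown task '%s'", cfg$task))
  chk(cfg$n_subjects >= 1, "n_subjects: must be >= 1")
  chk(cfg$n_items >= 1, "n_items: must be >= 1")
  chk(cfg$n_perm >= 1, "n_perm: must be >= 1")
  th <- cfg$thresholds
  chk(is.numeric(th$z) && th$z > 0, "thresholds.z: must be positive")
  chk(.is_prob(th$roi), "thresholds.roi: must be in [0, 1]")
  chk(.is_prob(th$side), "thresholds.side: must be in [0, 1]")
  chk(.is_prob(th$exclusion), "thresholds.exclusion: must be in [0, 1]")
  chk(.is_prob(th$alpha), "thresholds.alpha: must be in [0, 1]")
  chk(length(cfg$window_ms) == 2 && cfg$window_ms[2] > cfg$window_ms[1],
      "window_ms: must be an increasing interval")
  chk(all(unlist(cfg$window_ms) %% cfg$bin_ms == 0),
      "window_ms: must align to the bin grid")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s task: %d subjects, %d items, window %d..%d ms, %d permutations, seed %d\n",
              x$task, x$n_subjects, x$n_items, x$window_ms[1],
              x$window_ms[2], x$n_perm, x$seed))
  invisible(x)
}

#' Save a run configuration
#'
#' Writes a [load_run_config()] list back to YAML; loading the result
#' reproduces the configuration (round-trip stable).
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write gaze or annotation streams as delimited text
#'
#' Tabular outputs are comma-separated with a header row; positions are
#' screen proportions (origin top-left, y increasing downward) and times
#' are integer-valued ms relative to the alignment event.
#'
#' @param data Tabular data.
#' @param path Output path.
#' @export
write_gaze_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Run the full simulate-preprocess-cluster-effect-size pipeline
#'
#' Orchestrates one reproducible end-to-end run from a configuration:
#' simulates the multi-method experiment, preprocesses each method's
#' stream (binning, binarization, attention-based trial exclusion
#' propagated from the annotation channel when one exists), runs the
#' task-appropriate cluster permutation analysis per method (target-side
#' versus chance on both axes for fixation-style tasks; the condition
#' effect for cohort- and anticipatory-style tasks), and computes effect
#' sizes.  When `out_dir` is given, all stage outputs are written as
#' delimited text / JSON together with a manifest recording the package
#' version, seed, configuration digest and output digests.
#'
#' @param config A [load_run_config()] result (or a path to one).
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_result`: `experiment`, `binned`
#'   (per method), `exclusions`, `tests` (per method), `effect_sizes`
#'   (per method), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) || !inherits(config, "run_config"))
    config <- load_run_config(config)
  .assert(config$task != "pursuit",
          "use simulate_pursuit_gaze()/pursuit_offset_series() for the pursuit task")
  geom <- roi_geometry(config$geometry$center_fraction,
                       config$geometry$aspect_ratio)
  design <- task_design(config$task, geometry = geom)
  effects <- do.call(effect_spec, config$effects)
  methods <- lapply(config$methods, function(m) do.call(method_model, m))

  exp <- simulate_experiment(config$n_subjects, config$n_items, design,
                             effects, methods, seed = config$seed)

  th <- config$thresholds
  # attention exclusions from the first label channel, applied everywhere
  excl <- NULL
  if (!is.null(exp$frames)) {
    first_label <- exp$frames$method ==
      exp$frames$method[1]
    excl <- exclude_trials(exp$frames[first_label, ],
                           threshold = th$exclusion)
  }

  binned <- list()
  for (m in methods) {
    raw <- if (m$output_mode == "coordinates") {
      exp$samples[exp$samples$method == m$name, ]
    } else {
      exp$frames[exp$frames$method == m$name, ]
    }
    if (is.null(raw) || !nrow(raw)) next
    b <- bin_looks(raw, window = config$window_ms, bin_ms = config$bin_ms,
                   roi_threshold = th$roi, side_threshold = th$side,
                   geometry = geom)
    b <- derive_look_responses(b, exp$design)
    if (!is.null(excl)) b <- apply_trial_exclusions(b, excl)
    binned[[m$name]] <- b
  }

  fixation_style <- config$task %in% c("fixation", "lexical_fixation")
  tests <- list()
  esizes <- list()
  for (nm in names(binned)) {
    b <- binned[[nm]]
    if (fixation_style) {
      h <- cluster_permutation_test(
        b, bin_model_spec("look_target_hside", random = c("(1|subject)", "(1|item)")),
        scheme = "target_side", axis = "horizontal",
        n_perm = config$n_perm, threshold = th$z, alpha = th$alpha,
        seed = .sub_seed(config$seed, 1), bin_ms = config$bin_ms,
        window_start_ms = config$window_ms[1])
      v <- cluster_permutation_test(
        b, bin_model_spec("look_target_vside", random = c("(1|subject)", "(1|item)")),
        scheme = "target_side", axis = "vertical",
        n_perm = config$n_perm, threshold = th$z, alpha = th$alpha,
        seed = .sub_seed(config$seed, 2), bin_ms = config$bin_ms,
        window_start_ms = config$window_ms[1])
      tests[[nm]] <- list(horizontal = h, vertical = v)
      esizes[[nm]] <- proportion_effect_sizes(b, h, v)
    } else {
      resp <- if (config$task == "phonemic_cohort") "look_competitor"
              else "look_target"
      spec <- bin_model_spec(resp, fixed = "condition")
      tst <- cluster_permutation_test(
        b, spec, scheme = "condition_within_subject",
        n_perm = config$n_perm, threshold = th$z, alpha = th$alpha,
        seed = .sub_seed(config$seed, 1), bin_ms = config$bin_ms,
        window_start_ms = config$window_ms[1])
      tests[[nm]] <- tst
      esizes[[nm]] <- cohens_d_effect_sizes(b, tst, spec)
    }
  }

  manifest <- list(
    package = "gazeperm",
    version = as.character(utils::packageVersion("gazeperm")),
    task = config$task, seed = config$seed,
    n_subjects = config$n_subjects, n_items = config$n_items,
    methods = vapply(methods, function(m) m$name, character(1)),
    coordinate_convention = "screen proportion, origin top-left, y down",
    timestamp = format(Sys.time(), tz = "UTC"))

  res <- structure(list(experiment = exp, binned = binned,
                        exclusions = excl, tests = tests,
                        effect_sizes = esizes, manifest = manifest,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline(res, out_dir)
  res
}

.write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(res$experiment$samples)) {
    f <- file.path(out_dir, "gaze_samples.csv")
    write_gaze_csv(res$experiment$samples, f); files <- c(files, f)
  }
  if (!is.null(res$experiment$frames)) {
    f <- file.path(out_dir, "annotation_frames.csv")
    write_gaze_csv(res$experiment$frames, f); files <- c(files, f)
  }
  f <- file.path(out_dir, "design.csv")
  write_gaze_csv(res$experiment$design, f); files <- c(files, f)
  f <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(res$experiment$truth, f, digits = NA); files <- c(files, f)
  for (nm in names(res$binned)) {
    f <- file.path(out_dir, paste0("binned_", nm, ".csv"))
    write_gaze_csv(res$binned[[nm]], f); files <- c(files, f)
  }
  cl_out <- lapply(res$tests, function(t) {
    if (inherits(t, "cluster_perm_test")) list(clusters = t$clusters)
    else lapply(t, function(tt) list(clusters = tt$clusters))
  })
  f <- file.path(out_dir, "clusters.json")
  jsonlite::write_json(cl_out, f, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  files <- c(files, f)
  es_out <- lapply(res$effect_sizes, function(e) {
    e[c("metric", "analysis", "cluster", "maximum")]
  })
  f <- file.path(out_dir, "effect_sizes.json")
  jsonlite::write_json(es_out, f, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  files <- c(files, f)
  man <- res$manifest
  man$file_digests <- as.list(tools::md5sum(files))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s task, methods: %s\n",
              x$config$task, paste(names(x$binned), collapse = ", ")))
  for (nm in names(x$tests)) {
    cat("--", nm, "--\n")
    t <- x$tests[[nm]]
    if (inherits(t, "cluster_perm_test")) print(t)
    else { print(t$horizontal); print(t$vertical) }
  }
  invisible(x)
}
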