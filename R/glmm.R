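#' Specify a per-time-bin binomial mixed model
#'
#' Describes the logit mixed-effects model fitted to each 100 ms time bin in
#' a cluster analysis: the binary look indicator to model, the sum-coded
#' fixed effects (none for intercept-versus-chance analyses), and the
#' crossed random-effects structure.
#'
#' Fixed-effect factors are coded with +1/-1 sum contrasts, so for a
#' two-level factor the focal coefficient equals half the condition
#' difference on the logit scale; `z` statistics are unaffected by the
#' contrast magnitude.  Random slope terms are fitted as uncorrelated
#' (diagonal) blocks.
#'
#' @param response Name of the binary indicator column (e.g.
#'   `"look_target_hside"`, `"look_competitor"`).
#' @param fixed Character vector of fixed-effect factor columns, possibly
#'   including interactions (`"condition:method"`).  `NULL` fits an
#'   intercept-only model whose intercept tests the indicator against 50%
#'   chance.
#' @param random Character vector of lme4-style random terms; supported
#'   forms are `"(1|g)"`, `"(0+x|g)"` and `"(1+x|g)"` with `x` a two-level
#'   factor column.
#' @param focal Name of the fixed term whose estimate and `z` are extracted
#'   (default: the first fixed effect, or the intercept when `fixed` is
#'   `NULL`).
#' @return An object of class `bin_model_spec`.
#' @examples
#' bin_model_spec("look_target_hside")
#' bin_model_spec("look_competitor", fixed = "condition")
#' @export
bin_model_spec <- function(response,
                           fixed = NULL,
                           random = c("(1|subject)", "(1|item)"),
                           focal = NULL) {
  .assert(is.character(response) && length(response) == 1,
          "`response` must be a single column name")
  if (!is.null(fixed)) .assert(is.character(fixed), "`fixed` must be character")
  terms <- lapply(random, .parse_random_term)
  if (is.null(focal)) focal <- if (is.null(fixed)) "(Intercept)" else fixed[1]
  .assert(focal == "(Intercept)" || focal %in% fixed,
          "`focal` term '%s' does not appear in the fixed effects", focal)
  structure(list(response = response, fixed = fixed, random = random,
                 random_terms = terms, focal = focal),
            class = "bin_model_spec")
}

#' @export
print.bin_model_spec <- function(x, ...) {
  fx <- if (is.null(x$fixed)) "1" else paste(x$fixed, collapse = " + ")
  cat("<bin_model_spec> ", x$response, " ~ ", fx, " + ",
      paste(x$random, collapse = " + "),
      "  [focal: ", x$focal, "]\n", sep = "")
  invisible(x)
}

.parse_random_term <- function(term) {
  m <- regmatches(term, regexec("^\\(\\s*(0|1)\\s*(?:\\+\\s*([^|]+?)\\s*)?\\|\\s*([^)]+?)\\s*\\)$",
                                term))[[1]]
  .assert(length(m) == 4, "cannot parse random term '%s'", term)
  intercept <- m[2] == "1"
  slope <- if (nzchar(m[3])) m[3] else NA_character_
  list(group = m[4], slope = slope, intercept = intercept)
}

# Build the numeric inputs for the Laplace fitter: response vector, fixed
# design with sum contrasts, and one diagonal random block per term
# (an (1+x|g) term expands into an intercept block and a slope block).
.build_glmm_inputs <- function(data, spec) {
  y <- data[[spec$response]]
  .assert(!is.null(y), "response column '%s' not found", spec$response)
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(y[keep])

  n <- length(y)
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  cell <- rep(1L, n)
  if (!is.null(spec$fixed)) {
    base <- setdiff(unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE))),
                    character(0))
    codes <- list()
    for (v in base) {
      .assert(!is.null(data[[v]]), "fixed-effect column '%s' not found", v)
      codes[[v]] <- .sum_code(data[[v]])
    }
    for (trm in spec$fixed) {
      parts <- strsplit(trm, ":", fixed = TRUE)[[1]]
      col <- codes[[parts[1]]]
      if (length(parts) > 1) {
        for (pp in parts[-1]) {
          a <- col; b <- codes[[pp]]
          out <- matrix(0, n, ncol(a) * ncol(b))
          cn <- character(0)
          k <- 0
          for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
            k <- k + 1
            out[, k] <- a[, i] * b[, j]
            cn <- c(cn, paste0(colnames(a)[i], ":", colnames(b)[j]))
          }
          colnames(out) <- cn
          col <- out
        }
      }
      colnames(col) <- if (ncol(col) == 1) trm else paste0(trm, seq_len(ncol(col)))
      X <- cbind(X, col)
    }
    cell <- as.integer(interaction(data[base], drop = TRUE))
  }

  G <- NULL; Xr <- NULL; qk <- integer(0); term_names <- character(0)
  for (trm in spec$random_terms) {
    g <- data[[trm$group]]
    .assert(!is.null(g), "grouping column '%s' not found", trm$group)
    f <- factor(g)
    gi <- as.integer(f) - 1L
    if (trm$intercept) {
      G <- cbind(G, gi)
      Xr <- cbind(Xr, rep(1, n))
      qk <- c(qk, nlevels(f))
      term_names <- c(term_names, trm$group)
    }
    if (!is.na(trm$slope)) {
      sc <- .sum_code(data[[trm$slope]])
      .assert(ncol(sc) == 1, "random slopes require a two-level factor")
      G <- cbind(G, gi)
      Xr <- cbind(Xr, sc[, 1])
      qk <- c(qk, nlevels(f))
      term_names <- c(term_names, paste0(trm$group, ":", trm$slope))
    }
  }

  focal_col <- if (spec$focal == "(Intercept)") 1L else {
    idx <- which(colnames(X) == spec$focal |
                   startsWith(colnames(X), paste0(spec$focal, "sum_")) |
                   colnames(X) == paste0(spec$focal, "1"))
    .assert(length(idx) >= 1, "focal term '%s' not found in design", spec$focal)
    idx[1]
  }

  list(y = y, X = X, G = G, Xr = Xr, qk = qk, term_names = term_names,
       cell = cell, focal_col = focal_col, n = n)
}

# Degenerate-data checks mirroring the convention that a bin is inestimable
# when the response shows no variation overall or within a fixed-effect cell.
.check_estimable <- function(inp) {
  if (inp$n == 0) return("empty")
  if (length(unique(inp$y)) < 2) return("no_variation")
  for (cl in unique(inp$cell)) {
    yc <- inp$y[inp$cell == cl]
    if (length(unique(yc)) < 2) return("cell_no_variation")
  }
  NULL
}

#' Fit the logit mixed model for one time bin
#'
#' Fits a binomial-logit mixed-effects model with crossed random intercepts
#' (and optional uncorrelated random slopes) by maximum likelihood with a
#' Laplace approximation, and extracts the focal estimate, standard error
#' and `z = estimate/SE`.
#'
#' A fit with a random-effect standard deviation estimated below `1e-3`
#' (variance `1e-6`) is reported as `singular` but still counts as
#' converged.  Complete separation, a response without variation (overall or
#' within a fixed-effect cell), or a failed optimisation yield
#' `converged = FALSE` with a reason; cluster scans then apply the
#' carry-forward rule (see [scan_window()]).
#'
#' @param data Data frame with one row per trial (or trial x bin) holding
#'   the response and the model columns.
#' @param spec A [bin_model_spec()].
#' @param engine `"fast"` for the built-in profiled Laplace fitter (the
#'   default; optimised for permutation loops), `"fast_full"` for the
#'   built-in full Laplace fit (fixed effects in the outer optimisation,
#'   matching `glmer`'s estimation target; used where Wald-z calibration
#'   matters), or `"glmer"` for [lme4::glmer()].  All satisfy the same
#'   contract and agree to numerical tolerance.
#' @param sigma_init Optional starting values for the random-effect SDs.
#' @return A list of class `bin_model_fit` with elements `estimate`, `se`,
#'   `z`, `converged`, `singular`, `reason`, `n_obs`, `beta`, `sigma`.
#' @examples
#' d <- data.frame(subject = rep(1:6, each = 10),
#'                 item = rep(1:10, times = 6),
#'                 y = rbinom(60, 1, 0.6))
#' fit_bin_model(d, bin_model_spec("y"))
#' @export
fit_bin_model <- function(data, spec, engine = c("fast", "fast_full",
                                                 "glmer"),
                          sigma_init = NULL) {
  engine <- match.arg(engine)
  .assert(inherits(spec, "bin_model_spec"), "`spec` must be a bin_model_spec")
  inp <- .build_glmm_inputs(data, spec)
  bad <- .check_estimable(inp)
  if (!is.null(bad)) {
    return(.bin_fit(NA, NA, NA, FALSE, FALSE, bad, inp$n))
  }
  if (length(inp$qk) && any(inp$qk < 2))
    return(.bin_fit(NA, NA, NA, FALSE, FALSE, "single_level_group", inp$n))
  switch(engine,
         fast = .fit_fast(inp, sigma_init),
         fast_full = .fit_full(inp, sigma_init),
         glmer = .fit_glmer(data, spec, inp))
}

.bin_fit <- function(est, se, z, converged, singular, reason, n_obs,
                     beta = NULL, sigma = NULL, u = NULL) {
  structure(list(estimate = est, se = se, z = z, converged = converged,
                 singular = singular, reason = reason, n_obs = n_obs,
                 beta = beta, sigma = sigma, u = u),
            class = "bin_model_fit")
}

#' @export
print.bin_model_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<bin_model_fit> estimate %.4f (SE %.4f), z = %.3f%s, n = %d\n",
                x$estimate, x$se, x$z,
                if (x$singular) " [singular]" else "", x$n_obs))
  } else {
    cat(sprintf("<bin_model_fit> not converged (%s), n = %d\n",
                x$reason, x$n_obs))
  }
  invisible(x)
}

.fit_fast <- function(inp, sigma_init = NULL, ctrl = NULL) {
  K <- length(inp$qk)
  warm <- !is.null(sigma_init)
  if (!warm) sigma_init <- rep(0.5, K)
  if (length(sigma_init) != K) sigma_init <- rep(sigma_init[1], K)
  if (is.null(ctrl)) ctrl <- list(max_eval = 250, tol = 2e-6,
                                  step = if (warm) 0.2 else 0.3,
                                  final_tol = 1e-12)
  if (is.null(ctrl$final_tol)) ctrl$final_tol <- 1e-12
  G <- if (K) matrix(as.integer(inp$G), ncol = K) else matrix(0L, inp$n, 0)
  Xr <- if (K) matrix(inp$Xr, ncol = K) else matrix(0, inp$n, 0)
  res <- glmm_fit_cpp(inp$y, inp$X, G, Xr, as.integer(inp$qk),
                      as.numeric(sigma_init), FALSE,
                      ctrl$max_eval, ctrl$tol, ctrl$step, ctrl$final_tol)
  if (!res$converged) {
    reason <- if (isTRUE(res$separation)) "separation" else "no_convergence"
    return(.bin_fit(NA, NA, NA, FALSE, FALSE, reason, inp$n))
  }
  est <- res$beta[inp$focal_col]
  se <- res$se[inp$focal_col]
  sigma <- as.numeric(res$sigma)
  names(sigma) <- inp$term_names
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(inp$X)
  .bin_fit(est, se, est / se, TRUE, any(sigma < 1e-3), NA_character_,
           inp$n, beta = beta, sigma = sigma, u = res$u)
}

.fit_full <- function(inp, sigma_init = NULL) {
  K <- length(inp$qk)
  if (is.null(sigma_init)) sigma_init <- rep(0.5, K)
  if (length(sigma_init) != K) sigma_init <- rep(sigma_init[1], K)
  G <- if (K) matrix(as.integer(inp$G), ncol = K) else matrix(0L, inp$n, 0)
  Xr <- if (K) matrix(inp$Xr, ncol = K) else matrix(0, inp$n, 0)
  res <- glmm_fit_full_cpp(inp$y, inp$X, G, Xr, as.integer(inp$qk),
                           as.numeric(sigma_init))
  if (!res$converged) {
    reason <- if (isTRUE(res$separation)) "separation" else "no_convergence"
    return(.bin_fit(NA, NA, NA, FALSE, FALSE, reason, inp$n))
  }
  est <- res$beta[inp$focal_col]
  se <- res$se[inp$focal_col]
  sigma <- as.numeric(res$sigma)
  names(sigma) <- inp$term_names
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(inp$X)
  .bin_fit(est, se, est / se, TRUE, any(sigma < 1e-3), NA_character_,
           inp$n, beta = beta, sigma = sigma, u = res$u)
}

.fit_glmer <- function(data, spec, inp) {
  df <- data[!is.na(data[[spec$response]]), , drop = FALSE]
  df$.y <- as.numeric(df[[spec$response]])
  fixed_terms <- character(0)
  if (!is.null(spec$fixed)) {
    base <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
    for (v in base) df[[paste0(".c_", v)]] <- .sum_code(df[[v]])[, 1]
    fixed_terms <- vapply(spec$fixed, function(trm) {
      paste(paste0(".c_", strsplit(trm, ":", fixed = TRUE)[[1]]),
            collapse = ":")
    }, character(1))
  }
  for (trm in spec$random_terms) {
    if (!is.na(trm$slope)) {
      sl <- paste0(".c_", trm$slope)
      if (!sl %in% names(df)) df[[sl]] <- .sum_code(df[[trm$slope]])[, 1]
    }
  }
  rnd <- vapply(spec$random_terms, function(trm) {
    grp <- trm$group
    if (is.na(trm$slope)) sprintf("(1 | %s)", grp)
    else if (trm$intercept) sprintf("(1 + .c_%s || %s)", trm$slope, grp)
    else sprintf("(0 + .c_%s | %s)", trm$slope, grp)
  }, character(1))
  rhs <- paste(c(if (length(fixed_terms)) fixed_terms else "1", rnd),
               collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(form, data = df, family = binomial,
                  control = lme4::glmerControl(calc.derivs = FALSE)))),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(.bin_fit(NA, NA, NA, FALSE, FALSE, "no_convergence", inp$n))
  co <- summary(fit)$coefficients
  focal_name <- if (spec$focal == "(Intercept)") "(Intercept)" else {
    nm <- paste(paste0(".c_", strsplit(spec$focal, ":", fixed = TRUE)[[1]]),
                collapse = ":")
    rownames(co)[match(nm, rownames(co))]
  }
  est <- co[focal_name, "Estimate"]
  se <- co[focal_name, "Std. Error"]
  if (!is.finite(est) || !is.finite(se) || abs(est) > 12)
    return(.bin_fit(NA, NA, NA, FALSE, FALSE, "separation", inp$n))
  vc <- lme4::VarCorr(fit)
  sigma <- sqrt(unlist(lapply(vc, function(m) diag(m))))
  .bin_fit(est, se, est / se, TRUE, any(sigma < 1e-3), NA_character_,
           inp$n, beta = lme4::fixef(fit), sigma = sigma)
}

#' Scan an analysis window bin by bin
#'
#' Fits the per-bin model across an ordered sequence of contiguous time
#' bins and applies the fallback convention for inestimable bins: when a
#' bin's model does not converge or cannot be computed (e.g. no variation
#' in the response in a cell), that bin inherits the estimate, SE and `z`
#' used at the previous bin; a failure at the first bin yields
#' `(estimate, z) = (0, 0)`.  Inherited bins are flagged `carried`.
#'
#' @param data Binned look data: one row per trial x bin, with a `bin`
#'   column (see [bin_looks()]) and the columns named in `spec`.
#' @param spec A [bin_model_spec()].
#' @param bins Integer vector of bins to scan (default: all bins present,
#'   in ascending order).
#' @param engine Fitting engine, see [fit_bin_model()].
#' @return A tibble with one row per bin: `bin`, `estimate`, `se`, `z`,
#'   `converged`, `singular`, `carried`, `n_obs`, `reason`.
#' @export
scan_window <- function(data, spec, bins = NULL, engine = c("fast", "glmer")) {
  engine <- match.arg(engine)
  .assert(!is.null(data$bin), "`data` must have a `bin` column")
  if (is.null(bins)) bins <- sort(unique(data$bin))
  .assert(length(bins) >= 1, "empty scan window")
  prep <- .scan_prep(data, spec, bins)
  .scan_fit(prep, engine = engine, data = data, spec = spec)
}

# Precompute per-bin model inputs (rows, compacted group indices, cell row
# lists) once; permutation loops then only swap the response vector or the
# fixed-design columns before refitting, avoiding all data-frame work.
.scan_prep <- function(data, spec, bins) {
  inp <- .build_glmm_inputs(data, spec)
  kept <- which(!is.na(data[[spec$response]]))
  bin_of_row <- data$bin[kept]
  K <- length(inp$qk)
  sub <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    idx <- which(bin_of_row == bins[i])
    s <- list(y = inp$y[idx],
              X = inp$X[idx, , drop = FALSE],
              G = if (K) inp$G[idx, , drop = FALSE] else NULL,
              Xr = if (K) inp$Xr[idx, , drop = FALSE] else NULL,
              qk = inp$qk, term_names = inp$term_names,
              cell = inp$cell[idx], focal_col = inp$focal_col,
              n = length(idx), idx = idx)
    if (K && s$n > 0) {
      for (k in seq_len(K)) {
        f <- factor(s$G[, k])
        s$G[, k] <- as.integer(f) - 1L
        s$qk[k] <- nlevels(f)
      }
      s$G <- matrix(as.integer(s$G), ncol = K)
      s$Xr <- matrix(s$Xr, ncol = K)
    }
    s$cell_rows <- split(seq_len(s$n), s$cell)
    sub[[i]] <- s
  }
  list(bins = bins, sub = sub, kept = kept, spec = spec, p = ncol(inp$X))
}

# Fast estimability check on precomputed cell row lists.
.quick_estimable <- function(s) {
  if (s$n == 0) return("empty")
  sy <- sum(s$y)
  if (sy == 0 || sy == s$n) return("no_variation")
  for (rows in s$cell_rows) {
    syc <- sum(s$y[rows])
    if (syc == 0 || syc == length(rows)) return("cell_no_variation")
  }
  NULL
}

.scan_fit <- function(prep, engine = "fast", data = NULL, spec = NULL,
                      sigma_start = NULL) {
  bins <- prep$bins
  nb <- length(bins)
  out <- tibble(
    bin = bins, estimate = NA_real_, se = NA_real_, z = NA_real_,
    converged = FALSE, singular = FALSE, carried = FALSE,
    n_obs = 0L, reason = NA_character_)
  used_est <- 0; used_se <- NA_real_; used_z <- 0
  sigma_warm <- sigma_start
  sigmas <- vector("list", nb)
  for (i in seq_len(nb)) {
    s <- prep$sub[[i]]
    K <- length(s$qk)
    bad <- .quick_estimable(s)
    fit <- if (!is.null(bad)) {
      .bin_fit(NA, NA, NA, FALSE, FALSE, bad, s$n)
    } else if (K && any(s$qk < 2)) {
      .bin_fit(NA, NA, NA, FALSE, FALSE, "single_level_group", s$n)
    } else if (engine == "fast") {
      .fit_fast(s, sigma_init = sigma_warm)
    } else {
      .fit_glmer(data[data$bin == bins[i] &
                        !is.na(data[[spec$response]]), , drop = FALSE],
                 spec, s)
    }
    if (fit$converged) {
      used_est <- fit$estimate; used_se <- fit$se; used_z <- fit$z
      if (engine == "fast" && !is.null(fit$sigma)) {
        sigma_warm <- pmax(unname(fit$sigma), 0.05)
        sigmas[[i]] <- sigma_warm
      }
      out$estimate[i] <- fit$estimate; out$se[i] <- fit$se; out$z[i] <- fit$z
      out$converged[i] <- TRUE; out$singular[i] <- fit$singular
    } else {
      out$estimate[i] <- used_est; out$se[i] <- used_se; out$z[i] <- used_z
      out$carried[i] <- TRUE; out$reason[i] <- fit$reason
    }
    out$n_obs[i] <- fit$n_obs
  }
  attr(out, "sigmas") <- sigmas
  out
}

# Minimal scan used inside permutation loops: returns only the per-bin z
# series (with carry-forward applied), skipping tibble construction.
# `sigma_bins` supplies per-bin warm starts (e.g. the observed scan's
# variance estimates), which shortens the variance optimisation.
.scan_z <- function(prep, sigma_bins = NULL) {
  nb <- length(prep$bins)
  z <- numeric(nb)
  used_z <- 0
  sigma_warm <- NULL
  for (i in seq_len(nb)) {
    s <- prep$sub[[i]]
    bad <- .quick_estimable(s)
    if (is.null(bad) && (!length(s$qk) || all(s$qk >= 2))) {
      init <- if (!is.null(sigma_bins) && !is.null(sigma_bins[[i]]))
        sigma_bins[[i]] else sigma_warm
      # warm-started, with a shorter variance search than the observed
      # scan; the residual optimizer noise on z is well below the tie
      # guard applied when counting null statistics
      fit <- .fit_fast(s, sigma_init = init,
                       ctrl = list(max_eval = 60, tol = 1e-5, step = 0.1,
                                   final_tol = 1e-9))
      if (fit$converged) {
        used_z <- fit$z
        if (!is.null(fit$sigma)) sigma_warm <- pmax(unname(fit$sigma), 0.05)
      }
    }
    z[i] <- used_z
  }
  z
}

#' Exact-likelihood logit fit with one random intercept (reference fitter)
#'
#' Maximises the exact marginal likelihood of a binomial-logit model with a
#' single random intercept by adaptive-free Gauss-Hermite quadrature, with
#' the random-effect SD profiled on a grid.  Intended as an independent
#' reference for validating the Laplace fitter on small data sets, not for
#' production use (it is slow and limited to one grouping factor).
#'
#' @param data,spec As in [fit_bin_model()]; `spec` must contain exactly one
#'   random intercept term and no random slopes.
#' @param sigma_grid Grid of candidate random-intercept SDs.
#' @param nodes Number of Gauss-Hermite nodes.
#' @return A list with `beta`, `sigma`, `loglik`, `estimate`, `se`, `z`.
#' @export
fit_bin_exact <- function(data, spec, sigma_grid = seq(0, 3, by = 0.05),
                          nodes = 40) {
  inp <- .build_glmm_inputs(data, spec)
  .assert(length(inp$qk) == 1 && all(inp$Xr == 1),
          "exact fitter supports exactly one random intercept term")
  gh <- .gauss_hermite(nodes)
  g <- inp$G[, 1]
  groups <- split(seq_len(inp$n), g)
  negll <- function(beta, sigma) {
    eta0 <- drop(inp$X %*% beta)
    shift <- sqrt(2) * sigma * gh$nodes
    total <- 0
    for (rows in groups) {
      lp <- vapply(shift, function(s) {
        e <- eta0[rows] + s
        sum(inp$y[rows] * e - log1p(exp(e)))
      }, numeric(1))
      m <- max(lp)
      total <- total + m + log(sum(gh$weights * exp(lp - m)) / sqrt(pi))
    }
    -total
  }
  p <- ncol(inp$X)
  best <- list(val = Inf)
  beta0 <- rep(0, p)
  for (s in sigma_grid) {
    op <- optim(beta0, function(b) negll(b, s), method = "BFGS")
    if (op$value < best$val)
      best <- list(val = op$value, beta = op$par, sigma = s)
    beta0 <- op$par
  }
  h <- .num_hessian(function(b) negll(b, best$sigma), best$beta)
  se <- sqrt(diag(solve(h)))
  est <- best$beta[inp$focal_col]
  list(beta = setNames(best$beta, colnames(inp$X)), sigma = best$sigma,
       loglik = -best$val, estimate = est, se = se[inp$focal_col],
       z = est / se[inp$focal_col])
}

# Golub-Welsch nodes/weights for the physicists' Hermite weight exp(-x^2)
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- a
  J[cbind(i + 1, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

.num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h * h)
  }
  H
}
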