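#' Cubic B-spline basis for the frequency smooth
#'
#' Builds the design matrix of the penalized smooth of stimulus
#' mid-frequency: a cubic B-spline basis with `n_basis` functions, interior
#' knots at quantiles of the observed frequencies and boundary knots at the
#' data extremes. Being a B-spline basis it forms a partition of unity
#' (rows sum to 1), so the constant function — the intercept — lies in its
#' span and is left unpenalized by the difference penalty.
#'
#' @param freqs numeric vector of frequencies (kHz); at least 2 distinct
#'   values.
#' @param n_basis number of basis functions (`>= 4` for a cubic spline).
#' @param degree spline degree (3 = cubic).
#' @param knots,boundary optional explicit interior/boundary knots; by
#'   default taken from `freqs` (quantiles / range). Supply these when
#'   evaluating the basis of an existing fit at new points.
#' @return an `length(freqs) x n_basis` matrix with attributes `knots`,
#'   `boundary` and `degree` for re-evaluation.
#' @export
build_spline_basis <- function(freqs, n_basis = 8L, degree = 3L,
                               knots = NULL, boundary = NULL) {
  if (n_basis < degree + 1L)
    stop("n_basis must be at least degree + 1 (4 for a cubic spline)")
  if (is.null(boundary)) boundary <- range(freqs)
  if (length(unique(freqs)) < 2L && is.null(knots))
    stop("need at least 2 distinct frequencies to build a smooth")
  n_inner <- n_basis - degree - 1L
  if (is.null(knots)) {
    knots <- if (n_inner > 0L)
      as.numeric(quantile(freqs, probs = seq_len(n_inner) / (n_inner + 1L)))
    else numeric(0)
    # quantile ties would create coincident knots; nudge them apart
    eps <- diff(boundary) * 1e-8
    knots <- pmin(pmax(knots, boundary[1L] + eps), boundary[2L] - eps)
    if (n_inner > 1L) knots <- knots + seq_len(n_inner) * 0 +
        cumsum(c(0, diff(knots) == 0)) * eps
  }
  B <- splines::bs(freqs, knots = knots, degree = degree,
                   Boundary.knots = boundary, intercept = TRUE)
  B <- matrix(as.numeric(B), nrow = length(freqs))
  attr(B, "knots") <- knots
  attr(B, "boundary") <- boundary
  attr(B, "degree") <- degree
  B
}

# First-difference (P-spline) penalty matrix for k spline coefficients.
# Annihilates constant coefficient vectors, so the intercept direction is
# never shrunk and the smooth collapses to a flat line as lambda grows.
spline_penalty <- function(k) {
  if (k < 2L) return(matrix(0, k, k))
  D <- diff(diag(k), differences = 1L)
  crossprod(D)
}

# Penalized IRLS for binomial regression: maximize the binomial
# log-likelihood minus 0.5 * beta' P beta. Returns the coefficient vector,
# deviance, effective degrees of freedom (trace of the hat matrix) and
# convergence/separation flags. If the fit diverges (complete separation),
# a ridge of 1e-6 is added to all coefficients and the fit restarted.
pirls <- function(X, y, P, max_iter = 200L, tol = 1e-8) {
  run <- function(P) {
    pen_dev <- function(beta, mu)
      binomial_deviance(y, mu) + drop(crossprod(beta, P %*% beta))
    beta <- rep(0, ncol(X))
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    pd <- pen_dev(beta, mu)
    edf_of <- function(mu) {
      w <- pmax(mu * (1 - mu), 1e-12)
      XtW <- t(X * w)
      sum(diag(solve(XtW %*% X + P, XtW %*% X)))
    }
    finish <- function(converged, it) {
      list(ok = TRUE, beta = beta, deviance = binomial_deviance(y, mu),
           edf = edf_of(mu), fitted = pmin(pmax(mu, 1e-12), 1 - 1e-12),
           eta = eta, converged = converged, iter = it)
    }
    for (it in seq_len(max_iter)) {
      # Fisher scoring step on the clamped mean (glm-style), then step
      # halving on the penalized deviance so iterations are monotone even
      # under complete separation
      mu_c <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      w <- mu_c * (1 - mu_c)
      z <- eta + (y - mu_c) / w
      XtW <- t(X * w)
      prop <- tryCatch(drop(solve(XtW %*% X + P, XtW %*% z)),
                       error = function(e) NULL)
      if (is.null(prop) || any(!is.finite(prop))) return(list(ok = FALSE))
      step <- 1
      repeat {
        cand <- beta + step * (prop - beta)
        eta_c <- drop(X %*% cand)
        mu_new <- plogis(eta_c)
        pd_new <- pen_dev(cand, mu_new)
        if (is.finite(pd_new) && pd_new <= pd + 1e-12) break
        step <- step / 2
        if (step < 1e-10) return(finish(FALSE, it))
      }
      done <- abs(pd - pd_new) < tol * (abs(pd_new) + 0.1)
      beta <- cand; eta <- eta_c; mu <- mu_new; pd <- pd_new
      if (done) return(finish(TRUE, it))
    }
    finish(FALSE, max_iter)
  }
  res <- run(P)
  # a fitted logit beyond +-20 means some observation is modeled with
  # probability within ~2e-9 of 0 or 1: empirical separation, the
  # unpenalized optimum is at infinity
  if (!isTRUE(res$ok) || max(abs(res$eta)) > 20) {
    warning("IRLS diverged (likely separation); refitting with a 1e-6 ridge",
            call. = FALSE)
    res <- run(P + diag(1e-6, ncol(X)))
    if (!isTRUE(res$ok)) stop("penalized IRLS failed even with ridge fallback")
    res$separation <- TRUE
  } else {
    res$separation <- FALSE
  }
  res
}

# Held-out deviance over deterministic folds: rows are ordered by
# frequency and dealt round-robin into folds, so every fold spans the
# tested range and the assignment is reproducible without touching the
# RNG. Predictions are made on the linear predictor with the same cap as
# the fitting code so a saturated training fit pays a large (finite)
# price on held-out responses it gets wrong.
cv_deviance <- function(X, y, pen, lambda_grid, ord, n_folds = 5L) {
  n <- length(y)
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(n_folds), n)
  vapply(lambda_grid, function(lam) {
    tot <- 0
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      fit <- tryCatch(
        suppressWarnings(pirls(X[tr, , drop = FALSE], y[tr], lam * pen)),
        error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      eta <- drop(X[!tr, , drop = FALSE] %*% fit$beta)
      eta <- pmin(pmax(eta, -30), 30)
      tot <- tot + binomial_deviance(y[!tr], plogis(eta))
    }
    tot
  }, 0)
}

binomial_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Assemble design matrix + penalty for the recognition model.
recognition_design <- function(freq, notes, note_levels, n_basis,
                               include_notes, basis_attrs = NULL,
                               smooth = "shared") {
  if (n_basis == 0L) {
    B <- matrix(1, length(freq), 1L)
    attr(B, "knots") <- numeric(0)
    attr(B, "boundary") <- range(freq)
    attr(B, "degree") <- 0L
  } else if (is.null(basis_attrs)) {
    B <- build_spline_basis(freq, n_basis = n_basis)
  } else {
    B <- build_spline_basis(freq, n_basis = n_basis,
                            knots = basis_attrs$knots,
                            boundary = basis_attrs$boundary,
                            degree = basis_attrs$degree)
  }
  k <- ncol(B)
  if (smooth == "by_note" && include_notes) {
    Xs <- do.call(cbind, lapply(note_levels, function(l) B * (notes == l)))
    colnames(Xs) <- paste0("s", rep(note_levels, each = k), "_", seq_len(k))
    X <- Xs
    Pb <- spline_penalty(k)
    Pblocks <- replicate(length(note_levels), Pb, simplify = FALSE)
    pen <- block_diag(Pblocks)
    n_note_cols <- 0L
  } else {
    N <- NULL
    n_note_cols <- 0L
    if (include_notes && length(note_levels) > 1L) {
      N <- vapply(note_levels[-1L], function(l) as.numeric(notes == l),
                  numeric(length(notes)))
      colnames(N) <- paste0("note", note_levels[-1L])
      n_note_cols <- ncol(N)
    }
    X <- if (is.null(N)) B else cbind(B, N)
    pen <- block_diag(list(spline_penalty(k), diag(0, n_note_cols)))
  }
  list(X = X, pen = pen, basis = B, n_note_cols = n_note_cols)
}

block_diag <- function(mats) {
  mats <- mats[vapply(mats, ncol, 0L) > 0L]
  if (!length(mats)) return(matrix(0, 0L, 0L))
  sizes <- vapply(mats, ncol, 0L)
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(ncol(m))
    out[idx, idx] <- m
    at <- at + ncol(m)
  }
  out
}

#' Fit a per-population recognition surface
#'
#' Models the probability of a positive phonotactic response as a function
#' of stimulus mid-frequency and note number on the logit scale:
#' `logit p = f(frequency) + note_offset(k)`, where `f` is a penalized
#' cubic B-spline smooth and the note offsets are unpenalized additive
#' shifts (reference level = the lowest tested note count, offset 0). The
#' penalized binomial likelihood is maximized by iteratively reweighted
#' least squares. The smoothing parameter is chosen over a log-spaced
#' grid by 5-fold cross-validated deviance (default; folds assigned
#' deterministically by interleaving the frequency order, so fits are
#' reproducible), by UBRE/AIC (`D + 2 edf`), by GCV, by matching a
#' target effective degrees of freedom, or fixed by the caller.
#' Out-of-sample validation is the default because binary phonotaxis
#' data with a quasi-separated note variant (zero approaches for a
#' foreign call) make every in-sample criterion favor a near-
#' interpolating smooth.
#'
#' The note effect is tested by a likelihood-ratio test against the same
#' model without note offsets, fitted at the identical smoothing
#' parameter, referred to a chi-square with (note levels - 1) degrees of
#' freedom.
#'
#' @param trials trial table (see [read_trials_csv()]); may contain several
#'   populations, in which case `population` selects one.
#' @param population population id to fit; default: the single population
#'   present.
#' @param n_basis number of B-spline basis functions (0 gives the
#'   degenerate intercept-only model).
#' @param lambda_policy `"cv"` (default), `"ubre"`, `"gcv"`, `"fixed_df"`
#'   (choose lambda so the smooth's effective df is closest to
#'   `target_df`), or `"fixed"` (use `lambda`).
#' @param n_folds folds for `lambda_policy = "cv"`.
#' @param lambda smoothing parameter when `lambda_policy = "fixed"`.
#' @param target_df target effective df for `"fixed_df"`.
#' @param include_notes include the additive note-offset terms.
#' @param smooth `"shared"` (one smooth for all note levels, default) or
#'   `"by_note"` (a separate penalized smooth per note level; no offsets,
#'   no likelihood-ratio note test).
#' @param lambda_grid grid searched by `"gcv"` / `"fixed_df"`.
#' @param min_trials minimum number of trials required.
#' @return an object of class `"recognition_fit"`; see
#'   [summary.recognition_fit()], [predict_curves()].
#' @export
fit_recognition <- function(trials, population = NULL, n_basis = 8L,
                            lambda_policy = c("cv", "ubre", "gcv",
                                              "fixed_df", "fixed"),
                            lambda = NULL, target_df = 4, n_folds = 5L,
                            include_notes = TRUE,
                            smooth = c("shared", "by_note"),
                            lambda_grid = 10^seq(-4, 4, by = 0.5),
                            min_trials = 20L) {
  lambda_policy <- match.arg(lambda_policy)
  smooth <- match.arg(smooth)
  trials <- validate_trials(trials)
  pops <- unique(trials$population)
  if (is.null(population)) {
    if (length(pops) > 1L)
      stop("multiple populations present; specify 'population'")
    population <- pops
  }
  d <- trials[trials$population == population, , drop = FALSE]
  if (nrow(d) < min_trials)
    stop("population '", population, "' has ", nrow(d),
         " trials; need at least ", min_trials)
  y <- d$response
  if (length(unique(y)) < 2L)
    stop("population '", population,
         "' has only one response class; cannot fit")
  note_levels <- sort(unique(d$stimulus_notes))
  if (include_notes && smooth == "shared" && length(note_levels) < 2L)
    include_notes <- FALSE

  des <- recognition_design(d$stimulus_freq_khz, d$stimulus_notes,
                            note_levels, n_basis, include_notes,
                            smooth = smooth)
  fit_at <- function(lam) {
    res <- pirls(des$X, y, lam * des$pen)
    res$lambda <- lam
    res
  }
  n <- length(y)
  if (lambda_policy == "fixed") {
    if (is.null(lambda)) stop("lambda_policy = 'fixed' requires lambda")
    best <- fit_at(lambda)
  } else if (n_basis == 0L) {
    best <- fit_at(0)
    best$lambda <- 0
  } else if (lambda_policy == "cv") {
    cvs <- cv_deviance(des$X, y, des$pen, lambda_grid,
                       order(d$stimulus_freq_khz), n_folds)
    best <- fit_at(lambda_grid[which.min(cvs)])
  } else {
    # grid search quietly; any separation warning is re-raised once by the
    # final fit at the selected lambda
    cands <- suppressWarnings(lapply(lambda_grid, fit_at))
    score <- if (lambda_policy == "ubre") {
      vapply(cands, function(r) r$deviance + 2 * r$edf, 0)
    } else if (lambda_policy == "gcv") {
      vapply(cands, function(r) n * r$deviance / (n - r$edf)^2, 0)
    } else {
      nfix <- des$n_note_cols
      vapply(cands, function(r) abs((r$edf - nfix) - target_df), 0)
    }
    best <- fit_at(cands[[which.min(score)]]$lambda)
  }

  null_dev <- binomial_deviance(y, mean(y))
  k_spline <- ncol(des$basis)
  if (smooth == "by_note" && include_notes) {
    spl <- best$beta
    offs <- setNames(rep(NA_real_, length(note_levels)),
                     paste0("note", note_levels))
  } else {
    spl <- best$beta[seq_len(k_spline)]
    offs <- setNames(numeric(length(note_levels)),
                     paste0("note", note_levels))
    if (des$n_note_cols > 0L)
      offs[-1L] <- best$beta[k_spline + seq_len(des$n_note_cols)]
  }

  fit <- list(
    population = population,
    n_trials = n,
    note_levels = note_levels,
    note_offsets = offs,
    spline_coefficients = spl,
    smoothing_lambda = best$lambda,
    edf = best$edf,
    deviance = best$deviance,
    null_deviance = null_dev,
    deviance_explained = deviance_explained_value(best$deviance, null_dev),
    converged = best$converged,
    separation = best$separation,
    smooth = smooth,
    n_basis = n_basis,
    include_notes = include_notes,
    basis_attrs = list(knots = attr(des$basis, "knots"),
                       boundary = attr(des$basis, "boundary"),
                       degree = attr(des$basis, "degree")),
    freq_range = range(d$stimulus_freq_khz),
    fitted = best$fitted,
    data = d,
    note_effect_pvalue = NA_real_,
    note_effect_stat = NA_real_,
    note_effect_df = NA_integer_
  )
  class(fit) <- "recognition_fit"

  if (include_notes && smooth == "shared" && length(note_levels) > 1L) {
    reduced <- fit_recognition(d, population = population, n_basis = n_basis,
                               lambda_policy = "fixed", lambda = best$lambda,
                               include_notes = FALSE, min_trials = min_trials)
    nt <- note_effect_test(fit, reduced)
    fit$note_effect_pvalue <- nt$p_value
    fit$note_effect_stat <- nt$statistic
    fit$note_effect_df <- nt$df
    fit$reduced_deviance <- reduced$deviance
  }
  fit
}

# deviance-explained arithmetic shared by the fit and the exported helper
deviance_explained_value <- function(model_deviance, null_deviance,
                                     tol = 1e-3) {
  de <- 1 - model_deviance / null_deviance
  if (de < -tol)
    stop("model deviance exceeds null deviance; not a nested comparison")
  min(max(de, 0), 1)
}

#' Proportion of null deviance explained by a recognition fit
#'
#' The GAM analogue of R-squared reported as "explained variance":
#' `1 - D_model / D_null`, clamped to `[0, 1]` (an error is raised if the
#' model deviance exceeds the null deviance beyond tolerance).
#'
#' @param fit a `"recognition_fit"`, or a model deviance (number).
#' @param null_deviance the null deviance; defaults to the fit's own.
#' @return proportion in `[0, 1]`.
#' @export
deviance_explained <- function(fit, null_deviance = NULL) {
  if (inherits(fit, "recognition_fit")) {
    if (is.null(null_deviance)) null_deviance <- fit$null_deviance
    return(deviance_explained_value(fit$deviance, null_deviance))
  }
  if (is.null(null_deviance)) stop("supply null_deviance")
  deviance_explained_value(fit, null_deviance)
}

#' Likelihood-ratio test for the note-number effect
#'
#' Compares a recognition fit with note offsets to the nested fit without
#' them (same data, same smoothing parameter, so the smooth cancels). The
#' statistic `deviance(reduced) - deviance(full)` is referred to a
#' chi-square with (note levels - 1) degrees of freedom; only the
#' unpenalized note offsets are counted.
#'
#' @param full fit with note offsets.
#' @param reduced the same model without them.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
note_effect_test <- function(full, reduced) {
  stat <- reduced$deviance - full$deviance
  # deviances are only resolved to the IRLS convergence tolerance (and a
  # ridge fallback perturbs them by ~1e-5), so allow a small negative slop
  if (stat < -1e-3 * (abs(full$deviance) + 1))
    stop("reduced model fits better than full beyond tolerance; ",
         "models are not nested")
  stat <- max(stat, 0)
  df <- length(full$note_levels) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / k` for `k` population comparisons; with the study design
#' `alpha = 0.05, k = 8` this is 0.00625.
#'
#' @param alpha nominal level in `(0, 1]`.
#' @param k number of comparisons (positive integer).
#' @return the corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, k = 8L) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (!is.finite(k) || k < 1 || k != round(k))
    stop("k must be a positive integer")
  alpha / k
}

# Evaluate the linear predictor of a recognition fit at new covariates.
recognition_eta <- function(object, freq, notes) {
  ba <- object$basis_attrs
  des <- recognition_design(freq, notes, object$note_levels,
                            object$n_basis, object$include_notes,
                            basis_attrs = ba, smooth = object$smooth)
  if (object$smooth == "by_note" && object$include_notes) {
    drop(des$X %*% object$spline_coefficients)
  } else {
    eta <- drop(des$basis %*% object$spline_coefficients)
    unname(eta + object$note_offsets[match(notes, object$note_levels)])
  }
}

#' @export
predict.recognition_fit <- function(object, newdata = NULL,
                                    type = c("response", "link"),
                                    allow_extrapolation = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- qlogis(object$fitted)
    return(if (type == "response") object$fitted else eta)
  }
  freq <- newdata$stimulus_freq_khz
  notes <- newdata$stimulus_notes
  if (is.null(freq) || is.null(notes))
    stop("newdata needs columns stimulus_freq_khz and stimulus_notes")
  if (!allow_extrapolation &&
      (any(freq < object$freq_range[1L] - 1e-9) ||
       any(freq > object$freq_range[2L] + 1e-9)))
    stop("frequencies outside the observed range [",
         signif(object$freq_range[1L], 4), ", ",
         signif(object$freq_range[2L], 4),
         "] kHz; set allow_extrapolation = TRUE to override")
  if (!all(notes %in% object$note_levels))
    stop("untested note level(s): ",
         paste(setdiff(notes, object$note_levels), collapse = ", "))
  eta <- recognition_eta(object, freq, notes)
  if (type == "response") plogis(eta) else eta
}

#' Predicted response curves per note variant
#'
#' Evaluates the fitted response probability over a frequency grid, one
#' curve per tested note level — the per-population figure the
#' relative-response statistic integrates.
#'
#' @param fit a `"recognition_fit"`.
#' @param grid ascending frequency grid (kHz); default: 256 uniform points
#'   over the observed stimulus range.
#' @param n_grid grid size when `grid` is `NULL`.
#' @param allow_extrapolation permit grid points outside the observed
#'   range.
#' @return an object of class `"response_curves"`: list with `grid`,
#'   `prob` (matrix, one column per note level), `note_levels`,
#'   `population`.
#' @export
predict_curves <- function(fit, grid = NULL, n_grid = 256L,
                           allow_extrapolation = FALSE) {
  if (is.null(grid))
    grid <- seq(fit$freq_range[1L], fit$freq_range[2L], length.out = n_grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("frequency grid must be strictly increasing")
  prob <- vapply(fit$note_levels, function(l)
    predict(fit, data.frame(stimulus_freq_khz = grid, stimulus_notes = l),
            allow_extrapolation = allow_extrapolation),
    numeric(length(grid)))
  colnames(prob) <- paste0("note", fit$note_levels)
  out <- list(grid = grid, prob = prob, note_levels = fit$note_levels,
              population = fit$population)
  class(out) <- "response_curves"
  out
}

#' @export
print.recognition_fit <- function(x, ...) {
  cat("Recognition surface fit: population '", x$population, "' (",
      x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  deviance explained : %.1f%%\n", 100 * x$deviance_explained))
  if (!is.na(x$note_effect_pvalue))
    cat(sprintf("  note effect        : LRT = %.3f, df = %d, p = %.4g\n",
                x$note_effect_stat, x$note_effect_df, x$note_effect_pvalue))
  cat(sprintf("  smoothing lambda   : %.4g (edf %.2f)\n",
              x$smoothing_lambda, x$edf))
  if (x$separation) cat("  (separation detected; ridge fallback used)\n")
  invisible(x)
}

#' @export
summary.recognition_fit <- function(object, ...) {
  out <- list(
    population = object$population,
    n_trials = object$n_trials,
    note_levels = object$note_levels,
    note_offsets = object$note_offsets,
    smoothing_lambda = object$smoothing_lambda,
    edf = object$edf,
    deviance = object$deviance,
    null_deviance = object$null_deviance,
    deviance_explained = object$deviance_explained,
    note_effect_pvalue = object$note_effect_pvalue,
    note_effect_stat = object$note_effect_stat,
    note_effect_df = object$note_effect_df,
    converged = object$converged,
    separation = object$separation
  )
  class(out) <- "summary.recognition_fit"
  out
}

#' @export
print.summary.recognition_fit <- function(x, ...) {
  cat("Population:", x$population, "-", x$n_trials, "trials\n")
  cat("Note offsets (logit scale, reference =",
      paste0(x$note_levels[1L], "):\n"))
  print(round(x$note_offsets, 3))
  cat(sprintf("Deviance: %.2f on null %.2f (%.1f%% explained)\n",
              x$deviance, x$null_deviance, 100 * x$deviance_explained))
  if (!is.na(x$note_effect_pvalue))
    cat(sprintf("Note effect: LRT = %.3f, df = %d, p = %.4g\n",
                x$note_effect_stat, x$note_effect_df, x$note_effect_pvalue))
  cat(sprintf("Smoothing: lambda = %.4g, edf = %.2f\n",
              x$smoothing_lambda, x$edf))
  invisible(x)
}

#' @export
coef.recognition_fit <- function(object, ...) {
  c(setNames(object$spline_coefficients,
             paste0("spline", seq_along(object$spline_coefficients))),
    object$note_offsets[-1L])
}

#' @export
logLik.recognition_fit <- function(object, ...) {
  structure(-object$deviance / 2, df = object$edf, class = "logLik")
}

#' @export
residuals.recognition_fit <- function(object,
                                      type = c("deviance", "response"),
                                      ...) {
  type <- match.arg(type)
  y <- object$data$response
  mu <- object$fitted
  if (type == "response") return(y - mu)
  sign(y - mu) * sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' @export
simulate.recognition_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_trials
  out <- as.data.frame(replicate(nsim, rbinom(n, 1L, object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.recognition_fit <- function(x, n_grid = 256L, ...) {
  plot(predict_curves(x, n_grid = n_grid), ...)
}

#' @export
plot.response_curves <- function(x, col = NULL, lty = 1, lwd = 2,
                                 xlab = "Stimulus mid-frequency (kHz)",
                                 ylab = "P(phonotactic response)",
                                 main = NULL, ...) {
  if (is.null(col)) col <- seq_along(x$note_levels) + 1L
  if (is.null(main)) main <- x$population
  matplot(x$grid, x$prob, type = "l", col = col, lty = lty, lwd = lwd,
          ylim = c(0, 1), xlab = xlab, ylab = ylab, main = main, ...)
  legend("topright", legend = paste(x$note_levels, "notes"),
         col = col, lty = lty, lwd = lwd, bty = "n")
  invisible(x)
}
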