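make_null_trials <- function(n, p = 0.5, pop = "X", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(population = pop,
             stimulus_notes = sample(c(2L, 3L, 4L), n, replace = TRUE),
             stimulus_freq_khz = runif(n, 2.9, 3.3),
             response = rbinom(n, 1L, p))
}

test_that("B-spline basis is a partition of unity and matches de Boor", {
  set.seed(2)
  x <- runif(200, 2.8, 3.5)
  B <- build_spline_basis(x, n_basis = 8L)
  expect_equal(ncol(B), 8L)
  expect_true(all(abs(rowSums(B) - 1) < 1e-12))
  expect_error(build_spline_basis(rep(3, 10)), "distinct")

  # independent de Boor recursion on the same extended knot vector
  knots <- attr(B, "knots")
  bd <- attr(B, "boundary")
  full <- c(rep(bd[1L], 4L), knots, rep(bd[2L], 4L))
  for (xx in c(knots[2L], 3.0, 3.21)) {
    ours <- build_spline_basis(xx, n_basis = 8L, knots = knots,
                               boundary = bd)
    deboor <- vapply(0:7, function(i) de_boor_basis(xx, full, i, 3L), 0)
    expect_equal(as.numeric(ours), deboor, tolerance = 1e-12)
  }
})

test_that("degenerate intercept-only model recovers the response mean", {
  d <- data.frame(population = "X",
                  stimulus_notes = 2L,
                  stimulus_freq_khz = rep(c(3.0, 3.2), 50L),
                  response = rep(c(0L, 1L), each = 50L))
  f <- fit_recognition(d, n_basis = 0L, include_notes = FALSE)
  expect_equal(unique(round(f$fitted, 10)), 0.5)
  expect_equal(f$deviance_explained, 0)
})

test_that("known note offsets are recovered at large n", {
  sim <- simulate_trials("big", own_note = 4L, center_freq = 3.1,
                         note_offsets = c(`2` = -2.5, `3` = -1.0, `4` = 0),
                         n_trials = 2000L, seed = 77)
  f <- fit_recognition(sim$trials)
  # offsets are relative to the reference (2 notes): true values 1.5, 2.5
  expect_equal(unname(f$note_offsets["note3"]), 1.5, tolerance = 0.3)
  expect_equal(unname(f$note_offsets["note4"]), 2.5, tolerance = 0.3)
  expect_true(f$converged)
})

test_that("fitted mean matches the sample positive fraction", {
  for (seed in 1:3) {
    d <- make_null_trials(120, p = 0.35, seed = seed)
    f <- fit_recognition(d)
    expect_equal(mean(f$fitted), mean(d$response), tolerance = 1e-6)
  }
})

test_that("note-effect LRT arithmetic and nesting checks", {
  full <- list(deviance = 10, note_levels = c(2L, 3L, 4L))
  expect_equal(note_effect_test(full, list(deviance = 10))$p_value, 1)
  p <- note_effect_test(full, list(deviance = 15.99))
  expect_equal(p$statistic, 5.99)
  expect_equal(p$p_value, 0.05, tolerance = 1e-3)
  expect_error(note_effect_test(full, list(deviance = 9.5)), "nested")
})

test_that("deviance explained is the standard proportion", {
  expect_equal(deviance_explained(100, 100), 0)
  expect_equal(deviance_explained(0, 100), 1)
  expect_equal(deviance_explained(40, 100), 0.6)
  expect_error(deviance_explained(110, 100), "exceeds")
})

test_that("bonferroni threshold arithmetic", {
  expect_identical(bonferroni_threshold(0.05, 8L), 0.00625)
  expect_equal(bonferroni_threshold(0.05, 1L), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4L), 0.0025)
  expect_error(bonferroni_threshold(0, 8L), "alpha")
  expect_error(bonferroni_threshold(0.05, 0L), "k must be")
})

test_that("predicted curves respect additive offsets and the data range", {
  sim <- simulate_trials("pop", own_note = 4L, center_freq = 3.1,
                         note_offsets = c(`3` = -1, `4` = 0),
                         n_trials = 400L, seed = 3)
  f <- fit_recognition(sim$trials)
  cv <- predict_curves(f, n_grid = 64L)
  # additive logit offsets keep the curves ordered everywhere
  expect_true(all(cv$prob[, "note4"] > cv$prob[, "note3"]))
  expect_true(all(cv$prob > 0 & cv$prob < 1))
  expect_error(predict(f, data.frame(stimulus_freq_khz = 5,
                                     stimulus_notes = 4L)),
               "outside the observed range")
  # in-sample prediction reproduces fitted values
  expect_equal(predict(f, f$data), f$fitted, tolerance = 1e-12)
})

test_that("a unimodal response surface peaks near the true center", {
  sim <- simulate_trials("pop", own_note = 4L, center_freq = 3.1,
                         note_offsets = c(`2` = -1.5, `3` = -0.5, `4` = 0),
                         n_trials = 2000L, freq_halfwidth = 0.3, seed = 5)
  f <- fit_recognition(sim$trials)
  cv <- predict_curves(f, n_grid = 512L)
  peak <- cv$grid[which.max(cv$prob[, "note4"])]
  expect_lt(abs(peak - 3.1), 0.1)
})

test_that("large lambda flattens the smooth to a constant", {
  sim <- simulate_trials("pop", own_note = 4L, center_freq = 3.1,
                         note_offsets = c(`3` = -1, `4` = 0),
                         n_trials = 300L, seed = 8)
  f <- fit_recognition(sim$trials, lambda_policy = "fixed", lambda = 1e9)
  cv <- predict_curves(f, n_grid = 100L)
  expect_lt(diff(range(qlogis(cv$prob[, "note4"]))), 1e-3)
})

test_that("shuffling responses destroys a strong note effect", {
  sim <- simulate_trials("pop", own_note = 4L, center_freq = 3.1,
                         note_offsets = c(`2` = -3, `3` = -1.5, `4` = 0),
                         n_trials = 400L, seed = 13)
  f0 <- fit_recognition(sim$trials)
  expect_lt(f0$note_effect_pvalue, 1e-6)
  set.seed(99)
  ps <- replicate(60, {
    d <- sim$trials
    d$response <- sample(d$response)
    fit_recognition(d, lambda_policy = "fixed",
                    lambda = f0$smoothing_lambda)$note_effect_pvalue
  })
  expect_gt(median(ps), 0.2)
})

test_that("separation triggers the ridge fallback with a warning", {
  d <- data.frame(population = "X",
                  stimulus_notes = rep(c(2L, 4L), each = 30L),
                  stimulus_freq_khz = runif(60, 3, 3.4),
                  response = rep(c(0L, 1L), each = 30L))
  expect_warning(f <- fit_recognition(d, lambda_policy = "fixed",
                                      lambda = 1e-2),
                 "separation|ridge")
  expect_true(f$separation)
})

test_that("single-class data and tiny samples are rejected", {
  d <- make_null_trials(30, p = 0.5, seed = 1)
  d$response <- 1L
  expect_error(fit_recognition(d), "one response class")
  expect_error(fit_recognition(make_null_trials(10, seed = 1)),
               "at least 20")
})

test_that("recognition_fit methods round out the model object", {
  d <- make_null_trials(100, p = 0.4, seed = 6)
  f <- fit_recognition(d)
  expect_output(print(f), "Recognition surface")
  expect_s3_class(summary(f), "summary.recognition_fit")
  expect_length(residuals(f), 100L)
  expect_equal(dim(simulate(f, nsim = 2L, seed = 1)), c(100L, 2L))
  expect_s3_class(logLik(f), "logLik")
  expect_true(all(is.finite(coef(f))))
})

test_that("the by-note smooth variant fits and predicts", {
  sim <- simulate_trials("pop", own_note = 4L, center_freq = 3.1,
                         note_offsets = c(`3` = -1, `4` = 0),
                         n_trials = 500L, seed = 10)
  f <- fit_recognition(sim$trials, smooth = "by_note")
  cv <- predict_curves(f, n_grid = 32L)
  expect_equal(dim(cv$prob), c(32L, 2L))
  expect_true(all(cv$prob >= 0 & cv$prob <= 1))
  # note-4 stimuli elicit stronger mean response under the true surface
  expect_gt(mean(cv$prob[, "note4"]), mean(cv$prob[, "note3"]))
})

test_that("independent GAM cross-check agrees on the note effect direction", {
  skip_if_not_installed("mgcv")
  sim <- simulate_trials("pop", own_note = 4L, center_freq = 3.1,
                         note_offsets = c(`2` = -2, `3` = -1, `4` = 0),
                         n_trials = 1500L, seed = 17)
  f <- fit_recognition(sim$trials)
  d <- sim$trials
  d$note <- factor(d$stimulus_notes)
  g <- mgcv::gam(response ~ note + s(stimulus_freq_khz),
                 family = stats::binomial(), data = d)
  co <- stats::coef(g)[c("note3", "note4")]
  expect_equal(unname(f$note_offsets[c("note3", "note4")]),
               unname(co), tolerance = 0.25)
})
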