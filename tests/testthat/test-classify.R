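test_that("the stratified split reproduces the 70/30 design", {
  man <- simulate_manifest(generator_config(n_participants = 1,
                                            trials_per_condition = 10,
                                            seed = 12L))
  sp <- split_trials(man, 0.7, seed = 1)
  expect_length(sp$train, 112)
  expect_length(sp$test, 48)
  per_cell <- table(man$cond_id[man$trial_id %in% sp$train])
  expect_true(all(per_cell == 7))
  expect_identical(sp, split_trials(man, 0.7, seed = 1))

  tiny <- data.frame(trial_id = c("a", "b"), participant = 1, cond_id = 1)
  sp2 <- split_trials(tiny, 0.5, seed = 1)
  expect_length(sp2$train, 1)
  expect_length(sp2$test, 1)
})

test_that("penalty extremes behave as the objective dictates", {
  # overlapping classes keep the unregularized MLE finite and well-posed
  tc <- toy_classes(n = 20, p = 3, delta = 1)
  big <- fit_lasso_logistic(tc$x, tc$y, 1e6)
  expect_true(all(big$beta == 0))
  expect_equal(stats::plogis(big$beta0), mean(tc$y), tolerance = 1e-6)

  m0 <- fit_lasso_logistic(tc$x, tc$y, 0)
  g <- stats::glm(tc$y ~ tc$x, family = stats::binomial)
  expect_lt(max(abs(c(m0$beta0, m0$beta) - stats::coef(g))), 1e-4)
  expect_error(fit_lasso_logistic(tc$x, rep(1, 20), 1),
               class = "sts_degenerate_label_error")
})

test_that("the solution is a local minimum of the penalized objective", {
  tc <- toy_classes(n = 40, p = 6, delta = 2, seed = 9)
  lam <- 3
  m <- fit_lasso_logistic(tc$x, tc$y, lam)
  obj <- lasso_objective(m$beta0, m$beta, tc$x, tc$y, lam)
  expect_lte(obj, lasso_objective(0, rep(0, 6), tc$x, tc$y, lam))
  set.seed(2)
  for (i in 1:20) {
    pert <- m$beta + rnorm(6, 0, 0.01)
    expect_gte(lasso_objective(m$beta0, pert, tc$x, tc$y, lam) + 1e-8, obj)
  }
})

test_that("sparsity is non-increasing in the penalty", {
  tc <- toy_classes(n = 60, p = 10, delta = 1.5, seed = 3)
  nz <- vapply(default_lambda_grid(), function(l) {
    sum(fit_lasso_logistic(tc$x, tc$y, l)$beta != 0)
  }, numeric(1))
  expect_true(all(diff(nz) >= 0))  # grid is decreasing in lambda
})

test_that("permuted labels yield chance-level accuracy", {
  set.seed(14)
  acc <- replicate(30, {
    x <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- c(sample(rep(0:1, 10)), sample(rep(0:1, 10)))
    m <- fit_lasso_logistic(x[1:20, ], y[1:20], 2)
    mean(predict(m, x[21:40, ])$label == y[21:40])
  })
  expect_equal(mean(acc), 0.5, tolerance = 0.06)
})

test_that("lambda selection maximizes CV F-score with a sparser tie-break", {
  expect_equal(as.numeric(select_lambda(matrix(0, 4, 1), c(0, 1, 0, 1),
                                        grid = 0.5)), 0.5)
  tc <- toy_classes(n = 60, p = 8, delta = 4, seed = 6)
  lam <- select_lambda(tc$x, tc$y, folds = 5, seed = 2)
  cv <- attr(lam, "cv_table")
  expect_gt(max(cv$mean_f), 0.9)
  # tie rule: among equal scores the largest lambda is returned
  best <- max(cv$mean_f)
  expect_equal(as.numeric(lam), max(cv$lambda[cv$mean_f >= best - 1e-9]))
})

test_that("prediction follows the logistic closed form and tie rule", {
  m <- structure(list(beta0 = 0, beta = c(a = 0, b = 0), lambda = 1,
                      variable = NA), class = "sts_lasso")
  p <- predict(m, c(1, 1))
  expect_equal(p$prob, 0.5)
  expect_equal(p$label, 1L)

  m2 <- structure(list(beta0 = 0, beta = c(a = 1, b = 0), lambda = 1,
                       variable = NA), class = "sts_lasso")
  expect_equal(predict(m2, c(log(3), 5))$prob, 0.75)
  probs <- predict(m2, cbind(seq(-2, 2, 0.5), 0))$prob
  expect_true(all(diff(probs) > 0))
  expect_error(predict(m2, c(1, 2, 3)), class = "sts_data_error")
})

test_that("precision/recall/F match their definitions", {
  m <- evaluate_predictions(c(rep(1, 10), rep(0, 10)),
                            c(rep(1, 9), 0, 1, rep(0, 9)))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f_score, 0.9)
  perf <- evaluate_predictions(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perf[c("precision", "recall", "f_score")]),
               c(precision = 1, recall = 1, f_score = 1))
  expect_warning(none <- evaluate_predictions(c(0, 0), c(1, 0)),
                 "no positive predictions")
  expect_equal(none$precision, 0)
  # harmonic-mean consistency: P = 1.00, R = 0.99 -> F ~ 0.995
  expect_equal(2 * 1 * 0.99 / 1.99, 0.995, tolerance = 5e-4)
})

test_that("separability matches hand arithmetic and its invariances", {
  s <- separability(c(-1, 1, 2, 4), c(0, 0, 1, 1))
  expect_equal(s$eta, 1.125)
  expect_equal(s$sigma_w2, 2)
  expect_equal(s$sigma_b2, 2.25)
  same <- separability(c(1, 2, 3, 1, 2, 3), rep(0:1, each = 3))
  expect_equal(same$eta, 0)
  shifted <- separability(c(-1, 1, 2, 4) + 10, c(0, 0, 1, 1))
  expect_equal(shifted$eta, 1.125)
  scaled <- separability(3 * c(-1, 1, 2, 4), c(0, 0, 1, 1))
  expect_equal(scaled$eta, 1.125)
  expect_warning(inf <- separability(c(1, 1, 2, 2), c(0, 0, 1, 1)),
                 "infinite")
  expect_identical(inf$eta, Inf)
  expect_error(separability(c(1, 2, 3), c(0, 0, 0)), class = "sts_data_error")
})

test_that("coefficient aggregation groups by feature source", {
  zero <- stats::setNames(rep(0, 100), feature_names())
  mk <- function(beta) {
    structure(list(beta0 = 0, beta = beta, lambda = 1, variable = NA),
              class = "sts_lasso")
  }
  models <- list(stats::setNames(replicate(4, mk(zero), simplify = FALSE),
                                 control_variables()))
  expect_true(all(aggregate_coefficients(models) == 0))

  b <- zero
  b["TA_seg2_mean"] <- -2
  models[[1]]$up_speed <- mk(b)
  agg <- aggregate_coefficients(models)
  expect_equal(agg["up_speed", "TA"], 2 / 12)  # mean |beta| over 12 TA features
  expect_equal(sum(agg != 0), 1)
})

test_that("models survive JSON serialization", {
  tc <- toy_classes(n = 20, p = 3)
  m <- fit_lasso_logistic(tc$x, tc$y, 1, variable = "up_speed")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$beta0, m$beta0)
  expect_equal(m2$variable, "up_speed")
})
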