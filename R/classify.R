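#' Stratified train/test split of a trial manifest
#'
#' Splits trials within every (participant, condition) cell, so train and
#' test sets are balanced over the 16 control conditions. With the default
#' 10 trials per cell and `train_frac = 0.7` this gives the 7/3 split used
#' throughout the analysis.
#'
#' @param manifest Data frame with `trial_id`, `participant`, `cond_id`.
#' @param train_frac Fraction of each cell assigned to training.
#' @param seed Integer seed for the within-cell sampling.
#' @return List with character vectors `train` and `test` of trial ids.
#' @export
split_trials <- function(manifest, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    sts_error("sts_config_error", "train_frac must be in (0, 1)")
  }
  cells <- split(manifest$trial_id,
                 interaction(manifest$participant, manifest$cond_id,
                             drop = TRUE))
  train <- character(0)
  adjusted <- FALSE
  with_seed(seed, {
    for (ids in cells) {
      n <- length(ids)
      k <- round(train_frac * n)
      if (k < 1 || k >= n) {
        adjusted <- TRUE
        k <- min(max(k, 1), n - 1)
        if (n == 1) k <- 1
      }
      train <- c(train, sample(ids, k))
    }
  })
  if (adjusted) {
    warning("some cells too small for the requested split; used a proportional split")
  }
  list(train = train, test = setdiff(manifest$trial_id, train))
}

#' Default regularization grid
#'
#' Penalty weights on the total (un-normalized) log-loss scale of the
#' fitting objective; see [fit_lasso_logistic()].
#'
#' @return Decreasing numeric vector.
#' @export
default_lambda_grid <- function() {
  sort(10^seq(-1, 1.3, length.out = 8), decreasing = TRUE)
}

#' Fit an L1-regularized logistic classifier
#'
#' Minimizes the penalized negative log-likelihood
#' `-sum[y log p + (1-y) log(1-p)] + lambda * sum(|beta_j|)` with an
#' unpenalized intercept, via `glmnet` (whose per-observation penalty is
#' `lambda / N`). Features are assumed already standardized; no internal
#' rescaling is applied.
#'
#' @param x Standardized feature matrix (trials x p).
#' @param y Binary labels (1 = fast).
#' @param lambda Penalty weight on the total-log-loss scale, >= 0.
#' @param variable Optional name of the control variable being modeled.
#' @return Object of class `sts_lasso`: `beta0`, `beta` (named p-vector),
#'   `lambda`, `variable`.
#' @export
fit_lasso_logistic <- function(x, y, lambda, variable = NA_character_) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    sts_error("sts_degenerate_label_error",
              "both classes must be present in the training labels")
  }
  if (lambda < 0) sts_error("sts_config_error", "lambda must be >= 0")
  n <- nrow(x)
  lg <- lambda / n
  # descending path into the target improves glmnet's convergence at
  # small / zero penalties
  path <- sort(unique(c(lg, lg + c(0.5, 0.1, 0.02, 0.005))),
               decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", lambda = path,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e7)
  cf <- as.numeric(stats::coef(fit, s = lg, exact = TRUE, x = x, y = y))
  structure(list(beta0 = cf[1],
                 beta = stats::setNames(cf[-1], colnames(x)),
                 lambda = lambda, variable = variable,
                 n_train = n),
            class = "sts_lasso")
}

#' Penalized logistic objective
#'
#' The fitting objective of [fit_lasso_logistic()]: total negative
#' log-likelihood plus `lambda` times the L1 norm of the slope
#' coefficients (intercept unpenalized).
#'
#' @param beta0 Intercept.
#' @param beta Coefficient vector.
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param lambda Penalty weight.
#' @return Scalar objective value.
#' @export
lasso_objective <- function(beta0, beta, x, y, lambda) {
  eta <- beta0 + as.matrix(x) %*% beta
  # numerically stable -[y*log(p) + (1-y)*log(1-p)]
  nll <- sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  nll + lambda * sum(abs(beta))
}

#' @export
print.sts_lasso <- function(x, ...) {
  cat("<sts_lasso>", if (!is.na(x$variable)) x$variable else "",
      sprintf(" lambda=%.4g, %d/%d nonzero coefficients\n",
              x$lambda, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' Predict control-variable state
#'
#' `p = logistic(beta0 + x' beta)`; probabilities at or above 0.5 are
#' labeled fast (1).
#'
#' @param object An `sts_lasso` model.
#' @param newdata Standardized feature matrix or single vector.
#' @param ... Unused.
#' @return Data frame with columns `prob` and `label`.
#' @export
predict.sts_lasso <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta)) {
    sts_error("sts_data_error", "feature dimension does not match the model")
  }
  prob <- as.numeric(stats::plogis(object$beta0 + newdata %*% object$beta))
  data.frame(prob = prob, label = as.integer(prob >= 0.5))
}

# F-score without warnings, for internal CV use
f_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

#' Select the penalty by stratified cross-validated F-score
#'
#' K-fold cross-validation stratified on the labels; the penalty
#' maximizing the mean held-out F-score is returned, with ties broken
#' towards the larger (sparser) penalty.
#'
#' @param x Standardized feature matrix.
#' @param y Binary labels.
#' @param grid Candidate penalties (total-log-loss scale).
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return Selected penalty; the CV table is attached as attribute
#'   `"cv_table"`.
#' @export
select_lambda <- function(x, y, grid = default_lambda_grid(), folds = 5,
                          seed = 1L) {
  if (length(grid) == 0) sts_error("sts_config_error", "empty lambda grid")
  x <- as.matrix(x)
  y <- as.numeric(y)
  grid <- sort(unique(grid), decreasing = TRUE)
  if (length(grid) == 1) return(grid)
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  scores <- matrix(NA_real_, folds, length(grid))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    n_tr <- sum(tr)
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          lambda = grid / n_tr, standardize = FALSE,
                          thresh = 1e-10, maxit = 1e6)
    prob <- stats::predict(fit, x[!tr, , drop = FALSE], type = "response")
    for (j in seq_along(grid)) {
      jj <- which.min(abs(fit$lambda - grid[j] / n_tr))
      scores[k, j] <- f_score(as.integer(prob[, jj] >= 0.5), y[!tr])
    }
  }
  if (all(is.na(scores))) {
    sts_error("sts_degenerate_label_error", "all CV folds were degenerate")
  }
  mean_f <- colMeans(scores, na.rm = TRUE)
  best <- max(mean_f)
  # ties (within numerical noise) resolved towards the sparser model
  chosen <- grid[which(mean_f >= best - 1e-9)[1]]
  structure(chosen, cv_table = data.frame(lambda = grid, mean_f = mean_f))
}

#' Precision, recall and F-score of binary predictions
#'
#' The fast state (1) is the positive class. `F = 2PR/(P+R)`, defined as 0
#' when `P + R = 0`; precision is 0 (with a warning) when nothing is
#' predicted positive.
#'
#' @param pred Predicted labels (0/1).
#' @param truth True labels (0/1).
#' @return List with `precision`, `recall`, `f_score` and the confusion
#'   counts.
#' @export
evaluate_predictions <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    sts_error("sts_data_error", "predictions and labels must align and be nonempty")
  }
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  if (tp + fp == 0) {
    warning("no positive predictions; precision set to 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f_score = f,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Class separability of a single feature
#'
#' Fisher-style variance ratio `eta = sigma_B^2 / sigma_W^2` for balanced
#' binary classes, with `sigma_W^2 = (s0^2 + s1^2)/2` and `sigma_B^2 =
#' ((mu0 - mu)^2 + (mu1 - mu)^2)/2` where `mu` is the overall mean. Sample
#' (n-1) variances are used. Larger values mean easier classification;
#' `eta < 1` means within-class spread dominates.
#'
#' @param values Feature values.
#' @param labels Binary class labels (0/1), both classes with >= 2 values.
#' @return List with `eta` and its components (`sigma_w2`, `sigma_b2`,
#'   `mu0`, `mu1`, `mu_total`, `sd0`, `sd1`). `eta` is `Inf` (with a
#'   warning) when the within-class variance is zero.
#' @export
separability <- function(values, labels) {
  v0 <- values[labels == 0]
  v1 <- values[labels == 1]
  if (length(v0) < 2 || length(v1) < 2) {
    sts_error("sts_data_error",
              "need at least two values in each class for separability")
  }
  mu0 <- mean(v0); mu1 <- mean(v1); mu <- mean(values)
  sw2 <- (stats::var(v0) + stats::var(v1)) / 2
  sb2 <- ((mu0 - mu)^2 + (mu1 - mu)^2) / 2
  if (sw2 == 0) {
    warning("zero within-class variance; separability is infinite")
    eta <- Inf
  } else {
    eta <- sb2 / sw2
  }
  list(eta = eta, sigma_w2 = sw2, sigma_b2 = sb2, mu0 = mu0, mu1 = mu1,
       mu_total = mu, sd0 = stats::sd(v0), sd1 = stats::sd(v1))
}

# feature name -> coefficient source (segment-duration block or muscle)
feature_source <- function(nm) {
  ifelse(startsWith(nm, "dur_"), "len", sub("_.*$", "", nm))
}

#' Aggregate coefficient magnitudes across participants
#'
#' For each control variable, the mean absolute slope coefficient is
#' computed per feature source (the segment-duration block `len` and the
#' eight muscles) within each participant's model, then averaged across
#' participants -- the 4 x 9 contribution matrix.
#'
#' @param models List with one element per participant, each a named list
#'   of the four `sts_lasso` models (names = [control_variables()]).
#' @return 4 x 9 matrix, rows = control variables, columns = `len` then
#'   the muscles.
#' @export
aggregate_coefficients <- function(models) {
  sources <- c("len", sts_muscles())
  out <- matrix(0, 4, 9, dimnames = list(control_variables(), sources))
  for (v in control_variables()) {
    per_part <- vapply(models, function(pm) {
      b <- abs(pm[[v]]$beta)
      grp <- feature_source(names(b))
      vapply(sources, function(s) {
        if (any(grp == s)) mean(b[grp == s]) else 0
      }, numeric(1))
    }, numeric(9))
    out[v, ] <- rowMeans(per_part)
  }
  out
}

#' Train and evaluate the four control-variable classifiers
#'
#' Per participant (the default, matching per-participant reporting):
#' stratified 70/30 split over conditions, standardization fitted on the
#' training split, penalty selection by cross-validated F-score, one
#' L1-logistic model per control variable, and test-set
#' precision/recall/F. Separability `eta` is computed on the training
#' split for every feature each fitted model actually selected (nonzero
#' coefficient).
#'
#' @param features Feature data frame from [extract_dataset_features()]
#'   (or an `sts_feature_set`).
#' @param train_frac Training fraction of each (participant, condition)
#'   cell.
#' @param lambda_grid Candidate penalties for [select_lambda()].
#' @param folds CV folds for penalty selection.
#' @param seed Base seed for splits and CV folds.
#' @param per_participant Fit one model set per participant (`TRUE`) or a
#'   single pooled set (`FALSE`).
#' @return Object of class `sts_analysis`: per-participant fits (models,
#'   standardizer, split, test predictions), a per-participant metrics
#'   table, the cross-participant `summary` (mean and sd of P/R/F per
#'   variable), the selected-feature `eta_table`, and the aggregated
#'   coefficient matrix.
#' @export
run_sts_analysis <- function(features, train_frac = 0.7,
                             lambda_grid = default_lambda_grid(), folds = 5,
                             seed = 1L, per_participant = TRUE) {
  if (inherits(features, "sts_feature_set")) features <- features$features
  groups <- if (per_participant) unique(features$participant) else "pooled"
  fits <- list()
  metrics <- NULL
  eta_tab <- NULL
  for (g in groups) {
    fd <- if (per_participant) features[features$participant == g, ] else features
    sp <- split_trials(fd, train_frac, seed = mix_seed(seed, 31, g))
    tr <- fd[fd$trial_id %in% sp$train, ]
    te <- fd[fd$trial_id %in% sp$test, ]
    std <- fit_standardizer(feature_matrix(tr))
    xtr <- apply_standardizer(feature_matrix(tr), std)
    xte <- apply_standardizer(feature_matrix(te), std)
    models <- list()
    preds <- list()
    for (j in seq_along(control_variables())) {
      v <- control_variables()[j]
      lam <- select_lambda(xtr, tr[[v]], lambda_grid, folds,
                           seed = mix_seed(seed, 97, g, j))
      models[[v]] <- fit_lasso_logistic(xtr, tr[[v]], as.numeric(lam), v)
      pr <- predict(models[[v]], xte)
      preds[[v]] <- pr
      m <- evaluate_predictions(pr$label, te[[v]])
      metrics <- rbind(metrics, data.frame(
        participant = g, variable = v, lambda = as.numeric(lam),
        n_selected = sum(models[[v]]$beta != 0),
        precision = m$precision, recall = m$recall, f_score = m$f_score))
      sel <- names(models[[v]]$beta)[models[[v]]$beta != 0]
      for (f in sel) {
        eta_tab <- rbind(eta_tab, data.frame(
          participant = g, variable = v, feature = f,
          eta = separability(xtr[, f], tr[[v]])$eta))
      }
    }
    fits[[as.character(g)]] <- list(
      participant = g, models = models, standardizer = std, split = sp,
      test_ids = te$trial_id, predictions = preds)
  }
  summary_tab <- do.call(rbind, lapply(control_variables(), function(v) {
    mv <- metrics[metrics$variable == v, ]
    data.frame(variable = v,
               precision_mean = mean(mv$precision), precision_sd = stats::sd(mv$precision),
               recall_mean = mean(mv$recall), recall_sd = stats::sd(mv$recall),
               f_mean = mean(mv$f_score), f_sd = stats::sd(mv$f_score))
  }))
  structure(list(fits = fits, metrics = metrics, summary = summary_tab,
                 eta_table = eta_tab,
                 coefficients = aggregate_coefficients(
                   lapply(fits, `[[`, "models")),
                 per_participant = per_participant,
                 train_frac = train_frac, seed = seed),
            class = "sts_analysis")
}

#' @export
print.sts_analysis <- function(x, ...) {
  cat("<sts_analysis>", length(x$fits), "model set(s); test-set performance",
      "(mean +/- sd across participants):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s P %.2f+/-%.2f  R %.2f+/-%.2f  F %.2f+/-%.2f\n",
                s$variable[i], s$precision_mean[i], s$precision_sd[i],
                s$recall_mean[i], s$recall_sd[i], s$f_mean[i], s$f_sd[i]))
  }
  invisible(x)
}

#' Serialize a fitted classifier to JSON
#'
#' @param model An `sts_lasso`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(variable = model$variable, lambda = model$lambda,
                            beta0 = model$beta0, beta = as.list(model$beta),
                            n_train = model$n_train),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier serialized by [write_model_json()]
#'
#' @param path JSON file path.
#' @return An `sts_lasso`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beta0 = j$beta0, beta = unlist(j$beta), lambda = j$lambda,
                 variable = j$variable, n_train = j$n_train),
            class = "sts_lasso")
}
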