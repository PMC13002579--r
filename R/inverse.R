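#' Build per-condition prototype feature vectors
#'
#' The "classifier-inferred muscle activity" source: for every control
#' condition, the elementwise mean of the standardized training feature
#' vectors recorded under that condition.
#'
#' @param x Standardized training feature matrix (trials x 100).
#' @param cond_id Condition ids (1..16, see [condition_id()]) of the rows.
#' @return Object of class `sts_prototypes`: `mean` (16 x 100 matrix, NA
#'   rows for conditions absent from training) and `count`.
#' @export
build_prototypes <- function(x, cond_id) {
  x <- as.matrix(x)
  if (nrow(x) != length(cond_id)) {
    sts_error("sts_data_error", "one condition id per training row required")
  }
  proto <- matrix(NA_real_, 16, ncol(x),
                  dimnames = list(paste0("cond", 1:16), colnames(x)))
  count <- integer(16)
  for (ci in 1:16) {
    rows <- which(cond_id == ci)
    count[ci] <- length(rows)
    if (length(rows) > 0) proto[ci, ] <- colMeans(x[rows, , drop = FALSE])
  }
  structure(list(mean = proto, count = count), class = "sts_prototypes")
}

#' Infer the chair control condition for a target feature vector
#'
#' Runs the four binary classifiers independently and assembles their
#' fast/slow decisions into one 4-bit control condition.
#'
#' @param x Standardized 100-feature vector (or 1-row matrix).
#' @param models Named list of the four `sts_lasso` models.
#' @return An `sts_condition` (named 4-bit integer vector).
#' @export
infer_control <- function(x, models) {
  miss <- setdiff(control_variables(), names(models))
  if (length(miss) > 0) {
    sts_error("sts_data_error",
              paste("missing model(s):", paste(miss, collapse = ", ")))
  }
  bits <- vapply(control_variables(), function(v) {
    predict(models[[v]], x)$label
  }, integer(1))
  control_condition(bits[1], bits[2], bits[3], bits[4])
}

#' Normalized-distance similarity of a target to the inferred prototype
#'
#' Euclidean distances in the standardized 100-dimensional feature space
#' between the target vector and all 16 condition prototypes, normalized
#' by their sum. `s_inf` is the normalized distance to the prototype of
#' the estimated condition; `s_nt` is the mean of the 15 non-target
#' normalized distances, so `s_inf + 15 * s_nt = 1` identically.
#'
#' @param target Standardized 100-feature vector.
#' @param estimated The estimated condition (an `sts_condition`, 4-bit
#'   vector, or condition id 1..16).
#' @param prototypes An `sts_prototypes` from [build_prototypes()].
#' @return List with `s_inf`, `s_nt`, `est_id`, raw distances `d` and
#'   normalized distances `norm_d` (length 16).
#' @export
similarity <- function(target, estimated, prototypes) {
  est_id <- if (length(estimated) == 1) as.integer(estimated) else {
    b <- as_condition(estimated)
    condition_id(b[1], b[2], b[3], b[4])
  }
  if (est_id < 1 || est_id > 16) {
    sts_error("sts_data_error", "estimated condition id out of range")
  }
  if (anyNA(prototypes$mean)) {
    sts_error("sts_missing_prototype_error",
              "one or more conditions have no training prototype")
  }
  d <- sqrt(rowSums(sweep(prototypes$mean, 2, as.numeric(target))^2))
  if (sum(d) == 0) {
    sts_error("sts_data_error",
              "all prototype distances are zero; normalization undefined")
  }
  norm_d <- d / sum(d)
  s_inf <- unname(norm_d[est_id])
  list(s_inf = s_inf, s_nt = unname(mean(norm_d[-est_id])), est_id = est_id,
       d = unname(d), norm_d = unname(norm_d))
}

#' Wilcoxon rank-sum comparison of two similarity populations
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The p-value follows
#' `stats::wilcox.test` (exact for small tie-free samples, normal
#' approximation otherwise); `z` is always the tie-corrected,
#' continuity-corrected normal-approximation statistic.
#'
#' @param a,b Numeric samples (>= 2 values each).
#' @return List with `u` (Mann-Whitney U of `a`), `z`, `p`.
#' @export
compare_populations <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    sts_error("sts_data_error", "need at least two values per group")
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("all values tied; rank-sum test is uninformative")
    return(list(u = u, z = 0, p = 1))
  }
  mu <- n1 * n2 / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  list(u = u, z = z, p = p)
}

#' Offline inverse evaluation of the fitted classifiers
#'
#' For every test trial (the target): infer its control condition with the
#' four classifiers, build the condition prototypes from the training
#' split, and score how close the inferred condition's prototype lies to
#' the target relative to all 16 candidates ([similarity()]). Pooled
#' `s_inf` values are compared against the non-target baseline `s_nt` with
#' a rank-sum test.
#'
#' @param analysis An `sts_analysis` from [run_sts_analysis()].
#' @param features The same feature data frame the analysis was fitted on.
#' @return Object of class `sts_inverse`: per-trial `results` (estimated
#'   vs true condition, `s_inf`, `s_nt`), `test` (rank-sum z and p),
#'   and `summary` (means, sds, inference accuracy).
#' @export
evaluate_inverse <- function(analysis, features) {
  if (inherits(features, "sts_feature_set")) features <- features$features
  res <- NULL
  for (fit in analysis$fits) {
    fd <- if (analysis$per_participant) {
      features[features$participant == fit$participant, ]
    } else features
    tr <- fd[fd$trial_id %in% fit$split$train, ]
    te <- fd[fd$trial_id %in% fit$split$test, ]
    xtr <- apply_standardizer(feature_matrix(tr), fit$standardizer)
    xte <- apply_standardizer(feature_matrix(te), fit$standardizer)
    protos <- build_prototypes(xtr, tr$cond_id)
    for (i in seq_len(nrow(te))) {
      est <- infer_control(xte[i, ], fit$models)
      sim <- similarity(xte[i, ], est, protos)
      res <- rbind(res, data.frame(
        trial_id = te$trial_id[i], participant = fit$participant,
        true_cond = te$cond_id[i], est_cond = sim$est_id,
        correct = as.integer(sim$est_id == te$cond_id[i]),
        s_inf = sim$s_inf, s_nt = sim$s_nt))
    }
  }
  test <- compare_populations(res$s_inf, res$s_nt)
  structure(list(
    results = res, test = test,
    summary = list(s_inf_mean = mean(res$s_inf), s_inf_sd = stats::sd(res$s_inf),
                   s_nt_mean = mean(res$s_nt), s_nt_sd = stats::sd(res$s_nt),
                   accuracy = mean(res$correct), n_trials = nrow(res))
  ), class = "sts_inverse")
}

#' @export
print.sts_inverse <- function(x, ...) {
  s <- x$summary
  cat("<sts_inverse>", s$n_trials, "target trials\n")
  cat(sprintf("  S_INF %.3f +/- %.3f   S_NT %.3f +/- %.3f\n",
              s$s_inf_mean, s$s_inf_sd, s$s_nt_mean, s$s_nt_sd))
  cat(sprintf("  exact 4-bit inference accuracy %.2f\n", s$accuracy))
  cat(sprintf("  rank-sum |z| = %.2f, p = %.3g\n", abs(x$test$z), x$test$p))
  invisible(x)
}
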