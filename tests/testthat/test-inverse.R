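test_that("prototypes are per-condition means of training vectors", {
  x <- rbind(rep(0, 100), rep(2, 100), rep(5, 100))
  colnames(x) <- feature_names()
  pt <- build_prototypes(x, c(3, 3, 7))
  expect_equal(unname(pt$mean[3, ]), rep(1, 100))
  expect_equal(unname(pt$mean[7, ]), rep(5, 100))
  expect_equal(pt$count[c(3, 7)], c(2L, 1L))
  expect_true(anyNA(pt$mean[1, ]))
  expect_error(build_prototypes(x, c(1, 2)), class = "sts_data_error")
})

test_that("control inference assembles four thresholded predictions", {
  mk <- function(p) {
    b <- stats::setNames(rep(0, 2), c("a", "b"))
    structure(list(beta0 = stats::qlogis(p), beta = b, lambda = 1,
                   variable = NA), class = "sts_lasso")
  }
  models <- stats::setNames(lapply(c(0.9, 0.2, 0.7, 0.4), mk),
                            control_variables())
  est <- infer_control(c(0, 0), models)
  expect_equal(as.integer(est), c(1L, 0L, 1L, 0L))

  zero_models <- stats::setNames(lapply(rep(0.5, 4), mk), control_variables())
  expect_equal(as.integer(infer_control(c(0, 0), zero_models)),
               rep(1L, 4))  # 0.5 classifies as fast by the tie rule
  expect_error(infer_control(c(0, 0), models[1:3]), class = "sts_data_error")
})

test_that("similarity normalization follows its algebraic identities", {
  set.seed(33)
  protos <- build_prototypes(matrix(rnorm(16 * 100), 16, 100,
                                    dimnames = list(NULL, feature_names())),
                             1:16)
  # target equal to the estimated prototype
  s <- similarity(protos$mean[5, ], 5, protos)
  expect_equal(s$s_inf, 0)
  expect_equal(s$s_nt, 1 / 15, tolerance = 1e-12)
  # generic targets: distances sum to 1; S_INF + 15 S_NT = 1
  for (i in 1:20) {
    target <- rnorm(100)
    est <- sample(16, 1)
    s <- similarity(target, est, protos)
    expect_equal(sum(s$norm_d), 1, tolerance = 1e-12)
    expect_equal(s$s_inf + 15 * s$s_nt, 1, tolerance = 1e-12)
  }
  # equidistant prototypes: every normalized distance is 1/16
  eq <- structure(list(mean = diag(16) * 2, count = rep(1L, 16)),
                  class = "sts_prototypes")
  s2 <- similarity(rep(0, 16), 4, eq)
  expect_equal(s2$norm_d, rep(1 / 16, 16))
  expect_equal(s2$s_inf, 0.0625)
  # degenerate: all prototypes coincide with the target
  degen <- structure(list(mean = matrix(0, 16, 3), count = rep(1L, 16)),
                     class = "sts_prototypes")
  expect_error(similarity(c(0, 0, 0), 1, degen), class = "sts_data_error")
  # missing prototype refuses rather than imputes
  na_pt <- build_prototypes(matrix(rnorm(200), 2, 100), c(1, 2))
  expect_error(similarity(rnorm(100), 1, na_pt),
               class = "sts_missing_prototype_error")
})

test_that("rank-sum comparison matches exact enumeration on small samples", {
  r <- compare_populations(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  # exact two-sided p from enumerating all C(6,3) = 20 group assignments
  pool <- 1:6
  us <- apply(utils::combn(6, 3), 2, function(idx) {
    sum(rank(pool)[idx]) - 3 * 4 / 2
  })
  p_exact <- mean(abs(us - 4.5) >= abs(0 - 4.5))
  expect_equal(p_exact, 0.1)
  expect_equal(r$p, p_exact)

  same <- compare_populations(c(1, 2, 3), c(1, 2, 3))
  expect_lt(abs(same$z), 1e-8)
  expect_gt(same$p, 0.99)
  expect_warning(tied <- compare_populations(c(1, 1), c(1, 1)), "tied")
  expect_equal(tied$p, 1)
})

test_that("a well-separated pipeline infers conditions and ranks S_INF low", {
  res <- demo_pipeline()
  inv <- res$inverse
  expect_true(all(abs(inv$results$s_inf + 15 * inv$results$s_nt - 1) < 1e-12))
  # classifiers beat chance, so S_INF sits below the non-target baseline;
  # with only 16 test trials the rank-sum check is held at the 5% level
  # (the full-scale dataset is tested separately at 1%)
  expect_lt(inv$summary$s_inf_mean, inv$summary$s_nt_mean)
  expect_lt(inv$test$p, 0.05)
  # median below the uninformative 1/16 level for correctly inferred targets
  ok <- inv$results$correct == 1
  expect_gt(sum(ok), 0)
  expect_lt(stats::median(inv$results$s_inf[ok]), 1 / 16)
})

test_that("prototype counts follow the split design", {
  res <- demo_pipeline()
  fit <- res$analysis$fits[[1]]
  fd <- res$feature_set$features
  tr <- fd[fd$trial_id %in% fit$split$train, ]
  pt <- build_prototypes(apply_standardizer(feature_matrix(tr),
                                            fit$standardizer), tr$cond_id)
  expect_equal(pt$count, rep(3L, 16))  # round(0.7 * 4) = 3 per condition
})
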