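test_that("fold assignment partitions cases evenly and deterministically", {
  ids <- sprintf("c%02d", 1:14)
  f <- make_folds(ids, k_outer = 7, k_inner = 6, seed = 3)
  expect_setequal(f$outer$case_id, ids)
  expect_true(all(table(f$outer$outer_fold) == 2))
  f2 <- make_folds(ids, k_outer = 7, k_inner = 6, seed = 3)
  expect_identical(f$outer, f2$outer)
  expect_identical(f$inner, f2$inner)
  f3 <- make_folds(ids, k_outer = 7, k_inner = 6, seed = 4)
  expect_false(identical(f$outer, f3$outer))
  expect_error(make_folds(sprintf("c%d", 1:5), k_outer = 7), "at least 7")
  # balance within one case for non-divisible sizes
  f4 <- make_folds(sprintf("c%02d", 1:23), seed = 1)
  sizes <- table(f4$outer$outer_fold)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("inner folds partition each outer training set at the case level", {
  f <- make_folds(sprintf("c%02d", 1:30), seed = 9)
  for (o in 1:7) {
    train_cases <- f$outer$case_id[f$outer$outer_fold != o]
    inn <- f$inner[f$inner$outer_fold == o, ]
    expect_setequal(inn$case_id, train_cases)
    expect_setequal(unique(inn$inner_fold), 1:6)
    # no test case of the outer fold appears in its inner assignment
    expect_length(intersect(inn$case_id,
                            f$outer$case_id[f$outer$outer_fold == o]), 0)
  }
})

test_that("offset baseline adds exactly 5 mm Hg", {
  expect_equal(baseline_offset(35), 40)
  expect_equal(baseline_offset(0), 5)
  # on any dataset its MAE equals mean |gradient - 5|
  etco2 <- c(30, 34, 38, 42)
  grad <- c(3, 6, 9, 5)
  paco2 <- etco2 + grad
  expect_equal(error_metrics(paco2, baseline_offset(etco2))$mae, mean(abs(grad - 5)))
})

test_that("linear baseline is ordinary least squares on ETCO2 alone", {
  fit <- baseline_linear_fit(tibble::tibble(etco2 = c(30, 40), paco2 = c(36, 46)))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 6, tolerance = 1e-12)
  expect_equal(baseline_linear_predict(fit, 35), 41)
  expect_error(baseline_linear_fit(tibble::tibble(etco2 = rep(35, 5),
                                                  paco2 = 1:5)), "distinct")
  # normal-equations oracle on random sets
  withr::with_seed(41, {
    for (rep in 1:200) {
      n <- sample(5:50, 1)
      d <- tibble::tibble(etco2 = rnorm(n, 35, 3), paco2 = rnorm(n, 42, 4))
      f <- baseline_linear_fit(d)
      X <- cbind(1, d$etco2)
      beta <- solve(t(X) %*% X, t(X) %*% d$paco2)
      expect_equal(f$intercept, beta[1], tolerance = 1e-8)
      expect_equal(f$slope, beta[2], tolerance = 1e-8)
    }
  })
})

test_that("hyperparameter search honours its selection contract", {
  ft <- small_features()$features
  folds <- make_folds(ft$case_id, seed = 2)
  fn <- feature_names()
  predictors <- c(fn$continuous, fn$categorical)
  inner1 <- folds$inner[folds$inner$outer_fold == 1, ]
  train1 <- ft[ft$case_id %in% inner1$case_id, ]
  spec1 <- search_spec(budget = 1, nrounds = c(60, 120), seed = 8)
  res1 <- tune_and_train(train1, inner1, spec1, predictors)
  expect_equal(nrow(res1$trial_log), 1)
  expect_equal(res1$best$trial, 1)
  spec3 <- search_spec(budget = 3, nrounds = c(60, 120), seed = 8)
  res3 <- tune_and_train(train1, inner1, spec3, predictors)
  expect_equal(nrow(res3$trial_log), 3)
  expect_equal(res3$best$inner_mae, min(res3$trial_log$inner_mae))
})

test_that("a purely linear ETCO2 target is learnable to near-zero error", {
  withr::with_seed(6, {
    n <- 400
    ft <- tibble::tibble(etco2 = runif(n, 28, 42))
    ft$paco2 <- ft$etco2 + 5
  })
  m <- co2gap:::gbm_fit(ft["etco2"], ft$paco2,
                        list(max_depth = 4, learning_rate = 0.3,
                             nrounds = 300, reg_lambda = 1))
  mae <- mean(abs(ft$paco2 - co2gap:::gbm_predict(m, ft["etco2"])))
  expect_lt(mae, 0.5)
})

test_that("nested CV predicts every event once per model with case independence", {
  run <- small_run()
  cv <- run$cv
  ft <- run$features
  expect_equal(nrow(cv$predictions), 3 * nrow(ft))
  counts <- cv$predictions |>
    dplyr::count(event_id, model)
  expect_true(all(counts$n == 1))
  outer <- cv$folds$outer
  for (o in seq_len(cv$folds$k_outer)) {
    test_cases <- unique(cv$predictions$case_id[cv$predictions$outer_fold == o])
    train_cases <- outer$case_id[outer$outer_fold != o]
    expect_length(intersect(test_cases, train_cases), 0)
  }
  # scalers are refit per fold from that fold's training rows
  outer_of <- outer$outer_fold[match(ft$case_id, outer$case_id)]
  for (o in 1:2) {
    refit <- suppressWarnings(
      robust_scale_fit(ft[outer_of != o, ], feature_names()$continuous))
    expect_equal(cv$scalers[[o]]$stats, refit$stats)
  }
  expect_false(identical(cv$scalers[[1]]$stats$center,
                         cv$scalers[[2]]$stats$center))
})
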