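#' Case-grouped fold assignment for nested cross-validation
#'
#' Partitions surgical cases (never individual events) into `k_outer` outer
#' folds, and each outer fold's training cases into `k_inner` inner folds, so
#' that all events of a case share a fold and no case can appear on both sides
#' of any train/test split. Fold sizes are balanced within one case.
#'
#' @param case_ids Character vector of case identifiers (unique).
#' @param k_outer,k_inner Number of outer / inner folds.
#' @param seed Integer seed; assignment is deterministic given the seed.
#' @return A list of class `co2gap_folds` with `outer` (tibble `case_id`,
#'   `outer_fold`) and `inner` (tibble `outer_fold`, `case_id`, `inner_fold`,
#'   covering each outer fold's training cases).
#' @export
make_folds <- function(case_ids, k_outer = 7, k_inner = 6, seed = 1) {
  case_ids <- unique(case_ids)
  n <- length(case_ids)
  if (n < k_outer) stop_config("need at least ", k_outer, " cases, got ", n)
  set.seed(as.integer(seed))
  outer <- tibble::tibble(
    case_id = sample(case_ids),
    outer_fold = rep_len(seq_len(k_outer), n)
  ) |> dplyr::arrange(.data$case_id)
  inner <- purrr::map_dfr(seq_len(k_outer), function(o) {
    train_cases <- outer$case_id[outer$outer_fold != o]
    if (length(train_cases) < k_inner) {
      stop_config("outer fold ", o, " leaves fewer training cases than k_inner")
    }
    tibble::tibble(
      outer_fold = o,
      case_id = sample(train_cases),
      inner_fold = rep_len(seq_len(k_inner), length(train_cases))
    )
  }) |> dplyr::arrange(.data$outer_fold, .data$case_id)
  structure(list(outer = outer, inner = inner, k_outer = k_outer,
                 k_inner = k_inner, seed = as.integer(seed)),
            class = "co2gap_folds")
}

#' @export
print.co2gap_folds <- function(x, ...) {
  cat("<co2gap fold assignment>", nrow(x$outer), "cases,",
      x$k_outer, "outer x", x$k_inner, "inner folds (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Offset baseline: ETCO2 + 5 mm Hg
#'
#' The fixed-gradient rule of thumb; involves no fitting.
#'
#' @param etco2 ETCO2 window medians (mm Hg).
#' @return Predicted PaCO2 (mm Hg).
#' @export
baseline_offset <- function(etco2) etco2 + 5

#' Linear baseline on ETCO2 alone
#'
#' Ordinary least squares of PaCO2 on ETCO2 fitted on the training events of
#' the current outer fold only.
#'
#' @param train Data frame with `etco2` and `paco2`.
#' @return List with `slope`, `intercept`, and the `lm` fit.
#' @export
baseline_linear_fit <- function(train) {
  if (length(unique(train$etco2)) < 2) {
    stop_config("linear baseline needs >= 2 distinct ETCO2 values")
  }
  fit <- stats::lm(paco2 ~ etco2, data = train)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit = fit)
}

#' @rdname baseline_linear_fit
#' @param params Result of [baseline_linear_fit()].
#' @param etco2 ETCO2 values to predict for.
#' @export
baseline_linear_predict <- function(params, etco2) {
  params$intercept + params$slope * etco2
}

#' Hyperparameter search specification
#'
#' Seeded random search over the gradient-boosted tree regressor's main
#' hyperparameters; each trial is scored by its mean MAE across the inner
#' validation folds.
#'
#' @param budget Number of random trials (>= 1).
#' @param depth Integer range of tree depth.
#' @param learning_rate Range, sampled log-uniformly.
#' @param nrounds Integer range of boosting iterations.
#' @param reg_lambda Range of L2 leaf regularisation.
#' @param seed Seed for the trial sampler.
#' @return A list of class `co2gap_search_spec`.
#' @export
search_spec <- function(budget = 20, depth = c(3, 10),
                        learning_rate = c(0.01, 0.3), nrounds = c(100, 1000),
                        reg_lambda = c(1, 10), seed = 1) {
  if (!is_number(budget) || budget < 1) stop_config("`budget` must be >= 1")
  spec <- list(budget = as.integer(budget),
               depth = as.integer(check_pair(depth, "depth", lo = 1)),
               learning_rate = check_pair(learning_rate, "learning_rate", lo = 1e-6),
               nrounds = as.integer(check_pair(nrounds, "nrounds", lo = 1)),
               reg_lambda = check_pair(reg_lambda, "reg_lambda", lo = 0),
               seed = as.integer(seed))
  class(spec) <- "co2gap_search_spec"
  spec
}

sample_trials <- function(spec) {
  set.seed(spec$seed)
  tibble::tibble(
    trial = seq_len(spec$budget),
    max_depth = sample(seq(spec$depth[1], spec$depth[2]), spec$budget, replace = TRUE),
    learning_rate = exp(stats::runif(spec$budget, log(spec$learning_rate[1]),
                                     log(spec$learning_rate[2]))),
    nrounds = sample(seq(spec$nrounds[1], spec$nrounds[2]), spec$budget, replace = TRUE),
    reg_lambda = stats::runif(spec$budget, spec$reg_lambda[1], spec$reg_lambda[2])
  )
}

#' Tune and train the gradient-boosted regressor on one outer fold
#'
#' Evaluates `spec$budget` random hyperparameter configurations by mean MAE
#' across the inner validation folds, selects the minimiser, and retrains it
#' on the full outer training set.
#'
#' @param outer_train Feature rows of the outer training set (with `paco2`).
#' @param inner_assign Tibble `case_id`, `inner_fold` for these cases.
#' @param spec A [search_spec()].
#' @param predictors Character vector of predictor column names.
#' @return List with the trained `model`, `best` trial parameters, and the
#'   full `trial_log` (one row per trial with its inner MAE).
#' @export
tune_and_train <- function(outer_train, inner_assign, spec, predictors) {
  trials <- sample_trials(spec)
  fold_of <- inner_assign$inner_fold[match(outer_train$case_id, inner_assign$case_id)]
  if (anyNA(fold_of)) stop_config("inner assignment does not cover all training cases")
  k <- sort(unique(inner_assign$inner_fold))

  inner_mae <- vapply(seq_len(nrow(trials)), function(ti) {
    params <- as.list(trials[ti, ])
    maes <- vapply(k, function(f) {
      tr <- outer_train[fold_of != f, , drop = FALSE]
      va <- outer_train[fold_of == f, , drop = FALSE]
      if (nrow(va) == 0) return(NA_real_)
      m <- gbm_fit(tr[predictors], tr$paco2, params)
      mean(abs(va$paco2 - gbm_predict(m, va[predictors])))
    }, numeric(1))
    mean(maes, na.rm = TRUE)
  }, numeric(1))

  trials$inner_mae <- inner_mae
  best <- trials[which.min(trials$inner_mae), ]
  model <- gbm_fit(outer_train[predictors], outer_train$paco2, as.list(best))
  list(model = model, best = best, trial_log = trials)
}

#' Run the full case-grouped nested cross-validation
#'
#' For each outer fold: fits the two ETCO2 baselines and the tuned
#' gradient-boosted model on the training cases (robust-scaling continuous
#' features inside the fold), then predicts the held-out test events. Every
#' modeled event is predicted exactly once per model, always by a model whose
#' training set excluded the event's case.
#'
#' @param features Model-ready table from [assemble_feature_table()].
#' @param folds A [make_folds()] assignment covering the table's cases.
#' @param spec A [search_spec()].
#' @param scale_features Robust-scale continuous predictors within each fold
#'   (kept on by default to mirror the preprocessing contract; tree models are
#'   invariant to it, the linear baseline uses raw ETCO2 either way).
#' @return A list of class `co2gap_cv` with `predictions` (tibble: `event_id`,
#'   `case_id`, `outer_fold`, `model`, `actual`, `predicted`), `tuning_log`,
#'   `models` (per-fold boosters), `scalers`, `folds`, and `predictors`.
#' @export
run_nested_cv <- function(features, folds, spec = search_spec(),
                          scale_features = TRUE) {
  stopifnot(inherits(folds, "co2gap_folds"))
  fn <- feature_names(with_co = "co" %in% names(features))
  predictors <- c(fn$continuous, fn$categorical)
  missing_cols <- setdiff(c(predictors, "paco2", "case_id", "event_id"), names(features))
  if (length(missing_cols) > 0) {
    stop_schema("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  outer_of <- folds$outer$outer_fold[match(features$case_id, folds$outer$case_id)]
  if (anyNA(outer_of)) stop_config("fold assignment does not cover all cases")

  parts <- vector("list", folds$k_outer)
  logs <- vector("list", folds$k_outer)
  models <- vector("list", folds$k_outer)
  scalers <- vector("list", folds$k_outer)

  for (o in seq_len(folds$k_outer)) {
    train <- features[outer_of != o, , drop = FALSE]
    test <- features[outer_of == o, , drop = FALSE]
    if (nrow(test) == 0) stop_config("outer fold ", o, " has no test events")

    if (scale_features) {
      scaler <- robust_scale_fit(train, fn$continuous)
      train_x <- robust_scale_apply(scaler, train)
      test_x <- robust_scale_apply(scaler, test)
    } else {
      scaler <- NULL
      train_x <- train
      test_x <- test
    }

    lin <- baseline_linear_fit(train)
    inner_assign <- dplyr::filter(folds$inner, .data$outer_fold == o)
    tuned <- tune_and_train(train_x, inner_assign, spec, predictors)

    preds <- dplyr::bind_rows(
      tibble::tibble(model = "offset", predicted = baseline_offset(test$etco2)),
      tibble::tibble(model = "linear",
                     predicted = baseline_linear_predict(lin, test$etco2)),
      tibble::tibble(model = "gbm",
                     predicted = gbm_predict(tuned$model, test_x[predictors]))
    )
    parts[[o]] <- tibble::tibble(
      event_id = rep(test$event_id, 3),
      case_id = rep(test$case_id, 3),
      outer_fold = o,
      model = rep(c("offset", "linear", "gbm"), each = nrow(test)),
      actual = rep(test$paco2, 3),
      predicted = preds$predicted
    )
    logs[[o]] <- dplyr::mutate(tuned$trial_log, outer_fold = o, .before = 1)
    models[[o]] <- tuned$model
    scalers[[o]] <- scaler
  }

  structure(list(
    predictions = dplyr::bind_rows(parts),
    tuning_log = dplyr::bind_rows(logs),
    models = models,
    scalers = scalers,
    folds = folds,
    predictors = predictors,
    spec = spec
  ), class = "co2gap_cv")
}

#' @export
print.co2gap_cv <- function(x, ...) {
  n_ev <- length(unique(x$predictions$event_id))
  cat("<co2gap nested CV>", n_ev, "events x 3 models,",
      x$folds$k_outer, "outer folds\n")
  mae <- x$predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mae = mean(abs(.data$actual - .data$predicted)), .groups = "drop")
  for (i in seq_len(nrow(mae))) {
    cat(sprintf("  %-7s out-of-fold MAE %.3f mm Hg\n", mae$model[i], mae$mae[i]))
  }
  invisible(x)
}

#' @export
#' @rdname tidy.co2gap_report
tidy.co2gap_cv <- function(x, ...) x$predictions

#' @export
#' @rdname tidy.co2gap_report
glance.co2gap_cv <- function(x, ...) {
  x$predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae = mean(abs(.data$actual - .data$predicted)),
      rmse = sqrt(mean((.data$actual - .data$predicted)^2)),
      .groups = "drop"
    )
}
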