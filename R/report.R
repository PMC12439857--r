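#' Build the full evaluation report
#'
#' Assembles every evaluation artifact for the three models (offset baseline,
#' linear baseline, gradient-boosted model): fold-averaged MAE/MSE/RMSE with
#' 95% t-intervals overall and within each capnia subgroup, Bland-Altman bias
#' and limits of agreement, ICC(2,1), clinical-utility error bands, and the
#' additive feature-attribution summary for the boosted model.
#'
#' Subgroup metrics are computed per outer fold and then CI-averaged across
#' folds; folds in which a subgroup is empty are skipped with a warning.
#' RMSE is the square root of each fold's MSE, averaged afterwards.
#'
#' @param cv A `co2gap_cv` from [run_nested_cv()].
#' @param features The feature table the CV was run on (used for
#'   attributions).
#' @param seed Seed recorded in the provenance block.
#' @param icc_form Label of the ICC variant computed (fixed to `"ICC(2,1)"`,
#'   recorded in the report).
#' @param attribution Include the attribution block (requires the boosted
#'   models kept in `cv`).
#' @return A list of class `co2gap_report` with tibbles `metrics`,
#'   `agreement`, `utility`, `attribution`, `bland_altman_points`, `counts`,
#'   and a `provenance` list.
#' @export
build_report <- function(cv, features, seed = NA_integer_,
                         icc_form = "ICC(2,1)", attribution = TRUE) {
  stopifnot(inherits(cv, "co2gap_cv"))
  pred <- cv$predictions
  models <- c("offset", "linear", "gbm")
  if (!setequal(unique(pred$model), models)) {
    stop_config("prediction set must cover exactly the models: ",
                paste(models, collapse = ", "))
  }
  pred <- dplyr::mutate(pred, subgroup = assign_subgroup(.data$actual))

  per_fold <- function(rows) {
    rows |>
      dplyr::group_by(.data$outer_fold) |>
      dplyr::reframe(error_metrics(.data$actual, .data$predicted))
  }
  metric_block <- function(rows, model, subgroup) {
    if (nrow(rows) == 0) {
      warning(sprintf("subgroup '%s' has no events for model '%s'", subgroup, model),
              call. = FALSE)
      return(tibble::tibble(model = model, subgroup = subgroup,
                            metric = c("mae", "mse", "rmse"), mean = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_, k = 0L))
    }
    pf <- per_fold(rows)
    k_total <- cv$folds$k_outer
    if (nrow(pf) < k_total && subgroup != "all") {
      warning(sprintf("subgroup '%s' empty in %d fold(s) for model '%s'; CI uses %d folds",
                      subgroup, k_total - nrow(pf), model, nrow(pf)), call. = FALSE)
    }
    purrr::map_dfr(c("mae", "mse", "rmse"), function(m) {
      dplyr::mutate(fold_ci(pf[[m]]), metric = m, .before = 1)
    }) |>
      dplyr::mutate(model = model, subgroup = subgroup, .before = 1)
  }

  metrics <- purrr::map_dfr(models, function(mod) {
    rows <- dplyr::filter(pred, .data$model == mod)
    dplyr::bind_rows(
      metric_block(rows, mod, "all"),
      purrr::map_dfr(c("hypocapnic", "normocapnic", "hypercapnic"), function(sg) {
        metric_block(dplyr::filter(rows, .data$subgroup == sg), mod, sg)
      })
    )
  })

  ba_points <- list()
  agreement <- purrr::map_dfr(models, function(mod) {
    rows <- dplyr::filter(pred, .data$model == mod)
    ba <- bland_altman(rows$actual, rows$predicted)
    ba_points[[mod]] <<- dplyr::mutate(ba$points, model = mod, .before = 1)
    icc <- icc_agreement(rows$actual, rows$predicted)
    dplyr::bind_cols(
      tibble::tibble(model = mod),
      ba$summary,
      dplyr::rename(icc, icc = "icc", icc_ci_low = "ci_low",
                    icc_ci_high = "ci_high", icc_p = "p", n_icc = "n")
    )
  })

  utility <- purrr::map_dfr(models, function(mod) {
    rows <- dplyr::filter(pred, .data$model == mod)
    dplyr::bind_cols(tibble::tibble(model = mod),
                     utility_bins(rows$actual, rows$predicted))
  })

  attr_block <- if (attribution) attribution_summary(cv, features) else NULL

  counts <- pred |>
    dplyr::filter(.data$model == "gbm") |>
    dplyr::count(.data$subgroup, name = "n_events") |>
    dplyr::bind_rows(tibble::tibble(
      subgroup = "all",
      n_events = sum(pred$model == "gbm")
    ))

  out <- list(
    metrics = metrics,
    agreement = agreement,
    utility = utility,
    attribution = attr_block$summary,
    bland_altman_points = dplyr::bind_rows(ba_points),
    counts = counts,
    provenance = list(
      seed = seed,
      icc_form = icc_form,
      difference_sign = "predicted - actual",
      k_outer = cv$folds$k_outer,
      k_inner = cv$folds$k_inner,
      search_budget = cv$spec$budget,
      n_events = length(unique(pred$event_id)),
      n_cases = length(unique(pred$case_id))
    )
  )
  class(out) <- "co2gap_report"
  out
}

#' @export
print.co2gap_report <- function(x, ...) {
  cat("<co2gap evaluation report>\n")
  cat("  events:", x$provenance$n_events, " cases:", x$provenance$n_cases,
      " (", x$provenance$k_outer, "outer folds )\n")
  hl <- x$metrics |>
    dplyr::filter(.data$subgroup == "all", .data$metric == "mae")
  for (i in seq_len(nrow(hl))) {
    cat(sprintf("  %-7s MAE %.2f (95%% CI %.2f-%.2f) mm Hg\n",
                hl$model[i], hl$mean[i], hl$ci_low[i], hl$ci_high[i]))
  }
  ic <- x$agreement
  for (i in seq_len(nrow(ic))) {
    cat(sprintf("  %-7s bias %+.2f, LoA [%.2f, %.2f], %s %.3f\n",
                ic$model[i], ic$bias[i], ic$loa_low[i], ic$loa_high[i],
                x$provenance$icc_form, ic$icc[i]))
  }
  invisible(x)
}

#' Tidy and glance methods for co2gap results
#'
#' `tidy()` on a report returns one of its tables in long form; `glance()`
#' returns a one-row-per-model headline summary. On a `co2gap_cv`, `tidy()`
#' returns the out-of-fold predictions and `glance()` pooled error metrics.
#'
#' @param x A `co2gap_report` or `co2gap_cv`.
#' @param table Which report table to return.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.co2gap_report <- function(x, table = c("metrics", "agreement", "utility",
                                            "attribution", "counts"), ...) {
  table <- match.arg(table)
  out <- x[[table]]
  if (is.null(out)) stop_config("report has no '", table, "' block")
  out
}

#' @export
#' @rdname tidy.co2gap_report
glance.co2gap_report <- function(x, ...) {
  mae <- x$metrics |>
    dplyr::filter(.data$subgroup == "all", .data$metric == "mae") |>
    dplyr::select(model = "model", mae = "mean", mae_ci_low = "ci_low",
                  mae_ci_high = "ci_high")
  rmse <- x$metrics |>
    dplyr::filter(.data$subgroup == "all", .data$metric == "rmse") |>
    dplyr::select(model = "model", rmse = "mean")
  mae |>
    dplyr::left_join(rmse, by = "model") |>
    dplyr::left_join(dplyr::select(x$agreement, "model", "bias", "icc"), by = "model") |>
    dplyr::left_join(dplyr::select(x$utility, "model", "pct_lt5"), by = "model")
}

#' Bland-Altman panels for an evaluation report
#'
#' One panel per model: per-event difference (predicted - actual) against the
#' pair mean, with the bias and the 1.96-SD limits of agreement.
#'
#' @param object A `co2gap_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.co2gap_report <- function(object, ...) {
  pts <- object$bland_altman_points
  lines <- object$agreement |>
    tidyr::pivot_longer(c("bias", "loa_low", "loa_high"),
                        names_to = "which", values_to = "y")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$which == "bias"),
                        colour = "steelblue", show.legend = FALSE) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Mean of actual and predicted PaCO2 (mm Hg)",
                  y = "Predicted - actual (mm Hg)",
                  title = "Bland-Altman agreement by model") +
    ggplot2::theme_minimal()
}

#' Plot the mean absolute attribution ranking
#'
#' @param report A `co2gap_report` built with attributions.
#' @param top_n How many features to show.
#' @return A ggplot object.
#' @export
plot_attribution <- function(report, top_n = 15) {
  if (is.null(report$attribution)) stop_config("report has no attribution block")
  df <- dplyr::slice_min(report$attribution, .data$rank, n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_attr,
                                   y = stats::reorder(.data$feature,
                                                      .data$mean_abs_attr))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean |attribution| (mm Hg)", y = NULL,
                  title = "Feature importance of the boosted model") +
    ggplot2::theme_minimal()
}
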