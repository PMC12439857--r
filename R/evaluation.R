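#' Error metrics for a prediction set
#'
#' @param actual,predicted Numeric vectors of equal length (>= 1).
#' @return Tibble with `mae`, `mse`, `rmse`.
#' @export
error_metrics <- function(actual, predicted) {
  if (length(actual) == 0 || length(actual) != length(predicted)) {
    stop_config("`actual` and `predicted` must be non-empty and equal length")
  }
  err <- actual - predicted
  tibble::tibble(mae = mean(abs(err)), mse = mean(err^2),
                 rmse = sqrt(mean(err^2)))
}

#' Student-t confidence interval across outer folds
#'
#' `mean +/- t(k-1, 0.975) * SD / sqrt(k)` over per-fold metric values; the
#' convention used to summarise every fold-wise metric.
#'
#' @param values Per-fold metric values.
#' @param level Confidence level.
#' @return Tibble with `mean`, `ci_low`, `ci_high`, `k`; with fewer than two
#'   folds the CI is `NA` (flagged by `k`).
#' @export
fold_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  k <- length(values)
  m <- mean(values)
  if (k < 2) {
    return(tibble::tibble(mean = m, ci_low = NA_real_, ci_high = NA_real_, k = k))
  }
  half <- stats::qt(1 - (1 - level) / 2, df = k - 1) * stats::sd(values) / sqrt(k)
  tibble::tibble(mean = m, ci_low = m - half, ci_high = m + half, k = k)
}

#' Capnia subgroup of an arterial CO2 value
#'
#' Hypocapnic below 35 mm Hg, normocapnic 35-45 mm Hg inclusive, hypercapnic
#' above 45 mm Hg — always by the measured (actual) PaCO2.
#'
#' @param paco2 PaCO2 values (mm Hg, > 0).
#' @return Character vector of subgroup labels.
#' @export
assign_subgroup <- function(paco2) {
  dplyr::case_when(
    paco2 < 35 ~ "hypocapnic",
    paco2 <= 45 ~ "normocapnic",
    .default = "hypercapnic"
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences are `predicted - actual` (an overpredicting model has positive
#' bias); limits of agreement are `bias +/- 1.96 * SD` of the differences.
#'
#' @param actual,predicted Numeric vectors (length >= 2).
#' @return List with `summary` (tibble: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n`) and `points` (per-point means and differences for
#'   plotting).
#' @export
bland_altman <- function(actual, predicted) {
  if (length(actual) < 2) stop_config("Bland-Altman needs >= 2 pairs")
  d <- predicted - actual
  s <- stats::sd(d)
  bias <- mean(d)
  list(
    summary = tibble::tibble(bias = bias, loa_low = bias - 1.96 * s,
                             loa_high = bias + 1.96 * s, sd_diff = s,
                             n = length(d)),
    points = tibble::tibble(mean = (predicted + actual) / 2, difference = d)
  )
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) for single measurements, computed from the two-way ANOVA mean
#' squares of the n-subjects-by-2-raters table (actual vs predicted), with the
#' F-based confidence interval of McGraw & Wong and the F test of ICC = 0.
#'
#' @param actual,predicted Numeric vectors (n >= 5).
#' @param level Confidence level.
#' @return Tibble with `icc`, `ci_low`, `ci_high`, `p`, `n`; `icc` is `NA`
#'   (flagged) when the table has no variance at all.
#' @export
icc_agreement <- function(actual, predicted, level = 0.95) {
  n <- length(actual)
  if (n < 5 || n != length(predicted)) stop_config("ICC needs >= 5 complete pairs")
  k <- 2
  x <- cbind(actual, predicted)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  sst <- sum((x - grand)^2)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) {
    return(tibble::tibble(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, n = n))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong (1996) CI for ICC(A,1)
  alpha <- 1 - level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_low <- stats::qf(1 - alpha / 2, n - 1, v)
  f_up <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_low * mse) /
    (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_up * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_up * msr)

  f0 <- msr / mse
  p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  tibble::tibble(icc = icc, ci_low = ci_low, ci_high = ci_high, p = p, n = n)
}

#' Clinical-utility error bands
#'
#' Percentage of events with absolute error below 5 mm Hg (highly
#' acceptable), between 5 and 10 inclusive (moderately acceptable), and
#' exceeding 10 (unacceptable).
#'
#' @param actual,predicted Numeric vectors (>= 1 pair).
#' @return Tibble with `pct_lt5`, `pct_5to10`, `pct_gt10`, `n`.
#' @export
utility_bins <- function(actual, predicted) {
  if (length(actual) == 0) stop_config("utility bins need >= 1 pair")
  ae <- abs(predicted - actual)
  tibble::tibble(
    pct_lt5 = 100 * mean(ae < 5),
    pct_5to10 = 100 * mean(ae >= 5 & ae <= 10),
    pct_gt10 = 100 * mean(ae > 10),
    n = length(ae)
  )
}

#' Additive feature attributions for the tuned model
#'
#' Exact tree-path (SHAP) attributions computed out-of-fold: each event is
#' attributed by the model of the outer fold that held it out, via the
#' package's double-precision tree re-walk ([gbm_attribution()]). Per row, the
#' base value plus the attributions equals the model output to floating-point
#' rounding; the identity is verified on every row.
#'
#' @param cv A `co2gap_cv` from [run_nested_cv()].
#' @param features The feature table the CV was run on.
#' @param check_additivity Verify the additivity identity row-wise.
#' @param tol Additivity tolerance (absolute, relative to magnitude 1
#'   predictions; scaled by `max(1, |prediction|)`).
#' @return List with `summary` (per feature: `mean_abs_attr`, importance
#'   `rank`, `value_correlation` between feature value and signed attribution
#'   for continuous features) and `attributions` (long tibble per event and
#'   feature).
#' @export
attribution_summary <- function(cv, features, check_additivity = TRUE,
                                tol = 1e-6) {
  stopifnot(inherits(cv, "co2gap_cv"))
  folds <- cv$folds
  outer_of <- folds$outer$outer_fold[match(features$case_id, folds$outer$case_id)]
  parts <- vector("list", folds$k_outer)
  for (o in seq_len(folds$k_outer)) {
    test <- features[outer_of == o, , drop = FALSE]
    if (nrow(test) == 0) next
    test_x <- if (is.null(cv$scalers[[o]])) test else
      robust_scale_apply(cv$scalers[[o]], test)
    attr_o <- gbm_attribution(cv$models[[o]], test_x[cv$predictors])
    contrib <- attr_o$contrib
    if (check_additivity) {
      resid <- abs(rowSums(contrib) - attr_o$pred)
      bad <- resid > tol * pmax(1, abs(attr_o$pred))
      if (any(bad)) {
        stop("attribution additivity violated on ", sum(bad), " row(s); max |resid| = ",
             format(max(resid)), call. = FALSE)
      }
    }
    feat_cols <- setdiff(colnames(contrib), "(Intercept)")
    long <- tibble::tibble(
      event_id = rep(test$event_id, times = length(feat_cols)),
      feature = rep(feat_cols, each = nrow(test)),
      attribution = as.numeric(contrib[, feat_cols]),
      value = as.numeric(unlist(lapply(test[feat_cols], function(col) {
        if (is.numeric(col)) col else rep(NA_real_, length(col))
      })))
    )
    parts[[o]] <- long
  }
  attributions <- dplyr::bind_rows(parts)
  summary <- attributions |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      mean_abs_attr = mean(abs(.data$attribution)),
      value_correlation = if (all(is.na(.data$value)) ||
                              stats::sd(.data$value) == 0 ||
                              stats::sd(.data$attribution) == 0) NA_real_
        else stats::cor(.data$value, .data$attribution),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_attr)) |>
    dplyr::mutate(rank = dplyr::row_number())
  list(summary = summary, attributions = attributions)
}
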