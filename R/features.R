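#' Default physiologic plausibility bounds per channel
#'
#' Clinically impossible readings (sensor dropouts, transducer artifacts) are
#' removed before any statistic is computed. Bounds are deliberately wide:
#' they encode impossibility, not abnormality, and are configuration rather
#' than a claim about any particular cohort.
#'
#' @return Named list mapping channel to `c(min, max)`.
#' @export
default_plausibility <- function() {
  list(
    MAP = c(30, 200), HR = c(20, 220), SPO2 = c(50, 100), BT = c(30, 42),
    ETCO2 = c(5, 90), RR = c(4, 60), TV = c(50, 2000), MV = c(0.5, 30),
    PEEP = c(0, 30), PIP = c(5, 80), PPLAT = c(5, 80), MAWP = c(2, 60),
    FIO2 = c(0.21, 1), CO = c(1, 20)
  )
}

check_plausibility <- function(bounds) {
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2]) {
      stop_config("plausibility bounds for ", nm, " must satisfy min < max")
    }
  }
  bounds
}

#' Slice a trace to a half-open window
#'
#' Returns samples with `start <= time < end`, order preserved; an empty
#' result is handled downstream as a missing feature.
#'
#' @param trace Data frame with `time_s`, `value`.
#' @param window_start_s,window_end_s Window bounds (half-open).
#' @return Numeric vector of values inside the window.
#' @export
slice_window <- function(trace, window_start_s, window_end_s) {
  trace$value[trace$time_s >= window_start_s & trace$time_s < window_end_s]
}

#' Remove extreme outliers by the IQR rule
#'
#' Retains values within `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles computed
#' by linear interpolation. With `k = 3` (the default) only extreme artifacts
#' are removed.
#'
#' @param values Numeric vector (NAs dropped first).
#' @param k IQR multiplier.
#' @return Filtered numeric vector (possibly empty).
#' @export
filter_outliers_iqr <- function(values, k = 3) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(values)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

#' Remove physiologically implausible values
#'
#' @param values Numeric vector.
#' @param bounds Length-2 numeric `c(min, max)`.
#' @return Values inside `[min, max]`, NAs dropped.
#' @export
filter_plausibility <- function(values, bounds) {
  values <- values[!is.na(values)]
  values[values >= bounds[1] & values <= bounds[2]]
}

#' Window median
#'
#' Sample median (midpoint of the central two values for even n); an empty
#' input yields `NA`, which listwise deletion later removes.
#'
#' @param values Numeric vector.
#' @return Median or `NA_real_`.
#' @export
window_median <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  stats::median(values)
}

#' Ideal body weight (Devine)
#'
#' `50 + 2.3 kg` per inch over 60 inches for males, `45.5 + 2.3` for females,
#' floored at 30 kg for very short statures.
#'
#' @param height_cm Height in cm (> 0).
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Ideal body weight in kg.
#' @export
ideal_body_weight <- function(height_cm, sex) {
  if (any(height_cm <= 0)) stop_config("`height_cm` must be > 0")
  inches <- height_cm / 2.54
  base <- ifelse(sex == "male", 50, 45.5)
  pmax(base + 2.3 * (inches - 60), 30)
}

#' Respiratory-system compliance
#'
#' `CRS = TV / (PPLAT - PEEP)` in mL/cmH2O; a non-positive driving pressure is
#' physically invalid and yields `NA`.
#'
#' @param tv_ml Tidal volume (mL).
#' @param pplat_cmh2o Plateau pressure (cmH2O).
#' @param peep_cmh2o Positive end-expiratory pressure (cmH2O).
#' @return Compliance (mL/cmH2O) or `NA_real_`.
#' @export
respiratory_compliance <- function(tv_ml, pplat_cmh2o, peep_cmh2o) {
  dp <- pplat_cmh2o - peep_cmh2o
  ifelse(is.na(dp) | dp <= 0, NA_real_, tv_ml / dp)
}

#' Engineered physiological ratios
#'
#' SpO2/FiO2 oxygenation ratio, PEEP/FiO2 ratio, and the rapid shallow
#' breathing index `RSBI = RR / TV(L)` in breaths/min/L.
#'
#' @param spo2_pct SpO2 (%).
#' @param fio2_frac FiO2 as a fraction in `[0.21, 1]`.
#' @param peep PEEP (cmH2O).
#' @param rr Respiratory rate (breaths/min).
#' @param tv_ml Tidal volume (mL); 0 or NA makes RSBI missing.
#' @return Tibble with `sf_ratio`, `peep_fio2`, `rsbi`.
#' @export
engineered_ratios <- function(spo2_pct, fio2_frac, peep, rr, tv_ml) {
  tibble::tibble(
    sf_ratio = spo2_pct / fio2_frac,
    peep_fio2 = peep / fio2_frac,
    rsbi = ifelse(is.na(tv_ml) | tv_ml <= 0, NA_real_, rr / (tv_ml / 1000))
  )
}

#' Grade a preoperative pulmonary function test
#'
#' Spirometry pattern from the FEV1/FVC ratio and FVC percent-predicted,
#' using the conventional 0.70 ratio and 80% cutoffs: obstructive
#' (ratio < 0.70, FVC >= 80), restrictive (ratio >= 0.70, FVC < 80), mixed
#' (both criteria), otherwise none. Missing inputs grade as `none`.
#'
#' @param fev1_fvc_ratio FEV1/FVC as a fraction.
#' @param fvc_pct_predicted FVC as percent of predicted.
#' @return Character vector in `{none, obstructive, restrictive, mixed}`.
#' @export
classify_pft <- function(fev1_fvc_ratio, fvc_pct_predicted) {
  obstr <- !is.na(fev1_fvc_ratio) & fev1_fvc_ratio < 0.70
  restr <- !is.na(fvc_pct_predicted) & fvc_pct_predicted < 80
  dplyr::case_when(
    obstr & restr ~ "mixed",
    obstr ~ "obstructive",
    restr ~ "restrictive",
    .default = "none"
  )
}

signal_channels <- function() c("MAP", "HR", "SPO2", "BT", "ETCO2", "RR", "TV",
                                "MV", "PEEP", "PIP", "PPLAT", "MAWP", "FIO2", "CO")

feature_channel_map <- function() {
  c(bt = "BT", hr = "HR", spo2 = "SPO2", mv = "MV", peep = "PEEP", pip = "PIP",
    pplat = "PPLAT", mawp = "MAWP", rr = "RR", tv = "TV", fio2 = "FIO2",
    etco2 = "ETCO2", co = "CO")
}

#' Continuous and categorical feature names of the model-ready table
#'
#' @param with_co Include the optional cardiac-output column.
#' @return Named list with `continuous` and `categorical` character vectors.
#' @export
feature_names <- function(with_co = TRUE) {
  cont <- c("age", "height", "weight", "bt", "hr", "spo2", "mv", "peep", "pip",
            "pplat", "mawp", "rr", "tv", "fio2", "etco2",
            "tv_ibw", "sf_ratio", "peep_fio2", "crs", "rsbi")
  if (with_co) cont <- c(cont, "co")
  list(continuous = cont,
       categorical = c("sex", "surgery_type", "surgical_approach", "asa_class",
                       "pft_grade"))
}

#' Assemble the model-ready feature table
#'
#' For every aligned event point: slice each channel to the observation
#' window, apply the plausibility filter then the IQR filter, take the window
#' median, compute the engineered features (TV/IBW, SpO2/FiO2, PEEP/FiO2, CRS,
#' RSBI), and join the case's clinical fields with the pulmonary-function
#' grade. Events with any missing predictor are removed (listwise deletion)
#' and logged with the missing columns.
#'
#' @param events Event points from [align_events()].
#' @param clinical Clinical table (one row per case).
#' @param signals Long-format signals table.
#' @param plausibility Named per-channel bounds, see [default_plausibility()].
#' @param iqr_k IQR multiplier for outlier removal.
#' @param with_co Whether to use the optional CO channel as a feature.
#' @return List with `features` (one row per modeled event) and `exclusions`
#'   (event id + reason for every dropped event, including the upstream
#'   alignment exclusions).
#' @export
assemble_feature_table <- function(events, clinical, signals,
                                   plausibility = default_plausibility(),
                                   iqr_k = 3, with_co = TRUE) {
  plausibility <- check_plausibility(plausibility)
  unknown <- setdiff(events$case_id, clinical$case_id)
  if (length(unknown) > 0) {
    stop_schema("event references unknown case(s): ",
                paste(utils::head(unknown, 5), collapse = ", "))
  }
  chan_map <- feature_channel_map()
  if (!with_co) chan_map <- chan_map[names(chan_map) != "co"]

  aligned <- dplyr::filter(events, .data$status == "aligned")
  if (nrow(aligned) == 0) {
    stop_schema("no aligned events to extract features from; ",
                "check the alignment stage and its z threshold")
  }
  excl <- events |>
    dplyr::filter(.data$status != "aligned") |>
    dplyr::transmute(.data$event_id, reason = .data$status)

  sig <- dplyr::filter(signals, .data$channel %in% chan_map)
  sig_by <- split(sig[c("time_s", "value")],
                  list(sig$case_id, sig$channel), drop = TRUE, sep = "\r")

  med_rows <- purrr::map_dfr(seq_len(nrow(aligned)), function(i) {
    ev <- aligned[i, ]
    meds <- vapply(chan_map, function(ch) {
      tr <- sig_by[[paste(ev$case_id, ch, sep = "\r")]]
      if (is.null(tr)) return(NA_real_)
      vals <- slice_window(tr, ev$window_start_s, ev$window_end_s)
      vals <- filter_plausibility(vals, plausibility[[ch]])
      vals <- filter_outliers_iqr(vals, k = iqr_k)
      window_median(vals)
    }, numeric(1))
    tibble::as_tibble(as.list(meds))
  })
  base <- dplyr::bind_cols(
    aligned[c("event_id", "case_id", "paco2", "trigger_time_s")],
    med_rows
  )

  clin <- clinical |>
    dplyr::mutate(
      pft_grade = classify_pft(.data$fev1_fvc_ratio, .data$fvc_pct_predicted),
      ibw = ideal_body_weight(.data$height, .data$sex)
    ) |>
    dplyr::select("case_id", "age", "sex", "height", "weight", "asa_class",
                  "surgery_type", "surgical_approach", "pft_grade", "ibw")
  tab <- dplyr::left_join(base, clin, by = "case_id")

  tab <- tab |>
    dplyr::mutate(
      tv_ibw = .data$tv / .data$ibw,
      crs = respiratory_compliance(.data$tv, .data$pplat, .data$peep)
    ) |>
    dplyr::bind_cols(
      engineered_ratios(tab$spo2, tab$fio2, tab$peep, tab$rr, tab$tv)
    ) |>
    dplyr::select(-"ibw")

  fn <- feature_names(with_co = with_co)
  predictors <- c(fn$continuous, fn$categorical)
  miss <- is.na(tab[predictors])
  dropped <- rowSums(miss) > 0
  if (any(dropped)) {
    reasons <- apply(miss[dropped, , drop = FALSE], 1, function(r) {
      paste0("missing: ", paste(predictors[r], collapse = ", "))
    })
    excl <- dplyr::bind_rows(
      excl,
      tibble::tibble(event_id = tab$event_id[dropped], reason = reasons)
    )
  }
  features <- tab[!dropped, , drop = FALSE] |>
    dplyr::mutate(dplyr::across(dplyr::all_of(fn$categorical), as.factor))
  list(features = features, exclusions = excl)
}

#' Fit a robust (median/IQR) scaler on training rows
#'
#' Centres each continuous feature by its training median and scales by its
#' training IQR; a degenerate (zero) IQR gets scale 1 and the feature is
#' flagged constant. Fit strictly on training rows of the current fold so no
#' test-set statistic ever leaks into training.
#'
#' @param train Data frame of training rows.
#' @param columns Continuous feature names to scale.
#' @return A `co2gap_scaler` with per-feature `center` and `scale`.
#' @export
robust_scale_fit <- function(train, columns) {
  stats_tbl <- purrr::map_dfr(columns, function(cn) {
    x <- train[[cn]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE, type = 7)
    iqr <- q[3] - q[1]
    tibble::tibble(feature = cn, center = q[2],
                   scale = if (iqr > 0) iqr else 1,
                   constant = iqr <= 0)
  })
  if (any(stats_tbl$constant)) {
    warning("constant feature(s) left unscaled: ",
            paste(stats_tbl$feature[stats_tbl$constant], collapse = ", "),
            call. = FALSE)
  }
  structure(list(stats = stats_tbl, columns = columns), class = "co2gap_scaler")
}

#' Apply (or invert) a fitted robust scaler
#'
#' Uses only the stored training statistics; never recomputes anything from
#' the rows it transforms.
#'
#' @param state A `co2gap_scaler` from [robust_scale_fit()].
#' @param rows Data frame to transform.
#' @param invert If `TRUE`, undo the scaling.
#' @return Transformed tibble (categorical columns untouched).
#' @export
robust_scale_apply <- function(state, rows, invert = FALSE) {
  stopifnot(inherits(state, "co2gap_scaler"))
  out <- tibble::as_tibble(rows)
  for (i in seq_len(nrow(state$stats))) {
    cn <- state$stats$feature[i]
    ctr <- state$stats$center[i]
    scl <- state$stats$scale[i]
    out[[cn]] <- if (invert) out[[cn]] * scl + ctr else (out[[cn]] - ctr) / scl
  }
  out
}
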