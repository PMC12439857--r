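test_that("window slicing is half-open and order preserving", {
  tr <- tibble::tibble(time_s = 0:2000, value = as.numeric(0:2000))
  v <- slice_window(tr, 880, 940)
  expect_length(v, 60)
  expect_equal(v[1], 880)      # start included
  expect_equal(v[60], 939)     # end excluded
  expect_length(slice_window(tr, 5000, 5060), 0)
})

test_that("IQR filtering matches direct quartile computation", {
  expect_identical(filter_outliers_iqr(rep(3.2, 10)), rep(3.2, 10))
  # Q1 = 2, Q3 = 4, IQR = 2 -> bounds [-4, 10] remove the 100
  expect_equal(filter_outliers_iqr(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  withr::with_seed(23, {
    for (rep in 1:300) {
      x <- rnorm(sample(5:40, 1)) * sample(c(1, 10), 1)
      q1 <- oracle_quantile7(x, 0.25)
      q3 <- oracle_quantile7(x, 0.75)
      keep <- x[x >= q1 - 3 * (q3 - q1) & x <= q3 + 3 * (q3 - q1)]
      expect_identical(filter_outliers_iqr(x), keep)
    }
  })
})

test_that("plausibility filtering removes impossible readings only", {
  expect_equal(filter_plausibility(c(97, 250, 98), c(50, 100)), c(97, 98))
  expect_equal(filter_plausibility(c(97, 98), c(50, 100)), c(97, 98))
  # plausibility runs before the IQR rule; the combination equals both predicates
  x <- c(96, 97, 98, 97, 250)
  manual <- x[x >= 50 & x <= 100]
  q1 <- oracle_quantile7(manual, 0.25); q3 <- oracle_quantile7(manual, 0.75)
  manual <- manual[manual >= q1 - 3 * (q3 - q1) & manual <= q3 + 3 * (q3 - q1)]
  expect_identical(filter_outliers_iqr(filter_plausibility(x, c(50, 100))), manual)
})

test_that("window median uses the midpoint convention and encodes emptiness", {
  expect_equal(window_median(c(3, 1, 2)), 2)
  expect_equal(window_median(c(1, 2, 3, 4)), 2.5)
  expect_true(is.na(window_median(numeric())))
})

test_that("ideal body weight follows the Devine formula", {
  expect_equal(ideal_body_weight(177.8, "male"), 73.0, tolerance = 1e-6)
  expect_equal(ideal_body_weight(152.4, "female"), 45.5, tolerance = 1e-6)
  expect_equal(500 / ideal_body_weight(177.8, "male"), 6.849, tolerance = 1e-3)
  expect_equal(ideal_body_weight(100, "male"), 30)  # floored
  expect_error(ideal_body_weight(-1, "male"), "height")
})

test_that("respiratory compliance guards non-positive driving pressure", {
  expect_equal(respiratory_compliance(525, 20, 5), 35)
  expect_true(is.na(respiratory_compliance(500, 5, 5)))
  expect_equal(respiratory_compliance(1000, 20, 5),
               2 * respiratory_compliance(500, 20, 5))
})

test_that("engineered ratios follow their definitions", {
  r <- engineered_ratios(98, 0.5, 5, 14, 350)
  expect_equal(r$sf_ratio, 196)
  expect_equal(r$rsbi, 40)
  expect_equal(engineered_ratios(98, 0.4, 5, 14, 350)$peep_fio2, 12.5)
  expect_true(is.na(engineered_ratios(98, 0.5, 5, 14, 0)$rsbi))
})

test_that("pulmonary function grading uses the 0.70 / 80% cutoffs", {
  expect_equal(classify_pft(0.60, 90), "obstructive")
  expect_equal(classify_pft(0.80, 70), "restrictive")
  expect_equal(classify_pft(0.60, 70), "mixed")
  expect_equal(classify_pft(0.80, 90), "none")
  expect_equal(classify_pft(NA, NA), "none")
  expect_equal(classify_pft(c(0.6, 0.8), c(90, 70)), c("obstructive", "restrictive"))
})

test_that("feature assembly equals a hand-computed table on a tiny fixture", {
  # three cases with constant-valued channels so all medians are known exactly
  clin <- tibble::tibble(
    case_id = c("a", "b", "c"),
    age = c(40, 60, 55), sex = c("male", "female", "male"),
    height = c(177.8, 152.4, 170), weight = c(80, 55, 70),
    asa_class = c(1L, 2L, 3L),
    surgery_type = c("general", "thoracic", "general"),
    surgical_approach = c("open", "open", "laparoscopic"),
    fev1_fvc_ratio = c(0.8, 0.6, 0.75), fvc_pct_predicted = c(90, 90, 70)
  )
  vals <- list(
    a = c(MAP = 75, HR = 70, SPO2 = 98, BT = 36.5, ETCO2 = 35, RR = 14, TV = 500,
          MV = 7, PEEP = 5, PIP = 22, PPLAT = 20, MAWP = 10, FIO2 = 0.5, CO = 5),
    b = c(MAP = 80, HR = 65, SPO2 = 99, BT = 36.0, ETCO2 = 38, RR = 12, TV = 400,
          MV = 4.8, PEEP = 4, PIP = 18, PPLAT = 16, MAWP = 9, FIO2 = 0.4, CO = 4.5),
    c = c(MAP = 70, HR = 80, SPO2 = 97, BT = 37.0, ETCO2 = 30, RR = 16, TV = 450,
          MV = 7.2, PEEP = 6, PIP = 25, PPLAT = 21, MAWP = 11, FIO2 = 0.6, CO = 5.5)
  )
  sig <- purrr::map_dfr(names(vals), function(cid) {
    purrr::map_dfr(names(vals[[cid]]), function(ch) {
      tibble::tibble(case_id = cid, channel = ch, time_s = 0:1200,
                     value = vals[[cid]][[ch]])
    })
  })
  # drop PPLAT entirely for case c: its event must be dropped and logged
  sig <- sig[!(sig$case_id == "c" & sig$channel == "PPLAT"), ]
  events <- purrr::map_dfr(names(vals), function(cid) {
    build_event_point(
      tibble::tibble(case_id = cid, event_id = paste0(cid, "_e1"),
                     recorded_time_s = 1060, paco2 = 42),
      1000, alignment_config()
    )
  })
  ft <- assemble_feature_table(events, clin, sig)
  expect_equal(nrow(ft$features), 2)
  expect_equal(ft$exclusions$event_id, "c_e1")
  expect_match(ft$exclusions$reason, "pplat")
  expect_match(ft$exclusions$reason, "crs")
  a <- ft$features[ft$features$case_id == "a", ]
  expect_equal(a$etco2, 35)
  expect_equal(a$crs, 500 / 15)
  expect_equal(a$tv_ibw, 500 / 73.0, tolerance = 1e-6)
  expect_equal(a$sf_ratio, 196)
  expect_equal(a$rsbi, 28)
  expect_equal(a$peep_fio2, 10)
  expect_equal(as.character(a$pft_grade), "none")
  b <- ft$features[ft$features$case_id == "b", ]
  expect_equal(as.character(b$pft_grade), "obstructive")
  expect_equal(b$crs, 400 / 12)
  # unknown case is a hard error
  bad <- events
  bad$case_id[1] <- "zzz"
  expect_error(assemble_feature_table(bad, clin, sig), "unknown case")
})

test_that("emitted engineered features recompute exactly from their inputs", {
  ft <- small_features()$features
  co <- small_cohort()
  ibw <- ideal_body_weight(ft$height, as.character(ft$sex))
  expect_equal(ft$tv_ibw, ft$tv / ibw)
  expect_equal(ft$crs, ft$tv / (ft$pplat - ft$peep))
  expect_equal(ft$sf_ratio, ft$spo2 / ft$fio2)
  expect_equal(ft$peep_fio2, ft$peep / ft$fio2)
  expect_equal(ft$rsbi, ft$rr / (ft$tv / 1000))
})

test_that("exclusion accounting conserves events", {
  ev <- small_events()
  ft <- small_features()
  expect_equal(sum(ev$status == "aligned"),
               nrow(ft$features) +
                 sum(grepl("^missing", ft$exclusions$reason)))
  expect_equal(nrow(ev), nrow(ft$features) + nrow(ft$exclusions))
})

test_that("robust scaling centres by median, scales by IQR, and round-trips", {
  df <- tibble::tibble(xx = c(1, 2, 3, 4, 5), yy = c(10, 10, 10, 10, 10))
  expect_warning(sc <- robust_scale_fit(df, c("xx", "yy")), "constant")
  out <- robust_scale_apply(sc, df)
  expect_equal(out$xx, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(out$yy, rep(0, 5))  # constant: centred, scale 1
  back <- robust_scale_apply(sc, out, invert = TRUE)
  expect_equal(back$xx, df$xx, tolerance = 1e-12)
  # applying to new rows never recomputes statistics
  new <- tibble::tibble(xx = c(100, 200), yy = c(0, 1))
  out2 <- robust_scale_apply(sc, new)
  expect_equal(out2$xx, (new$xx - 3) / 2)
})
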