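test_that("window z scores standardise against the window's own distribution", {
  expect_identical(compute_window_zscores(rep(75, 50)), rep(0, 50))
  x <- c(72.4, 75.1, 78.3, 74.0, 69.9, 81.2)
  expect_equal(compute_window_zscores(x), (x - mean(x)) / sd(x))
  # an outlying sample scores (x - mean)/SD, past the threshold 3
  x <- c(rep(74, 10), rep(76, 10), 95)
  m <- mean(x); s <- sd(x)
  expect_equal(compute_window_zscores(x)[21], (95 - m) / s)
  expect_gt(compute_window_zscores(x)[21], 3)
  # missing values keep their place
  z <- compute_window_zscores(c(1, NA, 3))
  expect_true(is.na(z[2]) && !anyNA(z[c(1, 3)]))
})

test_that("z exceedance rate under normality matches the two-sided tail", {
  frac <- withr::with_seed(31, {
    mean(replicate(400, {
      z <- compute_window_zscores(rnorm(1200))
      mean(abs(z) > 3)
    }))
  })
  expect_lt(abs(frac - 0.0027), 5e-4)
})

test_that("abnormal periods are maximal runs above the threshold", {
  t <- 0:6
  p <- find_abnormal_periods(t, c(0, 0, 4, 5, 4, 0, 0), 3)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$start_s, p$end_s, p$peak_s), c(2, 4, 3))
  p2 <- find_abnormal_periods(0:9, c(0, 4, 4, 0, 0, 0, 5, 0, 0, 0), 3)
  expect_equal(nrow(p2), 2)
  expect_true(all(diff(p2$start_s) > 0))
  expect_equal(nrow(find_abnormal_periods(t, rep(0, 7), 3)), 0)
  # strictly positive side only
  expect_equal(nrow(find_abnormal_periods(0:2, c(0, -5, 0), 3)), 0)
})

test_that("abnormal periods agree with exhaustive run enumeration", {
  withr::with_seed(17, {
    for (rep in 1:200) {
      z <- rnorm(60)
      thr <- 1.2
      got <- find_abnormal_periods(seq_along(z), z, thr)
      # oracle: scan every index
      runs <- list()
      start <- NA
      for (i in seq_along(z)) {
        if (z[i] > thr && is.na(start)) start <- i
        if ((z[i] <= thr || i == length(z)) && !is.na(start)) {
          end <- if (z[i] > thr) i else i - 1
          runs[[length(runs) + 1]] <- c(start, end)
          start <- NA
        }
      }
      expect_equal(nrow(got), length(runs))
      for (k in seq_along(runs)) {
        expect_equal(got$start_s[k], runs[[k]][1])
        expect_equal(got$end_s[k], runs[[k]][2])
        idx <- runs[[k]][1]:runs[[k]][2]
        expect_equal(got$peak_s[k], idx[which.max(z[idx])])
      }
    }
  })
})

test_that("draw-time estimation selects the nearest period and peaks at max z", {
  base <- flat_trace(75)
  noisy <- base
  # bounded wander, as physiologic MAP variation: no chance exceedance of z=3
  noisy$value <- noisy$value + withr::with_seed(3, runif(nrow(base), -1, 1))
  # no exceedance -> no estimate
  expect_true(is.na(estimate_draw_time(noisy, 1500)))
  # single injected surge is found at its interval
  tr <- inject_surge(noisy, 600, 30, 30)
  est <- estimate_draw_time(tr, 660)
  expect_true(est >= 600 && est <= 630)
  # two surges: the one nearest the recorded timestamp wins
  tr2 <- inject_surge(inject_surge(noisy, 300, 30, 20), 580, 30, 20)
  est2 <- estimate_draw_time(tr2, 660)
  expect_true(est2 >= 580 && est2 <= 600)
  # too few samples -> cannot assess
  expect_true(is.na(estimate_draw_time(noisy[1:5, ], 4)))
})

test_that("with several abnormal periods the latest (nearest) one is chosen", {
  # the lookback is one-sided, so the nearest period boundary is the latest one
  t <- 0:1500
  v <- rep(75, 1501)
  v[c(201, 202)] <- 120
  v[c(701, 702)] <- 120
  v[c(1101, 1102)] <- 120
  est <- estimate_draw_time(tibble::tibble(time_s = t, value = v), 1400)
  expect_true(est %in% c(1100, 1101))
})

test_that("alignment never inspects samples after the recorded timestamp", {
  noisy <- flat_trace(75)
  noisy$value <- noisy$value + withr::with_seed(9, runif(nrow(noisy), -1, 1))
  tr <- inject_surge(noisy, 1000, 40, 20)  # surge strictly after recorded time
  expect_true(is.na(estimate_draw_time(tr, 900)))
})

test_that("event points implement the trigger/blackout/window arithmetic", {
  ab <- tibble::tibble(case_id = "c1", event_id = "e1",
                       recorded_time_s = 1040, paco2 = 40)
  ep <- build_event_point(ab, 1000, alignment_config())
  expect_equal(ep$trigger_time_s, 940)
  expect_equal(c(ep$window_start_s, ep$window_end_s), c(880, 940))
  expect_equal(ep$status, "aligned")
  ep2 <- build_event_point(ab, 1000, alignment_config(blackout_s = 30))
  expect_equal(c(ep2$window_start_s, ep2$window_end_s), c(850, 910))
  ep3 <- build_event_point(ab, NA_real_, alignment_config())
  expect_equal(ep3$status, "excluded_no_surge")
  expect_true(is.na(ep3$trigger_time_s))
  # window falling before the case start is excluded
  ep4 <- build_event_point(ab, 100, alignment_config())
  expect_equal(ep4$status, "excluded_insufficient_history")
})

test_that("alignment recovers true draw times and excludes surge-free events", {
  st <- alignment_study()
  m <- st$events |>
    dplyr::left_join(
      st$cohort$abga[c("event_id", "true_draw_time_s", "surge_present")],
      by = "event_id"
    ) |>
    dplyr::left_join(st$cohort$truth[c("event_id", "entry_delay_s")],
                     by = "event_id")
  surge <- m[m$surge_present, ]
  aligned <- surge[surge$status == "aligned", ]
  expect_gte(mean(abs(aligned$estimated_draw_time_s - aligned$true_draw_time_s) <= 15),
             0.95)
  expect_true(all(m$status[!m$surge_present] == "excluded_no_surge"))
  # the recovered entry-delay median reproduces the cohort's realized delay
  # median (the delay *distribution* calibration is tested at n = 10,000 in
  # the generator tests; here the question is alignment fidelity)
  recovered <- median(aligned$recorded_time_s - aligned$estimated_draw_time_s)
  expect_lt(abs(recovered - median(aligned$entry_delay_s)), 2)
})
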