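test_that("error metrics follow their definitions", {
  m <- error_metrics(c(1, -1, 1, -1) + 5, rep(5, 4))
  expect_equal(c(m$mae, m$mse, m$rmse), c(1, 1, 1))
  p <- error_metrics(1:10, 1:10)
  expect_equal(c(p$mae, p$mse, p$rmse), c(0, 0, 0))
  expect_error(error_metrics(numeric(), numeric()), "non-empty")
  withr::with_seed(12, {
    for (rep in 1:200) {
      n <- sample(3:50, 1)
      a <- rnorm(n, 42, 4); b <- rnorm(n, 42, 4)
      s_abs <- 0; s_sq <- 0
      for (i in seq_len(n)) {
        s_abs <- s_abs + abs(a[i] - b[i]); s_sq <- s_sq + (a[i] - b[i])^2
      }
      got <- error_metrics(a, b)
      expect_equal(got$mae, s_abs / n, tolerance = 1e-12)
      expect_equal(got$mse, s_sq / n, tolerance = 1e-12)
      expect_equal(got$rmse, sqrt(s_sq / n), tolerance = 1e-12)
    }
  })
})

test_that("fold confidence intervals are Student-t across folds", {
  ci <- fold_ci(rep(2.5, 5))
  expect_equal(c(ci$ci_low, ci$mean, ci$ci_high), c(2.5, 2.5, 2.5))
  ci7 <- fold_ci(1:7)
  expect_equal(ci7$mean, 4)
  expect_equal(round(c(ci7$ci_low, ci7$ci_high), 2), c(2.00, 6.00))
  # widens monotonically with SD at fixed k
  narrow <- fold_ci(c(3.9, 4, 4.1))
  wide <- fold_ci(c(3, 4, 5))
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
  one <- fold_ci(4)
  expect_true(is.na(one$ci_low) && one$k == 1)
})

test_that("capnia subgroups use the 35/45 boundaries on actual PaCO2", {
  expect_equal(assign_subgroup(c(34, 34.99, 35, 40, 45, 45.5)),
               c("hypocapnic", "hypocapnic", "normocapnic", "normocapnic",
                 "normocapnic", "hypercapnic"))
})

test_that("Bland-Altman bias and limits of agreement are 1.96-SD bands", {
  ba <- bland_altman(c(40, 41, 42), c(42, 43, 44))
  expect_equal(ba$summary$bias, 2)
  expect_equal(c(ba$summary$loa_low, ba$summary$loa_high), c(2, 2))
  ba2 <- bland_altman(c(40, 40), c(39, 41))
  expect_equal(ba2$summary$bias, 0)
  expect_equal(round(c(ba2$summary$loa_low, ba2$summary$loa_high), 2),
               c(-2.77, 2.77))
  # overprediction gives positive bias; the points table carries pair means
  over <- bland_altman(c(40, 42), c(45, 47))
  expect_gt(over$summary$bias, 0)
  expect_equal(over$points$mean, c(42.5, 44.5))
  expect_error(bland_altman(40, 45), ">= 2")
})

test_that("limits of agreement contain about 95% of Gaussian differences", {
  withr::with_seed(14, {
    actual <- rnorm(3000, 42, 4)
    predicted <- actual + rnorm(3000, 1, 2)
  })
  ba <- bland_altman(actual, predicted)
  inside <- mean(ba$points$difference >= ba$summary$loa_low &
                   ba$points$difference <= ba$summary$loa_high)
  expect_lt(abs(inside - 0.95), 0.02)
})

icc_oracle <- function(a, p) {
  # two-way ANOVA mean squares via lm/anova, independent of the closed form
  d <- data.frame(y = c(a, p),
                  subj = factor(rep(seq_along(a), 2)),
                  rater = factor(rep(c("a", "p"), each = length(a))))
  tab <- anova(lm(y ~ subj + rater, data = d))
  msr <- tab["subj", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- length(a); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

test_that("ICC(2,1) matches the ANOVA oracle and penalises offsets", {
  x <- c(38.2, 41.5, 44.7, 39.9, 46.1, 42.3)
  self <- icc_agreement(x, x)
  expect_equal(self$icc, 1, tolerance = 1e-12)
  offset <- icc_agreement(x, x + 10)
  expect_lt(offset$icc, 0.5)  # absolute agreement, unlike Pearson's 1
  expect_equal(cor(x, x + 10), 1)
  withr::with_seed(19, {
    for (rep in 1:120) {
      n <- sample(5:60, 1)
      a <- rnorm(n, 42, 4)
      p <- a + rnorm(n, 0.5, 2)
      got <- icc_agreement(a, p)
      expect_equal(got$icc, icc_oracle(a, p), tolerance = 1e-10)
      expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
      # order of the two raters is irrelevant
      expect_equal(got$icc, icc_agreement(p, a)$icc, tolerance = 1e-12)
    }
  })
  expect_error(icc_agreement(1:3, 1:3), ">= 5")
  flat <- icc_agreement(rep(5, 6), rep(5, 6))
  expect_true(is.na(flat$icc))
})

test_that("utility bands follow the below-5 / 5-to-10 / exceeding-10 rule", {
  u <- utility_bins(c(40, 40, 40), c(44.9, 50, 50.1))
  expect_equal(u$pct_lt5, 100 / 3)
  expect_equal(u$pct_5to10, 100 / 3)
  expect_equal(u$pct_gt10, 100 / 3)
  # boundaries: 5 and 10 are moderate
  b <- utility_bins(c(40, 40), c(45, 50))
  expect_equal(b$pct_5to10, 100)
  expect_equal(u$pct_lt5 + u$pct_5to10 + u$pct_gt10, 100)
})

test_that("subgroup error sums pool to the all-events sums per fold", {
  pred <- small_run()$cv$predictions
  pred$subgroup <- assign_subgroup(pred$actual)
  by_sub <- pred |>
    dplyr::group_by(model, outer_fold, subgroup) |>
    dplyr::summarise(s_abs = sum(abs(actual - predicted)), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::group_by(model, outer_fold) |>
    dplyr::summarise(s_abs = sum(s_abs), n = sum(n), .groups = "drop")
  total <- pred |>
    dplyr::group_by(model, outer_fold) |>
    dplyr::summarise(s_abs = sum(abs(actual - predicted)), n = dplyr::n(),
                     .groups = "drop")
  expect_equal(by_sub$s_abs, total$s_abs)
  expect_equal(by_sub$n, total$n)
})
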