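test_that("fit_rate recovers an exact line and applies the labeling correction", {
  f <- suppressWarnings(fit_rate(exact_series(100, 100)))
  expect_equal(f$rate, 100, tolerance = 1e-10)
  expect_true(f$detected)
  expect_equal(standard_error_of_rate(f), 0, tolerance = 1e-8)
  # labeling correction is exact inverse scaling: observed production at
  # label fraction 92.7% maps back to 100/0.927 per unit of substrate
  f2 <- suppressWarnings(fit_rate(exact_series(100, 100), label_excess = 92.7))
  expect_rel(f2$rate, 107.9, 0.001)
  expect_equal(f2$rate, f2$slope * 24 * 100 / 92.7)
})

test_that("a flat noisy series is below detection", {
  set.seed(11)
  tt <- rep(c(0, 6, 12, 24), 3)
  ts <- tracer_timeseries(tt, rnorm(12, 50, 5), rep(1:3, each = 4))
  f <- fit_rate(ts)
  expect_false(f$detected)
  # the rate is retained, not dropped
  expect_true(is.finite(f$rate))
})

test_that("degenerate designs and bad labeling are rejected", {
  expect_error(tracer_timeseries(c(5, 5, 5), c(1, 2, 3), 1:3), "degenerate")
  expect_error(fit_rate(exact_series(), label_excess = -10), "positive")
})

test_that("pooled fit is invariant to permuting replicate labels", {
  set.seed(3)
  tt <- rep(c(0, 6, 12, 24), 3)
  y <- 2 * tt + rnorm(12, 0, 4)
  a <- fit_rate(tracer_timeseries(tt, y, rep(1:3, each = 4)))
  b <- fit_rate(tracer_timeseries(tt, y, sample(rep(1:3, each = 4))))
  expect_identical(a$rate, b$rate)
  expect_identical(a$p_value, b$p_value)
})

test_that("slope SE matches the analytic OLS formula under known noise", {
  # single simulated dataset: compare against the closed-form OLS SE computed
  # from residuals, then check the Monte-Carlo spread against sigma/sqrt(Sxx)
  set.seed(21)
  tt <- rep(c(0, 6, 12, 24), 3)
  sigma <- 5
  sxx <- sum((tt - mean(tt))^2)
  slopes <- replicate(400, {
    y <- 3 * tt + rnorm(12, 0, sigma)
    fit_rate(tracer_timeseries(tt, y, rep(1:3, each = 4)))$slope
  })
  expect_rel(sd(slopes), sigma / sqrt(sxx), 0.15)
  # doubling the replicate count shrinks the SE by ~sqrt(2)
  tt2 <- rep(c(0, 6, 12, 24), 6)
  slopes2 <- replicate(400, {
    y <- 3 * tt2 + rnorm(24, 0, sigma)
    fit_rate(tracer_timeseries(tt2, y, rep(1:6, each = 4)))$slope
  })
  expect_rel(sd(slopes) / sd(slopes2), sqrt(2), 0.2)
})

test_that("nominal 95% slope intervals cover the truth about 95% of the time", {
  set.seed(5)
  tt <- rep(c(0, 6, 12, 24), 3)
  true_slope <- 2
  cover <- replicate(300, {
    y <- true_slope * tt + rnorm(12, 0, 6)
    f <- fit_rate(tracer_timeseries(tt, y, rep(1:3, each = 4)))
    tcrit <- qt(0.975, df = 10)
    abs(f$slope - true_slope) <= tcrit * f$slope_se
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("time-series CSV reader/writer round-trips", {
  tmp <- tempfile(fileext = ".csv")
  tt <- rep(c(0, 6, 12, 24), 3)
  df <- data.frame(incubation_id = "inc1", substrate = "nitrite",
                   replicate = rep(1:3, each = 4), time_h = tt,
                   product_15N_nmol_L = 2 * tt + 1)
  write.csv(df, tmp, row.names = FALSE)
  series <- read_timeseries_csv(tmp, label_excess = c(inc1 = 84.3))
  expect_named(series, "inc1")
  expect_equal(attr(series$inc1, "label_excess"), 84.3)
  expect_equal(series$inc1$product_15N_nmol_L, df$product_15N_nmol_L)
  fits <- suppressWarnings(lapply(series, fit_rate))
  out <- tempfile(fileext = ".csv")
  tab <- write_rate_table(fits, out)
  back <- read.csv(out)
  expect_equal(back$rate_nmol_L_d, tab$rate_nmol_L_d)
  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_timeseries_csv(bad), "missing columns")
})
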