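test_that("cell_enrichment sums planes, converts to excess, applies the filter", {
  # natural-abundance cell with ample counts: zero excess, passes
  enr <- cell_enrichment(n15 = rep(37, 40), n14 = rep(9963, 40))
  expect_equal(enr$n15_excess, 0, tolerance = 1e-10)
  expect_true(enr$passed_filter)
  # enriched cell: 5 at% fraction -> 4.63 at% excess
  enr <- cell_enrichment(500, 9500)
  expect_equal(enr$n15_excess, 4.63)
  # starved counts fail the filter with a ~32% error
  enr <- cell_enrichment(10, 90)
  expect_false(enr$passed_filter)
  expect_rel(enr$n_error, sqrt(1/10 + 1/90), 1e-10)
  expect_error(cell_enrichment(numeric(0), numeric(0)), "empty")
})

test_that("C and N filters are applied independently", {
  enr <- cell_enrichment(n15 = 5000, n14 = 95000, c13 = 10, c12 = 500)
  expect_true(enr$passed_n)
  expect_false(enr$passed_c)
  expect_false(enr$passed_filter)
})

test_that("n_assimilation_rate implements the enrichment-to-quota scaling", {
  # full turnover: excess equals the label, quota of 14 fg over one day
  r <- n_assimilation_rate(92.7, 92.7, 14, 1)
  expect_equal(r$rate_fg, 14)
  expect_equal(r$rate_fmol, 1)
  expect_equal(n_assimilation_rate(0, 92.7, 15, 1)$rate_fg, 0)
  r <- n_assimilation_rate(5, 92.7, 15.1, 1)
  expect_rel(r$rate_fg, 0.814, 0.001)
  expect_rel(r$rate_fmol, 0.058, 0.01)
  expect_error(n_assimilation_rate(5, 0, 15, 1), "label_excess")
  expect_error(n_assimilation_rate(5, 92.7, 15, 0), "time")
})

test_that("fg and fmol rates keep the exact /14 relation for any input", {
  set.seed(9)
  ex <- runif(200, 0, 50); quota <- runif(200, 1, 30)
  r <- n_assimilation_rate(ex, 84.3, quota, 1)
  expect_identical(r$rate_fmol, r$rate_fg / 14)
})

test_that("growth models behave as documented", {
  expect_equal(growth_rate_from_enrichment(0, 90, 1), 0)
  expect_equal(growth_rate_from_enrichment(0.53 * 92.7, 92.7, 1), 0.53)
  expect_equal(growth_rate_from_enrichment(45, 90, 1, "exponential"), log(2))
  expect_error(growth_rate_from_enrichment(95, 90, 1, "exponential"),
               "undefined")
  # linear growth rate == assimilation rate / quota when they share fgN
  fgN <- 15.09; le <- 84.3; ex <- 7.2; t <- 1
  gr <- growth_rate_from_enrichment(ex, le, t)
  ar <- n_assimilation_rate(ex, le, fgN, t)
  expect_equal(gr, ar$rate_fg / fgN)
})

test_that("Redfield C-from-N conversion and substrate combination", {
  expect_rel(c_assim_from_n(0.91), 6.03, 0.002)
  expect_equal(c_assim_from_n(0), 0)
  expect_rel(c_assim_from_n(0.12), 0.795, 0.001)
  expect_equal(combine_substrates(c(ammonium = 0.42, urea = 0.43,
                                    cyanate = 0.05, nitrite = 0.003)), 0.903)
  expect_equal(combine_substrates(c(a = 0.11, b = 0.005, c = 0.004)), 0.119)
  expect_equal(combine_substrates(c(urea = 0.3)), 0.3)
  expect_warning(combine_substrates(c(ammonium = 0.4),
                                    expected = c("ammonium", "urea")),
                 "urea")
})

test_that("group comparison is a one-sided rank-sum test", {
  # identical distributions -> p near 0.5 one-sided
  set.seed(2)
  x <- rnorm(50, 5)
  cmp <- compare_enrichment_groups(x, sample(x))
  expect_gt(cmp$p_value, 0.2)
  # disjoint supports, n = 10 each: W = 100, p = 1/choose(20,10) exactly
  a <- 11:20; b <- 1:10
  cmp <- compare_enrichment_groups(a, b)
  expect_equal(cmp$statistic, 100)
  expect_equal(cmp$p_value, 1 / choose(20, 10))
  # permutation within groups leaves the statistic unchanged
  cmp2 <- compare_enrichment_groups(sample(a), sample(b))
  expect_identical(cmp2$statistic, cmp$statistic)
  expect_error(compare_enrichment_groups(numeric(0), 1:3), "non-empty")
})

test_that("cell_rates drives the per-cell chain end to end", {
  sim <- simulate_nanosims_cells(tiny_scenario(cells = 6, planes = 20),
                                 "ammonium")
  tab <- cell_rates(sim$roi[sim$roi$taxon == "target_NOB", ],
                    label_excess = sim$truth$label_excess[1], t = 1,
                    quota_mode = "population", fgN_cell = 100 / 6.625)
  expect_equal(nrow(tab), 6)
  expect_identical(tab$n_assim_fmol, tab$n_assim_fg / 14)
  expect_equal(tab$c_assim_fmol, tab$n_assim_fmol * 6.625)
  # per-cell quota mode derives a volume from the ROI area
  tab2 <- cell_rates(sim$roi[sim$roi$taxon == "target_NOB", ],
                     label_excess = sim$truth$label_excess[1], t = 1,
                     quota_mode = "per_cell", shape = "capsule",
                     aspect_ratio = 3)
  expect_true(all(is.finite(tab2$volume_um3)))
  expect_true(all(tab2$fgN_cell > 0))
})

test_that("ROI table reader validates schema and negative counts", {
  tmp <- tempfile(fileext = ".tsv")
  sim <- simulate_nanosims_cells(tiny_scenario(cells = 3, planes = 4),
                                 "ammonium")
  write_roi_table(sim$roi, tmp)
  back <- read_roi_table(tmp)
  expect_equal(back$n15_counts, sim$roi$n15_counts)
  bad <- sim$roi; bad$n15_counts[1] <- -5
  write_roi_table(bad, tmp)
  expect_error(read_roi_table(tmp), "negative")
})
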