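test_that("same seed gives identical datasets, different seeds differ", {
  cfg <- tiny_scenario()
  a <- simulate_incubation_series(cfg, seed = 7)
  b <- simulate_incubation_series(cfg, seed = 7)
  expect_identical(a, b)
  c <- simulate_incubation_series(cfg, seed = 8)
  expect_false(identical(a$nitrite$product_15N_nmol_L,
                         c$nitrite$product_15N_nmol_L))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_nanosims_cells(cfg, "ammonium"))
  expect_identical(rnorm(1), before)
})

test_that("written synthetic datasets are byte-identical under a fixed seed", {
  cfg <- tiny_scenario()
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_synthetic_dataset(cfg, d1, seed = 5)
  p2 <- write_synthetic_dataset(cfg, d2, seed = 5)
  for (f in c("timeseries", "roi", "counts")) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])))
  }
})

test_that("noiseless series are exact lines that fit_rate recovers exactly", {
  cfg <- tiny_scenario()
  cfg$incubation$noise_sd <- 0
  series <- simulate_incubation_series(cfg)
  f <- suppressWarnings(fit_rate(series$nitrite))
  expect_equal(f$rate, 564, tolerance = 1e-9)
  f <- suppressWarnings(fit_rate(series$ammonium))
  expect_equal(f$rate, 2508, tolerance = 1e-9)
})

test_that("rate recovery is unbiased over repeated simulations", {
  cfg <- tiny_scenario()
  rates <- vapply(1:60, function(i) {
    s <- simulate_incubation_series(cfg, seed = 1000 + i)
    fit_rate(s$nitrite)$rate
  }, numeric(1))
  # SE of the mean ~ 9.3/sqrt(60): a 4-sigma band around the truth
  expect_lt(abs(mean(rates) - 564), 5)
})

test_that("simulated cells carry ground truth that the estimators recover", {
  cfg <- tiny_scenario(cells = 30, planes = 40)
  cfg$nanosims$mean_counts_per_plane <- 5000
  sim <- simulate_nanosims_cells(cfg, "ammonium", seed = 2)
  nob <- sim$roi[sim$roi$taxon == "target_NOB", ]
  truth <- sim$truth[sim$truth$taxon == "target_NOB", ]
  tab <- cell_rates(nob, label_excess = truth$label_excess[1], t = 1,
                    quota_mode = "population", fgN_cell = 15.09)
  expect_true(all(tab$passed_filter))
  # mean recovered growth rate near the configured 0.53/d
  expect_rel(mean(tab$growth_rate_n), 0.53, 0.05)
  # per-cell excess centered on the truth
  expect_rel(mean(tab$n15_excess), truth$true_excess[1], 0.05)
})

test_that("zero growth yields excess centered at zero", {
  cfg <- tiny_scenario(cells = 40, planes = 20)
  cfg$populations[[1]]$growth_rates$ammonium <- 0
  cfg$populations <- cfg$populations[1]
  sim <- simulate_nanosims_cells(cfg, "ammonium", seed = 3)
  enr <- vapply(split(sim$roi, sim$roi$cell_id), function(d)
    cell_enrichment(d$n15_counts, d$n14_counts)$n15_excess, numeric(1))
  se <- sd(enr) / sqrt(length(enr))
  expect_lt(abs(mean(enr)), 4 * se + 1e-4)
})

test_that("low ion counts fail the Poisson filter at the predicted frequency", {
  cfg <- tiny_scenario(cells = 50, planes = 4)
  cfg$nanosims$mean_counts_per_plane <- 60   # ~240 total ions per cell
  cfg$nanosims$area_cv <- 1e-6
  cfg$populations <- cfg$populations[1]
  sim <- simulate_nanosims_cells(cfg, "ammonium", seed = 6)
  res <- vapply(split(sim$roi, sim$roi$cell_id), function(d)
    poisson_error_filter(d$n15_counts, d$n14_counts)$pass, logical(1))
  # expected minor counts: x* ~ 0.449 at GR 0.53 -> ~108 minor ions,
  # error ~ sqrt(1/108 + 1/132) ~ 0.13: virtually every cell must fail
  expect_lt(mean(res), 0.1)
})

test_that("simulated counts recover the configured growth rate", {
  cfg <- tiny_scenario()
  cfg$counting$expected_counted_cells <- 2000
  counts <- simulate_cell_counts(cfg, seed = 11)
  nob <- counts[counts$taxon == "target_NOB", ]
  est <- growth_rate_counts_se(
    nob$observed_cells_per_L[1], nob$observed_cells_per_L[2], 1,
    nob$counted_cells[1], nob$counted_cells[2])
  expect_lt(abs(est$gr - 1.2), 4 * est$gr_se)
})

test_that("the reference scenario encodes its stated world", {
  cfg <- gom_fixture()
  expect_equal(cfg$incubation$timepoints_h, c(0, 6, 12, 24))
  expect_equal(cfg$incubation$replicates, 3)
  expect_equal(cfg$incubation$tracer_addition_M, 5e-6)
  expect_equal(cfg$bulk_rates, c(target_AOA = 2508, target_NOB = 564))
  expect_equal(cfg$delta_g, c(target_AOA = -262, target_NOB = -65))
  # mean of t0/t24 abundances reproduces the average-count convention
  for (pop in cfg$populations) {
    nt <- pop$abundance_t0 * exp(pop$combined_growth_rate)
    expect_rel(mean_abundance(pop$abundance_t0, nt), pop$abundance, 1e-10)
  }
})
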