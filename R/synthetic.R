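# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Scenario configuration for the synthetic-data generators
#'
#' Declares the "world" the generators emulate: population abundances, cell
#' shapes and per-substrate growth rates; the incubation design (triplicates
#' sampled at 0/6/12/24 h after 5 µM tracer additions); true bulk rates and
#' measurement noise; and the nanoSIMS acquisition (planes, mean ion counts,
#' cells measured).
#'
#' @param seed Base seed; every generator derives its stream from this.
#' @param populations List of population descriptions; each a list with
#'   `taxon`, `abundance` (cells/L), `shape`, `length_um`, `width_um`,
#'   `growth_rates` (named per substrate, d^-1), `combined_growth_rate`
#'   (d^-1, drives the cell-count dynamics), `fgC` (carbon quota anchor).
#' @param incubation List: `duration_d`, `timepoints_h`, `replicates`,
#'   `tracer_addition_M`, `tracer_purity`, `ambient_M` (named, mol/L),
#'   `true_bulk_rates` (named, nmol/L/d), `noise_sd` (nmol/L, Gaussian
#'   instrument noise on concentrations).
#' @param nanosims List: `planes`, `mean_counts_per_plane` (total N ions per
#'   plane for a nominal-area cell), `cells_per_taxon`, `area_cv`
#'   (lognormal CV of ROI areas).
#' @param counting List: `expected_counted_cells` per census (Poisson
#'   counting effort for microscopy abundances).
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(seed = 1L, populations, incubation, nanosims,
                            counting = list(expected_counted_cells = 500)) {
  stopifnot(is.list(populations), length(populations) >= 1)
  stopifnot(all(diff(incubation$timepoints_h) > 0),
            all(incubation$timepoints_h >= 0))
  if (any(unlist(incubation$true_bulk_rates) < 0))
    stop("bulk rates must be non-negative")
  structure(list(seed = as.integer(seed), populations = populations,
                 incubation = incubation, nanosims = nanosims,
                 counting = counting),
            class = "scenario_config")
}

#' Labeling state of a scenario substrate pool
#'
#' @param cfg A [scenario_config()].
#' @param substrate Substrate name present in the scenario's ambient pools.
#' @return A [labeling_state()].
#' @export
scenario_labeling <- function(cfg, substrate) {
  inc <- cfg$incubation
  ambient <- inc$ambient_M[[substrate]]
  if (is.null(ambient)) stop("no ambient pool for substrate: ", substrate)
  labeling_state(substrate, inc$tracer_addition_M, ambient,
                 tracer_atom_fraction = inc$tracer_purity %||% 0.99)
}

#' Simulate tracer incubation time series
#'
#' For each substrate with a true bulk rate, generates replicate 15N-product
#' concentrations as `rate * (label_excess/100) * t/24 + noise`, Gaussian
#' noise with the configured sd. Deterministic under a fixed seed.
#'
#' @param cfg A [scenario_config()].
#' @param seed Seed (defaults to the scenario's).
#' @return Named list of [tracer_timeseries()], one per substrate.
#' @export
simulate_incubation_series <- function(cfg, seed = cfg$seed) {
  inc <- cfg$incubation
  with_seed(seed, {
    out <- lapply(names(inc$true_bulk_rates), function(sub) {
      rate <- inc$true_bulk_rates[[sub]]
      le <- labeling_atom_percent(scenario_labeling(cfg, sub))
      tt <- rep(inc$timepoints_h, times = inc$replicates)
      rep_id <- rep(seq_len(inc$replicates), each = length(inc$timepoints_h))
      mu <- rate * (le / 100) * tt / 24
      obs <- mu + stats::rnorm(length(tt), 0, inc$noise_sd)
      tracer_timeseries(tt, obs, rep_id, substrate = sub, label_excess = le)
    })
    stats::setNames(out, names(inc$true_bulk_rates))
  })
}

#' Simulate nanoSIMS cell ROI tables
#'
#' For each population and labeled substrate, draws cells whose true atom
#' fraction is `natural + GR_true * t * label_excess/100 / 100` (linear label
#' accumulation over the incubation), then per acquisition plane draws
#' `minor ~ Poisson(x lambda)` and `major ~ Poisson((1-x) lambda)`, with
#' `lambda` scaled by the cell's ROI area relative to the nominal area of
#' its shape. ROI areas vary lognormally.
#'
#' @param cfg A [scenario_config()].
#' @param substrate Which labeled substrate's incubation to emulate.
#' @param seed Seed.
#' @return A list with `roi` (data.frame in the ROI-table schema) and
#'   `truth` (per-cell true excess and growth rate).
#' @export
simulate_nanosims_cells <- function(cfg, substrate = "ammonium",
                                    seed = cfg$seed) {
  ns <- cfg$nanosims
  t_d <- cfg$incubation$duration_d
  le <- labeling_atom_percent(scenario_labeling(cfg, substrate))
  nat <- natural_abundance()$n15_fraction
  with_seed(seed, {
    rois <- list(); truths <- list()
    for (pop in cfg$populations) {
      gr <- pop$growth_rates[[substrate]]
      if (is.null(gr)) next
      # linear label accumulation: excess (at%) = gr * t * le, fraction = /100
      x_true <- nat + gr * t_d * (le / 100)
      nominal_area <- switch(pop$shape,
        capsule = pop$width_um * (pop$length_um - pop$width_um) +
          pi * pop$width_um^2 / 4,
        prolate_spheroid = pi / 4 * pop$length_um * pop$width_um)
      n_cells <- ns$cells_per_taxon
      areas <- nominal_area *
        stats::rlnorm(n_cells, -0.5 * log(1 + (ns$area_cv %||% 0.2)^2),
                      sqrt(log(1 + (ns$area_cv %||% 0.2)^2)))
      for (i in seq_len(n_cells)) {
        lambda <- ns$mean_counts_per_plane * areas[i] / nominal_area
        minor <- stats::rpois(ns$planes, x_true * lambda)
        major <- stats::rpois(ns$planes, (1 - x_true) * lambda)
        id <- sprintf("%s_%s_%03d", pop$taxon, substrate, i)
        rois[[id]] <- data.frame(
          cell_id = id, taxon = pop$taxon, plane = seq_len(ns$planes) - 1L,
          area_um2 = areas[i], n15_counts = minor, n14_counts = major,
          incubation_id = substrate, stringsAsFactors = FALSE)
        truths[[id]] <- data.frame(
          cell_id = id, taxon = pop$taxon, substrate = substrate,
          true_growth_rate = gr, true_excess = gr * t_d * le,
          label_excess = le, stringsAsFactors = FALSE)
      }
    }
    roi <- do.call(rbind, rois); rownames(roi) <- NULL
    truth <- do.call(rbind, truths); rownames(truth) <- NULL
    list(roi = roi, truth = truth)
  })
}

#' Simulate microscopy cell-count censuses
#'
#' Populations grow exponentially at their combined growth rate;
#' observed abundances carry Poisson counting error at the configured
#' counting effort (expected cells actually counted per census).
#'
#' @param cfg A [scenario_config()].
#' @param seed Seed.
#' @return data.frame with columns `taxon, timepoint, true_cells_per_L,
#'   observed_cells_per_L, counted_cells, t_d`.
#' @export
simulate_cell_counts <- function(cfg, seed = cfg$seed) {
  t_d <- cfg$incubation$duration_d
  effort <- cfg$counting$expected_counted_cells
  with_seed(seed, {
    rows <- lapply(cfg$populations, function(pop) {
      gr <- pop$combined_growth_rate
      n0 <- pop$abundance_t0 %||% pop$abundance
      nt <- n0 * exp(gr * t_d)
      c0 <- stats::rpois(1, effort)
      ct <- stats::rpois(1, effort * nt / n0)
      data.frame(taxon = pop$taxon,
                 timepoint = c("t0", "t24"),
                 true_cells_per_L = c(n0, nt),
                 observed_cells_per_L = c(n0 * c0 / effort,
                                          n0 * ct / effort),
                 counted_cells = c(c0, ct),
                 t_d = t_d, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows); rownames(out) <- NULL
    out
  })
}

#' Reference scenario: Gulf-of-Mexico-style nitrifier world
#'
#' The stated world behind the worked examples and recovery tests: a
#' nitrite-oxidizer population (capsule-shaped cells, 0.25 µm³, 100 fg-C,
#' 1.32e7 cells/L average abundance, bulk nitrite oxidation 564 nmol/L/d,
#' ammonium-based growth 0.53 d^-1, combined growth 1.2 d^-1, catabolic
#' energy -65 kJ/mol) and an ammonia-oxidizer population (prolate spheroids
#' 0.6 x 0.4 µm, 0.06 µm³, 50 fg-C, 4.15e8 cells/L, bulk ammonia oxidation
#' 2508 nmol/L/d, ammonium growth 0.23 d^-1, combined 0.25 d^-1,
#' -262 kJ/mol). Ambient pools: ammonium 320 nM, nitrite 848 nM, nitrate
#' 2250 nM; 5 µM tracer additions; triplicates at 0/6/12/24 h;
#' 40 nanoSIMS planes.
#'
#' Start-of-incubation abundances are back-computed so that the mean of the
#' t0 and t24 abundances equals the average abundance above.
#'
#' @param seed Base seed.
#' @return A [scenario_config()] with extra fields `delta_g`,
#'   `c_assim_n_based`, `c_assim_measured` (per taxon) used by the yield
#'   chain.
#' @export
gom_fixture <- function(seed = 1L) {
  gr_nob <- 1.2; gr_aoa <- 0.25; t_d <- 1
  mean_nob <- 1.32e7; mean_aoa <- 4.15e8
  n0_nob <- mean_nob * 2 / (1 + exp(gr_nob * t_d))
  n0_aoa <- mean_aoa * 2 / (1 + exp(gr_aoa * t_d))
  cfg <- scenario_config(
    seed = seed,
    populations = list(
      list(taxon = "target_NOB", abundance = mean_nob, abundance_t0 = n0_nob,
           shape = "capsule", length_um = 1.48, width_um = 0.49,
           volume_um3 = 0.25, fgC = 100,
           growth_rates = list(ammonium = 0.53),
           combined_growth_rate = gr_nob),
      list(taxon = "target_AOA", abundance = mean_aoa, abundance_t0 = n0_aoa,
           shape = "prolate_spheroid", length_um = 0.6, width_um = 0.4,
           volume_um3 = 0.06, fgC = 50,
           growth_rates = list(ammonium = 0.23),
           combined_growth_rate = gr_aoa)),
    incubation = list(
      duration_d = t_d, timepoints_h = c(0, 6, 12, 24), replicates = 3,
      tracer_addition_M = 5e-6, tracer_purity = 0.99,
      ambient_M = list(ammonium = 320e-9, nitrite = 848e-9,
                       urea = 69e-9, cyanate = 11.5e-9),
      true_bulk_rates = list(nitrite = 564, ammonium = 2508),
      noise_sd = 10),
    nanosims = list(planes = 40, mean_counts_per_plane = 5000,
                    cells_per_taxon = 50, area_cv = 0.2))
  cfg$delta_g <- c(target_AOA = -262, target_NOB = -65)
  cfg$bulk_rates <- c(target_AOA = 2508, target_NOB = 564)
  cfg$c_assim_n_based <- c(target_AOA = 404, target_NOB = 79)
  cfg$c_assim_measured <- c(target_AOA = 69, target_NOB = 17)
  cfg
}

#' Write a full synthetic dataset to disk
#'
#' Emits the ROI TSV, time-series CSV and count CSV that the readers consume,
#' plus a ground-truth JSON. Same seed, same bytes.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @param seed Seed.
#' @param substrate Substrate for the nanoSIMS simulation.
#' @return Invisibly, the list of written paths.
#' @export
write_synthetic_dataset <- function(cfg, dir, seed = cfg$seed,
                                    substrate = "ammonium") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- simulate_incubation_series(cfg, seed)
  ts_df <- do.call(rbind, lapply(names(series), function(s) {
    d <- as.data.frame(series[[s]])
    data.frame(incubation_id = s, substrate = s, replicate = d$replicate,
               time_h = d$time_h, product_15N_nmol_L = d$product_15N_nmol_L)
  }))
  sim <- simulate_nanosims_cells(cfg, substrate, seed = seed + 1L)
  counts <- simulate_cell_counts(cfg, seed = seed + 2L)
  count_df <- data.frame(station = "S1", depth_m = 14,
                         taxon = counts$taxon, timepoint = counts$timepoint,
                         cells_per_ml = counts$observed_cells_per_L / 1000,
                         filter_fields_counted = NA,
                         counted_cells = counts$counted_cells)
  paths <- list(timeseries = file.path(dir, "timeseries.csv"),
                roi = file.path(dir, "roi.tsv"),
                counts = file.path(dir, "counts.csv"),
                truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(ts_df, paths$timeseries, row.names = FALSE)
  write_roi_table(sim$roi, paths$roi)
  utils::write.csv(count_df, paths$counts, row.names = FALSE)
  truth <- list(seed = seed,
                bulk_rates = cfg$incubation$true_bulk_rates,
                cells = sim$truth, counts = counts)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
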