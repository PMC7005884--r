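# shared fixtures and assertion helpers

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

# a noiseless triplicate series with a known daily production rate
exact_series <- function(rate_per_day = 100, label_excess = 100,
                         times = c(0, 6, 12, 24), reps = 3) {
  tt <- rep(times, reps)
  tracer_timeseries(tt, rate_per_day * (label_excess / 100) * tt / 24,
                    rep(seq_len(reps), each = length(times)),
                    label_excess = label_excess)
}

# small scenario for fast generator tests
tiny_scenario <- function(seed = 42L, cells = 10, planes = 8) {
  cfg <- gom_fixture(seed)
  cfg$nanosims$cells_per_taxon <- cells
  cfg$nanosims$planes <- planes
  cfg
}
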