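# Shared fixtures and comparison helpers.

expect_rel <- function(actual, reference, tol = 0.005) {
  expect_lt(abs(actual - reference) / abs(reference), tol)
}

# relative difference, for use inside loops
rel_diff <- function(a, b) abs(a - b) / abs(b)

default_params <- function() {
  list(baseline = national_baseline(),
       breeds = default_breeds(),
       managements = default_managements(),
       feed = feed_model())
}

# a tiny exactly-known performance table: weight 2.93 kg and cumulative
# feed 6.281081 kg at day 47 (the national per-bird statistics), linear
# between nodes
calibrated_ross_table <- function() {
  ages <- c(0, 10, 20, 30, 40, 47, 55)
  performance_table("Ross308", ages,
                    live_weight_kg = 2.93 * ages / 47,
                    cumulative_feed_kg = (58.1e9 / 9.25e9) * ages / 47)
}
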