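test_that("performance tables validate monotonicity and support interpolation", {
  expect_error(performance_table("x", c(1, 1, 2), c(1, 2, 3), c(1, 2, 3)),
               "strictly increasing")
  expect_error(performance_table("x", 1:3, c(1, 0.5, 2), c(1, 2, 3)),
               "non-decreasing")
  expect_error(performance_table("x", 1:3, c(1, 2, 3), c(1, 2, -1)))

  tab <- performance_table("x", c(0, 10, 20), c(0, 1, 3), c(0, 2, 5))
  expect_equal(table_weight_at(tab, 15), 2)   # linear between nodes
  expect_equal(table_feed_at(tab, 5), 1)
  expect_equal(table_weight_at(tab, 20), 3)   # node is exact
  expect_error(table_weight_at(tab, 25), "outside table range")
})

test_that("performance tables round-trip through CSV", {
  tab <- generate_performance_table(generator_spec(seed = 3), "RC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_performance_table(tab, path)
  rt <- read_performance_table(path, breed = "RC", source = "synthetic")
  expect_equal(as.data.frame(rt), as.data.frame(tab), tolerance = 1e-12)
  expect_error(read_performance_table(withr::local_tempfile(), "RC"),
               "not found")
})

test_that("weight scale factor divides national by table weight at slaughter age", {
  b <- national_baseline()
  spec <- generator_spec()
  ross <- generate_performance_table(spec, "Ross308")
  expect_equal(weight_scale_factor(b, ross), 2.93 / 3.35, tolerance = 1e-12)
  expect_rel(weight_scale_factor(b, ross), 0.8746, 1e-4)

  expect_equal(weight_scale_factor(b, calibrated_ross_table()), 1)

  short <- performance_table("Ross308", 0:40, seq(0, 2.5, length.out = 41),
                             seq(0, 4, length.out = 41))
  expect_error(weight_scale_factor(b, short), "outside table range")
})

test_that("scaled slaughter weight multiplies table weight by the factor", {
  spec <- generator_spec()
  rc <- generate_performance_table(spec, "RC")
  expect_equal(scaled_slaughter_weight(rc, 1, 57), table_weight_at(rc, 57))
  expect_equal(scaled_slaughter_weight(rc, 0.8746, 57),
               table_weight_at(rc, 57) * 0.8746)
  expect_error(scaled_slaughter_weight(rc, 0.87, 80), "outside table range")
})

test_that("performance scale factor reconciles table feed with national totals", {
  b <- national_baseline()
  ross <- generate_performance_table(generator_spec(), "Ross308")
  expect_rel(performance_scale_factor(b, ross), 1.35, 1e-3)
  # a table already reporting the national 6.281 kg/bird needs no scaling
  expect_equal(performance_scale_factor(b, calibrated_ross_table()), 1)
})

test_that("self-calibration of the conventional breed is a fixed point", {
  b <- national_baseline()
  ross <- generate_performance_table(generator_spec(), "Ross308")
  self <- calibrate_breed(ross, ross, b, slaughter_age_days = 47,
                          dressing_fraction = 0.74)
  expect_equal(self$scaled_live_weight_kg, 2.93, tolerance = 1e-12)
  expect_equal(self$feed_per_bird_kg, 58.1e9 / 9.25e9, tolerance = 1e-12)
  # the implied slaughter rate reproduces the national statistic exactly
  expect_rel(breed_slaughter_rate(b, self), 9.25e9, 1e-12)
})

test_that("scale factors ignore table rows outside the evaluation age", {
  b <- national_baseline()
  ross <- generate_performance_table(generator_spec(), "Ross308")
  df <- as.data.frame(ross)
  extended <- performance_table("Ross308",
                                c(df$age_days, 60, 70),
                                c(df$live_weight_kg, 4.6, 5.2),
                                c(df$cumulative_feed_kg, 8, 10))
  expect_equal(weight_scale_factor(b, extended), weight_scale_factor(b, ross))
  expect_equal(performance_scale_factor(b, extended),
               performance_scale_factor(b, ross))
})

test_that("calibration recovers the generator's breed parameters within 1%", {
  b <- national_baseline()
  spec <- generator_spec(seed = 11)
  ross <- generate_performance_table(spec, "Ross308")
  defaults <- default_breeds()
  ages <- c(RC = 57, RG = 57, RR = 69)
  for (nm in names(ages)) {
    tab <- generate_performance_table(spec, nm)
    cal <- calibrate_breed(tab, ross, b, slaughter_age_days = ages[[nm]])
    truth <- attr(tab, "truth")
    # feed per bird: table truth times the true performance factor
    expect_rel(cal$feed_per_bird_kg,
               truth$feed_at_slaughter_kg * truth$performance_scale_factor,
               0.01)
    # and it matches the package's effective defaults
    expect_rel(cal$feed_per_bird_kg, defaults[[nm]]$feed_per_bird_kg, 0.01)
    # scaled weight: table truth times the true weight factor
    expect_rel(cal$scaled_live_weight_kg,
               truth$weight_at_slaughter_kg * truth$weight_scale_factor,
               0.01)
    # demographic scaling agrees with the published multipliers
    expect_rel(breed_slaughter_rate(b, cal) / b$slaughter_rate_yr,
               defaults[[nm]]$slaughter_multiplier, 0.01)
  }
})

test_that("calibration is insensitive to daily-resolution interpolation", {
  b <- national_baseline()
  spec <- generator_spec()
  ross <- generate_performance_table(spec, "Ross308")
  # thin the table to every third day and evaluate at a non-node age
  df <- as.data.frame(ross)
  keep <- seq(1, nrow(df), by = 3)
  thinned <- performance_table("Ross308", df$age_days[keep],
                               df$live_weight_kg[keep],
                               df$cumulative_feed_kg[keep])
  expect_rel(weight_scale_factor(b, thinned), weight_scale_factor(b, ross),
             0.005)
  expect_rel(performance_scale_factor(b, thinned),
             performance_scale_factor(b, ross), 0.005)
})
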