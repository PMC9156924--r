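test_that("generation is deterministic in the seed", {
  s1 <- generator_spec(seed = 1, noise_sd = 0.02)
  s1b <- generator_spec(seed = 1, noise_sd = 0.02)
  s2 <- generator_spec(seed = 2, noise_sd = 0.02)
  t1 <- generate_performance_table(s1, "Ross308")
  expect_identical(as.data.frame(t1),
                   as.data.frame(generate_performance_table(s1b, "Ross308")))
  expect_false(identical(as.data.frame(t1),
                         as.data.frame(generate_performance_table(s2, "Ross308"))))
  # generation does not disturb the session RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_performance_table(s1, "RC"))
  expect_identical(runif(3), before)
})

test_that("zero-noise tables are the exact analytic curves and hit their anchors", {
  spec <- generator_spec(noise_sd = 0)
  for (nm in c("Ross308", "RC", "RG", "RR")) {
    tab <- generate_performance_table(spec, nm)
    g <- spec$breeds[[nm]]
    w_expected <- g$w_asym *
      exp(-exp(-g$growth_rate_day * (tab$age_days - g$inflection_days)))
    expect_equal(tab$live_weight_kg, w_expected, tolerance = 1e-12)
    expect_equal(table_weight_at(tab, g$slaughter_age_days),
                 g$anchor_weight_kg, tolerance = 1e-9)
    expect_equal(table_feed_at(tab, g$slaughter_age_days),
                 g$anchor_feed_kg, tolerance = 1e-9)
    expect_gte(max(tab$age_days), g$slaughter_age_days)
    expect_equal(min(tab$age_days), 0)
  }
})

test_that("noisy tables stay monotone and near the clean curve", {
  clean <- generate_performance_table(generator_spec(noise_sd = 0), "RR")
  for (seed in 1:5) {
    tab <- generate_performance_table(generator_spec(seed, noise_sd = 0.03),
                                      "RR")
    expect_true(all(diff(tab$live_weight_kg) >= 0))
    expect_true(all(diff(tab$cumulative_feed_kg) >= 0))
    expect_lt(max(abs(tab$live_weight_kg / clean$live_weight_kg - 1)), 0.25)
  }
})

test_that("calibration recovers the constructed true scale factors", {
  # a conventional table reading 3.35 kg and 4.653 kg feed at day 47
  # implies factors 2.93/3.35 = 0.8746 and 6.281/4.653 = 1.35
  b <- national_baseline()
  ross <- generate_performance_table(generator_spec(), "Ross308")
  expect_rel(weight_scale_factor(b, ross), 0.8746, 1e-4)
  expect_rel(performance_scale_factor(b, ross), 1.35, 1e-3)
})

test_that("noise-free national statistics reproduce the published baseline", {
  spec <- generator_spec()
  stats <- generate_national_stats(spec)
  ref <- national_baseline()
  for (f in names(unclass(ref)))
    expect_rel(stats[[f]], ref[[f]], 1e-3)

  zero <- generate_national_stats(spec, slaughter_rate_yr = 0)
  expect_identical(zero$feed_total_mmt, 0)
  expect_identical(zero$maize_mass_mmt, 0)
  expect_identical(zero$hen_placement_rate_yr, 0)
})

test_that("noisy national statistics differ by seed but stay self-consistent", {
  a <- generate_national_stats(generator_spec(seed = 1),
                               reporting_noise_sd = 0.02)
  b <- generate_national_stats(generator_spec(seed = 2),
                               reporting_noise_sd = 0.02)
  expect_false(a$feed_total_mmt == b$feed_total_mmt)
  for (x in list(a, b)) {
    expect_s3_class(x, "national_baseline")
    # steady state p = tau f holds for any generated baseline
    pop <- steady_state_population(x$slaughter_rate_yr,
                                   x$broiler_residence_days)
    expect_rel(pop, x$slaughter_rate_yr * x$broiler_residence_days / 365,
               1e-12)
    expect_lte(x$maize_mass_mmt + x$soy_mass_mmt, x$feed_total_mmt)
  }
})

test_that("synthetic table files and manifest are written and readable", {
  dir <- withr::local_tempdir()
  spec <- generator_spec(seed = 5)
  write_synthetic_tables(spec, dir)
  for (nm in names(spec$breeds)) {
    tab <- read_performance_table(file.path(dir, paste0(nm, ".csv")),
                                  breed = nm, source = "synthetic")
    expect_s3_class(tab, "performance_table")
  }
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$seed, 5)
  expect_equal(manifest$true_weight_scale_factor, 2.93 / 3.35,
               tolerance = 1e-9)
})

test_that("the full pipeline on synthetic inputs recovers ground truth within 1%", {
  spec <- generator_spec(seed = 17)
  stats <- generate_national_stats(spec)
  ross <- generate_performance_table(spec, "Ross308")
  rr <- generate_performance_table(spec, "RR")
  cal <- calibrate_breed(rr, ross, stats, slaughter_age_days = 69)

  # analytic ground truth from the generator parameters alone
  truth <- attr(rr, "truth")
  w_scaled <- truth$weight_at_slaughter_kg * truth$weight_scale_factor
  rate_truth <- baseline_production_kg(stats) / (w_scaled * 0.76)
  fpb_truth <- truth$feed_at_slaughter_kg * truth$performance_scale_factor
  feed_truth <- rate_truth * fpb_truth / 1e9
  land_truth <- sum(cropland_from_masses(feed_truth * 0.603,
                                         feed_truth * 0.268)) +
    rate_truth * 69 / 365 * 10.12 / 1e6

  fl <- breed_flock(stats, cal)
  fp <- footprint(fl, management_spec("pasture"))
  expect_rel(fp$total_km2, land_truth, 0.01)

  r <- run_scenario(cal, management_spec("pasture"), baseline = stats)
  scale_truth <- baseline_total_land(stats) / land_truth
  expect_rel(r$scale_factor, scale_truth, 0.01)
  expect_rel(r$max_consumption_mmt,
             baseline_production_kg(stats) / 1e9 * scale_truth, 0.01)
})
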