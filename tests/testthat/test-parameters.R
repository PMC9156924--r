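test_that("default baseline carries the published national statistics", {
  b <- national_baseline()
  expect_identical(b$slaughter_rate_yr, 9.25e9)
  expect_identical(b$broiler_residence_days, 47)
  expect_identical(b$hen_placement_rate_yr, 98.0e6)
  expect_identical(b$hen_residence_yr, 0.767)
  expect_identical(b$mean_live_weight_kg, 2.93)
  expect_identical(b$dressing_fraction, 0.74)
  expect_identical(b$feed_total_mmt, 58.1)
  expect_identical(b$maize_mass_mmt, 35.56)
  expect_identical(b$soy_mass_mmt, 15.78)

  f <- feed_model()
  expect_identical(f$maize_fraction, 0.603)
  expect_identical(f$soy_fraction, 0.268)
  expect_identical(f$other_fraction, 0.129)
  expect_identical(f$maize_yield_t_ac, 4.802)
  expect_identical(f$soy_yield_t_ac, 1.403)
  expect_identical(f$m2_per_acre, 4046.8564)

  m <- default_managements()
  expect_identical(m$cafo$cafo_stocking_m2, 0.0743)
  expect_identical(m$outdoor$outdoor_fraction, 0.75)
  expect_identical(m$pasture$pasture_stocking_m2, 10.12)
})

test_that("default breed set encodes the published demographic scaling", {
  br <- default_breeds()
  expect_named(br, c("Ross308", "RC", "RG", "RR"))
  expect_identical(br$Ross308$slaughter_multiplier, 1.0)
  expect_identical(br$RC$slaughter_multiplier, 1.1922)
  expect_identical(br$RG$slaughter_multiplier, 1.35)
  expect_identical(br$RR$slaughter_multiplier, 1.272)
  expect_identical(br$Ross308$residence_days, 47)
  expect_identical(br$RC$residence_days, 57)
  expect_identical(br$RG$residence_days, 57)
  # 69-day grow-out reconciles the slow breed's published multiplier with
  # its published 86.8% population increase: 1.272 * 69/47 = 1.868
  expect_identical(br$RR$residence_days, 69)
  expect_rel(br$RR$slaughter_multiplier * br$RR$residence_days / 47,
             1.868, 1e-3)
  expect_identical(br$Ross308$dressing_fraction, 0.74)
  for (nm in c("RC", "RG", "RR"))
    expect_identical(br[[nm]]$dressing_fraction, 0.76)
  for (b in br) expect_identical(b$mode, "multiplier")
})

test_that("parameter constructors reject out-of-range values", {
  expect_error(national_baseline(dressing_fraction = 1.5), "dressing_fraction")
  expect_error(national_baseline(slaughter_rate_yr = -1), "positive")
  expect_error(national_baseline(maize_mass_mmt = 50, soy_mass_mmt = 20),
               "exceeds")
  expect_error(breed_spec("x", 47, 0.74, slaughter_multiplier = 1,
                          scaled_live_weight_kg = 2.9, feed_per_bird_kg = 6),
               "exactly one")
  expect_error(breed_spec("x", 47, 0.74, feed_per_bird_kg = 6),
               "exactly one")
  expect_error(breed_spec("x", 0.5, 0.74, slaughter_multiplier = 1,
                          feed_per_bird_kg = 6), ">= 1 day")
  expect_error(feed_model(maize_fraction = 0.7), "sum to 1")
  expect_error(management_spec("cafo", cafo_stocking_m2 = 0), "positive")
  expect_error(management_spec("barn"))
})

test_that("empty config loads the full default parameter set", {
  for (src in list(NULL, "")) {
    p <- load_parameters(src)
    expect_identical(unclass(p$baseline), unclass(national_baseline()))
    expect_identical(unclass(p$feed), unclass(feed_model()))
    expect_equal(p$breeds, default_breeds())
    expect_true(all(p$provenance$baseline == "published-default"))
  }
})

test_that("config overrides are applied, validated and provenance-tracked", {
  p <- load_parameters("baseline:\n  mean_live_weight_kg: 3.1\n")
  expect_identical(p$baseline$mean_live_weight_kg, 3.1)
  expect_identical(unname(p$provenance$baseline["mean_live_weight_kg"]),
                   "user-supplied")
  expect_identical(unname(p$provenance$baseline["dressing_fraction"]),
                   "published-default")

  # overriding a field with its default value is a no-op on the record
  q <- load_parameters("feed:\n  maize_yield_t_ac: 4.802\n")
  expect_identical(unclass(q$feed), unclass(feed_model()))

  expect_error(load_parameters("baseline:\n  dressing_fraction: 1.5\n"),
               "dressing_fraction")
  expect_error(load_parameters("baseline:\n  typo_field: 1\n"), "typo_field")
  expect_error(load_parameters("nonsense_section:\n  a: 1\n"),
               "nonsense_section")
})

test_that("writing the default parameter set and re-loading round-trips exactly", {
  p <- load_parameters(NULL)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  q <- load_parameters(path)
  expect_identical(unclass(q$baseline), unclass(p$baseline))
  expect_identical(unclass(q$feed), unclass(p$feed))
  expect_identical(lapply(q$managements, unclass),
                   lapply(p$managements, unclass))
  for (nm in names(p$breeds))
    expect_identical(unclass(q$breeds[[nm]]), unclass(p$breeds[[nm]]))
})

test_that("breed tables round-trip through CSV, both parameterizations", {
  br <- default_breeds()
  br$WT <- breed_spec("WT", 60, 0.76, scaled_live_weight_kg = 2.5,
                      feed_per_bird_kg = 6.0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_breed_table(br, path)
  rt <- read_breed_table(path)
  expect_named(rt, names(br))
  for (nm in names(br)) expect_equal(unclass(rt[[nm]]), unclass(br[[nm]]))
  expect_identical(rt$WT$mode, "weight")
})
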