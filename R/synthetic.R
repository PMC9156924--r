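# Synthetic breeder performance tables and national statistics with known
# ground truth, so calibration and the full scenario pipeline are testable
# without the breeder supplements.
#
# Growth is a Gompertz curve W(t) = Wa * exp(-exp(-k (t - t_infl))); the
# asymptote Wa is derived from an anchor (weight at slaughter age), so the
# noise-free curve passes through the anchor exactly. Cumulative feed is
# FCR(t) * W(t) with FCR linear in age, again anchored at slaughter age.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.gompertz <- function(t, w_asym, k, t_infl) {
  w_asym * exp(-exp(-k * (t - t_infl)))
}

.breed_curve_params <- function(g) {
  w_asym <- g$anchor_weight_kg /
    exp(-exp(-g$growth_rate_day * (g$slaughter_age_days - g$inflection_days)))
  fcr_intercept <- g$anchor_feed_kg / g$anchor_weight_kg -
    g$fcr_slope_day * g$slaughter_age_days
  if (fcr_intercept <= 0)
    .stopf("breed '%s': fcr_slope_day too steep for the feed anchor", g$name)
  c(g, list(w_asym = w_asym, fcr_intercept = fcr_intercept))
}

#' Specification of the synthetic performance-table generator
#'
#' Per-breed Gompertz growth parameters (anchored so the noise-free curve
#' reproduces a stated weight and cumulative feed at slaughter age), a
#' feed-conversion profile linear in age, the true weight and performance
#' scale factors relating table values to national statistics, and a
#' noise scale. Defaults emulate published breeder objectives: the
#' conventional table reads 3.35 kg and 4.653 kg cumulative feed at day
#' 47, so the true factors are 2.93/3.35 = 0.8746 and 6.281/4.653 =
#' 1.3499.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param noise_sd Relative s.d. of multiplicative lognormal measurement
#'   noise on table rows (0 = exact analytic curves, the default).
#' @param breeds Named list of per-breed parameter lists with fields
#'   \code{name}, \code{slaughter_age_days}, \code{anchor_weight_kg},
#'   \code{anchor_feed_kg}, \code{growth_rate_day},
#'   \code{inflection_days}, \code{fcr_slope_day}.
#' @param true_weight_scale_factor,true_performance_scale_factor Ground
#'   truth linking table values to field statistics.
#' @param slaughter_rate_yr,hen_placement_rate_yr,hen_residence_yr,dressing_fraction
#'   National-scale constants used by [generate_national_stats()].
#' @return An object of class \code{generator_spec}.
#' @export
generator_spec <- function(seed = 1L,
                           noise_sd = 0,
                           breeds = NULL,
                           true_weight_scale_factor = 2.93 / 3.35,
                           true_performance_scale_factor = (58.1e9 / 9.25e9) / 4.653,
                           slaughter_rate_yr = 9.25e9,
                           hen_placement_rate_yr = 98.0e6,
                           hen_residence_yr = 0.767,
                           dressing_fraction = 0.74) {
  .check_nonneg(noise_sd, "noise_sd")
  if (is.null(breeds)) {
    breeds <- list(
      Ross308 = list(name = "Ross308", slaughter_age_days = 47,
                     anchor_weight_kg = 3.35, anchor_feed_kg = 4.653,
                     growth_rate_day = 0.050, inflection_days = 32,
                     fcr_slope_day = 0.010),
      RC = list(name = "RC", slaughter_age_days = 57,
                anchor_weight_kg = 2.7360, anchor_feed_kg = 4.7832,
                growth_rate_day = 0.040, inflection_days = 36,
                fcr_slope_day = 0.010),
      RG = list(name = "RG", slaughter_age_days = 57,
                anchor_weight_kg = 2.4162, anchor_feed_kg = 4.1875,
                growth_rate_day = 0.040, inflection_days = 36,
                fcr_slope_day = 0.010),
      RR = list(name = "RR", slaughter_age_days = 69,
                anchor_weight_kg = 2.5643, anchor_feed_kg = 4.8415,
                growth_rate_day = 0.033, inflection_days = 42,
                fcr_slope_day = 0.010)
    )
  }
  breeds <- lapply(breeds, .breed_curve_params)
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 breeds = breeds,
                 true_weight_scale_factor = true_weight_scale_factor,
                 true_performance_scale_factor = true_performance_scale_factor,
                 slaughter_rate_yr = slaughter_rate_yr,
                 hen_placement_rate_yr = hen_placement_rate_yr,
                 hen_residence_yr = hen_residence_yr,
                 dressing_fraction = dressing_fraction),
            class = "generator_spec")
}

#' Generate a synthetic performance table
#'
#' Daily rows from day 0 to one week past slaughter age. With zero noise
#' the rows are the exact analytic curve values; with noise, rows are
#' perturbed multiplicatively and then made monotone again by a running
#' maximum. Ground truth (exact curve values at slaughter age) is
#' attached as attribute \code{"truth"}.
#'
#' @param spec A [generator_spec()].
#' @param breed Breed label present in \code{spec$breeds}.
#' @return A [performance_table()] with source "synthetic".
#' @examples
#' tab <- generate_performance_table(generator_spec(seed = 1), "Ross308")
#' attr(tab, "truth")$weight_at_slaughter_kg # 3.35
#' @export
generate_performance_table <- function(spec, breed) {
  stopifnot(inherits(spec, "generator_spec"))
  g <- spec$breeds[[breed]]
  if (is.null(g)) .stopf("generator spec has no breed '%s'", breed)
  days <- 0:(g$slaughter_age_days + 7L)
  w <- .gompertz(days, g$w_asym, g$growth_rate_day, g$inflection_days)
  f <- (g$fcr_intercept + g$fcr_slope_day * days) * w
  if (spec$noise_sd > 0) {
    # one substream per breed, deterministic in (seed, breed)
    sub <- (spec$seed + sum(utf8ToInt(breed))) %% .Machine$integer.max
    noisy <- .with_seed(sub, {
      nw <- w * exp(stats::rnorm(length(w), 0, spec$noise_sd))
      nf <- f * exp(stats::rnorm(length(f), 0, spec$noise_sd))
      list(w = cummax(nw), f = cummax(nf))
    })
    w <- noisy$w
    f <- noisy$f
  }
  out <- performance_table(breed, days, w, f, source = "synthetic")
  attr(out, "truth") <- list(
    slaughter_age_days = g$slaughter_age_days,
    weight_at_slaughter_kg = .gompertz(g$slaughter_age_days, g$w_asym,
                                       g$growth_rate_day, g$inflection_days),
    feed_at_slaughter_kg = g$anchor_feed_kg,
    weight_scale_factor = spec$true_weight_scale_factor,
    performance_scale_factor = spec$true_performance_scale_factor)
  out
}

#' Generate national statistics consistent with the generator truth
#'
#' Top-down totals are per-bird ground truth times flock throughput: mean
#' live weight is the breed-mix average of table weights at slaughter age
#' times the true weight scale factor, and total feed is the mix-averaged
#' table cumulative feed times the true performance scale factor times
#' the slaughter rate. Maize and soy masses follow the published shares
#' of total feed. With the default (published-statistics) spec and a pure
#' conventional mix this reproduces the published baseline to within
#' rounding.
#'
#' @param spec A [generator_spec()].
#' @param true_breed_mix Named shares over \code{spec$breeds} summing to
#'   1; default pure conventional.
#' @param slaughter_rate_yr Flock throughput; 0 gives all-zero totals
#'   (returned as a plain list, since a zero baseline is not a valid
#'   parameter record).
#' @param reporting_noise_sd Relative s.d. of lognormal noise applied to
#'   the reported weight and feed totals (0 = exact).
#' @return A [national_baseline()], or a plain list of zero totals when
#'   \code{slaughter_rate_yr} is 0.
#' @export
generate_national_stats <- function(spec,
                                    true_breed_mix = c(Ross308 = 1),
                                    slaughter_rate_yr = spec$slaughter_rate_yr,
                                    reporting_noise_sd = 0) {
  stopifnot(inherits(spec, "generator_spec"))
  .check_nonneg(slaughter_rate_yr, "slaughter_rate_yr")
  if (abs(sum(true_breed_mix) - 1) > 1e-9)
    .stopf("breed mix shares must sum to 1")
  if (!all(names(true_breed_mix) %in% names(spec$breeds)))
    .stopf("breed mix names must match generator breeds")
  w_tab <- sum(vapply(names(true_breed_mix), function(b) {
    g <- spec$breeds[[b]]
    true_breed_mix[[b]] * g$anchor_weight_kg
  }, 0))
  f_tab <- sum(vapply(names(true_breed_mix), function(b) {
    spec$breeds[[b]]$anchor_feed_kg * true_breed_mix[[b]]
  }, 0))
  res_days <- sum(vapply(names(true_breed_mix), function(b) {
    spec$breeds[[b]]$slaughter_age_days * true_breed_mix[[b]]
  }, 0))
  live_wt <- w_tab * spec$true_weight_scale_factor
  feed_total <- slaughter_rate_yr * f_tab *
    spec$true_performance_scale_factor / .KG_PER_MMT
  if (reporting_noise_sd > 0) {
    fac <- .with_seed(spec$seed, exp(stats::rnorm(2, 0, reporting_noise_sd)))
    live_wt <- live_wt * fac[1]
    feed_total <- feed_total * fac[2]
  }
  maize_share <- 35.56 / 58.1
  soy_share <- 15.78 / 58.1
  if (slaughter_rate_yr == 0) {
    return(list(slaughter_rate_yr = 0, broiler_residence_days = res_days,
                hen_placement_rate_yr = 0,
                hen_residence_yr = spec$hen_residence_yr,
                mean_live_weight_kg = live_wt, dressing_fraction =
                  spec$dressing_fraction,
                feed_total_mmt = 0, maize_mass_mmt = 0, soy_mass_mmt = 0))
  }
  national_baseline(
    slaughter_rate_yr = slaughter_rate_yr,
    broiler_residence_days = res_days,
    hen_placement_rate_yr = spec$hen_placement_rate_yr *
      slaughter_rate_yr / spec$slaughter_rate_yr,
    hen_residence_yr = spec$hen_residence_yr,
    mean_live_weight_kg = live_wt,
    dressing_fraction = spec$dressing_fraction,
    feed_total_mmt = feed_total,
    maize_mass_mmt = feed_total * maize_share,
    soy_mass_mmt = feed_total * soy_share)
}

#' Write synthetic tables and a ground-truth manifest
#'
#' Writes one performance-table CSV per breed plus \code{manifest.yaml}
#' recording the generator's ground truth (anchors, true scale factors,
#' seed).
#'
#' @param spec A [generator_spec()].
#' @param dir Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_synthetic_tables <- function(spec, dir) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truths <- list()
  for (b in names(spec$breeds)) {
    tab <- generate_performance_table(spec, b)
    write_performance_table(tab, file.path(dir, paste0(b, ".csv")))
    truths[[b]] <- attr(tab, "truth")
  }
  manifest <- list(seed = spec$seed, noise_sd = spec$noise_sd,
                   true_weight_scale_factor = spec$true_weight_scale_factor,
                   true_performance_scale_factor =
                     spec$true_performance_scale_factor,
                   breeds = truths)
  writeLines(yaml::as.yaml(manifest, precision = 15),
             file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("Synthetic table generator: seed %d, noise sd %.3g, breeds %s\n",
              x$seed, x$noise_sd, paste(names(x$breeds), collapse = ", ")))
  cat(sprintf("  true weight scale factor      : %.4f\n",
              x$true_weight_scale_factor))
  cat(sprintf("  true performance scale factor : %.4f\n",
              x$true_performance_scale_factor))
  invisible(x)
}
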