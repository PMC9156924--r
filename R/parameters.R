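#' National baseline statistics for the conventional broiler system
#'
#' Constructs the set of national constants that anchor every scenario:
#' annual slaughter rate, grow-out and laying residence times, pullet
#' placement rate, mean live weight, dressing fraction and annual feed
#' masses. Defaults are the 2018/2019 USDA-NASS and National Chicken
#' Council statistics for the conventional Ross 308 system.
#'
#' @param slaughter_rate_yr Birds slaughtered (= placed, at steady state)
#'   per year. Default 9.25e9.
#' @param broiler_residence_days Mean grow-out period of a fattening bird,
#'   days. Default 47.
#' @param hen_placement_rate_yr Broiler-type pullet chicks placed into the
#'   breeding flock per year. Default 98.0e6.
#' @param hen_residence_yr Mean laying-cycle residence of a breeding hen,
#'   years (40 weeks). Default 0.767.
#' @param mean_live_weight_kg Mean live weight at slaughter, kg per bird.
#'   Default 2.93.
#' @param dressing_fraction Dressed (eviscerated carcass) mass over live
#'   mass. Default 0.74.
#' @param feed_total_mmt Total mixed feed used, million metric tons (MMT)
#'   per year. Default 58.1.
#' @param maize_mass_mmt Maize fed, MMT per year. Default 35.56.
#' @param soy_mass_mmt Soybeans fed, MMT per year. Default 15.78.
#' @return An object of class \code{national_baseline}: a validated named
#'   list of the above fields.
#' @examples
#' b <- national_baseline()
#' b$slaughter_rate_yr
#' @export
national_baseline <- function(slaughter_rate_yr = 9.25e9,
                              broiler_residence_days = 47,
                              hen_placement_rate_yr = 98.0e6,
                              hen_residence_yr = 0.767,
                              mean_live_weight_kg = 2.93,
                              dressing_fraction = 0.74,
                              feed_total_mmt = 58.1,
                              maize_mass_mmt = 35.56,
                              soy_mass_mmt = 15.78) {
  .check_positive(slaughter_rate_yr, "slaughter_rate_yr")
  .check_positive(broiler_residence_days, "broiler_residence_days")
  .check_positive(hen_placement_rate_yr, "hen_placement_rate_yr")
  .check_positive(hen_residence_yr, "hen_residence_yr")
  .check_positive(mean_live_weight_kg, "mean_live_weight_kg")
  .check_fraction(dressing_fraction, "dressing_fraction")
  .check_positive(feed_total_mmt, "feed_total_mmt")
  .check_positive(maize_mass_mmt, "maize_mass_mmt")
  .check_positive(soy_mass_mmt, "soy_mass_mmt")
  if (maize_mass_mmt + soy_mass_mmt > feed_total_mmt)
    .stopf("maize_mass_mmt + soy_mass_mmt (%g) exceeds feed_total_mmt (%g)",
           maize_mass_mmt + soy_mass_mmt, feed_total_mmt)
  structure(list(
    slaughter_rate_yr = slaughter_rate_yr,
    broiler_residence_days = broiler_residence_days,
    hen_placement_rate_yr = hen_placement_rate_yr,
    hen_residence_yr = hen_residence_yr,
    mean_live_weight_kg = mean_live_weight_kg,
    dressing_fraction = dressing_fraction,
    feed_total_mmt = feed_total_mmt,
    maize_mass_mmt = maize_mass_mmt,
    soy_mass_mmt = soy_mass_mmt
  ), class = "national_baseline")
}

#' Breed demographic and performance parameters
#'
#' A breed is parameterized either by a slaughter-rate multiplier (the
#' ratio of the breed's annual slaughter rate to the conventional baseline
#' at equal dressed-meat production; canonical mode) or by a scaled live
#' slaughter weight from which that multiplier is derived by conserving
#' annual dressed production. Exactly one of the two must be supplied.
#'
#' @param name Breed label, e.g. "Ross308", "RC", "RG", "RR".
#' @param residence_days Grow-out period to slaughter age, days (>= 1).
#' @param dressing_fraction Dressed over live mass for this breed.
#' @param slaughter_multiplier Breed slaughter rate / baseline slaughter
#'   rate at equal production (canonical parameterization), or NULL.
#' @param scaled_live_weight_kg Scaled live slaughter weight, kg per bird
#'   (alternative parameterization), or NULL.
#' @param feed_per_bird_kg Feed consumed per bird over the grow-out period,
#'   kg, after performance scaling.
#' @return An object of class \code{breed_spec} with a \code{mode} field,
#'   either \code{"multiplier"} or \code{"weight"}.
#' @seealso [default_breeds()], [breed_slaughter_rate()]
#' @export
breed_spec <- function(name, residence_days, dressing_fraction,
                       slaughter_multiplier = NULL,
                       scaled_live_weight_kg = NULL,
                       feed_per_bird_kg) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .stopf("'name' must be a non-empty string")
  .check_positive(residence_days, "residence_days")
  if (residence_days < 1) .stopf("'residence_days' must be >= 1 day")
  .check_fraction(dressing_fraction, "dressing_fraction")
  .check_positive(feed_per_bird_kg, "feed_per_bird_kg")
  has_mult <- !is.null(slaughter_multiplier)
  has_wt   <- !is.null(scaled_live_weight_kg)
  if (has_mult == has_wt)
    .stopf("breed '%s': supply exactly one of 'slaughter_multiplier' or 'scaled_live_weight_kg'",
           name)
  if (has_mult) .check_positive(slaughter_multiplier, "slaughter_multiplier")
  if (has_wt)   .check_positive(scaled_live_weight_kg, "scaled_live_weight_kg")
  structure(list(
    name = name,
    residence_days = residence_days,
    dressing_fraction = dressing_fraction,
    slaughter_multiplier = slaughter_multiplier,
    scaled_live_weight_kg = scaled_live_weight_kg,
    feed_per_bird_kg = feed_per_bird_kg,
    mode = if (has_mult) "multiplier" else "weight"
  ), class = "breed_spec")
}

#' Default breed set
#'
#' The four breeds of the national scenario analysis: the conventional
#' fast-growing Ross 308 and the three slower-growing GAP-approved
#' alternatives Ranger Classic (RC), Ranger Gold (RG) and Rowan Ranger
#' (RR). Slaughter multipliers are the published 19.22\%, 35.0\% and
#' 27.2\% rate increases required to hold dressed-meat production
#' constant; residence times are 57, 57 and 69 days. Effective
#' feed-per-bird values for the slower breeds are fixed by inverting the
#' published national indirect-land totals (91 229, 90 437 and
#' 98 521 km2) through the feed-to-cropland equations; Ross feed per bird
#' is the top-down national ratio 58.1e9 kg / 9.25e9 birds = 6.281 kg.
#'
#' @return A named list of [breed_spec()] objects:
#'   \code{Ross308}, \code{RC}, \code{RG}, \code{RR}.
#' @examples
#' default_breeds()$RC$slaughter_multiplier # 1.1922
#' @export
default_breeds <- function() {
  list(
    Ross308 = breed_spec("Ross308", residence_days = 47,
                         dressing_fraction = 0.74,
                         slaughter_multiplier = 1.0,
                         feed_per_bird_kg = 58.1e9 / 9.25e9),
    RC = breed_spec("RC", residence_days = 57, dressing_fraction = 0.76,
                    slaughter_multiplier = 1.1922,
                    feed_per_bird_kg = 6.456906),
    RG = breed_spec("RG", residence_days = 57, dressing_fraction = 0.76,
                    slaughter_multiplier = 1.35,
                    feed_per_bird_kg = 5.652662),
    RR = breed_spec("RR", residence_days = 69, dressing_fraction = 0.76,
                    slaughter_multiplier = 1.272,
                    feed_per_bird_kg = 6.535553)
  )
}

#' Management-system stocking rules
#'
#' Stocking rules for the three housing systems considered: confined
#' grow-out houses (CAFO, 20 000 birds per 1486 m2 house = 0.0743 m2 per
#' bird), CAFO housing with outdoor access (GAP rule: outdoor area at
#' least 75\% of indoor floor space, added to the indoor area) and
#' pasture (HFAC rule: 0.0101 km2 per 1000 birds = 10.12 m2 per bird).
#'
#' @param kind One of "cafo", "outdoor", "pasture".
#' @param cafo_stocking_m2 Indoor floor space per bird, m2. Default 0.0743.
#' @param outdoor_fraction Outdoor area as a fraction of indoor floor
#'   space, added on top of it. Default 0.75.
#' @param pasture_stocking_m2 Pasture area per bird, m2. Default 10.12.
#' @return An object of class \code{management_spec}.
#' @export
management_spec <- function(kind = c("cafo", "outdoor", "pasture"),
                            cafo_stocking_m2 = 0.0743,
                            outdoor_fraction = 0.75,
                            pasture_stocking_m2 = 10.12) {
  kind <- match.arg(kind)
  .check_positive(cafo_stocking_m2, "cafo_stocking_m2")
  .check_nonneg(outdoor_fraction, "outdoor_fraction")
  .check_positive(pasture_stocking_m2, "pasture_stocking_m2")
  structure(list(
    kind = kind,
    cafo_stocking_m2 = cafo_stocking_m2,
    outdoor_fraction = outdoor_fraction,
    pasture_stocking_m2 = pasture_stocking_m2
  ), class = "management_spec")
}

#' Default management set
#'
#' @return Named list of the three default [management_spec()] objects,
#'   in the order cafo, outdoor, pasture.
#' @export
default_managements <- function() {
  list(cafo = management_spec("cafo"),
       outdoor = management_spec("outdoor"),
       pasture = management_spec("pasture"))
}

#' Feed composition and crop-yield model
#'
#' Average composition of US broiler feed (maize 60.3\%, soybeans 26.8\%,
#' other 12.9\%) and FAO crop yields used to convert feed masses to
#' cropland. "Other" feed (largely mined minerals and fish by-products) is
#' conservatively assigned zero cropland.
#'
#' @param maize_fraction,soy_fraction,other_fraction Mass fractions of the
#'   feed mix; must sum to 1 within 1e-6.
#' @param maize_yield_t_ac,soy_yield_t_ac Crop yields, tonnes per acre.
#'   Defaults 4.802 and 1.403.
#' @param m2_per_acre Area of one acre, m2 (international acre).
#' @return An object of class \code{feed_model}.
#' @export
feed_model <- function(maize_fraction = 0.603,
                       soy_fraction = 0.268,
                       other_fraction = 0.129,
                       maize_yield_t_ac = 4.802,
                       soy_yield_t_ac = 1.403,
                       m2_per_acre = units_registry$m2_per_acre) {
  .check_fraction(maize_fraction, "maize_fraction")
  .check_fraction(soy_fraction, "soy_fraction")
  .check_nonneg(other_fraction, "other_fraction")
  if (abs(maize_fraction + soy_fraction + other_fraction - 1) > 1e-6)
    .stopf("feed fractions must sum to 1 within 1e-6 (got %.8f)",
           maize_fraction + soy_fraction + other_fraction)
  .check_positive(maize_yield_t_ac, "maize_yield_t_ac")
  .check_positive(soy_yield_t_ac, "soy_yield_t_ac")
  .check_positive(m2_per_acre, "m2_per_acre")
  structure(list(
    maize_fraction = maize_fraction,
    soy_fraction = soy_fraction,
    other_fraction = other_fraction,
    maize_yield_t_ac = maize_yield_t_ac,
    soy_yield_t_ac = soy_yield_t_ac,
    m2_per_acre = m2_per_acre
  ), class = "feed_model")
}

#' @export
print.national_baseline <- function(x, ...) {
  cat("National broiler baseline (conventional system)\n")
  cat(sprintf("  slaughter rate      : %.4g birds/yr\n", x$slaughter_rate_yr))
  cat(sprintf("  broiler residence   : %g days\n", x$broiler_residence_days))
  cat(sprintf("  hen placements      : %.4g hens/yr (residence %.3f yr)\n",
              x$hen_placement_rate_yr, x$hen_residence_yr))
  cat(sprintf("  live weight         : %.3g kg/bird (dressing %.2f)\n",
              x$mean_live_weight_kg, x$dressing_fraction))
  cat(sprintf("  feed                : %.4g MMT/yr (maize %.4g, soy %.4g)\n",
              x$feed_total_mmt, x$maize_mass_mmt, x$soy_mass_mmt))
  invisible(x)
}

#' @export
print.breed_spec <- function(x, ...) {
  drv <- if (x$mode == "multiplier")
    sprintf("slaughter multiplier %.4g", x$slaughter_multiplier)
  else
    sprintf("scaled live weight %.4g kg", x$scaled_live_weight_kg)
  cat(sprintf("Breed '%s': %g d residence, dressing %.2f, %s, feed %.4g kg/bird\n",
              x$name, x$residence_days, x$dressing_fraction, drv,
              x$feed_per_bird_kg))
  invisible(x)
}

#' @export
print.management_spec <- function(x, ...) {
  cat(sprintf("Management '%s' (cafo %.4g m2/bird, outdoor +%.0f%%, pasture %.4g m2/bird)\n",
              x$kind, x$cafo_stocking_m2, 100 * x$outdoor_fraction,
              x$pasture_stocking_m2))
  invisible(x)
}
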