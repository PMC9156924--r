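# Land-use accounting: direct housing/pasture land and indirect
# feed-cropland for a flock under a management system.

#' Direct land use of a fattening flock
#'
#' CAFO housing uses the indoor stocking rate (0.0743 m2/bird by default).
#' Outdoor access adds an outdoor area equal to \code{outdoor_fraction}
#' (default 75\%) of the indoor floor space on top of it; it never
#' substitutes for indoor space. Pasture uses the pasture stocking rate
#' (10.12 m2/bird). The breeding flock's housing is not counted.
#'
#' @param flock A [breed_flock()] result (or any list with a
#'   \code{fattening_population} field).
#' @param mgmt A [management_spec()].
#' @return Direct land, km2.
#' @examples
#' fl <- breed_flock(national_baseline(), default_breeds()$Ross308)
#' direct_land(fl, management_spec("cafo")) # ~88.5 km2
#' @export
direct_land <- function(flock, mgmt) {
  stopifnot(inherits(mgmt, "management_spec"))
  pop <- flock$fattening_population
  .check_nonneg(pop, "fattening_population")
  m2 <- switch(mgmt$kind,
    cafo = pop * mgmt$cafo_stocking_m2,
    outdoor = pop * mgmt$cafo_stocking_m2 * (1 + mgmt$outdoor_fraction),
    pasture = pop * mgmt$pasture_stocking_m2,
    .stopf("unknown management kind '%s'", mgmt$kind))
  m2 / .M2_PER_KM2
}

#' Cropland required to grow given crop masses
#'
#' Each crop's land is its mass divided by yield (acres) converted to
#' km2. "Other" feed carries no cropland by assumption, so only maize and
#' soy are accounted.
#'
#' @param maize_mmt,soy_mmt Crop masses, MMT per year.
#' @param feed A [feed_model()].
#' @return Named numeric vector \code{c(maize_km2, soy_km2)}.
#' @examples
#' cropland_from_masses(35.56, 15.78, feed_model()) # sums to ~75 484 km2
#' @export
cropland_from_masses <- function(maize_mmt, soy_mmt, feed = feed_model()) {
  stopifnot(inherits(feed, "feed_model"))
  .check_nonneg(maize_mmt, "maize_mmt")
  .check_nonneg(soy_mmt, "soy_mmt")
  t_per_mmt <- .KG_PER_MMT / 1000
  maize_km2 <- maize_mmt * t_per_mmt / feed$maize_yield_t_ac *
    feed$m2_per_acre / .M2_PER_KM2
  soy_km2 <- soy_mmt * t_per_mmt / feed$soy_yield_t_ac *
    feed$m2_per_acre / .M2_PER_KM2
  c(maize_km2 = maize_km2, soy_km2 = soy_km2)
}

#' Annual feed demand of a flock
#'
#' Total feed is the annual slaughter (placement) rate times the breed's
#' per-bird feed over the grow-out period; per-crop masses follow the
#' feed model's composition fractions. Management does not enter: feed
#' requirements are assumed management-invariant.
#'
#' @param flock A [breed_flock()] result.
#' @param feed A [feed_model()].
#' @return Named list: \code{total_mmt}, \code{maize_mmt}, \code{soy_mmt},
#'   \code{other_mmt}, all MMT per year.
#' @export
feed_demand <- function(flock, feed = feed_model()) {
  stopifnot(inherits(flock, "flock_state"), inherits(feed, "feed_model"))
  fpb <- flock$breed$feed_per_bird_kg
  if (is.null(fpb)) .stopf("breed '%s' has no feed_per_bird_kg", flock$breed$name)
  total <- flock$fattening_placement_rate_yr * fpb / .KG_PER_MMT
  list(total_mmt = total,
       maize_mmt = total * feed$maize_fraction,
       soy_mmt = total * feed$soy_fraction,
       other_mmt = total * feed$other_fraction)
}

#' Total land footprint of a flock under a management system
#'
#' Assembles direct land (housing or pasture) and indirect land (feed
#' cropland) into one record. With \code{baseline_mode = TRUE} the
#' indirect component uses the baseline's reported per-crop masses
#' directly (the national statistics route, matching the published
#' 75 488 km2 within 0.01\%) instead of composition times total feed
#' demand; this is the correct mode for the conventional Ross system,
#' whose feed masses are observed rather than modelled.
#'
#' @param flock A [breed_flock()] result.
#' @param mgmt A [management_spec()].
#' @param feed A [feed_model()].
#' @param baseline A [national_baseline()]; required when
#'   \code{baseline_mode = TRUE}.
#' @param baseline_mode Use reported baseline crop masses for the
#'   indirect component. Default FALSE.
#' @return An object of class \code{land_footprint} with fields
#'   \code{direct_km2}, \code{indirect_maize_km2}, \code{indirect_soy_km2},
#'   \code{total_km2}, \code{annual_feed_mmt}, \code{management} and
#'   \code{breed}.
#' @examples
#' b <- national_baseline()
#' fl <- breed_flock(b, default_breeds()$Ross308)
#' footprint(fl, management_spec("cafo"), feed_model(),
#'           baseline = b, baseline_mode = TRUE) # total ~75 573 km2
#' @export
footprint <- function(flock, mgmt, feed = feed_model(), baseline = NULL,
                      baseline_mode = FALSE) {
  direct <- direct_land(flock, mgmt)
  if (baseline_mode) {
    if (is.null(baseline))
      .stopf("baseline_mode = TRUE requires a 'baseline' record")
    crops <- cropland_from_masses(baseline$maize_mass_mmt,
                                  baseline$soy_mass_mmt, feed)
    feed_total <- baseline$feed_total_mmt
  } else {
    dem <- feed_demand(flock, feed)
    crops <- cropland_from_masses(dem$maize_mmt, dem$soy_mmt, feed)
    feed_total <- dem$total_mmt
  }
  structure(list(
    breed = flock$breed$name,
    management = mgmt$kind,
    direct_km2 = direct,
    indirect_maize_km2 = unname(crops["maize_km2"]),
    indirect_soy_km2 = unname(crops["soy_km2"]),
    total_km2 = direct + sum(crops),
    annual_feed_mmt = feed_total
  ), class = "land_footprint")
}

#' Baseline total land use (the constant-land cap)
#'
#' Total direct plus indirect land of the conventional Ross-in-CAFOs
#' system, computed from reported national statistics: the 75 577 km2
#' threshold every constant-land scenario is solved against.
#'
#' @param baseline A [national_baseline()].
#' @param mgmt Management of the baseline system (default CAFO).
#' @param feed A [feed_model()].
#' @return Total land, km2.
#' @export
baseline_total_land <- function(baseline = national_baseline(),
                                mgmt = management_spec("cafo"),
                                feed = feed_model()) {
  pop <- steady_state_population(baseline$slaughter_rate_yr,
                                 baseline$broiler_residence_days)
  crops <- cropland_from_masses(baseline$maize_mass_mmt,
                                baseline$soy_mass_mmt, feed)
  direct_land(list(fattening_population = pop), mgmt) + sum(crops)
}

#' @export
print.land_footprint <- function(x, ...) {
  cat(sprintf("Land footprint '%s' / %s:\n", x$breed, x$management))
  cat(sprintf("  direct   : %10.1f km2\n", x$direct_km2))
  cat(sprintf("  indirect : %10.1f km2 (maize %.0f + soy %.0f)\n",
              x$indirect_maize_km2 + x$indirect_soy_km2,
              x$indirect_maize_km2, x$indirect_soy_km2))
  cat(sprintf("  total    : %10.1f km2  (feed %.2f MMT/yr)\n",
              x$total_km2, x$annual_feed_mmt))
  invisible(x)
}

#' @export
as.data.frame.land_footprint <- function(x, ...) {
  data.frame(breed = x$breed, management = x$management,
             direct_km2 = x$direct_km2,
             indirect_maize_km2 = x$indirect_maize_km2,
             indirect_soy_km2 = x$indirect_soy_km2,
             total_km2 = x$total_km2,
             annual_feed_mmt = x$annual_feed_mmt)
}
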