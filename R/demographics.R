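# Steady-state flock demographics: populations, placement/slaughter rates
# and production mass for the conventional system and for alternative
# breeds at equal dressed-meat output.

#' Steady-state compartment population
#'
#' At steady state (placements = departures) the standing population of a
#' compartment is the throughput rate times the mean residence time:
#' p = tau * f. Residence may be given in days (default) or years.
#'
#' @param placement_rate_yr Throughput, animals per year.
#' @param residence Mean residence time in the compartment.
#' @param units Units of \code{residence}: "days" (converted at 365
#'   days/yr) or "years".
#' @return Standing population, animals.
#' @examples
#' steady_state_population(9.25e9, 47)            # ~1.19e9 broilers
#' steady_state_population(98.0e6, 0.767, "years") # ~7.52e7 hens
#' @export
steady_state_population <- function(placement_rate_yr, residence,
                                    units = c("days", "years")) {
  units <- match.arg(units)
  .check_nonneg(placement_rate_yr, "placement_rate_yr")
  .check_nonneg(residence, "residence")
  tau_yr <- if (units == "days") residence / .DAYS_PER_YEAR else residence
  placement_rate_yr * tau_yr
}

#' Dressed weight from live weight
#'
#' @param live_weight_kg Live mass at slaughter, kg.
#' @param dressing_fraction Eviscerated carcass mass over live mass,
#'   strictly in (0, 1).
#' @return Dressed weight, kg.
#' @examples
#' dressed_weight(2.93, 0.74) # 2.168 kg, the conventional mean
#' @export
dressed_weight <- function(live_weight_kg, dressing_fraction) {
  .check_nonneg(live_weight_kg, "live_weight_kg")
  .check_fraction(dressing_fraction, "dressing_fraction")
  live_weight_kg * dressing_fraction
}

#' Annual dressed production of the baseline system
#'
#' @param baseline A [national_baseline()].
#' @return Annual dressed production, kg per year (approximately
#'   2.006e10 kg = 20.06 MMT for the defaults).
#' @export
baseline_production_kg <- function(baseline) {
  stopifnot(inherits(baseline, "national_baseline"))
  baseline$slaughter_rate_yr *
    dressed_weight(baseline$mean_live_weight_kg, baseline$dressing_fraction)
}

#' Breed dressed weight per bird
#'
#' In multiplier mode the dressed weight is implied by conservation of
#' annual dressed production: baseline production divided by the breed's
#' slaughter rate. In weight mode it is the scaled live weight times the
#' breed's dressing fraction.
#'
#' @param baseline A [national_baseline()].
#' @param breed A [breed_spec()].
#' @return Dressed weight, kg per bird.
#' @export
breed_dressed_weight <- function(baseline, breed) {
  stopifnot(inherits(breed, "breed_spec"))
  if (breed$mode == "weight")
    dressed_weight(breed$scaled_live_weight_kg, breed$dressing_fraction)
  else
    baseline_production_kg(baseline) / breed_slaughter_rate(baseline, breed)
}

#' Breed slaughter rate at equal production
#'
#' The annual slaughter rate a breed needs to match the baseline's annual
#' dressed production. Multiplier mode scales the baseline rate directly;
#' weight mode divides baseline dressed production by the breed's dressed
#' weight per bird. The two modes are algebraic inverses of each other.
#'
#' @inheritParams breed_dressed_weight
#' @return Slaughter (= placement) rate, birds per year.
#' @examples
#' b <- national_baseline()
#' breed_slaughter_rate(b, default_breeds()$RC) / b$slaughter_rate_yr # 1.1922
#' @export
breed_slaughter_rate <- function(baseline, breed) {
  stopifnot(inherits(baseline, "national_baseline"),
            inherits(breed, "breed_spec"))
  if (breed$mode == "multiplier") {
    baseline$slaughter_rate_yr * breed$slaughter_multiplier
  } else {
    dw <- dressed_weight(breed$scaled_live_weight_kg, breed$dressing_fraction)
    baseline_production_kg(baseline) / dw
  }
}

#' Steady-state flock state for a breed
#'
#' Builds the full steady-state demographic state at baseline-equivalent
#' production: the fattening population from the breed slaughter rate and
#' residence, the breeding flock scaled proportionally to the fattening
#' population (the breeding:fattening ratio is held at its conventional
#' value), and the pullet placement rate from breeding population over
#' hen residence.
#'
#' @inheritParams breed_dressed_weight
#' @return An object of class \code{flock_state} with fields
#'   \code{fattening_population}, \code{breeding_population},
#'   \code{fattening_placement_rate_yr}, \code{hen_placement_rate_yr}
#'   and \code{breed}.
#' @examples
#' breed_flock(national_baseline(), default_breeds()$RR)
#' @export
breed_flock <- function(baseline, breed) {
  rate <- breed_slaughter_rate(baseline, breed)
  fat_pop <- steady_state_population(rate, breed$residence_days)
  base_fat_pop <- steady_state_population(baseline$slaughter_rate_yr,
                                          baseline$broiler_residence_days)
  base_breed_pop <- steady_state_population(baseline$hen_placement_rate_yr,
                                            baseline$hen_residence_yr, "years")
  breeding_pop <- base_breed_pop * fat_pop / base_fat_pop
  structure(list(
    fattening_population = fat_pop,
    breeding_population = breeding_pop,
    fattening_placement_rate_yr = rate,
    hen_placement_rate_yr = breeding_pop / baseline$hen_residence_yr,
    breed = breed
  ), class = "flock_state")
}

#' Production summary for a breed flock
#'
#' @inheritParams breed_dressed_weight
#' @return An object of class \code{production_summary}: dressed weight
#'   per bird (kg), annual dressed production (MMT/yr) and annual live
#'   production (MMT/yr).
#' @export
production_summary <- function(baseline, breed) {
  rate <- breed_slaughter_rate(baseline, breed)
  dw <- breed_dressed_weight(baseline, breed)
  structure(list(
    breed = breed$name,
    dressed_weight_kg = dw,
    annual_dressed_mmt = rate * dw / .KG_PER_MMT,
    annual_live_mmt = rate * dw / breed$dressing_fraction / .KG_PER_MMT
  ), class = "production_summary")
}

#' Scale a flock state by a common factor
#'
#' Multiplies every population and rate by \code{s}, as when consumption
#' is capped; the steady-state identity p = tau * f is preserved.
#'
#' @param flock A [breed_flock()] result.
#' @param s Non-negative scale factor.
#' @return A scaled \code{flock_state}.
#' @export
scale_flock <- function(flock, s) {
  stopifnot(inherits(flock, "flock_state"))
  .check_nonneg(s, "s")
  flock$fattening_population <- flock$fattening_population * s
  flock$breeding_population <- flock$breeding_population * s
  flock$fattening_placement_rate_yr <- flock$fattening_placement_rate_yr * s
  flock$hen_placement_rate_yr <- flock$hen_placement_rate_yr * s
  flock
}

#' @export
print.flock_state <- function(x, ...) {
  cat(sprintf("Flock state for '%s':\n", x$breed$name))
  cat(sprintf("  fattening population : %.4g birds (%.4g placed/yr)\n",
              x$fattening_population, x$fattening_placement_rate_yr))
  cat(sprintf("  breeding population  : %.4g hens (%.4g placed/yr)\n",
              x$breeding_population, x$hen_placement_rate_yr))
  invisible(x)
}

#' @export
print.production_summary <- function(x, ...) {
  cat(sprintf("Production '%s': %.3f kg dressed/bird, %.2f MMT dressed/yr (%.2f MMT live)\n",
              x$breed, x$dressed_weight_kg, x$annual_dressed_mmt,
              x$annual_live_mmt))
  invisible(x)
}

#' @export
as.data.frame.flock_state <- function(x, ...) {
  data.frame(breed = x$breed$name,
             fattening_population_birds = x$fattening_population,
             breeding_population_hens = x$breeding_population,
             fattening_placement_rate_birds_yr = x$fattening_placement_rate_yr,
             hen_placement_rate_hens_yr = x$hen_placement_rate_yr)
}
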