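# Calibration of breed parameters from breeder performance-objective
# tables: a weight scale factor reconciling breeder-reported slaughter
# weights with national statistics, and a performance scale factor doing
# the same for cumulative feed.

#' Performance-objective table
#'
#' Age-by-age live weight and cumulative feed intake for one breed, as
#' published by breeders. Ages must be strictly increasing; weight and
#' cumulative feed non-decreasing.
#'
#' @param breed Breed label.
#' @param age_days Integer-ish vector of ages, days.
#' @param live_weight_kg Live weight at each age, kg.
#' @param cumulative_feed_kg Cumulative feed intake at each age, kg.
#' @param source "supplementary" or "synthetic".
#' @return An object of class \code{performance_table}.
#' @export
performance_table <- function(breed, age_days, live_weight_kg,
                              cumulative_feed_kg,
                              source = c("synthetic", "supplementary")) {
  source <- match.arg(source)
  n <- length(age_days)
  if (n < 2L) .stopf("performance table needs at least two rows")
  if (length(live_weight_kg) != n || length(cumulative_feed_kg) != n)
    .stopf("age, weight and feed columns must have equal length")
  if (any(diff(age_days) <= 0))
    .stopf("ages must be strictly increasing")
  if (any(diff(live_weight_kg) < 0))
    .stopf("live weight must be non-decreasing in age")
  if (any(diff(cumulative_feed_kg) < 0))
    .stopf("cumulative feed must be non-decreasing in age")
  if (any(live_weight_kg < 0) || any(cumulative_feed_kg < 0))
    .stopf("weights and feed must be non-negative")
  structure(list(breed = breed,
                 age_days = as.numeric(age_days),
                 live_weight_kg = as.numeric(live_weight_kg),
                 cumulative_feed_kg = as.numeric(cumulative_feed_kg),
                 source = source),
            class = "performance_table")
}

#' Read a performance table from delimited text
#'
#' Expects a CSV with header \code{age_days,live_weight_kg,cumulative_feed_kg}.
#'
#' @param path CSV file path.
#' @param breed Breed label (defaults to the file name without extension).
#' @param source Passed to [performance_table()].
#' @return A \code{performance_table}.
#' @export
read_performance_table <- function(path, breed = NULL,
                                   source = "supplementary") {
  if (!file.exists(path)) .stopf("performance table '%s' not found", path)
  df <- utils::read.csv(path)
  need <- c("age_days", "live_weight_kg", "cumulative_feed_kg")
  if (!all(need %in% names(df)))
    .stopf("performance table '%s' must have columns %s", path,
           paste(need, collapse = ", "))
  if (is.null(breed)) breed <- sub("\\.[^.]*$", "", basename(path))
  performance_table(breed, df$age_days, df$live_weight_kg,
                    df$cumulative_feed_kg, source = source)
}

#' Write a performance table to delimited text
#'
#' @param table A [performance_table()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_performance_table <- function(table, path) {
  stopifnot(inherits(table, "performance_table"))
  utils::write.csv(data.frame(age_days = table$age_days,
                              live_weight_kg = table$live_weight_kg,
                              cumulative_feed_kg = table$cumulative_feed_kg),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Linear interpolation of a table column at an age, with range checking.
.table_at <- function(table, age, column) {
  rng <- range(table$age_days)
  if (age < rng[1] || age > rng[2])
    .stopf("age %g days outside table range [%g, %g] for breed '%s'",
           age, rng[1], rng[2], table$breed)
  stats::approx(table$age_days, table[[column]], xout = age)$y
}

#' Live weight at an age, by linear interpolation
#'
#' @param table A [performance_table()].
#' @param age_days Age, days; must lie within the table's range.
#' @return Live weight, kg.
#' @export
table_weight_at <- function(table, age_days) {
  stopifnot(inherits(table, "performance_table"))
  .table_at(table, age_days, "live_weight_kg")
}

#' Cumulative feed at an age, by linear interpolation
#'
#' @inheritParams table_weight_at
#' @return Cumulative feed, kg.
#' @export
table_feed_at <- function(table, age_days) {
  stopifnot(inherits(table, "performance_table"))
  .table_at(table, age_days, "cumulative_feed_kg")
}

#' Weight scale factor from national statistics
#'
#' Breeder tables tend to overstate field performance. The weight scale
#' factor is the national mean slaughter weight divided by the breeder
#' table's Ross weight at the conventional slaughter age (47 days by
#' default); slower breeds' table weights are multiplied by it to obtain
#' field-scaled slaughter weights.
#'
#' @param baseline A [national_baseline()].
#' @param ross_table [performance_table()] for the conventional breed.
#' @return Dimensionless factor (< 1 when the table overstates weight).
#' @export
weight_scale_factor <- function(baseline, ross_table) {
  stopifnot(inherits(baseline, "national_baseline"))
  w <- table_weight_at(ross_table, baseline$broiler_residence_days)
  if (w <= 0) .stopf("Ross table weight at day %g is not positive",
                     baseline$broiler_residence_days)
  baseline$mean_live_weight_kg / w
}

#' Field-scaled slaughter weight of a breed
#'
#' @param breed_table [performance_table()] for the breed.
#' @param factor Weight scale factor from [weight_scale_factor()].
#' @param slaughter_age_days Slaughter age, days.
#' @return Scaled live slaughter weight, kg.
#' @export
scaled_slaughter_weight <- function(breed_table, factor, slaughter_age_days) {
  .check_positive(factor, "factor")
  table_weight_at(breed_table, slaughter_age_days) * factor
}

#' Performance scale factor from national feed statistics
#'
#' Top-down national feed per bird (total feed mass over annual slaughter
#' rate; 6.281 kg for the defaults) divided by the breeder table's Ross
#' cumulative feed at the conventional slaughter age. Approximately 1.35
#' for published Ross performance objectives, i.e. tables understate
#' field feed use by about a third.
#'
#' @inheritParams weight_scale_factor
#' @return Dimensionless factor (> 1 when the table understates feed).
#' @export
performance_scale_factor <- function(baseline, ross_table) {
  stopifnot(inherits(baseline, "national_baseline"))
  f <- table_feed_at(ross_table, baseline$broiler_residence_days)
  if (f <= 0) .stopf("Ross table cumulative feed at day %g must be positive",
                     baseline$broiler_residence_days)
  national_fpb <- baseline$feed_total_mmt * .KG_PER_MMT /
    baseline$slaughter_rate_yr
  national_fpb / f
}

#' Calibrate a breed from performance tables
#'
#' Produces a weight-mode [breed_spec()]: the breed's table weight at
#' slaughter age scaled by the weight scale factor, and its table
#' cumulative feed scaled by the performance scale factor. Calibrating
#' the conventional table against itself at the conventional slaughter
#' age reproduces the national statistics exactly (the self-calibration
#' fixed point).
#'
#' @param breed_table [performance_table()] for the breed to calibrate.
#' @param ross_table [performance_table()] for the conventional breed.
#' @param baseline A [national_baseline()].
#' @param slaughter_age_days Breed slaughter age (becomes the residence).
#' @param dressing_fraction Breed dressing fraction. Default 0.76, the
#'   breeder-reported value for the slower-growing breeds.
#' @return A weight-mode [breed_spec()].
#' @export
calibrate_breed <- function(breed_table, ross_table, baseline,
                            slaughter_age_days, dressing_fraction = 0.76) {
  wsf <- weight_scale_factor(baseline, ross_table)
  psf <- performance_scale_factor(baseline, ross_table)
  breed_spec(name = breed_table$breed,
             residence_days = slaughter_age_days,
             dressing_fraction = dressing_fraction,
             scaled_live_weight_kg =
               scaled_slaughter_weight(breed_table, wsf, slaughter_age_days),
             feed_per_bird_kg =
               table_feed_at(breed_table, slaughter_age_days) * psf)
}

#' @export
print.performance_table <- function(x, ...) {
  cat(sprintf("Performance table '%s' (%s): days %g-%g, weight up to %.3g kg, feed up to %.3g kg\n",
              x$breed, x$source, min(x$age_days), max(x$age_days),
              max(x$live_weight_kg), max(x$cumulative_feed_kg)))
  invisible(x)
}

#' @export
as.data.frame.performance_table <- function(x, ...) {
  data.frame(age_days = x$age_days, live_weight_kg = x$live_weight_kg,
             cumulative_feed_kg = x$cumulative_feed_kg)
}
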