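# Constant-land scenario solving: how much consumption must change so a
# breed x management scenario fits inside the baseline land footprint.

#' Constant-land consumption scale factor
#'
#' The ratio baseline land over scenario land. Because every land
#' component is linear in flock size, running the scenario's flock at
#' this fraction of full consumption makes its total land exactly equal
#' the baseline's.
#'
#' @param scenario_land_km2 Total land of the scenario at full (current)
#'   consumption, km2. Must be positive.
#' @param baseline_land_km2 Baseline total land, km2.
#' @return Dimensionless scale factor (1 for the identity scenario).
#' @export
constant_land_scale <- function(scenario_land_km2, baseline_land_km2) {
  .check_positive(scenario_land_km2, "scenario_land_km2")
  .check_positive(baseline_land_km2, "baseline_land_km2")
  baseline_land_km2 / scenario_land_km2
}

#' Solve one breed x management constant-land scenario
#'
#' Builds the breed's flock at full (baseline-equivalent) consumption,
#' computes its land footprint, and caps consumption so total land equals
#' the conventional Ross-in-CAFOs baseline. Reports the capped
#' consumption, the decrease in MMT and percent, and the slaughter rate
#' and fattening population at the cap.
#'
#' @param breed A [breed_spec()].
#' @param mgmt A [management_spec()].
#' @param baseline A [national_baseline()].
#' @param feed A [feed_model()].
#' @param conventional Name of the conventional breed; the conventional
#'   breed's indirect land always uses the reported national crop masses
#'   (see [footprint()]), for any management.
#' @param baseline_land_km2 Optional precomputed cap; defaults to
#'   [baseline_total_land()] under CAFO management.
#' @return An object of class \code{scenario_result}.
#' @examples
#' run_scenario(default_breeds()$RR, management_spec("cafo"))
#' @export
run_scenario <- function(breed, mgmt, baseline = national_baseline(),
                         feed = feed_model(), conventional = "Ross308",
                         baseline_land_km2 = NULL) {
  stopifnot(inherits(breed, "breed_spec"), inherits(mgmt, "management_spec"))
  if (is.null(baseline_land_km2))
    baseline_land_km2 <- baseline_total_land(baseline,
                                             management_spec("cafo"), feed)
  is_conv <- identical(breed$name, conventional)
  full_flock <- breed_flock(baseline, breed)
  full_fp <- footprint(full_flock, mgmt, feed, baseline = baseline,
                       baseline_mode = is_conv)
  s <- constant_land_scale(full_fp$total_km2, baseline_land_km2)
  w_conv <- baseline_production_kg(baseline) / .KG_PER_MMT
  w_scen <- w_conv * s
  capped <- scale_flock(full_flock, s)
  structure(list(
    breed = breed$name,
    management = mgmt$kind,
    full_consumption_land = full_fp,
    baseline_land_km2 = baseline_land_km2,
    scale_factor = s,
    max_consumption_mmt = w_scen,
    consumption_decrease_mmt = w_conv - w_scen,
    consumption_decrease_pct = (1 - s) * 100,
    slaughter_rate_at_cap_yr = capped$fattening_placement_rate_yr,
    population_at_cap = capped$fattening_population,
    capped_flock = capped
  ), class = "scenario_result")
}

#' Run the full breed x management scenario cross-product
#'
#' Deterministic order: breeds outer, managements inner, both in input
#' order. The constant-land cap (conventional breed in CAFOs, reported
#' crop masses) is computed once and shared by every scenario.
#'
#' @param baseline A [national_baseline()].
#' @param breeds Named list of [breed_spec()] objects.
#' @param managements Named list of [management_spec()] objects.
#' @param feed A [feed_model()].
#' @param conventional Name of the conventional breed.
#' @return An object of class \code{scenario_set}: a list of
#'   \code{scenario_result} with the shared cap as an attribute.
#' @examples
#' res <- run_all()
#' summary(res)
#' @export
run_all <- function(baseline = national_baseline(),
                    breeds = default_breeds(),
                    managements = default_managements(),
                    feed = feed_model(), conventional = "Ross308") {
  if (!length(breeds) || !length(managements))
    .stopf("'breeds' and 'managements' must be non-empty")
  cap <- baseline_total_land(baseline, management_spec("cafo"), feed)
  out <- list()
  for (b in breeds) for (m in managements) {
    r <- run_scenario(b, m, baseline, feed, conventional = conventional,
                      baseline_land_km2 = cap)
    out[[paste(b$name, m$kind, sep = ":")]] <- r
  }
  structure(out, class = "scenario_set", baseline_land_km2 = cap,
            conventional = conventional)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' / %s (land cap %.0f km2):\n",
              x$breed, x$management, x$baseline_land_km2))
  cat(sprintf("  full-consumption land : %.0f km2 (scale factor %.4f)\n",
              x$full_consumption_land$total_km2, x$scale_factor))
  cat(sprintf("  max consumption       : %.2f MMT/yr (-%.2f MMT, -%.1f%%)\n",
              x$max_consumption_mmt, x$consumption_decrease_mmt,
              x$consumption_decrease_pct))
  cat(sprintf("  at cap: %.3g slaughtered/yr, population %.3g\n",
              x$slaughter_rate_at_cap_yr, x$population_at_cap))
  invisible(x)
}

#' @export
as.data.frame.scenario_result <- function(x, ...) {
  data.frame(breed = x$breed, management = x$management,
             max_consumption_mmt_yr = x$max_consumption_mmt,
             consumption_decrease_mmt_yr = x$consumption_decrease_mmt,
             consumption_decrease_pct = x$consumption_decrease_pct,
             slaughter_rate_at_cap_birds_yr = x$slaughter_rate_at_cap_yr,
             population_at_cap_birds = x$population_at_cap,
             scale_factor = x$scale_factor,
             full_land_total_km2 = x$full_consumption_land$total_km2,
             full_land_direct_km2 = x$full_consumption_land$direct_km2)
}

#' @export
as.data.frame.scenario_set <- function(x, ...) {
  do.call(rbind, c(lapply(unname(x), as.data.frame), make.row.names = FALSE))
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("Constant-land scenario set: %d scenarios, cap %.0f km2\n",
              length(x), attr(x, "baseline_land_km2")))
  df <- as.data.frame(x)
  df$max_consumption_mmt_yr <- round(df$max_consumption_mmt_yr, 1)
  df$slaughter_rate_at_cap_birds_yr <-
    signif(df$slaughter_rate_at_cap_birds_yr / 1e9, 3)
  df$population_at_cap_birds <- signif(df$population_at_cap_birds / 1e9, 3)
  names(df)[names(df) == "slaughter_rate_at_cap_birds_yr"] <-
    "slaughter_billion_yr"
  names(df)[names(df) == "population_at_cap_birds"] <- "population_billion"
  print(df[, c("breed", "management", "max_consumption_mmt_yr",
               "slaughter_billion_yr", "population_billion")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.scenario_set <- function(object, ...) {
  df <- as.data.frame(object)
  conv <- attr(object, "conventional")
  rng <- function(mk) {
    sub <- df[df$management == mk & df$breed != conv, ]
    if (!nrow(sub)) return(c(NA_real_, NA_real_))
    range(sub$full_land_total_km2)
  }
  structure(list(
    n = nrow(df),
    baseline_land_km2 = attr(object, "baseline_land_km2"),
    table = df,
    land_ranges_km2 = list(cafo = rng("cafo"), outdoor = rng("outdoor"),
                           pasture = rng("pasture"))
  ), class = "summary.scenario_set")
}

#' @export
print.summary.scenario_set <- function(x, ...) {
  cat(sprintf("%d scenarios against a %.0f km2 land cap\n", x$n,
              x$baseline_land_km2))
  for (mk in names(x$land_ranges_km2)) {
    r <- x$land_ranges_km2[[mk]]
    if (all(is.finite(r)))
      cat(sprintf("  full-consumption land, alternative breeds, %-7s: %6.0f - %6.0f km2\n",
                  mk, r[1], r[2]))
  }
  invisible(x)
}

#' Plot a scenario set
#'
#' Barplot of full-consumption total land by scenario, with the
#' constant-land cap as a reference line. Base graphics.
#'
#' @param x A [run_all()] result.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.scenario_set <- function(x, ...) {
  df <- as.data.frame(x)
  lab <- paste(df$breed, df$management, sep = "\n")
  mids <- graphics::barplot(df$full_land_total_km2 / 1e3, names.arg = lab,
                            las = 2, cex.names = 0.7,
                            ylab = "total land (thousand km2)", ...)
  graphics::abline(h = attr(x, "baseline_land_km2") / 1e3, lty = 2)
  invisible(mids)
}

#' Write scenario outputs to CSV
#'
#' Writes \code{scenarios.csv} (one row per scenario, consumption /
#' slaughter / population at cap plus land columns) and
#' \code{footprints.csv} (full-consumption land components) into a
#' directory.
#'
#' @param scenarios A [run_all()] result.
#' @param dir Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_scenario_report <- function(scenarios, dir) {
  stopifnot(inherits(scenarios, "scenario_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(scenarios),
                   file.path(dir, "scenarios.csv"), row.names = FALSE)
  fps <- do.call(rbind, c(lapply(unname(scenarios), function(r)
    as.data.frame(r$full_consumption_land)), make.row.names = FALSE))
  utils::write.csv(fps, file.path(dir, "footprints.csv"), row.names = FALSE)
  invisible(dir)
}
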