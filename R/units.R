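#' Unit conversion constants
#'
#' Fixed conversion factors used throughout the model. All unit conversions
#' route through this single record so that, e.g., a year is 365 days
#' everywhere and an acre is the international acre everywhere.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{days_per_year}{365}
#'   \item{kg_per_mmt}{kg per million metric tons, 1e9}
#'   \item{m2_per_km2}{1e6}
#'   \item{m2_per_acre}{international acre, 4046.8564 m2}
#' }
#' @export
units_registry <- list(
  days_per_year = 365,
  kg_per_mmt    = 1e9,
  m2_per_km2    = 1e6,
  m2_per_acre   = 4046.8564
)

# internal shorthands
.DAYS_PER_YEAR <- units_registry$days_per_year
.KG_PER_MMT    <- units_registry$kg_per_mmt
.M2_PER_KM2    <- units_registry$m2_per_km2
.M2_PER_ACRE   <- units_registry$m2_per_acre

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    .stopf("'%s' must be a single positive finite number (got %s)",
           name, paste(format(x), collapse = ", "))
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    .stopf("'%s' must be a single non-negative finite number (got %s)",
           name, paste(format(x), collapse = ", "))
  invisible(x)
}

.check_fraction <- function(x, name, open = TRUE) {
  .check_positive(x, name)
  if (open && x >= 1) .stopf("'%s' must lie strictly in (0, 1), got %g", name, x)
  if (!open && x > 1) .stopf("'%s' must lie in (0, 1], got %g", name, x)
  invisible(x)
}
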