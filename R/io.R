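# Config and delimited-table I/O for the parameter records.

.baseline_fields <- function() names(formals(national_baseline))
.feed_fields <- function() setdiff(names(formals(feed_model)), "m2_per_acre")
.mgmt_fields <- function() c("cafo_stocking_m2", "outdoor_fraction",
                             "pasture_stocking_m2")

.apply_overrides <- function(defaults, overrides, section) {
  prov <- rep("published-default", length(defaults))
  names(prov) <- names(defaults)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      .stopf("config section '%s': unknown field(s) %s", section,
             paste(sprintf("'%s'", unknown), collapse = ", "))
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 1L)
        .stopf("config section '%s': field '%s' must be a single number",
               section, nm)
      defaults[[nm]] <- v
      prov[[nm]] <- "user-supplied"
    }
  }
  list(values = defaults, provenance = prov)
}

#' Load a full parameter set from a structured config
#'
#' Reads a YAML config (file path or literal YAML text) with optional
#' sections \code{baseline}, \code{feed}, \code{management} and
#' \code{breeds}, validates every field, and fills everything absent with
#' the published defaults. An empty or missing config therefore yields the
#' full default parameter set. The breeds section may be an inline list of
#' breed records or the path of a breed CSV (see [read_breed_table()]).
#'
#' @param config_source Path to a YAML file, a YAML string, or NULL for
#'   all defaults.
#' @return A list with elements \code{baseline} ([national_baseline()]),
#'   \code{breeds} (named list of [breed_spec()]), \code{managements}
#'   (named list of [management_spec()]), \code{feed} ([feed_model()])
#'   and \code{provenance}, a per-field record of whether each value is a
#'   published default or user supplied.
#' @examples
#' p <- load_parameters(NULL)
#' p$baseline$slaughter_rate_yr
#' @export
load_parameters <- function(config_source = NULL) {
  cfg <- list()
  if (!is.null(config_source)) {
    if (length(config_source) == 1L && !grepl("\n", config_source) &&
        file.exists(config_source)) {
      cfg <- tryCatch(yaml::read_yaml(config_source),
                      error = function(e) .stopf("malformed config file '%s': %s",
                                                 config_source, conditionMessage(e)))
    } else {
      cfg <- tryCatch(yaml::yaml.load(paste(config_source, collapse = "\n")),
                      error = function(e) .stopf("malformed config text: %s",
                                                 conditionMessage(e)))
    }
    if (is.null(cfg)) cfg <- list()
    if (!is.list(cfg)) .stopf("config must be a YAML mapping")
    unknown <- setdiff(names(cfg), c("baseline", "feed", "management", "breeds"))
    if (length(unknown))
      .stopf("unknown config section(s): %s",
             paste(sprintf("'%s'", unknown), collapse = ", "))
  }

  base <- .apply_overrides(lapply(formals(national_baseline), eval),
                           cfg$baseline, "baseline")
  baseline <- do.call(national_baseline, base$values)

  feed_defaults <- lapply(formals(feed_model), eval)
  feed_defaults$m2_per_acre <- units_registry$m2_per_acre
  fd <- .apply_overrides(feed_defaults, cfg$feed, "feed")
  feed <- do.call(feed_model, fd$values)

  mg_defaults <- list(cafo_stocking_m2 = 0.0743, outdoor_fraction = 0.75,
                      pasture_stocking_m2 = 10.12)
  mg <- .apply_overrides(mg_defaults, cfg$management, "management")
  managements <- lapply(c(cafo = "cafo", outdoor = "outdoor",
                          pasture = "pasture"), function(k)
    do.call(management_spec, c(list(kind = k), mg$values)))

  breeds_prov <- "published-default"
  if (is.null(cfg$breeds)) {
    breeds <- default_breeds()
  } else if (is.character(cfg$breeds) && length(cfg$breeds) == 1L) {
    breeds <- read_breed_table(cfg$breeds)
    breeds_prov <- "user-supplied"
  } else {
    breeds <- lapply(cfg$breeds, function(rec) {
      if (!is.list(rec) || is.null(rec$name))
        .stopf("each breed record needs at least a 'name' field")
      do.call(breed_spec, rec[intersect(names(rec), names(formals(breed_spec)))])
    })
    names(breeds) <- vapply(breeds, `[[`, "", "name")
    breeds_prov <- "user-supplied"
  }

  list(baseline = baseline, breeds = breeds, managements = managements,
       feed = feed,
       provenance = list(baseline = base$provenance, feed = fd$provenance,
                         management = mg$provenance, breeds = breeds_prov))
}

#' Write a parameter set back to YAML config text
#'
#' Inverse of [load_parameters()]: serializes the numeric fields of a
#' parameter set so that re-loading reproduces every value exactly
#' (doubles are written with 17 significant digits).
#'
#' @param params A list as returned by [load_parameters()].
#' @param path Output file; if NULL the YAML text is returned invisibly.
#' @return The YAML text, invisibly.
#' @export
write_parameters <- function(params, path = NULL) {
  strip <- function(x, fields) {
    out <- unclass(x)[fields]
    out
  }
  doc <- list(
    baseline = strip(params$baseline, .baseline_fields()),
    feed = strip(params$feed, c(.feed_fields(), "m2_per_acre")),
    management = strip(params$managements$cafo, .mgmt_fields()),
    breeds = lapply(unname(params$breeds), function(b) {
      rec <- unclass(b)
      rec$mode <- NULL
      rec[!vapply(rec, is.null, TRUE)]
    })
  )
  txt <- yaml::as.yaml(doc, precision = 17)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Read a breed table from delimited text
#'
#' Expects a CSV with header
#' \code{name,residence_days,slaughter_multiplier,dressing_fraction,feed_per_bird_kg}.
#' An empty \code{slaughter_multiplier} cell together with an optional
#' \code{scaled_live_weight_kg} column selects weight-mode
#' parameterization.
#'
#' @param path CSV file path.
#' @return Named list of [breed_spec()] objects, in file order.
#' @export
read_breed_table <- function(path) {
  if (!file.exists(path)) .stopf("breed table '%s' not found", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "residence_days", "slaughter_multiplier",
            "dressing_fraction", "feed_per_bird_kg")
  missing <- setdiff(setdiff(need, "slaughter_multiplier"), names(df))
  if (length(missing))
    .stopf("breed table '%s' lacks column(s): %s", path,
           paste(missing, collapse = ", "))
  breeds <- lapply(seq_len(nrow(df)), function(i) {
    mult <- if ("slaughter_multiplier" %in% names(df)) df$slaughter_multiplier[i] else NA
    wt <- if ("scaled_live_weight_kg" %in% names(df)) df$scaled_live_weight_kg[i] else NA
    breed_spec(name = df$name[i],
               residence_days = df$residence_days[i],
               dressing_fraction = df$dressing_fraction[i],
               slaughter_multiplier = if (is.finite(mult)) mult else NULL,
               scaled_live_weight_kg = if (is.finite(wt)) wt else NULL,
               feed_per_bird_kg = df$feed_per_bird_kg[i])
  })
  names(breeds) <- df$name
  breeds
}

#' Write a breed table to delimited text
#'
#' @param breeds Named list of [breed_spec()] objects.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_breed_table <- function(breeds, path) {
  df <- do.call(rbind, lapply(breeds, function(b) {
    data.frame(name = b$name,
               residence_days = b$residence_days,
               slaughter_multiplier = if (is.null(b$slaughter_multiplier))
                 NA_real_ else b$slaughter_multiplier,
               dressing_fraction = b$dressing_fraction,
               feed_per_bird_kg = b$feed_per_bird_kg,
               scaled_live_weight_kg = if (is.null(b$scaled_live_weight_kg))
                 NA_real_ else b$scaled_live_weight_kg)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
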