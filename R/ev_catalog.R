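#' Convert person-minutes to equivalent values (EVs)
#'
#' The equivalent value of a public health service item is its person-time
#' divided by the duration of a standard clinic visit (a family physician
#' consulting one patient for 15 minutes, EV = 1 by definition). EVs put
#' heterogeneous services — home visits, bulletin boards, vaccination
#' sessions — on a single workload scale so they can be summed.
#'
#' @param workload_minutes Person-minutes required to deliver the item once
#'   (non-negative).
#' @param standard_visit_minutes Duration of the standard clinic visit in
#'   minutes (default 15; must be positive).
#' @return The equivalent value, unrounded. Vectorised over
#'   `workload_minutes`.
#' @examples
#' derive_ev(30)    # establishing one resident health record: EV 2
#' derive_ev(1170)  # an annual health-education plan, western region: EV 78
#' @export
derive_ev <- function(workload_minutes, standard_visit_minutes = 15) {
  if (!is_scalar_number(standard_visit_minutes) || standard_visit_minutes <= 0) {
    abort("`standard_visit_minutes` must be a single positive number",
          class = "evworkload_invalid_argument")
  }
  if (!is.numeric(workload_minutes) || any(!is.finite(workload_minutes)) ||
      any(workload_minutes < 0)) {
    abort("`workload_minutes` must be finite and non-negative",
          class = "evworkload_invalid_argument")
  }
  workload_minutes / standard_visit_minutes
}

catalog_units <- c("per_person", "per_visit", "per_time")

# internal constructor: items is a long tibble (one row per item x region)
# with columns item_id, service_type, item_name, unit, region, minutes.
# EVs are always rederived from minutes; a supplied ev column is checked
# against the derivation (tolerance half a display decimal) but never trusted.
new_ev_catalog <- function(items, standard_visit_minutes = 15,
                           regions = NULL, version = "",
                           ev_tolerance = 0.05) {
  required <- c("item_id", "service_type", "item_name", "unit", "region",
                "minutes")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    validation_error("catalog is missing required columns",
                     paste("column:", missing_cols))
  }
  if (nrow(items) == 0) {
    validation_error("catalog has no items")
  }
  items <- tibble::as_tibble(items)
  items$minutes <- as.numeric(items$minutes)

  problems <- character()
  bad_unit <- !(items$unit %in% catalog_units)
  if (any(bad_unit)) {
    problems <- c(problems, sprintf(
      "row %d: unit '%s' not one of %s", which(bad_unit),
      items$unit[bad_unit], paste(catalog_units, collapse = "/")))
  }
  bad_min <- !is.finite(items$minutes) | items$minutes <= 0
  if (any(bad_min)) {
    problems <- c(problems, sprintf(
      "row %d (%s, %s): minutes must be positive",
      which(bad_min), items$item_id[bad_min], items$region[bad_min]))
  }
  dup <- duplicated(items[, c("item_id", "region")])
  if (any(dup)) {
    problems <- c(problems, sprintf(
      "row %d: duplicate item_id '%s' for region '%s'",
      which(dup), items$item_id[dup], items$region[dup]))
  }
  if (length(problems) > 0) {
    validation_error("invalid catalog", problems)
  }

  regions <- regions %||% unique(items$region)
  derived <- derive_ev(items$minutes, standard_visit_minutes)
  if ("ev" %in% names(items)) {
    off <- abs(as.numeric(items$ev) - derived) > ev_tolerance
    off[is.na(off)] <- TRUE
    if (any(off)) {
      validation_error(
        "stored EV disagrees with minutes / standard_visit_minutes",
        sprintf("row %d (%s, %s): stored %s vs derived %.4f",
                which(off), items$item_id[off], items$region[off],
                items$ev[off], derived[off]))
    }
  }
  items$ev <- derived

  # every item must define minutes for every declared region, and item
  # metadata must agree across its regional rows
  by_item <- split(items, items$item_id)
  problems <- character()
  for (it in by_item) {
    miss <- setdiff(regions, it$region)
    if (length(miss) > 0) {
      problems <- c(problems, sprintf(
        "item '%s': no minutes for region(s) %s",
        it$item_id[1], paste(miss, collapse = ", ")))
    }
    if (length(unique(it$service_type)) > 1 || length(unique(it$unit)) > 1) {
      problems <- c(problems, sprintf(
        "item '%s': inconsistent service_type or unit across regions",
        it$item_id[1]))
    }
  }
  if (length(problems) > 0) {
    validation_error("invalid catalog", problems)
  }

  structure(
    list(standard_visit_minutes = standard_visit_minutes,
         regions = regions,
         items = items[, c("item_id", "service_type", "item_name", "unit",
                           "region", "minutes", "ev")],
         version = version),
    class = "ev_catalog")
}

#' Built-in two-region EV catalog for the 2016 NEPHS program
#'
#' The 2016 program comprised 12 service types (health records, health
#' education, immunizations, child / maternal / elderly health, hypertension,
#' diabetes, severe mental illness, infectious-disease reporting, traditional
#' Chinese medicine management and health-supervision assistance) broken into
#' 38 survey items. Person-minutes were set separately for two workload
#' regimes: `mid_east` (eastern and central China, combined because their
#' workload gap is small) and `western`, where lower population density and
#' mobile service delivery raise the time cost of many items.
#'
#' EVs are derived from the person-minutes at load time
#' (see [derive_ev()]); the file's stored EV column is only a checksum.
#'
#' @return An `ev_catalog` object with 38 items x 2 regions.
#' @seealso [load_catalog()] for user-supplied catalogs.
#' @examples
#' cat <- builtin_catalog()
#' length(unique(cat$items$service_type))  # 12
#' @export
builtin_catalog <- function() {
  path <- system.file("extdata", "ev_catalog.csv", package = "evworkload",
                      mustWork = TRUE)
  load_catalog(path, version = "nephs-2016")
}

#' Load an EV catalog from CSV or JSON
#'
#' The CSV layout is long: one row per item x region with columns
#' `item_id, service_type, item_name, unit, region, minutes` (an optional
#' `ev` column is validated against `minutes / standard_visit_minutes` and
#' rejected if off by more than 0.05, half the display precision, but the
#' derived value is always what is stored). The JSON layout is a list of
#' item objects with a nested `minutes_by_region` map. Lines starting with
#' `#` in CSV files are comments.
#'
#' @param path Path to the catalog file; format chosen by extension
#'   (`.json` vs anything else = CSV).
#' @param standard_visit_minutes Benchmark visit length, minutes (default 15).
#' @param version Version string recorded on the catalog.
#' @return An `ev_catalog` object.
#' @export
load_catalog <- function(path, standard_visit_minutes = 15, version = "") {
  if (!file.exists(path)) {
    abort(paste0("catalog file not found: ", path),
          class = "evworkload_invalid_argument")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    std <- raw$standard_visit_minutes %||% standard_visit_minutes
    version <- raw$version %||% version
    items <- dplyr::bind_rows(lapply(raw$items, function(it) {
      mins <- unlist(it$minutes_by_region)
      tibble::tibble(item_id = it$item_id %||% NA_character_,
                     service_type = it$service_type %||% NA_character_,
                     item_name = it$item_name %||% "",
                     unit = it$unit %||% NA_character_,
                     region = names(mins),
                     minutes = as.numeric(mins))
    }))
    return(new_ev_catalog(items, standard_visit_minutes = std,
                          version = version))
  }
  items <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(
                             item_id = readr::col_character(),
                             service_type = readr::col_character(),
                             item_name = readr::col_character(),
                             unit = readr::col_character(),
                             region = readr::col_character(),
                             minutes = readr::col_double(),
                             .default = readr::col_double()))
  new_ev_catalog(items, standard_visit_minutes = standard_visit_minutes,
                 version = version)
}

#' Write an EV catalog to CSV
#'
#' Writes the long-format catalog schema read by [load_catalog()], including
#' the derived `ev` column (used as a checksum on re-load).
#'
#' @param catalog An `ev_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ev_catalog"))
  readr::write_csv(catalog$items, path)
  invisible(path)
}

#' Look up the EV of a catalog item
#'
#' @param catalog An `ev_catalog`.
#' @param item An `item_id` or exact `item_name`.
#' @param region Region name declared in the catalog.
#' @return A one-row tibble with `minutes` and `ev`.
#' @examples
#' catalog_lookup(builtin_catalog(), "Postpartum visit", "mid_east")
#' @export
catalog_lookup <- function(catalog, item, region) {
  stopifnot(inherits(catalog, "ev_catalog"))
  if (!region %in% catalog$regions) {
    abort(paste0("unknown region: ", region),
          class = "evworkload_invalid_argument")
  }
  hit <- catalog$items[(catalog$items$item_id == item |
                          catalog$items$item_name == item) &
                         catalog$items$region == region, ]
  if (nrow(hit) != 1) {
    abort(paste0("item not found in catalog: ", item),
          class = "evworkload_invalid_argument")
  }
  hit
}

#' @export
print.ev_catalog <- function(x, ...) {
  cat(sprintf(
    "<ev_catalog%s: %d items, %d service types, regions: %s; standard visit %g min>\n",
    if (nzchar(x$version)) paste0(" ", x$version) else "",
    length(unique(x$items$item_id)),
    length(unique(x$items$service_type)),
    paste(x$regions, collapse = ", "),
    x$standard_visit_minutes))
  invisible(x)
}

# internal: catalog service types in first-appearance (guideline) order
catalog_types <- function(catalog) {
  unique(catalog$items$service_type)
}

# internal: catalog item ids in catalog order
catalog_item_ids <- function(catalog) {
  unique(catalog$items$item_id)
}
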