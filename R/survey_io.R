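#' THC survey datasets
#'
#' A survey dataset is a long tibble with one row per township hospital
#' center (THC) x service item:
#'
#' * `thc_id`, `county_id`, `prefecture_id`, `province_id` — the sampling
#'   hierarchy identifiers (THC ids unique within the dataset);
#' * `region` — the catalog region whose person-minutes apply to the THC;
#' * `item_id` — a catalog item;
#' * `volume` — annual number of deliveries of the item in the THC's
#'   catchment (non-negative; reals allowed since departments may report
#'   apportioned or annualised figures);
#' * `vd_share` — fraction in \[0, 1\] of the item's volume delivered by
#'   village doctors, as estimated by the THC's service departments.
#'
#' Shares are carried as fractions internally; all file surfaces use percent
#' (`vd_share_pct`), matching how such figures are reported. Items a THC
#' does not report are treated as not delivered (volume 0, share 0), never
#' as errors.
#'
#' @name thc_survey
NULL

survey_cols <- c("thc_id", "county_id", "prefecture_id", "province_id",
                 "region", "item_id", "volume", "vd_share")

# internal: build + validate a survey tibble against a catalog
new_survey <- function(records, catalog, catalog_version = catalog$version) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(survey_cols, names(records))
  if (length(missing_cols) > 0) {
    validation_error("survey is missing required columns",
                     paste("column:", missing_cols))
  }
  records <- records[, survey_cols]
  out <- validate_survey(records, catalog)
  attr(out, "catalog_version") <- catalog_version
  class(out) <- c("thc_survey", class(tibble::tibble()))
  out
}

#' Validate a survey dataset against a catalog
#'
#' Checks that every `item_id` exists in the catalog, every `region` is
#' declared by the catalog, volumes are non-negative, shares are fractions
#' in \[0, 1\], and no THC appears with two rows for the same item or under
#' two different hierarchy labels. Errors list the offending row numbers.
#'
#' @param records A survey tibble (see [thc_survey]).
#' @param catalog The companion `ev_catalog`.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_survey <- function(records, catalog) {
  stopifnot(inherits(catalog, "ev_catalog"))
  records <- tibble::as_tibble(records)
  problems <- character()

  alien <- !(records$item_id %in% catalog_item_ids(catalog))
  if (any(alien)) {
    problems <- c(problems, sprintf("row %d: unknown item_id '%s'",
                                    which(alien), records$item_id[alien]))
  }
  bad_region <- !(records$region %in% catalog$regions)
  if (any(bad_region)) {
    problems <- c(problems, sprintf("row %d: unknown region '%s'",
                                    which(bad_region),
                                    records$region[bad_region]))
  }
  bad_vol <- !is.finite(records$volume) | records$volume < 0
  if (any(bad_vol)) {
    problems <- c(problems, sprintf("row %d: negative or missing volume",
                                    which(bad_vol)))
  }
  bad_share <- !is.finite(records$vd_share) | records$vd_share < 0 |
    records$vd_share > 1
  if (any(bad_share)) {
    problems <- c(problems, sprintf(
      "row %d: vd_share %s outside [0, 1]", which(bad_share),
      format(records$vd_share[bad_share])))
  }
  dup <- duplicated(records[, c("thc_id", "item_id")])
  if (any(dup)) {
    problems <- c(problems, sprintf("row %d: duplicate item '%s' for THC '%s'",
                                    which(dup), records$item_id[dup],
                                    records$thc_id[dup]))
  }
  # a THC id must map to a single position in the sampling hierarchy
  ids <- unique(records[, c("thc_id", "county_id", "prefecture_id",
                            "province_id", "region")])
  clash <- ids$thc_id[duplicated(ids$thc_id)]
  if (length(clash) > 0) {
    problems <- c(problems, sprintf(
      "thc_id '%s' appears with conflicting hierarchy or region",
      unique(clash)))
  }
  if (length(problems) > 0) {
    validation_error("invalid survey dataset", problems)
  }
  invisible(records)
}

#' Read a THC survey from CSV or JSON
#'
#' The CSV layout is long with columns `thc_id, county_id, prefecture_id,
#' province_id, region, item_id, volume, vd_share_pct`; shares arrive as
#' percentages in \[0, 100\] and are divided by 100 on ingest. A JSON file
#' holds a list of THC objects with `volumes` and `vd_shares` maps keyed by
#' item id (shares already as fractions).
#'
#' @param path Input file; format chosen by extension.
#' @param catalog The `ev_catalog` the survey reports against.
#' @return A validated `thc_survey` tibble.
#' @export
read_survey <- function(path, catalog) {
  if (!file.exists(path)) {
    abort(paste0("survey file not found: ", path),
          class = "evworkload_invalid_argument")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    recs <- raw$records %||% raw
    records <- dplyr::bind_rows(lapply(recs, function(r) {
      ids <- names(r$volumes)
      tibble::tibble(thc_id = r$thc_id, county_id = r$county_id,
                     prefecture_id = r$prefecture_id,
                     province_id = r$province_id, region = r$region,
                     item_id = ids,
                     volume = as.numeric(unlist(r$volumes)),
                     vd_share = as.numeric(unlist(r$vd_shares))[
                       match(ids, names(r$vd_shares))])
    }))
    return(new_survey(records, catalog,
                      catalog_version = raw$catalog_version %||% catalog$version))
  }
  records <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                             col_types = readr::cols(
                               thc_id = readr::col_character(),
                               county_id = readr::col_character(),
                               prefecture_id = readr::col_character(),
                               province_id = readr::col_character(),
                               region = readr::col_character(),
                               item_id = readr::col_character(),
                               volume = readr::col_double(),
                               vd_share_pct = readr::col_double()))
  bad_pct <- !is.finite(records$vd_share_pct) | records$vd_share_pct < 0 |
    records$vd_share_pct > 100
  if (any(bad_pct)) {
    validation_error("invalid survey dataset",
                     sprintf("row %d: vd_share_pct %s outside [0, 100]",
                             which(bad_pct),
                             format(records$vd_share_pct[bad_pct])))
  }
  records$vd_share <- records$vd_share_pct / 100
  records$vd_share_pct <- NULL
  new_survey(records, catalog)
}

#' Write a THC survey to CSV
#'
#' Long format, one row per THC x item, shares written as percentages
#' (`vd_share_pct`) at full precision so a write/read round trip is
#' lossless.
#'
#' @param survey A survey tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- tibble::as_tibble(survey)[, survey_cols]
  out$vd_share_pct <- out$vd_share * 100
  out$vd_share <- NULL
  readr::write_csv(out, path)
  invisible(path)
}

#' Fill in unreported THC x item combinations as zero
#'
#' Expands a survey so every THC carries a row for every catalog item,
#' coding absent items as volume 0, share 0 (service not delivered). The
#' aggregation engine gives identical results with or without the zero rows;
#' this is for display and for per-record completeness checks.
#'
#' @param survey A validated survey tibble.
#' @param catalog The companion `ev_catalog`.
#' @return The completed survey tibble.
#' @export
complete_survey <- function(survey, catalog) {
  thcs <- unique(tibble::as_tibble(survey)[, c("thc_id", "county_id",
                                               "prefecture_id", "province_id",
                                               "region")])
  full <- tidyr::crossing(thcs, item_id = catalog_item_ids(catalog))
  out <- dplyr::left_join(full, tibble::as_tibble(survey),
                          by = c("thc_id", "county_id", "prefecture_id",
                                 "province_id", "region", "item_id"))
  out$volume[is.na(out$volume)] <- 0
  out$vd_share[is.na(out$vd_share)] <- 0
  out[, survey_cols]
}
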