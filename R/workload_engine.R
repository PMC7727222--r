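#' @title The EV aggregation engine
#' @description
#' The model reduces to three sums over surveyed (THC, item) pairs, with
#' A the item's EV in the THC's region, B the annual volume and C the
#' village-doctor fraction:
#' \deqn{Y = \sum A \times B} (total EVs delivered),
#' \deqn{X = \sum A \times B \times C} (EVs delivered by village doctors),
#' \deqn{share = X / Y \times 100\%.}
#' All aggregation is done on unrounded EVs; rounding happens only when a
#' report is rendered.
#' @name workload_engine
NULL

# internal: survey joined to catalog EVs, restricted to a scope.
# scope is a named list composing conjunctively over
# province / service_type / thc / item; NULL or empty = overall.
ev_terms <- function(survey, catalog, scope = NULL) {
  terms <- dplyr::inner_join(
    tibble::as_tibble(survey),
    catalog$items[, c("item_id", "region", "service_type", "ev")],
    by = c("item_id", "region"))
  if (is.null(scope) || length(scope) == 0) {
    return(terms)
  }
  allowed <- c("province", "service_type", "thc", "item")
  bad <- setdiff(names(scope), allowed)
  if (length(bad) > 0 || is.null(names(scope)) || any(names(scope) == "")) {
    abort(paste0("unknown scope field(s): ",
                 paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")),
          class = "evworkload_invalid_argument")
  }
  known <- list(province = unique(terms$province_id),
                service_type = catalog_types(catalog),
                thc = unique(terms$thc_id),
                item = catalog_item_ids(catalog))
  for (f in names(scope)) {
    unknown <- setdiff(scope[[f]], known[[f]])
    if (length(unknown) > 0) {
      abort(sprintf("scope %s refers to unknown value(s): %s", f,
                    paste(unknown, collapse = ", ")),
            class = "evworkload_invalid_argument")
    }
  }
  if (!is.null(scope$province)) {
    terms <- terms[terms$province_id %in% scope$province, ]
  }
  if (!is.null(scope$service_type)) {
    terms <- terms[terms$service_type %in% scope$service_type, ]
  }
  if (!is.null(scope$thc)) {
    terms <- terms[terms$thc_id %in% scope$thc, ]
  }
  if (!is.null(scope$item)) {
    terms <- terms[terms$item_id %in% scope$item, ]
  }
  terms
}

#' Total EVs delivered in a scope (Y)
#'
#' Sums EV x volume over all in-scope (THC, item) pairs, each item weighted
#' by the EV of the THC's own region.
#'
#' @param survey A validated survey tibble.
#' @param catalog The companion `ev_catalog`.
#' @param scope Optional named list composing conjunctively over
#'   `province`, `service_type`, `thc`, `item`; `NULL` means overall.
#' @return Total EVs (one EV = one standard clinic visit).
#' @export
total_ev <- function(survey, catalog, scope = NULL) {
  terms <- ev_terms(survey, catalog, scope)
  sum(terms$ev * terms$volume)
}

#' EVs delivered by village doctors in a scope (X)
#'
#' Sums EV x volume x village-doctor fraction over in-scope pairs.
#'
#' @inheritParams total_ev
#' @return Village-doctor EVs.
#' @export
vd_ev <- function(survey, catalog, scope = NULL) {
  terms <- ev_terms(survey, catalog, scope)
  sum(terms$ev * terms$volume * terms$vd_share)
}

#' Percentage share of workload delivered by village doctors
#'
#' @param x_ev Village-doctor EV total (X).
#' @param y_ev Overall EV total (Y).
#' @return `x_ev / y_ev * 100`; `NA` (undefined) when `y_ev` is 0. An X
#'   exceeding Y is flagged with a warning (it implies an upstream share
#'   above 1) but still returned.
#' @examples
#' share_pct(18.50, 42.32)  # 43.71...
#' @export
share_pct <- function(x_ev, y_ev) {
  if (any(y_ev < 0, na.rm = TRUE)) {
    abort("`y_ev` must be non-negative", class = "evworkload_invalid_argument")
  }
  if (any(x_ev > y_ev, na.rm = TRUE)) {
    warn("X exceeds Y: some input share is above 1",
         class = "evworkload_inconsistent_input")
  }
  ifelse(y_ev > 0, x_ev / y_ev * 100, NA_real_)
}

#' X, Y and share for one scope
#'
#' @inheritParams total_ev
#' @param threshold Compliance threshold in percent (default 40).
#' @return A one-row tibble: `y_ev`, `x_ev`, `share_pct`, `compliance`.
#' @export
workload <- function(survey, catalog, scope = NULL, threshold = 40) {
  terms <- ev_terms(survey, catalog, scope)
  y <- sum(terms$ev * terms$volume)
  x <- sum(terms$ev * terms$volume * terms$vd_share)
  s <- share_pct(x, y)
  tibble::tibble(y_ev = y, x_ev = x, share_pct = s,
                 compliance = compliance(s, threshold))
}

#' Compliance with the 40% delegation requirement
#'
#' Policy requires that no less than 40% of the NEPHS workload be assigned
#' to village doctors, so the bound is closed: a share of exactly 40 is
#' compliant. An undefined share (no workload in scope) is neither.
#'
#' @param share_pct Share percentage(s) in \[0, 100\], `NA` for undefined.
#' @param threshold Threshold percentage (default 40).
#' @return Character vector over `{"compliant", "non_compliant",
#'   "undefined"}`.
#' @export
compliance <- function(share_pct, threshold = 40) {
  ifelse(is.na(share_pct), "undefined",
         ifelse(share_pct >= threshold, "compliant", "non_compliant"))
}

# internal: X/Y per group, groups taken from a grouping column
group_workload <- function(terms, group_col, levels) {
  terms$.g <- factor(terms[[group_col]], levels = levels)
  out <- terms |>
    dplyr::group_by(.g, .drop = FALSE) |>
    dplyr::summarise(y_ev = sum(ev * volume),
                     x_ev = sum(ev * volume * vd_share),
                     .groups = "drop")
  names(out)[1] <- group_col
  out[[group_col]] <- as.character(out[[group_col]])
  out
}

#' Share of workload by service type
#'
#' Aggregates a survey into one row per service type (in catalog order)
#' plus a Total row; X and Y are exactly additive, so the Total row equals
#' the column sums of the unrounded type rows. Types with no in-scope
#' workload get an undefined share, excluded from the min/max summary.
#'
#' @inheritParams workload
#' @return A `share_report` of kind `"by_type"`.
#' @export
aggregate_by_type <- function(survey, catalog, threshold = 40) {
  terms <- ev_terms(survey, catalog)
  rows <- group_workload(terms, "service_type", catalog_types(catalog))
  rows$share_pct <- share_pct(rows$x_ev, rows$y_ev)
  rows$compliance <- compliance(rows$share_pct, threshold)
  total <- tibble::tibble(service_type = "Total",
                          y_ev = sum(rows$y_ev), x_ev = sum(rows$x_ev))
  total$share_pct <- share_pct(total$x_ev, total$y_ev)
  total$compliance <- compliance(total$share_pct, threshold)
  defined <- rows[!is.na(rows$share_pct), ]
  summary <- if (nrow(defined) > 0) {
    list(min = list(label = defined$service_type[which.min(defined$share_pct)],
                    share_pct = min(defined$share_pct)),
         max = list(label = defined$service_type[which.max(defined$share_pct)],
                    share_pct = max(defined$share_pct)))
  } else {
    list(min = NULL, max = NULL)
  }
  structure(list(kind = "by_type", rows = rows, total_row = total,
                 summary = summary, threshold = threshold),
            class = "share_report")
}

#' Share of workload by province
#'
#' Builds the province x service-type share matrix plus a per-province
#' Total row, and summarises the min and max of the provincial totals.
#' Province partition conserves X and Y: provincial totals sum exactly to
#' the overall totals.
#'
#' @inheritParams workload
#' @param provinces Optional character vector fixing the column order;
#'   defaults to first appearance order in the survey.
#' @return A `share_report` of kind `"by_province_matrix"`. `$rows` holds
#'   per-province totals (one row per province), `$matrix` the per-type
#'   share matrix in percent (types x provinces, `NA` = undefined),
#'   `$total_row` the overall aggregate.
#' @export
aggregate_by_province <- function(survey, catalog, threshold = 40,
                                  provinces = NULL) {
  terms <- ev_terms(survey, catalog)
  provinces <- provinces %||% unique(tibble::as_tibble(survey)$province_id)
  types <- catalog_types(catalog)

  cells <- terms |>
    dplyr::mutate(province_id = factor(province_id, levels = provinces),
                  service_type = factor(service_type, levels = types)) |>
    dplyr::group_by(province_id, service_type, .drop = FALSE) |>
    dplyr::summarise(y_ev = sum(ev * volume),
                     x_ev = sum(ev * volume * vd_share),
                     .groups = "drop")
  cells$share_pct <- share_pct(cells$x_ev, cells$y_ev)
  mat <- matrix(cells$share_pct, nrow = length(types),
                dimnames = list(types, provinces))

  rows <- cells |>
    dplyr::group_by(province_id) |>
    dplyr::summarise(y_ev = sum(y_ev), x_ev = sum(x_ev), .groups = "drop") |>
    dplyr::rename(province = province_id) |>
    dplyr::mutate(province = as.character(province),
                  share_pct = share_pct(x_ev, y_ev),
                  compliance = compliance(share_pct, threshold))

  total <- tibble::tibble(province = "Overall",
                          y_ev = sum(rows$y_ev), x_ev = sum(rows$x_ev))
  total$share_pct <- share_pct(total$x_ev, total$y_ev)
  total$compliance <- compliance(total$share_pct, threshold)

  defined <- rows[!is.na(rows$share_pct), ]
  summary <- if (nrow(defined) > 0) {
    list(min = list(label = defined$province[which.min(defined$share_pct)],
                    share_pct = min(defined$share_pct)),
         max = list(label = defined$province[which.max(defined$share_pct)],
                    share_pct = max(defined$share_pct)))
  } else {
    list(min = NULL, max = NULL)
  }
  structure(list(kind = "by_province_matrix", rows = rows, matrix = mat,
                 cells = cells, total_row = total, summary = summary,
                 threshold = threshold),
            class = "share_report")
}

#' @export
print.share_report <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}
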