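#' @title Report rendering
#' @description
#' Reports are rendered from `share_report` objects produced by
#' [aggregate_by_type()] / [aggregate_by_province()] (or constructed from
#' pre-aggregated totals). Rendering is pure — the same report always
#' yields identical bytes — and is the only place rounding happens: EV
#' totals are displayed in millions to 2 decimals, by-type shares to
#' 2 decimals, by-province shares to 1 decimal. Undefined shares (no
#' workload in scope) render as an em dash and are excluded from min/max
#' footers and compliance counts.
#' @name reporting
NULL

dash <- "—"

fmt_num <- function(x, digits) {
  ifelse(is.na(x), dash, sprintf(paste0("%.", digits, "f"), x))
}

#' Build a by-type share report from pre-aggregated EV totals
#'
#' For workflows where only per-type X and Y totals are available (e.g. the
#' published survey aggregates) rather than THC microdata.
#'
#' @param rows Tibble with `service_type`, `y_ev`, `x_ev` (no Total row;
#'   it is recomputed from the unrounded sums).
#' @param threshold Compliance threshold in percent.
#' @return A `share_report` of kind `"by_type"`.
#' @export
share_report_from_totals <- function(rows, threshold = 40) {
  rows <- tibble::as_tibble(rows)[, c("service_type", "y_ev", "x_ev")]
  rows$share_pct <- share_pct(rows$x_ev, rows$y_ev)
  rows$compliance <- compliance(rows$share_pct, threshold)
  total <- tibble::tibble(service_type = "Total",
                          y_ev = sum(rows$y_ev), x_ev = sum(rows$x_ev))
  total$share_pct <- share_pct(total$x_ev, total$y_ev)
  total$compliance <- compliance(total$share_pct, threshold)
  defined <- rows[!is.na(rows$share_pct), ]
  summary <- list(
    min = list(label = defined$service_type[which.min(defined$share_pct)],
               share_pct = min(defined$share_pct)),
    max = list(label = defined$service_type[which.max(defined$share_pct)],
               share_pct = max(defined$share_pct)))
  structure(list(kind = "by_type", rows = rows, total_row = total,
                 summary = summary, threshold = threshold),
            class = "share_report")
}

#' Build a by-province share report from a share matrix
#'
#' For rendering a province x service-type share matrix (plus provincial
#' total shares) when the underlying EV totals are not available, as with
#' the published provincial results.
#'
#' @param share_matrix Numeric matrix, service types x provinces, shares in
#'   percent (`NA` = undefined).
#' @param total_share_pct Named numeric vector of provincial total shares in
#'   percent, names matching the matrix columns.
#' @param threshold Compliance threshold in percent.
#' @return A `share_report` of kind `"by_province_matrix"` (EV totals `NA`).
#' @export
share_report_from_matrix <- function(share_matrix, total_share_pct,
                                     threshold = 40) {
  stopifnot(is.matrix(share_matrix),
            identical(colnames(share_matrix), names(total_share_pct)))
  rows <- tibble::tibble(province = colnames(share_matrix),
                         y_ev = NA_real_, x_ev = NA_real_,
                         share_pct = unname(total_share_pct))
  rows$compliance <- compliance(rows$share_pct, threshold)
  defined <- rows[!is.na(rows$share_pct), ]
  summary <- list(
    min = list(label = defined$province[which.min(defined$share_pct)],
               share_pct = min(defined$share_pct)),
    max = list(label = defined$province[which.max(defined$share_pct)],
               share_pct = max(defined$share_pct)))
  total <- tibble::tibble(province = "Overall", y_ev = NA_real_,
                          x_ev = NA_real_, share_pct = NA_real_,
                          compliance = "undefined")
  structure(list(kind = "by_province_matrix", rows = rows,
                 matrix = share_matrix, cells = NULL, total_row = total,
                 summary = summary, threshold = threshold),
            class = "share_report")
}

# internal: formatted (character) table for a by_type report
format_by_type <- function(report, millions = TRUE) {
  all_rows <- dplyr::bind_rows(report$rows, report$total_row)
  scale <- if (millions) 1e6 else 1
  unit <- if (millions) "millions of EVs" else "EVs"
  tibble::tibble(
    service_type = all_rows$service_type,
    total_ev = fmt_num(all_rows$y_ev / scale, 2),
    vd_ev = fmt_num(all_rows$x_ev / scale, 2),
    share_pct = fmt_num(all_rows$share_pct, 2),
    compliance = all_rows$compliance) |>
    structure(ev_unit = unit)
}

# internal: formatted table for a by_province_matrix report; the footer
# min/max rows carry the value only in the province achieving it
format_by_province <- function(report) {
  mat <- report$matrix
  body <- tibble::as_tibble(mat, rownames = "service_type")
  body[-1] <- lapply(body[-1], fmt_num, digits = 1)
  total <- c(service_type = "Total",
             setNames(fmt_num(report$rows$share_pct, 1),
                      report$rows$province))
  out <- dplyr::bind_rows(body, tibble::as_tibble_row(total))
  for (side in c("max", "min")) {
    s <- report$summary[[side]]
    if (is.null(s)) next
    row <- setNames(rep(dash, ncol(out)), names(out))
    row["service_type"] <- paste0(toupper(substring(side, 1, 1)),
                                  substring(side, 2), " provincial total")
    row[s$label] <- fmt_num(s$share_pct, 1)
    out <- dplyr::bind_rows(out, tibble::as_tibble_row(row))
  }
  out
}

render_formatted <- function(df, format, title = NULL) {
  format <- match.arg(format, c("text", "csv", "md"))
  if (format == "csv") {
    return(readr::format_csv(df))
  }
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(x) max(nchar(x), 0L), integer(1)))
  pad <- function(cells) {
    paste(mapply(formatC, cells, width = widths,
                 MoreArgs = list(flag = "-")), collapse = if (format == "md") " | " else "  ")
  }
  header <- pad(names(df))
  lines <- vapply(seq_len(nrow(df)), function(i) pad(unlist(df[i, ])),
                  character(1))
  if (format == "md") {
    header <- paste0("| ", header, " |")
    rule <- paste0("|", paste(strrep("-", widths + 2), collapse = "|"), "|")
    lines <- paste0("| ", lines, " |")
    body <- c(header, rule, lines)
  } else {
    body <- c(header, strrep("-", sum(widths) + 2 * (length(widths) - 1)),
              lines)
  }
  paste(c(title, body), collapse = "\n")
}

#' Render a by-type share report
#'
#' Columns: service type, total EVs, village-doctor EVs (both in millions
#' to 2 decimals unless `millions = FALSE`), share in percent (2 decimals)
#' and the compliance flag, with a final Total row. The `csv`, `md` and
#' `text` renderings contain identical numbers.
#'
#' @param report A `share_report` of kind `"by_type"`.
#' @param format `"text"`, `"csv"` or `"md"`.
#' @param millions Display EV totals in millions (default) or raw.
#' @return A single string.
#' @export
render_table2 <- function(report, format = "text", millions = TRUE) {
  stopifnot(inherits(report, "share_report"))
  if (report$kind != "by_type") {
    abort("render_table2() needs a by_type report",
          class = "evworkload_invalid_argument")
  }
  df <- format_by_type(report, millions = millions)
  title <- if (format != "csv") {
    sprintf("Village-doctor share of workload by service type (EVs in %s; threshold %g%%)",
            attr(df, "ev_unit"), report$threshold)
  }
  render_formatted(df, format, title = title)
}

#' Render a by-province share report
#'
#' One column per province in configuration order, shares in percent to
#' 1 decimal; a Total row of provincial total shares; footer rows marking
#' the maximum and minimum provincial totals.
#'
#' @param report A `share_report` of kind `"by_province_matrix"`.
#' @param format `"text"`, `"csv"` or `"md"`.
#' @return A single string.
#' @export
render_table3 <- function(report, format = "text") {
  stopifnot(inherits(report, "share_report"))
  if (report$kind != "by_province_matrix") {
    abort("render_table3() needs a by_province_matrix report",
          class = "evworkload_invalid_argument")
  }
  df <- format_by_province(report)
  title <- if (format != "csv") {
    sprintf("Village-doctor share of workload by province (%%; threshold %g%%)",
            report$threshold)
  }
  render_formatted(df, format, title = title)
}

# internal dispatcher used by print.share_report
render_report <- function(report, format = "text") {
  if (report$kind == "by_type") {
    render_table2(report, format)
  } else {
    render_table3(report, format)
  }
}

#' Write a rendered report to disk
#'
#' @param report A `share_report`.
#' @param path Output path.
#' @param format `"csv"` (default), `"text"` or `"md"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = "csv") {
  writeLines(sub("\n$", "", render_report(report, format)), path)
  invisible(path)
}
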