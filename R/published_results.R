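#' Published aggregate results of the 2016 six-province NEPHS workload survey
#'
#' The model was calibrated against a 2016 survey of 300 THCs in six
#' anonymised provinces (two each from eastern, central and western China).
#' These functions return the published aggregate results of that survey:
#' they are the calibration targets for the synthetic-data generator and the
#' worked-example inputs for the reporting functions. The raw THC microdata
#' were never released, which is why the package ships a generator instead.
#'
#' `published_shares_by_type()` gives, per service type, the total EVs
#' delivered by the sampled THCs and the EVs delivered by village doctors
#' (both in millions of EVs, rounded to 2 decimals as published) and the
#' published share percentage; the final row is the overall Total
#' (42.32 / 18.50 million EVs, share 43.71%). The published shares were
#' computed on unrounded EV totals, so recomputing a share from the rounded
#' EV columns reproduces the published value only to within about
#' +/- 0.6 percentage points.
#'
#' `published_shares_by_province()` gives the province x service-type share
#' matrix in percent (1 decimal as published); the final row is each
#' province's Total share, ranging from 28.5% to 63.4%.
#'
#' @return A tibble; the last row of each is the Total row.
#' @examples
#' t2 <- published_shares_by_type()
#' with(t2[t2$service_type == "Total", ],
#'      vd_ev_millions / total_ev_millions * 100)  # ~43.71
#' @name published_results
NULL

#' @rdname published_results
#' @export
published_shares_by_type <- function() {
  tibble::tribble(
    ~service_type, ~total_ev_millions, ~vd_ev_millions, ~share_pct,
    "Health records management service",                  6.59, 3.27, 49.54,
    "Health education",                                   7.13, 3.37, 47.24,
    "Immunizations",                                      3.86, 1.10, 28.42,
    "Health services for children aged 0 to 6 years",     6.03, 1.86, 30.91,
    "Maternal health services",                           1.40, 0.45, 31.83,
    "Elderly people's health services",                   4.27, 1.78, 41.80,
    "Health services for patients with hypertension",     7.35, 4.19, 57.00,
    "Health services for patients with type II diabetes", 1.98, 1.10, 55.42,
    "Health services for patients with severe mental illness",
                                                          0.68, 0.35, 51.76,
    "Reporting and management of infectious diseases and public health emergencies",
                                                          0.12, 0.02, 17.14,
    "Health management with Chinese medicine",            2.08, 0.80, 38.43,
    "Health supervision assistance services",             0.84, 0.22, 26.20,
    "Total",                                             42.32, 18.50, 43.71)
}

#' @rdname published_results
#' @export
published_shares_by_province <- function() {
  tibble::tribble(
    ~service_type, ~province_1, ~province_2, ~province_3, ~province_4,
    ~province_5, ~province_6,
    "Health records management service",              26.6, 48.1, 34.9, 78.0, 52.6, 49.4,
    "Health education",                               35.3, 45.6, 28.0, 59.6, 47.2, 64.2,
    "Immunizations",                                  34.4, 23.1, 21.6, 26.6, 27.8, 33.5,
    "Health services for children aged 0 to 6 years", 27.6, 28.9, 37.5, 30.2, 30.9, 30.0,
    "Maternal health services",                       29.7, 34.2, 37.9, 27.6, 24.1, 36.1,
    "Elderly people's health services",               44.5, 42.8, 32.1, 48.0, 46.3, 39.9,
    "Health services for patients with hypertension", 53.4, 64.2, 60.5, 59.0, 55.3, 49.8,
    "Health services for patients with type II diabetes",
                                                      48.1, 55.0, 57.2, 53.1, 55.6, 62.0,
    "Health services for patients with severe mental illness",
                                                      55.8, 46.5, 51.3, 48.1, 53.8, 54.6,
    "Reporting and management of infectious diseases and public health emergencies",
                                                      17.9, 18.8, 14.3, 18.6, 22.6, 13.2,
    "Health management with Chinese medicine",        40.0, 34.0, 39.3, 36.7, 41.5, 38.6,
    "Health supervision assistance services",         19.1, 41.6, 21.3, 17.8, 18.6, 41.0,
    "Total",                                          35.5, 45.5, 28.5, 59.2, 47.1, 63.4)
}
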