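#' Default province profiles for the synthetic generator
#'
#' One profile per anonymised province: its workload region, its target
#' village-doctor share per service type (the published province x type
#' share matrix divided by 100) and a volume scale multiplier. The published
#' results never map provinces 1-6 to named provinces or regions; assigning
#' provinces 1-4 to `mid_east` and 5-6 to `western` is a labelled assumption
#' (four of the six sampled provinces were eastern or central), overridable
#' by editing the profiles.
#'
#' @param catalog Catalog whose regions the profiles must use.
#' @return A named list of profiles, each a list with `province_id`,
#'   `region`, `target_share_by_type` (named fractions) and `volume_scale`.
#' @export
province_profiles <- function(catalog = builtin_catalog()) {
  pub <- published_shares_by_province()
  types <- pub$service_type[pub$service_type != "Total"]
  regions <- c(rep("mid_east", 4), rep("western", 2))
  profiles <- lapply(seq_len(6), function(p) {
    col <- paste0("province_", p)
    list(province_id = col,
         region = regions[p],
         target_share_by_type = setNames(
           pub[[col]][pub$service_type != "Total"] / 100, types),
         volume_scale = 1)
  })
  names(profiles) <- paste0("province_", seq_len(6))
  profiles
}

#' Default mean annual volumes per item
#'
#' The published results report only aggregate EVs per service type, never
#' raw service counts, so per-item mean volumes are invented. They are
#' derived deterministically from the published per-type EV totals: each
#' type's total (millions of EVs across the 300 surveyed THCs) is split
#' equally across the type's items in EV terms, then converted to a per-THC
#' annual count using the item's sampling-frame-weighted mean EV (4 mid-east
#' provinces to 2 western). This makes the default synthetic dataset total
#' about 42 million EVs, the published order of magnitude, with a realistic
#' per-type composition.
#'
#' @param catalog The `ev_catalog` to derive volumes for.
#' @param n_thcs Number of THCs in the sampling frame (default 300).
#' @return Named numeric vector, mean annual volume per `item_id`.
#' @export
default_base_volumes <- function(catalog = builtin_catalog(), n_thcs = 300) {
  pub <- published_shares_by_type()
  items <- catalog$items |>
    dplyr::group_by(item_id, service_type) |>
    dplyr::summarise(
      ev_weighted = sum(ev * ifelse(region == "mid_east", 4, 2)) / 6,
      .groups = "drop")
  items <- items |>
    dplyr::add_count(service_type, name = "n_items") |>
    dplyr::left_join(pub[, c("service_type", "total_ev_millions")],
                     by = "service_type")
  if (any(is.na(items$total_ev_millions))) {
    # types absent from the published table get a nominal EV budget
    items$total_ev_millions[is.na(items$total_ev_millions)] <- 1
  }
  vol <- with(items, pmax(1, round(
    total_ev_millions * 1e6 / (n_items * ev_weighted * n_thcs))))
  setNames(vol, items$item_id)[catalog_item_ids(catalog)]
}

#' Default generator configuration
#'
#' Reproduces the study's stratified sampling frame — 6 provinces x
#' 5 prefectures x 2 counties x 5 THCs = 300 THCs — with per-province,
#' per-type village-doctor share targets taken from the published share
#' matrix, invented per-item mean volumes (see [default_base_volumes()]),
#' log-normal volume noise with coefficient of variation 0.4 (between-THC
#' catchment-size variation) and Beta-distributed shares with precision 100
#' (between-THC standard deviation of roughly 5 percentage points around
#' the provincial target).
#'
#' @param seed Master seed (integer); every THC's random sub-stream is
#'   derived from it deterministically.
#' @param catalog Catalog the generated survey reports against.
#' @return An `ev_sim_config` list.
#' @export
default_config <- function(seed = 1, catalog = builtin_catalog()) {
  cfg <- list(n_provinces = 6,
              prefectures_per_province = 5,
              counties_per_prefecture = 2,
              thcs_per_county = 5,
              profiles = province_profiles(catalog),
              base_volume_by_item = default_base_volumes(catalog),
              volume_dispersion = 0.4,
              share_concentration = 100,
              seed = as.integer(seed))
  structure(cfg, class = "ev_sim_config")
}

# internal: reject structurally invalid configs
validate_config <- function(config, catalog) {
  problems <- character()
  counts <- c("n_provinces", "prefectures_per_province",
              "counties_per_prefecture", "thcs_per_county")
  for (f in counts) {
    v <- config[[f]]
    if (!is_scalar_number(v) || v < 1 || v != round(v)) {
      problems <- c(problems, paste0(f, " must be a positive integer"))
    }
  }
  if (length(config$profiles) != config$n_provinces) {
    problems <- c(problems, "need one profile per province")
  }
  for (pr in config$profiles) {
    if (!pr$region %in% catalog$regions) {
      problems <- c(problems, paste0("profile ", pr$province_id,
                                     ": unknown region ", pr$region))
    }
    tg <- pr$target_share_by_type
    if (any(tg < 0 | tg > 1)) {
      problems <- c(problems, paste0("profile ", pr$province_id,
                                     ": target shares outside [0, 1]"))
    }
    if (!all(catalog_types(catalog) %in% names(tg))) {
      problems <- c(problems, paste0("profile ", pr$province_id,
                                     ": missing target for some service type"))
    }
    if (!is_scalar_number(pr$volume_scale) || pr$volume_scale <= 0) {
      problems <- c(problems, paste0("profile ", pr$province_id,
                                     ": volume_scale must be positive"))
    }
  }
  miss <- setdiff(catalog_item_ids(catalog), names(config$base_volume_by_item))
  if (length(miss) > 0) {
    problems <- c(problems, paste("no base volume for item:", miss))
  }
  if (!is_scalar_number(config$volume_dispersion) ||
      config$volume_dispersion <= 0) {
    problems <- c(problems, "volume_dispersion must be positive")
  }
  sc <- config$share_concentration
  if (!(is.numeric(sc) && length(sc) == 1 && !is.na(sc) && sc > 0)) {
    problems <- c(problems, "share_concentration must be positive (Inf allowed)")
  }
  if (length(problems) > 0) {
    validation_error("invalid generator config", problems)
  }
  invisible(config)
}

# internal: deterministic per-THC seed below 2^31, a function of the master
# seed and the THC's position in the frame (not of generation order)
thc_seed <- function(master, index) {
  (as.numeric(master) * 1000003 + index * 7919) %% 2147483647 + 1
}

#' Generate a synthetic THC survey
#'
#' Emulates the study's data collection on its sampling frame: one record
#' per THC, each reporting an annual volume and a village-doctor share for
#' every catalog item. Volumes are log-normal around the item's mean volume
#' (coefficient of variation `volume_dispersion`), rounded to whole counts
#' and then multiplied by the province's volume scale, so rescaling a
#' province rescales its volumes exactly. Shares are Beta-distributed
#' with mean equal to the province x service-type target and precision
#' `share_concentration`; one draw per type per THC is applied to all of the
#' type's items, mirroring how THC departments report one delegation figure
#' per service area. `share_concentration = Inf` collapses the Beta to its
#' mean (every share equals its target exactly).
#'
#' Each THC has its own random sub-stream derived from the master seed, so
#' results are reproducible and independent of generation order. The
#' caller's RNG state is left untouched.
#'
#' @param config An `ev_sim_config`, e.g. [default_config()].
#' @param catalog The `ev_catalog` the survey reports against.
#' @return A validated `thc_survey` tibble with
#'   `n_provinces x prefectures x counties x thcs` records, each holding one
#'   row per catalog item.
#' @export
generate_survey <- function(config, catalog = builtin_catalog()) {
  validate_config(config, catalog)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }

  item_ids <- catalog_item_ids(catalog)
  item_type <- catalog$items$service_type[match(item_ids, catalog$items$item_id)]
  types <- catalog_types(catalog)
  base_vol <- config$base_volume_by_item[item_ids]
  sdlog <- sqrt(log(1 + config$volume_dispersion^2))
  phi <- config$share_concentration

  frame <- expand.grid(
    t = seq_len(config$thcs_per_county),
    c = seq_len(config$counties_per_prefecture),
    f = seq_len(config$prefectures_per_province),
    p = seq_len(config$n_provinces))
  frame <- frame[order(frame$p, frame$f, frame$c, frame$t), ]

  records <- lapply(seq_len(nrow(frame)), function(i) {
    cell <- frame[i, ]
    profile <- config$profiles[[cell$p]]
    set.seed(thc_seed(config$seed, i))

    # scale multiplies after integer rounding so that rescaling a province's
    # volumes (same seed) rescales every volume exactly, leaving shares
    # untouched; with the default scale of 1 volumes are whole counts
    meanlog <- log(base_vol) - sdlog^2 / 2
    volume <- profile$volume_scale *
      round(rlnorm(length(item_ids), meanlog, sdlog))

    mu <- profile$target_share_by_type[types]
    type_share <- if (is.infinite(phi)) {
      mu
    } else {
      setNames(rbeta(length(types), mu * phi, (1 - mu) * phi), types)
    }

    tibble::tibble(
      thc_id = sprintf("%s-F%d-C%d-T%d", profile$province_id,
                       cell$f, cell$c, cell$t),
      county_id = sprintf("%s-F%d-C%d", profile$province_id, cell$f, cell$c),
      prefecture_id = sprintf("%s-F%d", profile$province_id, cell$f),
      province_id = profile$province_id,
      region = profile$region,
      item_id = item_ids,
      volume = as.numeric(volume),
      vd_share = unname(type_share[item_type]))
  })
  new_survey(dplyr::bind_rows(records), catalog,
             catalog_version = catalog$version)
}

#' Recover generating share targets from a synthetic survey
#'
#' Closes the simulate-estimate loop: runs the aggregation engine on a
#' generated survey and returns the estimated village-doctor share per
#' province x service type alongside the provincial totals, for comparison
#' with the generator's targets.
#'
#' @param survey A survey tibble (typically from [generate_survey()]).
#' @param catalog The companion `ev_catalog`.
#' @return A list: `per_type` (tibble province, service_type, share_pct) and
#'   `totals` (tibble province, y_ev, x_ev, share_pct).
#' @export
recover_parameters <- function(survey, catalog = builtin_catalog()) {
  rep <- aggregate_by_province(survey, catalog)
  per_type <- rep$cells |>
    dplyr::transmute(province = as.character(province_id),
                     service_type = as.character(service_type),
                     share_pct = share_pct)
  list(per_type = per_type,
       totals = rep$rows[, c("province", "y_ev", "x_ev", "share_pct")])
}

#' Expected provincial total shares implied by a generator config
#'
#' Under the generator, a province's expected total share is the EV-weighted
#' mean of its per-type share targets, with type weights equal to the
#' expected EV volume of the type in that province's region. Volume noise is
#' independent of share noise, so recovered provincial totals should
#' fluctuate around these values.
#'
#' @param config An `ev_sim_config`.
#' @param catalog The companion `ev_catalog`.
#' @return Tibble with `province` and expected `share_pct`.
#' @export
expected_province_totals <- function(config, catalog = builtin_catalog()) {
  item_ids <- catalog_item_ids(catalog)
  rows <- lapply(config$profiles, function(profile) {
    it <- catalog$items[catalog$items$region == profile$region, ]
    it <- it[match(item_ids, it$item_id), ]
    w_item <- it$ev * config$base_volume_by_item[item_ids] *
      profile$volume_scale
    w_type <- tapply(w_item, it$service_type, sum)
    tg <- profile$target_share_by_type[names(w_type)]
    tibble::tibble(province = profile$province_id,
                   share_pct = sum(w_type * tg) / sum(w_type) * 100)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.ev_sim_config <- function(x, ...) {
  cat(sprintf(
    "<ev_sim_config: %d x %d x %d x %d frame (%d THCs), CV %.2f, Beta precision %s, seed %d>\n",
    x$n_provinces, x$prefectures_per_province, x$counties_per_prefecture,
    x$thcs_per_county,
    x$n_provinces * x$prefectures_per_province * x$counties_per_prefecture *
      x$thcs_per_county,
    x$volume_dispersion, format(x$share_concentration), x$seed))
  invisible(x)
}
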