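# In-code fixtures shared across the test files.

# a minimal two-type, two-region catalog built from raw minutes
tiny_catalog <- function() {
  items <- tibble::tribble(
    ~item_id, ~service_type, ~item_name, ~unit, ~region, ~minutes,
    "visit",  "Clinic care",  "Standard clinic visit", "per_visit", "north", 15,
    "visit",  "Clinic care",  "Standard clinic visit", "per_visit", "south", 15,
    "record", "Records",      "Create record",         "per_person", "north", 30,
    "record", "Records",      "Create record",         "per_person", "south", 7.5,
    "screen", "Records",      "Screening round",       "per_time",  "north", 60,
    "screen", "Records",      "Screening round",       "per_time",  "south", 90)
  evworkload:::new_ev_catalog(items, version = "tiny")
}

# one THC x item survey row with defaults suitable for hand calculations
survey_row <- function(thc = "T1", item = "visit", volume = 1, share = 0,
                       province = "P1", region = "north") {
  tibble::tibble(thc_id = thc, county_id = paste0(province, "-C"),
                 prefecture_id = paste0(province, "-F"),
                 province_id = province, region = region,
                 item_id = item, volume = volume, vd_share = share)
}

# random small dataset (<= 5 THCs x <= 5 items) for oracle comparisons
random_small_survey <- function(seed, catalog = tiny_catalog()) {
  set.seed(seed)
  n_thc <- sample(1:5, 1)
  items <- unique(catalog$items$item_id)
  provinces <- paste0("P", 1:2)
  rows <- lapply(seq_len(n_thc), function(t) {
    province <- sample(provinces, 1)
    region <- sample(catalog$regions, 1)
    picked <- sample(items, sample(seq_along(items), 1))
    dplyr::bind_rows(lapply(picked, function(i) {
      survey_row(thc = paste0("T", t), item = i,
                 volume = round(runif(1, 0, 500), 2),
                 share = runif(1), province = province, region = region)
    }))
  })
  dplyr::bind_rows(rows)
}

# independent oracle: explicit loops over records and catalog rows, no joins
naive_xy <- function(survey, catalog) {
  x <- 0
  y <- 0
  for (r in seq_len(nrow(survey))) {
    ev <- NA
    for (k in seq_len(nrow(catalog$items))) {
      if (catalog$items$item_id[k] == survey$item_id[r] &&
          catalog$items$region[k] == survey$region[r]) {
        ev <- catalog$items$ev[k]
      }
    }
    y <- y + ev * survey$volume[r]
    x <- x + ev * survey$volume[r] * survey$vd_share[r]
  }
  list(x = x, y = y,
       share = if (y > 0) x / y * 100 else NA_real_)
}

# a small sampling frame (2 x 2 x 1 x 2 = 8 THCs) for fast generator tests
small_config <- function(seed = 1, catalog = builtin_catalog(), ...) {
  cfg <- default_config(seed = seed, catalog = catalog)
  cfg$n_provinces <- 2
  cfg$prefectures_per_province <- 2
  cfg$counties_per_prefecture <- 1
  cfg$thcs_per_county <- 2
  cfg$profiles <- cfg$profiles[c("province_1", "province_5")]
  cfg$n_provinces <- length(cfg$profiles)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}
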