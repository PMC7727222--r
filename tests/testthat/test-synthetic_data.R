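test_that("default config reproduces the study sampling frame and targets", {
  cfg <- default_config(seed = 1)
  n_thc <- cfg$n_provinces * cfg$prefectures_per_province *
    cfg$counties_per_prefecture * cfg$thcs_per_county
  expect_equal(n_thc, 300)
  expect_length(cfg$profiles, 6)
  expect_equal(
    cfg$profiles$province_4$target_share_by_type[
      "Health records management service"],
    c("Health records management service" = 0.78))
  for (pr in cfg$profiles) {
    expect_true(all(pr$target_share_by_type >= 0 &
                      pr$target_share_by_type <= 1))
  }
  expect_identical(vapply(cfg$profiles, `[[`, "", "region"),
                   setNames(c(rep("mid_east", 4), rep("western", 2)),
                            names(cfg$profiles)))
  expect_length(cfg$base_volume_by_item, 38)
  expect_true(all(cfg$base_volume_by_item >= 1))
})

test_that("invalid configs are rejected", {
  cat_ <- builtin_catalog()
  cfg <- small_config()
  bad <- cfg; bad$thcs_per_county <- 0
  expect_error(generate_survey(bad, cat_),
               class = "evworkload_validation_error")
  bad <- cfg; bad$profiles$province_1$target_share_by_type[1] <- 1.5
  expect_error(generate_survey(bad, cat_),
               class = "evworkload_validation_error")
  bad <- cfg; bad$profiles$province_1$region <- "atlantis"
  expect_error(generate_survey(bad, cat_),
               class = "evworkload_validation_error")
  bad <- cfg; bad$volume_dispersion <- -1
  expect_error(generate_survey(bad, cat_),
               class = "evworkload_validation_error")
  bad <- cfg; bad$base_volume_by_item <- bad$base_volume_by_item[-1]
  expect_error(generate_survey(bad, cat_),
               class = "evworkload_validation_error")
})

test_that("generation is seeded, deterministic and leaves the caller RNG alone", {
  cat_ <- builtin_catalog()
  set.seed(123)
  before <- .Random.seed
  a <- generate_survey(small_config(seed = 4), cat_)
  expect_identical(.Random.seed, before)
  b <- generate_survey(small_config(seed = 4), cat_)
  c <- generate_survey(small_config(seed = 5), cat_)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
})

test_that("default frame yields 300 records with 38 item rows each", {
  cat_ <- builtin_catalog()
  survey <- generate_survey(default_config(seed = 1), cat_)
  expect_equal(nrow(survey), 300 * 38)
  per_thc <- table(survey$thc_id)
  expect_length(per_thc, 300)
  expect_true(all(per_thc == 38))
  expect_length(unique(survey$province_id), 6)
  expect_silent(validate_survey(survey, cat_))
  expect_true(all(survey$vd_share >= 0 & survey$vd_share <= 1))
  expect_true(all(survey$volume >= 0))
})

test_that("infinite share concentration collapses shares onto their targets", {
  cat_ <- builtin_catalog()
  cfg <- small_config(seed = 6, share_concentration = Inf)
  survey <- generate_survey(cfg, cat_)
  targets <- do.call(rbind, lapply(cfg$profiles, function(pr) {
    tibble::tibble(province_id = pr$province_id,
                   service_type = names(pr$target_share_by_type),
                   target = unname(pr$target_share_by_type))
  }))
  joined <- dplyr::left_join(
    dplyr::inner_join(tibble::as_tibble(survey),
                      cat_$items[cat_$items$region == "mid_east",
                                 c("item_id", "service_type")],
                      by = "item_id"),
    targets, by = c("province_id", "service_type"))
  expect_equal(joined$vd_share, joined$target, tolerance = 1e-12)

  # recovery is then exact
  rec <- recover_parameters(survey, cat_)
  per <- dplyr::left_join(rec$per_type, targets,
                          by = c("province" = "province_id", "service_type"))
  expect_equal(per$share_pct, per$target * 100, tolerance = 1e-9)
})

test_that("rescaling a province's volumes leaves recovered shares identical", {
  cat_ <- builtin_catalog()
  cfg <- small_config(seed = 8)
  cfg10 <- cfg
  for (p in names(cfg10$profiles)) {
    cfg10$profiles[[p]]$volume_scale <- 10
  }
  rec <- recover_parameters(generate_survey(cfg, cat_), cat_)
  rec10 <- recover_parameters(generate_survey(cfg10, cat_), cat_)
  expect_equal(rec10$per_type$share_pct, rec$per_type$share_pct,
               tolerance = 1e-12)
  expect_equal(rec10$totals$share_pct, rec$totals$share_pct,
               tolerance = 1e-12)
  expect_equal(rec10$totals$y_ev, 10 * rec$totals$y_ev, tolerance = 1e-12)
})

test_that("generated volumes and shares have the configured moments", {
  cat_ <- builtin_catalog()
  cfg <- default_config(seed = 17)
  survey <- generate_survey(cfg, cat_)
  # per-item volume means close to base volumes (CV 0.4 over 300 draws)
  means <- tapply(survey$volume, survey$item_id, mean)
  base <- cfg$base_volume_by_item[names(means)]
  expect_true(all(abs(means - base) / base < 0.15))
  # share spread per province x type around its target, sd ~ sqrt(mu(1-mu)/101)
  survey$service_type <- cat_$items$service_type[
    match(survey$item_id, cat_$items$item_id)]
  one <- survey[survey$province_id == "province_2" &
                  survey$service_type == "Immunizations", ]
  per_thc <- tapply(one$vd_share, one$thc_id, unique)
  expect_true(all(lengths(per_thc) == 1))  # one draw per type per THC
  mu <- cfg$profiles$province_2$target_share_by_type[["Immunizations"]]
  expect_lt(abs(mean(unlist(per_thc)) - mu), 0.03)
  expect_lt(abs(sd(unlist(per_thc)) - sqrt(mu * (1 - mu) / 101)), 0.02)
})

test_that("parameter recovery is unbiased within Monte-Carlo error across seeds", {
  cat_ <- builtin_catalog()
  seeds <- 1:20
  runs <- lapply(seeds, function(s) {
    recover_parameters(generate_survey(default_config(seed = s), cat_), cat_)
  })

  # province x type recovered shares vs generating targets
  per <- dplyr::bind_rows(lapply(runs, `[[`, "per_type"), .id = "run")
  stats <- per |>
    dplyr::group_by(province, service_type) |>
    dplyr::summarise(m = mean(share_pct), se = sd(share_pct) / sqrt(dplyr::n()),
                     .groups = "drop")
  cfg <- default_config(seed = 1)
  stats$target <- 100 * vapply(seq_len(nrow(stats)), function(i) {
    cfg$profiles[[stats$province[i]]]$target_share_by_type[[
      stats$service_type[i]]]
  }, numeric(1))
  z <- (stats$m - stats$target) / stats$se
  # individual cells fluctuate; systematic bias would show in the mean z
  expect_lt(abs(mean(z)), 1)
  expect_lt(max(abs(z)), 5)

  # provincial totals vs the EV-weighted means of the targets
  totals <- dplyr::bind_rows(lapply(runs, `[[`, "totals"))
  expected <- expected_province_totals(cfg, cat_)
  joined <- dplyr::left_join(totals, expected, by = "province",
                             suffix = c("", "_expected"))
  expect_lt(max(abs(joined$share_pct - joined$share_pct_expected)), 2)
})
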