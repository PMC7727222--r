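test_that("Y and X are the A*B and A*B*C sums", {
  cat_ <- tiny_catalog()
  # one record, one item: A = 2 (record/north), B = 100
  s1 <- survey_row(item = "record", volume = 100, share = 0)
  expect_equal(total_ev(s1, cat_), 200)
  # two items: A = 2, B = 10 and A = 0.5 (record/south), B = 40
  s2 <- dplyr::bind_rows(
    survey_row(thc = "T1", item = "record", volume = 10, share = 0.5,
               region = "north"),
    survey_row(thc = "T2", item = "record", volume = 40, share = 0.25,
               province = "P2", region = "south"))
  expect_equal(total_ev(s2, cat_), 40)  # 20 + 20
  expect_equal(vd_ev(s2, cat_), 15)     # 10 + 5
  # all shares zero / all shares one
  expect_equal(vd_ev(s1, cat_), 0)
  s3 <- s2; s3$vd_share <- 1
  expect_equal(vd_ev(s3, cat_), total_ev(s3, cat_))
  # all volumes zero
  s4 <- s2; s4$volume <- 0
  expect_equal(total_ev(s4, cat_), 0)
})

test_that("share is X/Y x 100, undefined at Y = 0, warns when X > Y", {
  expect_equal(round(share_pct(18.50, 42.32), 2), 43.71)
  expect_equal(round(share_pct(4.19, 7.35), 2), 57.01)
  expect_equal(share_pct(7.7, 7.7), 100)
  expect_true(is.na(share_pct(0, 0)))
  expect_warning(share_pct(5, 4), class = "evworkload_inconsistent_input")
  expect_error(share_pct(1, -1), class = "evworkload_invalid_argument")
})

test_that("compliance applies the closed 40% bound", {
  expect_identical(compliance(43.71), "compliant")
  expect_identical(compliance(28.5), "non_compliant")
  expect_identical(compliance(40.0), "compliant")
  expect_identical(compliance(NA_real_), "undefined")
  expect_identical(compliance(c(39.99, 40, NA), threshold = 40),
                   c("non_compliant", "compliant", "undefined"))
  expect_identical(compliance(45, threshold = 50), "non_compliant")
})

test_that("scopes compose conjunctively and reject unknown values", {
  cat_ <- builtin_catalog()
  survey <- generate_survey(small_config(seed = 5), cat_)
  types <- unique(cat_$items$service_type)
  y_all <- total_ev(survey, cat_)
  y_prov <- total_ev(survey, cat_, scope = list(province = "province_1"))
  y_both <- total_ev(survey, cat_,
                     scope = list(province = "province_1",
                                  service_type = types[3]))
  expect_lt(y_both, y_prov)
  expect_lt(y_prov, y_all)
  # conjunctive scope equals manual filtering
  manual <- tibble::as_tibble(survey)
  manual <- manual[manual$province_id == "province_1", ]
  keep <- cat_$items$item_id[cat_$items$service_type == types[3]]
  manual <- manual[manual$item_id %in% keep, ]
  expect_equal(y_both, total_ev(manual, cat_))

  expect_error(total_ev(survey, cat_, scope = list(province = "nowhere")),
               class = "evworkload_invalid_argument")
  expect_error(total_ev(survey, cat_, scope = list(flavour = "x")),
               class = "evworkload_invalid_argument")
})

test_that("by-type aggregation conserves totals and flags empty types undefined", {
  cat_ <- builtin_catalog()
  survey <- generate_survey(small_config(seed = 2), cat_)
  # keep only hypertension items
  htn <- "Health services for patients with hypertension"
  keep <- cat_$items$item_id[cat_$items$service_type == htn]
  only <- tibble::as_tibble(survey)
  only$volume[!only$item_id %in% keep] <- 0
  rep <- aggregate_by_type(only, cat_)
  expect_equal(nrow(rep$rows), 12)
  other <- rep$rows[rep$rows$service_type != htn, ]
  expect_true(all(other$y_ev == 0))
  expect_true(all(is.na(other$share_pct)))
  expect_true(all(other$compliance == "undefined"))
  htn_row <- rep$rows[rep$rows$service_type == htn, ]
  expect_equal(rep$total_row$y_ev, htn_row$y_ev)
  expect_equal(rep$total_row$x_ev, htn_row$x_ev)
  # min/max summary ignores the undefined rows
  expect_equal(rep$summary$min$label, htn)
  expect_equal(rep$summary$max$label, htn)

  # additivity on the full dataset
  rep_full <- aggregate_by_type(survey, cat_)
  expect_equal(rep_full$total_row$y_ev, sum(rep_full$rows$y_ev),
               tolerance = 1e-9)
  expect_equal(rep_full$total_row$x_ev, sum(rep_full$rows$x_ev),
               tolerance = 1e-9)
})

test_that("identical provinces all reproduce the overall share", {
  cat_ <- tiny_catalog()
  one <- dplyr::bind_rows(
    survey_row(item = "visit", volume = 50, share = 0.6),
    survey_row(item = "record", volume = 20, share = 0.3),
    survey_row(item = "screen", volume = 5, share = 0.1))
  clones <- lapply(1:4, function(p) {
    s <- one
    s$province_id <- paste0("P", p)
    s$thc_id <- paste0("T", p)
    s$county_id <- paste0("P", p, "-C")
    s$prefecture_id <- paste0("P", p, "-F")
    s
  })
  survey <- dplyr::bind_rows(clones)
  rep <- aggregate_by_province(survey, cat_)
  overall <- share_pct(vd_ev(survey, cat_), total_ev(survey, cat_))
  expect_equal(rep$rows$share_pct, rep(overall, 4), tolerance = 1e-12)
  expect_equal(rep$summary$min$share_pct, rep$summary$max$share_pct)
})

test_that("engine matches a naive triple loop on random small datasets", {
  cat_ <- tiny_catalog()
  for (seed in 1:20) {
    survey <- random_small_survey(seed, cat_)
    oracle <- naive_xy(survey, cat_)
    expect_equal(total_ev(survey, cat_), oracle$y, tolerance = 1e-12)
    expect_equal(vd_ev(survey, cat_), oracle$x, tolerance = 1e-12)
    got <- suppressWarnings(share_pct(vd_ev(survey, cat_),
                                      total_ev(survey, cat_)))
    expect_equal(got, oracle$share, tolerance = 1e-12)
  }
})

test_that("shares are invariant to rescaling all volumes", {
  cat_ <- tiny_catalog()
  for (seed in 1:10) {
    survey <- random_small_survey(seed, cat_)
    for (k in c(0.5, 3, 1e4)) {
      scaled <- survey
      scaled$volume <- scaled$volume * k
      expect_equal(
        share_pct(vd_ev(scaled, cat_), total_ev(scaled, cat_)),
        share_pct(vd_ev(survey, cat_), total_ev(survey, cat_)),
        tolerance = 1e-9)
    }
  }
})

test_that("province partition conserves X and Y exactly", {
  cat_ <- builtin_catalog()
  survey <- generate_survey(small_config(seed = 9), cat_)
  rep <- aggregate_by_province(survey, cat_)
  expect_equal(sum(rep$rows$y_ev), total_ev(survey, cat_), tolerance = 1e-12)
  expect_equal(sum(rep$rows$x_ev), vd_ev(survey, cat_), tolerance = 1e-12)
  expect_equal(rep$total_row$y_ev, sum(rep$rows$y_ev))
  expect_equal(rep$total_row$x_ev, sum(rep$rows$x_ev))
})

test_that("aggregate shares are weighted means of constituent shares", {
  cat_ <- tiny_catalog()
  for (seed in 21:35) {
    survey <- random_small_survey(seed, cat_)
    total <- share_pct(vd_ev(survey, cat_), total_ev(survey, cat_))
    expect_gte(total, 0)
    expect_lte(total, 100)
    # item-level shares bound every aggregate
    per_item <- vapply(unique(survey$item_id), function(i) {
      sc <- list(item = i)
      share_pct(vd_ev(survey, cat_, sc), total_ev(survey, cat_, sc))
    }, numeric(1))
    per_item <- per_item[!is.na(per_item)]
    if (length(per_item) > 0 && !is.na(total)) {
      expect_gte(total, min(per_item) - 1e-9)
      expect_lte(total, max(per_item) + 1e-9)
    }
  }
})

test_that("workload() bundles X, Y, share and compliance for a scope", {
  cat_ <- tiny_catalog()
  s <- survey_row(item = "record", volume = 100, share = 0.45)
  res <- workload(s, cat_)
  expect_equal(res$y_ev, 200)
  expect_equal(res$x_ev, 90)
  expect_equal(res$share_pct, 45)
  expect_identical(res$compliance, "compliant")
})
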