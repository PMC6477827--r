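daily_tbl <- function(species, dates, totals) {
  tibble::tibble(date = as.Date(dates), species = species, total = totals)
}

test_that("filter selection partitions the record stream", {
  recs <- random_records(100, seed = 3)
  parts <- lapply(0:2, function(f) select_standardized(recs, f))
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(recs))
  both <- select_standardized(recs, c(1, 2))
  expect_equal(nrow(both), nrow(parts[[2]]) + nrow(parts[[3]]))
  expect_equal(nrow(select_standardized(recs, integer())), 0)
})

test_that("annual totals equal a brute-force sum", {
  set.seed(21)
  d <- daily_tbl(sample(c("HB", "Pal"), 50, TRUE),
                 as.Date("2017-08-17") + sample(0:60, 50, TRUE),
                 runif(50, 0, 100))
  ann <- annual_totals(d, 2017)
  for (sp in unique(d$species)) {
    expect_equal(ann$total[ann$species == sp],
                 sum(d$total[d$species == sp]))
  }
  expect_equal(nrow(annual_totals(d, 2016)), 0)
})

test_that("passage quantiles scan the cumulative distribution", {
  one <- daily_tbl("Mon", "2017-09-05", 50)
  expect_equal(passage_quantile(one, "Mon", 0.01), as.Date("2017-09-05"))
  expect_equal(passage_quantile(one, "Mon", 0.99), as.Date("2017-09-05"))
  flat <- daily_tbl("Mon", as.Date("2017-09-01") + 0:9, rep(100, 10))
  expect_equal(passage_quantile(flat, "Mon", 0.01), as.Date("2017-09-01"))
  expect_equal(passage_quantile(flat, "Mon", 0.99), as.Date("2017-09-10"))
  set.seed(7)
  for (k in 1:10) {
    tot <- runif(30, 0, 50)
    d <- daily_tbl("Pal", as.Date("2017-08-20") + 0:29, tot)
    q <- runif(1, 0.01, 0.99)
    # independent cumulative-scan oracle
    oracle <- as.Date("2017-08-20") + (which(cumsum(tot) >= q * sum(tot))[1] - 1)
    expect_equal(passage_quantile(d, "Pal", q), oracle)
  }
  # monotone in q
  d <- daily_tbl("Pal", as.Date("2017-08-20") + 0:29, runif(30))
  qs <- sort(runif(5, 0.01, 0.99))
  dates <- as.Date(vapply(qs, function(q)
    as.character(passage_quantile(d, "Pal", q)), character(1)))
  expect_true(all(diff(dates) >= 0))
  expect_error(passage_quantile(daily_tbl("Pal", "2017-09-01", 0), "Pal", 0.5),
               "no passage")
})

test_that("the season window brackets the rule species quantiles", {
  # Montagu's 1% on Aug 20, Lesser Spotted Eagle 99% on Oct 13
  d <- rbind(
    daily_tbl("Mon", as.Date(c("2017-08-20", "2017-09-05")), c(2, 98)),
    daily_tbl("LesserSE", as.Date(c("2017-09-20", "2017-10-13")), c(98, 2)))
  w <- season_window(d, PROTO)
  expect_equal(w$start, as.Date("2017-08-17"))
  expect_equal(w$end, as.Date("2017-10-16"))
  one_day <- rbind(daily_tbl("Mon", "2017-09-10", 10),
                   daily_tbl("LesserSE", "2017-09-10", 10))
  w <- season_window(one_day, PROTO)
  expect_equal(w$start, as.Date("2017-09-07"))
  expect_equal(w$end, as.Date("2017-09-13"))
  expect_error(season_window(daily_tbl("Mon", "2017-09-10", 10), PROTO),
               "LesserSE")
})

test_that("age proportions come from the right protocol", {
  recs <- count_records(
    id = 1:6, date = "2017-09-10", time = "10:00:00",
    species = c("HB_JUV", "HB_NONJUV", "HB", "Pal", "Pal", "Pal"),
    number = c(20L, 80L, 500L, 3L, 1L, 2L),
    age = c(NA, NA, "juv", "juv", "ad", NA))
  hb <- age_proportions(recs, "HB", hierarchy = HIER)
  expect_equal(hb$fraction[hb$age == "juv"], 0.2)
  expect_equal(hb$fraction[hb$age == "nonjuv"], 0.8)
  pal <- age_proportions(recs, "Pal", hierarchy = HIER)
  expect_equal(pal$fraction[pal$age == "juv"], 0.75)
  expect_equal(sum(pal$fraction), 1)
  none <- age_proportions(recs, "Mar", hierarchy = HIER)
  expect_equal(nrow(none), 0)
})

test_that("age-class totals scale species totals and conserve them", {
  d <- daily_tbl("HB", as.Date(c("2017-09-10", "2017-09-11")), c(100, 60))
  props <- tibble::tibble(date = as.Date("2017-09-10"),
                          age = c("juv", "nonjuv"), n = c(20, 80),
                          fraction = c(0.2, 0.8))
  act <- age_class_totals(d, props, species = "HB")
  d1 <- act[act$date == as.Date("2017-09-10"), ]
  expect_equal(d1$total[d1$age == "juv"], 20)
  expect_equal(d1$total[d1$age == "nonjuv"], 80)
  expect_false(any(d1$fallback))
  # day without a sample uses season-pooled proportions, flagged
  d2 <- act[act$date == as.Date("2017-09-11"), ]
  expect_true(all(d2$fallback))
  expect_equal(d2$total[d2$age == "juv"], 12)
  # conservation per day
  for (dt in unique(act$date)) {
    expect_equal(sum(act$total[act$date == dt]),
                 d$total[d$date == dt])
  }
})

test_that("world-population percentages reproduce the printed arithmetic", {
  expect_equal(unname(world_population_percentage(499493, 280000, 420000)),
               c(119, 178))
  expect_equal(unname(world_population_percentage(3153, 40000, 60000)),
               c(5, 8))
  expect_equal(unname(world_population_percentage(4983, 149000, 188000)),
               c(3, 3))
  expect_equal(unname(world_population_percentage(1000, 1000, 1000)),
               c(100, 100))
  expect_error(world_population_percentage(10, 0, 100), "positive")
})

test_that("early-morning additions reproduce the printed arithmetic", {
  expect_equal(early_morning_addition(8458, 7296), 16)
  expect_equal(early_morning_addition(3262, 2997), 9)
  expect_equal(early_morning_addition(500, 500), 0)
  expect_warning(out <- early_morning_addition(10, 0))
  expect_true(is.na(out))
})
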