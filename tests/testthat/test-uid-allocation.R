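test_that("daily raw totals split species from groups and drop age samples", {
  recs <- count_records(
    id = 1:4, date = "2017-09-10", time = "10:00:00",
    species = c("HB", "HB", "MonPalHen", "HB_JUV"),
    number = c(10L, 5L, 11L, 7L))
  raw <- daily_raw_totals(recs, 1L, HIER)
  expect_equal(raw$species$total[raw$species$code == "HB"], 15)
  expect_equal(raw$groups$total[raw$groups$code == "MonPalHen"], 11)
  expect_false("HB_JUV" %in% c(raw$species$code, raw$groups$code))
})

test_that("one level allocates proportionally to identified totals", {
  res <- allocate_day(as.Date("2017-09-10"), c(HB = 60, StepBuz = 40),
                      c(Buzzard_SPEC = 10), HIER)
  expect_equal(res$totals[["HB"]], 66)
  expect_equal(res$totals[["StepBuz"]], 44)
})

test_that("nested groups iterate on running totals, most specific first", {
  # hand-computed: Buzzard_SPEC=10 over 60/40 -> 66/44; then MediumRaptor=12
  # over running 66/44/10 -> +6.6/+4.4/+1.0
  res <- allocate_day(as.Date("2017-09-10"),
                      c(HB = 60, StepBuz = 40, BlackKite = 10),
                      c(Buzzard_SPEC = 10, MediumRaptor = 12), HIER)
  expect_equal(res$totals[["HB"]], 72.6)
  expect_equal(res$totals[["StepBuz"]], 48.4)
  expect_equal(res$totals[["BlackKite"]], 11.0)
  expect_length(res$unallocated, 0)
  # independent single-pass-per-level oracle, computed explicitly
  t_hb <- 60; t_sb <- 40; t_bk <- 10
  share <- 10 * t_hb / (t_hb + t_sb); t_hb <- t_hb + share
  t_sb <- t_sb + 10 * 40 / 100
  pool2 <- t_hb + t_sb + t_bk
  oracle <- c(t_hb + 12 * t_hb / pool2, t_sb + 12 * t_sb / pool2,
              t_bk + 12 * t_bk / pool2)
  expect_equal(unname(res$totals[c("HB", "StepBuz", "BlackKite")]), oracle)
})

test_that("a pool with one identified species takes the whole group", {
  res <- allocate_day(as.Date("2017-09-10"), c(Pal = 4), c(MonPalHen = 10),
                      HIER)
  expect_equal(res$totals[["Pal"]], 14)
  expect_equal(res$totals[["Mon"]], 0)
  expect_equal(res$totals[["Hen"]], 0)
})

test_that("empty pools fall back to season proportions, then report", {
  res <- allocate_day(as.Date("2017-09-10"), c(), c(MonPalHen = 10), HIER,
                      fallback = "season_proportions",
                      season_pool_totals = c(Mon = 30, Pal = 10))
  expect_equal(res$totals[["Mon"]], 7.5)
  expect_equal(res$totals[["Pal"]], 2.5)
  res <- allocate_day(as.Date("2017-09-10"), c(), c(MonPalHen = 10), HIER,
                      fallback = "skip")
  expect_equal(res$unallocated[["MonPalHen"]], 10)
  res <- allocate_day(as.Date("2017-09-10"), c(), c(MonPalHen = 9), HIER,
                      fallback = "equal_split")
  expect_equal(res$totals[["Mon"]], 3)
})

test_that("allocation conserves individuals and is monotone", {
  set.seed(11)
  for (k in 1:20) {
    sp <- c(HB = sample(0:100, 1), StepBuz = sample(0:100, 1),
            BlackKite = sample(1:100, 1), Pal = sample(1:20, 1),
            Mar = sample(0:20, 1), LesserSE = sample(0:30, 1))
    gr <- c(Buzzard_SPEC = sample(0:50, 1), MediumRaptor = sample(0:50, 1),
            MonPalHen = sample(0:30, 1), Harrier_SPEC = sample(0:10, 1),
            Raptor_SPEC = sample(0:20, 1), LargeEAGLE = sample(0:10, 1))
    res <- allocate_day(as.Date("2017-09-10"), sp, gr, HIER,
                        fallback = "equal_split")
    expect_equal(sum(res$totals), sum(sp) + sum(gr), tolerance = 1e-10)
    expect_true(all(res$totals[names(sp)] >= sp - 1e-10))
    # raising a group count never lowers its pool species' allocations
    # (species outside the pool can lose shares of higher groups, since the
    # pool species now dominate those running totals)
    gr2 <- gr; gr2[["MediumRaptor"]] <- gr[["MediumRaptor"]] + 25
    res2 <- allocate_day(as.Date("2017-09-10"), sp, gr2, HIER,
                         fallback = "equal_split")
    pool <- HIER$pools$MediumRaptor
    expect_true(all(res2$totals[pool] >= res$totals[pool] - 1e-10))
    expect_equal(sum(res2$totals), sum(res$totals) + 25, tolerance = 1e-10)
  }
})

test_that("the allocation pool widens at each level up the buzzard chain", {
  sp <- c(HB = 80, StepBuz = 20, BlackKite = 50)
  one <- function(groups) {
    allocate_day(as.Date("2017-09-10"), sp, groups, HIER)$totals
  }
  # Buzzard_SPEC excludes kites; MediumRaptor includes them
  buz <- one(c(Buzzard_SPEC = 10))
  expect_equal(buz[["BlackKite"]], 50)
  med <- one(c(MediumRaptor = 10))
  expect_gt(med[["BlackKite"]], 50)
  expect_lt(med[["HB"]] - 80, buz[["HB"]] - 80)
})

test_that("daily species totals compose allocate_day over dates", {
  recs <- count_records(
    id = 1:5, date = c("2017-09-10", "2017-09-10", "2017-09-10",
                       "2017-09-11", "2017-09-11"),
    time = "10:00:00",
    species = c("HB", "StepBuz", "Buzzard_SPEC", "HB", "HB"),
    number = c(60L, 40L, 10L, 7L, 3L))
  daily <- estimate_daily_species_totals(recs, PROTO, HIER)
  d1 <- daily[daily$date == as.Date("2017-09-10"), ]
  expect_equal(d1$allocated[d1$species == "HB"], 66)
  expect_equal(d1$raw[d1$species == "HB"], 60)
  d2 <- daily[daily$date == as.Date("2017-09-11"), ]
  expect_equal(d2$allocated[d2$species == "HB"], 10)
  # no group records -> allocated equals raw
  expect_equal(d2$raw, d2$allocated)
  expect_true(all(daily$allocated >= daily$raw - 1e-10))
})

test_that("season-proportion fallback uses identified totals from other days", {
  recs <- count_records(
    id = 1:3, date = c("2017-09-10", "2017-09-10", "2017-09-11"),
    time = "10:00:00",
    species = c("Mon", "Pal", "MonPalHen"),
    number = c(30L, 10L, 8L))
  daily <- estimate_daily_species_totals(recs, PROTO, HIER)
  d2 <- daily[daily$date == as.Date("2017-09-11"), ]
  expect_equal(d2$allocated[d2$species == "Mon"], 6)
  expect_equal(d2$allocated[d2$species == "Pal"], 2)
  expect_equal(nrow(attr(daily, "unallocated")), 0)
})
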