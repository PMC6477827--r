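two_station_pair <- function(t2 = "10:04:00", z1 = "E2", z2 = "W2",
                             sp2 = "MonPalHen", n2 = 11L,
                             remark1 = "", remark2 = "") {
  count_records(id = 1:2, date = "2015-09-01",
                time = c("10:00:00", t2),
                species = c("Pal", sp2), number = c(3L, n2),
                station = c(1L, 2L), location = c(z1, z2),
                age = c("juv", NA), remark = c(remark1, remark2))
}

test_that("detail rank prefers species level, then attribute count", {
  r <- count_records(id = 1:6, date = "2017-09-10", time = "10:00:00",
                     species = c("Pal", "MonPalHen", "HB", "Buzzard_SPEC",
                                 "Mar", "Mar"),
                     number = 1L,
                     age = c("juv", NA, NA, "juv", "ad", NA),
                     sex = c(NA, NA, NA, NA, "f", "m"))
  expect_identical(detail_rank(r, HIER), c(5L, 0L, 4L, 1L, 6L, 5L))
})

test_that("candidate pairs respect window, overlap zones and flags", {
  p <- two_station_pair()
  expect_true(is_candidate_pair(p[1, ], p[2, ], PROTO, HIER))
  expect_false(is_candidate_pair(p[1, ], two_station_pair(t2 = "10:25:00")[2, ],
                                 PROTO, HIER))
  expect_false(is_candidate_pair(two_station_pair(z1 = "W3")[1, ], p[2, ],
                                 PROTO, HIER))
  expect_false(is_candidate_pair(p[1, ],
                                 two_station_pair(sp2 = "Mon")[2, ],
                                 PROTO, HIER))
  sc <- two_station_pair(remark2 = "single count")
  expect_false(is_candidate_pair(sc[1, ], sc[2, ], PROTO, HIER))
  same <- p; same$station <- c(1L, 1L)
  expect_false(is_candidate_pair(same[1, ], same[2, ], PROTO, HIER))
  noloc <- p; noloc$location[1] <- NA
  expect_warning(ok <- is_candidate_pair(noloc[1, ], noloc[2, ], PROTO, HIER))
  expect_false(ok)
})

test_that("the two-station worked example subtracts three from station 2", {
  res <- remove_double_counts(two_station_pair(), PROTO, HIER)
  s2 <- res$records[res$records$station == 2, ]
  expect_identical(s2$number, 8L)
  expect_identical(s2$dcremark, "1:-3")
  s1 <- res$records[res$records$station == 1, ]
  expect_identical(s1$number, 3L)
  expect_identical(s1$dcremark, "2:+3")
  expect_equal(res$report$n_individuals_removed, 3)
})

test_that("an exactly matched lower-ranked record is dropped", {
  p <- two_station_pair(n2 = 3L)
  res <- remove_double_counts(p, PROTO, HIER)
  expect_equal(nrow(res$records), 1)
  expect_identical(res$records$species, "Pal")
})

test_that("greedy matching picks the smallest time gap first", {
  r <- count_records(id = 1:3, date = "2017-09-10",
                     time = c("10:00:00", "10:07:00", "10:03:00"),
                     species = c("Pal", "MonPalHen", "MonPalHen"),
                     number = c(2L, 5L, 5L),
                     station = c(1L, 2L, 2L), location = c("E2", "W2", "W2"),
                     age = c("juv", NA, NA))
  m <- match_records(r, PROTO, HIER)
  expect_equal(nrow(m), 1)
  expect_identical(m$b_id, 3L)  # 3-minute gap beats 7
  expect_identical(m$quantity, 2L)
})

test_that("observer-flagged double counts are matched with priority", {
  r <- count_records(id = 1:3, date = "2017-09-10",
                     time = c("10:00:00", "10:02:00", "10:06:00"),
                     species = "Pal", number = c(4L, 4L, 4L),
                     station = c(1L, 2L, 2L), location = c("E2", "W2", "W2"),
                     age = "juv",
                     remark = c("", "", "double count"))
  m <- match_records(r, PROTO, HIER)
  # the flagged pair (gap 6) wins over the closer unflagged one (gap 2)
  expect_identical(m$b_id[1], 3L)
  expect_true(m$flagged[1])
})

test_that("removal never increases totals and is idempotent", {
  for (seed in 1:5) {
    recs <- random_match_instance(30, seed)
    res <- remove_double_counts(recs, PROTO, HIER)
    expect_lte(sum(res$records$number), sum(recs$number))
    per_in <- tapply(recs$number, recs$species, sum)
    per_out <- tapply(res$records$number, res$records$species, sum)
    for (sp in names(per_out)) expect_lte(per_out[[sp]], per_in[[sp]])
    # every reduction mirrored by a +q / -q dcremark pair
    adj <- res$report$adjustments
    for (k in seq_len(nrow(adj))) {
      kept <- res$records[res$records$id == adj$kept_id[k], ]
      expect_match(kept$dcremark,
                   paste0(adj$reduced_id[k], ":\\+", adj$quantity[k]))
    }
    expect_equal(sum(adj$quantity), res$report$n_individuals_removed)
    # second pass removes nothing (adjusted records carry dcremark links)
    res2 <- remove_double_counts(res$records, PROTO, HIER)
    expect_equal(res2$report$n_individuals_removed, 0)
    expect_identical(as.data.frame(res2$records),
                     as.data.frame(res$records))
  }
})

test_that("greedy removal matches the max-flow oracle on small instances", {
  n_cases <- 120
  equal <- logical(n_cases)
  for (seed in seq_len(n_cases)) {
    recs <- random_match_instance(sample(4:8, 1), seed = 1000 + seed)
    greedy <- remove_double_counts(recs, PROTO, HIER)
    g <- greedy$report$n_individuals_removed
    opt <- suppressWarnings(oracle_max_removal(recs, PROTO, HIER))
    expect_lte(g, opt)  # greedy can never remove more than the optimum
    equal[seed] <- g == opt
  }
  # the procedure is conservative by design; near-optimality is expected
  expect_gte(mean(equal), 0.95)
})
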