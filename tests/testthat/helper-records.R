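# shared fixtures: randomized valid record tables and an independent
# maximum-flow matching oracle for the double-count greedy procedure

HIER <- default_hierarchy()
PROTO <- default_protocol()

random_records <- function(n, seed = 1, species = NULL, one_day = FALSE) {
  set.seed(seed)
  codes <- if (!is.null(species)) species else
    c("HB", "StepBuz", "Pal", "Mon", "Mar", "LesserSE",
                          "BootedE", "MonPalHen", "Buzzard_SPEC",
                          "Harrier_SPEC", "LargeEAGLE", "Raptor_SPEC",
                          "WhiStork", "HB_JUV", "HB_NONJUV")
  dates <- if (one_day) as.Date("2017-09-10") else
    as.Date("2017-08-17") + sample(0:60, n, replace = TRUE)
  number <- sample(1:30, n, replace = TRUE)
  opt <- function(values, p_na = 0.5) {
    x <- sample(values, n, replace = TRUE)
    x[stats::runif(n) < p_na] <- NA_character_
    x
  }
  count_records(
    id = seq_len(n),
    date = dates,
    time = sprintf("%02d:%02d:%02d", sample(7:16, n, TRUE),
                   sample(0:59, n, TRUE), sample(0:59, n, TRUE)),
    species = sample(codes, n, replace = TRUE),
    number = number,
    north = sapply(number, function(k) sample(0:min(k, 3), 1)),
    station = sample(1:2, n, replace = TRUE),
    location = opt(raptorcount:::ZONE_LEVELS, 0.2),
    age = opt(c("ad", "imm", "nonjuv", "juv"), 0.6),
    sex = opt(c("f", "fc", "m"), 0.8),
    morph = opt(c("dark", "light"), 0.9),
    health = opt(c("kil", "inj"), 0.97),
    remark = sample(c("", "", "", "high stream"), n, replace = TRUE),
    filter = sample(0:2, n, replace = TRUE, prob = c(0.1, 0.8, 0.1))
  )
}

# dense two-station instances for matching tests: one day, overlap zones,
# close times
random_match_instance <- function(n, seed) {
  set.seed(seed)
  station <- sample(1:2, n, replace = TRUE)
  zones <- ifelse(station == 1,
                  sample(c("E1", "E2", "E3"), n, replace = TRUE),
                  sample(c("O", "W1", "W2", "W3"), n, replace = TRUE))
  count_records(
    id = seq_len(n),
    date = as.Date("2017-09-10"),
    time = minutes_time(600 + sample(0:40, n, replace = TRUE)),
    species = sample(c("Pal", "Mon", "MonPalHen", "Harrier_SPEC",
                       "HB", "Buzzard_SPEC"), n, replace = TRUE),
    number = sample(1:5, n, replace = TRUE),
    station = station,
    location = zones,
    age = ifelse(stats::runif(n) < 0.5, "juv", NA_character_)
  )
}

minutes_time <- function(min) sprintf("%02d:%02d:00", min %/% 60, min %% 60)

# independent oracle: maximum removable quantity is a max flow from
# station-1 records (capacity = number) to station-2 records through the
# candidate-pair edges. Ford-Fulkerson with BFS; instances are tiny.
oracle_max_removal <- function(records, config = PROTO, hierarchy = HIER) {
  a <- records[records$station == 1, ]
  b <- records[records$station == 2, ]
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(0L)
  edge <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      edge[i, j] <- suppressWarnings(
        is_candidate_pair(a[i, ], b[j, ], config, hierarchy))
    }
  }
  # nodes: 1 = source, 2..(na+1) = a, (na+2)..(na+nb+1) = b, last = sink
  nn <- na + nb + 2
  cap <- matrix(0, nn, nn)
  cap[1, 1 + seq_len(na)] <- a$number
  cap[1 + na + seq_len(nb), nn] <- b$number
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (edge[i, j]) cap[1 + i, 1 + na + j] <- sum(a$number) + sum(b$number)
  }
  flow <- 0
  repeat {
    # BFS for augmenting path in residual graph
    prev <- rep(NA_integer_, nn)
    prev[1] <- 0
    queue <- 1
    while (length(queue) && is.na(prev[nn])) {
      u <- queue[1]; queue <- queue[-1]
      nxt <- which(cap[u, ] > 0 & is.na(prev))
      prev[nxt] <- u
      queue <- c(queue, nxt)
    }
    if (is.na(prev[nn])) break
    # trace path, find bottleneck
    path <- nn
    while (path[1] != 1) path <- c(prev[path[1]], path)
    bn <- min(cap[cbind(path[-length(path)], path[-1])])
    for (k in seq_len(length(path) - 1)) {
      cap[path[k], path[k + 1]] <- cap[path[k], path[k + 1]] - bn
      cap[path[k + 1], path[k]] <- cap[path[k + 1], path[k]] + bn
    }
    flow <- flow + bn
  }
  flow
}
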