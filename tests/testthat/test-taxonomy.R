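test_that("ancestor chains walk the hierarchy bottom-up", {
  expect_equal(ancestors("HB", HIER),
               c("Pernis_SPEC", "Buzzard_SPEC", "MediumRaptor",
                 "Raptor_SPEC"))
  expect_equal(ancestors("Pal", HIER),
               c("MonPalHen", "Harrier_SPEC", "Raptor_SPEC"))
  expect_equal(ancestors("Raptor_SPEC", HIER), character(0))
  # chain property: each element is the parent of the previous one
  for (s in HIER$species) {
    chain <- c(s, ancestors(s, HIER))
    for (k in seq_len(length(chain) - 1)) {
      expect_identical(unname(HIER$parent[[chain[k]]]), chain[k + 1])
    }
  }
})

test_that("age-protocol codes resolve to their parent species", {
  expect_identical(base_code("HB_JUV", HIER), "HB")
  expect_identical(base_code("SB_NONJUV", HIER), "StepBuz")
  expect_identical(base_code(c("BK_JUV", "Pal"), HIER), c("BlackKite", "Pal"))
  expect_equal(ancestors("HB_JUV", HIER), ancestors("HB", HIER))
})

test_that("taxon compatibility is the ancestor relation, symmetric and reflexive", {
  expect_true(taxon_compatible("Pal", "MonPalHen", HIER))
  expect_false(taxon_compatible("Pal", "Mon", HIER))
  expect_false(taxon_compatible("HB", "LargeEAGLE", HIER))
  codes <- c(HIER$species, HIER$groups)
  set.seed(42)
  for (k in 1:200) {
    a <- sample(codes, 1); b <- sample(codes, 1)
    expect_identical(taxon_compatible(a, b, HIER),
                     taxon_compatible(b, a, HIER))
  }
  for (a in sample(codes, 20)) expect_true(taxon_compatible(a, a, HIER))
})

test_that("pools match the recording protocol", {
  expect_setequal(HIER$pools$MonPalHen, c("Mon", "Pal", "Hen"))
  expect_true(all(c("HB", "StepBuz") %in% HIER$pools$Buzzard_SPEC))
  expect_true(all(c("BlackKite", "HB") %in% HIER$pools$MediumRaptor))
  needed <- c("Pernis_SPEC", "Buzzard_SPEC", "LargeEAGLE", "MonPalHen",
              "Harrier_SPEC", "SparrowH_SPEC", "SPH_Goshawk", "LargeFALCON",
              "Hobby_RedFF", "Kestrel_SPEC", "Falcon_SPEC", "MediumRaptor",
              "Raptor_SPEC", "Stork_SPEC")
  expect_true(all(needed %in% HIER$groups))
  for (g in HIER$groups) {
    expect_gt(length(HIER$pools[[g]]), 0)
    expect_true(all(HIER$pools[[g]] %in% HIER$species))
  }
  for (s in HIER$pools$Raptor_SPEC) {
    expect_true("Raptor_SPEC" %in% ancestors(s, HIER))
  }
})

test_that("code resolution is case-sensitive and rejects unknowns", {
  expect_identical(resolve_code("Pal", HIER), "Pal")
  expect_identical(resolve_code("MonPalHen", HIER), "MonPalHen")
  expect_error(resolve_code("XYZ", HIER), "XYZ")
  expect_error(resolve_code("pal", HIER), "pal")
})

test_that("protocol configuration keeps its ordering invariants", {
  expect_lte(PROTO$window_minutes[["small"]], PROTO$window_minutes[["large"]])
  small <- PROTO$overlap_zones$small
  large <- PROTO$overlap_zones$large
  expect_true(all(paste(small$s1, small$s2) %in% paste(large$s1, large$s2)))
  expect_identical(size_class(c("Pal", "Hobby", "HB", "LesserSE"), PROTO),
                   c("small", "small", "large", "large"))
  expect_error(default_protocol(window_minutes = c(small = 20, large = 15)))
})

test_that("taxonomy and protocol load from a YAML config", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "taxonomy:",
    "  pools:",
    "    Stork_SPEC: [WhiStork, BlaStork]",
    "    MonPalHen: [Mon, Pal, Hen]",
    "protocol:",
    "  window_minutes: {small: 5, large: 12}"
  ), path)
  h <- load_hierarchy(path)
  expect_setequal(h$pools$MonPalHen, c("Mon", "Pal", "Hen"))
  p <- load_protocol(path)
  expect_equal(unname(p$window_minutes[c("small", "large")]), c(5, 12))
  # untouched fields keep defaults
  expect_identical(p$empty_pool_fallback, "season_proportions")
})
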