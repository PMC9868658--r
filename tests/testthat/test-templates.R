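test_that("template catalogs read with chain suffix and NA resolution", {
  path <- withr::local_tempfile(lines = c(
    "template_id\tchain\tresolution\tsequence",
    "1ABC\tA\t2.1\tADRR",
    "2DEF\tB\tNA\tRRVLT",
    "3GHI_C\tC\t3.0\tVLTY"
  ))
  cat <- read_template_catalog(path)
  expect_equal(cat$template_id, c("1ABC_A", "2DEF_B", "3GHI_C"))
  expect_true(is.na(cat$resolution[2]))
})

test_that("identity and resolution thresholds are inclusive boundaries", {
  target <- "ADRRVLTYADRRVLTYADRR"
  catalog <- tibble::tibble(
    template_id = c("low_id", "hi_res", "at_res", "good"),
    chain = "",
    resolution = c(2.0, 5.0, 4.5, 2.0),
    # low_id aligns with 1/4 identity via a crafted near-miss? simpler:
    # give it an unrelated sequence with a short positive alignment
    sequence = c("ADWWWWWW", "ADRRVLTY", "ADRRVLTY", "RRVLT")
  )
  aligned <- align_templates(catalog, target)
  kept <- filter_templates(aligned, identity_min = 25, resolution_max = 4.5)
  expect_false("hi_res" %in% kept$template_id)       # 5.0 A excluded
  expect_true("at_res" %in% kept$template_id)        # exactly 4.5 A included
  # identity exactly at the threshold is included
  kept_lo <- filter_templates(aligned, identity_min = 100)
  expect_true(all(kept_lo$identity_pct >= 100))
})

test_that("identity below threshold excludes a template", {
  aligned <- align_templates(
    tibble::tibble(template_id = "t", chain = "", resolution = 2.0,
                   sequence = "KNDE"),
    "ADRRVLTY"
  )
  # force the recomputed identity below 25% by raising the bar instead:
  # the catalog row survives at its own identity but not above it
  expect_equal(nrow(filter_templates(aligned, identity_min = aligned$identity_pct + 1)), 0)
  expect_equal(nrow(filter_templates(aligned, identity_min = aligned$identity_pct)), 1)
})

test_that("survivors rank by resolution then identity, NA resolution last", {
  target <- "ADRRVLTY"
  catalog <- tibble::tibble(
    template_id = c("nmr", "xray_hi", "xray_lo"),
    chain = "",
    resolution = c(NA, 1.5, 3.5),
    sequence = c("ADRRVLTY", "RRVLT", "ADRRVLTY")
  )
  kept <- filter_templates(align_templates(catalog, target))
  expect_equal(kept$template_id, c("xray_hi", "xray_lo", "nmr"))
})

test_that("the worked-example greedy cover picks templates A and C", {
  covs <- we_coverages()
  cov1 <- covs[["P00001"]]
  expect_setequal(cov1$selected$template_id, c("A", "C"))
  expect_equal(cov1$covered_aa, 7)
  expect_equal(cov1$covered_positions, 1:7)
  cov2 <- covs[["P00001-2"]]
  expect_equal(cov2$covered_aa, 6)
  expect_equal(cov2$covered_positions, c(1:3, 5:7))
})

test_that("degenerate covers behave: single full template, empty input", {
  full <- fake_alignment("only", 1:10)
  cov <- select_template_set(10, list(full, fake_alignment("part", 3:5)))
  expect_equal(cov$selected$template_id, "only")
  expect_equal(cov$covered_aa, 10)
  empty <- select_template_set(10, list())
  expect_equal(empty$covered_aa, 0)
  expect_equal(nrow(empty$selected), 0)
})

test_that("alphabetical order breaks exact ties", {
  cov <- select_template_set(8, list(
    fake_alignment("B", 1:2), fake_alignment("A", 1:2),
    fake_alignment("C", 3:7)
  ))
  expect_equal(cov$selected$template_id, c("C", "A"))
})

test_that("greedy cover is deterministic under catalog permutation", {
  set.seed(21)
  for (i in 1:20) {
    sets <- random_cover_instance(6, 25)
    als <- purrr::imap(sets, ~ fake_alignment(paste0("T", .y), .x))
    base <- select_template_set(25, als)
    perm <- select_template_set(25, sample(als))
    expect_identical(base, perm)
  }
})

test_that("coverage is monotone in the catalog and under filtering", {
  set.seed(22)
  for (i in 1:20) {
    sets <- random_cover_instance(5, 30)
    als <- purrr::imap(sets, ~ fake_alignment(paste0("T", .y), .x))
    cov_all <- select_template_set(30, als)
    cov_less <- select_template_set(30, als[-1])
    expect_gte(cov_all$covered_aa, cov_less$covered_aa)
    expect_lte(cov_all$covered_aa, 30)
    expect_true(all(cov_all$selected$n_new >= 1))
  }
})

test_that("greedy coverage equals the exhaustive-enumeration maximum", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    sets <- random_cover_instance(n, sample(10:30, 1))
    als <- purrr::imap(sets, ~ fake_alignment(paste0("T", .y), .x))
    cov <- select_template_set(30, als)
    best <- oracle_best_cover(sets)
    expect_equal(cov$covered_aa, best$coverage)
    expect_gte(nrow(cov$selected), best$size)
  }
})

test_that("positions collapse into maximal closed intervals", {
  iv <- positions_to_intervals(c(1, 2, 3, 5, 7, 8))
  expect_equal(iv$start, c(1, 5, 7))
  expect_equal(iv$end, c(3, 5, 8))
  expect_equal(nrow(positions_to_intervals(integer(0))), 0)
  # adjacency merges into one run
  expect_equal(nrow(positions_to_intervals(c(4, 5, 6))), 1)
})
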