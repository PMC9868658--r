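test_that("mutation tokens parse in both notations", {
  m <- parse_mutation_tokens(c("T2A", "Thr2Ala", "ARG3ALA"))
  expect_equal(m$wt, c("T", "T", "R"))
  expect_equal(m$position, c(2L, 2L, 3L))
  expect_equal(m$mut, c("A", "A", "A"))
  expect_equal(m$token, c("T2A", "T2A", "R3A"))
})

test_that("bad tokens become parse errors with the token echoed", {
  m <- parse_mutation_tokens(c("B5Q", "T0A", "T-1A", "notatoken", "R3A"))
  expect_equal(m$token, "R3A")
  probs <- parse_problems(m)
  expect_equal(nrow(probs), 4)
  expect_match(probs$problem[probs$header == "B5Q"], "unrecognized wild-type")
  expect_match(probs$problem[probs$header == "T0A"], "non-positive position")
})

test_that("silent tokens are kept with a warning and flagged", {
  expect_warning(m <- parse_mutation_tokens(c("A1A", "R3A")), "silent")
  expect_equal(m$silent, c(TRUE, FALSE))
})

test_that("one-letter and three-letter renderings parse identically", {
  three <- Biostrings::AMINO_ACID_CODE
  set.seed(42)
  std <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:50) {
    wt <- sample(std, 1); mut <- sample(setdiff(std, wt), 1)
    pos <- sample.int(500, 1)
    one <- suppressWarnings(parse_mutation_tokens(paste0(wt, pos, mut)))
    thr <- suppressWarnings(parse_mutation_tokens(
      paste0(three[[wt]], pos, three[[mut]])
    ))
    expect_equal(one[c("token", "wt", "position", "mut")],
                 thr[c("token", "wt", "position", "mut")])
  }
})

test_that("mapping follows the wild-type letter check per isoform", {
  iso <- we_isoforms()
  m <- parse_mutation_tokens(c("T2A", "R3A", "R4L", "R9L"))
  mp <- build_mutation_mapping(m, iso)
  per <- mp$per_isoform
  get <- function(acc, tok) per[per$accession == acc & per$token == tok, ]
  expect_false(get("P00001", "T2A")$mapped)       # position 2 is D
  expect_true(get("P00001", "R3A")$mapped)
  expect_true(get("P00001", "R4L")$mapped)
  expect_false(get("P00001-2", "R4L")$mapped)     # position 4 is K
  expect_equal(get("P00001-2", "R4L")$reason, "wt_mismatch")
  expect_false(get("P00001", "R9L")$mapped)       # beyond length
  expect_equal(get("P00001", "R9L")$reason, "out_of_range")
})

test_that("worked-example gene-level sets split as published", {
  mp <- build_mutation_mapping(we_mutations(), we_isoforms())
  expect_setequal(mp$found_anywhere$token, c("R3A", "R4L"))
  expect_equal(mp$found_nowhere$token, "T2A")
  expect_equal(sum(mp$per_isoform$mapped[mp$per_isoform$accession == "P00001"]), 2)
  expect_equal(sum(mp$per_isoform$mapped[mp$per_isoform$accession == "P00001-2"]), 1)
})

test_that("duplicates collapse and empty lists stay valid", {
  iso <- we_isoforms()
  mp <- build_mutation_mapping(parse_mutation_tokens(c("R3A", "R3A")), iso)
  expect_equal(nrow(mp$found_anywhere), 1)
  expect_equal(nrow(mp$per_isoform), 2)  # one per isoform

  none <- build_mutation_mapping(parse_mutation_tokens(character(0)), iso)
  expect_equal(nrow(none$found_anywhere), 0)
  expect_equal(nrow(none$found_nowhere), 0)

  nohit <- build_mutation_mapping(parse_mutation_tokens("W7A"), iso)
  expect_equal(nrow(nohit$found_anywhere), 0)
})

test_that("mapping is a pure function: permutations permute outputs", {
  iso <- we_isoforms()
  set.seed(7)
  toks <- c("T2A", "R3A", "R4L", "V5I", "L6M", "Y8F")
  base <- build_mutation_mapping(parse_mutation_tokens(toks), iso)
  for (i in 1:10) {
    perm <- sample(toks)
    mp <- build_mutation_mapping(parse_mutation_tokens(perm), iso)
    expect_setequal(mp$found_anywhere$token, base$found_anywhere$token)
    a <- dplyr::arrange(mp$per_isoform, accession, token)
    b <- dplyr::arrange(base$per_isoform, accession, token)
    expect_equal(a, b)
    expect_lte(nrow(mp$found_anywhere), length(unique(perm)))
  }
})

test_that("mutation files tolerate spaces, tabs and gene sections", {
  path <- withr::local_tempfile(lines = c(
    "TST1",
    "T2A\tR3A   R4L",
    "",
    "OTH1",
    "Gly1Ala"
  ))
  tbl <- read_mutation_file(path)
  expect_equal(tbl$gene_name, c("TST1", "TST1", "TST1", "OTH1"))
  expect_equal(tbl$raw_token, c("T2A", "R3A", "R4L", "Gly1Ala"))
})
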