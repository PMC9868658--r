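we_config <- function() {
  structure(
    list(w1 = 10, w2 = 10, identity_min = 25, resolution_max = 4.5,
         count_mode = "covered", max_interior_gap = 20),
    class = "run_config"
  )
}

test_that("variant sequences substitute exactly one residue", {
  expect_equal(build_variant_sequence("ADRRVLTY", "R", 3, "A"), "ADARVLTY")
  expect_equal(build_variant_sequence("ADRRVLTY", "R", 4, "L"), "ADRLVLTY")
  expect_error(build_variant_sequence("ADRRVLTY", "T", 2, "A"),
               "wild-type mismatch")
})

test_that("report.log carries scores, mappings and the selected isoform", {
  path <- withr::local_tempfile()
  write_report_log(we_reports(), we_config(), path)
  log <- readLines(path)
  expect_true(any(grepl("identity_threshold=25 resolution_threshold=4.5",
                        log)))
  expect_true(any(grepl("w1=10 w2=10", log)))
  expect_true(any(grepl("selected isoform: P00001$", log)))
  winner_line <- grep("^    P00001 \\[canonical\\]", log, value = TRUE)
  expect_match(winner_line, "covered_aa=7")
  expect_match(winner_line, "structural_function=0.875")
  expect_match(winner_line, "mutation_function=1")
  expect_match(winner_line, "selection=18.75")
  expect_true(any(grepl("R3A -> P00001 \\(pos 3\\), P00001-2 \\(pos 3\\)", log)))
  expect_true(any(grepl("not associated with any isoform: T2A", log)))
})

test_that("failed genes and empty mutation lists still report", {
  reports <- c(we_reports(),
               list(list(gene_name = "NOPE", failure = "gene not found: NOPE")))
  path <- withr::local_tempfile()
  write_report_log(reports, we_config(), path)
  log <- readLines(path)
  expect_true(any(grepl("gene NOPE", log)))
  expect_true(any(grepl("gene not found: NOPE", log)))

  # no mutations: mapping sections empty but selection still reported
  iso <- we_isoforms()
  mapping <- build_mutation_mapping(parse_mutation_tokens(character(0)), iso)
  scores <- score_isoforms(iso, we_coverages(), mapping)
  rep2 <- list(list(
    gene_name = "TST1", failure = NULL, isoforms = iso,
    mutations = parse_mutation_tokens(character(0)), mapping = mapping,
    coverages = we_coverages(), scores = scores
  ))
  write_report_log(rep2, we_config(), path)
  log2 <- readLines(path)
  expect_true(any(grepl("mapped mutations:", log2)))
  expect_true(any(grepl("selected isoform: P00001", log2)))
})

test_that("report.csv traces every (gene, mutation, isoform) triple", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- write_report_csv(we_reports(), path)
  expect_equal(nrow(rows), 6)  # 3 mutations x 2 isoforms
  expect_equal(names(rows),
               c("gene", "mutation_token", "isoform_accession", "mapped",
                 "position_matched", "inside_coverage"))
  t2a <- rows[rows$mutation_token == "T2A", ]
  expect_true(all(!t2a$mapped))
  r3a <- rows[rows$mutation_token == "R3A", ]
  expect_true(all(r3a$mapped))
  expect_true(all(r3a$inside_coverage))
  reread <- utils::read.csv(path)
  expect_equal(nrow(reread), 6)

  empty <- write_report_csv(list(), withr::local_tempfile(fileext = ".csv"))
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 6)
})

test_that("covered_intervals lists each template's contributed runs", {
  path <- withr::local_tempfile()
  write_covered_intervals(we_coverages(), path)
  txt <- readLines(path)
  expect_true(any(grepl("isoform P00001 length 8 covered 7 fraction 0.875",
                        txt)))
  expect_true(any(grepl("template A \\[1,2\\]", txt)))
  expect_true(any(grepl("template C \\[3,7\\]", txt)))
  # the second isoform's C contribution is split around the K4 mismatch
  expect_true(any(grepl("template C \\[3,3\\],\\[5,7\\]", txt)))

  none <- list(NONE = select_template_set(10, list()))
  write_covered_intervals(none, path)
  expect_true(any(grepl("no coverage", readLines(path))))
})

test_that("PIR output trims the target to the covered region", {
  rep <- we_reports()[[1]]
  prefix <- file.path(withr::local_tempdir(), "P00001_WT")
  paths <- write_pir_alignment(
    "P00001", "ADRRVLTY", rep$coverages[["P00001"]],
    rep$per_isoform[["P00001"]]$filtered$alignment, prefix
  )
  pir <- readLines(paths[1])
  tgt <- which(pir == ">P1;P00001")
  expect_equal(pir[tgt + 1], "sequence:P00001:1:.:7:.::::")
  expect_equal(pir[tgt + 2], "ADRRVLT*")  # Y8 trimmed
  a <- which(pir == ">P1;A")
  expect_equal(pir[a + 2], "AD-----*")
  c_ <- which(pir == ">P1;C")
  expect_equal(pir[c_ + 2], "--RRVLT*")
})

test_that("variant and wild-type PIR files differ at exactly one column", {
  rep <- we_reports()[[1]]
  dir <- withr::local_tempdir()
  als <- rep$per_isoform[["P00001"]]$filtered$alignment
  cov <- rep$coverages[["P00001"]]
  wt <- write_pir_alignment("P00001", "ADRRVLTY", cov, als,
                            file.path(dir, "wt"))
  var <- write_pir_alignment("P00001_R3A",
                             build_variant_sequence("ADRRVLTY", "R", 3, "A"),
                             cov, als, file.path(dir, "var"))
  wt_seq <- sub("\\*$", "", readLines(wt)[which(readLines(wt) == ">P1;P00001") + 2])
  var_lines <- readLines(var)
  var_seq <- sub("\\*$", "", var_lines[which(var_lines == ">P1;P00001_R3A") + 2])
  diffs <- which(strsplit(wt_seq, "")[[1]] != strsplit(var_seq, "")[[1]])
  expect_equal(diffs, 3L)
  # template rows are identical between the two files
  expect_equal(grep("^[A-Z-]+\\*$", readLines(wt), value = TRUE)[1:2],
               grep("^[A-Z-]+\\*$", var_lines, value = TRUE)[1:2])
})

test_that("ungapped single-template full coverage and empty covers", {
  al <- align_template("ADRRVLTY", "ADRRVLTY", "FULL_A")
  cov <- select_template_set(8, list(al))
  dir <- withr::local_tempdir()
  p <- write_pir_alignment("P1", "ADRRVLTY", cov, list(al),
                           file.path(dir, "full"))
  pir <- readLines(p)
  expect_equal(sum(pir == "ADRRVLTY*"), 2)  # template and target, no gaps

  empty <- select_template_set(8, list())
  expect_warning(
    none <- write_pir_alignment("P1", "ADRRVLTY", empty, list(),
                                file.path(dir, "none")),
    "no coverage"
  )
  expect_length(none, 0)
})

test_that("long interior uncovered runs split the target into domains", {
  mk <- function(id, tpos) {
    structure(list(
      template_id = id,
      pairs = tibble::tibble(
        target_pos = tpos, template_pos = seq_along(tpos),
        target_res = "A", template_res = "A",
        identical = TRUE
      ),
      identical_positions = tpos, n_aligned = length(tpos),
      identity_pct = 100, score = 10
    ), class = "template_alignment")
  }
  target <- paste(rep("A", 40), collapse = "")
  als <- list(mk("T1", 1:5), mk("T2", 30:34))
  cov <- select_template_set(40, als)
  dir <- withr::local_tempdir()
  split_paths <- write_pir_alignment("P1", target, cov, als,
                                     file.path(dir, "split"),
                                     max_interior_gap = 20)
  expect_length(split_paths, 2)
  expect_true(all(grepl("_domain[12]\\.pir$", split_paths)))
  # a short interior gap is retained as gap columns in one file
  als2 <- list(mk("T1", 1:5), mk("T2", 10:14))
  cov2 <- select_template_set(40, als2)
  one <- write_pir_alignment("P1", target, cov2, als2,
                             file.path(dir, "one"), max_interior_gap = 20)
  expect_length(one, 1)
  pir <- readLines(one)
  tgt <- which(pir == ">P1;P1")
  expect_equal(nchar(sub("\\*$", "", pir[tgt + 2])), 14)
})
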