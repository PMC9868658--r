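# Independent oracles and shared builders for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- worked example -------------------------------------------------------

we_isoforms <- function() {
  tibble::tibble(
    accession = c("P00001", "P00001-2"),
    entry_name = "TST1_HUMAN",
    gene_name = "TST1",
    description = c("Test protein OS=Homo sapiens GN=TST1",
                    "Isoform 2 of Test protein"),
    sequence = c("ADRRVLTY", "ADRKVLTY"),
    is_canonical = c(TRUE, FALSE),
    length = c(8L, 8L)
  )
}

we_catalog <- function() {
  tibble::tibble(
    template_id = c("A", "B", "C", "D"),
    chain = "",
    resolution = c(2.0, 2.0, 2.0, 2.0),
    sequence = c("AD", "AD", "RRVLT", "DRR")
  )
}

we_mutations <- function() parse_mutation_tokens(c("T2A", "R3A", "R4L"))

we_coverages <- function(isoforms = we_isoforms(), catalog = we_catalog()) {
  covs <- lapply(seq_len(nrow(isoforms)), function(i) {
    aligned <- align_templates(catalog, isoforms$sequence[i])
    kept <- filter_templates(aligned)
    select_template_set(isoforms$length[i], kept$alignment)
  })
  names(covs) <- isoforms$accession
  covs
}

we_reports <- function() {
  isoforms <- we_isoforms()
  catalog <- we_catalog()
  mutations <- we_mutations()
  mapping <- build_mutation_mapping(mutations, isoforms)
  coverages <- we_coverages(isoforms, catalog)
  per_isoform <- lapply(isoforms$accession, function(acc) {
    aligned <- align_templates(catalog,
                               isoforms$sequence[isoforms$accession == acc])
    list(filtered = filter_templates(aligned))
  })
  names(per_isoform) <- isoforms$accession
  scores <- score_isoforms(isoforms, coverages, mapping)
  list(list(
    gene_name = "TST1", failure = NULL, isoforms = isoforms,
    mutations = mutations, mapping = mapping, catalog = catalog,
    per_isoform = per_isoform, coverages = coverages, scores = scores
  ))
}

# writes a full on-disk input tree for the worked example and returns a
# run_config pointing at it
we_input_tree <- function(root) {
  dir.create(file.path(root, "templates"), recursive = TRUE,
             showWarnings = FALSE)
  writeLines(c(
    ">sp|P00001|TST1_HUMAN Test protein OS=Homo sapiens GN=TST1",
    "ADRRVLTY",
    ">sp|P00002|OTH1_HUMAN Other protein OS=Homo sapiens GN=OTH1",
    "MKTAYIAKQR"
  ), file.path(root, "canonical.fasta"))
  writeLines(c(
    ">sp|P00001-2|TST1_HUMAN Isoform 2 of Test protein",
    "ADRKVLTY"
  ), file.path(root, "varsplic.fasta"))
  writeLines("TST1", file.path(root, "genes.txt"))
  writeLines(c("TST1", "T2A\tR3A R4L"), file.path(root, "mutations.txt"))
  writeLines(c(
    "template_id\tchain\tresolution\tsequence",
    "A\t\t2\tAD",
    "B\t\t2\tAD",
    "C\t\t2\tRRVLT",
    "D\t\t2\tDRR"
  ), file.path(root, "templates", "TST1.tsv"))
  run_config(
    genes = file.path(root, "genes.txt"),
    mutations = file.path(root, "mutations.txt"),
    canonical = file.path(root, "canonical.fasta"),
    varsplic = file.path(root, "varsplic.fasta"),
    templates = file.path(root, "templates"),
    out = file.path(root, "out")
  )
}

# --- independent Smith-Waterman oracle (Gotoh affine gaps) ---------------

oracle_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# best local alignment score; gap of length L costs open + L * ext,
# matching the pairwise aligner's convention
oracle_sw_score <- function(a, b, open = 11, ext = 1) {
  mat <- oracle_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0, M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

random_aa_seq <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}

# --- brute-force set-cover oracle ----------------------------------------

# fake alignment object holding a known identical-position set
fake_alignment <- function(id, positions) {
  structure(
    list(template_id = id, identical_positions = as.integer(positions),
         pairs = NULL, n_aligned = length(positions),
         identity_pct = 100, score = 1),
    class = "template_alignment"
  )
}

# maximum achievable coverage and the minimal subset size achieving it,
# by exhaustive subset enumeration
oracle_best_cover <- function(position_sets) {
  n <- length(position_sets)
  best_cov <- 0L
  best_size <- 0L
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    u <- length(unique(unlist(position_sets[members])))
    if (u > best_cov || (u == best_cov && length(members) < best_size)) {
      best_cov <- u
      best_size <- length(members)
    }
  }
  list(coverage = best_cov, size = best_size)
}

random_cover_instance <- function(n_templates, target_len) {
  lapply(seq_len(n_templates), function(i) {
    k <- sample.int(target_len, 1)
    sort(sample.int(target_len, k))
  })
}

# --- fixture recovery ----------------------------------------------------

# runs the pipeline on a generated fixture and checks every planted
# expectation; returns a character vector of mismatch descriptions
fixture_mismatches <- function(seed, dir, tol = 1e-12, ...) {
  fx <- generate_fixture(dir, seed = seed, ...)
  cfg <- run_config(fx$paths$genes, fx$paths$mutations, fx$paths$canonical,
                    fx$paths$varsplic, fx$paths$templates,
                    file.path(dir, "out"))
  run <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  bad <- character(0)
  for (g in fx$manifest$genes) {
    rep <- Filter(function(r) identical(r$gene_name, g$gene_name),
                  run$reports)[[1]]
    sc <- rep$scores
    for (e in g$isoforms) {
      row <- sc[sc$accession == e$accession, ]
      ok <- nrow(row) == 1 &&
        row$total_aa == e$total_aa &&
        row$covered_aa == e$covered_aa &&
        abs(row$structural_function - e$structural_function) < tol &&
        row$modellable_count == e$modellable_count &&
        row$found_anywhere_count == e$found_anywhere_count &&
        abs(row$mutation_function - e$mutation_function) < tol &&
        abs(row$selection - e$selection) < tol
      if (!ok) {
        bad <- c(bad, paste0("seed ", seed, " ", e$accession))
      }
    }
    if (!identical(winning_isoform(rep$scores), g$expected_winner)) {
      bad <- c(bad, paste0("seed ", seed, " winner of ", g$gene_name))
    }
    nowhere <- rep$mapping$found_nowhere$token
    exp_nowhere <- as.character(unlist(g$found_nowhere))
    exp_nowhere_norm <- parse_mutation_tokens(exp_nowhere)$token
    if (!setequal(nowhere, exp_nowhere_norm)) {
      bad <- c(bad, paste0("seed ", seed, " found_nowhere of ", g$gene_name))
    }
  }
  bad
}

# deterministic digest of a file tree (path -> content lines)
tree_snapshot <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  stats::setNames(
    lapply(files, function(f) readLines(file.path(root, f), warn = FALSE)),
    files
  )
}
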