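# Seeded synthetic fixtures with planted ground truth.
#
# Construction, chosen so every expected value is exact arithmetic on the
# planted quantities (never a call into the engine under test):
#
# * The canonical sequence of each gene has a "shared" region (positions
#   1..40) drawn from one amino-acid alphabet and a "tail" (41..60) drawn
#   from a disjoint alphabet.
# * Alternative isoforms are truncations of the shared region carrying a
#   few conservative substitutions (strictly positive BLOSUM62 pairs), so a
#   template aligned over a substitution keeps its planted gapless
#   alignment and simply loses that one identical column.
# * In-range templates are exact substrings of the shared region common to
#   all isoforms; one tail template is an exact substring of the tail, and
#   because the tail alphabet is disjoint from the shared alphabet it can
#   never contribute an identically matched column on any alternative
#   isoform. One deliberately poor template (resolution above the default
#   threshold) checks the filter.
# * Mutations are planted inside covered intervals, never on a substitution
#   position: "shared" mutations map on every isoform, one "tail" mutation
#   maps only on the canonical, and one impossible mutation (tail-alphabet
#   wild type inside the shared region) maps nowhere.

FIX_SHARED_ALPHABET <- c("A", "D", "E", "F", "G", "I", "K", "L", "N", "Q",
                         "R", "S", "T", "V")
FIX_TAIL_ALPHABET <- c("C", "H", "M", "P", "W", "Y")
# conservative partners with strictly positive BLOSUM62 scores
FIX_PARTNER <- c(R = "K", K = "R", D = "E", E = "D", I = "V", V = "I",
                 S = "T", T = "S", Q = "E", A = "S")

FIX_SHARED_LEN <- 40L
FIX_TAIL_LEN <- 20L

#' Generate a synthetic study with planted ground truth
#'
#' Writes a gene list, mutation list, canonical and alternative FASTA
#' databases and per-gene template catalogs under `out_dir`, together with
#' a `manifest.json` recording the expected coverage, score components and
#' winning isoform of every gene — all computed by direct arithmetic on the
#' planted quantities, independent of the selection engine. Identical
#' parameters and seed reproduce the fixture tree byte for byte.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the pinned Mersenne-Twister generator.
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene (1 canonical + the rest
#'   alternatives).
#' @param templates_per_gene In-range templates per gene (a tail template
#'   and a below-threshold decoy are added on top).
#' @param mutation_count Mutations per gene: all map everywhere except that
#'   from 2 mutations up one maps only on the canonical, and from 3 up one
#'   maps nowhere.
#' @return Invisibly, a list with `manifest` (the expectations, as written
#'   to `manifest.json`) and `paths`.
#' @export
generate_fixture <- function(out_dir, seed = 1L, n_genes = 1L,
                             isoforms_per_gene = 2L, templates_per_gene = 4L,
                             mutation_count = 3L) {
  stopifnot(n_genes >= 1, isoforms_per_gene >= 1, templates_per_gene >= 1,
            mutation_count >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")

  dir.create(file.path(out_dir, "templates"), recursive = TRUE,
             showWarnings = FALSE)
  canonical_fa <- character(0)
  varsplic_fa <- character(0)
  mutation_lines <- character(0)
  genes <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    plan <- plant_gene(g, isoforms_per_gene, templates_per_gene,
                       mutation_count)
    canonical_fa <- c(canonical_fa, plan$canonical_fa)
    varsplic_fa <- c(varsplic_fa, plan$varsplic_fa)
    mutation_lines <- c(mutation_lines, plan$mutation_lines)
    writeLines(plan$catalog_lines,
               file.path(out_dir, "templates", paste0(plan$gene_name, ".tsv")))
    genes[[g]] <- plan$expected
  }

  gene_names <- vapply(genes, function(x) x$gene_name, character(1))
  writeLines(gene_names, file.path(out_dir, "genes.txt"))
  writeLines(mutation_lines, file.path(out_dir, "mutations.txt"))
  writeLines(canonical_fa, file.path(out_dir, "canonical.fasta"))
  writeLines(varsplic_fa, file.path(out_dir, "varsplic.fasta"))

  manifest <- list(
    seed = seed, n_genes = n_genes, isoforms_per_gene = isoforms_per_gene,
    templates_per_gene = templates_per_gene, mutation_count = mutation_count,
    w1 = 10, w2 = 10, genes = genes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    manifest = manifest,
    paths = list(
      genes = file.path(out_dir, "genes.txt"),
      mutations = file.path(out_dir, "mutations.txt"),
      canonical = file.path(out_dir, "canonical.fasta"),
      varsplic = file.path(out_dir, "varsplic.fasta"),
      templates = file.path(out_dir, "templates"),
      manifest = file.path(out_dir, "manifest.json")
    )
  ))
}

plant_gene <- function(g, isoforms_per_gene, templates_per_gene,
                       mutation_count) {
  gene_name <- paste0("SYNG", g)
  accession <- sprintf("P%05d", 10000 + g)
  total_len <- FIX_SHARED_LEN + FIX_TAIL_LEN

  shared <- sample(FIX_SHARED_ALPHABET, FIX_SHARED_LEN, replace = TRUE)
  tail_region <- sample(FIX_TAIL_ALPHABET, FIX_TAIL_LEN, replace = TRUE)
  canonical_seq <- c(shared, tail_region)

  n_alt <- isoforms_per_gene - 1L
  alt_len <- if (n_alt > 0) sample(30:38, n_alt, replace = TRUE) else integer(0)
  lmin <- min(c(FIX_SHARED_LEN, alt_len))

  # in-range template intervals, exact substrings of the shared region
  tmpl <- purrr::map(seq_len(templates_per_gene), function(k) {
    len <- sample(8:14, 1)
    start <- sample(seq_len(lmin - len + 1L), 1)
    list(id = sprintf("%dT%02d", g, k), start = start, end = start + len - 1L,
         resolution = round(stats::runif(1, 1.5, 3.5), 2))
  })
  union_in <- sort(unique(unlist(lapply(tmpl, function(t) t$start:t$end))))
  tail_start <- FIX_SHARED_LEN + 1L + sample(0:2, 1)
  tail_end <- min(tail_start + sample(12:16, 1) - 1L, total_len)
  tail_positions <- tail_start:tail_end

  # conservative substitutions on the alternatives, inside covered region
  substitutable <- union_in[canonical_seq[union_in] %in% names(FIX_PARTNER)]
  mismatches <- purrr::map(seq_len(n_alt), function(j) {
    k <- min(sample(1:2, 1), length(substitutable))
    sort(resample(substitutable, k))
  })
  all_mismatch <- sort(unique(unlist(mismatches)))

  # planted mutations
  n_tail_mut <- as.integer(mutation_count >= 2)
  n_nowhere <- as.integer(mutation_count >= 3)
  n_shared_mut <- mutation_count - n_tail_mut - n_nowhere
  eligible <- setdiff(union_in, all_mismatch)
  if (n_shared_mut > length(eligible)) {
    stop("infeasible fixture request: ", n_shared_mut,
         " planted mapped mutations but only ", length(eligible),
         " eligible residues", call. = FALSE)
  }
  shared_pos <- sort(resample(eligible, n_shared_mut))
  tail_pos <- if (n_tail_mut) resample(tail_positions, 1) else integer(0)
  nowhere_pos <- if (n_nowhere) sample(seq_len(lmin), 1) else integer(0)
  muts <- dplyr::bind_rows(
    tibble::tibble(
      position = shared_pos, wt = canonical_seq[shared_pos],
      kind = "shared"
    ),
    tibble::tibble(
      position = tail_pos, wt = canonical_seq[tail_pos], kind = "tail"
    ),
    tibble::tibble(
      position = nowhere_pos, wt = sample(FIX_TAIL_ALPHABET, n_nowhere),
      kind = "nowhere"
    )
  )
  muts$mut <- vapply(muts$wt, function(w)
    sample(setdiff(AA_STANDARD, w), 1), character(1))
  muts$token <- render_tokens(muts$wt, muts$position, muts$mut)

  # sequences and FASTA entries
  canonical_fa <- fasta_entry(
    paste0(">sp|", accession, "|", gene_name, "_HUMAN Synthetic protein ",
           gene_name, " OS=Homo sapiens GN=", gene_name),
    paste(canonical_seq, collapse = "")
  )
  alt_seqs <- purrr::map(seq_len(n_alt), function(j) {
    s <- canonical_seq[seq_len(alt_len[j])]
    s[mismatches[[j]]] <- FIX_PARTNER[s[mismatches[[j]]]]
    paste(s, collapse = "")
  })
  varsplic_fa <- unlist(purrr::map(seq_len(n_alt), function(j) {
    fasta_entry(
      paste0(">sp|", accession, "-", j + 1L, "|", gene_name,
             "_HUMAN Isoform ", j + 1L, " of Synthetic protein ", gene_name),
      alt_seqs[[j]]
    )
  })) %||% character(0)

  # template catalog: in-range + tail + below-threshold decoy
  catalog <- tibble::tibble(
    template_id = c(vapply(tmpl, function(t) t$id, character(1)),
                    sprintf("%dTTL", g), sprintf("%dTRJ", g)),
    chain = "A",
    resolution = c(vapply(tmpl, function(t) t$resolution, double(1)),
                   round(stats::runif(1, 1.5, 3.5), 2), 5.0),
    sequence = c(
      vapply(tmpl, function(t)
        paste(canonical_seq[t$start:t$end], collapse = ""), character(1)),
      paste(canonical_seq[tail_positions], collapse = ""),
      paste(canonical_seq[tmpl[[1]]$start:tmpl[[1]]$end], collapse = "")
    )
  )
  catalog_lines <- c(
    "template_id\tchain\tresolution\tsequence",
    sprintf("%s\t%s\t%s\t%s", catalog$template_id, catalog$chain,
            fmt_num(catalog$resolution), catalog$sequence)
  )

  # expectations by direct arithmetic on the planted quantities
  found_anywhere <- n_shared_mut + n_tail_mut
  iso_expected <- vector("list", isoforms_per_gene)
  covered_can <- length(union_in) + length(tail_positions)
  iso_expected[[1]] <- expected_isoform(
    accession, TRUE, total_len, covered_can,
    n_shared_mut + n_tail_mut, found_anywhere
  )
  for (j in seq_len(n_alt)) {
    covered_alt <- length(union_in) - length(mismatches[[j]])
    iso_expected[[j + 1]] <- expected_isoform(
      paste0(accession, "-", j + 1L), FALSE, alt_len[j], covered_alt,
      n_shared_mut, found_anywhere
    )
  }
  sel <- vapply(iso_expected, function(x) x$selection, double(1))
  canon <- vapply(iso_expected, function(x) x$is_canonical, logical(1))
  accs <- vapply(iso_expected, function(x) x$accession, character(1))
  ord <- order(-sel, !canon, isoform_suffix(accs), accs)

  list(
    gene_name = gene_name,
    canonical_fa = canonical_fa,
    varsplic_fa = varsplic_fa,
    mutation_lines = c(gene_name, paste(muts$token, collapse = " \t")),
    catalog_lines = catalog_lines,
    expected = list(
      gene_name = gene_name,
      canonical_accession = accession,
      expected_winner = accs[ord[1]],
      mutations = muts$token,
      found_nowhere = muts$token[muts$kind == "nowhere"],
      isoforms = iso_expected
    )
  )
}

expected_isoform <- function(accession, is_canonical, total_aa, covered_aa,
                             modellable, found_anywhere) {
  sf <- covered_aa / total_aa
  mf <- if (found_anywhere == 0) 0 else modellable / found_anywhere
  list(
    accession = accession, is_canonical = is_canonical,
    total_aa = total_aa, covered_aa = covered_aa,
    structural_function = sf,
    modellable_count = modellable, found_anywhere_count = found_anywhere,
    mutation_function = mf,
    selection = 10 * sf + 10 * mf
  )
}

render_tokens <- function(wt, position, mut) {
  three <- Biostrings::AMINO_ACID_CODE
  vapply(seq_along(wt), function(i) {
    if (i %% 2 == 0) {
      paste0(three[[wt[i]]], position[i], three[[mut[i]]])
    } else {
      paste0(wt[i], position[i], mut[i])
    }
  }, character(1))
}

# sample() that never falls into the 1:n trap on length-1 vectors
resample <- function(x, size) x[sample.int(length(x), size)]

fasta_entry <- function(header, sequence, width = 60L) {
  starts <- seq(1, nchar(sequence), by = width)
  c(header, substring(sequence, starts, pmin(starts + width - 1L, nchar(sequence))))
}
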