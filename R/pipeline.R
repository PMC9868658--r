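# End-to-end orchestration: gene list -> isoform collection -> mutation
# mapping -> template filter/align/cover -> scoring -> reports and PIR
# alignments. Per-gene failures (gene not found, no templates) are recorded
# in the reports and never abort the run.

#' Validate a pipeline configuration
#'
#' @param genes Path to the gene list (one symbol per line).
#' @param mutations Path to the mutation list ([read_mutation_file()]).
#' @param canonical Path to the canonical isoform FASTA database.
#' @param varsplic Path to the alternative isoform FASTA database.
#' @param templates Directory of per-gene template catalogs
#'   (`<GENE>.tsv`, [read_template_catalog()]).
#' @param out Output directory (created if missing).
#' @param w1,w2 Selection weights; default 10 each.
#' @param identity_min Template identity threshold, percent; default 25.
#' @param resolution_max Template resolution threshold, angstrom; default 4.5.
#' @param count_mode `"covered"` or `"mapped"`; see [score_isoforms()].
#' @param max_interior_gap PIR domain-split threshold; see
#'   [write_pir_alignment()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(genes, mutations, canonical, varsplic, templates, out,
                       w1 = 10, w2 = 10,
                       identity_min = 25, resolution_max = 4.5,
                       count_mode = c("covered", "mapped"),
                       max_interior_gap = 20) {
  count_mode <- match.arg(count_mode)
  for (p in c(genes, mutations, canonical, varsplic)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (!dir.exists(templates)) {
    stop("template catalog directory not found: ", templates, call. = FALSE)
  }
  stopifnot(w1 >= 0, w2 >= 0, identity_min > 0, resolution_max > 0,
            max_interior_gap >= 1)
  structure(
    list(
      genes = genes, mutations = mutations, canonical = canonical,
      varsplic = varsplic, templates = templates, out = out,
      w1 = w1, w2 = w2, identity_min = identity_min,
      resolution_max = resolution_max, count_mode = count_mode,
      max_interior_gap = max_interior_gap
    ),
    class = "run_config"
  )
}

read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Run the isoform-selection pipeline
#'
#' For every gene in the gene list: collect its isoforms from the two
#' databases, parse and map its mutations, align and filter the template
#' catalog against each isoform, run the greedy cover, score and rank the
#' isoforms, and write the audit artifacts (`report.log`, `report.csv`,
#' plus per-gene `covered_intervals.txt` and PIR files for the winning
#' isoform's wild type and each mapped, non-silent variant).
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-gene progress messages.
#' @return An object of class `isoselect_run`: list with `config`,
#'   `reports` (per-gene report objects), `scores` (combined ranked score
#'   tibble with a `gene_name` column), `failures` (character vector), and
#'   `paths` of the written artifacts. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[isoselect] ", ...)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  canonical_db <- parse_isoform_fasta(config$canonical, "canonical")
  varsplic_db <- parse_isoform_fasta(config$varsplic, "varsplic")
  gene_names <- read_gene_list(config$genes)
  mutation_tbl <- read_mutation_file(config$mutations)

  reports <- purrr::map(gene_names, function(gene) {
    say("gene ", gene, ": collecting isoforms")
    isoforms <- collect_gene_isoforms(canonical_db, varsplic_db, gene)
    if (nrow(isoforms) == 0) {
      say("gene ", gene, ": ", attr(isoforms, "failure"))
      return(list(gene_name = gene, failure = attr(isoforms, "failure")))
    }
    tokens <- mutation_tbl$raw_token[
      toupper(mutation_tbl$gene_name) == toupper(gene)
    ]
    mutations <- parse_mutation_tokens(tokens)
    mapping <- build_mutation_mapping(mutations, isoforms)

    catalog_path <- file.path(config$templates, paste0(gene, ".tsv"))
    catalog <- if (file.exists(catalog_path)) {
      read_template_catalog(catalog_path)
    } else {
      say("gene ", gene, ": no template catalog; structural score will be 0")
      tibble::tibble(template_id = character(), chain = character(),
                     resolution = double(), sequence = character())
    }
    say("gene ", gene, ": aligning ", nrow(catalog), " template(s) to ",
        nrow(isoforms), " isoform(s)")
    per_iso <- purrr::map(seq_len(nrow(isoforms)), function(i) {
      aligned <- align_templates(catalog, isoforms$sequence[i])
      kept <- filter_templates(aligned, config$identity_min,
                               config$resolution_max)
      list(
        filtered = kept,
        coverage = select_template_set(isoforms$length[i], kept$alignment)
      )
    })
    names(per_iso) <- isoforms$accession
    coverages <- purrr::map(per_iso, "coverage")

    scores <- score_isoforms(isoforms, coverages, mapping,
                             w1 = config$w1, w2 = config$w2,
                             count_mode = config$count_mode)
    say("gene ", gene, ": selected isoform ", winning_isoform(scores))
    list(
      gene_name = gene, failure = NULL, isoforms = isoforms,
      mutations = mutations, mapping = mapping, catalog = catalog,
      per_isoform = per_iso, coverages = coverages, scores = scores
    )
  })

  paths <- write_artifacts(reports, config)

  scores <- purrr::list_rbind(purrr::map(reports, function(rep) {
    if (is.null(rep$failure)) {
      dplyr::bind_cols(tibble::tibble(gene_name = rep$gene_name),
                       tibble::as_tibble(rep$scores))
    } else {
      NULL
    }
  }))
  failures <- purrr::map_chr(
    purrr::keep(reports, ~ !is.null(.x$failure)), "failure"
  )
  structure(
    list(config = config, reports = reports, scores = scores,
         failures = failures, paths = paths),
    class = "isoselect_run"
  )
}

write_artifacts <- function(reports, config) {
  paths <- c(
    report_log = file.path(config$out, "report.log"),
    report_csv = file.path(config$out, "report.csv")
  )
  write_report_log(reports, config, paths[["report_log"]])
  write_report_csv(reports, paths[["report_csv"]])
  for (rep in reports) {
    if (!is.null(rep$failure)) next
    gene_dir <- file.path(config$out, rep$gene_name)
    dir.create(gene_dir, recursive = TRUE, showWarnings = FALSE)
    write_covered_intervals(rep$coverages,
                            file.path(gene_dir, "covered_intervals.txt"))
    winner <- winning_isoform(rep$scores)
    wi <- match(winner, rep$isoforms$accession)
    cov <- rep$coverages[[winner]]
    alignments <- rep$per_isoform[[winner]]$filtered$alignment
    wt_seq <- rep$isoforms$sequence[wi]
    if (cov$covered_aa > 0) {
      write_pir_alignment(winner, wt_seq, cov, alignments,
                          file.path(gene_dir, paste0(winner, "_WT")),
                          config$max_interior_gap)
      mapped <- dplyr::filter(rep$mapping$per_isoform,
                              .data$accession == winner, .data$mapped,
                              !.data$silent)
      for (j in seq_len(nrow(mapped))) {
        variant <- build_variant_sequence(wt_seq, mapped$wt[j],
                                          mapped$position[j], mapped$mut[j])
        write_pir_alignment(
          paste0(winner, "_", mapped$token[j]), variant, cov, alignments,
          file.path(gene_dir, paste0(winner, "_", mapped$token[j])),
          config$max_interior_gap
        )
      }
    }
  }
  paths
}

#' @export
print.isoselect_run <- function(x, ...) {
  cat("<isoselect_run> ", length(x$reports), " gene(s), ",
      length(x$failures), " failure(s)\n", sep = "")
  if (!is.null(x$scores) && nrow(x$scores) > 0) {
    winners <- dplyr::slice_head(dplyr::group_by(x$scores, .data$gene_name),
                                 n = 1)
    for (i in seq_len(nrow(winners))) {
      cat("  ", winners$gene_name[i], ": ", winners$accession[i],
          " (selection ", fmt_num(winners$selection[i]), ")\n", sep = "")
    }
  }
  for (f in x$failures) cat("  ", f, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-isoform score table of a pipeline run
#'
#' @param x An `isoselect_run`.
#' @param ... Unused.
#' @return Tibble with one row per (gene, isoform): all score components,
#'   ranks within gene, and whether the isoform won.
#' @exportS3Method generics::tidy
tidy.isoselect_run <- function(x, ...) {
  if (is.null(x$scores) || nrow(x$scores) == 0) return(x$scores)
  dplyr::mutate(
    dplyr::group_by(x$scores, .data$gene_name),
    rank = dplyr::row_number(),
    winner = .data$rank == 1L
  ) |>
    dplyr::ungroup()
}

#' One-row summary of a pipeline run
#'
#' @param x An `isoselect_run`.
#' @param ... Unused.
#' @return One-row tibble: gene/isoform/mutation counts and failure count.
#' @exportS3Method generics::glance
glance.isoselect_run <- function(x, ...) {
  ok <- purrr::keep(x$reports, ~ is.null(.x$failure))
  tibble::tibble(
    n_genes = length(x$reports),
    n_genes_failed = length(x$failures),
    n_isoforms = sum(purrr::map_int(ok, ~ nrow(.x$isoforms))),
    n_mutations = sum(purrr::map_int(ok, ~ nrow(.x$mutations))),
    n_mutations_unmapped = sum(purrr::map_int(ok, ~ nrow(.x$mapping$found_nowhere))),
    mean_structural_function = if (is.null(x$scores) || nrow(x$scores) == 0) {
      NA_real_
    } else {
      mean(x$scores$structural_function)
    }
  )
}
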