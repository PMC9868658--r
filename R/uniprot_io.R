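# Reading and writing isoform sequence databases in the UniProt FASTA
# dialects (sprot for canonical isoforms, varsplic for alternatives).

#' Parse an isoform FASTA database
#'
#' Reads FASTA text in one of the two UniProt dialects and returns one row
#' per entry. Canonical (`sprot`) headers look like
#' `>sp|P00001|TST1_HUMAN Test protein OS=Homo sapiens GN=TST1`; alternative
#' (`varsplic`) headers carry an isoform suffix on the accession, e.g.
#' `>sp|P00001-2|TST1_HUMAN Isoform 2 of Test protein`. The gene symbol is
#' taken from the `GN=` field when present, otherwise from the entry-name
#' prefix before `_`.
#'
#' Malformed records (no `sp|ACC|NAME` block, empty sequence, illegal
#' residue codes) are dropped from the result but collected in the
#' `problems` attribute, so one bad entry never aborts a database read.
#'
#' @param x Path to a FASTA file, or a character vector of FASTA lines.
#' @param dialect `"canonical"` or `"varsplic"`; sets the `is_canonical`
#'   flag on every record.
#' @return A tibble with columns `accession`, `entry_name`, `gene_name`,
#'   `description`, `sequence`, `is_canonical`, `length`, plus a
#'   `problems` attribute (tibble of rejected records; retrieve with
#'   [parse_problems()]).
#' @examples
#' fa <- c(">sp|P00001|TST1_HUMAN Test OS=Homo sapiens GN=TST1", "ADRRVLTY")
#' parse_isoform_fasta(fa, "canonical")
#' @export
parse_isoform_fasta <- function(x, dialect = c("canonical", "varsplic")) {
  dialect <- match.arg(dialect)
  lines <- if (length(x) == 1 && !startsWith(x[[1]], ">") && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- as.character(lines %||% character(0))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_isoform_tbl(problems = empty_problem_tbl()))
  }
  is_header <- startsWith(lines, ">")
  if (!any(is_header)) {
    return(empty_isoform_tbl(problems = empty_problem_tbl()))
  }
  entry_id <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  bodies <- vapply(
    split(lines[!is_header], entry_id[!is_header]),
    paste0, character(1), collapse = ""
  )
  sequences <- character(length(headers))
  sequences[as.integer(names(bodies))] <- bodies

  records <- purrr::map2(headers, sequences, parse_uniprot_entry,
    is_canonical = dialect == "canonical"
  )
  ok <- purrr::map_lgl(records, "ok")
  problems <- tibble::tibble(
    record = which(!ok),
    header = headers[!ok],
    problem = purrr::map_chr(records[!ok], "problem")
  )
  out <- purrr::list_rbind(purrr::map(records[ok], "row"))
  if (nrow(problems) == 0) problems <- empty_problem_tbl()
  if (is.null(out) || nrow(out) == 0) out <- empty_isoform_tbl()
  attr(out, "problems") <- problems
  out
}

#' Rejected records from a database parse
#'
#' @param x A tibble returned by [parse_isoform_fasta()].
#' @return A tibble with columns `record`, `header`, `problem`.
#' @export
parse_problems <- function(x) {
  attr(x, "problems") %||% empty_problem_tbl()
}

parse_uniprot_entry <- function(header, sequence, is_canonical) {
  m <- stringr::str_match(header, "^sp\\|([A-Za-z0-9]+(?:-\\d+)?)\\|(\\S+)\\s*(.*)$")
  if (is.na(m[1, 1])) {
    return(list(ok = FALSE, problem = "malformed header (no accession block)"))
  }
  accession <- m[1, 2]
  entry_name <- m[1, 3]
  description <- m[1, 4]
  chk <- validate_aa_sequence(sequence)
  if (!chk$ok) {
    return(list(ok = FALSE, problem = chk$problem))
  }
  gn <- stringr::str_match(description, "\\bGN=(\\S+)")[1, 2]
  gene_name <- if (!is.na(gn)) gn else sub("_.*$", "", entry_name)
  list(ok = TRUE, problem = NA_character_, row = tibble::tibble(
    accession = accession,
    entry_name = entry_name,
    gene_name = gene_name,
    description = description,
    sequence = chk$sequence,
    is_canonical = is_canonical,
    length = nchar(chk$sequence)
  ))
}

empty_isoform_tbl <- function(problems = NULL) {
  out <- tibble::tibble(
    accession = character(), entry_name = character(),
    gene_name = character(), description = character(),
    sequence = character(), is_canonical = logical(), length = integer()
  )
  if (!is.null(problems)) attr(out, "problems") <- problems
  out
}

empty_problem_tbl <- function() {
  tibble::tibble(record = integer(), header = character(), problem = character())
}

#' Write isoform records back to a UniProt-dialect FASTA file
#'
#' Reconstructs `>sp|ACC|ENTRY description` headers from the record fields,
#' so a parse/write/parse round trip is lossless.
#'
#' @param isoforms Tibble as returned by [parse_isoform_fasta()].
#' @param path Output file path.
#' @param width Sequence line width.
#' @return `path`, invisibly.
#' @export
write_isoform_fasta <- function(isoforms, path, width = 60L) {
  lines <- purrr::pmap(
    list(isoforms$accession, isoforms$entry_name, isoforms$description,
         isoforms$sequence),
    function(acc, entry, desc, seq) {
      header <- paste0(">sp|", acc, "|", entry,
                       if (nzchar(desc)) paste0(" ", desc) else "")
      body <- substring(seq, seq(1, nchar(seq), by = width),
                        pmin(seq(1, nchar(seq), by = width) + width - 1L, nchar(seq)))
      c(header, body)
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}

base_accession <- function(accession) sub("-\\d+$", "", accession)

isoform_suffix <- function(accession) {
  suf <- stringr::str_match(accession, "-(\\d+)$")[, 2]
  ifelse(is.na(suf), 0L, as.integer(suf))
}

#' Assemble the isoform set of one gene
#'
#' Looks a gene symbol up in the parsed canonical database
#' (case-insensitive, exact symbol match, no synonym expansion) and attaches
#' every alternative-isoform record whose base accession matches the
#' canonical accession or whose gene name matches the symbol. When the
#' canonical database holds duplicate entries for a gene the first occurrence
#' wins with a warning.
#'
#' @param canonical_db,varsplic_db Tibbles from [parse_isoform_fasta()].
#' @param gene_name Gene symbol to collect.
#' @return A tibble of isoform records, canonical row first, alternatives
#'   ordered by isoform suffix then accession. A gene absent from the
#'   canonical database yields a zero-row tibble whose `failure` attribute
#'   holds a "gene not found" message; the caller records it and moves on.
#' @examples
#' can <- parse_isoform_fasta(
#'   c(">sp|P00001|TST1_HUMAN GN=TST1", "ADRRVLTY"), "canonical")
#' alt <- parse_isoform_fasta(
#'   c(">sp|P00001-2|TST1_HUMAN Isoform 2", "ADRKVLTY"), "varsplic")
#' collect_gene_isoforms(can, alt, "TST1")
#' @export
collect_gene_isoforms <- function(canonical_db, varsplic_db, gene_name) {
  hit <- dplyr::filter(canonical_db, toupper(.data$gene_name) == toupper(.env$gene_name))
  if (nrow(hit) == 0) {
    out <- empty_isoform_tbl()
    attr(out, "failure") <- paste0("gene not found: ", gene_name)
    return(out)
  }
  if (nrow(hit) > 1) {
    warning("duplicate canonical entries for gene ", gene_name,
            "; keeping the first (", hit$accession[1], ")", call. = FALSE)
    hit <- hit[1, , drop = FALSE]
  }
  alts <- dplyr::filter(
    varsplic_db,
    base_accession(.data$accession) == base_accession(hit$accession) |
      toupper(.data$gene_name) == toupper(.env$gene_name)
  )
  alts <- dplyr::arrange(alts, isoform_suffix(.data$accession), .data$accession)
  alts <- dplyr::distinct(alts, .data$accession, .keep_all = TRUE)
  alts$gene_name <- hit$gene_name
  out <- dplyr::bind_rows(hit, alts)
  if (anyDuplicated(out$accession)) {
    out <- dplyr::distinct(out, .data$accession, .keep_all = TRUE)
  }
  out
}
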