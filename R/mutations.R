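# Parsing missense mutation tokens and mapping them onto isoform sequences.
#
# A token is WT+position+MUT in one-letter ("T2A") or three-letter
# ("Thr2Ala", any case) notation. A mutation maps onto an isoform when its
# position lies inside the sequence and the isoform carries the stated
# wild-type residue there; no renumbering or alignment between isoforms is
# attempted.

#' Parse missense mutation tokens
#'
#' Accepts one-letter (`T2A`) and three-letter (`Thr2Ala`, case-insensitive)
#' substitutions. Residue codes must be one of the 20 standard amino acids;
#' ambiguity codes such as `B` are rejected. Tokens that do not parse are
#' collected in the `problems` attribute; silent tokens (`wt == mut`) are
#' kept with a warning and flagged, so they still appear in reports but are
#' excluded from variant building.
#'
#' @param tokens Character vector of mutation tokens.
#' @return A tibble with columns `raw_token`, `token` (normalized one-letter
#'   form), `wt`, `position`, `mut`, `silent`; rejected tokens are in the
#'   `problems` attribute ([parse_problems()]).
#' @examples
#' parse_mutation_tokens(c("T2A", "Arg3Ala", "R4L"))
#' @export
parse_mutation_tokens <- function(tokens) {
  tokens <- trimws(tokens)
  parsed <- purrr::map(tokens, parse_one_mutation)
  ok <- purrr::map_lgl(parsed, "ok")
  problems <- tibble::tibble(
    record = which(!ok),
    header = tokens[!ok],
    problem = purrr::map_chr(parsed[!ok], "problem")
  )
  out <- purrr::list_rbind(purrr::map(parsed[ok], "row"))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(
      raw_token = character(), token = character(), wt = character(),
      position = integer(), mut = character(), silent = logical()
    )
  }
  if (any(out$silent)) {
    warning("silent mutation token(s) kept: ",
            paste(out$raw_token[out$silent], collapse = ", "), call. = FALSE)
  }
  attr(out, "problems") <- problems
  out
}

parse_one_mutation <- function(token) {
  fail <- function(msg) list(ok = FALSE, problem = paste0(msg, ": '", token, "'"))
  m1 <- stringr::str_match(token, "^([A-Za-z])(\\d+)([A-Za-z])$")
  m3 <- stringr::str_match(token, "^([A-Za-z]{3})(\\d+)([A-Za-z]{3})$")
  if (!is.na(m1[1, 1])) {
    wt <- toupper(m1[1, 2]); mut <- toupper(m1[1, 4]); pos_txt <- m1[1, 3]
    if (!(wt %in% AA_STANDARD)) return(fail("unrecognized wild-type residue code"))
    if (!(mut %in% AA_STANDARD)) return(fail("unrecognized mutant residue code"))
  } else if (!is.na(m3[1, 1])) {
    three <- aa_three_to_one()
    wt <- three[toupper(m3[1, 2])]; mut <- three[toupper(m3[1, 4])]
    pos_txt <- m3[1, 3]
    if (is.na(wt)) return(fail("unrecognized wild-type residue code"))
    if (is.na(mut)) return(fail("unrecognized mutant residue code"))
    wt <- unname(wt); mut <- unname(mut)
  } else {
    return(fail("unrecognized mutation token"))
  }
  position <- suppressWarnings(as.integer(pos_txt))
  if (is.na(position) || position < 1) return(fail("non-positive position"))
  list(ok = TRUE, row = tibble::tibble(
    raw_token = token,
    token = paste0(wt, position, mut),
    wt = wt, position = position, mut = mut,
    silent = wt == mut
  ))
}

#' Read a whitespace-tolerant mutation list file
#'
#' The file holds one gene section per gene: the gene symbol on its own
#' line, followed by mutation tokens separated by any mix of spaces, tabs
#' and newlines. A line whose single token does not look like a mutation
#' token starts a new gene section.
#'
#' @param path Path to the mutation list file.
#' @return A tibble with columns `gene_name` and `raw_token` (unparsed).
#' @export
read_mutation_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  current <- NA_character_
  for (line in lines) {
    toks <- strsplit(trimws(line), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) next
    looks_mut <- grepl("^([A-Za-z]\\d+[A-Za-z]|[A-Za-z]{3}\\d+[A-Za-z]{3})$", toks)
    if (length(toks) == 1 && !looks_mut[1]) {
      current <- toks[1]
      next
    }
    if (is.na(current)) {
      stop("mutation file must start with a gene name line: ", path, call. = FALSE)
    }
    out[[length(out) + 1]] <- tibble::tibble(gene_name = current, raw_token = toks)
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_name = character(), raw_token = character()))
  }
  purrr::list_rbind(out)
}

#' Map mutations onto the isoforms of a gene
#'
#' Deduplicates the mutation list on (wt, position, mut), then tests every
#' mutation against every isoform independently: a mutation is mapped iff
#' its position lies inside the sequence and the residue there equals the
#' stated wild-type letter. Unmapped rows carry a reason code
#' (`"wt_mismatch"` or `"out_of_range"`).
#'
#' @param mutations Tibble from [parse_mutation_tokens()].
#' @param isoforms Tibble of isoform records ([collect_gene_isoforms()]).
#' @return An object of class `mutation_mapping`: a list with
#'   * `per_isoform`: tibble (`accession`, `token`, `wt`, `position`, `mut`,
#'     `silent`, `mapped`, `reason`), one row per (isoform, mutation) in
#'     input order;
#'   * `found_anywhere`: tibble of distinct mutations mapped on >= 1 isoform;
#'   * `found_nowhere`: tibble of distinct mutations mapped on none.
#' @examples
#' iso <- tibble::tibble(accession = c("P1", "P1-2"),
#'                       sequence = c("ADRRVLTY", "ADRKVLTY"))
#' mut <- parse_mutation_tokens(c("T2A", "R3A", "R4L"))
#' build_mutation_mapping(mut, iso)$found_anywhere$token
#' @export
build_mutation_mapping <- function(mutations, isoforms) {
  mutations <- dplyr::distinct(mutations, .data$wt, .data$position, .data$mut,
                               .keep_all = TRUE)
  if (nrow(isoforms) == 0 || nrow(mutations) == 0) {
    per_isoform <- tidyr::crossing(
      tibble::tibble(accession = isoforms$accession),
      mutations
    )
    per_isoform$mapped <- logical(nrow(per_isoform))
    per_isoform$reason <- character(nrow(per_isoform))
    return(new_mutation_mapping(per_isoform, mutations[0, ], mutations))
  }
  per_isoform <- purrr::list_rbind(purrr::map(seq_len(nrow(isoforms)), function(i) {
    seq_i <- isoforms$sequence[i]
    res <- substring(seq_i, mutations$position, mutations$position)
    in_range <- mutations$position <= nchar(seq_i)
    mapped <- in_range & res == mutations$wt
    reason <- dplyr::case_when(
      mapped ~ NA_character_,
      !in_range ~ "out_of_range",
      TRUE ~ "wt_mismatch"
    )
    dplyr::bind_cols(
      tibble::tibble(accession = isoforms$accession[i]),
      mutations,
      tibble::tibble(mapped = mapped, reason = reason)
    )
  }))
  anywhere <- dplyr::summarise(
    dplyr::group_by(per_isoform, .data$token),
    mapped = any(.data$mapped), .groups = "drop"
  )
  found_anywhere <- mutations[mutations$token %in% anywhere$token[anywhere$mapped], ]
  found_nowhere <- mutations[!mutations$token %in% found_anywhere$token, ]
  new_mutation_mapping(per_isoform, found_anywhere, found_nowhere)
}

new_mutation_mapping <- function(per_isoform, found_anywhere, found_nowhere) {
  structure(
    list(
      per_isoform = per_isoform,
      found_anywhere = found_anywhere,
      found_nowhere = found_nowhere
    ),
    class = "mutation_mapping"
  )
}

#' @export
print.mutation_mapping <- function(x, ...) {
  cat("<mutation_mapping>\n")
  cat("  mutations found on >=1 isoform:",
      paste(x$found_anywhere$token, collapse = ", "), "\n")
  cat("  mutations found nowhere:      ",
      paste(x$found_nowhere$token, collapse = ", "), "\n")
  print(x$per_isoform, ...)
  invisible(x)
}
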