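# Audit artifacts: report.log, report.csv, covered_intervals, and PIR
# (NBRF) alignment files for the wild-type and variant target sequences.
#
# The paper-of-record for these layouts is this package: the file grammars
# below are versioned here so tests can diff them byte-for-byte.

fmt_num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

#' Write the run log
#'
#' One block per gene, in input gene order: the configuration echo, the
#' per-isoform score components (by rank), the mapped mutations and the
#' isoform(s) they map on, the mutations not associated with any isoform,
#' and the isoform selected for modelling. All numbers are printed from the
#' scoring tables themselves.
#'
#' @param reports List of per-gene report objects (see [run_pipeline()]).
#' @param config A validated [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_log <- function(reports, config, path) {
  lines <- c(
    "# isoselect report.log v1",
    paste0(
      "config: w1=", fmt_num(config$w1), " w2=", fmt_num(config$w2),
      " identity_threshold=", fmt_num(config$identity_min),
      " resolution_threshold=", fmt_num(config$resolution_max),
      " mutation_count_mode=", config$count_mode,
      " max_interior_gap=", fmt_num(config$max_interior_gap)
    ),
    ""
  )
  for (rep in reports) {
    lines <- c(lines, paste0("gene ", rep$gene_name))
    if (!is.null(rep$failure)) {
      lines <- c(lines, paste0("  ", rep$failure), "")
      next
    }
    sc <- rep$scores
    lines <- c(lines, paste0("  isoforms: ", nrow(sc)))
    lines <- c(lines, "  scores:")
    for (i in seq_len(nrow(sc))) {
      lines <- c(lines, paste0(
        "    ", sc$accession[i],
        if (sc$is_canonical[i]) " [canonical]" else "",
        " total_aa=", sc$total_aa[i],
        " covered_aa=", sc$covered_aa[i],
        " structural_function=", fmt_num(sc$structural_function[i]),
        " modellable=", sc$modellable_count[i],
        " found_anywhere=", sc$found_anywhere_count[i],
        " mutation_function=", fmt_num(sc$mutation_function[i]),
        " selection=", fmt_num(sc$selection[i])
      ))
    }
    mapped <- dplyr::filter(rep$mapping$per_isoform, .data$mapped)
    lines <- c(lines, "  mapped mutations:")
    if (nrow(mapped) > 0) {
      for (tok in unique(mapped$token)) {
        on <- mapped[mapped$token == tok, ]
        lines <- c(lines, paste0(
          "    ", tok, " -> ",
          paste0(on$accession, " (pos ", on$position, ")", collapse = ", ")
        ))
      }
    } else {
      lines <- c(lines, "    (none)")
    }
    lines <- c(lines, paste0(
      "  mutations not associated with any isoform: ",
      if (nrow(rep$mapping$found_nowhere) > 0) {
        paste(rep$mapping$found_nowhere$token, collapse = ", ")
      } else "(none)"
    ))
    lines <- c(lines, paste0("  selected isoform: ", winning_isoform(sc)), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-mutation trace table
#'
#' One row per (gene, mutation, isoform): whether the mutation maps on that
#' isoform, the matched position, and whether the position lies inside the
#' isoform's template coverage.
#'
#' @inheritParams write_report_log
#' @return The tibble that was written, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  rows <- purrr::list_rbind(purrr::map(reports, function(rep) {
    if (!is.null(rep$failure) || nrow(rep$mapping$per_isoform) == 0) {
      return(NULL)
    }
    per <- rep$mapping$per_isoform
    inside <- purrr::map2_lgl(per$accession, per$position, function(acc, pos) {
      cov <- rep$coverages[[acc]]
      !is.null(cov) && pos %in% cov$covered_positions
    })
    tibble::tibble(
      gene = rep$gene_name,
      mutation_token = per$token,
      isoform_accession = per$accession,
      mapped = per$mapped,
      position_matched = ifelse(per$mapped, per$position, NA_integer_),
      inside_coverage = per$mapped & inside
    )
  }))
  if (is.null(rows) || ncol(rows) == 0) {
    rows <- tibble::tibble(
      gene = character(), mutation_token = character(),
      isoform_accession = character(), mapped = logical(),
      position_matched = integer(), inside_coverage = logical()
    )
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

#' Write per-isoform covered intervals
#'
#' For each isoform, each selected template is listed (in id order) with the
#' maximal 1-based closed intervals of the positions it newly contributed,
#' plus the total covered fraction.
#'
#' @param coverages Named list of [select_template_set()] results keyed by
#'   accession.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covered_intervals <- function(coverages, path) {
  lines <- "# covered_intervals v1"
  for (acc in names(coverages)) {
    cov <- coverages[[acc]]
    frac <- cov$covered_aa / cov$target_len
    lines <- c(lines, paste0(
      "isoform ", acc, " length ", cov$target_len,
      " covered ", cov$covered_aa, " fraction ", fmt_num(frac)
    ))
    if (nrow(cov$selected) == 0) {
      lines <- c(lines, "  no coverage")
      next
    }
    sel <- cov$selected[order(cov$selected$template_id), ]
    for (i in seq_len(nrow(sel))) {
      iv <- sel$intervals[[i]]
      lines <- c(lines, paste0(
        "  template ", sel$template_id[i], " ",
        paste0("[", iv$start, ",", iv$end, "]", collapse = ",")
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Apply a missense mutation to a sequence
#'
#' @param wt_seq Wild-type sequence.
#' @param wt,position,mut Mutation components; the wild-type letter must
#'   match `wt_seq` at `position`.
#' @return The variant sequence (same length, one substituted residue).
#' @examples
#' build_variant_sequence("ADRRVLTY", "R", 3, "A")
#' @export
build_variant_sequence <- function(wt_seq, wt, position, mut) {
  stopifnot(position >= 1, position <= nchar(wt_seq))
  if (substring(wt_seq, position, position) != wt) {
    stop("wild-type mismatch: sequence has '",
         substring(wt_seq, position, position), "' at position ", position,
         ", mutation says '", wt, "'", call. = FALSE)
  }
  paste0(
    substring(wt_seq, 1, position - 1), mut,
    substring(wt_seq, position + 1, nchar(wt_seq))
  )
}

template_chain <- function(template_id) {
  m <- stringr::str_match(template_id, "_([A-Za-z0-9])$")[, 2]
  ifelse(is.na(m), ".", m)
}

#' Write a PIR (NBRF) alignment for a target and its selected templates
#'
#' The target entry is trimmed to the covered region: leading and trailing
#' uncovered residues are dropped; interior uncovered runs shorter than
#' `max_interior_gap` are retained in the target (as gap columns in every
#' template), while longer ones split the target into per-domain PIR files
#' (`<prefix>_domain1.pir`, ...). Template rows carry the template residues
#' at their aligned columns and gaps elsewhere.
#'
#' @param target_name Name for the target entry (accession, possibly with a
#'   variant suffix).
#' @param target_seq Target sequence (wild type or variant; same length).
#' @param coverage A [select_template_set()] result for the wild type.
#' @param alignments List of [align_template()] results for the selected
#'   templates (others are ignored).
#' @param prefix Output path prefix (without extension).
#' @param max_interior_gap Interior uncovered run length at or above which
#'   the target is split into domains. Default 20.
#' @return Character vector of written file paths (empty, with a warning,
#'   when there is no coverage).
#' @export
write_pir_alignment <- function(target_name, target_seq, coverage, alignments,
                                prefix, max_interior_gap = 20) {
  covered <- coverage$covered_positions
  if (length(covered) == 0) {
    warning("no coverage for ", target_name, "; no PIR file written",
            call. = FALSE)
    return(invisible(character(0)))
  }
  sel_ids <- coverage$selected$template_id
  alignments <- purrr::keep(alignments, ~ .x$template_id %in% sel_ids)

  # split covered positions into domains at long interior uncovered runs
  gaps <- diff(covered) - 1L
  domain_id <- cumsum(c(0L, gaps >= max_interior_gap))
  domains <- split(covered, domain_id)
  multi <- length(domains) > 1

  paths <- character(0)
  for (d in seq_along(domains)) {
    cols <- seq(min(domains[[d]]), max(domains[[d]]))
    target_row <- paste(substring(target_seq, cols, cols), collapse = "")
    entries <- character(0)
    for (al in alignments) {
      hit <- al$pairs[al$pairs$target_pos %in% cols, ]
      if (nrow(hit) == 0) next
      row <- rep("-", length(cols))
      row[match(hit$target_pos, cols)] <- hit$template_res
      chain <- template_chain(al$template_id)
      entries <- c(entries, c(
        paste0(">P1;", al$template_id),
        paste0("structureX:", al$template_id, ":", min(hit$template_pos), ":",
               chain, ":", max(hit$template_pos), ":", chain, "::::"),
        paste0(paste(row, collapse = ""), "*")
      ))
    }
    entries <- c(entries, c(
      paste0(">P1;", target_name),
      paste0("sequence:", target_name, ":", min(cols), ":.:", max(cols), ":.::::"),
      paste0(target_row, "*")
    ))
    path <- if (multi) paste0(prefix, "_domain", d, ".pir") else paste0(prefix, ".pir")
    writeLines(entries, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
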