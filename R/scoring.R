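# Isoform scoring: the structural coverage fraction, the mutation coverage
# fraction, and their weighted sum used to rank the isoforms of a gene.
#
#   selection = w1 * structural_function + w2 * mutation_function
#
# with default weights w1 = w2 = 10. The structural term is the fraction of
# the isoform covered by the selected template set; the mutation term is the
# fraction of the gene's mappable mutations that can be modelled on this
# isoform.

#' Structural coverage fraction
#'
#' Number of residues covered by the selected template combination over the
#' isoform length.
#'
#' @param covered_aa Covered residue count.
#' @param total_aa Isoform length (>= 1).
#' @return `covered_aa / total_aa` as an exact double.
#' @examples
#' structural_function(7, 8)
#' @export
structural_function <- function(covered_aa, total_aa) {
  stopifnot(all(total_aa >= 1), all(covered_aa >= 0), all(covered_aa <= total_aa))
  covered_aa / total_aa
}

#' Mutation coverage fraction
#'
#' Mutations modellable on this isoform over mutations found on at least one
#' isoform of the gene. A gene with no mappable mutations at all gets 0 so
#' it is still ranked by structure alone; such values carry the attribute
#' `no_mappable_mutations = TRUE`.
#'
#' @param modellable_count Mutations modellable on this isoform.
#' @param found_anywhere_count Gene-level mutations mapped on >= 1 isoform.
#' @return The ratio, 0 when the denominator is 0.
#' @examples
#' mutation_function(1, 2)
#' @export
mutation_function <- function(modellable_count, found_anywhere_count) {
  stopifnot(all(modellable_count >= 0),
            all(found_anywhere_count >= modellable_count | found_anywhere_count == 0))
  out <- ifelse(found_anywhere_count == 0, 0,
                modellable_count / found_anywhere_count)
  if (any(found_anywhere_count == 0)) {
    attr(out, "no_mappable_mutations") <- TRUE
  }
  out
}

#' Weighted selection score
#'
#' @param sf Structural coverage fraction, in \[0, 1\].
#' @param mf Mutation coverage fraction, in \[0, 1\].
#' @param w1,w2 Non-negative weights; default 10 each.
#' @return `w1 * sf + w2 * mf`.
#' @examples
#' selection_score(0.875, 1)
#' @export
selection_score <- function(sf, mf, w1 = 10, w2 = 10) {
  stopifnot(w1 >= 0, w2 >= 0, is.finite(w1), is.finite(w2))
  w1 * sf + w2 * mf
}

#' Score and rank the isoforms of one gene
#'
#' Combines template coverage and the mutation mapping into the per-isoform
#' score table, ordered by selection score descending. Ties go to the
#' canonical isoform, then the lowest isoform suffix, then the accession.
#'
#' A mutation counts as modellable on an isoform when it maps there (wild
#' type matches at the position) and, under the default
#' `count_mode = "covered"`, its position additionally lies inside the
#' isoform's covered positions; `count_mode = "mapped"` drops the coverage
#' requirement.
#'
#' @param isoforms Isoform tibble ([collect_gene_isoforms()]).
#' @param coverages Named list of [select_template_set()] results, one per
#'   accession.
#' @param mapping A `mutation_mapping` ([build_mutation_mapping()]).
#' @param w1,w2 Selection weights.
#' @param count_mode `"covered"` (default) or `"mapped"`.
#' @return An `isoform_scores` tibble with columns `accession`,
#'   `is_canonical`, `total_aa`, `covered_aa`, `structural_function`,
#'   `modellable_count`, `found_anywhere_count`, `mutation_function`,
#'   `selection`, ordered by rank; the winner accession is in the `winner`
#'   attribute and first row.
#' @export
score_isoforms <- function(isoforms, coverages, mapping,
                           w1 = 10, w2 = 10,
                           count_mode = c("covered", "mapped")) {
  count_mode <- match.arg(count_mode)
  stopifnot(nrow(isoforms) >= 1)
  found_anywhere_count <- nrow(mapping$found_anywhere)
  rows <- purrr::map(seq_len(nrow(isoforms)), function(i) {
    acc <- isoforms$accession[i]
    cov <- coverages[[acc]]
    covered_aa <- if (is.null(cov)) 0L else cov$covered_aa
    covered_pos <- if (is.null(cov)) integer(0) else cov$covered_positions
    per <- dplyr::filter(mapping$per_isoform, .data$accession == acc, .data$mapped)
    modellable <- if (count_mode == "covered") {
      sum(per$position %in% covered_pos)
    } else {
      nrow(per)
    }
    sf <- structural_function(covered_aa, isoforms$length[i])
    mf <- as.numeric(mutation_function(modellable, found_anywhere_count))
    tibble::tibble(
      accession = acc,
      is_canonical = isoforms$is_canonical[i],
      total_aa = isoforms$length[i],
      covered_aa = covered_aa,
      structural_function = sf,
      modellable_count = modellable,
      found_anywhere_count = found_anywhere_count,
      mutation_function = mf,
      selection = selection_score(sf, mf, w1, w2)
    )
  })
  out <- rank_isoforms(purrr::list_rbind(rows))
  out
}

#' Order an isoform score table by rank
#'
#' @param scores Tibble with at least `accession`, `is_canonical`,
#'   `selection` columns.
#' @return The tibble ordered by selection descending with deterministic
#'   tie-breaks (canonical first, then lowest isoform suffix, then
#'   accession), classed `isoform_scores` with the winner accession in the
#'   `winner` attribute.
#' @export
rank_isoforms <- function(scores) {
  if (nrow(scores) == 0) stop("cannot rank an empty score table", call. = FALSE)
  ord <- order(-scores$selection, !scores$is_canonical,
               isoform_suffix(scores$accession), scores$accession)
  out <- scores[ord, , drop = FALSE]
  class(out) <- c("isoform_scores", class(tibble::tibble()))
  attr(out, "winner") <- out$accession[1]
  out
}

#' Winning isoform of a ranked score table
#'
#' @param scores An `isoform_scores` tibble.
#' @return The winner's accession.
#' @export
winning_isoform <- function(scores) attr(scores, "winner")
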