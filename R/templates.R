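# Template catalog handling: reading per-gene catalogs, identity/resolution
# filtering, and greedy selection of the minimal template set that covers
# the most target sequence.

#' Read a per-gene template catalog
#'
#' Catalogs are tab-separated text files with a header line and columns
#' `template_id`, `chain`, `resolution`, `sequence`; `resolution` may be
#' `NA` (e.g. NMR models). The structure identifier and chain are combined
#' into the working template id (`1ABC_A`) unless the id already carries the
#' chain suffix.
#'
#' @param path Path to the catalog file.
#' @return A tibble with columns `template_id`, `chain`, `resolution`
#'   (double, `NA` allowed), `sequence`.
#' @export
read_template_catalog <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = "character")
  need <- c("template_id", "chain", "resolution", "sequence")
  if (!all(need %in% names(raw))) {
    stop("template catalog ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw[need])
  out$resolution <- suppressWarnings(as.numeric(out$resolution))
  out$sequence <- toupper(out$sequence)
  suffix <- paste0("_", out$chain)
  has_chain <- nzchar(out$chain) & !is.na(out$chain)
  needs_suffix <- has_chain & !endsWith(out$template_id, suffix)
  out$template_id[needs_suffix] <- paste0(out$template_id[needs_suffix],
                                          suffix[needs_suffix])
  bad <- !nzchar(out$sequence) | is.na(out$sequence)
  if (any(bad)) {
    warning("dropping ", sum(bad), " catalog row(s) with empty sequence",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Align every catalog template to a target sequence
#'
#' @param catalog Tibble from [read_template_catalog()].
#' @param target_seq Target isoform sequence.
#' @return The catalog with list-column `alignment`
#'   ([align_template()] results) and columns `identity_pct`,
#'   `n_identical` recomputed from the alignments.
#' @export
align_templates <- function(catalog, target_seq) {
  catalog$alignment <- purrr::map2(
    catalog$sequence, catalog$template_id,
    function(seq, id) align_template(target_seq, seq, id)
  )
  catalog$identity_pct <- purrr::map_dbl(catalog$alignment, "identity_pct")
  catalog$n_identical <- purrr::map_int(
    catalog$alignment, ~ length(.x$identical_positions)
  )
  catalog
}

#' Filter aligned templates by identity and resolution thresholds
#'
#' Keeps templates whose recomputed alignment identity is at least
#' `identity_min` percent and whose resolution, when present, is at most
#' `resolution_max` angstrom (both boundaries inclusive). Templates without
#' a resolution value pass the resolution filter but rank after resolved
#' entries. Survivors are ordered by resolution ascending, then identity
#' descending, then template id.
#'
#' @param aligned Tibble from [align_templates()].
#' @param identity_min Minimum alignment identity, percent. Default 25.
#' @param resolution_max Maximum resolution, angstrom. Default 4.5.
#' @return The filtered, ranked tibble.
#' @export
filter_templates <- function(aligned, identity_min = 25, resolution_max = 4.5) {
  stopifnot(identity_min > 0, resolution_max > 0)
  if (nrow(aligned) == 0) return(aligned)
  keep <- aligned$identity_pct >= identity_min &
    (is.na(aligned$resolution) | aligned$resolution <= resolution_max)
  out <- aligned[keep, , drop = FALSE]
  out[order(ifelse(is.na(out$resolution), Inf, out$resolution),
            -out$identity_pct, out$template_id), , drop = FALSE]
}

#' Greedy minimal template set covering the most target sequence
#'
#' Repeatedly picks the template contributing the most not-yet-covered
#' identically matched positions; ties go to the template with more
#' identical positions overall, then to the alphabetically first id.
#' Selection stops when no template adds a new position, so the union over
#' the selected set always equals the union over all templates while the
#' set stays small.
#'
#' @param target_len Length of the target isoform.
#' @param alignments List of [align_template()] results (typically the
#'   `alignment` column of a filtered catalog).
#' @return An object of class `coverage_result`: list with `selected`
#'   (tibble `template_id`, `n_new`, `intervals` list-column of tibbles
#'   `start`/`end` of newly contributed runs), `covered_positions` (sorted
#'   integer vector), `covered_aa` and `target_len`.
#' @examples
#' als <- lapply(c(A = "AD", C = "RRVLT"), function(s)
#'   align_template("ADRRVLTY", s))
#' als <- Map(function(a, id) { a$template_id <- id; a }, als, names(als))
#' select_template_set(8, als)$covered_aa
#' @export
select_template_set <- function(target_len, alignments) {
  sets <- lapply(alignments, function(a) sort(unique(a$identical_positions)))
  ids <- vapply(alignments, function(a) a$template_id, character(1))
  covered <- integer(0)
  sel_id <- character(0)
  sel_new <- integer(0)
  sel_int <- list()
  remaining <- seq_along(sets)
  while (length(remaining) > 0) {
    gain <- vapply(remaining, function(i) length(setdiff(sets[[i]], covered)), integer(1))
    if (all(gain == 0)) break
    total <- vapply(remaining, function(i) length(sets[[i]]), integer(1))
    ord <- order(-gain, -total, ids[remaining])
    pick <- remaining[ord[1]]
    new_pos <- setdiff(sets[[pick]], covered)
    covered <- sort(union(covered, sets[[pick]]))
    sel_id <- c(sel_id, ids[pick])
    sel_new <- c(sel_new, length(new_pos))
    sel_int <- c(sel_int, list(positions_to_intervals(new_pos)))
    remaining <- setdiff(remaining, pick)
  }
  structure(
    list(
      selected = tibble::tibble(
        template_id = sel_id, n_new = sel_new, intervals = sel_int
      ),
      covered_positions = covered,
      covered_aa = length(covered),
      target_len = as.integer(target_len)
    ),
    class = "coverage_result"
  )
}

#' Collapse sorted positions into maximal closed intervals
#'
#' @param positions Integer vector of 1-based positions.
#' @return Tibble with columns `start`, `end`, one row per maximal run.
#' @export
positions_to_intervals <- function(positions) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  breaks <- c(0L, which(diff(positions) > 1L), length(positions))
  tibble::tibble(
    start = positions[breaks[-length(breaks)] + 1L],
    end = positions[breaks[-1L]]
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("<coverage_result> ", x$covered_aa, "/", x$target_len,
      " residues covered by {", paste(x$selected$template_id, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}
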