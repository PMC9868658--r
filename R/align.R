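# Pairwise template-to-target alignment.
#
# Templates are aligned to each isoform with a local Smith-Waterman
# alignment (BLOSUM62, gap open 11 / gap extend 1) via
# Biostrings::pairwiseAlignment. Coverage and identity are computed from the
# identically matched columns of that alignment; ambiguity/rare residue
# codes (X, U, B, Z) can never count as identical.

ALIGN_GAP_OPEN <- 11
ALIGN_GAP_EXTEND <- 1

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# U (selenocysteine) is absent from BLOSUM62; score it as X.
scorable <- function(seq) gsub("U", "X", seq, fixed = TRUE)

#' Align a template chain to a target isoform
#'
#' Computes the optimal local alignment between a template chain sequence
#' and a target isoform under the fixed scoring scheme (BLOSUM62, gap open
#' 11, gap extend 1), and extracts the aligned position pairs and the set of
#' identically matched target positions. If no positive-scoring local
#' alignment exists the template covers nothing.
#'
#' @param target_seq Target isoform sequence (uppercase).
#' @param template_seq Template chain sequence (uppercase).
#' @param template_id Identifier carried through to the result.
#' @return An object of class `template_alignment`: list with `template_id`,
#'   `pairs` (tibble `target_pos`, `template_pos`, `target_res`,
#'   `template_res`, `identical`), `identical_positions` (integer vector of
#'   target positions), `n_aligned`, `identity_pct` (100 * identical /
#'   aligned columns), and `score`.
#' @examples
#' al <- align_template("ADRRVLTY", "RRVLT", "C")
#' al$identical_positions
#' @export
align_template <- function(target_seq, template_seq, template_id = NA_character_) {
  stopifnot(nzchar(target_seq), nzchar(template_seq))
  pa <- Biostrings::pairwiseAlignment(
    pattern = scorable(template_seq), subject = scorable(target_seq),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND
  )
  if (Biostrings::score(pa) <= 0) {
    return(empty_alignment(template_id))
  }
  gapped_template <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  gapped_target <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  if (length(gapped_target) == 0) return(empty_alignment(template_id))

  target_pos <- template_pos <- integer(length(gapped_target))
  tp <- Biostrings::start(Biostrings::subject(pa)) - 1L
  pp <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  for (k in seq_along(gapped_target)) {
    if (gapped_target[k] != "-") tp <- tp + 1L
    if (gapped_template[k] != "-") pp <- pp + 1L
    target_pos[k] <- tp
    template_pos[k] <- pp
  }
  aligned <- gapped_target != "-" & gapped_template != "-"
  # identity is judged on the original residues, not the scoring proxies
  t_res <- substring(target_seq, target_pos, target_pos)
  p_res <- substring(template_seq, template_pos, template_pos)
  pairs <- tibble::tibble(
    target_pos = target_pos[aligned],
    template_pos = template_pos[aligned],
    target_res = t_res[aligned],
    template_res = p_res[aligned]
  )
  pairs$identical <- pairs$target_res == pairs$template_res &
    pairs$target_res %in% AA_STANDARD
  n_aligned <- nrow(pairs)
  identical_positions <- pairs$target_pos[pairs$identical]
  structure(
    list(
      template_id = template_id,
      pairs = pairs,
      identical_positions = identical_positions,
      n_aligned = n_aligned,
      identity_pct = if (n_aligned > 0) 100 * length(identical_positions) / n_aligned else 0,
      score = Biostrings::score(pa)
    ),
    class = "template_alignment"
  )
}

empty_alignment <- function(template_id) {
  structure(
    list(
      template_id = template_id,
      pairs = tibble::tibble(
        target_pos = integer(), template_pos = integer(),
        target_res = character(), template_res = character(),
        identical = logical()
      ),
      identical_positions = integer(0),
      n_aligned = 0L,
      identity_pct = 0,
      score = 0
    ),
    class = "template_alignment"
  )
}

#' @export
print.template_alignment <- function(x, ...) {
  cat("<template_alignment> ", x$template_id,
      ": ", x$n_aligned, " aligned columns, ",
      length(x$identical_positions), " identical (",
      format(x$identity_pct, digits = 4), "%)\n", sep = "")
  invisible(x)
}
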