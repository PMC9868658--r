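# Amino-acid alphabets shared across modules.
#
# Sequences tolerate the ambiguity/rare codes {X, U, B, Z} on top of the 20
# standard residues, but such positions never count as identically matched in
# alignments and are not acceptable residue codes in mutation tokens.

AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

AA_EXTRA <- c("X", "U", "B", "Z")

AA_ALLOWED <- c(AA_STANDARD, AA_EXTRA)

# Three-letter -> one-letter lookup for the 20 standard residues, derived from
# Biostrings' canonical code table. Names are upper-cased three-letter codes.
aa_three_to_one <- function() {
  code <- Biostrings::AMINO_ACID_CODE[AA_STANDARD]
  stats::setNames(names(code), toupper(unname(code)))
}

#' Validate an amino-acid sequence string
#'
#' Checks that a sequence is non-empty and uses only the 20 standard
#' one-letter codes plus the tolerated extras `X`, `U`, `B`, `Z`.
#'
#' @param sequence Character scalar, amino-acid sequence (any case).
#' @return A list with `ok` (logical), `sequence` (upper-cased) and
#'   `problem` (`NA` or a short description).
#' @keywords internal
validate_aa_sequence <- function(sequence) {
  seq_up <- toupper(trimws(sequence %||% ""))
  if (is.na(seq_up) || !nzchar(seq_up)) {
    return(list(ok = FALSE, sequence = seq_up, problem = "empty sequence"))
  }
  chars <- strsplit(seq_up, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALLOWED)
  if (length(bad) > 0) {
    return(list(
      ok = FALSE, sequence = seq_up,
      problem = paste0("illegal residue code(s): ", paste(bad, collapse = ", "))
    ))
  }
  list(ok = TRUE, sequence = seq_up, problem = NA_character_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
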