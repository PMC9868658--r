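# Cleaning raw PDB text for use as modelling templates: waters, hetero
# ligands, alternate-location duplicates and non-standard residues are
# removed, and per-chain one-letter sequences are extracted from what
# remains. Input coordinate lines that survive are preserved byte-for-byte.

PDB_STANDARD_RES <- toupper(unname(Biostrings::AMINO_ACID_CODE[AA_STANDARD]))

#' Clean a PDB structure for template use
#'
#' Removes water residues (`HOH`), all `HETATM` ligand records, `ANISOU`
#' records, and `ATOM` records of residues outside the 20 standard amino
#' acids. Alternate-location duplicates keep the first altloc code
#' encountered per (chain, residue, atom name). All other record types
#' (header, remarks, `TER`, ...) pass through untouched. Coordinate lines
#' too short to carry a residue field are skipped with a warning count.
#'
#' @param pdb_text Character vector of PDB lines, or one string with
#'   embedded newlines, or a path to a PDB file.
#' @return An object of class `cleaned_structure`: list with `text`
#'   (cleaned lines), `chains` (tibble `chain`, `sequence`), `n_removed`
#'   (coordinate lines dropped) and `n_skipped` (unparseable lines).
#' @export
clean_structure_text <- function(pdb_text) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    lines <- readLines(pdb_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_het <- rec == "HETATM"
  is_anisou <- rec == "ANISOU"
  coord <- is_atom | is_het

  keep <- !coord & !is_anisou
  n_skipped <- 0L
  seen_atom <- character(0)     # chain|resno|icode|atomname, first altloc wins
  chain_res <- list()           # per chain: named residue list in order

  atom_idx <- which(coord)
  keep_atom <- logical(length(atom_idx))
  for (j in seq_along(atom_idx)) {
    i <- atom_idx[j]
    line <- lines[i]
    if (nchar(line) < 27) {
      n_skipped <- n_skipped + 1L
      next
    }
    resname <- trimws(substr(line, 18, 20))
    if (is_het[i] || resname == "HOH" || !(resname %in% PDB_STANDARD_RES)) next
    atomname <- substr(line, 13, 16)
    chain <- substr(line, 22, 22)
    resno <- substr(line, 23, 26)
    icode <- substr(line, 27, 27)
    atom_key <- paste(chain, resno, icode, atomname, sep = "|")
    if (atom_key %in% seen_atom) next  # alternate location duplicate
    seen_atom <- c(seen_atom, atom_key)
    keep_atom[j] <- TRUE
    res_key <- paste(resno, icode, sep = "|")
    if (is.null(chain_res[[chain]])) chain_res[[chain]] <- character(0)
    if (!res_key %in% names(chain_res[[chain]])) {
      chain_res[[chain]][res_key] <- resname
    }
  }
  keep[atom_idx[keep_atom]] <- TRUE
  if (n_skipped > 0) {
    warning(n_skipped, " unparseable coordinate line(s) skipped", call. = FALSE)
  }

  three_to_one <- stats::setNames(AA_STANDARD, PDB_STANDARD_RES)
  chains <- tibble::tibble(
    chain = names(chain_res) %||% character(0),
    sequence = vapply(chain_res, function(res)
      paste(three_to_one[unname(res)], collapse = ""), character(1),
      USE.NAMES = FALSE)
  )
  structure(
    list(
      text = lines[keep],
      chains = chains,
      n_removed = sum(coord) - sum(keep_atom),
      n_skipped = n_skipped
    ),
    class = "cleaned_structure"
  )
}

#' @export
print.cleaned_structure <- function(x, ...) {
  cat("<cleaned_structure> ", length(x$text), " lines kept, ",
      x$n_removed, " coordinate lines removed\n", sep = "")
  for (i in seq_len(nrow(x$chains))) {
    cat("  chain ", x$chains$chain[i], ": ",
        nchar(x$chains$sequence[i]), " residues\n", sep = "")
  }
  invisible(x)
}
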