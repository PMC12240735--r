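#' The 20 canonical amino acids, one-letter codes
#'
#' Alphabetical vector of the natural amino-acid alphabet used throughout
#' the package. All peptides are validated against it.
#'
#' @export
amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate and canonicalise a peptide sequence
#'
#' Uppercases the input and checks that every residue belongs to the
#' 20-letter natural amino-acid alphabet. Errors name the offending
#' character and its position.
#'
#' @param text A single string of one-letter residue codes,
#'   e.g. `"HMTEVVRHC"` (residues 168-176 of the p53 R175H neoantigen).
#' @return The validated, uppercase sequence (character scalar).
#' @examples
#' parse_peptide("hmtevvrhc")
#' @export
parse_peptide <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single, non-missing string.")
  }
  seq <- toupper(trimws(text))
  if (!nzchar(seq)) {
    abort("Peptide sequence is empty.")
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% amino_acids)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-canonical residue '%s' at position %d of '%s'.",
      res[bad[1]], bad[1], seq
    ))
  }
  seq
}

# Vectorised residue split for validated peptides.
peptide_residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Format a mutant code
#'
#' Canonical single-site mutant notation `<from><position><to>`, e.g.
#' `"V5I"`. Positions are 1-based, matching standard mutation
#' nomenclature such as R175H.
#'
#' @param from_res,to_res One-letter residue codes.
#' @param position 1-based position on the parent peptide.
#' @return Character vector of codes.
#' @export
format_mutant_code <- function(from_res, position, to_res) {
  paste0(from_res, position, to_res)
}

#' Parse mutant codes against a parent peptide
#'
#' Validates codes like `"V5I"` against `parent`: the position must lie
#' on the peptide, the from-residue must match the parent at that
#' position, and the substitution must actually change the residue.
#'
#' @param code Character vector of mutant codes.
#' @param parent Parent peptide sequence (validated with
#'   [parse_peptide()]).
#' @return A mutant tibble with columns `parent`, `position`,
#'   `from_res`, `to_res`, `code`, `sequence`.
#' @export
parse_mutant_code <- function(code, parent) {
  parent <- parse_peptide(parent)
  m <- regmatches(code, regexec("^([A-Ya-y])([0-9]+)([A-Ya-y])$", code))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(sprintf("Malformed mutant code '%s'.", code[which(bad)[1]]))
  }
  from_res <- toupper(vapply(m, `[`, "", 2L))
  position <- as.integer(vapply(m, `[`, "", 3L))
  to_res <- toupper(vapply(m, `[`, "", 4L))
  res <- peptide_residues(parent)
  if (any(position < 1L | position > length(res))) {
    abort(sprintf(
      "Mutant position out of range for a %d-mer parent.", length(res)
    ))
  }
  mismatch <- from_res != res[position]
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    abort(sprintf(
      "Code '%s': parent has '%s' at position %d, not '%s'.",
      code[i], res[position[i]], position[i], from_res[i]
    ))
  }
  if (any(!to_res %in% amino_acids)) {
    abort("Substituted residue outside the canonical alphabet.")
  }
  if (any(to_res == from_res)) {
    abort("Identity substitutions are not valid mutants.")
  }
  new_mutant_tbl(parent, position, from_res, to_res)
}

# Assemble the canonical mutant tibble; `sequence` is the mutated peptide.
new_mutant_tbl <- function(parent, position, from_res, to_res) {
  res0 <- peptide_residues(parent)
  sequence <- vapply(seq_along(position), function(i) {
    res <- res0
    res[position[i]] <- to_res[i]
    paste(res, collapse = "")
  }, character(1))
  tibble(
    parent = rep(parent, length(position)),
    position = as.integer(position),
    from_res = as.character(from_res),
    to_res = as.character(to_res),
    code = format_mutant_code(as.character(from_res), as.integer(position),
                              as.character(to_res)),
    sequence = sequence
  )
}

#' Enumerate all single-site mutants of a peptide
#'
#' Every substitution of every position by each of the 19 alternative
#' residues, in canonical order (position ascending, then substituted
#' residue alphabetical). A 9-mer such as HMTEVVRHC yields
#' 9 x 19 = 171 mutants, the exhaustive single-site space screened for
#' mimotopes.
#'
#' @inheritParams parse_mutant_code
#' @return A mutant tibble (see [parse_mutant_code()]) with
#'   `19 * nchar(parent)` rows.
#' @examples
#' nrow(enumerate_single_mutants("HMTEVVRHC")) # 171
#' @export
enumerate_single_mutants <- function(parent) {
  parent <- parse_peptide(parent)
  res <- peptide_residues(parent)
  grid <- tidyr::expand_grid(
    position = seq_along(res),
    to_res = amino_acids
  )
  grid <- dplyr::mutate(grid, from_res = res[.data$position])
  grid <- dplyr::filter(grid, .data$to_res != .data$from_res)
  new_mutant_tbl(parent, grid$position, grid$from_res, grid$to_res)
}

#' Alanine scan of a peptide
#'
#' One X-to-A mutant per position whose wild-type residue is not already
#' alanine; the classic breadth-first mutagenesis pattern.
#'
#' @inheritParams parse_mutant_code
#' @return A mutant tibble, position ascending (possibly 0 rows).
#' @export
alanine_scan <- function(parent) {
  parent <- parse_peptide(parent)
  res <- peptide_residues(parent)
  keep <- which(res != "A")
  new_mutant_tbl(parent, keep, res[keep], rep("A", length(keep)))
}

#' X-scan the neighbourhood of a candidate mutant
#'
#' Substitutes the candidate's mutated residue X at positions within
#' `breadth` of the candidate position (both directions, clipped at the
#' termini), skipping the candidate position itself and any position
#' whose wild-type residue already equals X. This is the breadth
#' component of the DFS+Bn acquisition strategy.
#'
#' @param parent Parent peptide sequence.
#' @param candidate_code Mutant code of the depth-first candidate,
#'   e.g. `"V5I"`.
#' @param breadth Non-negative integer: how many neighbouring positions
#'   on each side to scan.
#' @return A mutant tibble in canonical order; empty when `breadth = 0`.
#' @export
x_scan_neighborhood <- function(parent, candidate_code, breadth) {
  parent <- parse_peptide(parent)
  stopifnot(length(breadth) == 1L, breadth >= 0)
  cand <- parse_mutant_code(candidate_code, parent)
  res <- peptide_residues(parent)
  pos <- setdiff(
    seq_along(res)[abs(seq_along(res) - cand$position) <= breadth],
    cand$position
  )
  pos <- pos[res[pos] != cand$to_res]
  if (length(pos) == 0L) {
    return(new_mutant_tbl(parent, integer(0), character(0), character(0)))
  }
  pos <- sort(pos)
  new_mutant_tbl(parent, pos, res[pos], rep(cand$to_res, length(pos)))
}

#' Read peptides from FASTA or a plain sequence list
#'
#' FASTA records are read with Biostrings (descriptions ignored); plain
#' files are one sequence per line. Every sequence is validated.
#'
#' @param path File path.
#' @param format `"auto"` (sniff a leading `>`), `"fasta"`, or
#'   `"lines"`.
#' @return Character vector of validated peptide sequences.
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "lines"
  }
  seqs <- if (format == "fasta") {
    as.character(Biostrings::readAAStringSet(path))
  } else {
    l <- readLines(path)
    l[nzchar(trimws(l))]
  }
  vapply(unname(seqs), parse_peptide, character(1), USE.NAMES = FALSE)
}
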