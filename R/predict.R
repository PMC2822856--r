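# 9-mer binding-core scanning.
#
# MHC class II peptides (typically 13-25 residues) bind via a 9-residue
# core; the register is not known in advance, so every length-9 window of a
# peptide is scored against the matrix and the highest-scoring window is
# reported as the predicted core.

#' Find the best-scoring 9-mer binding core of a peptide
#'
#' Scores every length-9 window of `peptide` as the sum of matrix values at
#' positions 1-9 and returns the maximum; ties are broken by the smallest
#' (leftmost) offset.
#'
#' @param peptide one-letter amino-acid string, length >= 9.
#' @param matrix an `mhc_pssm` (see [load_matrix()]).
#' @return list with `peptide`, `core`, `offset` (0-based start of the core
#'   within the peptide), `score` and `matrix` (allele/source label).
#' @examples
#' best_core("PKYVKQNTLKLAT", load_matrix("contact_dr0101"))
#' @export
best_core <- function(peptide, matrix) {
  peptide <- toupper(peptide)
  if (nchar(peptide) < 9L) stop("peptide shorter than 9 residues")
  ch <- pep_chars(peptide)
  ai <- match(ch, AA1)
  if (anyNA(ai)) {
    stop(sprintf("non-standard residue '%s' in peptide",
                 ch[which(is.na(ai))[1]]))
  }
  m <- unclass(matrix)
  n <- length(ch) - 8L
  scores <- vapply(seq_len(n), function(o) {
    sum(m[cbind(ai[o:(o + 8L)], 1:9)])
  }, numeric(1))
  o <- which.max(scores)   # ties resolved to the leftmost window
  list(peptide = peptide, core = substr(peptide, o, o + 8L),
       offset = o - 1L, score = scores[o],
       matrix = matrix_label(matrix))
}

matrix_label <- function(matrix) {
  lab <- attr(matrix, "source")
  if (is.na(lab) || lab == "") lab <- attr(matrix, "allele")
  if (is.na(lab) || lab == "") lab <- "pssm"
  lab
}

#' Batch best-core prediction
#'
#' Applies [best_core()] to every peptide, preserving input order. Invalid
#' peptides (too short, or containing non-standard residues) are routed to a
#' rejects table with a reason instead of aborting the batch.
#'
#' @param peptides character vector of one-letter peptides.
#' @param matrix an `mhc_pssm`.
#' @return list with `results` (data frame: `peptide`, `core`, `offset`,
#'   `score`, `matrix`) and `rejects` (data frame: `peptide`, `reason`).
#'   Errors if no peptide is valid.
#' @export
predict_batch <- function(peptides, matrix) {
  peptides <- toupper(peptides)
  reason <- rep(NA_character_, length(peptides))
  reason[nchar(peptides) < 9L] <- "too short"
  bad <- is.na(reason) & !vapply(peptides, is_valid_peptide, logical(1))
  reason[bad] <- "non-standard residue"
  ok <- is.na(reason)
  if (!any(ok)) stop("no valid peptides in input")
  if (any(!ok)) {
    warning(sprintf("%d peptide(s) rejected", sum(!ok)))
  }
  rows <- lapply(peptides[ok], best_core, matrix = matrix)
  results <- data.frame(
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    core = vapply(rows, `[[`, character(1), "core"),
    offset = vapply(rows, `[[`, integer(1), "offset"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    matrix = vapply(rows, `[[`, character(1), "matrix"),
    stringsAsFactors = FALSE)
  rejects <- data.frame(peptide = peptides[!ok], reason = reason[!ok],
                        stringsAsFactors = FALSE)
  list(results = results, rejects = rejects)
}

#' Read peptides from a plain-text or FASTA file
#'
#' Plain text: one peptide per line (blank lines and `#` comments ignored).
#' FASTA (first non-blank line starts with `>`): parsed with Biostrings.
#'
#' @param path input file.
#' @return character vector of peptide sequences.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no peptides in input")
  if (startsWith(lines[1], ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA input requires the Biostrings package")
    }
    seqs <- Biostrings::readAAStringSet(path)
    return(as.character(seqs, use.names = FALSE))
  }
  lines
}
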