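# Amino-acid alphabets and conversions shared by all modules.

#' Standard amino-acid codes
#'
#' Three-letter codes for the 20 standard amino acids, in the row order used
#' by the packaged scoring matrices (glutamate before glutamine), together
#' with the matching one-letter codes.
#'
#' @format `AA3` and `AA1` are character vectors of length 20.
#' @export
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' @rdname AA3
#' @export
AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes (`aa_1to3`: one-letter; `aa_3to1`:
#'   three-letter).
#' @return character vector of the converted codes; unknown codes give `NA`.
#' @examples
#' aa_1to3(c("A", "W"))
#' aa_3to1("LYS")
#' @export
aa_1to3 <- function(x) AA3[match(toupper(x), AA1)]

#' @rdname aa_1to3
#' @export
aa_3to1 <- function(x) AA1[match(toupper(x), AA3)]

# Integer index (1..20) of a three-letter code; NA for non-standard residues.
aa_index <- function(x) match(toupper(x), AA3)

# Split a one-letter peptide string into a character vector.
pep_chars <- function(peptide) strsplit(peptide, "", fixed = TRUE)[[1]]

# TRUE if every character of the peptide is a standard one-letter code.
is_valid_peptide <- function(peptide) {
  ch <- pep_chars(toupper(peptide))
  length(ch) > 0L && all(ch %in% AA1)
}
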