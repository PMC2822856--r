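# Position-specific scoring matrices (20 amino acids x 9 core positions).
#
# Contact-derived matrices score amino acid s at core position i as
# ln(p(i,s) + r), where p is a contact-based enrichment and r = 0.05 guards
# against underflow at p = 0 (every unobserved cell therefore equals
# ln(0.05) = -3.00 at two decimals). Two packaged matrices for HLA-DRB1*0101
# ship with the package: a contact-map matrix ("contact_dr0101") and a
# molecular-dynamics free-energy matrix ("md_dr0101", kcal/mol relative to
# alanine; positive = favourable). Both are scanned by maximising the
# 9-position sum.

new_pssm <- function(scores, allele = NA_character_, source = NA_character_,
                     r = NA_real_) {
  stopifnot(is.matrix(scores), nrow(scores) == 20L, ncol(scores) == 9L,
            all(is.finite(scores)))
  rownames(scores) <- AA3
  colnames(scores) <- as.character(1:9)
  structure(scores, class = c("mhc_pssm", "matrix"),
            allele = allele, source = source, r = r)
}

#' @export
print.mhc_pssm <- function(x, ...) {
  cat(sprintf("mhc_pssm: allele=%s source=%s r=%s\n",
              attr(x, "allele"), attr(x, "source"),
              format(attr(x, "r"))))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Build a PSSM from the contacts of a single peptide:MHC complex
#'
#' With one structure, the probability of amino acid s at core position i is
#' `p(i,s) = N(s,i) / w` for the amino acid observed at i (zero for all
#' others), where N(s,i) is the residue's contact count and the free
#' parameter w is the average number of contacts per core residue. Scores
#' are `ln(p + r)`.
#'
#' @param cc a `contact_counts` built from exactly one structure.
#' @param r underflow constant added to every probability.
#' @param allele optional allele label stored in the matrix metadata.
#' @return an `mhc_pssm`.
#' @export
build_pssm_single <- function(cc, r = 0.05, allele = NA_character_) {
  stopifnot(inherits(cc, "contact_counts"))
  if (cc$n_structures != 1L) stop("contact counts must come from one structure")
  if (!is.finite(cc$w) || cc$w <= 0) stop("no contacts observed (w = 0)")
  p <- matrix(0, 20, 9, dimnames = list(AA3, NULL))
  ai <- match(cc$core_aa[1, ], AA1)
  p[cbind(ai, 1:9)] <- cc$N_mat[1, ] / cc$w
  new_pssm(log(p + r), allele = allele, source = "contact_map_single", r = r)
}

#' Build a PSSM from the contacts of several peptide:MHC complexes
#'
#' With multiple structures, `p(i,s)` is the product of a frequency term
#' `Q(i,s) / sum_{s' in E(i)} Q(i,s')` (how often s occupies position i
#' across the cores) and an enrichment term `N_av(s,i) / N_av` (its mean
#' contact count relative to the grand mean over all core residues). Amino
#' acids never seen at a position score `ln(r)`.
#'
#' @param cc a `contact_counts` from at least two structures.
#' @inheritParams build_pssm_single
#' @return an `mhc_pssm`.
#' @export
build_pssm_multi <- function(cc, r = 0.05, allele = NA_character_) {
  stopifnot(inherits(cc, "contact_counts"))
  if (cc$n_structures < 2L) stop("need at least two structures")
  if (cc$N_av <= 0) stop("no contacts observed (N_av = 0)")
  p <- matrix(0, 20, 9, dimnames = list(AA3, NULL))
  for (i in 1:9) {
    qsum <- sum(cc$Q[, i])
    obs <- which(cc$Q[, i] > 0)
    p[obs, i] <- (cc$Q[obs, i] / qsum) * (cc$N_av_si[obs, i] / cc$N_av)
  }
  new_pssm(log(p + r), allele = allele, source = "contact_map_multi", r = r)
}

#' Load a packaged or on-disk scoring matrix
#'
#' Two matrices for HLA-DRB1*0101 ship with the package:
#' \describe{
#'   \item{`"contact_dr0101"`}{contact-map PSSM (natural-log units) derived
#'     from six crystal structures of peptide:HLA-DRB1*0101 complexes.}
#'   \item{`"md_dr0101"`}{binding free-energy differences relative to alanine
#'     (kcal/mol) from MM-PBSA evaluation of molecular-dynamics snapshots;
#'     positive values favour binding.}
#' }
#' Any other value is treated as a file path in the package's matrix TSV
#' format.
#'
#' @param name packaged matrix name or path.
#' @return an `mhc_pssm`.
#' @examples
#' m <- load_matrix("contact_dr0101")
#' m["TYR", 1]
#' @export
load_matrix <- function(name) {
  packaged <- c(contact_dr0101 = "matrix_contact_dr0101.tsv",
                md_dr0101 = "matrix_md_dr0101.tsv")
  if (name %in% names(packaged)) {
    path <- system.file("extdata", packaged[[name]], package = "mhc2struct",
                        mustWork = TRUE)
  } else if (file.exists(name)) {
    path <- name
  } else {
    stop(sprintf("unknown matrix '%s'; packaged matrices: %s", name,
                 paste(names(packaged), collapse = ", ")))
  }
  read_pssm(path)
}

#' Write / read a PSSM in the package's TSV format
#'
#' First column: three-letter amino acid; columns 1-9: positions; values
#' serialised at two decimals. Header comment lines `#allele=`, `#source=`
#' and `#r=` carry the metadata.
#'
#' @param pssm an `mhc_pssm`.
#' @param path file path.
#' @return `read_pssm` returns an `mhc_pssm`.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#allele=%s", attr(pssm, "allele")),
               sprintf("#source=%s", attr(pssm, "source")),
               sprintf("#r=%s", format(attr(pssm, "r"))),
               paste(c("aa", 1:9), collapse = "\t")), con)
  for (a in AA3) {
    writeLines(paste(c(a, sprintf("%.2f", unclass(pssm)[a, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  getp <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(h) == 0L) return(NA_character_)
    sub(paste0("#", key, "="), "", h[1], fixed = TRUE)
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) != 20L || ncol(tab) != 10L) {
    stop(sprintf("'%s' is not a 20x9 matrix file", path))
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- toupper(tab[[1]])
  if (!setequal(rownames(m), AA3)) {
    stop(sprintf("'%s' does not cover the 20 standard amino acids", path))
  }
  m <- m[AA3, , drop = FALSE]
  storage.mode(m) <- "double"
  r <- suppressWarnings(as.numeric(getp("r")))
  new_pssm(m, allele = getp("allele"), source = getp("source"), r = r)
}
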