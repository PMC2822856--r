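# Peptide-MHC atomic contact detection and per-core-position tabulation.
#
# Four counting schemas are supported, mirroring the usual choices for
# crystal-structure contact analysis:
#   dist4        any heavy-atom pair within 4.0 A
#   hb           hydrogen bonds only (N/O donor-acceptor heavy atoms <= 3.5 A;
#                no angular term, since hydrogens are absent from X-ray data)
#   hb_vdw       hydrogen bonds + van der Waals overlaps
#                (d <= r_vdw(a) + r_vdw(b) + 0.5 A, Bondi radii)
#   hb_vdw_phob  hb_vdw + hydrophobic carbon-carbon pairs within 4.5 A
# An atom pair is counted once no matter how many interaction types it
# satisfies. The geometric thresholds are this package's own calibration
# (config-exposed), chosen to be structurally standard.

#' Default contact-detection parameters
#'
#' @param dist4 distance threshold (Angstrom) for the plain-distance schema.
#' @param hb donor-acceptor heavy-atom distance threshold for hydrogen bonds.
#' @param vdw_slack tolerance added to the sum of van der Waals radii.
#' @param phob carbon-carbon distance threshold for hydrophobic contacts.
#' @param radii named vector of van der Waals radii (Angstrom) by element.
#' @return list of parameters consumed by [find_contacts()].
#' @export
contact_params <- function(dist4 = 4.0, hb = 3.5, vdw_slack = 0.5,
                           phob = 4.5,
                           radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)) {
  list(dist4 = dist4, hb = hb, vdw_slack = vdw_slack, phob = phob,
       radii = radii)
}

CONTACT_SCHEMAS <- list(
  dist4        = "dist4",
  hb           = "hb",
  hb_vdw       = c("hb", "vdw"),
  hb_vdw_phob  = c("hb", "vdw", "phob")
)

#' Detect peptide-MHC atomic contacts
#'
#' Evaluates every peptide-atom x MHC-atom pair (heavy atoms only) against
#' the chosen schema's criteria and records each qualifying pair exactly
#' once, together with the interaction types it satisfies.
#'
#' @param x an `mhc_structure`.
#' @param peptide_chain chain identifier of the peptide.
#' @param mhc_chains chain identifiers of the MHC molecule.
#' @param schema one of `"dist4"`, `"hb"`, `"hb_vdw"`, `"hb_vdw_phob"`.
#' @param params parameter list from [contact_params()].
#' @return object of class `contact_set`: list with
#'   \describe{
#'     \item{pairs}{data frame of qualifying atom pairs (`pep_atom`,
#'       `mhc_atom` row indices into the structure's atom table, peptide
#'       residue identifiers, `dist`, `types`).}
#'     \item{per_residue}{data frame over all peptide residues (`resno`,
#'       `insert`, `resid`, `n_contacts`).}
#'     \item{peptide_seq}{one-letter peptide sequence.}
#'     \item{schema}{the schema used.}
#'   }
#' @export
find_contacts <- function(x, peptide_chain, mhc_chains,
                          schema = c("hb_vdw_phob", "dist4", "hb", "hb_vdw"),
                          params = contact_params()) {
  schema <- match.arg(tolower(schema[1]),
                      c("hb_vdw_phob", "dist4", "hb", "hb_vdw"))
  types <- CONTACT_SCHEMAS[[schema]]
  at <- x$atom
  pep <- which(at$chain == peptide_chain)
  mhc <- which(at$chain %in% mhc_chains)
  if (length(pep) == 0L) stop(sprintf("peptide chain '%s' not found",
                                      peptide_chain))
  if (length(mhc) == 0L) stop("no MHC chain atoms found")

  pxyz <- as.matrix(at[pep, c("x", "y", "z")])
  mxyz <- as.matrix(at[mhc, c("x", "y", "z")])
  d2 <- outer(rowSums(pxyz^2), rowSums(mxyz^2), "+") - 2 * pxyz %*% t(mxyz)
  d <- sqrt(pmax(d2, 0))

  pe <- at$elesy[pep]; me <- at$elesy[mhc]
  hit <- matrix(FALSE, length(pep), length(mhc))
  tlab <- matrix("", length(pep), length(mhc))
  add <- function(mask, label) {
    tlab[mask] <<- ifelse(tlab[mask] == "", label,
                          paste(tlab[mask], label, sep = "+"))
    hit <<- hit | mask
  }
  if ("dist4" %in% types) add(d <= params$dist4, "dist4")
  if ("hb" %in% types) {
    dono <- pe %in% c("N", "O")
    acce <- me %in% c("N", "O")
    add(outer(dono, acce, "&") & d <= params$hb, "hb")
  }
  if ("vdw" %in% types) {
    rp <- params$radii[pe]; rm_ <- params$radii[me]
    rp[is.na(rp)] <- 1.8; rm_[is.na(rm_)] <- 1.8
    thr <- outer(as.numeric(rp), as.numeric(rm_), "+") + params$vdw_slack
    add(d <= thr, "vdw")
  }
  if ("phob" %in% types) {
    add(outer(pe == "C", me == "C", "&") & d <= params$phob, "phob")
  }

  sel <- which(hit, arr.ind = TRUE)
  pairs <- data.frame(
    pep_atom = pep[sel[, 1]], mhc_atom = mhc[sel[, 2]],
    pep_resno = at$resno[pep[sel[, 1]]],
    pep_insert = at$insert[pep[sel[, 1]]],
    pep_resid = at$resid[pep[sel[, 1]]],
    dist = d[sel], types = tlab[sel],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$pep_atom, pairs$mhc_atom), , drop = FALSE]
  rownames(pairs) <- NULL

  pat <- at[pep, , drop = FALSE]
  rkey <- paste(pat$resno, pat$insert, sep = "\r")
  res <- pat[!duplicated(rkey), c("resno", "insert", "resid")]
  rownames(res) <- NULL
  pk <- paste(pairs$pep_resno, pairs$pep_insert, sep = "\r")
  res$n_contacts <- as.integer(table(factor(pk, levels = unique(rkey))))
  structure(list(pairs = pairs, per_residue = res,
                 peptide_seq = paste(aa_3to1(res$resid), collapse = ""),
                 schema = schema),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set (%s): %d atom pairs over %d peptide residues\n",
              x$schema, nrow(x$pairs), nrow(x$per_residue)))
  invisible(x)
}

#' Aggregate per-core-position contact counts across complexes
#'
#' Maps each structure's 9-mer binding core onto its peptide chain (leftmost
#' sequence match) and tabulates, per core position i and amino acid s, how
#' many atomic contacts the core residues make. Houses the quantities used
#' for PSSM construction: Q(i,s), the number of cores with s at i; N(s,i)
#' and its across-structure mean; the grand mean contacts per core residue;
#' and the per-position sets of observed amino acids.
#'
#' @param contact_sets list of `contact_set` objects (one per complex).
#' @param cores character vector of 9-mer core sequences (one-letter), one
#'   per contact set.
#' @return object of class `contact_counts`: list with `n_structures`,
#'   `cores`, `core_aa` (structures x 9 one-letter matrix), `N_mat`
#'   (structures x 9 contact counts), `Q` (20 x 9), `N_av_si` (20 x 9),
#'   `N_av` (grand mean), `E` (list of observed amino acids per position),
#'   `w` (average contacts per residue; single-structure case).
#' @export
count_core_contacts <- function(contact_sets, cores) {
  if (length(contact_sets) != length(cores) || length(cores) == 0L) {
    stop("need one core sequence per contact set")
  }
  if (any(nchar(cores) != 9L)) stop("all cores must be 9-mers")
  ns <- length(cores)
  core_aa <- matrix("", ns, 9)
  N_mat <- matrix(0, ns, 9)
  for (s in seq_len(ns)) {
    cs <- contact_sets[[s]]
    off <- regexpr(toupper(cores[s]), cs$peptide_seq, fixed = TRUE)
    if (off < 0) {
      stop(sprintf("core '%s' is not a substring of peptide '%s'",
                   cores[s], cs$peptide_seq))
    }
    idx <- off:(off + 8L)
    core_aa[s, ] <- pep_chars(toupper(cores[s]))
    N_mat[s, ] <- cs$per_residue$n_contacts[idx]
  }
  Q <- matrix(0L, 20, 9, dimnames = list(AA3, NULL))
  N_av_si <- matrix(0, 20, 9, dimnames = list(AA3, NULL))
  for (i in 1:9) {
    ai <- match(core_aa[, i], AA1)
    Q[, i] <- tabulate(ai, nbins = 20L)
    for (a in unique(ai)) {
      N_av_si[a, i] <- mean(N_mat[ai == a, i])
    }
  }
  E <- lapply(1:9, function(i) AA3[Q[, i] > 0])
  structure(list(n_structures = ns, cores = toupper(cores),
                 core_aa = core_aa, N_mat = N_mat, Q = Q,
                 N_av_si = N_av_si, N_av = mean(N_mat), E = E,
                 w = if (ns == 1L) mean(N_mat[1, ]) else NA_real_),
            class = "contact_counts")
}

#' Write / read per-core-position contact counts as TSV
#'
#' One structure per file: columns `position`, `aa` (one-letter) and `count`.
#'
#' @param cc a `contact_counts` built from a single structure, or the output
#'   of [find_contacts()] combined with a core via [count_core_contacts()].
#' @param path file path.
#' @param structure for `write_contact_counts` with multi-structure input,
#'   which structure to write.
#' @return `read_contact_counts` returns a one-row core/count list suitable
#'   for [combine_contact_counts()].
#' @export
write_contact_counts <- function(cc, path, structure = 1L) {
  stopifnot(inherits(cc, "contact_counts"))
  tab <- data.frame(position = 1:9, aa = cc$core_aa[structure, ],
                    count = cc$N_mat[structure, ])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_counts
#' @export
read_contact_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("position", "aa", "count") %in% names(tab)) ||
      nrow(tab) != 9L) {
    stop(sprintf("'%s' is not a 9-position contact count table", path))
  }
  tab <- tab[order(tab$position), ]
  list(core = paste(tab$aa, collapse = ""), counts = tab$count)
}

#' Combine single-structure count tables into a `contact_counts` object
#'
#' @param entries list of `list(core =, counts =)` entries as returned by
#'   [read_contact_counts()].
#' @return a `contact_counts` object covering all entries.
#' @export
combine_contact_counts <- function(entries) {
  ns <- length(entries)
  if (ns == 0L) stop("no contact count entries")
  cores <- vapply(entries, function(e) e$core, character(1))
  sets <- lapply(entries, function(e) {
    res <- data.frame(resno = 1:9, insert = "",
                      resid = aa_1to3(pep_chars(e$core)),
                      n_contacts = as.integer(e$counts))
    structure(list(pairs = NULL, per_residue = res,
                   peptide_seq = toupper(e$core), schema = "precomputed"),
              class = "contact_set")
  })
  count_core_contacts(sets, cores)
}
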