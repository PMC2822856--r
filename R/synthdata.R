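# Seeded generators for synthetic test inputs: toy peptide:MHC complexes in
# PDB format with exactly controlled contact counts, training sets of
# centroid chains for pair-potential derivation, and affinity datasets with
# a known expected AUC. These stand in for crystal structures and benchmark
# data so that every part of the package is testable offline; they are
# geometrically idealised, not physically relaxed.

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1.00, b = 0.00, element = substr(name, 1, 1)) {
  # wwPDB fixed columns: name 13-16 (short names start at 14), resName
  # 18-20, chainID 22, resSeq 23-26, coordinates 31-54, element 77-78
  namef <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namef, resid, chain, resno, xyz[1], xyz[2], xyz[3],
          occ, b, element)
}

# ~uniformly distributed unit vectors (golden-spiral construction)
unit_sphere_grid <- function(n = 240) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Specification of a synthetic toy peptide:MHC complex
#'
#' @param peptide one-letter peptide sequence (9-16 residues).
#' @param contacts integer vector, one entry per peptide residue: the exact
#'   number of MHC pseudo-atoms to place within 4 Angstrom of that residue
#'   (each touching only the residue's alpha carbon).
#' @param peptide_chain,mhc_chain,scaffold_chain chain identifiers.
#' @param sigma per-residue Gaussian positional noise (Angstrom).
#' @param seed random seed recorded in the emitted REMARK header.
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(peptide, contacts = rep(2L, nchar(peptide)),
                             peptide_chain = "C", mhc_chain = "A",
                             scaffold_chain = "B", sigma = 0, seed = 1L) {
  peptide <- toupper(peptide)
  if (!is_valid_peptide(peptide)) stop("invalid peptide sequence")
  if (nchar(peptide) < 9L || nchar(peptide) > 16L) {
    stop("peptide must be 9-16 residues")
  }
  if (length(contacts) != nchar(peptide) || any(contacts < 0)) {
    stop("contacts must be one non-negative count per residue")
  }
  structure(list(peptide = peptide, contacts = as.integer(contacts),
                 peptide_chain = peptide_chain, mhc_chain = mhc_chain,
                 scaffold_chain = scaffold_chain, sigma = sigma,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Generate a toy peptide:MHC complex as PDB text
#'
#' Builds a peptide chain with idealised backbones (residues spaced 12
#' Angstrom apart so that contact geometry is unambiguous) and an MHC chain
#' of pseudo-atoms placed so that, under the plain 4-Angstrom contact schema,
#' each peptide residue participates in exactly the requested number of
#' atom pairs; all other MHC atoms (including a distant scaffold chain) stay
#' at least 6 Angstrom away. Output is deterministic for a fixed spec.
#'
#' @param spec a [toy_complex_spec()].
#' @return single character string of PDB-format text.
#' @examples
#' pdb <- make_toy_complex(toy_complex_spec("YVKQNTLKL", contacts = 0:8))
#' cs <- find_contacts(read_structure(pdb), "C", c("A", "B"), "dist4")
#' cs$per_residue$n_contacts
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(spec$seed)
  nres <- nchar(spec$peptide)
  aa3 <- aa_1to3(pep_chars(spec$peptide))

  # backbone template offsets relative to the residue base point
  offs <- list(N = c(-1.20, 0.86, 0), CA = c(0, 0, 0), C = c(1.31, 0.78, 0),
               O = c(1.25, 2.01, 0), CB = c(-0.54, -1.42, 0))
  res_atoms <- vector("list", nres)
  for (i in seq_len(nres)) {
    base <- c(12 * (i - 1), 0, 0) + stats::rnorm(3, 0, spec$sigma)
    names_i <- c("N", "CA", "C", "O", if (aa3[i] != "GLY") "CB")
    res_atoms[[i]] <- t(vapply(names_i, function(nm) base + offs[[nm]],
                               numeric(3)))
  }
  all_pep <- do.call(rbind, res_atoms)

  # MHC pseudo-atoms: for residue i, `contacts[i]` atoms at 3.4 A from its
  # backbone O (the residue's most exposed atom), each >= 4.2 A from the
  # residue's other atoms and >= 6 A from every other residue, so each
  # placed atom forms exactly one sub-4-Angstrom pair
  dirs <- unit_sphere_grid()
  mhc_xyz <- NULL
  for (i in seq_len(nres)) {
    need <- spec$contacts[i]
    if (need == 0L) next
    anchor <- res_atoms[[i]]["O", ]
    cand <- sweep(3.4 * dirs, 2, anchor, "+")
    ok <- rep(TRUE, nrow(cand))
    for (j in seq_len(nres)) {
      dj <- sqrt(pmax(outer(rowSums(cand^2), rowSums(res_atoms[[j]]^2), "+") -
                        2 * cand %*% t(res_atoms[[j]]), 0))
      lim <- if (j == i) 4.2 else 6.0
      near <- dj < lim
      if (j == i) near[, rownames(res_atoms[[j]]) == "O"] <- FALSE
      ok <- ok & rowSums(near) == 0
    }
    if (sum(ok) < need) {
      stop(sprintf("infeasible contact request for residue %d (%d placeable)",
                   i, sum(ok)))
    }
    mhc_xyz <- rbind(mhc_xyz, cand[which(ok)[seq_len(need)], , drop = FALSE])
  }

  lines <- c("REMARK 999 SYNTHETIC TOY PEPTIDE:MHC COMPLEX",
             sprintf("REMARK 999 SEED %d", spec$seed))
  serial <- 0L
  emit <- function(name, resid, chain, resno, xyz) {
    serial <<- serial + 1L
    lines <<- c(lines, pdb_atom_line(serial, name, resid, chain, resno, xyz))
  }
  for (i in seq_len(nres)) {
    for (nm in rownames(res_atoms[[i]])) {
      emit(nm, aa3[i], spec$peptide_chain, i, res_atoms[[i]][nm, ])
    }
  }
  lines <- c(lines, "TER")
  if (!is.null(mhc_xyz)) {
    for (k in seq_len(nrow(mhc_xyz))) {
      emit("CA", "GLY", spec$mhc_chain, k, mhc_xyz[k, ])
    }
    lines <- c(lines, "TER")
  }
  # distant scaffold so the MHC side always has more than one chain
  for (k in 1:3) {
    base <- c(12 * (k - 1), 0, -30)
    for (nm in c("N", "CA", "C", "O")) {
      emit(nm, "GLY", spec$scaffold_chain, k, base + offs[[nm]])
    }
  }
  lines <- c(lines, "TER", "END")
  paste(lines, collapse = "\n")
}

#' Generate a synthetic training set for pair-potential derivation
#'
#' Emits chains whose residue centroids are placed uniformly at random in a
#' sphere (radius scaled to keep constant density across the length range
#' 300-460, typical of single-chain globular training structures) with sequences drawn independently of geometry --
#' the null model under which the derived potential tends to zero. With
#' `type_dependent = TRUE`, residue pairs closer than `enrich_below`
#' Angstrom are relabelled to the designated amino-acid pair with
#' probability `(enrichment - 1) / 199`, which enriches that pair
#' `enrichment`-fold at short range relative to the 1/200 background rate,
#' so the derived potential recovers a well of depth `-ln(enrichment)`.
#'
#' @param n_structures number of chains.
#' @param type_dependent enrich a short-range amino-acid pair signal?
#' @param seed random seed.
#' @param length_range chain length range (residues).
#' @param enrichment fold enrichment of the designated pair at short range.
#' @param enrich_pair the enriched pair (three-letter codes).
#' @param enrich_below short-range zone (Angstrom).
#' @param separation_min minimum sequence separation of relabelled pairs,
#'   matching the counting filter.
#' @param format `"model"` returns `centroid_model` objects (scheme CM);
#'   `"pdb"` returns PDB-format text with a side-chain placeholder atom at
#'   each centroid.
#' @return list of centroid models or PDB text strings.
#' @export
make_potential_training_set <- function(n_structures, type_dependent = FALSE,
                                        seed = 1L,
                                        length_range = c(300, 460),
                                        enrichment = 2,
                                        enrich_pair = c("LYS", "ASP"),
                                        enrich_below = 5,
                                        separation_min = 10,
                                        format = c("model", "pdb")) {
  if (n_structures < 1L) stop("n_structures must be >= 1")
  format <- match.arg(format)
  set.seed(seed)
  pi_relabel <- (enrichment - 1) / 199

  out <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    L <- sample(length_range[1]:length_range[2], 1L)
    R <- 15 * (L / 400)^(1 / 3)            # constant residue density
    pts <- matrix(numeric(0), 0, 3)
    while (nrow(pts) < L) {
      cand <- matrix(stats::runif(3 * 2 * L, -R, R), ncol = 3)
      cand <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts <- pts[seq_len(L), , drop = FALSE]
    seqs <- sample(AA3, L, replace = TRUE)

    if (type_dependent) {
      d <- as.matrix(stats::dist(pts))
      ut <- which(upper.tri(d))
      ii <- ((ut - 1L) %% L) + 1L
      jj <- ((ut - 1L) %/% L) + 1L
      sep_ok <- abs(ii - jj) >= separation_min
      short <- sep_ok & d[ut] < enrich_below
      counted <- sep_ok & d[ut] < 20       # calibration matches the default
                                           # counting range
      # choose the per-pair conversion probability so that the expected
      # short-range rate of the enriched pair is `enrichment` times its
      # overall rate, accounting for the short pairs' own contribution to
      # the overall rate
      b <- 2 / 400                         # background unordered-pair rate
      f <- sum(short) / max(1L, sum(counted))
      s_target <- enrichment * (1 - f) * b / (1 - enrichment * f)
      pr <- max(0, min(1, (s_target - b) / (1 - b)))
      sel <- which(short)[stats::runif(sum(short)) < pr]
      assigned <- logical(L)
      for (q in sel) {
        # assign the pair, swapping types with random carriers elsewhere so
        # that the chain's amino-acid composition is preserved; carriers are
        # never taken from positions already holding an enriched assignment
        for (side in 1:2) {
          pos <- if (side == 1L) ii[q] else jj[q]
          want <- enrich_pair[side]
          if (seqs[pos] != want) {
            carriers <- which(seqs == want & !assigned)
            carriers <- carriers[!(carriers %in% c(ii[q], jj[q]))]
            if (length(carriers) > 0L) {
              k <- carriers[sample.int(length(carriers), 1L)]
              seqs[k] <- seqs[pos]
            }
            seqs[pos] <- want
          }
        }
        assigned[ii[q]] <- assigned[jj[q]] <- TRUE
      }
    }

    m <- data.frame(chain = "A", resno = seq_len(L), insert = "",
                    resid = seqs, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    stringsAsFactors = FALSE)
    model <- structure(m, class = c("centroid_model", "data.frame"),
                       scheme = "CM")
    out[[s]] <- if (format == "model") model else {
      centroid_model_pdb(model, seed = seed)
    }
  }
  out
}

# Emit a centroid model as PDB text: idealised backbone plus a CB
# placeholder at the centroid (so CM reduction recovers the centroid).
centroid_model_pdb <- function(model, seed = NA) {
  ca_off <- c(0.878, 0.878, 0.878)        # 1.52 A from the centroid
  lines <- c("REMARK 999 SYNTHETIC TRAINING CHAIN",
             sprintf("REMARK 999 SEED %s", seed))
  serial <- 0L
  for (i in seq_len(nrow(model))) {
    cen <- c(model$x[i], model$y[i], model$z[i])
    ca <- cen + ca_off
    at <- list(N = ca + c(-1.20, 0.86, 0), CA = ca, C = ca + c(1.31, 0.78, 0),
               O = ca + c(1.25, 2.01, 0), CB = cen)
    for (nm in names(at)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, nm, model$resid[i],
                                      model$chain[i], model$resno[i],
                                      at[[nm]]))
    }
  }
  paste(c(lines, "TER", "END"), collapse = "\n")
}

#' Generate a synthetic affinity dataset with known expected AUC
#'
#' Scores of binders and non-binders are drawn from unit-variance Gaussians
#' separated by `separation`, so the expected AUC is
#' `pnorm(separation / sqrt(2))` (see [binormal_auc()]). IC50 values are
#' placed strictly below (binders) or at/above (non-binders) the threshold.
#'
#' @param n_pos,n_neg class sizes.
#' @param separation difference of the class score means.
#' @param seed random seed.
#' @param threshold binder IC50 threshold in nM.
#' @return data frame with columns `peptide`, `ic50_nM`, `label` (logical),
#'   `score`.
#' @export
make_affinity_dataset <- function(n_pos, n_neg, separation = 1, seed = 1L,
                                  threshold = 1000) {
  if (n_pos < 1L || n_neg < 1L) stop("class sizes must be >= 1")
  set.seed(seed)
  n <- n_pos + n_neg
  label <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  score <- stats::rnorm(n, mean = ifelse(label, separation, 0), sd = 1)
  ic50 <- ifelse(label,
                 exp(stats::runif(n, log(1), log(threshold * 0.999))),
                 exp(stats::runif(n, log(threshold), log(50 * threshold))))
  peptide <- vapply(seq_len(n), function(i) {
    paste(sample(AA1, 15, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(peptide = peptide, ic50_nM = ic50, label = label, score = score,
             stringsAsFactors = FALSE)
}

#' Expected AUC of the binormal model
#'
#' For class scores N(d, 1) vs N(0, 1) the AUC is `pnorm(d / sqrt(2))`.
#'
#' @param separation mean difference d.
#' @return expected AUC.
#' @export
binormal_auc <- function(separation) stats::pnorm(separation / sqrt(2))
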