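# Structure input and reduced (centroid) representations.
#
# Parsing is delegated to bio3d::read.pdb; on top of it this module applies
# the filtering rules used throughout the package: water, hetero groups,
# hydrogens and non-standard residues are dropped, alternate locations are
# resolved by occupancy, and multi-model files are either collapsed to the
# first model (default) or kept as trajectory frames.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read a protein structure from PDB text or file
#'
#' Parses PDB-format input and retains only heavy atoms of the 20 standard
#' amino acids. For residues with alternate locations, the highest-occupancy
#' atom is kept (ties broken in favour of altloc `"A"`, then alphabetically).
#' By default only the first MODEL is retained; with `trajectory = TRUE` all
#' models are kept as coordinate frames (the package's container for
#' molecular-dynamics snapshots).
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format text
#'   (either one string with embedded newlines or one element per line).
#' @param trajectory logical; keep all MODEL blocks as frames?
#' @return an object of class `mhc_structure`: a list with elements
#'   \describe{
#'     \item{atom}{data frame with one row per retained atom: `chain`,
#'       `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `o`.}
#'     \item{xyz}{numeric matrix of coordinates, one row per frame and three
#'       columns (x, y, z) per atom, in atom-table order.}
#'     \item{nframes}{number of coordinate frames.}
#'   }
#' @examples
#' pdb <- make_toy_complex(toy_complex_spec("YVKQNTLKL", contacts = rep(2, 9)))
#' s <- read_structure(pdb)
#' structure_chains(s)
#' @export
read_structure <- function(pdb, trajectory = FALSE) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (!any(startsWith(lines, "ATOM"))) {
    stop("no ATOM records found in PDB input")
  }
  bad <- which(startsWith(lines, "ATOM") & nchar(lines) < 54L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed ATOM record at line %d: '%s'", bad[1],
                 lines[bad[1]]))
  }

  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path), add = TRUE)
  writeLines(lines, path)
  p <- bio3d::read.pdb(path, multi = trajectory, rm.alt = FALSE,
                       verbose = FALSE)

  at <- p$atom
  at$row <- seq_len(nrow(at))
  keep <- at$type == "ATOM" & toupper(at$resid) %in% AA3
  # drop hydrogens / deuterium by element symbol, falling back to atom name
  ele <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                        sub("^[0-9]*([A-Za-z]).*", "\\1", at$elety),
                        trimws(at$elesy)))
  keep <- keep & !(ele %in% c("H", "D"))
  at$elesy <- ele
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard amino-acid atoms retained from input")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc resolution: per (chain, residue, atom name) keep the
  # highest-occupancy copy; ties prefer altloc "A", then alphabetical.
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  pref <- order(key, -at$o, at$alt != "A", at$alt)
  at <- at[pref, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  # residue ordering within a chain: number, then insertion code
  at <- at[order(at$chain, at$resno, at$insert, at$row), , drop = FALSE]

  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z))) {
    stop("non-finite coordinates in ATOM records")
  }

  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- bio3d::atom2xyz(at$row)
  xyz <- xyz[, cols, drop = FALSE]
  if (!trajectory) xyz <- xyz[1, , drop = FALSE]
  # frame 1 coordinates mirror the atom table
  at$x <- xyz[1, seq(1, ncol(xyz), 3)]
  at$y <- xyz[1, seq(2, ncol(xyz), 3)]
  at$z <- xyz[1, seq(3, ncol(xyz), 3)]

  atom <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                     resid = toupper(at$resid), elety = at$elety,
                     elesy = at$elesy, x = at$x, y = at$y, z = at$z,
                     o = at$o, stringsAsFactors = FALSE)
  structure(list(atom = atom, xyz = xyz, nframes = nrow(xyz)),
            class = "mhc_structure")
}

#' @export
print.mhc_structure <- function(x, ...) {
  cat(sprintf("mhc_structure: %d atoms, %d residues, chains [%s], %d frame(s)\n",
              nrow(x$atom), nrow(unique(x$atom[c("chain", "resno", "insert")])),
              paste(structure_chains(x), collapse = ","), x$nframes))
  invisible(x)
}

#' Chains and sequences of a structure
#'
#' @param x an `mhc_structure`.
#' @param chain chain identifier (for `chain_sequence`).
#' @return `structure_chains`: the chain identifiers present;
#'   `chain_sequence`: the chain's one-letter amino-acid sequence.
#' @export
structure_chains <- function(x) unique(x$atom$chain)

#' @rdname structure_chains
#' @export
chain_sequence <- function(x, chain) {
  at <- x$atom[x$atom$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("chain '%s' not found", chain))
  res <- at[!duplicated(paste(at$resno, at$insert, sep = "\r")), , drop = FALSE]
  paste(aa_3to1(res$resid), collapse = "")
}

# Coordinates of frame i as an n_atoms x 3 matrix.
frame_coords <- function(x, i = 1) {
  if (i < 1 || i > x$nframes) stop("frame index out of range")
  matrix(x$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Construct a virtual beta carbon
#'
#' Places an idealised C-beta 1.522 Angstrom from the alpha carbon, making
#' equal (~110.5 degree) angles with the N-CA and C-CA bonds, on the side of
#' the backbone plane that gives an L-amino-acid configuration. Used for
#' glycine (which has no side chain) and as a fallback for residues with
#' missing side-chain atoms.
#'
#' @param n,ca,c numeric length-3 coordinates of backbone N, CA and C.
#' @param bond_length CA-CB distance in Angstrom.
#' @return numeric length-3 coordinates of the virtual C-beta.
#' @export
virtual_cbeta <- function(n, ca, c, bond_length = 1.522) {
  u1 <- n - ca; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c - ca; u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) stop("degenerate backbone geometry (N, CA, C collinear)")
  bis <- bis / nb
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  np <- sqrt(sum(perp^2))
  if (np < 1e-8) stop("degenerate backbone geometry (N, CA, C collinear)")
  perp <- perp / np
  # direction making the target angle with both u1 and u2
  target <- 110.5 * pi / 180
  half <- sum(u1 * bis)                 # cos of half the N-CA-C angle
  cg <- min(1, max(-1, -cos(target) / half))
  sg <- sqrt(max(0, 1 - cg^2))
  dir <- -bis * cg + perp * sg
  ca + bond_length * dir / sqrt(sum(dir^2))
}

#' Reduce a structure to one interaction centre per residue
#'
#' Builds the reduced representation used by the statistical pair potential:
#' each residue is represented by a single centroid under one of three
#' schemes -- `"CA"` (alpha carbon), `"CB"` (beta carbon, virtual for
#' glycine) or `"CM"` (unweighted mean of the heavy side-chain atoms; for
#' alanine this is the C-beta itself, and glycine falls back to the virtual
#' C-beta).
#'
#' @param x an `mhc_structure` (first frame is used).
#' @param scheme `"CA"`, `"CB"` or `"CM"`.
#' @return an object of class `centroid_model`: a data frame with columns
#'   `chain`, `resno`, `insert`, `resid`, `x`, `y`, `z` and attribute
#'   `scheme`.
#' @examples
#' pdb <- make_toy_complex(toy_complex_spec("YVKQNTLKL", contacts = rep(0, 9)))
#' cm <- reduce_structure(read_structure(pdb), "CM")
#' @export
reduce_structure <- function(x, scheme = c("CM", "CA", "CB")) {
  scheme <- toupper(match.arg(toupper(scheme)[1], c("CM", "CA", "CB")))
  at <- x$atom
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  idx <- split(seq_len(nrow(at)), factor(rkey, levels = unique(rkey)))

  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    rows <- idx[[j]]
    sub <- at[rows, , drop = FALSE]
    label <- sprintf("%s %s%d%s", sub$resid[1], sub$chain[1], sub$resno[1],
                     sub$insert[1])
    co <- function(name) {
      k <- which(sub$elety == name)
      if (length(k) == 0L) {
        stop(sprintf("missing backbone atom %s in residue %s", name, label))
      }
      c(sub$x[k[1]], sub$y[k[1]], sub$z[k[1]])
    }
    cen <- switch(scheme,
      CA = co("CA"),
      CB = {
        k <- which(sub$elety == "CB")
        if (length(k) == 1L) {
          c(sub$x[k], sub$y[k], sub$z[k])
        } else {
          if (sub$resid[1] != "GLY") {
            warning(sprintf("residue %s has no CB; using virtual C-beta",
                            label))
          }
          virtual_cbeta(co("N"), co("CA"), co("C"))
        }
      },
      CM = {
        side <- which(!(sub$elety %in% BACKBONE_ATOMS))
        if (length(side) > 0L) {
          c(mean(sub$x[side]), mean(sub$y[side]), mean(sub$z[side]))
        } else {
          if (sub$resid[1] != "GLY") {
            warning(sprintf(
              "residue %s has no side-chain atoms; using virtual C-beta",
              label))
          }
          virtual_cbeta(co("N"), co("CA"), co("C"))
        }
      })
    out[[j]] <- data.frame(chain = sub$chain[1], resno = sub$resno[1],
                           insert = sub$insert[1], resid = sub$resid[1],
                           x = cen[1], y = cen[2], z = cen[3],
                           stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, out)
  rownames(m) <- NULL
  structure(m, class = c("centroid_model", "data.frame"), scheme = scheme)
}

centroid_scheme <- function(m) attr(m, "scheme")

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that superpose point set `a`
#' onto point set `b` with minimum root-mean-square deviation.
#'
#' @param a,b numeric n x 3 coordinate matrices with matching rows, n >= 3.
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length 3)
#'   and `rmsd`; the fitted coordinates are `a %*% rotation + translation`
#'   (translation recycled across rows).
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' superpose(a, a)$rmsd
#' @export
superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L) {
    stop("coordinate sets must be n x 3 matrices of equal size")
  }
  if (nrow(a) < 3L) stop("at least 3 points are required")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite coordinates")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("degenerate point sets")
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cb - ca %*% R), rmsd = rmsd)
}

# Backbone (CA/C/N/O) atom selection of one chain set, as row indices.
backbone_rows <- function(x, chains = NULL) {
  at <- x$atom
  sel <- at$elety %in% c("CA", "C", "N", "O")
  if (!is.null(chains)) sel <- sel & at$chain %in% chains
  which(sel)
}

#' Per-frame backbone RMSD of a trajectory against a reference
#'
#' Each frame's backbone (CA, C, N, O) atoms are rigidly superposed onto the
#' reference structure's backbone and the post-fit RMSD is reported, as used
#' to follow the drift of a molecular-dynamics trajectory from its starting
#' structure.
#'
#' @param ref an `mhc_structure` (frame 1 used as reference).
#' @param traj an `mhc_structure` read with `trajectory = TRUE`.
#' @param chains optional chain subset; atoms are matched by
#'   (chain, residue, atom name) between reference and trajectory.
#' @return data frame with columns `frame` and `rmsd`.
#' @export
trajectory_rmsd <- function(ref, traj, chains = NULL) {
  rref <- backbone_rows(ref, chains)
  rtrj <- backbone_rows(traj, chains)
  kref <- with(ref$atom[rref, ], paste(chain, resno, insert, elety, sep = "\r"))
  ktrj <- with(traj$atom[rtrj, ], paste(chain, resno, insert, elety, sep = "\r"))
  common <- intersect(kref, ktrj)
  if (length(common) < 3L) stop("fewer than 3 matching backbone atoms")
  ia <- rref[match(common, kref)]
  ib <- rtrj[match(common, ktrj)]
  refxyz <- frame_coords(ref, 1)[ia, , drop = FALSE]
  out <- data.frame(frame = seq_len(traj$nframes), rmsd = NA_real_)
  for (f in seq_len(traj$nframes)) {
    out$rmsd[f] <- superpose(frame_coords(traj, f)[ib, , drop = FALSE],
                             refxyz)$rmsd
  }
  out
}

#' Per-residue backbone RMSF across trajectory frames
#'
#' For each residue, the root-mean-square fluctuation of its backbone atoms
#' (CA, C, N, O) about their across-frame mean positions, averaged over the
#' atoms. Frames must already be superposed onto a common reference --
#' residual rigid-body motion inflates the fluctuations.
#'
#' @param traj an `mhc_structure` with at least two frames.
#' @param chains optional chain subset.
#' @return data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `rmsf` (Angstrom).
#' @export
backbone_rmsf <- function(traj, chains = NULL) {
  if (traj$nframes < 2L) stop("at least two frames are required")
  rows <- backbone_rows(traj, chains)
  if (length(rows) == 0L) stop("no backbone atoms in selection")
  at <- traj$atom[rows, , drop = FALSE]
  # per-atom fluctuation: sqrt of mean squared distance to the mean position
  fl <- numeric(length(rows))
  for (j in seq_along(rows)) {
    cols <- (rows[j] - 1L) * 3L + 1:3
    xyz <- traj$xyz[, cols, drop = FALSE]
    mu <- colMeans(xyz)
    fl[j] <- sqrt(mean(rowSums(sweep(xyz, 2, mu)^2)))
  }
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  agg <- tapply(fl, factor(key, levels = unique(key)), mean)
  res <- at[!duplicated(key), c("chain", "resno", "insert", "resid")]
  rownames(res) <- NULL
  res$rmsf <- as.numeric(agg)
  res
}
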