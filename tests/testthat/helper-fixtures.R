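# Shared fixtures and independent oracles used across the test files.

# --- minimal hand-written PDB text -----------------------------------------

pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1.00, alt = " ", element = substr(name, 1, 1)) {
  namef <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namef, alt, resid, chain, resno, x, y, z, occ, 0, element)
}

# a two-residue (ALA, GLY) single-chain toy structure
toy_two_residue_pdb <- function() {
  paste(c(
    pdb_line(1, "N",  "ALA", "A", 1, 0.0, 1.4, 0.0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.2, 0.6, 0.0),
    pdb_line(3, "C",  "ALA", "A", 1, 2.4, 1.4, 0.0),
    pdb_line(4, "O",  "ALA", "A", 1, 2.5, 2.6, 0.0),
    pdb_line(5, "CB", "ALA", "A", 1, 1.2, -0.5, 1.2),
    pdb_line(6, "N",  "GLY", "A", 2, 3.5, 0.8, 0.0),
    pdb_line(7, "CA", "GLY", "A", 2, 4.8, 1.4, 0.0),
    pdb_line(8, "C",  "GLY", "A", 2, 6.0, 0.6, 0.0),
    pdb_line(9, "O",  "GLY", "A", 2, 6.1, -0.6, 0.0),
    "END"), collapse = "\n")
}

# wrap one or more coordinate variants of the same atoms into MODEL blocks
multi_model_pdb <- function(frames_atom_lines) {
  blocks <- lapply(seq_along(frames_atom_lines), function(i) {
    c(sprintf("MODEL     %4d", i), frames_atom_lines[[i]], "ENDMDL")
  })
  paste(c(unlist(blocks), "END"), collapse = "\n")
}

# atom lines for a simple n-residue backbone, optionally displaced
backbone_lines <- function(n = 5, shift = c(0, 0, 0), jitter = NULL,
                           chain = "A", resid = "ALA") {
  serial <- 0
  lines <- character(0)
  offs <- list(N = c(-1.2, 0.86, 0), CA = c(0, 0, 0), C = c(1.31, 0.78, 0),
               O = c(1.25, 2.01, 0))
  for (i in seq_len(n)) {
    base <- c(4 * (i - 1), 0, 0) + shift
    for (nm in names(offs)) {
      serial <- serial + 1
      p <- base + offs[[nm]]
      if (!is.null(jitter)) p <- p + jitter(serial)
      lines <- c(lines, pdb_line(serial, nm, resid, chain, i,
                                 p[1], p[2], p[3]))
    }
  }
  lines
}

# --- centroid models built directly (bypassing PDB parsing) ----------------

make_centroid_model <- function(resid, xyz, chain = "A", scheme = "CM",
                                resno = seq_along(resid)) {
  m <- data.frame(chain = chain, resno = resno, insert = "", resid = resid,
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  stringsAsFactors = FALSE)
  structure(m, class = c("centroid_model", "data.frame"), scheme = scheme)
}

# --- independent oracles ----------------------------------------------------

# quadratic-time Mann-Whitney AUC (ties credited 0.5)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# naive window enumeration for best-core scanning
best_core_oracle <- function(peptide, m) {
  ch <- strsplit(peptide, "")[[1]]
  best <- -Inf; besto <- NA
  for (o in 1:(length(ch) - 8)) {
    sc <- 0
    for (i in 1:9) sc <- sc + unclass(m)[aa_1to3(ch[o + i - 1]), i]
    if (sc > best) { best <- sc; besto <- o }
  }
  list(offset = besto - 1L, score = best,
       core = substr(peptide, besto, besto + 8))
}

# exhaustive double-loop pair counting for count_pairs
count_pairs_oracle <- function(model, bin_width, max_distance,
                               separation_min) {
  n <- nrow(model)
  nbins <- ceiling(max_distance / bin_width)
  counts <- array(0, dim = c(20, 20, nbins))
  pos <- stats::ave(seq_len(n), model$chain, FUN = seq_along)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same <- model$chain[i] == model$chain[j]
    if (same && abs(pos[i] - pos[j]) < separation_min) next
    d <- sqrt(sum((c(model$x[i], model$y[i], model$z[i]) -
                     c(model$x[j], model$y[j], model$z[j]))^2))
    if (d >= max_distance) next
    k <- floor(d / bin_width) + 1
    a <- match(model$resid[i], AA3); b <- match(model$resid[j], AA3)
    counts[a, b, k] <- counts[a, b, k] + 1
    if (a != b) counts[b, a, k] <- counts[b, a, k] + 1
  }
  counts
}

# exhaustive double-loop complex scoring
score_complex_oracle <- function(pep, mhc, pot, cutoff) {
  total <- 0; npairs <- 0
  for (i in seq_len(nrow(pep))) for (j in seq_len(nrow(mhc))) {
    d <- sqrt(sum((c(pep$x[i], pep$y[i], pep$z[i]) -
                     c(mhc$x[j], mhc$y[j], mhc$z[j]))^2))
    if (d > cutoff) next
    total <- total + potential_at(pot, pep$resid[i], mhc$resid[j], d)
    npairs <- npairs + 1
  }
  list(raw = total, n_pairs = npairs)
}

# brute-force rigid superposition: random axis-angle search followed by
# local refinement over the rotation vector, independent of the Kabsch path
superpose_rmsd_oracle <- function(a, b, n_try = 5000, seed = 99) {
  A <- sweep(a, 2, colMeans(a)); B <- sweep(b, 2, colMeans(b))
  rotmat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    ax <- v / th
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) sqrt(mean(rowSums((A %*% t(rotmat(v)) - B)^2)))
  set.seed(seed)
  best_v <- c(0, 0, 0); best <- obj(best_v)
  for (t in seq_len(n_try)) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2)) * stats::runif(1, 0, pi)
    r <- obj(v)
    if (r < best) { best <- r; best_v <- v }
  }
  stats::optim(best_v, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# Table 3 of peptide/core pairs used for core-recovery checks
crystal_cores <- data.frame(
  pdb = c("2FSE", "1KLG", "1SJE", "1AQD", "1T5W", "2G9H"),
  peptide = c("AGFKGEQGPKGEPG", "GELIGILNAAKVPAD", "PEVIPMFSALSEGATP",
              "GSDWRFLRGYHQYA", "AAYSDQATPLLLSPR", "PKYVKQNTLKLAT"),
  core = c("FKGEQGPKG", "IGILNAAKV", "VIPMFSALS", "WRFLRGYHQ",
           "YSDQATPLL", "YVKQNTLKL"),
  stringsAsFactors = FALSE)

random_peptide <- function(len) paste(sample(AA1, len, TRUE), collapse = "")
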