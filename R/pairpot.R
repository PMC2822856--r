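# Distance-dependent statistical pair potential.
#
# The potential is a knowledge-based pseudo-energy: for amino-acid pair
# (a, b) and distance bin k,
#
#   u(a, b, k) = -ln[ P_obs(k | a, b) / P_exp(k) ]
#
# where P_obs is the binned distance distribution of (a, b) centroid pairs
# observed in a training set of structures and P_exp is the pooled all-pair
# distance distribution (the type-independent expectation). Negative values
# are favourable. Complexes are scored by summing u over all inter-chain
# peptide-MHC centroid pairs within a distance cutoff.

#' Count amino-acid pair observations at binned centroid distances
#'
#' Tabulates, over a set of reduced structures, how often each unordered
#' amino-acid pair (a, b) occurs with centroid distance in each bin of width
#' `bin_width` below `max_distance`. Within a chain only pairs separated by
#' at least `separation_min` positions in sequence are counted (focusing the
#' statistics on non-local interactions); pairs across different chains of
#' one structure carry no separation filter.
#'
#' @param models list of `centroid_model` objects sharing one scheme.
#' @param bin_width bin width in Angstrom.
#' @param max_distance maximum counted distance in Angstrom (exclusive).
#' @param separation_min minimum intra-chain sequence separation (default 10,
#'   i.e. separations greater than 9 are counted).
#' @return object of class `pair_count_table`: list with `counts` (20 x 20 x
#'   nbins symmetric array of unordered-pair observation counts), `bin_width`,
#'   `max_distance`, `separation_min`, `scheme`, `n_structures`.
#' @export
count_pairs <- function(models, bin_width = 0.25, max_distance = 20,
                        separation_min = 10) {
  if (length(models) == 0L) stop("empty structure list")
  if (bin_width <= 0) stop("bin_width must be positive")
  schemes <- unique(vapply(models, centroid_scheme, character(1)))
  if (length(schemes) != 1L) {
    stop("all centroid models must share one scheme; found: ",
         paste(schemes, collapse = ", "))
  }
  nbins <- as.integer(ceiling(max_distance / bin_width))
  acc <- numeric(400L * nbins)

  for (m in models) {
    n <- nrow(m)
    if (n < 2L) next
    a <- aa_index(m$resid)
    if (anyNA(a)) stop("non-standard residue in centroid model")
    # position index within each chain, in table order
    pos <- stats::ave(seq_len(n), m$chain, FUN = seq_along)
    d <- as.matrix(stats::dist(cbind(m$x, m$y, m$z)))
    ut <- which(upper.tri(d))
    i <- ((ut - 1L) %% n) + 1L
    j <- ((ut - 1L) %/% n) + 1L
    dd <- d[ut]
    same <- m$chain[i] == m$chain[j]
    ok <- dd < max_distance & (!same | abs(pos[i] - pos[j]) >= separation_min)
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]; dd <- dd[ok]
    k <- pmin(nbins, floor(dd / bin_width) + 1L)
    lo <- pmin(a[i], a[j]); hi <- pmax(a[i], a[j])
    lin <- (k - 1L) * 400L + (lo - 1L) * 20L + hi
    acc <- acc + tabulate(lin, nbins = 400L * nbins)
  }

  counts <- array(0, dim = c(20, 20, nbins),
                  dimnames = list(AA3, AA3, NULL))
  arr <- array(acc, dim = c(20, 20, nbins))   # [hi, lo, k] by lin layout
  for (k in seq_len(nbins)) {
    s <- t(arr[, , k])                        # [lo, hi]
    counts[, , k] <- s + t(s) - diag(diag(s))
  }
  structure(list(counts = counts, bin_width = bin_width,
                 max_distance = max_distance,
                 separation_min = separation_min,
                 scheme = schemes, n_structures = length(models)),
            class = "pair_count_table")
}

# Per-bin totals over unordered pair types.
bin_totals <- function(pc) {
  nbins <- dim(pc$counts)[3]
  vapply(seq_len(nbins), function(k) {
    m <- pc$counts[, , k]
    (sum(m) + sum(diag(m))) / 2
  }, numeric(1))
}

#' Derive the statistical pair potential from pair counts
#'
#' Converts observation counts to the potential
#' `u = -ln[(counts/pair_total) / (bin_total/grand_total)]` (natural log;
#' favourable interactions are negative). Bins in which a pair type was never
#' observed but other pairs were receive a repulsive cap of +3.0; bins with
#' no observations at all score 0 (no information). Bins lying wholly below
#' `steric_cutoff` store `steric_penalty`, and any query below the cutoff
#' returns the penalty regardless of binning.
#'
#' @param pc a `pair_count_table`.
#' @param steric_cutoff distance below which the steric penalty applies (Angstrom).
#' @param steric_penalty penalty value for sub-steric distances.
#' @param scoring_cutoff default interaction cutoff stored for scoring (Angstrom).
#' @param zero_obs_value value assigned to zero-observation bins.
#' @return object of class `pair_potential`: list with `u` (20 x 20 x nbins
#'   symmetric array), `bin_width`, `max_distance`, `steric_cutoff`,
#'   `steric_penalty`, `scoring_cutoff`, `scheme`, `provenance`.
#' @export
derive_potential <- function(pc, steric_cutoff = 1.0, steric_penalty = 2.0,
                             scoring_cutoff = 7.5, zero_obs_value = 3.0) {
  stopifnot(inherits(pc, "pair_count_table"))
  tot <- bin_totals(pc)
  grand <- sum(tot)
  if (grand <= 0) stop("pair count table is empty")
  nbins <- dim(pc$counts)[3]
  pair_tot <- apply(pc$counts, c(1, 2), sum)

  u <- array(0, dim = dim(pc$counts), dimnames = dimnames(pc$counts))
  pexp <- tot / grand
  for (k in seq_len(nbins)) {
    ck <- pc$counts[, , k]
    uk <- matrix(0, 20, 20)
    if (pexp[k] > 0) {
      pobs <- ck / pair_tot          # NaN where pair never observed at all
      val <- -log(pobs / pexp[k])
      zero <- !is.finite(val) | ck == 0
      val[zero] <- zero_obs_value
      uk <- val
    }
    u[, , k] <- uk
  }
  # bins wholly below the steric cutoff store the penalty
  upper_edges <- seq_len(nbins) * pc$bin_width
  u[, , upper_edges <= steric_cutoff] <- steric_penalty

  structure(list(u = u, bin_width = pc$bin_width,
                 max_distance = pc$max_distance,
                 steric_cutoff = steric_cutoff,
                 steric_penalty = steric_penalty,
                 scoring_cutoff = scoring_cutoff, scheme = pc$scheme,
                 provenance = sprintf(
                   "derived from %d structure(s), separation_min=%d",
                   pc$n_structures, pc$separation_min)),
            class = "pair_potential")
}

#' Query a pair potential at a distance
#'
#' @param pot a `pair_potential`.
#' @param a,b amino acids (three- or one-letter codes), vectorised.
#' @param d distances in Angstrom, recycled against `a`/`b`.
#' @return potential values; distances below `steric_cutoff` return the
#'   steric penalty, distances at or beyond `max_distance` return 0.
#' @export
potential_at <- function(pot, a, b, d) {
  a3 <- ifelse(nchar(a) == 1, aa_1to3(a), toupper(a))
  b3 <- ifelse(nchar(b) == 1, aa_1to3(b), toupper(b))
  ia <- aa_index(a3); ib <- aa_index(b3)
  if (anyNA(ia) || anyNA(ib)) stop("unknown amino acid code")
  n <- max(length(ia), length(ib), length(d))
  ia <- rep_len(ia, n); ib <- rep_len(ib, n); d <- rep_len(d, n)
  nbins <- dim(pot$u)[3]
  k <- pmin(nbins, floor(d / pot$bin_width) + 1L)
  val <- pot$u[cbind(ia, ib, k)]
  val[d < pot$steric_cutoff] <- pot$steric_penalty
  val[d >= pot$max_distance] <- 0
  val
}

#' Score a peptide:MHC complex with a pair potential
#'
#' Sums the potential over all inter-chain peptide-residue x MHC-residue
#' centroid pairs within `cutoff` Angstrom. The raw sum is a pseudo-energy
#' (lower = more favourable); `score` is its negation so that larger values
#' rank stronger predicted binders first.
#'
#' @param peptide,mhc `centroid_model` objects sharing the potential's scheme.
#' @param pot a `pair_potential`.
#' @param cutoff interaction distance cutoff in Angstrom (default: the
#'   potential's stored `scoring_cutoff`).
#' @return list with `raw` (summed potential), `score` (= -raw) and
#'   `n_pairs` (number of contributing pairs).
#' @export
score_complex <- function(peptide, mhc, pot, cutoff = pot$scoring_cutoff) {
  if (centroid_scheme(peptide) != pot$scheme ||
      centroid_scheme(mhc) != pot$scheme) {
    stop(sprintf("centroid scheme mismatch (potential uses %s)", pot$scheme))
  }
  pa <- aa_index(peptide$resid); ma <- aa_index(mhc$resid)
  pxyz <- cbind(peptide$x, peptide$y, peptide$z)
  mxyz <- cbind(mhc$x, mhc$y, mhc$z)
  d2 <- outer(rowSums(pxyz^2), rowSums(mxyz^2), "+") - 2 * pxyz %*% t(mxyz)
  d <- sqrt(pmax(d2, 0))
  sel <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0L) {
    return(list(raw = 0, score = 0, n_pairs = 0L))
  }
  vals <- potential_at(pot, AA3[pa[sel[, 1]]], AA3[ma[sel[, 2]]],
                       d[sel])
  list(raw = sum(vals), score = -sum(vals), n_pairs = nrow(sel))
}

#' Write / read a pair potential as TSV
#'
#' The serialisation stores one row per unordered amino-acid pair and bin,
#' with header comment lines recording the scheme, binning and penalty
#' parameters.
#'
#' @param pot a `pair_potential`.
#' @param path output / input file path.
#' @return `read_potential` returns a `pair_potential`.
#' @export
write_potential <- function(pot, path) {
  nbins <- dim(pot$u)[3]
  idx <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(nbins), function(k) {
    data.frame(aa1 = AA3[idx[, 1]], aa2 = AA3[idx[, 2]], bin_index = k - 1L,
               bin_lo = (k - 1L) * pot$bin_width,
               u = pot$u[cbind(idx[, 1], idx[, 2], k)])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#scheme=%s", pot$scheme),
               sprintf("#bin_width=%g", pot$bin_width),
               sprintf("#max_distance=%g", pot$max_distance),
               sprintf("#steric_cutoff=%g", pot$steric_cutoff),
               sprintf("#steric_penalty=%g", pot$steric_penalty),
               sprintf("#scoring_cutoff=%g", pot$scoring_cutoff),
               sprintf("#provenance=%s", pot$provenance),
               "aa1\taa2\tbin_index\tbin_lo\tu"), con)
  utils::write.table(format(rows, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  getp <- function(key, default = NA) {
    h <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(h) == 0L) return(default)
    sub(paste0("#", key, "="), "", h[1], fixed = TRUE)
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  bw <- as.numeric(getp("bin_width"))
  md <- as.numeric(getp("max_distance"))
  nbins <- as.integer(ceiling(md / bw))
  u <- array(0, dim = c(20, 20, nbins), dimnames = list(AA3, AA3, NULL))
  ia <- aa_index(tab$aa1); ib <- aa_index(tab$aa2)
  k <- tab$bin_index + 1L
  u[cbind(ia, ib, k)] <- tab$u
  u[cbind(ib, ia, k)] <- tab$u
  structure(list(u = u, bin_width = bw, max_distance = md,
                 steric_cutoff = as.numeric(getp("steric_cutoff", 1)),
                 steric_penalty = as.numeric(getp("steric_penalty", 2)),
                 scoring_cutoff = as.numeric(getp("scoring_cutoff", 7.5)),
                 scheme = getp("scheme", "CM"),
                 provenance = getp("provenance", "")),
            class = "pair_potential")
}
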