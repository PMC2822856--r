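# Binder classification and prediction-performance metrics.
#
# Peptides are classified as binders when their measured IC50 is strictly
# below a threshold (default 1000 nM; exactly-threshold counts as
# non-binder). Discrimination is summarised by the ROC curve and its AUC
# (computed as the Mann-Whitney statistic, ties credited 0.5), with the
# Hanley-McNeil closed-form standard error, and optionally by the Pearson
# correlation against log-transformed affinities.

#' Classify peptides as binders by IC50
#'
#' @param ic50 IC50 values in nM (positive).
#' @param threshold binder threshold in nM; binder iff `ic50 < threshold`.
#' @return logical vector (TRUE = binder).
#' @examples
#' classify_binder(c(999, 1000, 50000))
#' @export
classify_binder <- function(ic50, threshold = 1000) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be positive and finite")
  }
  ic50 < threshold
}

#' ROC curve and AUC
#'
#' Computes the area under the ROC curve as the normalised Mann-Whitney
#' statistic (probability that a random positive outscores a random
#' negative, ties credited 0.5), together with the tie-aware ROC points
#' obtained by sweeping the score cutoff from highest to lowest.
#'
#' @param scores numeric prediction scores (higher = predicted binder).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return object of class `mhc_eval`: list with `roc_points` (data frame
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be equal-length and complete")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes required to compute a ROC curve")
  }
  r <- rank(scores)                       # midranks handle ties at 0.5
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  last <- cumsum(rle(s)$lengths)          # one ROC point per distinct cutoff
  tpr <- cumsum(l)[last] / n_pos
  fpr <- cumsum(!l)[last] / n_neg
  structure(list(roc_points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "mhc_eval")
}

#' @export
print.mhc_eval <- function(x, ...) {
  cat(sprintf("mhc_eval: AUC = %.3f (n_pos = %d, n_neg = %d)",
              x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$se)) cat(sprintf(" +/- %.3f", x$se))
  if (!is.null(x$pcc)) cat(sprintf(", PCC = %.3f", x$pcc))
  cat("\n")
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form standard error of the area under a ROC curve given the class
#' sizes, with intermediates `Q1 = A/(2-A)` and `Q2 = 2*A^2/(1+A)`:
#' `se = sqrt([A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)] /
#' (n_pos*n_neg))`.
#'
#' @param auc area under the curve, in \[0, 1\].
#' @param n_pos,n_neg positive / negative class sizes (>= 1).
#' @return the standard error.
#' @examples
#' hanley_se(0.682, 2939, 943)
#' @export
hanley_se <- function(auc, n_pos, n_neg) {
  if (any(auc < 0 | auc > 1)) stop("auc must lie in [0, 1]")
  if (any(n_pos < 1) || any(n_neg < 1)) stop("class sizes must be >= 1")
  A <- auc
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) + (n_neg - 1) * (Q2 - A^2)) /
         (n_pos * n_neg))
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation with input validation (equal lengths >= 3,
#' non-degenerate variance), as used to relate prediction scores to
#' log-transformed binding affinities.
#'
#' @param x,y numeric vectors.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations required")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input")
  }
  stats::cor(x, y)
}

#' Transform IC50 to a normalised affinity
#'
#' The conventional immunoinformatics transform
#' `1 - log(ic50) / log(max_ic50)`, clamped to \[0, 1\]; 1 = strongest
#' binding, 0 = no measurable binding at `max_ic50` nM.
#'
#' @param ic50 IC50 values in nM.
#' @param max_ic50 normalisation constant in nM.
#' @return affinities in \[0, 1\].
#' @export
ic50_to_affinity <- function(ic50, max_ic50 = 50000) {
  if (any(ic50 <= 0)) stop("IC50 values must be positive")
  pmin(1, pmax(0, 1 - log(ic50) / log(max_ic50)))
}

#' Full evaluation of predictions against measured affinities
#'
#' Classifies binders by IC50, computes ROC/AUC, attaches the Hanley-McNeil
#' standard error and (when requested) the Pearson correlation between
#' scores and transformed affinities.
#'
#' @param scores prediction scores (higher = predicted binder).
#' @param ic50 measured IC50 values in nM.
#' @param threshold binder threshold in nM.
#' @param pcc also compute the Pearson correlation against
#'   [ic50_to_affinity()] values?
#' @param max_ic50 normalisation constant for the affinity transform.
#' @return an `mhc_eval` with elements `roc_points`, `auc`, `se`, `n_pos`,
#'   `n_neg` and optionally `pcc`.
#' @export
evaluate_predictions <- function(scores, ic50, threshold = 1000, pcc = TRUE,
                                 max_ic50 = 50000) {
  labels <- classify_binder(ic50, threshold)
  res <- roc_auc(scores, labels)
  res$se <- hanley_se(res$auc, res$n_pos, res$n_neg)
  if (isTRUE(pcc)) {
    res$pcc <- pearson(scores, ic50_to_affinity(ic50, max_ic50))
  }
  res
}

#' Read a peptide affinity table
#'
#' CSV with columns `peptide`, `ic50_nM` and optionally `score`.
#'
#' @param path input CSV.
#' @return data frame.
#' @export
read_affinity_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide", "ic50_nM")
  if (!all(need %in% names(tab))) {
    stop(sprintf("'%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  }
  tab
}
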