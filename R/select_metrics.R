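#' Largest-gap (lagged-difference) variable selection
#'
#' Ranks the inclusion probabilities in decreasing order, computes the
#' first-order lagged differences of the ranked sequence, locates the
#' largest gap, and selects every variable ranked above it. Ties in the
#' maximal gap are broken toward the earlier cut (the smaller selected
#' set). When all probabilities are equal no gap exists; an empty set is
#' returned with a warning.
#'
#' @param probs Numeric vector of inclusion probabilities (length >= 2).
#' @return Integer vector of selected indices (possibly empty).
#' @examples
#' ld_select(c(0.9, 0.85, 0.2, 0.1))  # selects the top 2
#' @export
ld_select <- function(probs) {
  p <- length(probs)
  if (p < 2) stop("need at least two probabilities")
  ord <- order(probs, decreasing = TRUE)
  ip <- probs[ord]
  gaps <- ip[-p] - ip[-1]
  if (all(gaps == 0)) {
    warning("all inclusion probabilities are equal; no gap exists")
    return(integer(0))
  }
  cut <- which.max(gaps)  # which.max takes the earliest maximal gap
  sort(ord[seq_len(cut)])
}

#' ROC curve over inclusion-probability thresholds
#'
#' Sweeps 22 thresholds — 0 together with 21 log-spaced values from
#' 1.01e-3 to 1.01 — counting variables with inclusion probability strictly
#' above each threshold as selected, and computes `TPR = TP / |truth|`,
#' `FPR = FP / (p - |truth|)` at each. The area under the curve is obtained
#' by trapezoidal integration over the achieved points augmented with the
#' (0,0) and (1,1) corners.
#'
#' @param probs Inclusion probabilities (length p).
#' @param truth Integer indices of the truly influential variables; must be
#'   nonempty and a proper subset.
#' @param thresholds Optional replacement threshold sequence.
#' @return Object of class `roc_curve` with `thresholds`, `points` (a
#'   data.frame of FPR, TPR per threshold) and `auc`.
#' @export
roc_curve <- function(probs, truth,
                      thresholds = c(0, exp(seq(log(1.01e-3), log(1.01),
                                                length.out = 21)))) {
  p <- length(probs)
  truth <- as.integer(truth)
  if (length(truth) == 0 || length(truth) >= p)
    stop("truth must be a nonempty proper subset of the variables")
  is_true <- seq_len(p) %in% truth
  tpr <- fpr <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- probs > thresholds[t]
    tpr[t] <- sum(sel & is_true) / sum(is_true)
    fpr[t] <- sum(sel & !is_true) / sum(!is_true)
  }
  pts <- unique(rbind(cbind(fpr = 0, tpr = 0), cbind(fpr, tpr),
                      cbind(fpr = 1, tpr = 1)))
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
  auc <- sum(diff(pts[, "fpr"]) *
               (head(pts[, "tpr"], -1) + pts[-1, "tpr"]) / 2)
  structure(list(thresholds = thresholds,
                 points = data.frame(threshold = thresholds, fpr = fpr,
                                     tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC over", length(x$thresholds), "thresholds; AUC =",
      signif(x$auc, 4), "\n")
  invisible(x)
}

#' F-score of a selected set
#'
#' Harmonic mean of precision (`TP / (TP + FP)`) and recall
#' (`TP / |truth|`); defined as 0 when no true positive is selected.
#'
#' @param selected Integer indices selected by an approach.
#' @param truth Nonempty integer indices of the truly influential set.
#' @return The F-score in `[0, 1]`.
#' @export
f_score <- function(selected, truth) {
  truth <- as.integer(truth)
  if (length(truth) == 0) stop("truth must be nonempty")
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  if (tp == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / length(truth)
  2 * precision * recall / (precision + recall)
}

#' Spearman rank correlation between true effects and inclusion
#' probabilities
#'
#' Rank correlation between the absolute true coefficients and the
#' inclusion probabilities, with average-rank tie handling (the
#' product-moment correlation of the rank vectors).
#'
#' @param true_beta True coefficient vector.
#' @param probs Inclusion probabilities of the same length.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rank <- function(true_beta, probs) {
  if (length(true_beta) != length(probs)) stop("length mismatch")
  if (length(probs) < 2) stop("need at least two variables")
  a <- abs(true_beta)
  if (var(a) == 0 || var(probs) == 0)
    stop("rank correlation undefined: a rank vector has zero variance")
  cor(a, probs, method = "spearman")
}

#' Evaluate one approach on one simulated dataset
#'
#' Computes the metrics record for a vector of inclusion probabilities (or
#' a plain selected set) against the simulation truth: AUC, F-score (via
#' [ld_select()] when selection is not native), Spearman rank correlation,
#' and TP/FP counts. Approaches that output only a selected set get an
#' F-score and counts, with AUC and the rank correlation recorded as `NA`.
#'
#' @param probs Inclusion probabilities, or `NULL` when only `selected` is
#'   available.
#' @param selected Optional native selected set (used instead of
#'   [ld_select()]).
#' @param truth Indices of the truly influential variables.
#' @param true_beta True coefficient vector (for the rank correlation).
#' @return A one-row `data.frame` with `auc`, `f_score`, `spearman_rho`,
#'   `tp`, `fp`.
#' @export
metrics_record <- function(probs = NULL, selected = NULL, truth,
                           true_beta = NULL) {
  p <- if (!is.null(probs)) length(probs) else length(true_beta)
  auc <- rho <- NA_real_
  if (!is.null(probs)) {
    auc <- roc_curve(probs, truth)$auc
    rho <- if (!is.null(true_beta) && var(abs(true_beta)) > 0 &&
               var(probs) > 0)
      spearman_rank(true_beta, probs) else NA_real_
    if (is.null(selected))
      selected <- suppressWarnings(ld_select(probs))
  }
  if (is.null(selected)) stop("supply probs or selected")
  data.frame(auc = auc,
             f_score = f_score(selected, truth),
             spearman_rho = rho,
             tp = length(intersect(selected, truth)),
             fp = length(setdiff(selected, truth)))
}
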