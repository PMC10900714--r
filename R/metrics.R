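## The evaluation suite: eight metrics plus a row-normalized confusion
## matrix. Conventions are pinned: threshold metrics use strictly-greater
## thresholding (a score of exactly 0.5 is a predicted non-hit); AUROC uses
## the Mann-Whitney half-credit convention for ties; AUPRC is the
## step-integrated (trapezoid-free) area, i.e. average precision; the Brier
## skill reference is the climatology predictor that always emits the
## positive base rate.

auroc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

auprc <- function(y, p) {
  n_pos <- sum(y == 1)
  if (n_pos == 0L || all(y == 1)) return(NA_real_)
  ## Process tied scores as blocks: precision/recall are only defined at
  ## distinct thresholds.
  o <- order(p, decreasing = TRUE)
  y <- y[o]; p <- p[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(p[-length(p)] != p[-1], TRUE)   # last index of each tie block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Classifier performance metrics
#'
#' Computes the eight-metric evaluation suite: sensitivity (recall),
#' specificity, precision, F1, AUROC, AUPRC, Brier score and Brier skill
#' score. Threshold metrics use predicted hits `p > threshold`. The Brier
#' skill score is `1 - Brier / Brier_ref` with `Brier_ref = pbar * (1 -
#' pbar)`, the Brier score of the base-rate (climatology) predictor, so a
#' constant prediction at the base rate scores exactly 0.
#'
#' With a single-class `y`, rank metrics (AUROC, AUPRC) and the skill score
#' are reported as `NA`; threshold metrics are still computed.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probabilities in `[0, 1]`.
#' @param threshold Decision threshold; predicted hit iff `p > threshold`.
#' @return Named list of class `metric_report` with the 8 metrics.
#' @export
compute_metrics <- function(y, p, threshold = 0.5) {
  y <- as.numeric(y); p <- as.numeric(p)
  if (length(y) != length(p)) stop_validation("y and p must have equal length")
  if (length(y) == 0L) stop_validation("empty input")
  if (!all(y %in% c(0, 1))) stop_validation("y must be binary 0/1")
  yhat <- as.numeric(p > threshold)
  tp <- sum(yhat == 1 & y == 1); fn <- sum(yhat == 0 & y == 1)
  tn <- sum(yhat == 0 & y == 0); fp <- sum(yhat == 1 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  brier <- mean((p - y)^2)
  pbar <- mean(y)
  bref <- pbar * (1 - pbar)
  bss <- if (bref > 0) 1 - brier / bref else NA_real_
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, auroc = auroc(y, p), auprc = auprc(y, p),
                 brier = brier, brier_skill = bss),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-12s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  invisible(x)
}

#' Confusion matrix with row-normalized percentages
#'
#' Rows are the true class (hit, non-hit), columns the predicted class.
#' Percentages are normalized within each true-class row and sum to 100.
#'
#' @param y True binary labels.
#' @param yhat Predicted binary labels.
#' @return List with integer `counts` and numeric `percent` 2x2 matrices.
#' @export
confusion_matrix_rownorm <- function(y, yhat) {
  if (length(y) == 0L) stop_validation("empty input")
  if (length(y) != length(yhat)) stop_validation("length mismatch")
  lv <- c(1, 0)
  counts <- matrix(0L, 2, 2,
                   dimnames = list(true = c("hit", "non_hit"),
                                   predicted = c("hit", "non_hit")))
  for (i in 1:2) for (j in 1:2)
    counts[i, j] <- sum(y == lv[i] & yhat == lv[j])
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs == 0, NA, rs) * 100
  list(counts = counts, percent = percent)
}
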