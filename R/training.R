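## Imbalance handling and cross-validation planning. Labels are a
## data.frame with columns transcript_id and hit (1 = CRISPRi hit).

check_labels <- function(labels) {
  if (!is.data.frame(labels) || !all(c("transcript_id", "hit") %in% names(labels)))
    stop_validation("labels must be a data.frame with transcript_id and hit")
  if (anyDuplicated(labels$transcript_id))
    stop_validation("duplicate transcript ids in labels")
  if (!all(labels$hit %in% c(0, 1)))
    stop_validation("hit must be 0 or 1")
  labels
}

#' Default positive-class cost weight for imbalanced training
#'
#' The cost multiplier applied to misclassified hits, defined as the class
#' ratio `n_negative / n_positive` (exact rational value; rounding is for
#' display only). For the screen-scale label set of 50,847 transcripts with
#' 911 hits this is 54.81 to two decimals.
#'
#' @param labels Label data.frame (`transcript_id`, `hit`).
#' @return Scalar weight `n_neg / n_pos`.
#' @export
default_scale_pos_weight <- function(labels) {
  check_labels(labels)
  n_pos <- sum(labels$hit == 1)
  n_neg <- sum(labels$hit == 0)
  if (n_pos == 0L) stop_validation("no positive labels: weight undefined")
  n_neg / n_pos
}

#' Random under-sampling of the majority (non-hit) class
#'
#' Keeps every positive and draws `round(n_pos / strategy)` negatives
#' uniformly, with or without replacement, so the retained set has a
#' minority:majority ratio of `strategy`. At `strategy = 0.5` with 911 hits
#' this retains 1,822 non-hits.
#'
#' @param labels Label data.frame.
#' @param strategy Target `n_pos / n_neg_retained` ratio in (0, 1].
#' @param replacement Sample negatives with replacement?
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Character vector (multiset when `replacement = TRUE`) of retained
#'   transcript ids: all positives followed by the sampled negatives.
#' @export
undersample_negatives <- function(labels, strategy, replacement = FALSE, seed = 0) {
  check_labels(labels)
  if (!is.numeric(strategy) || strategy <= 0 || strategy > 1)
    stop_validation("strategy must lie in (0, 1]")
  pos <- labels$transcript_id[labels$hit == 1]
  neg <- labels$transcript_id[labels$hit == 0]
  n_draw <- round(length(pos) / strategy)
  if (!replacement && n_draw > length(neg))
    stop_validation("cannot draw %d negatives without replacement from %d",
                    n_draw, length(neg))
  drawn <- with_seed(seed, sample(neg, n_draw, replace = replacement))
  c(pos, drawn)
}

#' Repeated stratified k-fold cross-validation plan
#'
#' Within each repeat the ids are partitioned into `k` folds preserving the
#' class proportions to within one sample per class; each fold in turn is
#' the test set (10% at the default k = 10) and the remainder the training
#' set. Three repeats with different randomizations give 30 splits.
#'
#' @param labels Label data.frame.
#' @param k Number of folds (default 10).
#' @param repeats Number of randomized repetitions (default 3).
#' @param seed Root seed; repeat `r` uses stream `seed + r - 1`.
#' @return Object of class `cv_plan`: list with `k`, `repeats`, `seed` and
#'   `splits`, each split a list of `train` / `test` id vectors plus its
#'   repeat and fold index.
#' @export
repeated_stratified_kfold <- function(labels, k = 10, repeats = 3, seed = 0) {
  check_labels(labels)
  pos <- labels$transcript_id[labels$hit == 1]
  neg <- labels$transcript_id[labels$hit == 0]
  if (length(pos) < k || length(neg) < k)
    stop_validation("each class needs at least k = %d members (have %d pos, %d neg)",
                    k, length(pos), length(neg))
  splits <- list()
  for (r in seq_len(repeats)) {
    fold_of <- with_seed(seed + r - 1L, {
      f <- c(stats::setNames(rep_len(seq_len(k), length(pos)), sample(pos)),
             stats::setNames(rep_len(seq_len(k), length(neg)), sample(neg)))
      f
    })
    for (f in seq_len(k)) {
      test <- names(fold_of)[fold_of == f]
      splits[[length(splits) + 1L]] <- list(
        train = setdiff(labels$transcript_id, test),
        test = test, repeat_idx = r, fold = f)
    }
  }
  structure(list(k = k, repeats = repeats, seed = seed, splits = splits),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation, %d repeat(s), seed %d: %d splits\n",
              x$k, x$repeats, x$seed, length(x$splits)))
  invisible(x)
}
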