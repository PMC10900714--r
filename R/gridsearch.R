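## Cross-validated evaluation and hyperparameter grid search.

mean_or_na <- function(v) { v <- v[!is.na(v)]; if (length(v)) mean(v) else NA_real_ }

metric_names <- c("sensitivity", "specificity", "precision", "f1",
                  "auroc", "auprc", "brier", "brier_skill")

#' Cross-validated metrics for one configuration
#'
#' Fits the classifier on each training split of `cv` and evaluates the
#' eight-metric suite on the corresponding held-out fold. Optional random
#' under-sampling of the majority class is applied to the training portion
#' only; test folds keep the natural imbalance.
#'
#' @param x Feature matrix with transcript rownames.
#' @param labels Label data.frame (`transcript_id`, `hit`).
#' @param config [boost_config()].
#' @param cv [repeated_stratified_kfold()] plan.
#' @param undersample Optional list `list(strategy =, replacement =)`
#'   applied per split to the training labels.
#' @param threshold Decision threshold for the threshold metrics.
#' @return List with `per_split` (data.frame, one row per split) and `mean`
#'   (named vector of split-averaged metrics).
#' @export
cross_validate <- function(x, labels, config, cv, undersample = NULL,
                           threshold = 0.5) {
  check_labels(labels)
  if (!inherits(cv, "cv_plan")) stop_validation("cv must be a cv_plan")
  lab <- stats::setNames(labels$hit, labels$transcript_id)
  rows <- lapply(seq_along(cv$splits), function(i) {
    sp <- cv$splits[[i]]
    train_ids <- sp$train
    if (!is.null(undersample)) {
      tl <- labels[labels$transcript_id %in% train_ids, , drop = FALSE]
      train_ids <- undersample_negatives(
        tl, undersample$strategy,
        replacement = isTRUE(undersample$replacement),
        seed = cv$seed + 1000L + i)
    }
    fit <- lncboost(x[train_ids, , drop = FALSE], lab[train_ids], config)
    p <- predict(fit, x[sp$test, , drop = FALSE])
    m <- compute_metrics(lab[sp$test], p, threshold)
    c(repeat_idx = sp$repeat_idx, fold = sp$fold, unlist(m))
  })
  per_split <- as.data.frame(do.call(rbind, rows))
  means <- vapply(metric_names, function(nm) mean_or_na(per_split[[nm]]), numeric(1))
  list(per_split = per_split, mean = means)
}

#' Grid search over boosted-tree configurations
#'
#' Evaluates every configuration by cross-validation and selects the one
#' maximizing the balanced criterion `mean(sensitivity, specificity)`
#' averaged over splits. Ties are broken toward the smaller
#' `scale_pos_weight`, then the earlier grid position.
#'
#' @param x Feature matrix.
#' @param labels Label data.frame.
#' @param grid List of [boost_config()] objects.
#' @param cv [repeated_stratified_kfold()] plan.
#' @param threshold Decision threshold used inside the balanced criterion.
#' @return List with `best_config`, `best_index`, and `report` — one row
#'   per configuration with its resolved `scale_pos_weight`, the eight
#'   split-averaged metrics and the `balanced` criterion.
#' @export
grid_search <- function(x, labels, grid, cv, threshold = 0.5) {
  if (!is.list(grid) || length(grid) == 0L)
    stop_validation("grid must be a non-empty list of boost_config objects")
  if (!all(vapply(grid, inherits, logical(1), "boost_config")))
    stop_validation("grid entries must be boost_config objects")
  spw_res <- vapply(grid, function(cf) {
    if (identical(cf$scale_pos_weight, "default"))
      default_scale_pos_weight(labels) else cf$scale_pos_weight
  }, numeric(1))
  evals <- lapply(grid, function(cf) cross_validate(x, labels, cf, cv,
                                                    threshold = threshold))
  report <- do.call(rbind, lapply(seq_along(grid), function(i) {
    m <- evals[[i]]$mean
    data.frame(config = i,
               scale_pos_weight = spw_res[i],
               learning_rate = grid[[i]]$learning_rate,
               max_depth = grid[[i]]$max_depth,
               t(m),
               balanced = mean(c(m["sensitivity"], m["specificity"])))
  }))
  ## argmax of balanced criterion; ties -> smaller weight, then grid order
  ord <- order(-report$balanced, report$scale_pos_weight, report$config)
  best <- ord[1]
  list(best_config = grid[[best]], best_index = best, report = report)
}
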