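## The core model: a cost-sensitive gradient-boosted tree classifier.

#' Hyperparameter configuration for the boosted-tree classifier
#'
#' Defaults are the tuned values used for genome-wide scoring: learning
#' rate 0.05, maximum depth 5, L2 regularization lambda 5.0, gamma 1.0,
#' 100 boosting rounds, base score 0.5 and seed 0. `scale_pos_weight` is
#' the cost ratio for misclassifying a hit versus a non-hit; `"default"`
#' resolves to the class ratio `n_neg / n_pos` of the training labels at
#' fit time (see [default_scale_pos_weight()]), and the tuned model uses
#' 100.
#'
#' @param learning_rate Shrinkage in (0, 1].
#' @param max_depth Maximum tree depth (>= 1).
#' @param reg_lambda L2 regularization on leaf weights.
#' @param gamma Minimum loss reduction to split.
#' @param n_trees Number of boosting rounds (>= 1).
#' @param scale_pos_weight Positive scalar or `"default"`.
#' @param base_score Initial probability guess.
#' @param seed Integer seed for the tree construction RNG.
#' @return Object of class `boost_config`.
#' @export
boost_config <- function(learning_rate = 0.05, max_depth = 5, reg_lambda = 5.0,
                         gamma = 1.0, n_trees = 100, scale_pos_weight = 100,
                         base_score = 0.5, seed = 0) {
  if (learning_rate <= 0 || learning_rate > 1)
    stop_validation("learning_rate must lie in (0, 1]")
  if (max_depth < 1 || n_trees < 1)
    stop_validation("max_depth and n_trees must be >= 1")
  if (!identical(scale_pos_weight, "default") &&
      (!is.numeric(scale_pos_weight) || scale_pos_weight <= 0))
    stop_validation("scale_pos_weight must be positive or \"default\"")
  if (base_score <= 0 || base_score >= 1)
    stop_validation("base_score must lie in (0, 1)")
  structure(list(learning_rate = learning_rate, max_depth = max_depth,
                 reg_lambda = reg_lambda, gamma = gamma, n_trees = n_trees,
                 scale_pos_weight = scale_pos_weight, base_score = base_score,
                 seed = as.integer(seed)),
            class = "boost_config")
}

#' @export
print.boost_config <- function(x, ...) {
  cat("Boosted-tree configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Fit the cost-sensitive functional-lncRNA classifier
#'
#' Trains a gradient-boosted tree ensemble on a transcript feature matrix
#' and binary hit labels with a logistic objective. Class imbalance is
#' handled by cost weighting: the loss of a misclassified positive is
#' multiplied by `scale_pos_weight`. Fitting is deterministic for fixed
#' inputs and seed (single-threaded tree construction).
#'
#' @param x Numeric feature matrix with transcript-id rownames and feature
#'   colnames (see [assemble_features()]).
#' @param y Binary labels: either a 0/1 vector aligned with `rows(x)` or a
#'   label data.frame (`transcript_id`, `hit`) matched by rowname.
#' @param config [boost_config()] object.
#' @return Object of class `lncboost`: the fitted ensemble plus the frozen
#'   feature order, resolved cost weight and class counts.
#' @seealso [predict.lncboost()], [shap_values()], [score_transcripts()]
#' @export
lncboost <- function(x, y, config = boost_config()) {
  if (!is.matrix(x) || !is.numeric(x)) stop_validation("x must be a numeric matrix")
  if (is.null(colnames(x))) stop_validation("x must have feature column names")
  if (any(!is.finite(x))) stop_validation("non-finite feature values in x")
  if (is.data.frame(y)) {
    check_labels(y)
    if (is.null(rownames(x))) stop_validation("x needs rownames to match labels")
    keep <- intersect(rownames(x), y$transcript_id)
    if (length(keep) < nrow(y))
      stop_validation("labels refer to transcripts missing from x")
    x <- x[y$transcript_id, , drop = FALSE]
    y <- y$hit
  }
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop_validation("length(y) must equal nrow(x)")
  if (!all(y %in% c(0, 1))) stop_validation("y must be binary 0/1")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop_validation("training requires both classes (have %d pos, %d neg)", n_pos, n_neg)

  spw <- config$scale_pos_weight
  if (identical(spw, "default")) spw <- n_neg / n_pos

  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(objective = "binary:logistic",
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 lambda = config$reg_lambda,
                 gamma = config$gamma,
                 scale_pos_weight = spw,
                 base_score = config$base_score,
                 nthread = 1,
                 seed = config$seed)
  booster <- xgboost::xgb.train(params, dtrain, nrounds = config$n_trees,
                                verbose = 0)
  structure(list(booster = booster,
                 feature_names = colnames(x),
                 config = config,
                 scale_pos_weight = spw,
                 n_pos = n_pos, n_neg = n_neg,
                 call = match.call()),
            class = "lncboost")
}

check_feature_alignment <- function(object, newdata) {
  if (!is.matrix(newdata)) stop_validation("newdata must be a matrix")
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names)) {
    if (!is.null(colnames(newdata)) &&
        setequal(colnames(newdata), object$feature_names))
      return(newdata[, object$feature_names, drop = FALSE])
    stop_validation("newdata columns do not match the model's features")
  }
  newdata
}

#' Predict from a fitted lncboost model
#'
#' @param object Fitted [lncboost()] model.
#' @param newdata Feature matrix with the model's columns (any order).
#' @param type `"response"` for probabilities in `[0, 1]` (the functionality
#'   score), `"margin"` for the raw additive margin (log-odds scale;
#'   `response = plogis(margin)`), or `"contrib"` for per-feature SHAP
#'   contributions plus an intercept column in margin units.
#' @param ... Unused.
#' @return Numeric vector (or matrix for `"contrib"`), named by rownames of
#'   `newdata`.
#' @export
predict.lncboost <- function(object, newdata,
                             type = c("response", "margin", "contrib"), ...) {
  type <- match.arg(type)
  newdata <- check_feature_alignment(object, newdata)
  dm <- xgboost::xgb.DMatrix(newdata, nthread = 1)
  out <- switch(type,
    response = stats::predict(object$booster, dm),
    margin = stats::predict(object$booster, dm, outputmargin = TRUE),
    contrib = stats::predict(object$booster, dm, predcontrib = TRUE))
  if (is.matrix(out)) rownames(out) <- rownames(newdata)
  else names(out) <- rownames(newdata)
  out
}

#' @export
print.lncboost <- function(x, ...) {
  cat("Cost-sensitive boosted-tree lncRNA classifier\n")
  cat(sprintf("  features: %d   training: %d hits / %d non-hits (1:%.1f)\n",
              length(x$feature_names), x$n_pos, x$n_neg, x$n_neg / x$n_pos))
  cat(sprintf("  trees: %d  depth: %d  eta: %g  lambda: %g  gamma: %g\n",
              x$config$n_trees, x$config$max_depth, x$config$learning_rate,
              x$config$reg_lambda, x$config$gamma))
  cat(sprintf("  scale_pos_weight: %.4g  seed: %d\n",
              x$scale_pos_weight, x$config$seed))
  invisible(x)
}

#' Summarize a fitted lncboost model
#'
#' Reports the configuration, class balance and (when a feature matrix is
#' supplied) the top features ranked by mean absolute SHAP contribution.
#'
#' @param object Fitted model.
#' @param x Optional feature matrix for SHAP-based importance.
#' @param top Number of features to display.
#' @param ... Unused.
#' @export
summary.lncboost <- function(object, x = NULL, top = 10, ...) {
  print(object)
  if (!is.null(x)) {
    imp <- global_importance(shap_values(object, x))
    cat(sprintf("\nTop %d features by mean |SHAP|:\n", min(top, nrow(imp))))
    print(utils::head(imp, top), row.names = FALSE)
  }
  invisible(object)
}

#' Plot SHAP feature importance for a fitted model
#'
#' Horizontal bar chart of the top features by mean absolute SHAP value
#' over the supplied feature matrix.
#'
#' @param x Fitted [lncboost()] model.
#' @param data Feature matrix to attribute over.
#' @param top Number of features to show.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.lncboost <- function(x, data, top = 20, ...) {
  imp <- global_importance(shap_values(x, data))
  imp <- utils::head(imp, top)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(imp$mean_abs_shap), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, xlab = "mean |SHAP| (margin units)",
                    main = "Feature importance", ...)
  invisible(imp)
}
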