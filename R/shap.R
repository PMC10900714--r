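## Model explanation: exact tree-SHAP attributions, global importance
## ranking, per-transcript explanation reports, and SHAP-driven recursive
## feature elimination.

#' SHAP attributions for a fitted model
#'
#' Exact tree-SHAP contributions in margin (log-odds) units. Local accuracy
#' holds for every sample: `base_value + sum(phi) == predict(margin)` up to
#' floating-point tolerance, so `plogis(base_value + rowSums(phi))`
#' reconstructs the functionality score.
#'
#' @param model Fitted [lncboost()] model.
#' @param x Feature matrix with the model's columns.
#' @return Object of class `shap_matrix`: list with `phi` (samples x
#'   features), `base_value` (expected margin), `margin` (per-sample
#'   predicted margin) and `feature_names`.
#' @export
shap_values <- function(model, x) {
  contrib <- predict(model, x, type = "contrib")
  bias_col <- ncol(contrib)
  phi <- contrib[, -bias_col, drop = FALSE]
  structure(list(phi = phi,
                 base_value = contrib[1, bias_col],
                 margin = rowSums(contrib),
                 feature_names = colnames(phi)),
            class = "shap_matrix")
}

#' Global feature importance from SHAP values
#'
#' Ranks features by the mean absolute SHAP contribution over samples,
#' descending; ties are broken lexicographically by feature name.
#'
#' @param shap A [shap_values()] result, or a bare phi matrix.
#' @return data.frame with columns `feature`, `mean_abs_shap`, in rank order.
#' @export
global_importance <- function(shap) {
  phi <- if (inherits(shap, "shap_matrix")) shap$phi else shap
  if (is.null(dim(phi)) || ncol(phi) == 0L) stop_validation("empty SHAP matrix")
  imp <- colMeans(abs(phi))
  ord <- order(-imp, colnames(phi))
  data.frame(feature = colnames(phi)[ord], mean_abs_shap = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Explain the functionality score of a single transcript
#'
#' Decomposes one transcript's score into signed per-feature SHAP
#' contributions (sorted by absolute impact) plus the base value; the
#' contributions reconcile with the score through
#' `score = plogis(base_value + sum(phi))`.
#'
#' @param model Fitted model.
#' @param x Feature matrix containing the transcript's row.
#' @param transcript_id Row name to explain.
#' @return List with `transcript_id`, `base_value`, `margin`, `score` and
#'   `contributions` (data.frame feature / value / phi, sorted by `|phi|`).
#' @export
explain_transcript <- function(model, x, transcript_id) {
  if (!transcript_id %in% rownames(x))
    stop_validation("unknown transcript id: %s", transcript_id)
  row <- x[transcript_id, , drop = FALSE]
  sv <- shap_values(model, row)
  phi <- sv$phi[1, ]
  ord <- order(-abs(phi), names(phi))
  list(transcript_id = transcript_id,
       base_value = sv$base_value,
       margin = unname(sv$margin[1]),
       score = unname(stats::plogis(sv$margin[1])),
       contributions = data.frame(feature = names(phi)[ord],
                                  value = unname(row[1, ord]),
                                  phi = unname(phi[ord]),
                                  stringsAsFactors = FALSE))
}

#' SHAP-based recursive feature elimination
#'
#' Iteratively drops the least important feature, one per iteration, where
#' importance is the mean absolute SHAP value pooled over the held-out
#' (validation) folds of a stratified cross-validation. At each step the
#' mean cross-validated sensitivity and specificity are recorded; the
#' selected feature count maximizes the balanced score
#' `mean(sensitivity, specificity)`, ties resolved toward fewer features.
#' Elimination ties are resolved lexicographically (the alphabetically
#' first tied feature is dropped).
#'
#' @param x Feature matrix (>= 2 columns).
#' @param labels Label data.frame.
#' @param cv [repeated_stratified_kfold()] plan (reused at every step).
#' @param config [boost_config()].
#' @param step Features removed per iteration (fixed at 1).
#' @param threshold Decision threshold for sensitivity/specificity.
#' @return Object of class `rfe_trace`: `steps` data.frame (`n_features`,
#'   `features`, `sensitivity`, `specificity`, `balanced`), `feature_sets`
#'   list, `selected_n`, `selected_features`.
#' @export
shap_rfe <- function(x, labels, cv, config = boost_config(), step = 1,
                     threshold = 0.5) {
  if (step != 1) stop_validation("only step = 1 is supported")
  if (ncol(x) < 2L) stop_validation("need at least 2 features for elimination")
  check_labels(labels)
  lab <- stats::setNames(labels$hit, labels$transcript_id)
  features <- colnames(x)
  steps <- list(); feature_sets <- list()
  while (TRUE) {
    sens <- spec <- numeric(length(cv$splits))
    abs_phi_sum <- stats::setNames(numeric(length(features)), features)
    n_val <- 0L
    for (i in seq_along(cv$splits)) {
      sp <- cv$splits[[i]]
      fit <- tryCatch(
        lncboost(x[sp$train, features, drop = FALSE], lab[sp$train], config),
        error = function(e) stop_validation(
          "fit failed in repeat %d fold %d: %s", sp$repeat_idx, sp$fold,
          conditionMessage(e)))
      xval <- x[sp$test, features, drop = FALSE]
      p <- predict(fit, xval)
      m <- compute_metrics(lab[sp$test], p, threshold)
      sens[i] <- m$sensitivity; spec[i] <- m$specificity
      sv <- shap_values(fit, xval)
      abs_phi_sum <- abs_phi_sum + colSums(abs(sv$phi))
      n_val <- n_val + nrow(xval)
    }
    k <- length(steps) + 1L
    steps[[k]] <- data.frame(n_features = length(features),
                             features = paste(features, collapse = ","),
                             sensitivity = mean_or_na(sens),
                             specificity = mean_or_na(spec))
    feature_sets[[k]] <- features
    if (length(features) == 1L) break
    imp <- abs_phi_sum / n_val
    drop_ord <- order(imp, names(imp))     # least important, ties lexicographic
    features <- setdiff(features, names(imp)[drop_ord[1]])
  }
  trace <- do.call(rbind, steps)
  trace$balanced <- (trace$sensitivity + trace$specificity) / 2
  sel <- order(-trace$balanced, trace$n_features)[1]
  structure(list(steps = trace, feature_sets = feature_sets,
                 selected_n = trace$n_features[sel],
                 selected_features = feature_sets[[sel]]),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf("SHAP recursive feature elimination: %d -> 1 features\n",
              x$steps$n_features[1]))
  cat(sprintf("  selected: %d features (balanced score %.4f)\n",
              x$selected_n,
              x$steps$balanced[x$steps$n_features == x$selected_n]))
  invisible(x)
}

#' Write an RFE trace as TSV
#' @param trace [shap_rfe()] result.
#' @param path Output path.
#' @export
write_rfe_trace <- function(trace, path) {
  utils::write.table(trace$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
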