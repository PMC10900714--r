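## Genome-wide scoring and the candidate-selection filter cascade.

#' Score transcripts genome-wide
#'
#' Applies the fitted classifier to every row of the feature matrix. The
#' functionality score is the predicted probability in `[0, 1]`; a
#' transcript is a predicted hit when its score is strictly greater
#' than 0.5 (a score of exactly 0.5 is not a hit).
#'
#' @param model Fitted [lncboost()] model.
#' @param x Feature matrix.
#' @param threshold Hit-call threshold (default 0.5, strict).
#' @return data.frame with `transcript_id`, `score`, `predicted_hit`.
#' @export
score_transcripts <- function(model, x, threshold = 0.5) {
  p <- predict(model, x)
  data.frame(transcript_id = rownames(x),
             score = as.numeric(p),
             predicted_hit = as.numeric(p) > threshold,
             stringsAsFactors = FALSE)
}

#' Configuration for candidate selection
#'
#' Thresholds and exclusion sets for the validation-candidate filter
#' cascade: functional candidates need a score of at least
#' `functional_min_score` (0.5); non-functional controls a score below
#' `nonfunctional_max_score` (0.4) — scores in `[0.4, 0.5)` belong to
#' neither pool. Both pools then exclude transcripts already characterized
#' in prior screens, transcripts with low expression (log2 FPKM < 0),
#' transcripts absent from the annotation set, and transcripts whose TSS
#' lies within 1 kb of the nearest protein-coding TSS (strictly closer than
#' 1000 bp; exactly 1000 bp is kept).
#'
#' @param functional_min_score,nonfunctional_max_score Score cutoffs.
#' @param min_log2_fpkm Expression floor (exclusive: values below excluded).
#' @param min_pcg_tss_distance Proximity floor in bp (exclusive).
#' @param prior_hit_ids Transcripts functionally characterized previously.
#' @param annotated_ids Ids considered annotated; `NULL` disables the
#'   annotation filter.
#' @return Object of class `candidate_filter_config`.
#' @export
candidate_filter_config <- function(functional_min_score = 0.5,
                                    nonfunctional_max_score = 0.4,
                                    min_log2_fpkm = 0,
                                    min_pcg_tss_distance = 1000,
                                    prior_hit_ids = character(),
                                    annotated_ids = NULL) {
  if (nonfunctional_max_score >= functional_min_score)
    stop_validation("nonfunctional_max_score must be < functional_min_score")
  structure(list(functional_min_score = functional_min_score,
                 nonfunctional_max_score = nonfunctional_max_score,
                 min_log2_fpkm = min_log2_fpkm,
                 min_pcg_tss_distance = min_pcg_tss_distance,
                 prior_hit_ids = prior_hit_ids,
                 annotated_ids = annotated_ids),
            class = "candidate_filter_config")
}

#' Select validation candidates with a per-filter exclusion ledger
#'
#' Applies the candidate filter cascade to scored transcripts. Filters run
#' in a fixed order — score band, prior characterization, low expression,
#' missing annotation, protein-coding TSS proximity — and the ledger
#' attributes each excluded transcript to the first filter it fails. The
#' surviving set is independent of filter order.
#'
#' @param scores [score_transcripts()] output.
#' @param features Feature matrix containing `tss_pc_distance` and the
#'   expression column.
#' @param config [candidate_filter_config()].
#' @param mode `"functional"` (score >= 0.5) or `"nonfunctional_control"`
#'   (score < 0.4).
#' @param expression_column Which log2 FPKM column gates the expression
#'   filter; defaults to the first `log2_fpkm_*` column (the scoring cell
#'   line).
#' @return List with `candidates` (surviving ids) and `ledger` (data.frame
#'   `transcript_id`, `excluded_by` covering every excluded transcript).
#' @export
select_candidates <- function(scores, features, config,
                              mode = c("functional", "nonfunctional_control"),
                              expression_column = NULL) {
  mode <- match.arg(mode)
  if (!inherits(config, "candidate_filter_config"))
    stop_validation("config must be a candidate_filter_config")
  if (!"tss_pc_distance" %in% colnames(features))
    stop_validation("features lacks required column tss_pc_distance")
  if (is.null(expression_column)) {
    ec <- grep("^log2_fpkm_", colnames(features), value = TRUE)
    if (length(ec) == 0L)
      stop_validation("features lacks a log2_fpkm_* expression column")
    expression_column <- ec[1]
  } else if (!expression_column %in% colnames(features)) {
    stop_validation("features lacks required column %s", expression_column)
  }
  ids <- scores$transcript_id
  fx <- features[ids, , drop = FALSE]
  score_ok <- if (mode == "functional")
    scores$score >= config$functional_min_score
  else
    scores$score < config$nonfunctional_max_score

  reason <- rep(NA_character_, length(ids))
  reason[!score_ok] <- "score"
  flag <- function(fail, label) {
    reason[is.na(reason) & fail] <<- label
  }
  flag(ids %in% config$prior_hit_ids, "prior_hit")
  flag(fx[, expression_column] < config$min_log2_fpkm, "low_expression")
  if (!is.null(config$annotated_ids))
    flag(!ids %in% config$annotated_ids, "not_annotated")
  flag(fx[, "tss_pc_distance"] < config$min_pcg_tss_distance, "pcg_proximity")

  keep <- is.na(reason)
  list(candidates = ids[keep],
       ledger = data.frame(transcript_id = ids[!keep],
                           excluded_by = reason[!keep],
                           stringsAsFactors = FALSE))
}
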