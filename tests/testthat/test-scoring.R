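test_that("genome-wide scores are probabilities with strict hit calls", {
  fx <- shared_small_fixture()
  sc <- score_transcripts(shared_small_model(), fx$matrix)
  expect_equal(sc$transcript_id, rownames(fx$matrix))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_identical(sc$predicted_hit, sc$score > 0.5)
  # all-identical rows score identically
  x2 <- fx$matrix[rep(1, 5), ]
  rownames(x2) <- paste0("R", 1:5)
  expect_length(unique(score_transcripts(shared_small_model(), x2)$score), 1)
  # planted-signal property: hits score higher on average
  hit <- stats::setNames(fx$labels$hit, fx$labels$transcript_id)[sc$transcript_id]
  expect_gt(mean(sc$score[hit == 1]), mean(sc$score[hit == 0]))
})

mk_scored <- function() {
  # constructed table with known filter composition
  scores <- data.frame(
    transcript_id = sprintf("C%02d", 1:8),
    score = c(0.9, 0.9, 0.9, 0.9, 0.45, 0.2, 0.2, 0.6),
    stringsAsFactors = FALSE)
  scores$predicted_hit <- scores$score > 0.5
  features <- cbind(
    tss_pc_distance = c(5000, 5000, 999, 1000, 5000, 5000, 900, 5000),
    log2_fpkm_K562 = c(2, -0.5, 2, 2, 2, 2, 2, 2))
  rownames(features) <- scores$transcript_id
  list(scores = scores, features = features)
}

test_that("the candidate filter cascade excludes with attributed reasons", {
  s <- mk_scored()
  cfg <- candidate_filter_config(prior_hit_ids = "C08")
  sel <- select_candidates(s$scores, s$features, cfg, mode = "functional")
  expect_setequal(sel$candidates, c("C01", "C04"))   # exactly 1 kb is kept
  led <- stats::setNames(sel$ledger$excluded_by, sel$ledger$transcript_id)
  expect_equal(led[["C02"]], "low_expression")   # high score, log2 FPKM < 0
  expect_equal(led[["C03"]], "pcg_proximity")    # 999 bp: strictly within 1 kb
  expect_equal(led[["C05"]], "score")            # 0.45 is in neither pool
  expect_equal(led[["C08"]], "prior_hit")
  # every transcript is either kept or in the ledger
  expect_setequal(c(sel$candidates, sel$ledger$transcript_id),
                  s$scores$transcript_id)
})

test_that("functional and non-functional pools are disjoint; survivors pass all filters", {
  s <- mk_scored()
  cfg <- candidate_filter_config()
  fun <- select_candidates(s$scores, s$features, cfg, mode = "functional")
  ctl <- select_candidates(s$scores, s$features, cfg,
                           mode = "nonfunctional_control")
  expect_length(intersect(fun$candidates, ctl$candidates), 0)
  expect_setequal(ctl$candidates, c("C06"))      # C07 fails pcg proximity
  # order-insensitivity of the surviving set: survivors satisfy every
  # predicate, excluded transcripts fail at least one
  all_pred <- function(id) {
    sc <- s$scores$score[s$scores$transcript_id == id]
    sc >= 0.5 && s$features[id, "log2_fpkm_K562"] >= 0 &&
      s$features[id, "tss_pc_distance"] >= 1000
  }
  expect_true(all(vapply(fun$candidates, all_pred, logical(1))))
  expect_true(all(!vapply(
    fun$ledger$transcript_id, all_pred, logical(1))))
})

test_that("annotation filter applies only when an annotated set is supplied", {
  s <- mk_scored()
  cfg <- candidate_filter_config(annotated_ids = c("C01"))
  sel <- select_candidates(s$scores, s$features, cfg, mode = "functional")
  expect_setequal(sel$candidates, "C01")
  led <- stats::setNames(sel$ledger$excluded_by, sel$ledger$transcript_id)
  expect_equal(led[["C04"]], "not_annotated")
  expect_error(candidate_filter_config(nonfunctional_max_score = 0.6),
               "must be <")
  expect_error(select_candidates(s$scores, s$features[, 1, drop = FALSE],
                                 candidate_filter_config(), "functional"),
               "log2_fpkm")
})
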