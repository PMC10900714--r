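test_that("a linearly separable toy problem is fit to training AUROC 1", {
  toy <- separable_toy()
  fit <- lncboost(toy$x, toy$y, boost_config(scale_pos_weight = 1))
  p <- predict(fit, toy$x)
  expect_equal(compute_metrics(toy$y, p)$auroc, 1.0)
})

test_that("pure-noise features under 1:50 imbalance give null-band CV AUROC", {
  set.seed(123)
  n_pos <- 20; n_neg <- 1000
  x <- matrix(rnorm((n_pos + n_neg) * 10), ncol = 10,
              dimnames = list(sprintf("T%04d", seq_len(n_pos + n_neg)),
                              paste0("f", 1:10)))
  lab <- data.frame(transcript_id = rownames(x),
                    hit = rep(c(1L, 0L), c(n_pos, n_neg)))
  cv <- repeated_stratified_kfold(lab, k = 5, repeats = 1, seed = 0)
  res <- cross_validate(x, lab, boost_config(n_trees = 50), cv)
  expect_gte(res$mean[["auroc"]], 0.35)
  expect_lte(res$mean[["auroc"]], 0.65)
})

test_that("fitting is deterministic and margins reconcile with probabilities", {
  fx <- shared_small_fixture()
  cfg <- boost_config(n_trees = 30)
  f1 <- lncboost(fx$matrix, fx$labels, cfg)
  f2 <- lncboost(fx$matrix, fx$labels, cfg)
  p1 <- predict(f1, fx$matrix); p2 <- predict(f2, fx$matrix)
  expect_identical(p1, p2)
  m <- predict(f1, fx$matrix, type = "margin")
  expect_equal(p1, stats::plogis(m), tolerance = 1e-6)
  # probability is monotone in margin
  expect_identical(order(p1), order(m))
})

test_that("'default' cost weight resolves to the training class ratio", {
  fx <- shared_small_fixture()
  fit <- lncboost(fx$matrix, fx$labels,
                  boost_config(scale_pos_weight = "default", n_trees = 5))
  expect_identical(fit$scale_pos_weight, default_scale_pos_weight(fx$labels))
})

test_that("prediction rejects mismatched features and fit rejects bad input", {
  fx <- shared_small_fixture()
  model <- shared_small_model()
  bad <- fx$matrix[, -1, drop = FALSE]
  expect_error(predict(model, bad), "features")
  # column reordering is tolerated (order is restored internally)
  shuffled <- fx$matrix[, rev(colnames(fx$matrix))]
  expect_equal(predict(model, shuffled), predict(model, fx$matrix))
  xna <- fx$matrix; xna[1, 1] <- NA
  expect_error(lncboost(xna, fx$labels), "non-finite")
  expect_error(lncboost(fx$matrix, rep(1, nrow(fx$matrix))), "both classes")
  expect_error(boost_config(learning_rate = 0), "learning_rate")
  expect_error(boost_config(scale_pos_weight = -3), "scale_pos_weight")
})

test_that("raising the cost weight does not reduce training-set sensitivity", {
  fx <- shared_small_fixture()
  y <- stats::setNames(fx$labels$hit, fx$labels$transcript_id)
  for (seed in 0:2) {
    sens <- vapply(c(1, 10, 100), function(spw) {
      fit <- lncboost(fx$matrix, fx$labels,
                      boost_config(scale_pos_weight = spw, n_trees = 50,
                                   seed = seed))
      compute_metrics(y[rownames(fx$matrix)],
                      predict(fit, fx$matrix))$sensitivity
    }, numeric(1))
    # monotone non-decreasing up to a single small inversion
    expect_true(all(diff(sens) >= -0.02))
  }
})

test_that("grid search reports all configs and selects by the balanced criterion", {
  fx <- shared_small_fixture()
  cv <- repeated_stratified_kfold(fx$labels, k = 4, repeats = 1, seed = 0)
  one <- list(boost_config(n_trees = 20))
  gs1 <- grid_search(fx$matrix, fx$labels, one, cv)
  expect_identical(gs1$best_config, one[[1]])
  grid <- list(boost_config(scale_pos_weight = 1, n_trees = 20),
               boost_config(scale_pos_weight = "default", n_trees = 20),
               boost_config(scale_pos_weight = 100, n_trees = 20))
  gs <- grid_search(fx$matrix, fx$labels, grid, cv)
  expect_equal(nrow(gs$report), 3)
  expect_true(all(c("sensitivity", "specificity", "precision", "f1", "auroc",
                    "auprc", "brier", "brier_skill") %in% names(gs$report)))
  expect_equal(gs$report$balanced,
               (gs$report$sensitivity + gs$report$specificity) / 2)
  # the winner attains the maximal balanced criterion
  expect_equal(gs$report$balanced[gs$best_index], max(gs$report$balanced))
  expect_error(grid_search(fx$matrix, fx$labels, list(), cv), "non-empty")
})

test_that("per-split under-sampling leaves the test folds untouched", {
  fx <- shared_small_fixture()
  cv <- repeated_stratified_kfold(fx$labels, k = 4, repeats = 1, seed = 0)
  res <- cross_validate(fx$matrix, fx$labels, boost_config(n_trees = 20), cv,
                        undersample = list(strategy = 0.5))
  expect_equal(nrow(res$per_split), 4)
  expect_true(all(is.finite(res$mean[c("auroc", "brier")])))
})
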