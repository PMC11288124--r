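test_that("fold assignment is stratified, seeded, and guards small classes", {
  y <- rep(c("cancer", "healthy"), each = 20)
  f <- make_folds(y, k = 5, seed = 3)
  expect_true(all(table(f, y) == 4))
  expect_identical(f, make_folds(y, k = 5, seed = 3))
  expect_false(identical(f, make_folds(y, k = 5, seed = 4)))
  expect_error(make_folds(c(rep("cancer", 3), rep("healthy", 9)), k = 5),
               "at least k")
})

test_that("grid search produces one candidate per family/grid point with OOF scores", {
  gb <- gaussian_blocks()
  folds <- make_folds(gb$labels, 5, seed = 1)
  pool <- train_base_grid(gb$blocks$CNV, gb$labels, folds, grids1(), seed = 2)
  expect_length(pool, 5)  # 1 point per family
  expect_setequal(vapply(pool, `[[`, "", "family"),
                  c("glmnet", "xgb_gbtree", "xgb_dart", "ranger", "nnet"))
  for (cand in pool) {
    expect_false(anyNA(cand$oof))
    expect_true(all(cand$oof >= 0 & cand$oof <= 1))
  }
  # separable block: the best candidate discriminates almost perfectly
  expect_gte(max(vapply(pool, `[[`, 0, "cv_auc")), 0.95)
  # determinism
  pool2 <- train_base_grid(gb$blocks$CNV, gb$labels, folds, grids1(), seed = 2)
  expect_equal(vapply(pool, `[[`, 0, "cv_auc"), vapply(pool2, `[[`, 0, "cv_auc"))
})

test_that("out-of-fold discipline: no candidate saw its scored fold in training", {
  gb <- gaussian_blocks(n_per_class = 16, p = 8)
  folds <- make_folds(gb$labels, 4, seed = 5)
  pool <- train_base_grid(gb$blocks$NF, gb$labels, folds, grids1(), seed = 6)
  for (cand in pool)
    for (j in seq_len(max(folds)))
      expect_length(intersect(which(folds == j), cand$fold_train_rows[[j]]), 0)
})

test_that("label permutation drives cross-validation AUC to chance", {
  gb <- gaussian_blocks(n_per_class = 30, p = 15)
  set.seed(8)
  yperm <- sample(gb$labels)
  folds <- make_folds(yperm, 5, seed = 8)
  pool <- train_base_grid(gb$blocks$CNV, yperm, folds, grids1(), seed = 8)
  best <- max(vapply(pool, `[[`, 0, "cv_auc"))
  expect_lt(best, 0.72)   # max over 5 null candidates stays near chance
  expect_gt(best, 0.35)
})

test_that("top-k selection sorts by AUC with deterministic tie-breaking", {
  mk <- function(auc, fam_i, grid_i)
    list(family = paste0("fam", fam_i), family_index = fam_i,
         grid_index = grid_i, params = list(), cv_auc = auc,
         oof = rep(auc, 4), model = NULL, prep = NULL,
         fold_train_rows = list(), folds = rep(1:2, 2))
  pool <- list(mk(0.7, 3, 1), mk(0.9, 1, 2), mk(0.9, 1, 1), mk(0.8, 2, 1),
               mk(0.95, 5, 1), mk(0.6, 4, 1), mk(0.9, 2, 1))
  ens <- build_block_ensemble(pool, top_k = 5)
  expect_equal(vapply(ens$members, `[[`, 0, "cv_auc"),
               c(0.95, 0.9, 0.9, 0.9, 0.8))
  # among the 0.9 ties, family 1 precedes family 2, grid 1 precedes grid 2
  expect_equal(vapply(ens$members[2:4], `[[`, 0, "family_index"), c(1, 1, 2))
  expect_equal(vapply(ens$members[2:3], `[[`, 0, "grid_index"), c(1, 2))

  small <- build_block_ensemble(pool[1:3], top_k = 5)
  expect_length(small$members, 3)
  expect_error(build_block_ensemble(list()), "empty")
  # ensemble OOF is the unweighted member mean
  expect_equal(ens$oof, rowMeans(vapply(ens$members, `[[`, numeric(4), "oof")))
})

test_that("stacked score is the unweighted block mean and is monotone", {
  expect_equal(stack_score(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(stack_score(c(0.2, 0.4, 0.9)), 0.5)
  expect_gt(stack_score(c(0.3, 0.4, 0.9)), stack_score(c(0.2, 0.4, 0.9)))
  expect_error(stack_score(c(0.2, NA, 0.9)), "missing")
})

test_that("threshold calibration covers the specificity target on new controls", {
  ctrl <- seq(0.1, 1.0, 0.1)
  scores <- c(ctrl, 0.85, 0.95)
  labels <- c(rep("healthy", 10), "cancer", "cancer")
  t95 <- calibrate_threshold(scores, labels, 0.95)
  # brute force over a fine grid: t95 must be the smallest qualifying cut
  spec_at <- function(t) mean(ctrl < t)
  expect_gte(spec_at(t95), 0.95)
  grid <- seq(0, t95 - 1e-6, length.out = 2000)
  expect_true(all(vapply(grid, spec_at, 0) < 0.95))
  expect_gt(t95, max(ctrl))  # with n=10 controls, 0.95 forces all below t

  t80 <- calibrate_threshold(scores, labels, 0.80)
  # add-one rule: m = ceiling(0.8 * 11) = 9, training specificity 0.9
  expect_equal(spec_at(t80), 0.9)
  expect_equal(t80, sort(ctrl)[9] + 1e-9)

  # perfectly separated: smallest qualifying threshold keeps sensitivity 1
  sep_scores <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  sep_labels <- c("healthy", "healthy", "healthy", "cancer", "cancer")
  t <- calibrate_threshold(sep_scores, sep_labels, 0.95)
  expect_true(t > 0.3 && t <= 0.8)
  expect_equal(mean(sep_scores[4:5] >= t), 1)
  expect_error(calibrate_threshold(0.5, "cancer", 0.95), "no control")
})

test_that("stacked training is deterministic and beats its blocks on average", {
  gb <- gaussian_blocks()
  m <- train_stacked(gb$blocks, gb$labels, k = 5, grids = grids1(), seed = 7)
  expect_length(m$ensembles, 3)
  expect_true(all(m$oof >= 0 & m$oof <= 1))
  expect_true(m$threshold >= 0 && m$threshold <= 1 + 1e-6)

  m2 <- train_stacked(gb$blocks, gb$labels, k = 5, grids = grids1(), seed = 7)
  expect_identical(m$oof, m2$oof)
  expect_identical(m$threshold, m2$threshold)

  stacked_auc <- roc_auc(m$oof, gb$labels)
  block_aucs <- vapply(colnames(m$block_oof), function(b)
    roc_auc(m$block_oof[, b], gb$labels), 0)
  expect_gte(stacked_auc, mean(block_aucs) - 0.02)
})

test_that("prediction returns bounded scores and enforces feature contracts", {
  gb <- gaussian_blocks()
  m <- train_stacked(gb$blocks, gb$labels, k = 5, grids = grids1(), seed = 7)
  p <- predict(m, gb$blocks)
  expect_true(all(is.finite(p$score) & p$score >= 0 & p$score <= 1))
  expect_identical(p$call, p$score >= m$threshold)
  p2 <- predict(m, gb$blocks)
  expect_identical(p$score, p2$score)

  bad <- gb$blocks
  colnames(bad$CNV)[1] <- "renamed"
  expect_error(predict(m, bad), "feature mismatch")
})

test_that("repeated random partitions give reproducible robustness metrics", {
  # enough validation controls that the add-one threshold can reach the
  # target: expected specificity with n controls is 1 - 1/(n+1)
  gb <- gaussian_blocks(n_per_class = 60, p = 12, shift = c(3, 3, 3))
  splits <- c(train = 0.4, val = 0.3, test = 0.3)
  r <- repeated_partition_eval(gb$blocks, gb$labels, n_repeats = 5, k = 3,
                               split_fractions = splits,
                               grids = grids1(), seed = 12)
  expect_equal(nrow(r$per_repeat), 5)
  r2 <- repeated_partition_eval(gb$blocks, gb$labels, n_repeats = 5, k = 3,
                                split_fractions = splits,
                                grids = grids1(), seed = 12)
  expect_identical(r$per_repeat, r2$per_repeat)
  # separable blocks classify well on held-out thirds
  expect_gte(r$summary$sensitivity["mean"], 0.9)
  expect_gte(r$summary$specificity["mean"], 0.9)
  expect_true(r$summary$auc["lo"] <= r$summary$auc["mean"],
              r$summary$auc["mean"] <= r$summary$auc["hi"])
})
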