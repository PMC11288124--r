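#' Coerce cohort labels to binary 0/1
#'
#' Positive class is "cancer" for character/factor labels (any other value
#' is treated as control); logical and 0/1 numeric labels pass through.
#' @param labels vector of labels.
#' @return integer vector of 0/1.
#' @export
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == "cancer")
}

#' Stratified k-fold assignment
#'
#' Folds are label-stratified and near-equal in size; the same assignment
#' is reused verbatim by all feature blocks so that out-of-fold scores are
#' comparable and averageable across blocks.
#'
#' @param labels cohort labels (see [as_binary_labels()]).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold indices in 1..k.
#' @export
make_folds <- function(labels, k = 5, seed = 1L) {
  y <- as_binary_labels(labels)
  if (any(table(y) < k))
    stop("each class needs at least k = ", k, " samples")
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Default hyperparameter grids
#'
#' Five learner families: a regularized linear classifier (glmnet), two
#' gradient-boosted tree variants (xgboost gbtree and dart boosters), a
#' random forest (ranger) and a feed-forward neural network (nnet). The
#' grids are deliberately small so a desk-scale run finishes in minutes;
#' they are plain data.frames and fully user-editable.
#'
#' @return named list of data.frames, one per family, in the fixed family
#'   order used for deterministic tie-breaking.
#' @export
default_grids <- function() {
  list(
    glmnet = expand.grid(alpha = c(0, 1), lambda = c(0.01, 0.1)),
    xgb_gbtree = expand.grid(max_depth = c(2, 4), eta = 0.3, nrounds = 50),
    xgb_dart = expand.grid(max_depth = c(2, 4), eta = 0.3, nrounds = 50),
    ranger = expand.grid(num_trees = 300, mtry_frac = c(0.2, 0.6)),
    nnet = expand.grid(size = 3, decay = c(0.5, 2))
  )
}

# --- preprocessing: median imputation + standardization, train folds only ---
.prep_fit <- function(X) {
  med <- apply(X, 2, function(v) stats::median(v, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(median = med, center = ctr, scale = scl)
}

.prep_apply <- function(X, prep) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- prep$median[j]
  sweep(sweep(X, 2, prep$center), 2, prep$scale, "/")
}

.fit_family <- function(family, params, X, y, seed) {
  set.seed(seed)
  switch(family,
    # glmnet warns about class counts < 8 on small CV folds; the advisory
    # adds nothing here, where fold sizes are the caller's design choice
    glmnet = withCallingHandlers(
      glmnet::glmnet(X, y, family = "binomial",
                     alpha = params$alpha, lambda = params$lambda),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    xgb_gbtree = ,
    xgb_dart = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    booster = if (family == "xgb_dart") "dart" else "gbtree",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = params$nrounds, verbose = 0),
    ranger = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                            probability = TRUE,
                            num.trees = params$num_trees,
                            mtry = max(1, floor(params$mtry_frac * ncol(X))),
                            seed = seed, num.threads = 1),
    nnet = nnet::nnet(x = X, y = y, size = params$size, decay = params$decay,
                      maxit = 300, entropy = TRUE, trace = FALSE),
    stop("unknown learner family: ", family))
}

.predict_family <- function(family, model, X) {
  p <- switch(family,
    glmnet = as.numeric(stats::predict(model, X, type = "response",
                                       s = model$lambda[1])),
    xgb_gbtree = ,
    xgb_dart = as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X))),
    ranger = as.numeric(stats::predict(model, data = X,
                                       num.threads = 1)$predictions[, "1"]),
    nnet = as.numeric(stats::predict(model, X)))
  pmin(pmax(p, 0), 1)
}

#' Grid-searched base-learner candidate pool for one feature block
#'
#' For every learner family and every grid point: fit on each of the k-1
#' training folds, predict the held-out fold, pool the out-of-fold
#' probabilities, and record the pooled cross-validation AUC. New samples
#' are later scored by the unweighted mean of the k fold models, so
#' prediction scores live on the same scale as the out-of-fold scores that
#' calibrate the decision threshold. Features are median-imputed and
#' standardized using the training folds only. Deterministic given `seed`.
#'
#' @param block samples x features numeric matrix.
#' @param labels cohort labels.
#' @param folds fold assignment from [make_folds()].
#' @param grids hyperparameter grids (default [default_grids()]).
#' @param seed RNG seed.
#' @return list of candidates, each with `family`, `params`, `cv_auc`,
#'   `oof` (out-of-fold probabilities), `fold_models` (k per-fold fits
#'   with their preprocessing), `fold_train_rows` (bookkeeping of which
#'   rows trained each fold's model).
#' @export
train_base_grid <- function(block, labels, folds, grids = default_grids(),
                            seed = 1L) {
  X <- as.matrix(block)
  if (any(!is.finite(X) & !is.na(X))) stop("non-finite feature values")
  y <- as_binary_labels(labels)
  stopifnot(nrow(X) == length(y), length(folds) == length(y))
  k <- max(folds)
  for (j in seq_len(k))
    if (length(unique(y[folds != j])) < 2) stop("degenerate single-class fold")
  set.seed(seed)
  seed_pool <- sample.int(2147483646L, 10000L)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seed_pool[si] }

  pool <- list()
  for (fam_i in seq_along(grids)) {
    fam <- names(grids)[fam_i]
    grid <- grids[[fam_i]]
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      oof <- rep(NA_real_, length(y))
      fold_train_rows <- vector("list", k)
      fold_models <- vector("list", k)
      for (j in seq_len(k)) {
        tr <- which(folds != j); te <- which(folds == j)
        fold_train_rows[[j]] <- tr
        prep <- .prep_fit(X[tr, , drop = FALSE])
        fit <- .fit_family(fam, params, .prep_apply(X[tr, , drop = FALSE], prep),
                           y[tr], next_seed())
        oof[te] <- .predict_family(fam, fit, .prep_apply(X[te, , drop = FALSE], prep))
        fold_models[[j]] <- list(fit = fit, prep = prep)
      }
      pool[[length(pool) + 1L]] <- list(
        family = fam, family_index = fam_i, grid_index = g, params = params,
        cv_auc = roc_auc(oof, y), oof = oof, fold_models = fold_models,
        fold_train_rows = fold_train_rows, folds = folds)
    }
  }
  pool
}

#' Top-k block ensemble
#'
#' Selects the `top_k` candidates by cross-validation AUC (ties broken by
#' the fixed family order, then grid order) and aggregates them by the
#' unweighted mean of member probabilities. If the pool holds fewer than
#' `top_k` candidates, all are used.
#'
#' @param pool candidate list from [train_base_grid()].
#' @param top_k number of members (default 5).
#' @param block_id optional label ("CNV", "FSD", "NF").
#' @return object of class `block_ensemble`: `members`, `oof` (mean member
#'   out-of-fold score), `member_table` (family, params, cv_auc).
#' @export
build_block_ensemble <- function(pool, top_k = 5, block_id = NULL) {
  if (!length(pool)) stop("empty candidate pool")
  aucs <- vapply(pool, `[[`, 0, "cv_auc")
  fam <- vapply(pool, `[[`, 0, "family_index")
  grd <- vapply(pool, `[[`, 0, "grid_index")
  o <- order(-aucs, fam, grd)
  members <- pool[o[seq_len(min(top_k, length(pool)))]]
  oof <- rowMeans(vapply(members, `[[`, numeric(length(members[[1]]$oof)), "oof"))
  member_table <- data.frame(
    family = vapply(members, `[[`, "", "family"),
    params = vapply(members, function(m)
      paste(names(m$params), unlist(m$params), sep = "=", collapse = ","), ""),
    cv_auc = vapply(members, `[[`, 0, "cv_auc"))
  structure(list(block_id = block_id, members = members, oof = oof,
                 member_table = member_table),
            class = "block_ensemble")
}

#' Score new samples with a block ensemble
#' @param ensemble a `block_ensemble`.
#' @param X samples x features matrix in the block's feature order.
#' @return numeric scores in \[0, 1\].
#' @export
predict_block <- function(ensemble, X) {
  X <- as.matrix(X)
  m <- vapply(ensemble$members, function(m) .predict_candidate(m, X),
              numeric(nrow(X)))
  rowMeans(matrix(m, nrow = nrow(X)))
}

# candidate score on new data: mean over the k fold models
.predict_candidate <- function(cand, X) {
  m <- vapply(cand$fold_models, function(fm)
    .predict_family(cand$family, fm$fit, .prep_apply(X, fm$prep)),
    numeric(nrow(X)))
  rowMeans(matrix(m, nrow = nrow(X)))
}

#' Average block scores into the final cancer score
#'
#' @param block_scores numeric vector (or matrix with one column per block)
#'   of per-block ensemble scores in \[0, 1\].
#' @return unweighted mean score in \[0, 1\].
#' @export
stack_score <- function(block_scores) {
  if (is.matrix(block_scores)) {
    if (anyNA(block_scores)) stop("missing block score")
    return(rowMeans(block_scores))
  }
  if (anyNA(block_scores)) stop("missing block score")
  mean(block_scores)
}

#' Specificity-targeted decision threshold
#'
#' Threshold t such that a new control sample is called positive
#' (`score >= t`) with probability at most `1 - target_specificity`: t sits
#' just above the m-th control order statistic with
#' m = ceiling(target * (n + 1)), the add-one (conformal) quantile. The
#' naive choice m = ceiling(target * n) - the smallest cut whose empirical
#' training specificity reaches the target - only covers the
#' m/(n+1) quantile in expectation (about 0.90 for n = 20 at target 0.95)
#' and systematically under-covers on held-out controls; the add-one form
#' restores the intended specificity without distributional assumptions.
#' When m exceeds n, t is placed just above the largest control score.
#' Scores must be out-of-fold, never resubstitution.
#'
#' @param scores numeric scores.
#' @param labels cohort labels (controls define specificity).
#' @param target_specificity default 0.95.
#' @return threshold t.
#' @export
calibrate_threshold <- function(scores, labels, target_specificity = 0.95) {
  y <- as_binary_labels(labels)
  ctrl <- sort(scores[y == 0])
  if (!length(ctrl)) stop("no control samples to calibrate on")
  m <- ceiling(target_specificity * (length(ctrl) + 1))
  if (m < 1) return(min(scores))
  ctrl[min(m, length(ctrl))] + 1e-9
}

#' Train the two-tier stacked ensemble
#'
#' One fold assignment shared by all blocks; per block a grid-searched
#' candidate pool reduced to its top-5 ensemble; the stacked out-of-fold
#' score is the mean of the three block out-of-fold scores.
#'
#' The decision threshold targets `target_specificity` on training-control
#' scores that were never touched by model selection. Because the top-5
#' members are chosen by their cross-validation AUC, the ensemble's own
#' out-of-fold scores are optimistically compressed for controls (the
#' selection step has already seen them); a threshold read off those scores
#' under-covers on new data. With `nested_calibration = TRUE` (default) the
#' whole pipeline - grid search, member selection, averaging - is re-run k
#' times with one fold held out, each fold is scored by the pipeline that
#' excluded it, and the threshold is calibrated on those scores, which are
#' exchangeable with scores of genuinely new samples.
#'
#' @param blocks named list of samples x features matrices (same row order).
#' @param labels cohort labels.
#' @param k folds (default 5).
#' @param grids hyperparameter grids.
#' @param top_k ensemble size per block (default 5).
#' @param target_specificity threshold calibration target (default 0.95).
#' @param nested_calibration calibrate the threshold on nested-CV scores
#'   (default TRUE); FALSE falls back to the plain out-of-fold scores,
#'   appropriate when the threshold is later re-tuned on a separate
#'   validation set.
#' @param seed master seed; all learner seeds derive from it.
#' @return object of class `stacked_model`: `ensembles`, `threshold`,
#'   `folds`, `oof` (stacked out-of-fold scores), `block_oof`,
#'   `calibration_scores`, `seed`.
#' @export
train_stacked <- function(blocks, labels, k = 5, grids = default_grids(),
                          top_k = 5, target_specificity = 0.95,
                          nested_calibration = TRUE, seed = 1L) {
  stopifnot(length(blocks) >= 1)
  n <- nrow(blocks[[1]])
  if (!all(vapply(blocks, nrow, 0L) == n)) stop("blocks disagree on sample count")
  folds <- make_folds(labels, k, seed)
  set.seed(seed)
  block_seeds <- sample.int(2147483646L, length(blocks))
  nested_seeds <- sample.int(2147483646L, k * (length(blocks) + 1))
  ensembles <- lapply(seq_along(blocks), function(b)
    build_block_ensemble(
      train_base_grid(blocks[[b]], labels, folds, grids, block_seeds[b]),
      top_k, block_id = names(blocks)[b]))
  names(ensembles) <- names(blocks)
  block_oof <- vapply(ensembles, `[[`, numeric(n), "oof")
  oof <- stack_score(block_oof)

  calib <- oof
  if (nested_calibration) {
    calib <- rep(NA_real_, n)
    for (j in seq_len(k)) {
      tr <- folds != j
      inner <- make_folds(labels[tr], k - 1,
                          nested_seeds[(j - 1) * (length(blocks) + 1) + 1])
      bs <- vapply(seq_along(blocks), function(b) {
        ens <- build_block_ensemble(
          train_base_grid(blocks[[b]][tr, , drop = FALSE], labels[tr], inner,
                          grids,
                          nested_seeds[(j - 1) * (length(blocks) + 1) + 1 + b]),
          top_k, block_id = names(blocks)[b])
        predict_block(ens, blocks[[b]][!tr, , drop = FALSE])
      }, numeric(sum(!tr)))
      calib[!tr] <- stack_score(matrix(bs, nrow = sum(!tr)))
    }
  }

  structure(list(ensembles = ensembles,
                 threshold = calibrate_threshold(calib, labels, target_specificity),
                 target_specificity = target_specificity,
                 folds = folds, oof = oof, block_oof = block_oof,
                 calibration_scores = calib,
                 feature_names = lapply(blocks, colnames),
                 seed = seed),
            class = "stacked_model")
}

#' @exportS3Method base::print
print.stacked_model <- function(x, ...) {
  cat("<stacked_model> ", length(x$ensembles), " block ensembles, threshold ",
      round(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Predict cancer scores and calls
#'
#' @param object a `stacked_model`.
#' @param blocks named list of feature matrices matching the training
#'   blocks (names, feature order).
#' @param ... unused.
#' @return data.frame: `score` (mean of block scores, in \[0, 1\]), `call`
#'   (score >= threshold), plus one score column per block.
#' @export
predict.stacked_model <- function(object, blocks, ...) {
  stopifnot(identical(sort(names(blocks)), sort(names(object$ensembles))))
  for (b in names(blocks)) {
    want <- object$feature_names[[b]]
    if (!is.null(want) && !identical(colnames(as.matrix(blocks[[b]])), want))
      stop("feature mismatch in block ", b)
  }
  bs <- vapply(names(object$ensembles), function(b)
    predict_block(object$ensembles[[b]], blocks[[b]]),
    numeric(nrow(as.matrix(blocks[[1]]))))
  bs <- matrix(bs, ncol = length(object$ensembles),
               dimnames = list(NULL, names(object$ensembles)))
  score <- stack_score(bs)
  out <- data.frame(score = score, call = score >= object$threshold)
  cbind(out, as.data.frame(bs))
}

#' Repeated random-partition robustness evaluation
#'
#' For each repeat: a stratified train/validation/test split, a stacked
#' model fit on the training portion, a threshold tuned on the validation
#' scores, and test-set sensitivity/specificity. Returns the per-repeat
#' distribution with its mean and percentile interval.
#'
#' @param blocks named list of feature matrices for the full cohort.
#' @param labels cohort labels.
#' @param n_repeats number of random partitions (default 10).
#' @param split_fractions train/val/test fractions summing to 1.
#' @param k inner CV folds.
#' @param grids hyperparameter grids (a 1-point-per-family grid keeps
#'   repeats fast).
#' @param top_k ensemble size.
#' @param target_specificity validation threshold target.
#' @param conf percentile interval level (default 0.95).
#' @param seed master seed.
#' @return list: `per_repeat` (data.frame repeat, sensitivity, specificity,
#'   auc), `summary` (means and percentile CIs).
#' @export
repeated_partition_eval <- function(blocks, labels, n_repeats = 10,
                                    split_fractions = c(train = 0.6, val = 0.2, test = 0.2),
                                    k = 5, grids = default_grids(), top_k = 5,
                                    target_specificity = 0.95, conf = 0.95,
                                    seed = 1L) {
  y <- as_binary_labels(labels)
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_repeats)
  rows <- lapply(seq_len(n_repeats), function(r) {
    set.seed(rep_seeds[r])
    part <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      n_tr <- round(split_fractions[1] * length(idx))
      n_va <- round(split_fractions[2] * length(idx))
      part[idx] <- rep(c(1L, 2L, 3L),
                       c(n_tr, n_va, length(idx) - n_tr - n_va))
    }
    if (any(tapply(part, y, function(p) length(unique(p))) < 3))
      stop("split leaves a class empty in some partition")
    tr <- part == 1L; va <- part == 2L; te <- part == 3L
    sub <- function(m, w) m[w, , drop = FALSE]
    fit <- train_stacked(lapply(blocks, sub, tr), y[tr], k = k, grids = grids,
                         top_k = top_k, target_specificity = target_specificity,
                         nested_calibration = FALSE, seed = rep_seeds[r])
    val_scores <- predict(fit, lapply(blocks, sub, va))$score
    thr <- calibrate_threshold(val_scores, y[va], target_specificity)
    test_scores <- predict(fit, lapply(blocks, sub, te))$score
    calls <- test_scores >= thr
    data.frame(repeat_i = r,
               sensitivity = mean(calls[y[te] == 1]),
               specificity = mean(!calls[y[te] == 0]),
               auc = roc_auc(test_scores, y[te]))
  })
  per_repeat <- do.call(rbind, rows)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  summ <- lapply(c("sensitivity", "specificity", "auc"), function(m)
    c(mean = mean(per_repeat[[m]]),
      lo = unname(stats::quantile(per_repeat[[m]], qs[1])),
      hi = unname(stats::quantile(per_repeat[[m]], qs[2]))))
  names(summ) <- c("sensitivity", "specificity", "auc")
  list(per_repeat = per_repeat, summary = summ)
}
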