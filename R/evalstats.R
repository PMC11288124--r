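#' Area under the ROC curve
#'
#' The probability that a random positive sample outscores a random
#' negative one, with ties counted 1/2 (equivalent to trapezoidal ROC
#' integration). Computed from mean ranks, so it is exact for any tie
#' structure.
#'
#' @param scores numeric scores.
#' @param labels labels (see [as_binary_labels()]).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile CI for the AUC
#'
#' Stratified resampling (cases and controls resampled separately, so every
#' replicate contains both classes), AUC recomputed per replicate, interval
#' from the empirical quantiles.
#'
#' @param scores,labels as in [roc_auc()].
#' @param B bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 1000, conf = 0.95, seed = 1L) {
  y <- as_binary_labels(labels)
  stopifnot(B >= 1)
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) stop("both classes required")
  set.seed(seed)
  stat <- vapply(seq_len(B), function(b) {
    j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    roc_auc(scores[j], y[j])
  }, 0)
  qs <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  c(lo = qs[1], hi = qs[2])
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric `c(lo, hi)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n, n >= 1")
  z <- stats::qnorm((1 + conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Clopper-Pearson (exact binomial) interval
#'
#' @inheritParams wilson_interval
#' @return named numeric `c(lo, hi)`.
#' @export
exact_binomial_interval <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n, n >= 1")
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo = lo, hi = hi)
}

#' Sensitivity and specificity with confidence intervals
#'
#' @param calls logical (or 0/1) predicted positives.
#' @param labels true labels.
#' @param ci "wilson" (default) or "exact" (Clopper-Pearson).
#' @param conf confidence level.
#' @return list: `sensitivity`, `specificity`, each with `estimate`, `x`,
#'   `n`, `ci`.
#' @export
sens_spec <- function(calls, labels, ci = c("wilson", "exact"), conf = 0.95) {
  ci <- match.arg(ci)
  y <- as_binary_labels(labels)
  calls <- as.logical(calls)
  if (length(unique(y)) < 2) stop("both classes required")
  f <- if (ci == "wilson") wilson_interval else exact_binomial_interval
  tp <- sum(calls & y == 1); fn <- sum(!calls & y == 1)
  tn <- sum(!calls & y == 0); fp <- sum(calls & y == 0)
  list(sensitivity = list(estimate = tp / (tp + fn), x = tp, n = tp + fn,
                          ci = f(tp, tp + fn, conf)),
       specificity = list(estimate = tn / (tn + fp), x = tn, n = tn + fp,
                          ci = f(tn, tn + fp, conf)))
}

#' Positive percent agreement between paired call vectors
#'
#' Fraction of pairs where the test condition's call equals the reference
#' condition's call, with a Wilson interval.
#'
#' @param reference_calls,test_calls equal-length call vectors.
#' @param conf confidence level.
#' @return list of class `ppa_result`: `n_pairs`, `n_agree`, `ppa`, `ci`.
#' @export
ppa <- function(reference_calls, test_calls, conf = 0.95) {
  if (length(reference_calls) != length(test_calls))
    stop("call vectors differ in length")
  if (!length(reference_calls)) stop("empty input")
  agree <- sum(reference_calls == test_calls)
  structure(list(n_pairs = length(reference_calls), n_agree = agree,
                 ppa = agree / length(reference_calls),
                 ci = wilson_interval(agree, length(reference_calls), conf)),
            class = "ppa_result")
}

# all JT statistics over distinct permutations of group memberships
.jt_statistic <- function(groups) {
  s <- 0
  for (i in seq_along(groups)[-length(groups)])
    for (j in (i + 1):length(groups)) {
      xi <- groups[[i]]; xj <- groups[[j]]
      cmp <- outer(xi, xj, "<")
      tie <- outer(xi, xj, "==")
      s <- s + sum(cmp) + 0.5 * sum(tie)
    }
  s
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for an ordered trend in location across k ordered groups; the
#' statistic is the sum over ordered group pairs of Mann-Whitney counts
#' (ties counted 1/2). The p-value uses the tie-corrected normal
#' approximation; for small samples (total n <= `exact_n_max`) an exact
#' permutation distribution is enumerated instead.
#'
#' @param groups list of numeric vectors in increasing group order.
#' @param alternative "increasing" (default), "decreasing" or "two.sided".
#' @param exact NULL (auto: exact when total n <= `exact_n_max`), TRUE or
#'   FALSE.
#' @param exact_n_max size cap for enumeration (default 12).
#' @return list: `statistic`, `p_value`, `method`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing", "two.sided"),
                                exact = NULL, exact_n_max = 12) {
  alternative <- match.arg(alternative)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  ns <- lengths(groups)
  N <- sum(ns)
  jt <- .jt_statistic(groups)
  if (is.null(exact)) exact <- N <= exact_n_max

  if (exact) {
    vals <- unlist(groups)
    gsz <- ns
    # enumerate all distinct assignments of the pooled values to groups
    stats_all <- numeric(0)
    recurse <- function(remaining_idx, gi, acc) {
      if (gi == length(gsz)) {
        stats_all[length(stats_all) + 1L] <<-
          .jt_statistic(c(acc, list(vals[remaining_idx])))
        return(invisible())
      }
      cmb <- utils::combn(remaining_idx, gsz[gi])
      for (cix in seq_len(ncol(cmb))) {
        pick <- cmb[, cix]
        recurse(setdiff(remaining_idx, pick), gi + 1L,
                c(acc, list(vals[pick])))
      }
    }
    recurse(seq_len(N), 1L, list())
    p <- switch(alternative,
      increasing = mean(stats_all >= jt - 1e-9),
      decreasing = mean(stats_all <= jt + 1e-9),
      two.sided = min(1, 2 * min(mean(stats_all >= jt - 1e-9),
                                 mean(stats_all <= jt + 1e-9))))
    return(list(statistic = jt, p_value = p, method = "exact_permutation"))
  }

  # tie-corrected normal approximation
  vals <- unlist(groups)
  tj <- table(vals)
  mu <- (N^2 - sum(ns^2)) / 4
  t1 <- N * (N - 1) * (2 * N + 5) - sum(ns * (ns - 1) * (2 * ns + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  t2 <- sum(ns * (ns - 1) * (ns - 2)) * sum(tj * (tj - 1) * (tj - 2))
  t3 <- sum(ns * (ns - 1)) * sum(tj * (tj - 1))
  v <- t1 / 72 + t2 / (36 * N * (N - 1) * (N - 2)) + t3 / (8 * N * (N - 1))
  # continuity correction: the statistic is discrete on a 1/2 lattice
  p <- switch(alternative,
    increasing = stats::pnorm((jt - 0.5 - mu) / sqrt(v), lower.tail = FALSE),
    decreasing = stats::pnorm((jt + 0.5 - mu) / sqrt(v)),
    two.sided = 2 * stats::pnorm(-(abs(jt - mu) - 0.5) / sqrt(v)))
  list(statistic = jt, p_value = min(1, p), method = "normal_approximation")
}

#' Differential feature selection by multiple t-tests
#'
#' Welch two-sample t-test per feature, Benjamini-Hochberg adjustment
#' across all tested features, selection at adjusted p < `alpha`. Features
#' with zero variance in both groups are skipped and reported.
#'
#' @param X samples x features matrix.
#' @param labels two-class labels.
#' @param alpha adjusted-p cutoff (default 0.01).
#' @return data.frame: `feature`, `t`, `p`, `p_adj`, `selected`, `skipped`.
#' @export
differential_features <- function(X, labels, alpha = 0.01) {
  X <- as.matrix(X)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 samples per class")
  g1 <- X[y == 1, , drop = FALSE]; g0 <- X[y == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2, stats::var); v0 <- apply(g0, 2, stats::var)
  tol <- 1e-12 * (abs(m1) + abs(m0) + 1e-12)  # constant features, up to float noise
  skipped <- (v1 <= tol & v0 <= tol)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[skipped] <- NA
  p_adj <- rep(NA_real_, length(p))
  p_adj[!skipped] <- stats::p.adjust(p[!skipped], method = "BH")
  data.frame(feature = colnames(X) %||% as.character(seq_along(p)),
             t = tt, p = p, p_adj = p_adj,
             selected = !is.na(p_adj) & p_adj < alpha,
             skipped = skipped, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric (over-representation) test of a hit list
#' against each gene set, within a fixed universe; raw and BH-adjusted
#' p-values are reported.
#'
#' @param hit_genes character vector (subset of `universe`).
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all testable genes.
#' @param alpha significance cutoff on the raw p (default 0.05, matching
#'   common pathway-analysis practice); adjusted p is also reported.
#' @return data.frame: `set`, `n_set`, `n_overlap`, `p`, `p_adj`,
#'   `significant`.
#' @export
hypergeom_enrich <- function(hit_genes, gene_sets, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  hit_genes <- intersect(unique(hit_genes), universe)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    k <- length(intersect(hit_genes, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(hit_genes), lower.tail = FALSE)
    data.frame(set = id, n_set = length(set), n_overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out
}

#' Limit of detection at 50\% sensitivity
#'
#' Logistic regression of detection on log10 tumor fraction over a
#' titration series; `f50` is the tumor fraction at fitted detection
#' probability 0.5. Tumor fractions of 0 are floored at `f_floor` before
#' the log. Under complete separation the logistic slope diverges, so the
#' fit is replaced by the interval between the largest fully-undetected
#' and the smallest fully-detected grid point, with `f50` at its geometric
#' midpoint.
#'
#' @param f tumor fractions of the titration samples.
#' @param detected logical detection calls.
#' @param f_floor floor applied to f = 0 (default 1e-4).
#' @return list of class `lod_fit`: `f50`, `slope`, `method`,
#'   `f50_interval` (separation branch only), `model` (glm fit when used).
#' @export
lod50 <- function(f, detected, f_floor = 1e-4) {
  stopifnot(length(f) == length(detected))
  detected <- as.logical(detected)
  lf <- log10(pmax(f, f_floor))
  if (length(unique(f)) < 2) stop("need at least 2 distinct tumor fractions")
  sep_branch <- function() {
    ff <- sort(unique(pmax(f, f_floor)))
    rate <- vapply(ff, function(v) mean(detected[pmax(f, f_floor) == v]), 0)
    f_lo <- if (any(rate == 0)) max(ff[rate == 0]) else f_floor
    f_hi <- if (any(rate == 1)) min(ff[rate == 1 & ff > f_lo]) else max(ff)
    list(f50 = sqrt(f_lo * f_hi), slope = Inf, method = "separation",
         f50_interval = c(f_lo, f_hi), model = NULL)
  }
  if (all(detected) || all(!detected)) return(structure(sep_branch(), class = "lod_fit"))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(detected ~ lf, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || abs(stats::coef(fit)[2]) > 50)
    return(structure(sep_branch(), class = "lod_fit"))
  b <- stats::coef(fit)
  structure(list(f50 = 10^(-b[1] / b[2]), slope = unname(b[2]),
                 method = "logistic", f50_interval = NULL, model = fit),
            class = "lod_fit")
}
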