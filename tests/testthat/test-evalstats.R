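test_that("roc_auc equals brute-force pair counting, including ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- round(stats::runif(n), 2)  # rounding forces occasional ties
    expect_equal(roc_auc(s, y), brute_auc(s, y))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("roc_auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- stats::rnorm(60)
  y <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("bootstrap AUC interval is seeded, stratified and degenerate-safe", {
  set.seed(3)
  y <- rep(c(1, 0), each = 40)
  s <- c(stats::rnorm(40, 2), stats::rnorm(40, 0))
  ci <- bootstrap_auc_ci(s, y, B = 200, seed = 5)
  expect_identical(ci, bootstrap_auc_ci(s, y, B = 200, seed = 5))
  expect_true(ci["lo"] <= roc_auc(s, y) && roc_auc(s, y) <= ci["hi"])

  sep <- c(stats::runif(100, 0.9, 1), stats::runif(100, 0, 0.1))
  ysep <- rep(c(1, 0), each = 100)
  ci2 <- bootstrap_auc_ci(sep, ysep, B = 100, seed = 1)
  expect_gte(ci2["lo"], 0.99)
  ci3 <- bootstrap_auc_ci(s, y, B = 1, seed = 2)
  expect_equal(ci3["lo"], ci3["hi"], ignore_attr = TRUE)
})

test_that("Wilson intervals match the closed form and shrink to x/n", {
  for (case in list(c(8, 8), c(3, 5), c(43, 47), c(65, 66), c(44, 45))) {
    got <- wilson_interval(case[1], case[2])
    expect_equal(unname(got), wilson_oracle(case[1], case[2]), tolerance = 1e-10)
  }
  tightened <- wilson_interval(3, 5, conf = 1e-9)
  expect_equal(unname(tightened), c(0.6, 0.6), tolerance = 1e-6)
  expect_error(wilson_interval(6, 5), "0 <= x <= n")
})

test_that("Clopper-Pearson matches its beta closed forms", {
  n <- 8; conf <- 0.95
  got <- exact_binomial_interval(n, n, conf)
  expect_equal(unname(got[1]), (0.025)^(1 / n), tolerance = 1e-10)
  expect_equal(unname(got[2]), 1)
  expect_equal(unname(exact_binomial_interval(0, 10)[1]), 0)
  expect_equal(unname(exact_binomial_interval(44, 45)[1]), 0.882,
               tolerance = 5e-4)
})

test_that("sens/spec counts true calls and attaches the chosen interval", {
  y <- c(rep(1, 5), rep(0, 5))
  calls <- c(rep(TRUE, 5), rep(FALSE, 5))
  ss <- sens_spec(calls, y)
  expect_equal(ss$sensitivity$estimate, 1)
  expect_equal(ss$specificity$estimate, 1)

  calls2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, rep(FALSE, 5))
  ss2 <- sens_spec(calls2, y)
  expect_equal(ss2$sensitivity$estimate, 0.6)
  expect_equal(unname(ss2$sensitivity$ci),
               unname(wilson_interval(3, 5)), tolerance = 1e-12)
  ss3 <- sens_spec(calls2, y, ci = "exact")
  expect_equal(unname(ss3$sensitivity$ci),
               unname(exact_binomial_interval(3, 5)), tolerance = 1e-12)
  expect_error(sens_spec(calls, rep(1, 10)), "both classes")
})

test_that("PPA counts agreeing pairs with a Wilson interval", {
  r <- ppa(c(TRUE, TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(r$ppa, 1)
  expect_equal(unname(r$ci), unname(wilson_interval(4, 4)), tolerance = 1e-12)

  r2 <- ppa(rep(TRUE, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$ppa, 0.6)
  expect_equal(r2$n_agree, 3)
  expect_error(ppa(TRUE, c(TRUE, FALSE)), "length")
  expect_error(ppa(logical(), logical()), "empty")
})

test_that("JT statistic and exact permutation p match enumeration oracles", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- jonckheere_terpstra(g)
  expect_equal(res$statistic, 12)  # the maximum possible
  expect_equal(res$statistic, jt_stat_oracle(g))
  expect_identical(res$method, "exact_permutation")
  # only 1 of the 6!/(2!2!2!) = 90 arrangements reaches the maximum
  expect_equal(res$p_value, 1 / 90)

  tied <- list(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(jonckheere_terpstra(tied)$p_value, 1)
  expect_error(jonckheere_terpstra(list(1:3)), "2 non-empty")
})

test_that("JT normal approximation tracks the permutation distribution", {
  set.seed(13)
  g <- list(round(stats::rnorm(4, 0), 1), round(stats::rnorm(4, 0.5), 1),
            round(stats::rnorm(4, 1), 1))
  p_norm <- jonckheere_terpstra(g, exact = FALSE)$p_value
  expect_lt(abs(p_norm - jt_perm_p(g)), 0.02)
  p_exact <- jonckheere_terpstra(g, exact = TRUE)$p_value
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("BH adjustment matches the hand oracle and preserves order", {
  p <- c(0.001, 0.01, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), c(0.004, 0.02, 0.04, 0.04))
  set.seed(9)
  pr <- stats::runif(50)
  adj <- stats::p.adjust(pr, "BH")
  expect_equal(adj, bh_oracle(pr))
  expect_true(all(diff(adj[order(pr)]) >= -1e-12))
})

test_that("differential selection is calibrated under the null and powered", {
  lay <- tiny_layout()
  sites <- miniature_sites(lay, n_sets = 20, sites_per_set = 150, seed = 19)
  active <- sprintf("TF%02d", 1:10)
  prof <- sim_profile(active_sites = active)
  coh <- c(simulate_cohort(prof, lay, 12, 0,
                           f_dist = function(n) rep(0.2, n),
                           depth = 2, seed = 23, sites = sites),
           simulate_cohort(prof, lay, 0, 12, depth = 2, seed = 24,
                           sites = sites))
  X <- t(vapply(coh, function(s) nf_features(s, sites), numeric(60)))
  y <- vapply(coh, function(s) s$metadata$label, "")

  res <- differential_features(X, y, alpha = 0.01)
  central <- res[endsWith(res$feature, ".central"), ]
  sel <- central$feature[central$selected]
  truth <- paste0(active, ".central")
  expect_gte(length(intersect(sel, truth)), 8)            # power
  if (length(sel)) expect_gte(mean(sel %in% truth), 0.8)  # precision
  # 'average' features are identically 1 by normalization: skipped, not tested
  expect_true(all(res$skipped[endsWith(res$feature, ".average")]))

  # permuted labels: selections at most at the nominal level
  set.seed(31)
  n_false <- vapply(1:5, function(i) {
    sum(differential_features(X, sample(y), alpha = 0.01)$selected,
        na.rm = TRUE)
  }, 0)
  expect_lte(mean(n_false) / sum(!res$skipped), 0.05)
  expect_error(differential_features(X[1:2, ], y[1:2]), "2 samples")
})

test_that("hypergeometric enrichment flags the planted set and stays flat on noise", {
  universe <- sprintf("g%03d", 1:200)
  sets <- list(planted = universe[1:20], other = universe[101:130])
  hits <- universe[1:20]
  res <- hypergeom_enrich(hits, sets, universe)
  expect_lt(res$p[res$set == "planted"], 1e-4)
  expect_equal(res$n_overlap[res$set == "other"], 0)
  expect_gt(res$p[res$set == "other"], 0.99)

  # null calibration: the test is discrete, hence conservative; random hit
  # lists must not be flagged above the nominal level
  set.seed(41)
  null_p <- replicate(200, {
    h <- sample(universe, 20)
    hypergeom_enrich(h, sets["planted"], universe)$p
  })
  expect_lt(mean(null_p <= 0.05), 0.08)
  expect_gt(mean(null_p > 0.5), 0.3)
  expect_error(hypergeom_enrich(hits, sets, character()), "empty universe")
})

test_that("lod50 recovers a known logistic and handles separation", {
  set.seed(17)
  f_grid <- c(0.001, 0.002, 0.004, 0.008, 0.016, 0.032, 0.064)
  f50_true <- 0.008
  f <- rep(f_grid, each = 20)
  p <- stats::plogis(2.5 * (log10(f) - log10(f50_true)))
  det <- stats::runif(length(f)) < p
  fit <- lod50(f, det)
  expect_identical(fit$method, "logistic")
  expect_lt(abs(log(fit$f50 / f50_true)), log(1.5))

  # every sample detected: f50 lies below the smallest grid point
  all_det <- lod50(rep(f_grid, each = 3), rep(TRUE, 21))
  expect_identical(all_det$method, "separation")
  expect_lt(all_det$f50, min(f_grid))

  # clean separation between adjacent grid points
  f2 <- rep(c(0.001, 0.01), each = 10)
  sep <- lod50(f2, f2 > 0.005)
  expect_identical(sep$method, "separation")
  expect_equal(sep$f50_interval, c(0.001, 0.01))
  expect_true(sep$f50 > 0.001 && sep$f50 < 0.01)

  # symmetric design with 50% detection at the middle point
  f3 <- rep(c(0.004, 0.008, 0.016), each = 20)
  det3 <- c(rep(FALSE, 20), rep(c(TRUE, FALSE), 10), rep(TRUE, 20))
  fit3 <- lod50(f3, det3)
  expect_equal(fit3$f50, 0.008, tolerance = 1e-6)
  expect_error(lod50(rep(0.01, 5), c(TRUE, FALSE, TRUE, TRUE, FALSE)),
               "distinct")
})
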