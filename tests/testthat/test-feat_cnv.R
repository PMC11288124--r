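test_that("bin counting uses fragment midpoints with half-open bins", {
  lay <- build_layout(data.frame(chrom = "c1", length = 2e6))
  bins <- make_bins(lay, 1e6)
  # midpoints 10, 999999, 1000000: the third sits exactly on the boundary
  fr <- data.frame(chrom = "c1",
                   start = c(0, 999919, 999920),
                   end = c(20, 1000079, 1000080))
  s <- sample_fragments("x", fr)
  expect_equal((fr$start + fr$end) / 2, c(10, 999999, 1000000))
  expect_equal(bin_depths(s, bins), c(2, 1))
  empty <- sample_fragments("e", data.frame(chrom = "c9", start = 1, end = 170))
  expect_equal(bin_depths(empty, bins), c(0, 0))
})

test_that("flat simulated coverage gives Poisson-dispersed bin counts", {
  lay <- tiny_layout()
  bins <- make_bins(lay, 1e6)
  s <- simulate_sample(sim_profile(gc_bias = 0), lay, 0, depth = 1, seed = 3)
  d <- bin_depths(s, bins)
  disp <- stats::var(d) / mean(d)  # ~1 for Poisson
  expect_gt(disp, 0.3)
  expect_lt(disp, 3)
})

test_that("GC correction flattens a constructed bias and preserves the mean", {
  set.seed(4)
  gc <- stats::runif(100, 0.35, 0.6)
  flat <- rep(50, 100)
  expect_equal(gc_correct(flat, gc), flat, tolerance = 1e-6)

  biased <- 100 + 200 * gc  # pure linear GC effect
  corr <- gc_correct(biased, gc)
  expect_lt(max(abs(corr - mean(corr))) / mean(corr), 0.02)
  expect_lt(abs(mean(corr) - mean(biased)) / mean(biased), 1e-6)
  expect_error(gc_correct(biased[1:5], gc[1:5]), "10 kept bins")
})

test_that("log2 ratios are zero against own baseline and median-centered", {
  x <- c(10, 12, 9, 11, 10.5)
  expect_equal(log2_ratios(x, x), rep(0, 5))
  r <- log2_ratios(c(10, 10, 20, 10, 10), rep(10, 5))
  expect_equal(stats::median(r), 0)
  expect_error(log2_ratios(x, rep(0, 5)), "positive")
})

test_that("injected gains and losses recover the single-copy closed form", {
  lay <- miniature_layout()
  prof <- miniature_profile(cnv_segments = data.frame(
    chrom = c("chrA", "chrA"), start = c(5e6, 30e6), end = c(20e6, 45e6),
    copy_number = c(3, 1)))
  bins <- sim_bin_gc(make_bins(lay), prof, lay)
  healthy <- lapply(1:5, function(i)
    simulate_sample(sim_profile(), lay, 0, depth = 2, seed = 400 + i))
  bl <- cnv_baseline(healthy, bins)
  f <- 0.4
  s <- simulate_sample(prof, lay, f, depth = 2, seed = 77)
  d <- gc_correct(bin_depths(s, bins), bins$gc, bins$kept)
  r <- log2_ratios(d, bl, bins$kept)
  gain <- bins$chrom == "chrA" & bins$start >= 5e6 & bins$end <= 20e6
  loss <- bins$chrom == "chrA" & bins$start >= 30e6 & bins$end <= 45e6
  expect_lt(abs(stats::median(r[gain]) - log2(1 + f / 2)), 0.03)
  expect_lt(abs(stats::median(r[loss]) - log2(1 - f / 2)), 0.03)
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
  params <- hmm_params()
  lay <- build_layout(data.frame(chrom = "c1", length = 8e6))
  bins <- make_bins(lay, 1e6)
  set.seed(10)
  for (rep in 1:4) {
    x <- stats::rnorm(8, sample(c(-0.3, 0, 0.25, 0.6), 8, replace = TRUE,
                                prob = c(0.2, 0.5, 0.2, 0.1)), 0.15)
    res <- hmm_segment(x, bins, params)
    oracle <- brute_viterbi(x, params)
    expect_identical(unname(res$states),
                     names(params$mu)[oracle$path])
    expect_equal(res$loglik, oracle$loglik, tolerance = 1e-9)
  }
})

test_that("all-zero input decodes as a single neutral segment", {
  lay <- build_layout(data.frame(chrom = "c1", length = 2e7))
  bins <- make_bins(lay, 1e6)
  res <- hmm_segment(rep(0, 20), bins, hmm_params())
  expect_true(all(res$states == "neutral"))
  expect_equal(nrow(res$segments), 1)
  expect_error(hmm_segment(c(rep(0, 19), Inf), bins, hmm_params()),
               "non-finite")
})

test_that("an injected 10-bin gain is recovered by the adaptive HMM", {
  lay <- build_layout(data.frame(chrom = "c1", length = 4e7))
  bins <- make_bins(lay, 1e6)
  f <- 0.3
  set.seed(6)
  x <- stats::rnorm(40, 0, 0.03)
  x[16:25] <- x[16:25] + log2(1 + f / 2)
  res <- hmm_segment(x, bins)
  expect_gte(sum(res$states[16:25] == "gain"), 8)
})

test_that("tumor fraction inverts segment log2 ratios", {
  none <- data.frame(chrom = "c", start = 0, end = 1e6, state = "neutral",
                     median_log2 = 0, n_bins = 1)
  expect_equal(estimate_tumor_fraction(none)$f_hat, 0)

  one <- data.frame(chrom = "c", start = 0, end = 1e7, state = "gain",
                    median_log2 = 0.2630344, n_bins = 10)
  expect_equal(estimate_tumor_fraction(one)$f_hat, 0.40, tolerance = 1e-4)

  loss <- data.frame(chrom = "c", start = 0, end = 1e7, state = "loss",
                     median_log2 = -0.3219281, n_bins = 10)
  expect_equal(estimate_tumor_fraction(loss)$f_hat, 0.40, tolerance = 1e-4)
})

test_that("estimated tumor fraction is monotone over a titration grid", {
  lay <- miniature_layout()
  prof <- miniature_profile()
  bins <- sim_bin_gc(make_bins(lay), prof, lay)
  healthy <- lapply(1:5, function(i)
    simulate_sample(sim_profile(), lay, 0, depth = 2, seed = 500 + i))
  bl <- cnv_baseline(healthy, bins)
  f_grid <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  tit <- titration_series(prof, lay, f_grid, reps_per_f = 5, depth = 2, seed = 61)
  truth <- vapply(tit, function(s) s$metadata$truth_f, 0)
  est <- vapply(tit, function(s) cnv_profile(s, bins, bl)$tumor_fraction$f_hat, 0)
  expect_gt(stats::cor(truth, est, method = "spearman"), 0.9)
})

test_that("feature rows align across samples and sit near zero for healthy", {
  lay <- tiny_layout()
  prof <- sim_profile()
  bins <- sim_bin_gc(make_bins(lay), prof, lay)
  healthy <- lapply(1:5, function(i)
    simulate_sample(prof, lay, 0, depth = 1, seed = 600 + i))
  bl <- cnv_baseline(healthy, bins)
  s <- simulate_sample(prof, lay, 0, depth = 1, seed = 99)
  v <- cnv_features(log2_ratios(
    gc_correct(bin_depths(s, bins), bins$gc, bins$kept), bl, bins$kept), bins)
  expect_length(v, sum(bins$kept))
  expect_lt(abs(stats::median(v)), 0.02)
  s2 <- simulate_sample(prof, lay, 0, depth = 1, seed = 98)
  v2 <- cnv_features(log2_ratios(
    gc_correct(bin_depths(s2, bins), bins$gc, bins$kept), bl, bins$kept), bins)
  expect_identical(names(v), names(v2))
})
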