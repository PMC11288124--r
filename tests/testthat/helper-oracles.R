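# Independent oracles, kept deliberately naive and separate from the
# package implementations they check.

# AUC by exhaustive positive/negative pair counting
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Viterbi oracle: enumerate every K^n state path
brute_viterbi <- function(x, params) {
  K <- length(params$mu); n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lA <- matrix(NA_real_, K, K)
  for (j in seq_len(K)) for (k in seq_len(K))
    lA[j, k] <- if (j == k) log(params$self) else
      log((1 - params$self) * params$state_weights[k] /
            sum(params$state_weights[-j]))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(params$init[p[1]]) +
      sum(stats::dnorm(x, params$mu[p], params$sigma, log = TRUE))
    if (n > 1) lp <- lp + sum(lA[cbind(p[-n], p[-1])])
    if (lp > best) { best <- lp; best_path <- p }
  }
  list(path = unname(best_path), loglik = best)
}

# Benjamini-Hochberg by the step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Jonckheere-Terpstra statistic, naive double loop
jt_stat_oracle <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (a in groups[[i]]) for (b in groups[[j]])
      s <- s + (a < b) + 0.5 * (a == b)
  s
}

# Monte-Carlo permutation p for the increasing alternative
jt_perm_p <- function(groups, B = 20000, seed = 7) {
  set.seed(seed)
  obs <- jt_stat_oracle(groups)
  vals <- unlist(groups)
  ns <- lengths(groups)
  hits <- 0
  for (b in seq_len(B)) {
    v <- sample(vals)
    g <- split(v, rep(seq_along(ns), ns))
    if (jt_stat_oracle(g) >= obs - 1e-9) hits <- hits + 1
  }
  hits / B
}

# Wilson interval written independently from the package closed form
wilson_oracle <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  lo <- (2 * n * p + z^2 - z * sqrt(z^2 + 4 * n * p * (1 - p))) / (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + z * sqrt(z^2 + 4 * n * p * (1 - p))) / (2 * (n + z^2))
  c(lo, hi)
}
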