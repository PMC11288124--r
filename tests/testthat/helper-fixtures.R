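# Shared fixtures. Heavy objects are built lazily and cached for the whole
# test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small two-chromosome genome for fast unit tests (14 Mb)
tiny_layout <- function() {
  build_layout(
    data.frame(chrom = c("chrT1", "chrT2"), length = c(8e6, 6e6)),
    data.frame(chrom = c("chrT1", "chrT2"),
               start = c(3.9e6, 2.9e6), end = c(4.1e6, 3.1e6)))
}

# one-point-per-family grids: fast deterministic training for plumbing tests
grids1 <- function() {
  list(glmnet = data.frame(alpha = 0, lambda = 0.05),
       xgb_gbtree = data.frame(max_depth = 2, eta = 0.3, nrounds = 30),
       xgb_dart = data.frame(max_depth = 2, eta = 0.3, nrounds = 30),
       ranger = data.frame(num_trees = 200, mtry_frac = 0.3),
       nnet = data.frame(size = 2, decay = 1))
}

# separable gaussian feature blocks for classifier plumbing tests
gaussian_blocks <- function(n_per_class = 20, p = 25, shift = c(2, 1.5, 1),
                            seed = 99) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c("cancer", "healthy"), each = n_per_class)
  mk <- function(s) {
    X <- matrix(stats::rnorm(n * p), n, p)
    X[seq_len(n_per_class), 1:5] <- X[seq_len(n_per_class), 1:5] + s
    dimnames(X) <- list(sprintf("s%02d", seq_len(n)), sprintf("f%02d", seq_len(p)))
    X
  }
  list(blocks = list(CNV = mk(shift[1]), FSD = mk(shift[2]), NF = mk(shift[3])),
       labels = y)
}

# the default end-to-end synthetic study (miniature genome, depth 5,
# 20+20 train / 10+10 test); cached because several acceptance properties
# read from the same run
default_study <- function() {
  cached("default_study", run_pipeline(list(seed = 1L)))
}
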