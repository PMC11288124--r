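#' Per-bin fragment counts
#'
#' Each fragment is assigned to the bin containing its midpoint (half-open),
#' so every fragment is counted exactly once. Counts are returned for all
#' bins (kept or not), zero-filled.
#'
#' @param sample a `sample_fragments`.
#' @param bins a `bin_grid`.
#' @return integer vector, one count per bin row.
#' @export
bin_depths <- function(sample, bins) {
  counts <- integer(nrow(bins))
  fr <- sample$fragments
  for (cc in unique(bins$chrom)) {
    bi <- which(bins$chrom == cc)
    fi <- fr$chrom == cc
    if (!any(fi)) next
    mid <- (fr$start[fi] + fr$end[fi]) / 2
    edges <- c(bins$start[bi], bins$end[bi[length(bi)]])
    j <- findInterval(mid, edges, rightmost.closed = FALSE)
    j <- j[j >= 1 & j <= length(bi)]
    tab <- tabulate(j, nbins = length(bi))
    counts[bi] <- counts[bi] + tab
  }
  counts
}

#' GC-correct per-bin depths
#'
#' Fits a loess curve of depth against bin GC on the kept bins, divides
#' depths by the fitted expectation, and rescales so the genome-wide mean
#' depth over kept bins is preserved.
#'
#' @param depths numeric per-bin depths.
#' @param bin_gc per-bin GC fractions.
#' @param kept logical mask of usable bins (default all).
#' @param span loess span (default 0.75).
#' @return corrected depths (same length; non-kept bins passed through
#'   uncorrected).
#' @export
gc_correct <- function(depths, bin_gc, kept = NULL, span = 0.75) {
  if (is.null(kept)) kept <- rep(TRUE, length(depths))
  kept <- kept & !is.na(bin_gc)
  if (sum(kept) < 10) stop("need at least 10 kept bins to fit a GC curve")
  fit <- stats::loess(d ~ g, data = data.frame(d = depths[kept], g = bin_gc[kept]),
                      span = span, degree = 2, family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  pred <- stats::predict(fit, newdata = data.frame(g = bin_gc[kept]))
  floorv <- 0.1 * mean(depths[kept])
  pred <- pmax(pred, floorv)
  out <- depths
  corr <- depths[kept] / pred
  out[kept] <- corr * mean(depths[kept]) / mean(corr)
  out
}

#' Healthy-panel baseline for copy-number calling
#'
#' The expected depth of each kept bin is the per-bin median across a
#' healthy reference panel after GC correction. Panel membership is the
#' caller's configuration.
#'
#' @param samples list of healthy `sample_fragments`.
#' @param bins a `bin_grid` with a `gc` column.
#' @return list `expected` (per-bin, NA for non-kept), `gc`, `n_panel`.
#' @export
cnv_baseline <- function(samples, bins) {
  if (is.null(bins$gc)) stop("bin grid has no gc column; see attach_bin_gc()")
  mat <- vapply(samples, function(s)
    gc_correct(bin_depths(s, bins), bins$gc, bins$kept), numeric(nrow(bins)))
  expected <- apply(as.matrix(mat), 1, stats::median)
  expected[!bins$kept] <- NA_real_
  if (any(bins$kept & (is.na(expected) | expected <= 0)))
    warning("baseline non-positive on some kept bins; they will error in log2_ratios")
  list(expected = expected, gc = bins$gc, n_panel = length(samples))
}

#' Per-bin log2 depth ratios versus a baseline
#'
#' log2(corrected depth / baseline expectation) on kept bins, then
#' median-centered so a predominantly neutral genome sits at 0.
#'
#' @param corrected GC-corrected per-bin depths.
#' @param baseline a [cnv_baseline()] result (or numeric expected depths).
#' @param kept logical mask of usable bins.
#' @return numeric per-bin log2 ratio (NA on non-kept bins).
#' @export
log2_ratios <- function(corrected, baseline, kept = NULL) {
  expected <- if (is.list(baseline)) baseline$expected else baseline
  if (is.null(kept)) kept <- !is.na(expected)
  if (any(kept & (is.na(expected) | expected <= 0)))
    stop("baseline must be positive on kept bins")
  r <- rep(NA_real_, length(corrected))
  r[kept] <- log2(pmax(corrected[kept], 1e-9) / expected[kept])
  r[kept] <- r[kept] - stats::median(r[kept])
  r
}

#' HMM parameters for copy-number segmentation
#'
#' Four Gaussian-emission states (loss, neutral, gain, amplification) with
#' shared SD and a sticky self-transition; a simplified ichorCNA-style
#' model without subclonal states or B-allele frequencies.
#'
#' @param mu state means on the log2 scale.
#' @param sigma shared emission SD.
#' @param self self-transition probability.
#' @param init initial state distribution (defaults strongly neutral).
#' @param state_weights relative probability of entering each state on a
#'   transition; the default downweights amplification so that a segment
#'   equally well explained as a single-copy gain or as an amplification at
#'   half the tumor fraction resolves to the parsimonious single-copy call.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(mu = c(loss = -0.30, neutral = 0, gain = 0.25,
                              amplification = 0.60),
                       sigma = 0.15, self = 0.999,
                       init = c(0.001, 0.997, 0.001, 0.001),
                       state_weights = c(1, 1, 1, 0.2)) {
  stopifnot(length(mu) == 4, !is.unsorted(mu), sigma > 0,
            self > 0, self < 1, length(init) == 4,
            length(state_weights) == 4, all(state_weights > 0))
  structure(list(mu = mu, sigma = sigma, self = self, init = init / sum(init),
                 state_weights = state_weights),
            class = "hmm_params")
}

# Viterbi decoding for one chromosome's log2 sequence (log space);
# returns the state path and the path log-probability
.viterbi <- function(x, params) {
  K <- length(params$mu)
  n <- length(x)
  if (n == 0L) return(list(path = integer(), loglik = 0))
  w <- params$state_weights
  lA <- matrix(0, K, K)
  for (j in 1:K) {
    out <- (1 - params$self) * w / sum(w[-j])
    out[j] <- params$self
    lA[j, ] <- log(out)
  }
  emis <- function(t) stats::dnorm(x[t], params$mu, params$sigma, log = TRUE)
  V <- matrix(-Inf, K, n)
  bp <- matrix(0L, K, n)
  V[, 1] <- log(params$init) + emis(1)
  if (n > 1) for (t in 2:n) {
    e <- emis(t)
    for (k in 1:K) {
      cand <- V[, t - 1] + lA[, k]
      bp[k, t] <- which.max(cand)
      V[k, t] <- cand[bp[k, t]] + e[k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(V[, n])
  if (n > 1) for (t in (n - 1):1) path[t] <- bp[path[t + 1], t + 1]
  list(path = path, loglik = max(V[, n]))
}

# robust per-bin noise SD from successive differences of kept bins
.robust_sigma <- function(bin_log2, bins, floor = 0.01) {
  d <- unlist(lapply(unique(bins$chrom), function(cc) {
    x <- bin_log2[bins$chrom == cc]
    diff(x[!is.na(x)])
  }))
  if (length(d) < 5) return(0.15)
  max(stats::mad(d) / sqrt(2), floor)
}

#' Segment log2 ratios with a 4-state Gaussian HMM
#'
#' Viterbi decoding per chromosome (chromosomes are independent); segments
#' are maximal runs of consecutive kept bins in the same state.
#'
#' With explicit `params` the given state means and SD are used directly.
#' With `params = NULL` (the default) the model adapts to the data the way
#' tumor-fraction-aware callers do: the emission SD is estimated robustly
#' from successive bin differences, and the state means are scanned over a
#' grid of candidate tumor fractions \eqn{f_c} (loss \eqn{\log_2(1-f_c/2)},
#' gain \eqn{\log_2(1+f_c/2)}, amplification \eqn{\log_2(1+f_c)}); the
#' candidate whose Viterbi path has the highest log-probability wins. This
#' is what makes shallow single-copy events at low tumor fraction callable.
#'
#' @param bin_log2 per-bin log2 ratios (NA on non-kept bins).
#' @param bins the `bin_grid` the ratios were computed on.
#' @param params an [hmm_params()], or NULL for the adaptive scan.
#' @param f_scan candidate tumor fractions for the adaptive scan.
#' @return list: `states` (character per bin, NA on non-kept), `segments`
#'   (data.frame chrom, start, end, state, median_log2, n_bins), `params`
#'   (the parameters used) and `loglik`.
#' @export
hmm_segment <- function(bin_log2, bins, params = NULL,
                        f_scan = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.8)) {
  if (is.null(params)) {
    sigma <- .robust_sigma(bin_log2, bins)
    best <- NULL
    for (fc in f_scan) {
      pc <- hmm_params(mu = c(loss = log2(1 - fc / 2), neutral = 0,
                              gain = log2(1 + fc / 2),
                              amplification = log2(1 + fc)),
                       sigma = sigma)
      res <- hmm_segment(bin_log2, bins, pc)
      if (is.null(best) || res$loglik > best$loglik) best <- res
    }
    return(best)
  }
  kept <- !is.na(bin_log2)
  if (any(!is.finite(bin_log2[kept]))) stop("non-finite log2 input")
  state_names <- names(params$mu)
  states <- rep(NA_character_, length(bin_log2))
  segs <- list()
  loglik <- 0
  for (cc in unique(bins$chrom)) {
    idx <- which(bins$chrom == cc & kept)
    if (!length(idx)) next
    vit <- .viterbi(bin_log2[idx], params)
    path <- vit$path
    loglik <- loglik + vit$loglik
    states[idx] <- state_names[path]
    runs <- rle(path)
    stop_at <- cumsum(runs$lengths)
    start_at <- c(1L, utils::head(stop_at, -1) + 1L)
    for (j in seq_along(runs$values)) {
      ii <- idx[start_at[j]:stop_at[j]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = cc, start = bins$start[ii[1]], end = bins$end[ii[length(ii)]],
        state = state_names[runs$values[j]],
        median_log2 = stats::median(bin_log2[ii]),
        n_bins = length(ii), stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               state = character(), median_log2 = numeric(), n_bins = integer())
  list(states = states, segments = segments, params = params, loglik = loglik)
}

#' Tumor fraction from called copy-number segments
#'
#' Inverts the single-copy clonal model for each non-neutral segment
#' (gain: \eqn{f = 2(2^r - 1)}; loss: \eqn{f = 2(1 - 2^r)} with r the
#' segment median log2 ratio) and combines them by a bin-count-weighted
#' median, clipped to \[0, 1\]. Zero when no CNA segment is called.
#'
#' @param segments segment table from [hmm_segment()].
#' @return list: `f_hat`, `n_cna_bins`, `method`.
#' @export
estimate_tumor_fraction <- function(segments) {
  cna <- segments[segments$state != "neutral", , drop = FALSE]
  if (!nrow(cna))
    return(list(f_hat = 0, n_cna_bins = 0L, method = "single_copy_inversion"))
  r <- cna$median_log2
  f <- ifelse(cna$state %in% c("gain", "amplification"),
              2 * (2^r - 1), 2 * (1 - 2^r))
  f <- pmin(pmax(f, 0), 1)
  o <- order(f)
  f <- f[o]; wt <- cna$n_bins[o]
  cw <- cumsum(wt) / sum(wt)
  f_hat <- f[which(cw >= 0.5)[1]]  # weighted median
  list(f_hat = f_hat, n_cna_bins = sum(cna$n_bins),
       method = "single_copy_inversion")
}

#' Copy-number feature row
#'
#' The ordered vector of per-kept-bin log2 ratios, named by bin coordinate;
#' fixed length across a cohort sharing one bin grid.
#'
#' @param bin_log2 per-bin log2 ratios.
#' @param bins the `bin_grid`.
#' @return named numeric vector (kept bins only).
#' @export
cnv_features <- function(bin_log2, bins) {
  kept <- which(!is.na(bin_log2))
  v <- bin_log2[kept]
  names(v) <- paste0(bins$chrom[kept], ":", bins$start[kept])
  v
}

#' Full copy-number profile for one sample
#'
#' Convenience wrapper: bin depths, GC correction, log2 ratios against the
#' baseline, HMM segmentation, tumor-fraction estimate.
#'
#' @param sample a `sample_fragments`.
#' @param bins a `bin_grid` with `gc`.
#' @param baseline a [cnv_baseline()].
#' @param params an [hmm_params()].
#' @return list: `bin_log2`, `states`, `segments`, `tumor_fraction`,
#'   `features`.
#' @export
cnv_profile <- function(sample, bins, baseline, params = NULL) {
  d <- gc_correct(bin_depths(sample, bins), bins$gc, bins$kept)
  r <- log2_ratios(d, baseline, bins$kept)
  seg <- hmm_segment(r, bins, params)
  list(bin_log2 = r, states = seg$states, segments = seg$segments,
       tumor_fraction = estimate_tumor_fraction(seg$segments),
       features = cnv_features(r, bins))
}
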