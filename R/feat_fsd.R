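#' Default fragment-size bin edges
#'
#' 24 contiguous half-open 5-bp bins starting at 110 bp:
#' \[110,115), ..., \[225,230). The bin count (24 per arm, 936 = 39 x 24
#' features genome-wide) is the load-bearing contract; edges are config.
#'
#' @return numeric vector of 25 edges.
#' @export
fsd_bin_edges <- function() seq(110, 230, by = 5)

#' Arm-by-size fragment counts
#'
#' Fragments are assigned to the chromosome arm containing their midpoint
#' and to the half-open size bin containing their length; fragments outside
#' the size range or outside every arm are ignored.
#'
#' @param sample a `sample_fragments`.
#' @param arms an `arm_set` (see [list_arms()], [hg19_arms()]).
#' @param bin_edges strictly increasing size-bin edges (default
#'   [fsd_bin_edges()]).
#' @return integer matrix, arms x size bins, dimnames
#'   (`chrom.arm`, `lo_hi`).
#' @export
fsd_counts <- function(sample, arms, bin_edges = fsd_bin_edges()) {
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  arm_names <- paste0(arms$chrom, arms$arm)
  counts <- matrix(0L, nrow(arms), nb,
                   dimnames = list(arm_names,
                                   paste0(utils::head(bin_edges, -1), "_",
                                          utils::tail(bin_edges, -1))))
  fr <- sample$fragments
  sz <- findInterval(fr$length, bin_edges, rightmost.closed = FALSE)
  in_range <- sz >= 1 & sz <= nb & fr$length < bin_edges[nb + 1L]
  mid <- (fr$start + fr$end) / 2
  for (a in seq_len(nrow(arms))) {
    sel <- in_range & fr$chrom == arms$chrom[a] &
      mid >= arms$start[a] & mid < arms$end[a]
    if (!any(sel)) next
    counts[a, ] <- tabulate(sz[sel], nbins = nb)
  }
  counts
}

#' Within-sample z-scoring of the FSD matrix
#'
#' Standardizes every cell against the single sample-wide mean and SD of
#' all cells (not per-arm), isolating the shape of the size distribution
#' from sequencing-depth differences. Uses the n-1 (sample) SD.
#'
#' @param raw_counts matrix from [fsd_counts()].
#' @return matrix of z-scores, same shape.
#' @export
fsd_zscore <- function(raw_counts) {
  x <- as.numeric(raw_counts)
  if (length(x) < 2) stop("need at least 2 cells")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant FSD matrix: zero SD")
  z <- (raw_counts - mean(x)) / s
  z
}

#' Fragment-size-distribution feature row
#'
#' Row-major flatten of the z-scored arm x size-bin matrix (arm-major,
#' size-bin-minor), with stable names, so ordering is identical for every
#' sample sharing the arm/edge configuration. Default hg19 configuration:
#' 39 arms x 24 bins = 936 features.
#'
#' @inheritParams fsd_counts
#' @return named numeric vector of length `nrow(arms) * (length(bin_edges)-1)`.
#' @export
fsd_features <- function(sample, arms, bin_edges = fsd_bin_edges()) {
  z <- fsd_zscore(fsd_counts(sample, arms, bin_edges))
  v <- as.numeric(t(z))
  names(v) <- as.character(outer(colnames(z), rownames(z),
                                 function(b, a) paste0(a, "_", b))[TRUE])
  v
}
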