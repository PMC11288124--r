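#' Read TFBS site sets from BED files
#'
#' One BED file per site set; the set id defaults to the file base name.
#' Site centers are interval midpoints; strand comes from column 6 when
#' present (else "+"). Minus-strand sites have their composite profile
#' mirrored downstream.
#'
#' @param bed_paths character vector of BED paths, optionally named (names
#'   become set ids).
#' @return named list of data.frames (`chrom`, `center`, `strand`).
#' @export
read_sites <- function(bed_paths) {
  ids <- names(bed_paths)
  if (is.null(ids)) ids <- rep(NA_character_, length(bed_paths))
  ids[is.na(ids) | !nzchar(ids)] <-
    sub("\\.bed(\\.gz)?$", "", basename(bed_paths[is.na(ids) | !nzchar(ids)]))
  if (anyDuplicated(ids)) stop("duplicate site-set id: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  out <- lapply(bed_paths, function(p) {
    tab <- utils::read.table(p, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, fill = TRUE)
    if (ncol(tab) < 3 || !is.numeric(tab[[2]]) || !is.numeric(tab[[3]]) ||
        any(tab[[3]] <= tab[[2]]))
      stop("malformed BED: ", p)
    data.frame(chrom = as.character(tab[[1]]),
               center = floor((tab[[2]] + tab[[3]]) / 2),
               strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "+",
               stringsAsFactors = FALSE)
  })
  names(out) <- ids
  out
}

#' Composite coverage profile around a site set
#'
#' Coverage is accumulated in 15-bp offset bins spanning -960..+960 bp
#' around each site center (129 offsets), summed over all sites of the set
#' (minus-strand sites flipped), optionally weighting each fragment by a GC
#' model, and normalized so the mean over offsets is 1.
#'
#' @param sample a `sample_fragments`.
#' @param site_set data.frame with `chrom`, `center`, `strand`.
#' @param gc_model optional function(gc) -> weight (see [fit_gc_model()]).
#' @param window half-window in bp (default 960).
#' @param step offset bin width in bp (default 15).
#' @return list of class `composite_profile`: `offsets` (bin centers, bp)
#'   and `coverage` (mean-1-normalized values).
#' @export
composite_profile <- function(sample, site_set, gc_model = NULL,
                              window = 960, step = 15) {
  if (nrow(site_set) < 10) stop("need at least 10 sites")
  n_off <- 2L * as.integer(window / step) + 1L
  offsets <- seq(-window, window, by = step)
  half <- window + step / 2
  cov <- numeric(n_off)
  fr <- sample$fragments
  max_len <- 1000  # fragments are bounded; used only to narrow the search
  w_all <- if (!is.null(gc_model) && !is.null(fr$gc)) gc_model(fr$gc) else NULL
  for (cc in unique(site_set$chrom)) {
    fi <- which(fr$chrom == cc)
    if (!length(fi)) next
    st <- fr$start[fi]; en <- fr$end[fi]
    sites <- site_set[site_set$chrom == cc, , drop = FALSE]
    lo <- sites$center - half
    hi <- sites$center + half
    i1 <- findInterval(lo - max_len, st) + 1L
    i2 <- findInterval(hi, st)
    n_k <- pmax(i2 - i1 + 1L, 0L)
    if (!sum(n_k)) next
    frag <- sequence(n_k, from = i1)
    site <- rep.int(seq_len(nrow(sites)), n_k)
    ok <- en[frag] > lo[site]
    frag <- frag[ok]; site <- site[ok]
    if (!length(frag)) next
    b0 <- pmax(floor((st[frag] - lo[site]) / step), 0)
    b1 <- pmin(ceiling((en[frag] - lo[site]) / step) - 1, n_off - 1)
    ok <- b1 >= b0
    frag <- frag[ok]; site <- site[ok]; b0 <- b0[ok]; b1 <- b1[ok]
    if (!length(frag)) next
    nrep <- as.integer(b1 - b0 + 1L)
    idx <- sequence(nrep, from = as.integer(b0 + 1L))
    flip <- rep.int(sites$strand[site] == "-", nrep)
    idx[flip] <- n_off + 1L - idx[flip]
    w <- if (is.null(w_all)) rep.int(1, length(frag)) else w_all[fi[frag]]
    acc <- rowsum(rep.int(w, nrep), idx)
    cov[as.integer(rownames(acc))] <- cov[as.integer(rownames(acc))] + acc[, 1]
  }
  m <- mean(cov)
  if (m <= 0) stop("no fragments near any site")
  structure(list(offsets = offsets, coverage = cov / m),
            class = "composite_profile")
}

#' Nucleosome-footprint summaries of a composite profile
#'
#' Three dimensionless summaries per site set: central coverage (mean of
#' offsets within +/-30 bp of the center), average coverage (mean over the
#' whole +/-1000 bp window, i.e. all offsets), and the amplitude of the
#' ~193-bp nucleosome periodicity, read from the discrete Fourier component
#' of the mean-subtracted profile at the frequency index nearest a 193-bp
#' period (index 10 of the 129-point window), scaled by 2/N.
#'
#' @param profile a `composite_profile`.
#' @param central_halfwidth bp (default 30).
#' @param period_bp nucleosome period targeted by the amplitude (default 193).
#' @return list: `central`, `average`, `amplitude`.
#' @export
nf_summaries <- function(profile, central_halfwidth = 30, period_bp = 193) {
  v <- profile$coverage
  off <- profile$offsets
  n <- length(v)
  span <- (off[2] - off[1]) * n
  k <- round(span / period_bp)
  x <- v - mean(v)
  amp <- 2 / n * Mod(stats::fft(x)[k + 1L])
  list(central = mean(v[abs(off) <= central_halfwidth]),
       average = mean(v),
       amplitude = amp)
}

#' Fragment-level GC weighting model
#'
#' Estimates a smooth acceptance curve by comparing the sample's fragment
#' GC density with the expected GC density implied by the genome's bin GC
#' annotation, and returns the inverse-acceptance weight function
#' `w(gc) = expected(gc) / observed(gc)` (clipped, mean-normalized over the
#' sample's fragments).
#'
#' @param sample a `sample_fragments` with a `gc` column.
#' @param expected_gc numeric vector of reference GC values (e.g. the kept
#'   bins' GC, or simulated fragment GC under no bias).
#' @param clip weight clip range (default c(0.2, 5)).
#' @return function(gc) -> weight, or NULL when the sample has no fragment GC.
#' @export
fit_gc_model <- function(sample, expected_gc, clip = c(0.2, 5)) {
  gc <- sample$fragments$gc
  if (is.null(gc)) return(NULL)
  grid <- seq(0, 1, length.out = 201)
  bw <- 0.02
  d_obs <- stats::density(gc, bw = bw, from = 0, to = 1, n = 201)$y
  d_exp <- stats::density(expected_gc, bw = bw, from = 0, to = 1, n = 201)$y
  ratio <- pmin(pmax(d_exp / pmax(d_obs, 1e-6), clip[1]), clip[2])
  f <- stats::approxfun(grid, ratio, rule = 2)
  m <- mean(f(gc))
  function(g) f(g) / m
}

#' Nucleosome-footprint feature row
#'
#' For each site set in order: central coverage, average coverage, FFT
#' amplitude. Default collection of 854 TFBS sets yields 2562 features.
#'
#' @param sample a `sample_fragments`.
#' @param site_sets named list of site sets (see [read_sites()],
#'   [miniature_sites()]).
#' @param gc_model optional function(gc) -> weight.
#' @param window,step see [composite_profile()].
#' @return named numeric vector of length `3 * length(site_sets)`.
#' @export
nf_features <- function(sample, site_sets, gc_model = NULL,
                        window = 960, step = 15) {
  out <- lapply(names(site_sets), function(id) {
    s <- nf_summaries(composite_profile(sample, site_sets[[id]], gc_model,
                                        window, step))
    stats::setNames(c(s$central, s$average, s$amplitude),
                    paste0(id, c(".central", ".average", ".amplitude")))
  })
  unlist(out)
}
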