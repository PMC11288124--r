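#' Simulation profile for synthetic plasma cohorts
#'
#' Describes the generative model for cfDNA fragments in a plasma sample
#' carrying tumor fraction `f`:
#' \itemize{
#'   \item healthy fragment lengths from a two-mode truncated normal mixture
#'     (mono- and di-nucleosome peaks);
#'   \item tumor-derived fragments use the same mixture with its means
#'     shifted by `tumor_length_shift` bp (negative = shorter, the hallmark
#'     of ctDNA);
#'   \item local fragment density scaled by tumor copy number: a locus at
#'     copy number \eqn{c} has relative depth \eqn{(1-f) + f c/2};
#'   \item tumor fragments overlapping "active" transcription-factor site
#'     sets are thinned by `depletion`, carving an f-dependent nucleosome
#'     depletion footprint;
#'   \item a monotone logistic GC acceptance bias (coefficient `gc_bias`)
#'     so that GC correction downstream has real signal to remove.
#' }
#'
#' @param healthy_length_mix list with `weights`, `means`, `sds` (bp) and
#'   `range` (truncation bounds, bp). Default: 0.9 N(167, 10) + 0.1
#'   N(320, 25) truncated to \[60, 500\].
#' @param tumor_length_shift bp added to tumor-component means (default -20).
#' @param cnv_segments data.frame `chrom`, `start`, `end`, `copy_number`
#'   describing the tumor genome (NULL = flat diploid).
#' @param active_sites character vector of site-set ids depleted in tumor.
#' @param depletion depletion depth in (0, 1]: tumor fragments overlapping
#'   an active site center are retained with probability `1 - depletion`.
#' @param gc_bias logistic acceptance coefficient (0 = no bias).
#' @param gc_wave list `mean`, `amp`, `period` (bp): smooth sinusoidal GC
#'   baseline along the concatenated genome from which fragment GC is drawn.
#' @param gc_noise SD of per-fragment GC around the baseline.
#' @return object of class `sim_profile`.
#' @export
sim_profile <- function(healthy_length_mix = list(weights = c(0.9, 0.1),
                                                  means = c(167, 320),
                                                  sds = c(10, 25),
                                                  range = c(60, 500)),
                        tumor_length_shift = -20,
                        cnv_segments = NULL,
                        active_sites = character(),
                        depletion = 0.7,
                        gc_bias = 1,
                        gc_wave = list(mean = 0.45, amp = 0.08, period = 2e7),
                        gc_noise = 0.04) {
  mix <- healthy_length_mix
  stopifnot(abs(sum(mix$weights) - 1) < 1e-8,
            length(mix$weights) == length(mix$means),
            length(mix$means) == length(mix$sds),
            depletion > 0, depletion <= 1)
  if (!is.null(cnv_segments)) {
    cnv_segments <- as.data.frame(cnv_segments)
    stopifnot(all(c("chrom", "start", "end", "copy_number") %in% names(cnv_segments)),
              all(cnv_segments$copy_number >= 0))
  }
  structure(list(healthy_length_mix = mix,
                 tumor_length_shift = tumor_length_shift,
                 cnv_segments = cnv_segments,
                 active_sites = active_sites,
                 depletion = depletion,
                 gc_bias = gc_bias, gc_wave = gc_wave, gc_noise = gc_noise),
            class = "sim_profile")
}

#' Mean of the healthy fragment-length mixture
#' @param profile a `sim_profile`.
#' @return mixture mean in bp (truncation ignored; its mass is negligible at
#'   the default parameters).
#' @export
healthy_mixture_mean <- function(profile) {
  mix <- profile$healthy_length_mix
  sum(mix$weights * mix$means)
}

#' Miniature two-chromosome test genome
#'
#' 50 Mb + 30 Mb chromosomes with centromeres at their midpoints: small
#' enough that 5x-equivalent cohorts are generated in seconds, large enough
#' to carry multi-Mb CNV segments and hundreds of TFBS.
#'
#' @return a `genome_layout` with chromosomes `chrA`, `chrB`.
#' @export
miniature_layout <- function() {
  build_layout(
    data.frame(chrom = c("chrA", "chrB"), length = c(5e7, 3e7)),
    data.frame(chrom = c("chrA", "chrB"),
               start = c(24.75e6, 14.85e6), end = c(25.25e6, 15.15e6)))
}

#' Default simulation profile for the miniature genome
#'
#' The reference tumor genome carries one single-copy gain (chrA 5-20 Mb,
#' copy number 3) and one single-copy loss (chrB 18-28 Mb, copy number 1),
#' and the first three TFBS site sets are "active" (nucleosome-depleted in
#' tumor).
#'
#' @param ... overrides forwarded to [sim_profile()].
#' @return a `sim_profile`.
#' @export
miniature_profile <- function(...) {
  args <- list(...)
  defaults <- list(
    cnv_segments = data.frame(chrom = c("chrA", "chrB"),
                              start = c(5e6, 18e6), end = c(20e6, 28e6),
                              copy_number = c(3, 1)),
    active_sites = c("TF01", "TF02", "TF03"))
  do.call(sim_profile, utils::modifyList(defaults, args))
}

#' Random TFBS site-set collection on a layout
#'
#' Site centers are placed uniformly on chromosome arms (clear of
#' centromeres and chromosome ends); strands are random. Used as the NF
#' fixture for synthetic cohorts.
#'
#' @param layout a `genome_layout`.
#' @param n_sets number of site sets (default 10).
#' @param sites_per_set sites per set (default 200).
#' @param seed RNG seed.
#' @return named list of data.frames (`chrom`, `center`, `strand`) with ids
#'   `TF01`, `TF02`, ...
#' @export
miniature_sites <- function(layout, n_sets = 10, sites_per_set = 200, seed = 42L) {
  set.seed(seed)
  arms <- list_arms(layout, drop_acrocentric_p = FALSE)
  margin <- 2000
  arms$start <- arms$start + margin
  arms$end <- arms$end - margin
  w <- arms$end - arms$start
  out <- lapply(seq_len(n_sets), function(i) {
    a <- sample.int(nrow(arms), sites_per_set, replace = TRUE, prob = w)
    data.frame(chrom = arms$chrom[a],
               center = floor(arms$start[a] + stats::runif(sites_per_set) * w[a]),
               strand = sample(c("+", "-"), sites_per_set, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  names(out) <- sprintf("TF%02d", seq_len(n_sets))
  out
}

# GC baseline along the concatenated genome
.gc_baseline <- function(profile, gpos) {
  w <- profile$gc_wave
  w$mean + w$amp * sin(2 * pi * gpos / w$period)
}

#' Per-bin GC annotation consistent with a simulation profile
#'
#' Evaluates the profile's GC baseline at bin midpoints, so the bin GC used
#' by copy-number correction matches the expectation of the simulated
#' fragment GC.
#'
#' @param bins a `bin_grid`.
#' @param profile a `sim_profile`.
#' @param layout the `genome_layout` the bins were made from.
#' @return the bin grid with a `gc` column.
#' @export
sim_bin_gc <- function(bins, profile, layout) {
  off <- .chrom_offsets(layout)
  gpos <- off[bins$chrom] + (bins$start + bins$end) / 2
  attach_bin_gc(bins, .gc_baseline(profile, gpos))
}

# piecewise (chrom, start, end, copy_number) cover of the genome
.cn_pieces <- function(profile, layout) {
  ch <- layout$chroms
  segs <- profile$cnv_segments
  pieces <- lapply(seq_len(nrow(ch)), function(i) {
    L <- ch$length[i]
    cuts <- c(0, L)
    if (!is.null(segs)) {
      s <- segs[segs$chrom == ch$chrom[i], , drop = FALSE]
      cuts <- sort(unique(c(cuts, pmax(0, pmin(L, c(s$start, s$end))))))
    }
    p <- data.frame(chrom = ch$chrom[i], start = cuts[-length(cuts)],
                    end = cuts[-1], copy_number = 2, stringsAsFactors = FALSE)
    if (!is.null(segs)) {
      s <- segs[segs$chrom == ch$chrom[i], , drop = FALSE]
      for (j in seq_len(nrow(s))) {
        mid <- (p$start + p$end) / 2
        p$copy_number[mid >= s$start[j] & mid < s$end[j]] <- s$copy_number[j]
      }
    }
    p
  })
  do.call(rbind, pieces)
}

#' Simulate one plasma sample
#'
#' Draws fragments from the mixture of a healthy and a tumor component at
#' tumor fraction `f` (see [sim_profile()] for the generative model).
#' Deterministic given `seed`.
#'
#' @param profile a `sim_profile`.
#' @param layout a `genome_layout`.
#' @param f tumor fraction in \[0, 1\].
#' @param depth target mean depth (x), default 5.
#' @param seed RNG seed.
#' @param sites named list of site sets (as from [miniature_sites()]);
#'   needed only when the profile names active sites.
#' @param sample_id identifier (default derived from seed).
#' @return a `sample_fragments` whose metadata carries `label`
#'   ("cancer"/"healthy"), `truth_f` and `seed`.
#' @export
simulate_sample <- function(profile, layout, f, depth = 5, seed = 1L,
                            sites = NULL, sample_id = NULL) {
  if (f < 0 || f > 1) stop("tumor fraction f must be in [0, 1]")
  stopifnot(depth > 0)
  set.seed(seed)
  if (is.null(sample_id)) sample_id <- sprintf("sim_%d", seed)

  pieces <- .cn_pieces(profile, layout)
  w <- (1 - f) + f * pieces$copy_number / 2
  plen <- pieces$end - pieces$start
  L <- sum(plen)
  p_tumor_overall <- sum(f * pieces$copy_number / 2 * plen) / sum(w * plen)
  mix <- profile$healthy_length_mix
  mean_len <- sum(mix$weights * mix$means) + p_tumor_overall * profile$tumor_length_shift
  n_target <- round(depth * L / mean_len)

  # estimate the GC-bias acceptance rate so realized depth hits the target
  p_acc <- 1
  if (profile$gc_bias != 0) {
    gpos0 <- stats::runif(20000, 0, L)
    gc0 <- .gc_baseline(profile, gpos0) + stats::rnorm(20000, 0, profile$gc_noise)
    p_acc <- mean(stats::plogis(profile$gc_bias * (gc0 - profile$gc_wave$mean) / 0.1))
  }
  n_draw <- ceiling(n_target / p_acc)

  pc <- sample.int(nrow(pieces), n_draw, replace = TRUE, prob = w * plen)
  start <- floor(pieces$start[pc] + stats::runif(n_draw) * plen[pc])
  chrom <- pieces$chrom[pc]
  is_tumor <- stats::runif(n_draw) < (f * pieces$copy_number[pc] / 2) / w[pc]

  comp <- sample.int(length(mix$weights), n_draw, replace = TRUE, prob = mix$weights)
  mu <- mix$means[comp] + profile$tumor_length_shift * is_tumor
  len <- round(stats::rnorm(n_draw, mu, mix$sds[comp]))
  len <- pmin(pmax(len, mix$range[1]), mix$range[2])
  chrom_len <- layout$chroms$length[match(chrom, layout$chroms$chrom)]
  end <- pmin(start + len, chrom_len)

  off <- .chrom_offsets(layout)
  gpos <- off[chrom] + (start + end) / 2
  gc <- pmin(pmax(.gc_baseline(profile, gpos) +
                    stats::rnorm(n_draw, 0, profile$gc_noise), 0), 1)

  keep <- rep(TRUE, n_draw)
  if (profile$gc_bias != 0) {
    keep <- stats::runif(n_draw) <
      stats::plogis(profile$gc_bias * (gc - profile$gc_wave$mean) / 0.1)
  }

  # f-scaled nucleosome depletion: thin tumor fragments at active sites
  if (length(profile$active_sites) && !is.null(sites) && f > 0) {
    half <- 150
    act <- do.call(rbind, sites[intersect(profile$active_sites, names(sites))])
    if (!is.null(act) && nrow(act)) {
      for (cc in unique(act$chrom)) {
        ws <- sort(act$center[act$chrom == cc]) - half
        we <- sort(act$center[act$chrom == cc]) + half
        sel <- which(chrom == cc & is_tumor & keep)
        if (!length(sel)) next
        j <- findInterval(start[sel], ws)
        hit <- (j >= 1 & start[sel] < we[pmax(j, 1)]) |
          (j < length(ws) & end[sel] > ws[pmin(j + 1, length(ws))])
        drop <- hit & stats::runif(length(sel)) < profile$depletion
        keep[sel[drop]] <- FALSE
      }
    }
  }

  fr <- data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
                   gc = gc[keep], stringsAsFactors = FALSE)
  sample_fragments(sample_id, fr,
                   metadata = list(label = if (f > 0) "cancer" else "healthy",
                                   truth_f = f, seed = seed))
}

#' Simulate a labeled cohort
#'
#' Cancer samples draw their tumor fraction from `f_dist`; per-sample seeds
#' are derived from the master seed, so the whole cohort is reproducible.
#' Cancer samples get a pseudo-stage from their tumor fraction (I < 0.1
#' <= II < 0.2 <= III < 0.3 <= IV), mirroring the stage-tumor-burden
#' association real cohorts show.
#'
#' @param profile a `sim_profile`.
#' @param layout a `genome_layout`.
#' @param n_cancer,n_healthy sample counts.
#' @param f_dist function(n) returning n tumor fractions (default uniform
#'   on \[0.05, 0.30\]).
#' @param depth target depth (x).
#' @param seed master seed.
#' @param sites site-set collection (see [simulate_sample()]).
#' @return list of `sample_fragments`.
#' @export
simulate_cohort <- function(profile, layout, n_cancer, n_healthy,
                            f_dist = function(n) stats::runif(n, 0.05, 0.30),
                            depth = 5, seed = 1L, sites = NULL) {
  plan <- .cohort_plan(n_cancer, n_healthy, f_dist, seed)
  lapply(seq_len(nrow(plan)), function(i) {
    s <- simulate_sample(profile, layout, plan$f[i], depth, plan$seed[i],
                         sites, sample_id = plan$id[i])
    if (!is.na(plan$stage[i])) s$metadata$stage <- plan$stage[i]
    s
  })
}

# per-sample tumor fractions, derived seeds, ids and pseudo-stages for a
# cohort; shared by simulate_cohort() and the streaming pipeline
.cohort_plan <- function(n_cancer, n_healthy, f_dist, seed) {
  stopifnot(n_cancer >= 0, n_healthy >= 0)
  set.seed(seed)
  n <- n_cancer + n_healthy
  f <- c(if (n_cancer) f_dist(n_cancer), rep(0, n_healthy))
  seeds <- sample.int(2147483646L, n)
  data.frame(
    id = sprintf("%s%03d", ifelse(f > 0, "C", "H"), seq_len(n)),
    f = f, seed = seeds,
    label = ifelse(f > 0, "cancer", "healthy"),
    stage = ifelse(f > 0,
                   as.character(cut(f, c(0, 0.1, 0.2, 0.3, 1),
                                    labels = c("I", "II", "III", "IV"))),
                   NA_character_),
    stringsAsFactors = FALSE)
}

#' Titration series for limit-of-detection estimation
#'
#' `reps_per_f` independent samples at each tumor fraction of `f_grid`,
#' each labeled with its truth.
#'
#' @param profile a `sim_profile`.
#' @param layout a `genome_layout`.
#' @param f_grid tumor fractions in \[0, 1\].
#' @param reps_per_f replicates per grid point.
#' @param depth target depth (x).
#' @param seed master seed.
#' @param sites site-set collection.
#' @return list of `sample_fragments` (metadata `truth_f` holds the grid f).
#' @export
titration_series <- function(profile, layout, f_grid, reps_per_f, depth = 5,
                             seed = 1L, sites = NULL) {
  if (!length(f_grid)) stop("empty titration grid")
  stopifnot(all(f_grid >= 0 & f_grid <= 1), reps_per_f >= 1)
  set.seed(seed)
  f <- rep(f_grid, each = reps_per_f)
  seeds <- sample.int(2147483646L, length(f))
  lapply(seq_along(f), function(i)
    simulate_sample(profile, layout, f[i], depth, seeds[i], sites,
                    sample_id = sprintf("T%03d_f%g", i, f[i])))
}
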