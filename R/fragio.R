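#' Construct a per-sample fragment container
#'
#' `sample_fragments` is the raw substrate of all features: one row per
#' cfDNA fragment (chrom, start, end, 0-based half-open), plus sample
#' metadata (label, stage, grade, batch, handling-condition tags). Fragments
#' are kept sorted by (chrom, start); duplicates are permitted (PCR
#' deduplication is an upstream concern).
#'
#' @param sample_id non-empty sample identifier.
#' @param fragments data.frame with `chrom`, `start`, `end` and optionally
#'   `gc` (fragment GC fraction in \[0, 1\]).
#' @param metadata named list (e.g. `label`, `stage`, `grade`, `batch`).
#' @return object of class `sample_fragments`.
#' @export
sample_fragments <- function(sample_id, fragments, metadata = list()) {
  if (!nzchar(sample_id)) stop("sample_id must be non-empty")
  fragments <- as.data.frame(fragments)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(fragments))) stop("fragments need chrom/start/end")
  fragments$chrom <- as.character(fragments$chrom)
  fragments$start <- as.numeric(fragments$start)
  fragments$end <- as.numeric(fragments$end)
  if (any(fragments$end <= fragments$start)) stop("fragment with end <= start")
  if (!is.null(fragments$gc) &&
      any(!is.na(fragments$gc) & (fragments$gc < 0 | fragments$gc > 1)))
    stop("fragment gc outside [0, 1]")
  o <- order(fragments$chrom, fragments$start, fragments$end, method = "radix")
  fragments <- fragments[o, , drop = FALSE]
  rownames(fragments) <- NULL
  fragments$length <- fragments$end - fragments$start
  structure(list(sample_id = sample_id, fragments = fragments,
                 metadata = metadata),
            class = "sample_fragments")
}

#' @exportS3Method base::print
print.sample_fragments <- function(x, ...) {
  cat("<sample_fragments> ", x$sample_id, ": ",
      format(nrow(x$fragments), big.mark = ","), " fragments",
      if (!is.null(x$metadata$label)) paste0(" [", x$metadata$label, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Read fragment intervals from BED or TSV
#'
#' BED3 with an optional 4th numeric column holding fragment GC, or a
#' headered TSV with at least `chrom`, `start`, `end` columns. Gzip input is
#' transparent. In strict mode a malformed line aborts; in lenient mode it
#' is skipped and counted (attribute `n_skipped` on the result).
#'
#' @param path input file (optionally .gz).
#' @param format "bed", "tsv" or "auto" (headered file detected by a
#'   non-numeric second field on line 1).
#' @param sample_id defaults to the file base name.
#' @param mode "strict" (default) or "lenient".
#' @param metadata optional metadata list.
#' @return a [sample_fragments()] object.
#' @export
read_fragments <- function(path, format = c("auto", "bed", "tsv"),
                           sample_id = NULL, mode = c("strict", "lenient"),
                           metadata = list()) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(bed|tsv)(\\.gz)?$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty fragment file: ", path)
  if (format == "auto") {
    f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
    format <- if (length(f1) >= 2 && is.na(suppressWarnings(as.numeric(f1[2]))))
      "tsv" else "bed"
  }
  tab <- utils::read.table(path, sep = "\t", header = (format == "tsv"),
                           stringsAsFactors = FALSE, fill = TRUE)
  if (format == "bed") {
    names(tab)[1:3] <- c("chrom", "start", "end")
    if (ncol(tab) >= 4 && is.numeric(tab[[4]])) names(tab)[4] <- "gc"
  }
  keep <- intersect(c("chrom", "start", "end", "gc"), names(tab))
  tab <- tab[, keep, drop = FALSE]
  tab$start <- suppressWarnings(as.numeric(tab$start))
  tab$end <- suppressWarnings(as.numeric(tab$end))
  bad <- is.na(tab$start) | is.na(tab$end) | !nzchar(tab$chrom) |
    tab$end <= tab$start
  if (any(bad)) {
    if (mode == "strict")
      stop(sum(bad), " malformed fragment line(s) in ", path)
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no valid fragments in ", path)
  out <- sample_fragments(sample_id, tab, metadata)
  attr(out, "n_skipped") <- if (mode == "lenient") sum(bad) else 0L
  out
}

#' Write fragment intervals as BED
#'
#' BED3, plus a 4th GC column when fragment GC is present. Round-trips
#' losslessly through [read_fragments()].
#'
#' @param sample a `sample_fragments`.
#' @param path output path (".gz" suffix compresses).
#' @return the path, invisibly.
#' @export
write_fragments <- function(sample, path) {
  fr <- sample$fragments
  cols <- c("chrom", "start", "end", intersect("gc", names(fr)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(fr[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean haploid coverage depth of a sample
#'
#' Depth is defined as total fragment bases divided by total genome length —
#' fragments, not reads, are the unit of this pipeline, and a single scalar
#' supports the uniform down-sampling rule.
#'
#' @param sample a `sample_fragments`.
#' @param layout a `genome_layout`.
#' @return mean depth (x).
#' @export
coverage_depth <- function(sample, layout) {
  if (nrow(sample$fragments) == 0L) stop("empty sample")
  sum(sample$fragments$length) / genome_length(layout)
}

#' Down-sample a sample to a target depth
#'
#' Samples above `target` are thinned by independent Bernoulli retention at
#' rate `target/depth`, giving expected depth `target`; samples at or below
#' the target are returned unchanged (never up-sampled). Deterministic given
#' `seed`.
#'
#' @param sample a `sample_fragments`.
#' @param layout a `genome_layout`.
#' @param target target depth (x), default 5.
#' @param seed integer RNG seed.
#' @return a `sample_fragments` (subset of the input).
#' @export
downsample_to_depth <- function(sample, layout, target = 5, seed = 1L) {
  stopifnot(target > 0)
  depth <- coverage_depth(sample, layout)
  if (depth <= target) return(sample)
  rate <- target / depth
  set.seed(seed)
  keep <- stats::runif(nrow(sample$fragments)) < rate
  sample_fragments(sample$sample_id,
                   sample$fragments[keep, c("chrom", "start", "end",
                                            intersect("gc", names(sample$fragments)))],
                   sample$metadata)
}

#' Basic QC summary for a sample
#'
#' @param sample a `sample_fragments`.
#' @param layout a `genome_layout`.
#' @param size_range fragment-size window reported as an in-range fraction
#'   (default the 110-220 bp mononucleosomal window).
#' @return list: `n_fragments`, `mean_depth`, `median_length`,
#'   `frac_in_range`.
#' @export
qc_record <- function(sample, layout, size_range = c(110, 220)) {
  len <- sample$fragments$length
  list(n_fragments = length(len),
       mean_depth = coverage_depth(sample, layout),
       median_length = stats::median(len),
       frac_in_range = mean(len >= size_range[1] & len <= size_range[2]))
}
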