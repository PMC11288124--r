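#' Build a genome layout
#'
#' A `genome_layout` is the shared coordinate frame for all feature
#' extractors: ordered chromosomes with lengths, centromere intervals,
#' and excluded regions (e.g. low-mappability blacklist). Coordinates are
#' 0-based, half-open (BED convention) throughout the package.
#'
#' @param chrom_sizes two-column data.frame (`chrom`, `length`) or path to a
#'   chrom.sizes TSV (no header).
#' @param centromeres data.frame (`chrom`, `start`, `end`) or path to a TSV
#'   with those three columns (no header). Optional; required by
#'   [list_arms()].
#' @param exclusions data.frame (`chrom`, `start`, `end`) or path to a BED3
#'   file of regions whose bins should be dropped. Optional.
#' @return object of class `genome_layout`: a list with `chroms`
#'   (data.frame: chrom, length, cen_start, cen_end) and `excluded`
#'   (data.frame: chrom, start, end).
#' @export
build_layout <- function(chrom_sizes, centromeres = NULL, exclusions = NULL) {
  if (is.character(chrom_sizes)) {
    chrom_sizes <- utils::read.table(chrom_sizes, sep = "\t", header = FALSE,
                                     col.names = c("chrom", "length"),
                                     colClasses = c("character", "numeric"))
  }
  chrom_sizes <- as.data.frame(chrom_sizes)
  if (nrow(chrom_sizes) == 0L) stop("empty chromosome sizes table")
  names(chrom_sizes)[1:2] <- c("chrom", "length")
  if (anyDuplicated(chrom_sizes$chrom)) stop("duplicated chromosome name")
  if (any(chrom_sizes$length <= 0)) stop("non-positive chromosome length")

  chroms <- data.frame(chrom = as.character(chrom_sizes$chrom),
                       length = as.numeric(chrom_sizes$length),
                       cen_start = NA_real_, cen_end = NA_real_,
                       stringsAsFactors = FALSE)

  if (!is.null(centromeres)) {
    if (is.character(centromeres)) {
      centromeres <- utils::read.table(centromeres, sep = "\t", header = FALSE,
                                       col.names = c("chrom", "start", "end"),
                                       colClasses = c("character", "numeric", "numeric"))
    }
    centromeres <- as.data.frame(centromeres)
    names(centromeres)[1:3] <- c("chrom", "start", "end")
    bad <- setdiff(centromeres$chrom, chroms$chrom)
    if (length(bad)) stop("unknown chromosome in centromere table: ",
                          paste(bad, collapse = ", "))
    i <- match(centromeres$chrom, chroms$chrom)
    chroms$cen_start[i] <- centromeres$start
    chroms$cen_end[i] <- centromeres$end
    ok <- is.na(chroms$cen_start) |
      (chroms$cen_start >= 0 & chroms$cen_end <= chroms$length &
         chroms$cen_start < chroms$cen_end)
    if (!all(ok)) stop("centromere interval outside chromosome: ",
                       paste(chroms$chrom[!ok], collapse = ", "))
  }

  if (!is.null(exclusions)) {
    if (is.character(exclusions)) {
      exclusions <- utils::read.table(exclusions, sep = "\t", header = FALSE)[, 1:3]
    }
    exclusions <- as.data.frame(exclusions)
    names(exclusions)[1:3] <- c("chrom", "start", "end")
    exclusions$chrom <- as.character(exclusions$chrom)
    bad <- setdiff(exclusions$chrom, chroms$chrom)
    if (length(bad)) stop("unknown chromosome in exclusion table: ",
                          paste(bad, collapse = ", "))
    len <- chroms$length[match(exclusions$chrom, chroms$chrom)]
    if (any(exclusions$start < 0 | exclusions$end > len |
              exclusions$start >= exclusions$end))
      stop("excluded region outside chromosome bounds")
  } else {
    exclusions <- data.frame(chrom = character(), start = numeric(),
                             end = numeric(), stringsAsFactors = FALSE)
  }

  structure(list(chroms = chroms, excluded = exclusions),
            class = "genome_layout")
}

#' @exportS3Method base::print
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chroms), " chromosomes, ",
      format(sum(x$chroms$length), big.mark = ","), " bp, ",
      nrow(x$excluded), " excluded regions\n", sep = "")
  invisible(x)
}

#' Total genome length of a layout
#' @param layout a `genome_layout`.
#' @return total length in bp.
#' @export
genome_length <- function(layout) sum(layout$chroms$length)

.autosome_like <- function(chrom) grepl("^(chr)?[0-9]+$", chrom)

#' Enumerate chromosome arms
#'
#' Splits each chromosome at its centromere into a p and a q arm. The
#' default chromosome selection keeps autosomes only when the layout uses
#' human-style names (sex chromosomes and chrM are dropped); for layouts
#' without such names all chromosomes are used. The p arms of the five
#' acrocentric chromosomes (13, 14, 15, 21, 22), which are essentially
#' unsequenced in short-read data, are dropped by default: for hg19 this
#' yields the canonical 39-arm set (22 autosomes x 2 arms - 5).
#'
#' @param layout a `genome_layout` with centromeres for the selected
#'   chromosomes.
#' @param drop_acrocentric_p drop p-arms of chr13/14/15/21/22 (default TRUE).
#' @param chroms optional character vector restricting which chromosomes to
#'   use (overrides the autosome default).
#' @return object of class `arm_set`: data.frame with `chrom`, `arm`
#'   ("p"/"q"), `start`, `end`, sorted by chromosome (input order), p before q.
#' @export
list_arms <- function(layout, drop_acrocentric_p = TRUE, chroms = NULL) {
  ch <- layout$chroms
  if (is.null(chroms)) {
    auto <- .autosome_like(ch$chrom)
    chroms <- if (any(auto)) ch$chrom[auto] else ch$chrom
  }
  ch <- ch[match(chroms, ch$chrom), , drop = FALSE]
  if (anyNA(ch$chrom)) stop("requested chromosome not in layout")
  if (anyNA(ch$cen_start)) stop("missing centromere for: ",
                                paste(ch$chrom[is.na(ch$cen_start)], collapse = ", "))
  arms <- data.frame(
    chrom = rep(ch$chrom, each = 2L),
    arm = rep(c("p", "q"), times = nrow(ch)),
    start = as.numeric(rbind(0, ch$cen_end)),
    end = as.numeric(rbind(ch$cen_start, ch$length)),
    stringsAsFactors = FALSE)
  if (drop_acrocentric_p) {
    acro <- paste0(c("", "chr"), rep(c(13, 14, 15, 21, 22), each = 2))
    arms <- arms[!(arms$arm == "p" & arms$chrom %in% acro), , drop = FALSE]
  }
  rownames(arms) <- NULL
  structure(arms, class = c("arm_set", "data.frame"))
}

#' Default hg19 chromosome-arm table
#'
#' The packaged 39-row arm membership table (autosomes, acrocentric p-arms
#' excluded) used by the default fragment-size-distribution configuration.
#' The table is config, not code: edit a copy and pass it through `include`
#' semantics by subsetting the result of [list_arms()].
#'
#' @return data.frame with columns `chrom`, `arm` (39 rows).
#' @export
default_arm_table <- function() {
  utils::read.table(system.file("extdata", "hg19_arms.tsv", package = "fragstack"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' hg19 genome layout from packaged tables
#'
#' Builds a [build_layout()] object from the packaged hg19 chrom.sizes and
#' centromere (UCSC gap track) tables: 24 chromosomes (1-22, X, Y).
#'
#' @return a `genome_layout`.
#' @export
hg19_layout <- function() {
  build_layout(
    system.file("extdata", "hg19.chrom.sizes", package = "fragstack"),
    system.file("extdata", "hg19_centromeres.tsv", package = "fragstack"))
}

#' hg19 default arm set (39 arms)
#' @return an `arm_set` of 39 arms with coordinates from the packaged layout.
#' @export
hg19_arms <- function() {
  layout <- hg19_layout()
  arms <- list_arms(layout, drop_acrocentric_p = TRUE)
  tab <- default_arm_table()
  keep <- paste(arms$chrom, arms$arm) %in% paste(tab$chrom, tab$arm)
  out <- arms[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("arm_set", "data.frame"))
}

#' Tile a layout with fixed-width bins
#'
#' Each chromosome is tiled independently with `width_bp` bins (the last bin
#' of a chromosome may be shorter). Bins overlapping any excluded region get
#' `kept = FALSE` and are dropped from downstream copy-number features.
#'
#' @param layout a `genome_layout`.
#' @param width_bp bin width in bp (default 1 Mb).
#' @return object of class `bin_grid`: data.frame `chrom`, `start`, `end`,
#'   `kept`, with attribute `width_bp`. Optionally a `gc` column after
#'   [attach_bin_gc()].
#' @export
make_bins <- function(layout, width_bp = 1e6) {
  stopifnot(width_bp > 0)
  ch <- layout$chroms
  pieces <- lapply(seq_len(nrow(ch)), function(i) {
    n <- ceiling(ch$length[i] / width_bp)
    start <- (seq_len(n) - 1) * width_bp
    data.frame(chrom = ch$chrom[i], start = start,
               end = pmin(start + width_bp, ch$length[i]),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$kept <- TRUE
  ex <- layout$excluded
  if (nrow(ex)) {
    for (j in seq_len(nrow(ex))) {
      hit <- bins$chrom == ex$chrom[j] & bins$start < ex$end[j] & bins$end > ex$start[j]
      bins$kept[hit] <- FALSE
    }
  }
  rownames(bins) <- NULL
  structure(bins, class = c("bin_grid", "data.frame"), width_bp = width_bp)
}

#' Attach per-bin GC fractions to a bin grid
#'
#' GC content arrives as an annotation (no sequence handling in this
#' package): either a numeric vector aligned with the bins or a table with
#' `chrom`, `start`, `gc` columns.
#'
#' @param bins a `bin_grid`.
#' @param gc numeric vector (length `nrow(bins)`) or data.frame with
#'   `chrom`, `start`, `gc`.
#' @return the bin grid with a `gc` column.
#' @export
attach_bin_gc <- function(bins, gc) {
  if (is.data.frame(gc)) {
    i <- match(paste(bins$chrom, bins$start), paste(gc$chrom, gc$start))
    gc <- gc$gc[i]
  }
  if (length(gc) != nrow(bins)) stop("gc annotation does not match bin grid")
  if (any(!is.na(gc) & (gc < 0 | gc > 1))) stop("gc fractions must be in [0, 1]")
  bins$gc <- as.numeric(gc)
  bins
}

# global (concatenated-genome) offset per chromosome, for fast bin lookup
.chrom_offsets <- function(layout) {
  off <- c(0, cumsum(layout$chroms$length))
  names(off) <- c(layout$chroms$chrom, "..end")
  off
}
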