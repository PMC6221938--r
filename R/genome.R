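#' Describe a genome build as an ordered set of chromosomes
#'
#' A minimal stand-in for a reference genome: chromosome names and lengths in
#' base pairs, in a fixed order. All genomic coordinates in this package are
#' 0-based, half-open (BED convention) unless a function says otherwise.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @return An object of class `genome_build`: a data.frame with columns
#'   `chrom` and `length`, row order defining chromosome order.
#' @examples
#' genome_build(c("chr1", "chr2"), c(1e7, 5e6))
#' @export
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("at least one chromosome is required")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in size")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Small toy genome build for simulations and tests
#'
#' Defaults to 6 chromosomes of 25 Mb each (150 Mb total, i.e. 3,000 bins at
#' the 50 kb bin size), so that full pipeline runs finish in seconds.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return A [genome_build()].
#' @export
toy_build <- function(n_chrom = 6, chrom_length = 25e6) {
  genome_build(paste0("chr", seq_len(n_chrom)), rep(chrom_length, n_chrom))
}

#' Partition a genome into fixed-width, non-overlapping bins
#'
#' Each chromosome is tiled with half-open bins `[0,b), [b,2b), ...`; the last
#' bin per chromosome is truncated at the chromosome length. Bins carry a
#' stable global index following build chromosome order, then start.
#'
#' @param build A [genome_build()].
#' @param bin_size Bin width in bp (default 50,000).
#' @return An object of class `genome_binning`: a list with `build`,
#'   `bin_size`, and `bins` (data.frame `chrom`, `start`, `end`, 0-based
#'   half-open).
#' @examples
#' bn <- make_bins(toy_build(2, 120000), 50000)
#' nrow(bn$bins)  # 3 bins per chromosome, last of width 20000
#' @export
make_bins <- function(build, bin_size = 50000) {
  stopifnot(inherits(build, "genome_build"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("bin_size must be a positive number")
  }
  bin_size <- as.numeric(bin_size)
  pieces <- lapply(seq_len(nrow(build)), function(i) {
    len <- build$length[i]
    n_bins <- ceiling(len / bin_size)
    starts <- (seq_len(n_bins) - 1) * bin_size
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = build$chrom[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  structure(list(build = build, bin_size = bin_size, bins = bins),
            class = "genome_binning")
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("genome_binning: %d bins of %g bp over %d chromosome(s)\n",
              nrow(x$bins), x$bin_size, nrow(x$build)))
  invisible(x)
}

#' Per-bin read counts for one sample
#'
#' @param binning A [make_bins()] result.
#' @param counts Non-negative integer vector, one entry per bin.
#' @param sample_id Sample label.
#' @return An object of class `binned_counts` with fields `binning`, `counts`,
#'   `total_reads`, `sample_id`.
#' @export
binned_counts <- function(binning, counts, sample_id = "sample") {
  stopifnot(inherits(binning, "genome_binning"))
  counts <- as.numeric(counts)
  if (length(counts) != nrow(binning$bins)) {
    stop("counts length must match the number of bins")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(binning = binning, counts = counts,
                 total_reads = sum(counts), sample_id = as.character(sample_id)),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("binned_counts '%s': %d bins, %g reads\n",
              x$sample_id, length(x$counts), x$total_reads))
  invisible(x)
}

as_read_frame <- function(reads) {
  if (inherits(reads, "GRanges")) {
    reads <- data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
                        start = GenomicRanges::start(reads) - 1L,
                        end = GenomicRanges::end(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("chrom", "start") %in% names(reads)))
  reads
}

#' Count reads in genome bins by 5' start position
#'
#' Each read is assigned to exactly one bin: the bin containing its 5'-most
#' start coordinate (0-based). With half-open bins, a read starting exactly at
#' a bin boundary belongs to the downstream bin.
#'
#' @param reads Read positions: a data.frame with columns `chrom`, `start`
#'   (0-based; `end` optional and ignored for assignment), a `GRanges`, or a
#'   path to a BED file (read with `rtracklayer`).
#' @param binning A [make_bins()] result.
#' @param on_unknown What to do with reads on chromosomes absent from the
#'   build (or with out-of-range starts): `"error"` (default) or `"skip"`
#'   (drop with a message).
#' @param sample_id Sample label for the result.
#' @return A [binned_counts()] whose counts sum to the number of assigned
#'   reads.
#' @export
count_reads <- function(reads, binning, on_unknown = c("error", "skip"),
                        sample_id = "sample") {
  stopifnot(inherits(binning, "genome_binning"))
  on_unknown <- match.arg(on_unknown)
  if (is.character(reads) && length(reads) == 1L) reads <- read_bed(reads)
  reads <- as_read_frame(reads)
  build <- binning$build
  chrom_len <- stats::setNames(build$length, build$chrom)
  known <- reads$chrom %in% build$chrom
  in_range <- known & reads$start >= 0 &
    reads$start < chrom_len[match(reads$chrom, names(chrom_len))]
  in_range[is.na(in_range)] <- FALSE
  if (any(!in_range)) {
    if (on_unknown == "error") {
      stop(sprintf("%d read(s) on unknown chromosomes or out of range",
                   sum(!in_range)))
    }
    message(sprintf("count_reads: skipping %d read(s) outside the build",
                    sum(!in_range)))
    reads <- reads[in_range, , drop = FALSE]
  }
  if (nrow(reads) == 0L) {
    return(binned_counts(binning, rep(0, nrow(binning$bins)), sample_id))
  }
  # 1-based width-1 ranges at the 5' start; half-open bins become 1-based
  # closed [start+1, end] so countOverlaps reproduces the BED convention.
  gr_reads <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = reads$start + 1L, width = 1L))
  gr_bins <- GenomicRanges::GRanges(
    binning$bins$chrom,
    IRanges::IRanges(start = binning$bins$start + 1L, end = binning$bins$end))
  counts <- GenomicRanges::countOverlaps(gr_bins, gr_reads)
  binned_counts(binning, counts, sample_id)
}

#' Read a BED file of read positions
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write read positions to a BED file
#'
#' @param reads data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  reads <- as_read_frame(reads)
  if (is.null(reads$end)) reads$end <- reads$start + 1L
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = reads$start + 1L, end = reads$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a two-column chromosome sizes table
#'
#' Standard "chrom.sizes" format: chromosome name, length, tab-separated.
#'
#' @param path File path.
#' @return A [genome_build()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "length"),
                           stringsAsFactors = FALSE)
  genome_build(tab$chrom, tab$length)
}
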