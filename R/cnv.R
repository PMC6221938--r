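#' Tumor/normal logR copy-number profile on fixed genome bins
#'
#' For every bin the log2 ratio of library-size-normalized tumor to normal
#' counts, `logR = log2((t_i/T) / (n_i/N))`, is computed; bins whose normal
#' count falls below `min_normal_count` are masked as unreliable. Tumor bins
#' with zero reads (and a reliable normal) use a half-count substitution
#' (t_i <- 0.5) to avoid -Inf without inventing signal. The profile is then
#' median-centered on the unmasked bins so a copy-neutral genome sits at 0;
#' no explicit ploidy model is fitted.
#'
#' @param tumor,normal [binned_counts()] on the same binning, totals > 0.
#' @param min_normal_count Bins with normal count below this are masked
#'   (default 10).
#' @param sample_id Label for the resulting profile (default tumor's id).
#' @return An object of class `cnv_profile`: list with `binning`, `logr`
#'   (numeric, NA where masked), `mask` (TRUE = masked), `sample_id`.
#' @export
compute_logr <- function(tumor, normal, min_normal_count = 10,
                         sample_id = NULL) {
  stopifnot(inherits(tumor, "binned_counts"), inherits(normal, "binned_counts"))
  if (!identical(tumor$binning$bins, normal$binning$bins)) {
    stop("tumor and normal counts must share the same binning")
  }
  if (tumor$total_reads <= 0 || normal$total_reads <= 0) {
    stop("both samples need a positive read total")
  }
  mask <- normal$counts < min_normal_count
  if (all(mask)) stop("all bins masked: normal sample too shallow")
  t_i <- tumor$counts
  t_i[t_i == 0 & !mask] <- 0.5
  logr <- rep(NA_real_, length(t_i))
  logr[!mask] <- log2((t_i[!mask] / tumor$total_reads) /
                        (normal$counts[!mask] / normal$total_reads))
  logr <- logr - stats::median(logr[!mask])
  structure(list(binning = tumor$binning, logr = logr, mask = mask,
                 sample_id = sample_id %||% tumor$sample_id),
            class = "cnv_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("cnv_profile '%s': %d bins (%d masked), logR range [%.2f, %.2f]\n",
              x$sample_id, length(x$logr), sum(x$mask),
              min(x$logr, na.rm = TRUE), max(x$logr, na.rm = TRUE)))
  invisible(x)
}

default_sex_chroms <- c("chrX", "chrY", "X", "Y")

joint_unmasked <- function(a, b, exclude_chroms) {
  if (!identical(a$binning$bins, b$binning$bins)) {
    stop("profiles must share the same binning")
  }
  use <- !a$mask & !b$mask
  use & !(a$binning$bins$chrom %in% exclude_chroms)
}

#' Correlate two copy-number profiles
#'
#' Pearson correlation of per-bin logR over the jointly unmasked autosomal
#' bins, with a two-sided p-value from the t transform. P-values below the
#' double-precision floor are reported at that floor (printed downstream as
#' "< 2.2e-16").
#'
#' @param a,b [compute_logr()] profiles on the same binning.
#' @param exclude_chroms Chromosomes dropped before comparison (default sex
#'   chromosomes, to avoid sex-mismatch artifacts).
#' @return list with `r`, `p`, `n_bins`.
#' @export
compare_profiles <- function(a, b, exclude_chroms = default_sex_chroms) {
  use <- joint_unmasked(a, b, exclude_chroms)
  if (sum(use) < 3L) stop("need at least 3 jointly unmasked bins")
  x <- a$logr[use]; y <- b$logr[use]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: a profile is constant over the joint bins")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = max(ct$p.value, .Machine$double.xmin),
       n_bins = sum(use))
}

#' Chromosomal instability score (fraction of genome altered)
#'
#' The fraction of unmasked autosomal bins whose |logR| reaches
#' `logr_threshold`. A flat profile scores 0; a genome altered everywhere
#' scores 1.
#'
#' @param profile A [compute_logr()] profile.
#' @param logr_threshold Positive |logR| cutoff (default 0.15, below the
#'   single-copy-gain level of ~0.58 so diluted tumor signal still counts).
#' @param exclude_chroms Chromosomes to drop (default sex chromosomes).
#' @return Fraction in \[0, 1\].
#' @export
instability_score <- function(profile, logr_threshold = 0.15,
                              exclude_chroms = default_sex_chroms) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (!is.numeric(logr_threshold) || logr_threshold <= 0) {
    stop("logr_threshold must be > 0")
  }
  use <- !profile$mask &
    !(profile$binning$bins$chrom %in% exclude_chroms)
  if (!any(use)) stop("no unmasked bins")
  mean(abs(profile$logr[use]) >= logr_threshold)
}

#' Amplitude attenuation of one profile relative to a reference
#'
#' Least-squares slope through the origin of observed on reference logR over
#' the jointly unmasked bins. A slope of 1 means equal amplitude; values
#' below 1 indicate attenuation of the copy-number signal, as expected for
#' cfDNA profiles where the tumor contributes only a fraction of the
#' circulating DNA.
#'
#' @param observed,reference [compute_logr()] profiles on the same binning.
#' @param exclude_chroms Chromosomes to drop (default sex chromosomes).
#' @return The slope (a number).
#' @export
attenuation_factor <- function(observed, reference,
                               exclude_chroms = default_sex_chroms) {
  use <- joint_unmasked(observed, reference, exclude_chroms)
  if (sum(use) < 3L) stop("need at least 3 jointly unmasked bins")
  x <- reference$logr[use]; y <- observed$logr[use]
  if (sum(x^2) == 0) stop("degenerate reference: all logR zero")
  sum(x * y) / sum(x^2)
}

#' Export a profile as a SEG-like per-bin TSV
#'
#' Columns: sample, chrom, start, end, n_bins (always 1: no segmentation is
#' performed), logr, masked.
#'
#' @param profile A [compute_logr()] profile.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_seg <- function(profile, path) {
  stopifnot(inherits(profile, "cnv_profile"))
  bins <- profile$binning$bins
  seg <- data.frame(sample = profile$sample_id, chrom = bins$chrom,
                    start = bins$start, end = bins$end, n_bins = 1L,
                    logr = profile$logr, masked = profile$mask)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a profile back from a SEG-like per-bin TSV
#'
#' Inverse of [write_profile_seg()]; the genome build is inferred from the
#' bin extents (chromosome length = last bin end).
#'
#' @param path TSV written by [write_profile_seg()].
#' @return A `cnv_profile`.
#' @export
read_profile_seg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "logr", "masked")
  if (!all(need %in% names(tab))) {
    stop("SEG TSV must have columns: ", paste(need, collapse = ", "))
  }
  chroms <- unique(tab$chrom)
  lens <- vapply(chroms, function(ch) max(tab$end[tab$chrom == ch]), numeric(1))
  bin_size <- max(tab$end - tab$start)
  binning <- make_bins(genome_build(chroms, lens), bin_size)
  if (!identical(binning$bins$start, as.numeric(tab$start))) {
    stop("SEG TSV bins are not a fixed-width tiling of the inferred build")
  }
  structure(list(binning = binning, logr = as.numeric(tab$logr),
                 mask = as.logical(tab$masked), sample_id = tab$sample[1]),
            class = "cnv_profile")
}

#' Read per-bin counts from a TSV
#'
#' Expected columns `chrom`, `start`, `end`, `count`; bins must match the
#' supplied binning exactly (same order).
#'
#' @param path TSV path.
#' @param binning The [make_bins()] result the counts refer to.
#' @param sample_id Sample label.
#' @return A [binned_counts()].
#' @export
read_bin_counts <- function(path, binning, sample_id = "sample") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(tab))) {
    stop("bin-count TSV must have columns: ", paste(need, collapse = ", "))
  }
  ref <- binning$bins
  if (nrow(tab) != nrow(ref) || !all(tab$chrom == ref$chrom) ||
      !all(tab$start == ref$start) || !all(tab$end == ref$end)) {
    stop("bin-count TSV does not match the binning")
  }
  binned_counts(binning, tab$count, sample_id)
}

#' Write per-bin counts to a TSV
#'
#' @param counts A [binned_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(counts, path) {
  stopifnot(inherits(counts, "binned_counts"))
  tab <- cbind(counts$binning$bins, count = counts$counts)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
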