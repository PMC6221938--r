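# Independent brute-force oracles. These deliberately re-derive results with
# naive loops, separate from the package's code paths.

# -ln(1 - 1000/20000), frozen from a 30-digit arbitrary-precision evaluation
LAMBDA_1000_20000 <- 0.0512932943875505334261961442546
# closed-form quantities for the worked well (200, 800, 10, 18990):
VAF_WORKED_WELL <- 0.203387738008793040101818874699

# O(reads x bins) per-read loop: assign each read to the bin containing its
# 5' start
brute_count_reads <- function(reads, binning) {
  bins <- binning$bins
  counts <- integer(nrow(bins))
  for (i in seq_len(nrow(reads))) {
    hit <- which(bins$chrom == reads$chrom[i] &
                   bins$start <= reads$start[i] &
                   reads$start[i] < bins$end)
    stopifnot(length(hit) == 1L)
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# clause-by-clause re-evaluation of the filter cascade, one record at a time
brute_passes_filters <- function(rec, max_af = 0.01, min_vaf = 0.20) {
  if (rec$consequence != "nonsynonymous") return(FALSE)
  for (af in c(rec$af_dbsnp, rec$af_exac, rec$af_1000g)) {
    if (!is.na(af) && af >= max_af) return(FALSE)
  }
  if (is.na(rec$vaf_tumor)) stop("missing VAF")
  rec$vaf_tumor >= min_vaf
}

brute_tier <- function(rec, cadd_min = 20, require_sift = TRUE) {
  if (isTRUE(rec$in_net_genes)) return(1L)
  if (isTRUE(rec$in_cosmic_census)) return(2L)
  path <- !is.na(rec$cadd_phred) && rec$cadd_phred >= cadd_min
  if (require_sift) {
    path <- path && !is.na(rec$sift) && rec$sift == "deleterious"
  }
  if (path) 3L else 4L
}

brute_chrom_key <- function(chrom) {
  s <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.numeric(s))
  base <- if (!is.na(n)) n else if (s == "X") 23 else if (s == "Y") 24 else 25
  sprintf("%06.2f_%s", base, chrom)
}

# independent ranking: tier, then descending CADD, then chromosome, then pos
brute_rank_ids <- function(df, cadd_min = 20, require_sift = TRUE) {
  if (nrow(df) == 0L) return(character())
  tiers <- vapply(seq_len(nrow(df)), function(i)
    brute_tier(df[i, ], cadd_min, require_sift), integer(1))
  cadd <- ifelse(is.na(df$cadd_phred), -Inf, df$cadd_phred)
  key <- order(tiers, -cadd,
               vapply(df$chrom, brute_chrom_key, character(1)), df$pos)
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")[key]
}

brute_survivor_ids <- function(df, max_af = 0.01, min_vaf = 0.20) {
  keep <- vapply(seq_len(nrow(df)), function(i)
    brute_passes_filters(df[i, ], max_af, min_vaf), logical(1))
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")[keep]
}

vid <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

# tiny builds used across tests
tiny_build <- function() genome_build(c("chrA", "chrB"), c(1e7, 1e7))

# hand-built cnv_profile (bypasses compute_logr) for unit tests of the
# profile statistics
manual_profile <- function(logr, binning, mask = rep(FALSE, length(logr)),
                           sample_id = "manual") {
  lr <- logr
  lr[mask] <- NA_real_
  structure(list(binning = binning, logr = lr, mask = mask,
                 sample_id = sample_id), class = "cnv_profile")
}

# random variant data.frame touching every clause, for property tests
random_variant_df <- function(n, seed) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      consequence = character(), vaf_tumor = numeric(),
                      af_dbsnp = numeric(), af_exac = numeric(),
                      af_1000g = numeric(), cadd_phred = numeric(),
                      sift = character(), in_net_genes = logical(),
                      in_cosmic_census = logical(), stringsAsFactors = FALSE))
  }
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    maybe_af <- function(k) {
      af <- runif(k, 0, 0.05)
      af[runif(k) < 0.4] <- NA
      af
    }
    data.frame(
      chrom = paste0("chr", sample(c(1:22, "X"), n, replace = TRUE)),
      pos = sample.int(1e8, n), ref = ref, alt = unname(alt),
      gene = paste0("G", seq_len(n)),
      consequence = sample(c("nonsynonymous", "synonymous", "other"), n,
                           replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      vaf_tumor = runif(n), af_dbsnp = maybe_af(n), af_exac = maybe_af(n),
      af_1000g = maybe_af(n),
      cadd_phred = ifelse(runif(n) < 0.1, NA, runif(n, 0, 45)),
      sift = sample(c("deleterious", "tolerated", NA), n, replace = TRUE),
      in_net_genes = runif(n) < 0.1, in_cosmic_census = runif(n) < 0.15,
      stringsAsFactors = FALSE)
  })
}
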