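#' @title Synthetic ground-truth generators
#' @description Every input the pipeline consumes can be simulated with known
#' ground truth: segmental integer copy-number truths with tumor purity,
#' binned read counts and read positions, droplet wells under Poisson
#' template loading, two-channel droplet amplitudes, and annotated variant
#' tables with known survivor sets. All generators take an explicit `seed`
#' and are bit-reproducible; none touch the global random state outside
#' `withr::with_seed()`.
#' @name synthetic-data
NULL

#' Ground-truth segmental copy number with tumor purity
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `copy` (integer >= 0); segments must tile each chromosome of
#'   the build completely without overlap.
#' @param build The [genome_build()] the segments refer to.
#' @param purity Tumor cell fraction in \[0, 1\].
#' @param ploidy_normal Copy number of the admixed normal genome (default 2).
#' @return Object of class `copy_number_truth`.
#' @export
copy_number_truth <- function(segments, build, purity = 1, ploidy_normal = 2) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "copy") %in% names(segments)),
            inherits(build, "genome_build"))
  if (purity < 0 || purity > 1) stop("purity must lie in [0, 1]")
  if (any(segments$copy < 0 | segments$copy != round(segments$copy))) {
    stop("copy numbers must be non-negative integers")
  }
  for (ch in build$chrom) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    len <- build$length[build$chrom == ch]
    if (nrow(seg) == 0L || seg$start[1] != 0 || seg$end[nrow(seg)] != len ||
        (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)]))) {
      stop(sprintf("segments do not tile chromosome %s completely", ch))
    }
  }
  structure(list(segments = segments, build = build, purity = purity,
                 ploidy_normal = ploidy_normal),
            class = "copy_number_truth")
}

#' All-diploid truth for a build
#'
#' @param build A [genome_build()].
#' @param purity Tumor purity (irrelevant when everything is diploid, kept
#'   for symmetry).
#' @return A diploid [copy_number_truth()].
#' @export
diploid_truth <- function(build, purity = 1) {
  copy_number_truth(
    data.frame(chrom = build$chrom, start = 0, end = build$length, copy = 2L,
               stringsAsFactors = FALSE),
    build, purity = purity)
}

#' Simulate a segmental copy-number ground truth
#'
#' Places exactly `n_events` non-diploid segments uniformly and without
#' overlap on the build, with copy numbers drawn from `copy_range` excluding
#' 2 and segment boundaries snapped to `bin_size` multiples, so downstream
#' bins never straddle a truth boundary. Everything not covered by an event
#' is diploid. Defaults emulate a genomically unstable neuroendocrine tumor:
#' a handful of chromosome-arm-scale events spanning deep loss through
#' multi-copy gain. Event positions and lengths are random; event copy
#' numbers cycle deterministically through the allowed non-diploid states
#' (0, 1, 3, ... in order), so every generated genome with enough events
#' exercises the full amplitude range — the generator is a test-pattern
#' source for recovery tests, not a tumor-evolution model.
#'
#' @param build A [genome_build()].
#' @param n_events Number of non-diploid segments (>= 0).
#' @param seed Integer seed.
#' @param copy_range Integer pair within \[0, 8\]; event copies cycle through
#'   this range with 2 removed.
#' @param purity Tumor purity recorded in the truth (default 1).
#' @param bin_size Grid to which event boundaries are snapped (default 50 kb).
#' @param event_bins Integer pair: min/max event length in bins (default
#'   50–300, i.e. 2.5–15 Mb at 50 kb — arm-scale on the toy build).
#' @return A [copy_number_truth()] with exactly `n_events` non-diploid
#'   segments.
#' @export
simulate_copy_number_truth <- function(build, n_events = 8, seed = 1,
                                       copy_range = c(0, 5), purity = 1,
                                       bin_size = 50000,
                                       event_bins = c(50, 300)) {
  stopifnot(inherits(build, "genome_build"))
  if (n_events < 0 || n_events != round(n_events)) stop("n_events must be >= 0")
  if (copy_range[1] < 0 || copy_range[2] > 8 || copy_range[1] > copy_range[2]) {
    stop("copy_range must lie within [0, 8]")
  }
  copies_allowed <- setdiff(seq(copy_range[1], copy_range[2]), 2L)
  if (n_events > 0 && length(copies_allowed) == 0L) {
    stop("copy_range contains no non-diploid copy number")
  }
  n_bins_chrom <- floor(build$length / bin_size)
  if (any(n_bins_chrom < 1) && n_events > 0) {
    stop("chromosomes shorter than one bin cannot host events")
  }
  withr::with_seed(seed, {
    events <- data.frame(chrom = character(), start_bin = integer(),
                         end_bin = integer(), copy = integer(),
                         stringsAsFactors = FALSE)
    tries <- 0L
    max_tries <- max(1000L, 1000L * n_events)
    while (nrow(events) < n_events) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place the requested events without overlap on this build")
      }
      ci <- sample.int(nrow(build), 1L, prob = n_bins_chrom)
      # sample() on a length-1 vector would sample 1:x; index explicitly
      len_choices <- seq(event_bins[1], event_bins[2])
      len_bins <- len_choices[sample.int(length(len_choices), 1L)]
      len_bins <- min(len_bins, n_bins_chrom[ci])
      start_bin <- sample.int(n_bins_chrom[ci] - len_bins + 1L, 1L) - 1L
      end_bin <- start_bin + len_bins
      same <- events[events$chrom == build$chrom[ci], , drop = FALSE]
      if (nrow(same) && any(start_bin < same$end_bin & end_bin > same$start_bin)) {
        next
      }
      events <- rbind(events, data.frame(
        chrom = build$chrom[ci], start_bin = start_bin, end_bin = end_bin,
        copy = copies_allowed[(nrow(events) %% length(copies_allowed)) + 1L],
        stringsAsFactors = FALSE))
    }
  })
  # tile each chromosome: diploid gaps around the placed events
  seg_list <- lapply(seq_len(nrow(build)), function(i) {
    ch <- build$chrom[i]; len <- build$length[i]
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start_bin), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(ev$start_bin, ev$end_bin)) * bin_size, len)
    copies <- rep(2L, length(bounds) - 1L)
    if (nrow(ev)) copies[seq(2L, by = 2L, length.out = nrow(ev))] <- ev$copy
    seg <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                      end = bounds[-1], copy = copies, stringsAsFactors = FALSE)
    seg[seg$end > seg$start, , drop = FALSE]
  })
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  copy_number_truth(segments, build, purity = purity)
}

# integer copy number at given positions, from the truth segments
truth_copy_at <- function(truth, chrom, pos) {
  out <- rep(NA_real_, length(chrom))
  for (ch in unique(chrom)) {
    seg <- truth$segments[truth$segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    sel <- chrom == ch
    if (nrow(seg) == 0L) next
    idx <- findInterval(pos[sel], seg$start)
    idx[idx < 1L] <- NA_integer_
    out[sel] <- seg$copy[idx]
  }
  if (anyNA(out)) stop("positions outside the truth segments")
  out
}

#' Simulate tumor (or normal) binned read counts under a copy-number truth
#'
#' Per-bin counts are drawn independently with expectation
#' `mean_depth_per_bin * (purity * c + (1 - purity) * 2) / 2`, where `c` is
#' the truth copy number at the bin midpoint. `dispersion = 0` gives Poisson
#' draws; `dispersion > 0` gives negative-binomial draws parameterized so the
#' variance is `mean * (1 + dispersion * mean)` (Poisson recovered in the
#' limit).
#'
#' @param truth A [copy_number_truth()].
#' @param binning A [make_bins()] result on the truth's build.
#' @param mean_depth_per_bin Expected reads per diploid bin (> 0).
#' @param dispersion Overdispersion knob (>= 0, default 0).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A [binned_counts()].
#' @export
simulate_binned_counts <- function(truth, binning, mean_depth_per_bin = 100,
                                   dispersion = 0, seed = 1,
                                   sample_id = "sim") {
  stopifnot(inherits(truth, "copy_number_truth"),
            inherits(binning, "genome_binning"))
  if (mean_depth_per_bin <= 0) stop("mean_depth_per_bin must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  mid <- (binning$bins$start + binning$bins$end) / 2
  cc <- truth_copy_at(truth, binning$bins$chrom, mid)
  mu <- mean_depth_per_bin *
    (truth$purity * cc + (1 - truth$purity) * truth$ploidy_normal) / 2
  counts <- withr::with_seed(seed, {
    if (dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    }
  })
  binned_counts(binning, counts, sample_id)
}

#' Scatter read positions consistent with binned counts
#'
#' Emits exactly `counts[b]` read intervals inside bin `b`, each fully
#' contained in the bin, so that [count_reads()] on the output reproduces the
#' counts exactly (round-trip identity).
#'
#' @param counts A [binned_counts()].
#' @param seed Integer seed.
#' @param read_length Nominal read length in bp (clipped at bin ends).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), suitable
#'   for [write_bed()].
#' @export
simulate_read_positions <- function(counts, seed = 1, read_length = 50) {
  stopifnot(inherits(counts, "binned_counts"))
  bins <- counts$binning$bins
  n <- counts$counts
  total <- sum(n)
  if (total == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  chrom <- rep(bins$chrom, n)
  bstart <- rep(bins$start, n)
  bend <- rep(bins$end, n)
  starts <- withr::with_seed(seed, {
    bstart + floor(stats::runif(total) * (bend - bstart))
  })
  ends <- pmin(starts + read_length, bend)
  data.frame(chrom = chrom, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Droplet-generation ground truth
#'
#' @param lambda_mut,lambda_wt Mean mutant / wild-type template molecules per
#'   droplet (>= 0).
#' @param n_droplets Number of droplets (default 20,000, the usual partition
#'   count of a nanoliter-droplet generator).
#' @param droplet_volume_nl Droplet volume in nL (default 0.85).
#' @return Object of class `droplet_truth`.
#' @export
droplet_truth <- function(lambda_mut, lambda_wt, n_droplets = 20000,
                          droplet_volume_nl = 0.85) {
  if (lambda_mut < 0 || lambda_wt < 0) stop("lambdas must be >= 0")
  if (n_droplets < 1 || n_droplets != round(n_droplets)) {
    stop("n_droplets must be a positive integer")
  }
  if (droplet_volume_nl <= 0) stop("droplet_volume_nl must be > 0")
  structure(list(lambda_mut = lambda_mut, lambda_wt = lambda_wt,
                 n_droplets = as.integer(n_droplets),
                 droplet_volume_nl = droplet_volume_nl),
            class = "droplet_truth")
}

#' Simulate a ddPCR well under Poisson template loading
#'
#' Each droplet receives independent Poisson(lambda_mut) mutant and
#' Poisson(lambda_wt) wild-type molecule counts; the droplet is classed
#' mutant-only / wild-type-only / double-positive / negative by presence of
#' each molecule type.
#'
#' @param truth A [droplet_truth()].
#' @param seed Integer seed.
#' @return A [droplet_well()]; class counts always sum to `n_droplets`.
#' @export
simulate_droplet_well <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "droplet_truth"))
  withr::with_seed(seed, {
    m <- stats::rpois(truth$n_droplets, truth$lambda_mut) > 0
    w <- stats::rpois(truth$n_droplets, truth$lambda_wt) > 0
  })
  droplet_well(n_mut_only = sum(m & !w), n_wt_only = sum(!m & w),
               n_double = sum(m & w), n_negative = sum(!m & !w))
}

#' Simulate two-channel droplet amplitudes for a classed well
#'
#' One row per droplet, with channel amplitudes drawn from the
#' class-appropriate normal (independent channels). Requires separable
#' classes: in each channel the positive mean must exceed the negative mean
#' by at least four noise standard deviations, so that
#' [classify_droplets()] recovers the input class counts exactly.
#'
#' @param well A [droplet_well()].
#' @param channel_means 2x2 numeric matrix: rows = channels (ch1 mutant, ch2
#'   wild-type), columns = (negative, positive) cluster means.
#' @param noise_sd Amplitude standard deviation (>= 0).
#' @param seed Integer seed.
#' @return data.frame with `ch1`, `ch2` and the generating `class`.
#' @export
simulate_droplet_amplitudes <- function(well,
                                        channel_means = rbind(c(1000, 9000),
                                                              c(1200, 7000)),
                                        noise_sd = 300, seed = 1) {
  stopifnot(inherits(well, "droplet_well"))
  channel_means <- as.matrix(channel_means)
  stopifnot(identical(dim(channel_means), c(2L, 2L)))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sep <- channel_means[, 2] - channel_means[, 1]
  if (any(sep < 4 * noise_sd) || any(sep <= 0)) {
    stop("channels not separable: positive mean must exceed negative mean by >= 4 * noise_sd")
  }
  cls <- rep(c("mut_only", "wt_only", "double", "negative"),
             c(well$n_mut_only, well$n_wt_only, well$n_double, well$n_negative))
  mut_pos <- cls %in% c("mut_only", "double")
  wt_pos <- cls %in% c("wt_only", "double")
  n <- length(cls)
  withr::with_seed(seed, {
    ch1 <- channel_means[1, 1 + mut_pos] + stats::rnorm(n, 0, noise_sd)
    ch2 <- channel_means[2, 1 + wt_pos] + stats::rnorm(n, 0, noise_sd)
  })
  data.frame(ch1 = ch1, ch2 = ch2, class = cls, stringsAsFactors = FALSE)
}

net_seed_genes <- c("MEN1", "DAXX", "ATRX", "EPAS1")
cosmic_stand_in_genes <- c("TP53", "KRAS", "ERG", "BUB1", "MYH11")

rand_base_pair <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate an annotated variant table with known filter-cascade ground truth
#'
#' Generates variants in seven categories, each exercising one clause of the
#' select-a-target cascade:
#' `common` (population AF >= 0.01 somewhere), `synonymous`, `low_vaf`
#' (tumor VAF < 20%), `net_gene` (passes all filters, known
#' neuroendocrine-tumor gene), `cosmic` (passes, census gene), `high_cadd`
#' (passes, CADD >= 20 and SIFT deleterious) and `fail_all` (passes the
#' filters but matches no prioritization tier). The returned ground truth —
#' survivor identifiers and the unique expected target — is computed from the
#' category labels, independently of the filter implementation.
#'
#' @param seed Integer seed.
#' @param n_per_category Named integer vector/list over the seven categories;
#'   omitted categories default to 0.
#' @return list with `variants` (a [variant_table()] with a `category`
#'   attribute), `category` (per-row labels), `survivors` (character ids),
#'   `target` (character id or NA), `target_tier`.
#' @export
simulate_variant_table <- function(seed = 1,
                                   n_per_category = c(common = 5,
                                                      synonymous = 3,
                                                      low_vaf = 3,
                                                      net_gene = 2,
                                                      cosmic = 2,
                                                      high_cadd = 2,
                                                      fail_all = 2)) {
  all_cats <- c("common", "synonymous", "low_vaf", "net_gene", "cosmic",
                "high_cadd", "fail_all")
  n_cat <- stats::setNames(rep(0L, length(all_cats)), all_cats)
  n_per_category <- unlist(n_per_category)
  if (length(n_per_category)) {
    bad <- setdiff(names(n_per_category), all_cats)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    n_cat[names(n_per_category)] <- as.integer(n_per_category)
  }
  n <- sum(n_cat)
  cats <- rep(all_cats, n_cat)
  withr::with_seed(seed, {
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    pos <- sample.int(2e8, n)
    ba <- if (n) rand_base_pair(n) else list(ref = character(), alt = character())
    rare_af <- function(k) {
      af <- stats::runif(k, 0, 0.009)
      af[stats::runif(k) < 0.5] <- NA  # absent from the database
      af
    }
    df <- data.frame(
      chrom = chrom, pos = pos, ref = ba$ref, alt = ba$alt,
      gene = paste0("GENE", seq_len(max(n, 0))),
      consequence = "nonsynonymous",
      vaf_tumor = stats::runif(n, 0.20, 0.95),
      af_dbsnp = rare_af(n), af_exac = rare_af(n), af_1000g = rare_af(n),
      cadd_phred = stats::runif(n, 0, 19.9),
      sift = sample(c("tolerated", NA), n, replace = TRUE),
      in_net_genes = FALSE, in_cosmic_census = FALSE,
      stringsAsFactors = FALSE)
    idx <- function(cat) which(cats == cat)
    i <- idx("common")
    if (length(i)) df$af_exac[i] <- stats::runif(length(i), 0.01, 0.5)
    i <- idx("synonymous")
    if (length(i)) df$consequence[i] <- "synonymous"
    i <- idx("low_vaf")
    if (length(i)) df$vaf_tumor[i] <- stats::runif(length(i), 0, 0.1999)
    i <- idx("net_gene")
    if (length(i)) {
      df$gene[i] <- sample(net_seed_genes, length(i), replace = TRUE)
      df$in_net_genes[i] <- TRUE
      df$cadd_phred[i] <- stats::runif(length(i), 10, 40)
    }
    i <- idx("cosmic")
    if (length(i)) {
      df$gene[i] <- sample(cosmic_stand_in_genes, length(i), replace = TRUE)
      df$in_cosmic_census[i] <- TRUE
      df$cadd_phred[i] <- stats::runif(length(i), 10, 40)
    }
    i <- idx("high_cadd")
    if (length(i)) {
      df$cadd_phred[i] <- stats::runif(length(i), 20, 45)
      df$sift[i] <- "deleterious"
    }
  })
  variants <- variant_table(df)
  ids <- variant_id(variants)
  surviving_cats <- c("net_gene", "cosmic", "high_cadd", "fail_all")
  survivors <- ids[cats %in% surviving_cats]
  # ground-truth target from category labels (independent of the filters)
  tier_of <- c(net_gene = 1L, cosmic = 2L, high_cadd = 3L, fail_all = 4L)
  target <- NA_character_
  target_tier <- "none"
  if (length(survivors)) {
    sel <- cats %in% surviving_cats
    key <- order(tier_of[cats[sel]],
                 -ifelse(is.na(variants$cadd_phred[sel]), -Inf,
                         variants$cadd_phred[sel]),
                 chrom_rank(variants$chrom[sel]), variants$pos[sel])
    top <- which(sel)[key[1]]
    target <- ids[top]
    target_tier <- c("NET_gene", "cosmic_census", "pathogenicity",
                     "none")[tier_of[cats[top]]]
  }
  list(variants = variants, category = cats, survivors = survivors,
       target = target, target_tier = target_tier)
}
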