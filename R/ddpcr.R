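#' Per-well droplet class counts
#'
#' A ddPCR well summarized as the four droplet classes used in two-channel
#' mutation assays: mutant-only, wild-type-only, double-positive and
#' template-negative. The accepted-droplet total is the sum of the four.
#'
#' @param n_mut_only,n_wt_only,n_double,n_negative Non-negative integer
#'   droplet counts.
#' @return An object of class `droplet_well`.
#' @examples
#' droplet_well(n_mut_only = 12, n_wt_only = 340, n_double = 2,
#'              n_negative = 19646)
#' @export
droplet_well <- function(n_mut_only = 0, n_wt_only = 0, n_double = 0,
                         n_negative = 0) {
  counts <- c(n_mut_only = n_mut_only, n_wt_only = n_wt_only,
              n_double = n_double, n_negative = n_negative)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("droplet counts must be non-negative integers")
  }
  n_accepted <- sum(counts)
  if (n_accepted <= 0) stop("a well must contain at least one droplet")
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(c(as.list(counts), list(n_accepted = as.integer(n_accepted))),
            class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf(
    "droplet_well: %d accepted (mut-only %d, wt-only %d, double %d, negative %d)\n",
    x$n_accepted, x$n_mut_only, x$n_wt_only, x$n_double, x$n_negative))
  invisible(x)
}

#' Pool replicate ddPCR wells
#'
#' Component-wise sum of class counts, the standard treatment of replicate
#' wells run with the same assay.
#'
#' @param wells A list of [droplet_well()] objects (at least one).
#' @return A single pooled [droplet_well()].
#' @export
merge_wells <- function(wells) {
  if (inherits(wells, "droplet_well")) wells <- list(wells)
  if (!is.list(wells) || length(wells) == 0L) {
    stop("merge_wells needs at least one well")
  }
  stopifnot(all(vapply(wells, inherits, logical(1), "droplet_well")))
  droplet_well(
    n_mut_only = sum(vapply(wells, `[[`, numeric(1), "n_mut_only")),
    n_wt_only = sum(vapply(wells, `[[`, numeric(1), "n_wt_only")),
    n_double = sum(vapply(wells, `[[`, numeric(1), "n_double")),
    n_negative = sum(vapply(wells, `[[`, numeric(1), "n_negative")))
}

# optimal 1-D split into two clusters minimizing within-cluster variance;
# exhaustive scan over the sorted sample (exact, deterministic)
split_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_left <- cs2[k] - cs[k]^2 / k
  nr <- n - k
  sr <- cs[n] - cs[k]
  ss_right <- (cs2[n] - cs2[k]) - sr^2 / nr
  tot <- ss_left + ss_right
  kbest <- which.min(tot)
  m1 <- cs[kbest] / kbest
  m2 <- (cs[n] - cs[kbest]) / (n - kbest)
  list(centers = c(m1, m2),
       sds = c(sqrt(max(ss_left[kbest], 0) / kbest),
               sqrt(max(ss_right[kbest], 0) / (n - kbest))),
       threshold = (m1 + m2) / 2)
}

# bimodality check: the cluster separation must reach twice the summed
# cluster SDs (for equal SDs this is the same 4-sigma separability the
# amplitude simulator enforces); a lone Gaussian cluster fails this.
auto_threshold <- function(x, channel) {
  sp <- split_1d(x)
  sep <- abs(diff(sp$centers))
  if (sep == 0) {
    stop(sprintf("channel %s has a single amplitude cluster; supply manual thresholds",
                 channel))
  }
  min_sep <- 2 * sum(sp$sds)
  if (sep < min_sep) {
    stop(sprintf(paste0(
      "channel %s does not look bimodal (cluster separation %.3g < required ",
      "%.3g); supply manual thresholds"), channel, sep, min_sep))
  }
  sp$threshold
}

#' Classify droplets from two-channel fluorescence amplitudes
#'
#' Replaces the manual per-well thresholding of ddPCR analysis software with a
#' deterministic rule: a droplet is positive in a channel iff its amplitude
#' exceeds that channel's threshold. Channel 1 reports the mutant probe,
#' channel 2 the wild-type probe. With `thresholds = NULL`, each channel's
#' threshold is set automatically to the midpoint of the two cluster centers
#' of the optimal two-cluster 1-D partition (minimum within-cluster variance);
#' auto mode refuses channels whose clusters are separated by less than 2
#' pooled within-cluster standard deviations.
#'
#' @param amplitudes data.frame with numeric columns `ch1` and `ch2`, one row
#'   per droplet (at least 100 droplets).
#' @param thresholds Numeric length-2 vector `c(ch1, ch2)` of manual
#'   thresholds, or `NULL` for automatic per-channel thresholds.
#' @return A [droplet_well()] of class counts.
#' @export
classify_droplets <- function(amplitudes, thresholds = NULL) {
  stopifnot(is.data.frame(amplitudes),
            all(c("ch1", "ch2") %in% names(amplitudes)))
  if (nrow(amplitudes) < 100L) {
    stop("classification needs at least 100 droplets")
  }
  if (is.null(thresholds)) {
    thresholds <- c(auto_threshold(amplitudes$ch1, "ch1"),
                    auto_threshold(amplitudes$ch2, "ch2"))
  }
  stopifnot(is.numeric(thresholds), length(thresholds) == 2L)
  mut <- amplitudes$ch1 > thresholds[1]
  wt <- amplitudes$ch2 > thresholds[2]
  droplet_well(n_mut_only = sum(mut & !wt), n_wt_only = sum(!mut & wt),
               n_double = sum(mut & wt), n_negative = sum(!mut & !wt))
}

#' Poisson occupancy correction for digital PCR
#'
#' Converts a positive-droplet fraction to the mean number of template
#' molecules per droplet: `lambda = -ln(1 - n_positive/n_accepted)`. This is
#' the standard digital PCR correction for droplets containing more than one
#' molecule. Saturated wells (all droplets positive) are unquantifiable and
#' raise an error.
#'
#' @param n_positive Number of positive droplets (0 <= n_positive < n_accepted).
#' @param n_accepted Total accepted droplets (> 0).
#' @return Mean molecules per droplet (0 when `n_positive` is 0).
#' @examples
#' estimate_lambda(1000, 20000)  # -log(0.95)
#' @export
estimate_lambda <- function(n_positive, n_accepted) {
  if (!is.finite(n_positive) || !is.finite(n_accepted) ||
      n_positive < 0 || n_accepted <= 0 ||
      n_positive != round(n_positive) || n_accepted != round(n_accepted)) {
    stop("n_positive and n_accepted must be non-negative integers, n_accepted > 0")
  }
  if (n_positive >= n_accepted) {
    stop("well is saturated (all droplets positive): concentration unquantifiable")
  }
  if (n_positive == 0) return(0)
  -log1p(-n_positive / n_accepted)
}

#' Quantification configuration (volumes and positivity threshold)
#'
#' Volume defaults follow the QX200 workflow: 0.85 nL droplets, 20 uL
#' reactions containing 9 uL of template. The eluate and plasma volumes have
#' no universal defaults; when either is `NULL`, per-mL-plasma outputs are
#' reported as `NA` rather than guessed.
#'
#' @param droplet_volume_nl Droplet volume in nanoliters.
#' @param reaction_volume_ul Reaction volume in microliters.
#' @param template_volume_ul Template (DNA + water) volume per reaction in
#'   microliters.
#' @param elution_volume_ul Total cfDNA eluate volume in microliters, or NULL.
#' @param plasma_volume_ml Plasma volume extracted, in mL, or NULL.
#' @param positivity_threshold Minimum mutant-containing droplets for a
#'   positive ctDNA call (default 2).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(droplet_volume_nl = 0.85, reaction_volume_ul = 20,
                         template_volume_ul = 9, elution_volume_ul = NULL,
                         plasma_volume_ml = NULL, positivity_threshold = 2) {
  vols <- c(droplet_volume_nl, reaction_volume_ul, template_volume_ul,
            elution_volume_ul, plasma_volume_ml)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    stop("all volumes must be positive")
  }
  if (!is.finite(positivity_threshold) || positivity_threshold < 1 ||
      positivity_threshold != round(positivity_threshold)) {
    stop("positivity_threshold must be an integer >= 1")
  }
  structure(list(droplet_volume_nl = droplet_volume_nl,
                 reaction_volume_ul = reaction_volume_ul,
                 template_volume_ul = template_volume_ul,
                 elution_volume_ul = elution_volume_ul,
                 plasma_volume_ml = plasma_volume_ml,
                 positivity_threshold = as.integer(positivity_threshold)),
            class = "quant_config")
}

#' ctDNA positivity call
#'
#' A sample is called ctDNA-positive when the number of mutant-containing
#' droplets (mutant-only plus double-positive) reaches the threshold; the
#' conventional limit is two mutant-positive droplets.
#'
#' @param well A [droplet_well()].
#' @param threshold Integer >= 1 (default 2).
#' @return Logical flag.
#' @export
call_positivity <- function(well, threshold = 2) {
  stopifnot(inherits(well, "droplet_well"))
  if (threshold < 1 || threshold != round(threshold)) {
    stop("threshold must be an integer >= 1")
  }
  (well$n_mut_only + well$n_double) >= threshold
}

#' Per-sample detection limit
#'
#' The smallest mutant fraction callable in a well given its informative
#' droplets: `threshold / total positive droplets`. The denominator defaults
#' to all non-negative droplets (mutant-only + wild-type-only +
#' double-positive); a wild-type-only-based denominator
#' (`denominator = "wt_positive"`, i.e. wt-only + double) is also exposed
#' since usage in the field is ambiguous.
#'
#' @param well A [droplet_well()].
#' @param threshold Positivity threshold (integer >= 1, default 2).
#' @param denominator `"all_positive"` (default) or `"wt_positive"`.
#' @return Fraction in (0, 1].
#' @export
detection_limit <- function(well, threshold = 2,
                            denominator = c("all_positive", "wt_positive")) {
  stopifnot(inherits(well, "droplet_well"))
  denominator <- match.arg(denominator)
  if (threshold < 1 || threshold != round(threshold)) {
    stop("threshold must be an integer >= 1")
  }
  total <- if (denominator == "all_positive") {
    well$n_mut_only + well$n_wt_only + well$n_double
  } else {
    well$n_wt_only + well$n_double
  }
  if (total < threshold) {
    stop("fewer informative droplets than the positivity threshold: detection limit undefined")
  }
  threshold / total
}

#' Poisson-corrected quantification of a ddPCR well
#'
#' Computes mean molecules per droplet for the mutant and wild-type targets
#' (double-positive droplets count toward both, since they contain at least
#' one molecule of each), concentrations in copies/uL of reaction, the
#' occupancy-corrected variant allele fraction
#' `VAF = lambda_mut / (lambda_mut + lambda_wt)`, the positivity call, the
#' per-sample detection limit, and — when eluate and plasma volumes are
#' configured — copies and positive droplets per mL of plasma via the
#' reaction -> eluate -> plasma volume chain.
#'
#' @param well A [droplet_well()].
#' @param config A [quant_config()].
#' @return An object of class `quant_result` (a list; see fields in the
#'   description).
#' @examples
#' w <- droplet_well(200, 800, 10, 18990)
#' quantify(w, quant_config())$vaf  # ~0.2034
#' @export
quantify <- function(well, config = quant_config()) {
  stopifnot(inherits(well, "droplet_well"), inherits(config, "quant_config"))
  lambda_mut <- estimate_lambda(well$n_mut_only + well$n_double, well$n_accepted)
  lambda_wt <- estimate_lambda(well$n_wt_only + well$n_double, well$n_accepted)
  conc_mut <- lambda_mut / (config$droplet_volume_nl / 1000)  # copies/uL
  conc_wt <- lambda_wt / (config$droplet_volume_nl / 1000)
  vaf <- if (lambda_mut + lambda_wt == 0) 0 else lambda_mut / (lambda_mut + lambda_wt)
  per_ml <- function(conc) {
    if (is.null(config$elution_volume_ul) || is.null(config$plasma_volume_ml)) {
      return(NA_real_)
    }
    conc * config$reaction_volume_ul *
      (config$elution_volume_ul / config$template_volume_ul) /
      config$plasma_volume_ml
  }
  droplets_per_ml <- function(n) {
    if (is.null(config$elution_volume_ul) || is.null(config$plasma_volume_ml)) {
      return(NA_real_)
    }
    n * (config$elution_volume_ul / config$template_volume_ul) /
      config$plasma_volume_ml
  }
  total_pos <- well$n_mut_only + well$n_wt_only + well$n_double
  dl <- if (total_pos >= config$positivity_threshold) {
    detection_limit(well, config$positivity_threshold)
  } else {
    NA_real_
  }
  structure(list(
    lambda_mut = lambda_mut, lambda_wt = lambda_wt,
    conc_mut = conc_mut, conc_wt = conc_wt,
    vaf = vaf,
    copies_per_ml_plasma_mut = per_ml(conc_mut),
    copies_per_ml_plasma_wt = per_ml(conc_wt),
    droplets_per_ml_plasma_mut = droplets_per_ml(well$n_mut_only + well$n_double),
    droplets_per_ml_plasma_wt = droplets_per_ml(well$n_wt_only + well$n_double),
    positive = call_positivity(well, config$positivity_threshold),
    detection_limit = dl), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "quant_result: VAF %.4f, lambda mut/wt %.4g/%.4g, %s (detection limit %s)\n",
    x$vaf, x$lambda_mut, x$lambda_wt,
    if (x$positive) "ctDNA-POSITIVE" else "ctDNA-negative",
    if (is.na(x$detection_limit)) "undefined"
    else sprintf("%.3g%%", 100 * x$detection_limit)))
  invisible(x)
}

#' Correlate paired VAF measurements
#'
#' Pearson product-moment correlation with a two-sided p-value from the usual
#' t transform on n - 2 degrees of freedom; the workhorse for comparing, e.g.,
#' ddPCR VAFs in tumor DNA with exome-derived VAFs.
#'
#' @param vaf_a,vaf_b Numeric vectors of equal length >= 3 with non-degenerate
#'   variance.
#' @return list with `r`, `p` and `n`.
#' @export
correlate_vafs <- function(vaf_a, vaf_b) {
  stopifnot(length(vaf_a) == length(vaf_b))
  if (length(vaf_a) < 3L) stop("need at least 3 pairs")
  if (stats::sd(vaf_a) == 0 || stats::sd(vaf_b) == 0) {
    stop("degenerate variance in one coordinate")
  }
  ct <- stats::cor.test(vaf_a, vaf_b, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(vaf_a))
}

#' Read per-well droplet class counts from a TSV
#'
#' Expected columns: `well`, `n_mut_only`, `n_wt_only`, `n_double`,
#' `n_negative`.
#'
#' @param path TSV path.
#' @return Named list of [droplet_well()] objects, one per `well` value.
#' @export
read_well_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("well", "n_mut_only", "n_wt_only", "n_double", "n_negative")
  if (!all(need %in% names(tab))) {
    stop("well-count TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    droplet_well(tab$n_mut_only[i], tab$n_wt_only[i], tab$n_double[i],
                 tab$n_negative[i])
  })
  stats::setNames(out, tab$well)
}

#' Read per-droplet amplitudes from a TSV
#'
#' Expected columns: `well`, `ch1`, `ch2`.
#'
#' @param path TSV path.
#' @return Named list of data.frames (one per well) suitable for
#'   [classify_droplets()].
#' @export
read_amplitudes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("well", "ch1", "ch2")
  if (!all(need %in% names(tab))) {
    stop("amplitude TSV must have columns: ", paste(need, collapse = ", "))
  }
  split(tab[c("ch1", "ch2")], tab$well)
}
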