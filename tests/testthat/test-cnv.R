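test_that("compute_logr is zero for identical samples and centers the median", {
  bn <- make_bins(tiny_build(), 50000)
  x <- withr::with_seed(1, rpois(nrow(bn$bins), 100))
  a <- binned_counts(bn, x, "a")
  prof <- compute_logr(a, a)
  expect_true(all(abs(prof$logr[!prof$mask]) < 1e-12))
  expect_false(any(prof$mask[x >= 10]))

  b <- binned_counts(bn, withr::with_seed(2, rpois(nrow(bn$bins), 100)), "b")
  p2 <- compute_logr(a, b)
  expect_equal(median(p2$logr[!p2$mask]), 0)
})

test_that("a doubled region sits one logR unit above the baseline", {
  bn <- make_bins(genome_build("c1", 2e7), 50000)  # 400 bins
  n <- nrow(bn$bins)
  base <- rep(1000, n)
  tum <- base
  tum[1:100] <- 2000  # deterministic doubling of a quarter of the genome
  prof <- compute_logr(binned_counts(bn, tum), binned_counts(bn, base))
  gained <- mean(prof$logr[1:100])
  flat <- mean(prof$logr[101:n])
  expect_equal(gained - flat, 1, tolerance = 1e-12)
})

test_that("compute_logr is invariant under library-size scaling", {
  bn <- make_bins(tiny_build(), 50000)
  t_counts <- withr::with_seed(3, rpois(nrow(bn$bins), 120))
  n_counts <- withr::with_seed(4, rpois(nrow(bn$bins), 80))
  p1 <- compute_logr(binned_counts(bn, t_counts), binned_counts(bn, n_counts))
  p2 <- compute_logr(binned_counts(bn, 3 * t_counts),
                     binned_counts(bn, n_counts))
  p3 <- compute_logr(binned_counts(bn, t_counts),
                     binned_counts(bn, 5 * n_counts))
  expect_equal(p1$logr, p2$logr)
  expect_equal(p1$logr, p3$logr)
})

test_that("masking and zero-count substitution behave as documented", {
  bn <- make_bins(genome_build("c1", 5e5), 50000)  # 10 bins
  norm <- c(0, 5, rep(100, 8))   # two unreliable normal bins
  tum <- c(50, 50, 0, rep(100, 7))
  prof <- compute_logr(binned_counts(bn, tum), binned_counts(bn, norm), 10)
  expect_true(all(prof$mask[1:2]))
  expect_true(all(is.na(prof$logr[1:2])))
  # zero tumor count with reliable normal: finite (half-count substituted)
  expect_true(is.finite(prof$logr[3]))
  expect_lt(prof$logr[3], min(prof$logr[4:10]))
  expect_error(compute_logr(binned_counts(bn, tum),
                            binned_counts(bn, rep(1, 10)), 10), "masked")
})

test_that("logR recovers a single-copy gain under the generative model", {
  build <- toy_build()
  bn <- make_bins(build)
  # 200-bin (10 Mb) gain on chr1; small altered fraction keeps the
  # median-centering anchored on the diploid bins
  segs <- rbind(
    data.frame(chrom = "chr1", start = c(0, 1e7), end = c(1e7, 25e6),
               copy = c(3L, 2L)),
    data.frame(chrom = setdiff(build$chrom, "chr1"), start = 0,
               end = 25e6, copy = 2L))
  gained_bins <- bn$bins$chrom == "chr1" & bn$bins$end <= 1e7
  for (purity in c(1, 0.5)) {
    truth <- copy_number_truth(segs, build, purity = purity)
    tum <- simulate_binned_counts(truth, bn, 100, seed = 20 + purity * 10)
    nor <- simulate_binned_counts(diploid_truth(build), bn, 100,
                                  seed = 30 + purity * 10)
    prof <- compute_logr(tum, nor)
    expected <- log2((purity * 3 + (1 - purity) * 2) / 2)
    expect_lt(abs(mean(prof$logr[gained_bins & !prof$mask]) - expected), 0.05)
  }
})

test_that("compare_profiles matches cor.test and handles degeneracy", {
  bn <- make_bins(tiny_build(), 50000)
  n <- nrow(bn$bins)
  lr <- withr::with_seed(5, rnorm(n, 0, 0.5))
  p <- manual_profile(lr, bn)
  self <- compare_profiles(p, p)
  expect_equal(self$r, 1)
  expect_equal(self$n_bins, n)

  q <- manual_profile(withr::with_seed(6, lr + rnorm(n, 0, 0.3)), bn)
  cmp <- compare_profiles(p, q)
  expect_equal(cmp$r, cor(p$logr, q$logr))
  expect_gt(cmp$p, 0)  # floored, never exactly zero
  expect_error(compare_profiles(p, manual_profile(rep(0, n), bn)),
               "degenerate")
})

test_that("compare_profiles respects masks and chromosome exclusions", {
  bn <- make_bins(genome_build(c("chr1", "chrX"), c(1e6, 1e6)), 50000)
  n <- nrow(bn$bins)
  lr_a <- withr::with_seed(7, rnorm(n))
  lr_b <- withr::with_seed(8, rnorm(n))
  mask <- rep(FALSE, n); mask[1:3] <- TRUE
  a <- manual_profile(lr_a, bn, mask)
  b <- manual_profile(lr_b, bn)
  cmp <- compare_profiles(a, b)
  # masked bins and chrX dropped
  use <- !mask & bn$bins$chrom == "chr1"
  expect_equal(cmp$n_bins, sum(use))
  expect_equal(cmp$r, cor(lr_a[use], lr_b[use]))
  # sex chromosomes can be opted back in
  cmp2 <- compare_profiles(a, b, exclude_chroms = character())
  expect_equal(cmp2$n_bins, n - 3)
})

test_that("instability_score is the fraction of altered bins", {
  bn <- make_bins(tiny_build(), 50000)
  n <- nrow(bn$bins)
  expect_equal(instability_score(manual_profile(rep(0, n), bn)), 0)
  expect_equal(instability_score(manual_profile(rep(1, n), bn)), 1)
  lr <- rep(0, n); lr[1:round(0.3 * n)] <- -0.6
  expect_equal(instability_score(manual_profile(lr, bn)), 0.3)
  # exactly at the threshold counts as altered
  expect_equal(instability_score(manual_profile(rep(0.15, n), bn), 0.15), 1)
  expect_error(instability_score(manual_profile(rep(0, n), bn), -1), "> 0")
})

test_that("instability recovers the simulated altered fraction at high depth", {
  build <- toy_build()
  bn <- make_bins(build)
  segs <- data.frame(chrom = build$chrom, start = 0, end = build$length,
                     copy = 2L)
  segs$copy[1:2] <- c(3L, 1L)  # 1000 of 3000 bins altered -> 0.333
  truth <- copy_number_truth(segs, build, purity = 1)
  tum <- simulate_binned_counts(truth, bn, 2000, seed = 40)
  nor <- simulate_binned_counts(diploid_truth(build), bn, 2000, seed = 41)
  prof <- compute_logr(tum, nor)
  expect_lt(abs(instability_score(prof) - 1 / 3), 0.05)
})

test_that("attenuation_factor is the through-origin regression slope", {
  bn <- make_bins(tiny_build(), 50000)
  n <- nrow(bn$bins)
  ref <- manual_profile(withr::with_seed(9, rnorm(n, 0, 0.7)), bn)
  expect_equal(attenuation_factor(ref, ref), 1)
  half <- manual_profile(ref$logr * 0.5, bn)
  expect_equal(attenuation_factor(half, ref), 0.5)
  # closed form: sum(xy)/sum(x^2)
  obs <- manual_profile(withr::with_seed(10, 0.3 * ref$logr + rnorm(n, 0, 0.1)),
                        bn)
  expect_equal(attenuation_factor(obs, ref),
               sum(obs$logr * ref$logr) / sum(ref$logr^2))
  expect_error(attenuation_factor(obs, manual_profile(rep(0, n), bn)),
               "degenerate")
})

test_that("profiles round-trip through the SEG TSV", {
  bn <- make_bins(tiny_build(), 50000)
  n <- nrow(bn$bins)
  mask <- rep(FALSE, n); mask[5] <- TRUE
  prof <- manual_profile(withr::with_seed(11, rnorm(n, 0, 0.4)), bn, mask,
                         sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".seg.tsv")
  write_profile_seg(prof, path)
  back <- read_profile_seg(path)
  expect_equal(back$logr, prof$logr)
  expect_equal(back$mask, prof$mask)
  expect_equal(back$sample_id, "s1")
  expect_equal(back$binning$bins, bn$bins)
})

test_that("bin-count TSVs round-trip and validate the binning", {
  bn <- make_bins(tiny_build(), 50000)
  cc <- binned_counts(bn, withr::with_seed(12, rpois(nrow(bn$bins), 30)), "t")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_counts(cc, path)
  back <- read_bin_counts(path, bn, "t")
  expect_equal(back$counts, cc$counts)
  other <- make_bins(tiny_build(), 100000)
  expect_error(read_bin_counts(path, other, "t"), "does not match")
})
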