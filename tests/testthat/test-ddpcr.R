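test_that("estimate_lambda evaluates the occupancy correction exactly", {
  expect_identical(estimate_lambda(0, 20000), 0)
  # frozen 30-digit arbitrary-precision reference, checked to 12 sig digits
  expect_equal(estimate_lambda(1000, 20000), LAMBDA_1000_20000,
               tolerance = 1e-13)
  expect_error(estimate_lambda(20000, 20000), "saturated")
  expect_error(estimate_lambda(-1, 100), "non-negative")
  expect_error(estimate_lambda(5, 0), "non-negative")
})

test_that("estimate_lambda is monotone and never below the naive fraction", {
  n <- 5000
  prev <- -1
  for (k in c(0, 1, 7, 50, 499, 2500, 4999)) {
    lam <- estimate_lambda(k, n)
    expect_gt(lam, prev)
    expect_gte(lam, k / n)  # occupancy correction only increases
    prev <- lam
  }
})

test_that("estimate_lambda is unbiased under the generative model", {
  lam_true <- 0.05
  est <- vapply(1:200, function(s) {
    w <- simulate_droplet_well(droplet_truth(lam_true, 0, 20000), seed = s)
    estimate_lambda(w$n_mut_only + w$n_double, w$n_accepted)
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - lam_true), 3 * se)
})

test_that("quantify reproduces the closed-form worked example", {
  w <- droplet_well(n_mut_only = 200, n_wt_only = 800, n_double = 10,
                    n_negative = 18990)
  q <- quantify(w, quant_config())
  expect_equal(q$lambda_mut, -log(1 - 210 / 20000))
  expect_equal(q$lambda_wt, -log(1 - 810 / 20000))
  # frozen arbitrary-precision value of lambda_m / (lambda_m + lambda_w)
  expect_equal(q$vaf, VAF_WORKED_WELL, tolerance = 1e-12)
  expect_equal(q$conc_mut, q$lambda_mut / 0.85e-3)
  # volumes absent: per-mL outputs withheld, not guessed
  expect_true(is.na(q$copies_per_ml_plasma_mut))

  # no mutant signal -> VAF 0 by definition
  expect_equal(quantify(droplet_well(0, 100, 0, 900))$vaf, 0)
  # symmetric well -> VAF exactly 0.5
  expect_equal(quantify(droplet_well(300, 300, 17, 1000))$vaf, 0.5)
})

test_that("quantify scales to copies and droplets per mL plasma", {
  cfg <- quant_config(elution_volume_ul = 50, plasma_volume_ml = 4)
  w <- droplet_well(200, 800, 10, 18990)
  q <- quantify(w, cfg)
  conc <- -log(1 - 210 / 20000) / 0.85e-3
  expect_equal(q$copies_per_ml_plasma_mut, conc * 20 * (50 / 9) / 4)
  expect_equal(q$droplets_per_ml_plasma_mut, 210 * (50 / 9) / 4)
  expect_equal(q$droplets_per_ml_plasma_wt, 810 * (50 / 9) / 4)
})

test_that("quantify recovers simulated concentrations within Monte-Carlo error", {
  lam_m <- 0.02; lam_w <- 0.3
  vafs <- numeric(200); lams <- numeric(200)
  for (s in 1:200) {
    w <- simulate_droplet_well(droplet_truth(lam_m, lam_w, 20000), seed = s)
    q <- quantify(w)
    vafs[s] <- q$vaf; lams[s] <- q$lambda_mut
  }
  expect_lt(abs(mean(lams) - lam_m), 3 * sd(lams) / sqrt(200))
  true_vaf <- lam_m / (lam_m + lam_w)
  expect_lt(abs(mean(vafs) - true_vaf), 3 * sd(vafs) / sqrt(200))
})

test_that("positivity follows the two-droplet rule", {
  # exactly two mutant-containing droplets at threshold 2: positive
  expect_true(call_positivity(droplet_well(2, 100, 0, 898), 2))
  expect_true(call_positivity(droplet_well(1, 100, 1, 898), 2))
  # one mutant-containing droplet: negative
  expect_false(call_positivity(droplet_well(1, 100, 0, 899), 2))
  # no mutant droplets: negative at any threshold
  expect_false(call_positivity(droplet_well(0, 100, 0, 900), 1))
  expect_error(call_positivity(droplet_well(2, 1, 0, 1), 0), ">= 1")
})

test_that("detection_limit equals threshold over informative droplets", {
  expect_equal(detection_limit(droplet_well(0, 1000, 0, 19000), 2), 0.002)
  # boundary: exactly as many positives as the threshold
  expect_equal(detection_limit(droplet_well(0, 2, 0, 100), 2), 1.0)
  expect_error(detection_limit(droplet_well(0, 1, 0, 100), 2), "undefined")
  # alternative denominator exposed: WT-containing droplets only
  expect_equal(
    detection_limit(droplet_well(10, 90, 10, 900), 2, "wt_positive"), 2 / 100)
  expect_equal(detection_limit(droplet_well(10, 90, 10, 900), 2), 2 / 110)
})

test_that("detection_limit matches brute force over many totals and decreases", {
  prev <- Inf
  for (total in c(2:50, 100, 377, 1000, 5000, 10000)) {
    well <- droplet_well(0, total, 0, 10)
    dl <- detection_limit(well, 2)
    # exhaustive oracle: smallest m/total with integer m >= threshold
    expect_equal(dl, min((2:total) / total)[1])
    expect_lte(dl, 1)
    expect_lt(dl, prev + 1e-12)
    prev <- dl
  }
})

test_that("merge_wells pools replicate wells", {
  a <- droplet_well(10, 100, 2, 888)
  b <- droplet_well(30, 500, 8, 10000)
  expect_identical(unclass(merge_wells(list(a))), unclass(a))
  m <- merge_wells(list(a, b))
  expect_equal(m$n_accepted, a$n_accepted + b$n_accepted)
  expect_equal(m$n_mut_only, 40)
  # pooled lambda lies between the per-well lambdas
  lam <- function(w) estimate_lambda(w$n_mut_only + w$n_double, w$n_accepted)
  expect_true(lam(m) >= min(lam(a), lam(b)) && lam(m) <= max(lam(a), lam(b)))
  expect_error(merge_wells(list()), "at least one")
})

test_that("classify_droplets applies fixed and automatic thresholds", {
  # all amplitudes below both thresholds: every droplet negative
  amp <- data.frame(ch1 = runif(200, 0, 100), ch2 = runif(200, 0, 100))
  w <- classify_droplets(amp, thresholds = c(1000, 1000))
  expect_equal(w$n_negative, 200)

  # auto threshold on two point masses sits at the midpoint
  amp2 <- data.frame(ch1 = rep(c(100, 900), each = 100),
                     ch2 = rep(c(200, 1000), times = 100))
  w2 <- classify_droplets(amp2)
  expect_equal(w2$n_mut_only + w2$n_double, 100)
  expect_equal(w2$n_wt_only + w2$n_double, 100)

  # a unimodal channel must be refused in auto mode
  amp3 <- data.frame(ch1 = withr::with_seed(1, rnorm(200, 500, 50)),
                     ch2 = rep(c(0, 1000), each = 100))
  expect_error(classify_droplets(amp3), "bimodal|single amplitude")
  expect_error(classify_droplets(amp[1:50, ]), "at least 100")
})

test_that("round-trip classification recovers simulated class counts", {
  for (seed in 1:5) {
    w <- simulate_droplet_well(droplet_truth(0.02, 0.4, 2000), seed = seed)
    amp <- simulate_droplet_amplitudes(w, noise_sd = 250, seed = seed + 50)
    back <- classify_droplets(amp[c("ch1", "ch2")])
    expect_identical(unclass(back)[1:4], unclass(w)[1:4])
  }
})

test_that("correlate_vafs matches the textbook Pearson formula", {
  x <- c(0.1, 0.25, 0.4, 0.33, 0.8)
  y <- c(0.12, 0.2, 0.45, 0.3, 0.75)
  res <- correlate_vafs(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_manual)
  tstat <- r_manual * sqrt((5 - 2) / (1 - r_manual^2))
  expect_equal(res$p, 2 * pt(abs(tstat), df = 3, lower.tail = FALSE))

  # exact line: r = 1; swapping coordinates leaves r unchanged
  expect_equal(correlate_vafs(1:5 / 10, 2 * (1:5) / 10 + 0.01)$r, 1)
  expect_equal(correlate_vafs(y, x)$r, res$r)
  expect_error(correlate_vafs(c(0.1, 0.2), c(0.2, 0.3)), "at least 3")
  expect_error(correlate_vafs(rep(0.1, 5), 1:5 / 10), "degenerate")
})

test_that("well-count and amplitude TSVs round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(well = c("A01", "A02"), n_mut_only = c(5, 0),
                         n_wt_only = c(100, 50), n_double = c(1, 0),
                         n_negative = c(894, 950)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  wells <- read_well_counts(path)
  expect_equal(names(wells), c("A01", "A02"))
  expect_equal(wells$A01$n_accepted, 1000)

  w <- droplet_well(5, 80, 1, 414)
  amp <- simulate_droplet_amplitudes(w, seed = 1)
  apath <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(well = "A01", amp[c("ch1", "ch2")]), apath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  back <- read_amplitudes(apath)
  expect_identical(unclass(classify_droplets(back$A01))[1:4], unclass(w)[1:4])
})
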