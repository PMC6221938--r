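---
title: "Models and methods: tumor-informed liquid biopsy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: tumor-informed liquid biopsy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidbiopsy)
```

# Scope and workflow

This package implements the computational core of a tumor-informed liquid
biopsy workflow for solid tumors (developed with pancreatic neuroendocrine
tumors in mind): the resected tumor and matched germline DNA are exome
sequenced, one tumor-specific single-nucleotide variant is chosen as a
tracking target, plasma cell-free DNA (cfDNA) is genotyped for that target
by droplet digital PCR (ddPCR), and shallow whole-genome-style binned read
counts provide copy-number profiles of tumor and cfDNA for comparison.
Sequencing, alignment, and somatic variant calling are upstream of this
package; it consumes annotated variant tables, droplet data, and read
positions or per-bin counts.

# Variant selection cascade

## Model

Each candidate is a somatic SNV with tumor variant allele fraction (VAF),
population allele frequencies from three databases (dbSNP, ExAC,
1000 Genomes), a consequence class, CADD PHRED and SIFT pathogenicity
annotations, and two gene-set flags. The cascade is three pure, per-record
filters plus a total ordering:

1. **Rarity and consequence** — keep non-synonymous variants with population
   AF < `max_af` (default 0.01). A missing frequency passes: absence from a
   population database is evidence of rarity. By default *all* non-missing
   database AFs must be below the threshold (the strictest reading); an
   `"any"` mode is exposed because usage differs between groups.
2. **Minimum VAF** — keep `vaf_tumor >= min_vaf` (default 0.20). The
   boundary is inclusive: "below 20% excluded" means exactly 20% survives.
   The cutoff exists so the chosen target is validatable by Sanger
   sequencing, which needs roughly ≥ 20% mutant fraction. A missing VAF is
   an error, not a pass — it indicates malformed caller output.
3. **Prioritization** — tier 1: variant in a known
   neuroendocrine-tumor-associated gene; tier 2: in a cancer gene census
   gene; tier 3: high predicted pathogenicity. "High pathogenicity" is
   operationalized as CADD PHRED ≥ `cadd_min` (default 20, the conventional
   notability point: top 1% of variants) and, by default, SIFT
   "deleterious". The conjunctive default follows the workflow this package
   reimplements, which lists the two predictors jointly; a disjunctive mode
   (`require_sift_deleterious = FALSE`) is available since practice varies.

Ties inside a tier are broken by descending CADD, then genomic coordinate.
The published workflow never states how one variant was chosen among several
same-tier candidates; *some* deterministic total order is required for
reproducibility, and CADD-then-coordinate is the least surprising one. The
target is the best-ranked survivor with a real tier, falling back to the
best tier-"none" survivor; an empty survivor set yields no target rather
than an error, since "no trackable variant" is a legitimate clinical result.

The shipped NET gene list (`inst/extdata/net_genes.txt`) seeds only the four
genes that are uncontroversially NET-associated (*MEN1*, *DAXX*, *ATRX*,
*EPAS1*); it is a starting point to edit, not a curated resource. The census
file is a clearly labelled synthetic stand-in because the real cancer gene
census cannot be redistributed.

## Why an audit trail

Filter cascades are opaque in retrospect: six months later nobody remembers
why a variant disappeared. `select_target()` therefore records, per input
variant, the exact clause that removed it or the tier it survived with, and
the pipeline report embeds those counts.

# ddPCR quantification

## Poisson occupancy model

A reaction is partitioned into `n` ≈ 20,000 droplets of volume `v`
(default 0.85 nL, the QX200 convention — the instrument literature says only
"nanoliter droplets", so this is configurable; the VAF is unaffected by
`v`). Template molecules load independently, so the count per droplet is
Poisson with mean λ and the fraction of *negative* droplets estimates
e^{−λ}. Hence

$$\hat\lambda = -\ln(1 - k/n),$$

with `k` the positive-droplet count. This correction for multiple occupancy
always satisfies λ ≥ k/n and is the reason digital PCR is quantitative
without a standard curve. A fully positive well is saturated and raises an
error: λ is unidentifiable there.

Double-positive droplets contain at least one molecule of each target, so
they count toward both channels' `k`. The VAF is computed from corrected
lambdas, `VAF = λ_mut/(λ_mut + λ_wt)` (defined as 0 when both are 0): a
raw-count ratio is biased upward at high loading, while at the low loadings
typical of cfDNA the two agree to within rounding — which is why reported
percentages from either convention coincide in practice.

## Positivity and detection limit

A sample is called ctDNA-positive at ≥ 2 mutant-containing droplets
(`n_mut_only + n_double`), the conventional minimal-event rule. The
per-sample detection limit is `threshold / total positive droplets`, the
smallest mutant fraction that could have produced a positive call given the
observed informative droplets. "Total positive" is read as all non-negative
droplets (mutant-only + WT-only + double); a WT-based denominator is exposed
as an option because the phrase is ambiguous in the field. With, say, 500
informative droplets the limit is 0.4% — the statistic makes explicit that
sensitivity is droplet-count-limited per sample.

## Per-mL plasma scaling

Copies/µL of reaction convert to copies/mL plasma through an explicit volume
chain: × reaction volume (default 20 µL) → × eluate/template ratio (template
default 9 µL) → ÷ plasma volume. Eluate and plasma volumes have no sensible
defaults; when absent the per-mL outputs are `NA` rather than silently
guessed. Raw positive-droplet counts scale by the same chain (without the
reaction-volume factor) for droplets-per-mL reporting.

## Automatic droplet classification

Production ddPCR software thresholds are often set manually. The automatic
mode fits each channel with the optimal two-cluster 1-D partition (exact
exhaustive scan minimizing within-cluster variance) and thresholds at the
midpoint of the cluster centers. It refuses channels whose cluster
separation is below twice the *sum* of the two cluster SDs. This specific
form was chosen deliberately: for equal SDs it reduces to the 4-sigma
separability the amplitude simulator itself enforces, and—unlike a rule
based on the root-mean-square pooled SD, which a single Gaussian cluster
passes with separation ≈ 2.6 pooled SDs—it actually rejects unimodal
channels and instructs the user to threshold manually. No modeling of
"rain" (intermediate droplets) is attempted.

# Copy-number profiling

## Binning and counting

The genome is tiled with non-overlapping 50 kb bins, half-open 0-based
intervals, the last bin per chromosome truncated. Reads are assigned to the
bin containing their 5' start coordinate — not midpoint- or
overlap-weighted — because start assignment is unambiguous, convention-free,
and exactly testable against a brute-force loop. A read starting on a bin
boundary belongs to the downstream bin (half-open convention).

## logR

For tumor/normal pairs, `logR_i = log2((t_i/T)/(n_i/N))` with library-size
totals `T`, `N`, so the statistic is invariant to sequencing depth of either
sample. Bins with normal count < 10 are masked rather than pseudocounted:
below ~10 reads the ratio denominator is too noisy to interpret, and
pseudocounts would invent signal. Tumor zeros over a reliable normal get a
half-count substitute (t_i ← 0.5), which keeps deep deletions finite and
strongly negative without fabricating precision. Profiles are then
median-centered on unmasked bins in place of any ploidy model: a balanced
genome sits at 0 by construction, and identical-sample input yields an
exactly-zero profile (asserted in tests). No GC or mappability correction is
applied — the upstream tooling that includes those corrections is explicitly
out of scope, and a correction stage can be inserted before `compute_logr`
if needed. One consequence of median-centering worth knowing: when a large
fraction of the genome is altered, the median slides off the diploid level
and absolute logR levels shift slightly; recovery tests therefore use
moderate altered fractions.

## Profile comparison, instability, attenuation

Profiles on the same binning are compared by Pearson correlation over
jointly unmasked bins, p-value from the usual t transform, floored at the
double-precision minimum (reported downstream as "< 2.2e-16"). Sex
chromosomes are excluded by default to avoid sex-mismatch artifacts between
samples. The chromosomal-instability score is the fraction of genome
altered: the proportion of unmasked bins with |logR| ≥ 0.15. The default
threshold sits well below a pure single-copy gain (0.585) so that diluted
tumor signal still registers, while staying above the per-bin noise at the
depths the package targets.

The attenuation factor regresses an observed profile on a reference through
the origin: slope 1 means equal amplitude, < 1 a diluted signal. Two caveats
are documented rather than hidden. First, classical regression dilution:
noise in the *reference* biases the slope downward (≈ σ²_sig/(σ²_sig+σ²_noise)),
so even a self-comparison of two noisy replicates sits below 1. Second, the
slope tracks the ctDNA fraction only in the small-|logR| regime where
log2((f·c+(1−f)·2)/2) is approximately linear in f; homozygous deletions
(c = 0) respond very non-linearly and drag the slope far below the true
fraction. The monotone decrease with dilution — the property the pipeline
relies on — holds regardless.

# Synthetic data: what it emulates, what it does not

All generators take explicit seeds, never touch global random state, and are
bit-reproducible.

- **Copy-number truths** place a requested number of non-overlapping
  segments with boundaries snapped to the bin grid (so bins never straddle a
  truth boundary — deliberately removing partial-overlap ambiguity from
  recovery tests). Positions and lengths are random; defaults are
  arm-scale events (50–300 bins, i.e. 2.5–15 Mb on the toy build's 25 Mb
  chromosomes), matching the chromosome-arm-level aneuploidy typical of
  genomically unstable neuroendocrine tumors. Event copy numbers *cycle*
  deterministically through the allowed non-diploid states (0, 1, 3, 4, 5 by
  default) instead of being drawn i.i.d.: the generator is a test-pattern
  source whose job is to exercise the full amplitude range — deep loss
  through multi-copy gain — in every generated genome, not a model of tumor
  evolution. (With i.i.d. copies, ~17% of genomes would by chance contain no
  deep loss and carry too little signal variance for high same-truth profile
  correlations at shallow depth.)
- **Binned counts** draw per-bin reads with expectation
  `depth × (purity·c + (1−purity)·2)/2` from the truth copy `c` at the bin
  midpoint; `dispersion = 0` gives Poisson and `dispersion > 0` a negative
  binomial with variance `mean·(1 + dispersion·mean)` — a single
  overdispersion knob whose Poisson limit is testable. Real shallow-WGS
  noise (GC waves, mappability, batch effects) is *not* modeled; a green
  recovery test establishes correctness of the estimators under the stated
  sampling model, not robustness to instrument artifacts.
- **Read positions** scatter exactly `count` read starts uniformly inside
  each bin, so counting them back is an exact round-trip identity.
- **Droplet wells** load mutant and WT molecules per droplet as independent
  Poissons and class droplets by presence of each type — precisely the model
  the occupancy correction inverts. No rain, probe cross-reactivity, or PCR
  inhibition.
- **Droplet amplitudes** draw two independent channels from class-dependent
  normals and require ≥ 4-sigma mean separation so classification is exact
  by construction; the real difficulty of manual gating is out of scope.
- **Variant tables** generate one category per cascade clause (common,
  synonymous, low-VAF, NET-gene pass, census pass, high-CADD pass,
  fail-all-tiers) with the survivor set and unique expected target derived
  from the category labels, independently of the filter implementation.

The toy genome defaults to 6 × 25 Mb chromosomes (3,000 bins at 50 kb) so
every simulation-backed test finishes in seconds on one CPU; all statistics
scale to a real genome by changing the chromosome table.

# Numerical and design choices

- `-log1p(-p)` instead of `-log(1-p)` for the occupancy correction preserves
  precision at small positive fractions.
- Integer bin arithmetic in `make_bins` (a float `seq()` produced spurious
  zero-width bins at some chromosome lengths).
- Chromosome ordering for tie-breaks parses "chr11"-style names numerically
  with X/Y after 22 and unknown names last, alphabetically.
- Determinism end-to-end: identical case inputs and configuration produce
  byte-identical JSON reports; the report embeds the resolved configuration
  and its MD5 hash, which suffices to re-run the identical analysis.
- Pipeline configs and case descriptions are JSON (no YAML dependency in the
  supported stack).
- Partial cases produce partial reports with explicit `"not computed"`
  sections; silent omission is treated as a bug.

# Known limitations

- No segmentation (CBS/HMM), absolute copy-number calling, or purity
  estimation from profiles; logR profiles are per-bin only.
- The per-sample detection limit is a counting bound, not a probabilistic
  LOD; it ignores false-positive droplet rates.
- The cascade consumes annotations (CADD, SIFT, population AFs); it does not
  compute them, and its results are only as good as the annotation sidecar.
- The synthetic world is deliberately idealized (see above); green tests
  bound implementation error, not biological or instrumental variation.
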