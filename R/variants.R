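#' @title Somatic variant tables
#' @description A variant table is a plain data.frame with one row per
#' annotated somatic SNV and the columns listed in [variant_table()]. All
#' filter and prioritization functions operate row-wise on such tables and
#' preserve row order.
#' @name variant-tables
NULL

variant_columns <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "vaf_tumor", "af_dbsnp", "af_exac", "af_1000g",
                     "cadd_phred", "sift", "in_net_genes", "in_cosmic_census")

#' Construct and validate a variant table
#'
#' @param df data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single bases), `gene`, `consequence` (one of "nonsynonymous",
#'   "synonymous", "other"), `vaf_tumor` (fraction), `af_dbsnp`, `af_exac`,
#'   `af_1000g` (fractions, NA = absent from that database), `cadd_phred`
#'   (>= 0 or NA), `sift` ("deleterious", "tolerated" or NA), `in_net_genes`,
#'   `in_cosmic_census` (logical).
#' @return The validated data.frame (class `variant_table` prepended).
#' @export
variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(variant_columns, names(df))
  if (length(missing_cols)) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df)) {
    if (any(df$ref == df$alt)) stop("ref and alt must differ")
    if (any(df$pos < 1)) stop("pos is 1-based and must be >= 1")
    frac <- c(df$vaf_tumor, df$af_dbsnp, df$af_exac, df$af_1000g)
    frac <- frac[!is.na(frac)]
    if (any(frac < 0 | frac > 1)) stop("allele fractions must lie in [0, 1]")
    if (!all(df$consequence %in% c("nonsynonymous", "synonymous", "other"))) {
      stop("consequence must be nonsynonymous/synonymous/other")
    }
    if (!all(df$sift %in% c("deleterious", "tolerated", NA))) {
      stop("sift must be deleterious/tolerated/NA")
    }
  }
  if (!inherits(df, "variant_table")) class(df) <- c("variant_table", class(df))
  df
}

variant_id <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Keep rare, non-synonymous variants
#'
#' Retains variants whose consequence is non-synonymous and whose population
#' allele frequency is below `af_threshold` in the consulted databases
#' (dbSNP, ExAC, 1000 Genomes columns). With `mode = "all"` (default,
#' strictest) every non-missing database frequency must be below the
#' threshold; with `mode = "any"` one suffices. A missing frequency counts as
#' passing: absence from a population database is evidence of rarity.
#'
#' @param variants A [variant_table()].
#' @param af_threshold Population-AF cutoff in (0, 1]; default 0.01.
#' @param mode `"all"` or `"any"` (which databases must be below threshold).
#' @return The filtered table, original row order preserved.
#' @export
filter_rare_nonsynonymous <- function(variants, af_threshold = 0.01,
                                      mode = c("all", "any")) {
  variants <- variant_table(variants)
  mode <- match.arg(mode)
  if (!is.numeric(af_threshold) || af_threshold <= 0 || af_threshold > 1) {
    stop("af_threshold must lie in (0, 1]")
  }
  if (nrow(variants) == 0L) return(variants)
  afs <- cbind(variants$af_dbsnp, variants$af_exac, variants$af_1000g)
  below <- afs < af_threshold
  below[is.na(below)] <- TRUE  # missing AF passes
  rare <- if (mode == "all") rowSums(!below) == 0 else rowSums(below) > 0
  keep <- variants$consequence == "nonsynonymous" & rare
  variants[keep, , drop = FALSE]
}

#' Exclude low-VAF variants
#'
#' Drops variants whose tumor VAF is below `min_vaf`; the boundary is
#' inclusive (a variant at exactly the threshold survives). The default 20%
#' cutoff keeps variants amenable to orthogonal validation. A missing tumor
#' VAF is an error — it signals malformed caller output.
#'
#' @param variants A [variant_table()].
#' @param min_vaf Minimum tumor VAF in \[0, 1\]; default 0.20.
#' @return The filtered table, original row order preserved.
#' @export
filter_min_vaf <- function(variants, min_vaf = 0.20) {
  variants <- variant_table(variants)
  if (!is.numeric(min_vaf) || min_vaf < 0 || min_vaf > 1) {
    stop("min_vaf must lie in [0, 1]")
  }
  if (anyNA(variants$vaf_tumor)) {
    stop("missing vaf_tumor: malformed variant caller output")
  }
  variants[variants$vaf_tumor >= min_vaf, , drop = FALSE]
}

# numeric rank for chromosome names: chr1..chr22 < chrX < chrY < others
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  rank <- ifelse(!is.na(num), num,
                 ifelse(stripped == "X", 23,
                        ifelse(stripped == "Y", 24, 25)))
  # unknown names break ties alphabetically via a secondary key
  rank + match(chrom, sort(unique(chrom))) / (length(unique(chrom)) + 1) * 1e-6
}

tier_levels <- c("NET_gene", "cosmic_census", "pathogenicity", "none")

assign_tiers <- function(variants, cadd_min = 20,
                         require_sift_deleterious = TRUE) {
  high_path <- !is.na(variants$cadd_phred) & variants$cadd_phred >= cadd_min
  if (require_sift_deleterious) {
    high_path <- high_path & !is.na(variants$sift) &
      variants$sift == "deleterious"
  }
  ifelse(variants$in_net_genes, "NET_gene",
         ifelse(variants$in_cosmic_census, "cosmic_census",
                ifelse(high_path, "pathogenicity", "none")))
}

#' Prioritize surviving variants for ddPCR tracking
#'
#' Assigns each variant to a tier — known neuroendocrine-tumor-associated
#' gene, then cancer gene census membership, then high predicted
#' pathogenicity (CADD PHRED >= `cadd_min`, by default also requiring a
#' deleterious SIFT call) — and ranks by tier, then descending CADD score,
#' then genomic coordinate. Variants matching no tier rank last with tier
#' `"none"`.
#'
#' @param variants A [variant_table()].
#' @param cadd_min CADD PHRED cutoff for the pathogenicity tier (default 20,
#'   the conventional notability point).
#' @param require_sift_deleterious Also require SIFT "deleterious" for the
#'   pathogenicity tier (default TRUE).
#' @return The table re-ordered by rank, with a `tier` column prepended to
#'   the ranking result.
#' @export
prioritize <- function(variants, cadd_min = 20, require_sift_deleterious = TRUE) {
  variants <- variant_table(variants)
  if (!is.numeric(cadd_min) || cadd_min < 0) stop("cadd_min must be >= 0")
  tier <- assign_tiers(variants, cadd_min, require_sift_deleterious)
  out <- variants
  out$tier <- factor(tier, levels = tier_levels)
  if (nrow(out) == 0L) return(out)
  cadd <- ifelse(is.na(out$cadd_phred), -Inf, out$cadd_phred)
  ord <- order(as.integer(out$tier), -cadd, chrom_rank(out$chrom), out$pos)
  out[ord, , drop = FALSE]
}

#' Select one ddPCR-trackable target from a somatic variant list
#'
#' Applies the full cascade: rarity/consequence filter, minimum-VAF filter,
#' then tiered prioritization. The target is the top-ranked survivor with a
#' real tier, falling back to the top survivor of tier "none", or `NULL` when
#' nothing survives (no trackable variant for this patient). An audit trail
#' records, per input variant, the clause that removed it or its final tier.
#'
#' @param variants A [variant_table()].
#' @param config List of cascade parameters: `max_af` (default 0.01),
#'   `af_mode` ("all"/"any"), `min_vaf` (default 0.20), `cadd_min` (default
#'   20), `require_sift_deleterious` (default TRUE).
#' @return An object of class `selection_result`: list with `survivors`
#'   (ranked table with tiers), `target` (single-row table or NULL), `tier`
#'   (character), and `audit` (data.frame `variant`, `fate`).
#' @export
select_target <- function(variants, config = list()) {
  variants <- variant_table(variants)
  cfg <- utils::modifyList(
    list(max_af = 0.01, af_mode = "all", min_vaf = 0.20, cadd_min = 20,
         require_sift_deleterious = TRUE), config)
  ids <- variant_id(variants)
  fate <- rep(NA_character_, nrow(variants))

  s1 <- filter_rare_nonsynonymous(variants, cfg$max_af, cfg$af_mode)
  fate[!(ids %in% variant_id(s1))] <- "removed: common_or_not_nonsynonymous"
  s2 <- filter_min_vaf(s1, cfg$min_vaf)
  fate[is.na(fate) & !(ids %in% variant_id(s2))] <- "removed: low_vaf"
  ranked <- prioritize(s2, cfg$cadd_min, cfg$require_sift_deleterious)
  fate[is.na(fate)] <- paste0("survivor: tier_",
                              as.character(ranked$tier)[match(
                                ids[is.na(fate)], variant_id(ranked))])

  target <- NULL
  tier <- "none"
  if (nrow(ranked) > 0L) {
    target <- ranked[1, , drop = FALSE]
    tier <- as.character(ranked$tier[1])
  }
  structure(list(survivors = ranked, target = target, tier = tier,
                 audit = data.frame(variant = ids, fate = fate,
                                    stringsAsFactors = FALSE),
                 config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d survivor(s), tier %s, target %s\n",
              nrow(x$survivors), x$tier,
              if (is.null(x$target)) "none" else variant_id(x$target)))
  invisible(x)
}

#' Flag variants by gene-set membership
#'
#' Sets `in_net_genes` / `in_cosmic_census` from newline-delimited gene list
#' files or character vectors. The package ships a seed list of
#' neuroendocrine-tumor-associated genes (`net_genes.txt`) and a synthetic
#' stand-in for a cancer gene census (`cosmic_census_synthetic.txt`) under
#' `inst/extdata`; both are meant to be replaced by curated lists.
#'
#' @param variants A [variant_table()].
#' @param net_genes Character vector of genes, or a file path.
#' @param cosmic_genes Character vector of genes, or a file path.
#' @return The table with both flags set.
#' @export
annotate_gene_sets <- function(variants,
                               net_genes = default_gene_list("net_genes.txt"),
                               cosmic_genes = default_gene_list("cosmic_census_synthetic.txt")) {
  variants <- variant_table(variants)
  as_set <- function(x) {
    if (length(x) == 1L && is.character(x) && file.exists(x)) {
      x <- read_gene_list(x)
    }
    unique(x)
  }
  variants$in_net_genes <- variants$gene %in% as_set(net_genes)
  variants$in_cosmic_census <- variants$gene %in% as_set(cosmic_genes)
  variants
}

default_gene_list <- function(fname) {
  system.file("extdata", fname, package = "liquidbiopsy", mustWork = TRUE)
}

#' Read a newline-delimited gene list
#'
#' @param path File path; blank lines and `#` comments are ignored.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a variant table from a TSV file
#'
#' A single TSV carrying all [variant_table()] columns; empty strings in
#' annotation columns are treated as missing.
#'
#' @param path TSV path with a header row.
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."))
  for (col in c("in_net_genes", "in_cosmic_census")) {
    tab[[col]] <- as.logical(tab[[col]])
  }
  variant_table(tab)
}

#' Write a variant table (or selection survivors) to TSV
#'
#' @param variants A [variant_table()] (a `tier` column, if present, is
#'   written too).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read variants from a VCF with a TSV annotation sidecar
#'
#' The VCF supplies coordinates and alleles; the sidecar, keyed by
#' `chrom:pos:ref:alt` (column `variant`), supplies the annotation columns of
#' [variant_table()] (gene, consequence, VAF, population AFs, CADD, SIFT).
#' Gene-set flags default to FALSE unless present in the sidecar; use
#' [annotate_gene_sets()] afterwards.
#'
#' @param vcf_path Path to an (uncompressed) VCF.
#' @param annotation_path Path to the sidecar TSV.
#' @return A [variant_table()].
#' @export
read_vcf_with_annotations <- function(vcf_path, annotation_path) {
  lines <- readLines(vcf_path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) stop("VCF contains no variant records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  vcf <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    pos = as.integer(vapply(fields, `[`, character(1), 2)),
    ref = vapply(fields, `[`, character(1), 4),
    alt = vapply(fields, `[`, character(1), 5),
    stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."))
  if (!"variant" %in% names(ann)) {
    stop("annotation sidecar needs a 'variant' key column (chrom:pos:ref:alt)")
  }
  key <- paste(vcf$chrom, vcf$pos, vcf$ref, vcf$alt, sep = ":")
  idx <- match(key, ann$variant)
  if (anyNA(idx)) {
    stop(sprintf("%d VCF record(s) missing from the annotation sidecar",
                 sum(is.na(idx))))
  }
  ann <- ann[idx, , drop = FALSE]
  for (col in c("in_net_genes", "in_cosmic_census")) {
    if (is.null(ann[[col]])) ann[[col]] <- FALSE
    ann[[col]][is.na(ann[[col]])] <- FALSE
    ann[[col]] <- as.logical(ann[[col]])
  }
  for (col in c("cadd_phred", "vaf_tumor", "af_dbsnp", "af_exac", "af_1000g")) {
    if (is.null(ann[[col]])) ann[[col]] <- NA_real_
  }
  if (is.null(ann$sift)) ann$sift <- NA_character_
  variant_table(cbind(vcf, ann[setdiff(variant_columns,
                                       c("chrom", "pos", "ref", "alt"))]))
}
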