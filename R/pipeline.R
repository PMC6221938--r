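#' Bundle one patient's inputs for the end-to-end workflow
#'
#' A case holds whatever subset of inputs is available: the annotated somatic
#' variant table from the tumor exome, tumor/normal binned counts for the
#' copy-number arm, per-timepoint cfDNA binned counts, and per-timepoint
#' plasma ddPCR wells. Missing pieces lead to partial reports with explicit
#' "not computed" sections, never silent omission.
#'
#' @param patient_id Patient label.
#' @param disease_status `"localized"` or `"metastatic"`.
#' @param variants A [variant_table()] or NULL.
#' @param tumor_counts,normal_counts [binned_counts()] or NULL.
#' @param cfdna_counts Named list of [binned_counts()] per plasma timepoint
#'   (names like "T1").
#' @param plasma_wells Named list of [droplet_well()] per plasma timepoint;
#'   at least one timepoint (well or counts) is required.
#' @return Object of class `patient_case`.
#' @export
patient_case <- function(patient_id, disease_status = c("localized", "metastatic"),
                         variants = NULL, tumor_counts = NULL,
                         normal_counts = NULL, cfdna_counts = list(),
                         plasma_wells = list()) {
  disease_status <- match.arg(disease_status)
  if (length(plasma_wells) == 0L && length(cfdna_counts) == 0L) {
    stop("a case needs at least one plasma timepoint (ddPCR well or cfDNA counts)")
  }
  if (length(plasma_wells) && is.null(names(plasma_wells))) {
    stop("plasma_wells must be a named list (timepoint labels)")
  }
  if (length(cfdna_counts) && is.null(names(cfdna_counts))) {
    stop("cfdna_counts must be a named list (timepoint labels)")
  }
  structure(list(patient_id = as.character(patient_id),
                 disease_status = disease_status, variants = variants,
                 tumor_counts = tumor_counts, normal_counts = normal_counts,
                 cfdna_counts = cfdna_counts, plasma_wells = plasma_wells),
            class = "patient_case")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

quant_section <- function(well, qc) {
  q <- quantify(well, qc)
  list(n_accepted = well$n_accepted, n_mut_only = well$n_mut_only,
       n_wt_only = well$n_wt_only, n_double = well$n_double,
       n_negative = well$n_negative,
       lambda_mut = q$lambda_mut, lambda_wt = q$lambda_wt,
       conc_mut = q$conc_mut, conc_wt = q$conc_wt, vaf = q$vaf,
       copies_per_ml_plasma_mut = q$copies_per_ml_plasma_mut,
       copies_per_ml_plasma_wt = q$copies_per_ml_plasma_wt,
       droplets_per_ml_plasma_mut = q$droplets_per_ml_plasma_mut,
       droplets_per_ml_plasma_wt = q$droplets_per_ml_plasma_wt,
       positive = q$positive, detection_limit = q$detection_limit)
}

#' Run the full per-patient workflow and build a structured case report
#'
#' Deterministic composition of the three analysis arms on whatever inputs
#' the case provides: target selection from the variant table, Poisson
#' quantification of each plasma timepoint, and copy-number profiling
#' (tumor/normal logR, per-timepoint cfDNA profiles, tumor-vs-cfDNA
#' correlations, instability and attenuation). Sections whose inputs are
#' absent are reported as `"not computed"`.
#'
#' @param case A [patient_case()].
#' @param config List of sub-configs: `selection` (see [select_target()]),
#'   `quant` (arguments to [quant_config()] or a ready object), `cnv`
#'   (`min_normal_count`, `logr_threshold`, `exclude_chroms`).
#' @return Object of class `case_report` — a nested list with `schema_version`,
#'   `patient`, `selection`, `quant` (per timepoint), `cnv`, `provenance`.
#' @export
run_case <- function(case, config = list()) {
  stopifnot(inherits(case, "patient_case"))
  cfg <- utils::modifyList(
    list(selection = list(), quant = list(),
         cnv = list(min_normal_count = 10, logr_threshold = 0.15,
                    exclude_chroms = default_sex_chroms)),
    config)
  qc <- if (inherits(cfg$quant, "quant_config")) cfg$quant
        else do.call(quant_config, cfg$quant)

  selection <- "not computed"
  if (!is.null(case$variants)) {
    sel <- select_target(case$variants, cfg$selection)
    selection <- list(
      n_input = nrow(case$variants),
      n_survivors = nrow(sel$survivors),
      tier = sel$tier,
      target = if (is.null(sel$target)) NULL else as.list(sel$target[1, ]),
      survivors = sel$survivors,
      audit = sel$audit)
  }

  quant <- "not computed"
  if (length(case$plasma_wells)) {
    quant <- lapply(case$plasma_wells, quant_section, qc = qc)
  }

  cnv <- "not computed"
  have_pair <- !is.null(case$tumor_counts) && !is.null(case$normal_counts)
  if (have_pair || (length(case$cfdna_counts) && !is.null(case$normal_counts))) {
    mnc <- cfg$cnv$min_normal_count
    thr <- cfg$cnv$logr_threshold
    excl <- cfg$cnv$exclude_chroms
    tumor_profile <- NULL
    cnv <- list()
    if (have_pair) {
      tumor_profile <- compute_logr(case$tumor_counts, case$normal_counts, mnc)
      cnv$tumor <- list(
        n_bins = length(tumor_profile$logr),
        n_masked = sum(tumor_profile$mask),
        instability = instability_score(tumor_profile, thr, excl))
    }
    for (tp in names(case$cfdna_counts)) {
      prof <- compute_logr(case$cfdna_counts[[tp]], case$normal_counts, mnc,
                           sample_id = tp)
      entry <- list(n_bins = length(prof$logr), n_masked = sum(prof$mask),
                    instability = instability_score(prof, thr, excl))
      if (!is.null(tumor_profile)) {
        cmp <- compare_profiles(tumor_profile, prof, excl)
        entry$vs_tumor <- list(r = cmp$r, p = cmp$p, n_bins = cmp$n_bins,
                               attenuation = attenuation_factor(
                                 prof, tumor_profile, excl))
      }
      cnv[[paste0("cfdna_", tp)]] <- entry
    }
  }

  structure(list(
    schema_version = "1.0",
    patient = list(patient_id = case$patient_id,
                   disease_status = case$disease_status),
    selection = selection,
    quant = quant,
    cnv = cnv,
    provenance = list(
      package = "liquidbiopsy",
      version = as.character(utils::packageVersion("liquidbiopsy")),
      config = cfg[c("selection", "cnv")],
      quant_config = unclass(qc),
      config_hash = config_hash(list(selection = cfg$selection,
                                     cnv = cfg$cnv, quant = unclass(qc))))),
    class = "case_report")
}

#' Write a case report as JSON
#'
#' Serialization is deterministic: the same report yields byte-identical
#' files.
#'
#' @param report A [run_case()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  stopifnot(inherits(report, "case_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("case_report for %s (%s): selection %s, %d quant timepoint(s), cnv %s\n",
              x$patient$patient_id, x$patient$disease_status,
              if (identical(x$selection, "not computed")) "not computed"
              else x$selection$tier,
              if (identical(x$quant, "not computed")) 0L else length(x$quant),
              if (identical(x$cnv, "not computed")) "not computed" else "computed"))
  invisible(x)
}

#' Longitudinal trend table across plasma timepoints
#'
#' Tabulates VAF, mutant copies/mL, positivity and instability per timepoint
#' and the deltas between consecutive timepoints. Accepts one report with
#' several timepoints, or a list of reports for the same patient.
#'
#' @param reports A `case_report` or list of them (same patient).
#' @return data.frame, one row per timepoint, with `delta_vaf`,
#'   `delta_copies_per_ml`, `delta_instability` columns (NA for the first
#'   timepoint).
#' @export
longitudinal_summary <- function(reports) {
  if (inherits(reports, "case_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "case_report")))
  pids <- vapply(reports, function(r) r$patient$patient_id, character(1))
  if (length(unique(pids)) != 1L) {
    stop("longitudinal_summary requires reports of a single patient")
  }
  rows <- list()
  for (r in reports) {
    if (identical(r$quant, "not computed")) next
    for (tp in names(r$quant)) {
      q <- r$quant[[tp]]
      instab <- NA_real_
      if (!identical(r$cnv, "not computed")) {
        key <- paste0("cfdna_", tp)
        if (!is.null(r$cnv[[key]])) instab <- r$cnv[[key]]$instability
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pids[1], timepoint = tp, vaf = q$vaf,
        copies_per_ml = q$copies_per_ml_plasma_mut, positive = q$positive,
        instability = instab, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) < 2L) {
    stop("longitudinal_summary needs at least 2 timepoints")
  }
  out <- do.call(rbind, rows)
  out$delta_vaf <- c(NA, diff(out$vaf))
  out$delta_copies_per_ml <- c(NA, diff(out$copies_per_ml))
  out$delta_instability <- c(NA, diff(out$instability))
  out
}
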