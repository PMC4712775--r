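#' Write a target-size report to JSON
#'
#' Serialises every field of a [TargetSizeSummary-class] together with
#' provenance: the md5 checksums of the input files the transcript was
#' loaded from, when given. The report notes that allele loss and larger
#' deletions are additional unenumerable LOF routes.
#'
#' @param summary a [TargetSizeSummary-class].
#' @param path output path (`.json`).
#' @param inputs optional character vector of input file paths to checksum.
#' @return the output path, invisibly.
#' @export
writeTargetSizeReport <- function(summary, path, inputs = character(0)) {
  stopifnot(is(summary, "TargetSizeSummary"))
  slots <- c("transcriptId", "totalSNVs", "nonsenseSNVs", "nonNonsenseSNVs",
             "stopConvertibleCodons", "hotspotMissenseSNVs",
             "frameshiftPositions", "spliceSiteBases", "hotspotCodonFraction",
             "lofToHotspotRatio")
  out <- lapply(stats::setNames(slots, slots), function(s) slot(summary, s))
  out$note <- paste("larger deletions, rearrangements and allele loss are",
                    "additional unenumerable LOF routes not included in",
                    "these counts")
  if (length(inputs)) {
    inputs <- inputs[file.exists(inputs)]
    out$provenance <- as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                              basename(inputs)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-patient classification reports and a cohort category table
#'
#' Writes one JSON report per patient (category, evidence trail, warnings,
#' flags) and a tab-separated cohort table of category assignments.
#'
#' @param cohortResult the list returned by [classifyCohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeClassificationReports <- function(cohortResult, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rep in cohortResult$reports) {
    out <- list(patient_id = rep@patientId,
                category = rep@category,
                evidence = rep@evidence,
                warnings = rep@warnings,
                near_boundary = rep@nearBoundary,
                inheritance = rep@inheritance)
    jsonlite::write_json(out, file.path(dir, paste0(rep@patientId, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  tab <- data.frame(
    patient_id = vapply(cohortResult$reports, function(r) r@patientId, ""),
    category = vapply(cohortResult$reports, category, ""),
    near_boundary = vapply(cohortResult$reports, function(r) r@nearBoundary,
                           TRUE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(dir, "cohort_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
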