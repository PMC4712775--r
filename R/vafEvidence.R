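#' Detection and zygosity policies
#'
#' `detectionPolicy()` bundles the thresholds under which a deep-sequencing
#' observation counts as a detection: the per-base substitution error rate
#' of the platform (default 0.07%, the Ion Torrent estimate for base
#' substitutions), a minimum number of variant reads, and a minimum
#' fold-change of the observed VAF over the error rate. The read-count and
#' fold conventions are exposed because only the error-rate anchor is given
#' by the platform characterisation.
#'
#' `zygosityPolicy()` bundles the allele-frequency bands: below
#' `subHetUpper` (default 35%) a variant is sub-heterozygous (the mosaic
#' band); between `subHetUpper` and `hetUpper` (default 65%, a symmetric
#' convention around 50%) it is in the approximately-heterozygous band.
#'
#' @param errorRate per-base substitution error rate (fraction).
#' @param minVarReads minimum variant read count.
#' @param minFoldOverError minimum VAF as a multiple of `errorRate`.
#' @param subHetUpper upper bound of the sub-heterozygous band (exclusive).
#' @param hetUpper upper bound of the heterozygous band (inclusive).
#' @return a policy list of class `"DetectionPolicy"` / `"ZygosityPolicy"`.
#' @export
detectionPolicy <- function(errorRate = 0.0007, minVarReads = 3L,
                            minFoldOverError = 3) {
  stopifnot(errorRate > 0, minVarReads > 0, minFoldOverError > 0)
  structure(list(errorRate = errorRate,
                 minVarReads = as.integer(minVarReads),
                 minFoldOverError = minFoldOverError),
            class = "DetectionPolicy")
}

#' @rdname detectionPolicy
#' @export
zygosityPolicy <- function(subHetUpper = 0.35, hetUpper = 0.65) {
  stopifnot(subHetUpper > 0, subHetUpper < hetUpper, hetUpper <= 1)
  structure(list(subHetUpper = subHetUpper, hetUpper = hetUpper),
            class = "ZygosityPolicy")
}

#' Variant allele frequency from read counts
#'
#' Full-precision ratio of variant-supporting reads to total reads;
#' formatting to percent for reports is left to the caller.
#'
#' @param varReads,totalReads non-negative integer vectors;
#'   `totalReads` must be positive.
#' @return numeric fraction(s) in `[0, 1]`.
#' @examples
#' vaf(22, 477)    # 0.0461...
#' vaf(1837, 1988) # 0.924...
#' @export
vaf <- function(varReads, totalReads) {
  if (any(!is.na(totalReads) & totalReads <= 0))
    stop("totalReads must be > 0")
  if (any(!is.na(varReads) & !is.na(totalReads) & varReads > totalReads))
    stop("varReads cannot exceed totalReads")
  varReads / totalReads
}

#' Is a variant detected in a specimen observation?
#'
#' For sequencing observations with read counts, detection requires at least
#' `minVarReads` variant reads *and* a VAF of at least
#' `minFoldOverError * errorRate`; observations at or below the platform
#' error rate never count as detections on their own. Sanger (or otherwise
#' count-free) observations carry a trinary detected/not/unknown flag which
#' is returned as-is. When counts are absent but a reported VAF percentage
#' is available, the VAF criterion alone is applied.
#'
#' @param obs a one-row specimen data.frame (columns `var_reads`,
#'   `total_reads`, optionally `detected`, `vaf_pct`, `assay`), or a list
#'   with those fields.
#' @param policy a [detectionPolicy()].
#' @return `TRUE`, `FALSE`, or `NA` when the observation is uninformative.
#' @export
isDetected <- function(obs, policy = detectionPolicy()) {
  vr <- obs$var_reads; tr <- obs$total_reads
  if (!is.null(vr) && !is.null(tr) && length(vr) == 1L &&
      !is.na(vr) && !is.na(tr)) {
    f <- vaf(vr, tr)
    return(vr >= policy$minVarReads &&
           f >= policy$minFoldOverError * policy$errorRate)
  }
  vp <- obs$vaf_pct
  if (!is.null(vp) && length(vp) == 1L && !is.na(vp)) {
    return(vp / 100 >= policy$minFoldOverError * policy$errorRate)
  }
  det <- obs$detected
  if (!is.null(det) && length(det) == 1L && !is.na(det)) return(det == 1)
  NA
}

#' Classify an allele frequency into a zygosity band
#'
#' Fractions below the sub-heterozygous bound are `sub_heterozygous`
#' (consistent with mosaicism in a normal tissue); fractions from the bound
#' up to the heterozygous upper bound inclusive are `heterozygous_range`;
#' higher fractions are `above_het_range` (in a tumor, suggestive of allele
#' loss).
#'
#' @param f numeric fraction(s) in `[0, 1]`.
#' @param policy a [zygosityPolicy()].
#' @return character vector over `{sub_heterozygous, heterozygous_range,
#'   above_het_range}`.
#' @examples
#' zygosityClass(c(0.42, 0.152, 0.35))
#' @export
zygosityClass <- function(f, policy = zygosityPolicy()) {
  if (any(!is.na(f) & (f < 0 | f > 1)))
    stop("allele frequency outside [0, 1]")
  ifelse(is.na(f), NA_character_,
    ifelse(f < policy$subHetUpper, "sub_heterozygous",
      ifelse(f <= policy$hetUpper, "heterozygous_range", "above_het_range")))
}

#' Assess allele loss from tumor VAF and purity
#'
#' In a tumor specimen of purity `p`, a heterozygous somatic variant without
#' allele loss is expected at VAF `p / 2`. The observed read counts are
#' tested against that null with a one-sided exact binomial test; a
#' significantly higher VAF is `consistent_with_loss` of the wild-type
#' allele. Specimens of low or unknown purity are `indeterminate`: allele
#' loss is difficult to establish in specimens that are a mixture of
#' neoplastic and non-neoplastic cells.
#'
#' @param varReads,totalReads read counts at the site.
#' @param purity tumor cell fraction in `[0, 1]`, or NA.
#' @param alpha significance level of the one-sided test.
#' @param purityFloor below this purity the call is `indeterminate`.
#' @return one of `"consistent_with_loss"`, `"not_supported"`,
#'   `"indeterminate"`.
#' @examples
#' inferAlleleLoss(1837, 1988, purity = 0.95)  # consistent_with_loss
#' @export
inferAlleleLoss <- function(varReads, totalReads, purity,
                            alpha = 0.01, purityFloor = 0.30) {
  if (is.na(purity) || purity < purityFloor) return("indeterminate")
  if (is.na(varReads) || is.na(totalReads) || totalReads <= 0)
    return("indeterminate")
  expected <- purity / 2
  p <- stats::binom.test(varReads, totalReads, p = expected,
                         alternative = "greater")$p.value
  if (p < alpha) "consistent_with_loss" else "not_supported"
}

#' Validate a specimen observation table
#'
#' Checks the column contract of per-specimen variant observations:
#' `patient_id`, `specimen_id`, `tissue`, `role` (one of blood,
#' normal_tissue, tumor), `organ`, `purity` (fraction, tumor specimens
#' only), `assay` (sanger, ngs, nanostring), `chgvs`, `var_reads`,
#' `total_reads`, `allele_loss` (0/1); optional `phgvs`, `vaf_pct`,
#' `detected` (trinary 1/0/NA for count-free assays), `cnv`, `source`.
#' Read counts must satisfy `var_reads <= total_reads`.
#'
#' @param df a data.frame of observations.
#' @return the validated data.frame with optional columns filled with NA.
#' @export
validateSpecimens <- function(df) {
  req <- c("patient_id", "specimen_id", "tissue", "role", "organ", "purity",
           "assay", "chgvs", "var_reads", "total_reads", "allele_loss")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("specimen table lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (opt in c("phgvs", "vaf_pct", "detected", "cnv", "source"))
    if (!opt %in% names(df)) df[[opt]] <- NA
  ok_roles <- c("blood", "normal_tissue", "tumor")
  if (any(!df$role %in% ok_roles))
    stop("role must be one of ", paste(ok_roles, collapse = ", "))
  ok_assays <- c("sanger", "ngs", "nanostring")
  if (any(!df$assay %in% ok_assays))
    stop("assay must be one of ", paste(ok_assays, collapse = ", "))
  bad <- !is.na(df$var_reads) & !is.na(df$total_reads) &
    df$var_reads > df$total_reads
  if (any(bad))
    stop("var_reads exceeds total_reads in specimen ",
         df$specimen_id[which(bad)[1L]])
  if (any(!is.na(df$purity) & (df$purity < 0 | df$purity > 1)))
    stop("purity must lie in [0, 1]")
  if (any(!is.na(df$purity) & df$role != "tumor"))
    warning("purity given for non-tumor specimen(s); ignored")
  df$allele_loss[is.na(df$allele_loss)] <- 0L
  df
}

#' Read a specimen observation table from TSV
#'
#' @param path path to a tab-separated file with the columns described in
#'   [validateSpecimens()].
#' @return a validated data.frame.
#' @export
readSpecimenTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validateSpecimens(df)
}
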