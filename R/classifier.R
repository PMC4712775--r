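#' Classify a proband into a mutation category
#'
#' Implements the multi-tissue decision procedure over all specimen
#' observations of one patient. Rules fire in precedence order:
#'
#' 1. **germline** - a non-synonymous coding or splice variant at
#'    approximately heterozygous frequency in blood or other normal tissue.
#'    Blood takes precedence: when blood carries the same variant at a
#'    frequency outside the heterozygous band, the normal-tissue
#'    heterozygous observation does not fire this rule and a disagreement
#'    warning is recorded. A hotspot missense variant in the heterozygous
#'    blood band is still reported as germline but with a
#'    "hotspot-in-blood" caution (such alleles are likely inviable as true
#'    germline variants).
#' 2. **mosaic** - the variant is detected at sub-heterozygous frequency in
#'    at least one blood/normal specimen, *or* the identical variant is
#'    detected in two or more primary tumors of different organs (bilateral
#'    ovaries count as one organ). Subtype `mosaic_hotspot` when the shared
#'    variant is a hotspot missense, else `mosaic_lof`.
#' 3. **tumor_specific** - a single tumor carries both a hotspot missense
#'    and a loss-of-function hit (truncating variant or allele-loss flag)
#'    while nothing is detected in blood or normal tissue.
#' 4. otherwise **unresolved**.
#'
#' An observation below the detection policy's error-rate threshold
#' contributes no evidence on its own; in particular, a trace-level blood
#' observation does not block the multi-organ tumor rule. The procedure is
#' fully deterministic and invariant to specimen order, and any call that
#' flips when the sub-heterozygous bound moves by 5 percentage points is
#' flagged near-boundary.
#'
#' @param record a [PatientRecord-class], or a specimen data.frame
#'   (see [validateSpecimens()]) for a single patient.
#' @param transcript a [CodingTranscript-class] used to classify variants.
#' @param detection a [detectionPolicy()].
#' @param zygosity a [zygosityPolicy()].
#' @return a [ClassificationReport-class].
#' @examples
#' recs <- hotspotEvidenceFixture()
#' classifyPatient(recs[["104"]], dicer1Transcript())
#' @export
classifyPatient <- function(record, transcript,
                            detection = detectionPolicy(),
                            zygosity = zygosityPolicy()) {
  if (is(record, "PatientRecord")) {
    specimens <- record@specimens
    patient_id <- record@patientId
    parents <- record@parents
  } else {
    specimens <- record
    patient_id <- as.character(specimens$patient_id[1L])
    parents <- list()
  }
  specimens <- validateSpecimens(specimens)

  res <- .classifyOnce(specimens, transcript, detection, zygosity)

  # threshold-sensitivity probe: does the call survive moving the
  # sub-heterozygous bound by +/- 5 percentage points?
  near <- FALSE
  for (d in c(-0.05, 0.05)) {
    zp <- zygosityPolicy(subHetUpper = zygosity$subHetUpper + d,
                         hetUpper = zygosity$hetUpper)
    alt <- suppressWarnings(.classifyOnce(specimens, transcript, detection, zp))
    if (alt$category != res$category) { near <- TRUE; break }
  }

  inh <- NA_character_
  if (res$category == "germline" && length(parents) &&
      !is.null(res$variant)) {
    inh <- inheritanceStatus(res$variant, parents, detection, zygosity)
  }

  new("ClassificationReport",
      patientId = patient_id,
      category = res$category,
      evidence = res$evidence,
      warnings = res$warnings,
      nearBoundary = near,
      inheritance = inh)
}

# Annotate specimen rows with detection, VAF and functional class, then
# apply the rules once. Returns list(category, evidence, warnings, variant).
.classifyOnce <- function(specimens, transcript, detection, zygosity) {
  # canonical internal order so the result cannot depend on input order
  role_rank <- match(specimens$role, c("blood", "normal_tissue", "tumor"))
  specimens <- specimens[order(role_rank, specimens$specimen_id,
                               specimens$chgvs, method = "radix"), ,
                         drop = FALSE]
  warnings_out <- character(0)

  n <- nrow(specimens)
  det <- logical(n); f <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    row <- specimens[i, ]
    d <- isDetected(row, detection)
    det[i] <- isTRUE(d)
    if (!is.na(row$var_reads) && !is.na(row$total_reads)) {
      f[i] <- vaf(row$var_reads, row$total_reads)
    } else if (!is.na(row$vaf_pct)) f[i] <- row$vaf_pct / 100
  }

  uniq <- unique(specimens$chgvs[!is.na(specimens$chgvs)])
  fclass <- stats::setNames(character(length(uniq)), uniq)
  fnote <- stats::setNames(rep(NA_character_, length(uniq)), uniq)
  for (v in uniq) {
    pc <- tryCatch(
      withCallingHandlers(
        proteinConsequence(v, transcript),
        warning = function(w) {
          warnings_out <<- c(warnings_out, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(pc)) { fclass[v] <- "vus"; next }
    fclass[v] <- classifyFunctional(pc, transcript)
    fnote[v] <- pc@notation
    # cross-check against any supplied p. string: a mismatch is logged,
    # never an error
    supplied <- unique(specimens$phgvs[specimens$chgvs %in% v &
                                       !is.na(specimens$phgvs)])
    bad <- setdiff(supplied, pc@notation)
    if (length(bad))
      warnings_out <- c(warnings_out, sprintf(
        "supplied p. string %s for %s differs from computed %s",
        bad[1L], v, pc@notation))
  }
  klass <- rep(NA_character_, n)
  has_var <- !is.na(specimens$chgvs)
  klass[has_var] <- fclass[specimens$chgvs[has_var]]

  normal <- specimens$role %in% c("blood", "normal_tissue")
  zyg <- rep(NA_character_, n)
  zyg[!is.na(f)] <- zygosityClass(f[!is.na(f)], zygosity)
  base_organ <- sub("_(left|right)$", "", specimens$organ)

  ev <- function(rule, detail) data.frame(rule = rule, detail = detail,
                                          stringsAsFactors = FALSE)

  # -- rule 1: germline ------------------------------------------------------
  germ_idx <- which(normal & det & !is.na(zyg) & zyg == "heterozygous_range" &
                    has_var & klass != "synonymous")
  germ_keep <- integer(0)
  for (i in germ_idx) {
    v <- specimens$chgvs[i]
    blood_same <- which(specimens$role == "blood" & specimens$chgvs %in% v &
                        !is.na(f))
    if (specimens$role[i] != "blood" && length(blood_same) &&
        !any(zyg[blood_same] == "heterozygous_range", na.rm = TRUE)) {
      warnings_out <- c(warnings_out, sprintf(
        "blood and normal tissue disagree for %s (blood outside heterozygous band); blood given precedence",
        v))
    } else germ_keep <- c(germ_keep, i)
  }
  if (length(germ_keep)) {
    blood_first <- order(specimens$role[germ_keep] != "blood",
                         -f[germ_keep])
    pick <- germ_keep[blood_first[1L]]
    v <- specimens$chgvs[pick]
    if (length(unique(specimens$chgvs[germ_keep])) > 1L)
      warnings_out <- c(warnings_out, paste(
        "conflict: more than one distinct variant in the heterozygous band;",
        "classified by precedence"))
    if (klass[pick] == "hotspot_missense")
      warnings_out <- c(warnings_out, paste(
        "caution: hotspot missense at heterozygous frequency in blood/normal;",
        "germline hotspot alleles are likely inviable"))
    return(list(category = "germline",
                evidence = ev("germline_het_in_normal", sprintf(
                  "%s at VAF %.1f%% in %s", v, 100 * f[pick],
                  specimens$tissue[pick])),
                warnings = warnings_out, variant = v))
  }

  # -- rule 2: mosaic ---------------------------------------------------------
  cand <- list()
  sub_idx <- which(normal & det & !is.na(zyg) & zyg == "sub_heterozygous" &
                   has_var & klass != "synonymous")
  for (i in sub_idx) {
    v <- specimens$chgvs[i]
    cand[[v]] <- unique(c(cand[[v]], sprintf(
      "sub-heterozygous in %s (VAF %.2f%%)", specimens$tissue[i], 100 * f[i])))
  }
  multi <- character(0)
  for (v in uniq) {
    tum <- which(specimens$role == "tumor" & specimens$chgvs %in% v & det)
    orgs <- unique(base_organ[tum])
    if (length(orgs) >= 2L) {
      multi <- c(multi, v)
      cand[[v]] <- unique(c(cand[[v]], sprintf(
        "detected in primary tumors of %d organs (%s)",
        length(orgs), paste(orgs, collapse = ", "))))
    }
  }
  if (length(cand)) {
    vs <- names(cand)
    support <- vapply(cand, length, 1L)
    hot <- fclass[vs] == "hotspot_missense"
    pick_order <- order(-hot, -support, vs, method = "radix")
    v <- vs[pick_order[1L]]
    if (length(vs) > 1L)
      warnings_out <- c(warnings_out, sprintf(
        "conflict: %d distinct mosaic candidate variants; classified on %s",
        length(vs), v))
    subtype <- if (fclass[v] == "hotspot_missense") "mosaic_hotspot"
               else "mosaic_lof"
    return(list(category = subtype,
                evidence = do.call(rbind, lapply(cand[[v]], function(d)
                  ev("mosaic_evidence", paste0(v, ": ", d)))),
                warnings = warnings_out, variant = v))
  }

  # -- rule 3: tumor-specific -------------------------------------------------
  normal_detected <- any(det[normal])
  if (!normal_detected) {
    for (sp in unique(specimens$specimen_id[specimens$role == "tumor"])) {
      rows <- which(specimens$specimen_id == sp)
      hot_here <- any(det[rows] & !is.na(klass[rows]) &
                      klass[rows] == "hotspot_missense")
      lof_here <- any(det[rows] & !is.na(klass[rows]) &
                      klass[rows] == "lof_truncating") ||
                  any(specimens$allele_loss[rows] == 1L)
      if (hot_here && lof_here) {
        return(list(category = "tumor_specific",
                    evidence = ev("biallelic_single_tumor", sprintf(
                      "hotspot + LOF hit confined to %s; nothing detected in blood/normal",
                      specimens$tissue[rows[1L]])),
                    warnings = warnings_out, variant = NULL))
      }
    }
  }

  list(category = "unresolved",
       evidence = ev("no_rule_fired",
                     "no predisposing variant detectable under the policies"),
       warnings = warnings_out, variant = NULL)
}

#' Inherited versus de novo status from a parental trio
#'
#' Given the proband's germline variant and sequencing observations from the
#' parents: `inherited` when a parent carries the variant in the
#' heterozygous band; `de_novo` when both parents were assayed and neither
#' shows the variant; `possible_parental_mosaicism` when a parent shows
#' reads above the platform error rate but below the sub-heterozygous
#' bound (marginal evidence at best); `indeterminate` when parental data
#' are missing.
#'
#' @param probandVariant the proband's c. variant string.
#' @param parents list with elements `mother` and/or `father`, each a
#'   specimen data.frame containing observations for the variant.
#' @param detection a [detectionPolicy()].
#' @param zygosity a [zygosityPolicy()].
#' @return one of `"inherited"`, `"de_novo"`,
#'   `"possible_parental_mosaicism"`, `"indeterminate"`.
#' @export
inheritanceStatus <- function(probandVariant, parents,
                              detection = detectionPolicy(),
                              zygosity = zygosityPolicy()) {
  sides <- intersect(c("mother", "father"), names(parents))
  sides <- sides[vapply(sides, function(s) {
    df <- parents[[s]]
    is.data.frame(df) && nrow(df) > 0L
  }, TRUE)]
  if (length(sides) == 0L) return("indeterminate")

  any_het <- FALSE; any_marginal <- FALSE; n_informative <- 0L
  for (s in sides) {
    df <- parents[[s]]
    rows <- if ("chgvs" %in% names(df))
      df[is.na(df$chgvs) | df$chgvs == probandVariant, , drop = FALSE]
    else df
    if (nrow(rows) == 0L) next
    n_informative <- n_informative + 1L
    for (i in seq_len(nrow(rows))) {
      vr <- rows$var_reads[i]; tr <- rows$total_reads[i]
      if (is.na(vr) || is.na(tr)) next
      fr <- vaf(vr, tr)
      if (isTRUE(isDetected(rows[i, , drop = FALSE], detection)) &&
          zygosityClass(fr, zygosity) == "heterozygous_range")
        any_het <- TRUE
      else if (fr > detection$errorRate && fr < zygosity$subHetUpper)
        any_marginal <- TRUE
    }
  }
  if (any_het) return("inherited")
  if (any_marginal) return("possible_parental_mosaicism")
  if (n_informative == 2L) return("de_novo")
  "indeterminate"
}

#' Classify a whole cohort
#'
#' Applies [classifyPatient()] to every record and tabulates the category
#' counts (all five categories reported, including zeros).
#'
#' @param records list of [PatientRecord-class] objects (or specimen
#'   data.frames).
#' @param transcript a [CodingTranscript-class].
#' @param detection a [detectionPolicy()].
#' @param zygosity a [zygosityPolicy()].
#' @return list with `counts` (named integer vector over
#'   [mutationCategories()]) and `reports` (list of
#'   [ClassificationReport-class]).
#' @export
classifyCohort <- function(records, transcript,
                           detection = detectionPolicy(),
                           zygosity = zygosityPolicy()) {
  reports <- lapply(records, classifyPatient, transcript = transcript,
                    detection = detection, zygosity = zygosity)
  cats <- vapply(reports, category, "")
  counts <- stats::setNames(integer(length(mutationCategories())),
                            mutationCategories())
  tab <- table(factor(cats, levels = mutationCategories()))
  counts[names(tab)] <- as.integer(tab)
  names(reports) <- vapply(reports, function(r) r@patientId, "")
  list(counts = counts, reports = reports)
}
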