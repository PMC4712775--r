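#' Generate a random open reading frame with brute-force ground truth
#'
#' Builds a valid random ORF (ATG initiator, sense codons only, single exon
#' span unless `nIntrons` is drawn) with a randomly chosen hotspot codon
#' set, and computes its target-space counts with the independent
#' brute-force oracle [bruteForceTargetCounts()], which mutates every base,
#' re-translates the whole ORF and diffs the protein -- sharing no logic
#' with [enumerateSNVs()].
#'
#' @param nCodons number of sense codons (>= 2).
#' @param seed integer seed.
#' @param nHotspots number of hotspot codons to annotate (capped at
#'   `nCodons - 1`).
#' @return list with `transcript` (a [CodingTranscript-class]) and `truth`
#'   (list of oracle counts).
#' @export
makeRandomORF <- function(nCodons, seed = 1L, nHotspots = 3L) {
  if (nCodons < 2L)
    stop("an ORF needs at least 2 codons (ATG plus a body)")
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), .stopCodons)
  codons <- c("ATG", sample(sense, nCodons - 1L, replace = TRUE))
  seq <- paste(codons, collapse = "")
  aa <- .translateCds(seq)
  n_hot <- min(nHotspots, nCodons - 1L)
  hot_idx <- sort(sample(2:nCodons, n_hot))
  ann <- list(
    id = sprintf("randomORF_%d_%d", nCodons, seed),
    exons = list(c(1L, 3L * nCodons)),
    n_introns = sample(0:8, 1L),
    domains = list("RNase IIIb" = c(max(2L, nCodons - 4L), nCodons)),
    hotspots = lapply(hot_idx, function(i) list(i, aa[i])))
  tx <- loadTranscript(Biostrings::DNAStringSet(stats::setNames(seq, ann$id)),
                       ann)
  list(transcript = tx, truth = bruteForceTargetCounts(tx))
}

#' Brute-force oracle for the mutational target space
#'
#' Independent re-implementation of the target-space counts: every base of
#' the CDS is substituted to every alternate, the *whole* ORF is
#' re-translated, and the mutant protein is diffed against the reference.
#' Used to validate [enumerateSNVs()] and [targetSizeReport()]; it is
#' deliberately slower and structurally different from the per-codon
#' enumeration path.
#'
#' @param t a [CodingTranscript-class].
#' @return list with `totalSNVs`, `nonsenseSNVs`, `nonNonsenseSNVs`,
#'   `stopConvertibleCodons`, `hotspotMissenseSNVs`, `synonymousSNVs`,
#'   `missenseSNVs`, `frameshiftPositions`, `spliceSiteBases`.
#' @export
bruteForceTargetCounts <- function(t) {
  stopifnot(is(t, "CodingTranscript"))
  chars <- strsplit(as.character(t@cds), "")[[1L]]
  n <- length(chars) %/% 3L
  prot <- .translateCds(paste(chars, collapse = ""))
  hs <- t@hotspots$codon
  total <- 0L; nonsense <- 0L; syn <- 0L; mis <- 0L; hot_mis <- 0L
  stop_conv <- logical(n)
  for (pos in seq_along(chars)) {
    for (alt in setdiff(.bases, chars[pos])) {
      m <- chars; m[pos] <- alt
      mprot <- .translateCds(paste(m, collapse = ""))
      total <- total + 1L
      diffs <- which(mprot != prot)
      if (length(diffs) == 0L) { syn <- syn + 1L; next }
      ci <- diffs[1L]
      if (mprot[ci] == "*") {
        nonsense <- nonsense + 1L
        stop_conv[ci] <- TRUE
      } else {
        mis <- mis + 1L
        if (ci %in% hs) hot_mis <- hot_mis + 1L
      }
    }
  }
  list(totalSNVs = total,
       nonsenseSNVs = nonsense,
       nonNonsenseSNVs = total - nonsense,
       stopConvertibleCodons = sum(stop_conv),
       hotspotMissenseSNVs = hot_mis,
       synonymousSNVs = syn,
       missenseSNVs = mis,
       frameshiftPositions = 3L * n,
       spliceSiteBases = 4L * t@nIntrons)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions: 124 probands in category
#' proportions 90 germline : 5 mosaic LOF : 7 mosaic hotspot : 12
#' tumor-specific : 10 unresolved; mean sequencing depth 3000 with per-base
#' substitution error 0.07%; germline blood VAFs drawn from the observed
#' 42.0-57.1% heterozygous band; mosaic allele fractions from 0.5-30%
#' (sub-heterozygous); per-category age (months; mean/sd 36/31, 27/12,
#' 11/6, 42/31) and disease-foci (1.8/1.0, 1.6/0.5, 15/6.4, 1/0)
#' distributions matching the published per-category summaries. Unresolved
#' patients take cohort-typical age (36/31) and a single focus.
#'
#' @param nPatients cohort size.
#' @param categoryProportions named proportions over the five categories
#'   (scaled to `nPatients`).
#' @param depthMean mean sequencing depth (Poisson).
#' @param errorRate per-base substitution error rate.
#' @param germlineVafBand range of germline blood VAFs.
#' @param mosaicFractionRange range of mosaic allele fractions.
#' @param ageParams,fociParams named lists of `c(mean, sd)` per category.
#' @param seed integer seed.
#' @return list of class `"CohortGenConfig"`.
#' @export
cohortGenConfig <- function(nPatients = 124L,
                            categoryProportions = c(germline = 90, mosaic_lof = 5,
                                                    mosaic_hotspot = 7,
                                                    tumor_specific = 12,
                                                    unresolved = 10),
                            depthMean = 3000, errorRate = 0.0007,
                            germlineVafBand = c(0.42, 0.571),
                            mosaicFractionRange = c(0.005, 0.30),
                            ageParams = list(germline = c(36, 31),
                                             mosaic_lof = c(27, 12),
                                             mosaic_hotspot = c(11, 6),
                                             tumor_specific = c(42, 31),
                                             unresolved = c(36, 31)),
                            fociParams = list(germline = c(1.8, 1.0),
                                              mosaic_lof = c(1.6, 0.5),
                                              mosaic_hotspot = c(15, 6.4),
                                              tumor_specific = c(1, 0),
                                              unresolved = c(1, 0)),
                            seed = 1L) {
  stopifnot(all(mutationCategories() %in% names(categoryProportions)),
            depthMean > 0, errorRate > 0,
            germlineVafBand[1] < germlineVafBand[2],
            mosaicFractionRange[1] < mosaicFractionRange[2])
  structure(list(nPatients = as.integer(nPatients),
                 categoryProportions = categoryProportions,
                 depthMean = depthMean, errorRate = errorRate,
                 germlineVafBand = germlineVafBand,
                 mosaicFractionRange = mosaicFractionRange,
                 ageParams = ageParams, fociParams = fociParams,
                 seed = as.integer(seed)),
            class = "CohortGenConfig")
}

# shifted count model matched to a mean/sd pair: foci = 1 + X with X
# negative-binomial when overdispersed, Poisson otherwise
.drawFoci <- function(n, mean_sd) {
  m1 <- mean_sd[1L] - 1; v <- mean_sd[2L]^2
  if (m1 <= 0) return(rep(1L, n))
  x <- if (v > m1) {
    stats::rnbinom(n, size = m1^2 / (v - m1), mu = m1)
  } else stats::rpois(n, m1)
  as.integer(1L + x)
}

.drawAge <- function(n, mean_sd) {
  pmax(0, stats::rnorm(n, mean_sd[1L], mean_sd[2L]))
}

.specimenRow <- function(patient_id, specimen_id, tissue, role, organ,
                         purity, chgvs, vaf_true, depth_mean, error_rate,
                         allele_loss = 0L) {
  depth <- stats::rpois(1L, depth_mean)
  if (depth < 1L) depth <- 1L
  p <- min(1, vaf_true + (1 - vaf_true) * error_rate)
  data.frame(patient_id = patient_id, specimen_id = specimen_id,
             tissue = tissue, role = role, organ = organ, purity = purity,
             assay = "ngs", chgvs = chgvs, phgvs = NA_character_,
             var_reads = stats::rbinom(1L, depth, p), total_reads = depth,
             vaf_pct = NA_real_, detected = NA_integer_,
             allele_loss = allele_loss, cnv = NA_character_,
             source = "synthetic", stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort of patient records whose specimen read counts are
#' binomial samples at the configured depth and error rate. Germline
#' patients carry one truncating variant at a heterozygous-band blood VAF;
#' mosaic-LOF patients carry a truncating variant at a sub-heterozygous
#' allele fraction in blood plus lung tumors bearing independent hotspot
#' second hits; mosaic-hotspot patients share one hotspot missense variant
#' across a normal tissue and two or more tumors of different organs, each
#' tumor with its own independent LOF hit or allele loss; tumor-specific
#' patients carry a biallelic hotspot + LOF pair in a single tumor with
#' error-only blood reads; unresolved patients carry no variant.
#'
#' @param config a [cohortGenConfig()].
#' @param transcript a [CodingTranscript-class] with a non-empty hotspot
#'   set; defaults to the packaged transcript.
#' @return list with `records` (list of [PatientRecord-class]) and `truth`
#'   (data.frame: `patient_id`, `category`, `variant`, `fraction`,
#'   `age_first_dx_months`, `foci_count`).
#' @examples
#' cohort <- makeCohort(cohortGenConfig(nPatients = 12, seed = 3))
#' cohort$truth$category
#' @export
makeCohort <- function(config = cohortGenConfig(),
                       transcript = dicer1Transcript()) {
  stopifnot(inherits(config, "CohortGenConfig"),
            nrow(transcript@hotspots) > 0L)
  set.seed(config$seed)

  props <- config$categoryProportions[mutationCategories()]
  n_per <- round(props / sum(props) * config$nPatients)
  while (sum(n_per) != config$nPatients) {
    i <- which.max(n_per)
    n_per[i] <- n_per[i] + sign(config$nPatients - sum(n_per))
  }
  cats <- rep(names(n_per), n_per)

  snvs <- enumerateSNVs(transcript)
  nonsense <- snvs[snvs$klass == "nonsense", ]
  hot_mis <- snvs[snvs$klass == "missense" &
                  snvs$codonIndex %in% transcript@hotspots$codon, ]
  chars <- strsplit(as.character(transcript@cds), "")[[1L]]

  rand_lof <- function() {
    if (stats::runif(1) < 0.5) {
      r <- nonsense[sample.int(nrow(nonsense), 1L), ]
      sprintf("c.%d%s>%s", r$cdsPos, r$refBase, r$altBase)
    } else {
      pos <- sample.int(length(chars) - 3L, 1L)
      sprintf("c.%ddel%s", pos, chars[pos])
    }
  }
  rand_hot <- function(exclude = character(0)) {
    repeat {
      r <- hot_mis[sample.int(nrow(hot_mis), 1L), ]
      v <- sprintf("c.%d%s>%s", r$cdsPos, r$refBase, r$altBase)
      if (!v %in% exclude) return(v)
    }
  }
  organs <- c("lung", "kidney", "ovary", "thyroid", "nasal_cavity")

  records <- vector("list", length(cats))
  truth <- vector("list", length(cats))
  for (i in seq_along(cats)) {
    cat_i <- cats[i]
    pid <- sprintf("S%04d", i)
    frac <- NA_real_; variant <- NA_character_
    rows <- NULL
    if (cat_i == "germline") {
      variant <- rand_lof()
      frac <- stats::runif(1, config$germlineVafBand[1L],
                           config$germlineVafBand[2L])
      rows <- .specimenRow(pid, paste0(pid, "-b"), "Blood", "blood", "blood",
                           NA, variant, frac, config$depthMean,
                           config$errorRate)
    } else if (cat_i == "mosaic_lof") {
      variant <- rand_lof()
      frac <- stats::runif(1, config$mosaicFractionRange[1L],
                           config$mosaicFractionRange[2L])
      rows <- .specimenRow(pid, paste0(pid, "-b"), "Blood", "blood", "blood",
                           NA, variant, frac, config$depthMean,
                           config$errorRate)
      used_hot <- character(0)
      for (tum in seq_len(sample(1:2, 1L))) {
        purity <- stats::runif(1, 0.2, 0.9)
        hot <- rand_hot(used_hot); used_hot <- c(used_hot, hot)
        sid <- paste0(pid, "-t", tum)
        rows <- rbind(rows,
          .specimenRow(pid, sid, "Lung, PPB", "tumor", "lung", purity,
                       variant, min(0.5, purity / 2 + frac / 2),
                       config$depthMean, config$errorRate),
          .specimenRow(pid, sid, "Lung, PPB", "tumor", "lung", purity,
                       hot, purity / 2, config$depthMean, config$errorRate))
      }
    } else if (cat_i == "mosaic_hotspot") {
      variant <- rand_hot()
      frac <- stats::runif(1, config$mosaicFractionRange[1L],
                           config$mosaicFractionRange[2L])
      rows <- rbind(
        .specimenRow(pid, paste0(pid, "-b"), "Blood", "blood", "blood", NA,
                     variant, frac / 10, config$depthMean, config$errorRate),
        .specimenRow(pid, paste0(pid, "-n"), "Normal tissue", "normal_tissue",
                     "fallopian_tube", NA, variant, frac, config$depthMean,
                     config$errorRate))
      orgs <- sample(organs, sample(2:3, 1L))
      for (j in seq_along(orgs)) {
        purity <- stats::runif(1, 0.2, 0.9)
        sid <- paste0(pid, "-t", j)
        tumor_vaf <- (purity + (1 - purity) * frac) / 2
        rows <- rbind(rows,
          .specimenRow(pid, sid, paste0(orgs[j], " tumor"), "tumor", orgs[j],
                       purity, variant, tumor_vaf, config$depthMean,
                       config$errorRate))
        if (stats::runif(1) < 0.5) {
          rows$allele_loss[nrow(rows)] <- 1L
        } else {
          rows <- rbind(rows,
            .specimenRow(pid, sid, paste0(orgs[j], " tumor"), "tumor",
                         orgs[j], purity, rand_lof(), purity / 2,
                         config$depthMean, config$errorRate))
        }
      }
    } else if (cat_i == "tumor_specific") {
      variant <- rand_hot()
      purity <- stats::runif(1, 0.3, 0.95)
      sid <- paste0(pid, "-t1")
      rows <- rbind(
        .specimenRow(pid, paste0(pid, "-b"), "Blood", "blood", "blood", NA,
                     variant, 0, config$depthMean, config$errorRate),
        .specimenRow(pid, sid, "Lung, PPB", "tumor", "lung", purity, variant,
                     purity / 2, config$depthMean, config$errorRate))
      if (stats::runif(1) < 0.5) {
        rows$allele_loss[nrow(rows)] <- 1L
      } else {
        rows <- rbind(rows,
          .specimenRow(pid, sid, "Lung, PPB", "tumor", "lung", purity,
                       rand_lof(), purity / 2, config$depthMean,
                       config$errorRate))
      }
    } else {                                    # unresolved
      rows <- .specimenRow(pid, paste0(pid, "-b"), "Blood", "blood", "blood",
                           NA, NA_character_, 0, config$depthMean,
                           config$errorRate)
    }
    age <- .drawAge(1L, config$ageParams[[cat_i]])
    foci <- .drawFoci(1L, config$fociParams[[cat_i]])
    records[[i]] <- new("PatientRecord", patientId = pid, specimens = rows,
                        parents = list(), lesions = data.frame(),
                        ageFirstDxMonths = age)
    truth[[i]] <- data.frame(patient_id = pid, category = cat_i,
                             variant = variant, fraction = frac,
                             age_first_dx_months = age, foci_count = foci,
                             stringsAsFactors = FALSE)
  }
  names(records) <- vapply(truth, function(t) t$patient_id, "")
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate parental trio observations for a proband variant
#'
#' @param probandVariant the proband's c. variant string.
#' @param parentalStatus one of `"inherited"`, `"de_novo"`,
#'   `"parental_mosaic"`.
#' @param seed integer seed.
#' @param depthMean mean sequencing depth.
#' @param errorRate per-base substitution error rate.
#' @param mosaicFraction parent allele fraction for `"parental_mosaic"`.
#' @return list with `mother` and `father` specimen data.frames, suitable
#'   for [inheritanceStatus()].
#' @export
makeTrio <- function(probandVariant, parentalStatus, seed = 1L,
                     depthMean = 3000, errorRate = 0.0007,
                     mosaicFraction = 0.02) {
  parentalStatus <- match.arg(parentalStatus,
                              c("inherited", "de_novo", "parental_mosaic"))
  set.seed(seed)
  draw <- function(vaf_true) {
    depth <- stats::rpois(1L, depthMean)
    p <- min(1, vaf_true + (1 - vaf_true) * errorRate)
    data.frame(chgvs = probandVariant,
               var_reads = stats::rbinom(1L, depth, p),
               total_reads = depth, stringsAsFactors = FALSE)
  }
  carrier <- sample(c("mother", "father"), 1L)
  out <- list()
  for (s in c("mother", "father")) {
    vaf_true <- switch(parentalStatus,
      inherited = if (s == carrier) stats::runif(1, 0.42, 0.571) else 0,
      de_novo = 0,
      parental_mosaic = if (s == carrier) mosaicFraction else 0)
    out[[s]] <- draw(vaf_true)
  }
  out
}
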