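#' Enumerate every possible single-nucleotide variant of a transcript
#'
#' Exhaustively lists the `9 * nCodons(t)` single-base substitutions of the
#' coding sequence (3 alternates at each of the 3 positions of every sense
#' codon) and classifies each against the standard genetic code as
#' synonymous, missense or nonsense. The order is deterministic: by CDS
#' position, then alternate base alphabetically, so downstream reports are
#' byte-stable.
#'
#' @param t a [CodingTranscript-class].
#' @return a data.frame with columns `cdsPos`, `codonIndex`, `posInCodon`,
#'   `refBase`, `altBase`, `refCodon`, `altCodon`, `refAA`, `altAA`,
#'   `klass`.
#' @examples
#' tx <- loadTranscript(Biostrings::DNAStringSet(c(x = "ATGGAG")),
#'                      list(exons = list(c(1, 6)), n_introns = 0))
#' table(enumerateSNVs(tx)$klass)
#' @export
enumerateSNVs <- function(t) {
  stopifnot(is(t, "CodingTranscript"))
  seq <- as.character(t@cds)
  n <- nCodons(t)
  codons <- .splitCodons(seq)
  ref_aa <- .translateCds(seq)

  cds_pos <- rep(seq_len(3L * n), each = 3L)
  ref_base <- rep(strsplit(seq, "")[[1L]], each = 3L)
  alt_mat <- vapply(strsplit(seq, "")[[1L]],
                    function(b) setdiff(.bases, b), character(3L))
  alt_base <- as.vector(alt_mat)

  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_pos - 1L) %% 3L + 1L

  ref_codon <- codons[codon_idx]
  alt_codon <- ref_codon
  substr_vec <- function(x, pos, value) {
    substr(x, pos, pos) <- value
    x
  }
  alt_codon <- mapply(substr_vec, ref_codon, pos_in_codon, alt_base,
                      USE.NAMES = FALSE)
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])

  klass <- ifelse(alt_aa == "*", "nonsense",
                  ifelse(alt_aa == ref_aa[codon_idx], "synonymous", "missense"))

  data.frame(
    cdsPos = cds_pos,
    codonIndex = codon_idx,
    posInCodon = pos_in_codon,
    refBase = ref_base,
    altBase = alt_base,
    refCodon = ref_codon,
    altCodon = alt_codon,
    refAA = ref_aa[codon_idx],
    altAA = alt_aa,
    klass = klass,
    stringsAsFactors = FALSE
  )
}

#' Nonsense target-space counts
#'
#' `countNonsenseSNVs()` counts single-base substitutions whose alternate
#' codon is a stop (TAA/TAG/TGA); `countStopConvertibleCodons()` counts the
#' distinct codons with at least one such substitution. The latter is always
#' less than or equal to the former since a codon can reach a stop in more
#' than one way.
#'
#' @param t a [CodingTranscript-class].
#' @return an integer count.
#' @export
countNonsenseSNVs <- function(t) {
  snvs <- enumerateSNVs(t)
  sum(snvs$klass == "nonsense")
}

#' @rdname countNonsenseSNVs
#' @export
countStopConvertibleCodons <- function(t) {
  snvs <- enumerateSNVs(t)
  length(unique(snvs$codonIndex[snvs$klass == "nonsense"]))
}

#' Count missense substitutions available at the hotspot codons
#'
#' Counts single-base substitutions at the annotated hotspot codons whose
#' consequence is missense; nonsense and synonymous changes at hotspot
#' codons are excluded (a stop at a hotspot codon is a loss-of-function
#' route, not a neomorphic one).
#'
#' @param t a [CodingTranscript-class].
#' @return integer; 0 with a warning when the hotspot set is empty.
#' @export
countHotspotMissenseSNVs <- function(t) {
  hs <- t@hotspots
  if (nrow(hs) == 0L) {
    warning("transcript has an empty hotspot set; returning 0")
    return(0L)
  }
  snvs <- enumerateSNVs(t)
  sum(snvs$klass == "missense" & snvs$codonIndex %in% hs$codon)
}

#' Count point locations at which an indel shifts the reading frame
#'
#' Every base of the open reading frame is a location at which insertion or
#' deletion of one or a few (non-multiple-of-3) nucleotides shifts the
#' frame, so the count is `3 * nCodons(t)`.
#'
#' @param t a [CodingTranscript-class].
#' @return integer.
#' @export
countFrameshiftPositions <- function(t) {
  3L * nCodons(t)
}

#' Count canonical splice-site bases
#'
#' Under the canonical splice model each intron contributes a 2-base donor
#' (GT) and a 2-base acceptor (AG): 4 bases per intron. The intron count is
#' taken from the annotation input, not recomputed from a gene model.
#'
#' @param nIntrons non-negative integer intron count, or a
#'   [CodingTranscript-class] from which it is taken.
#' @param basesPerIntron bases per intron under the splice model (fixed at
#'   4 = 2 donor + 2 acceptor for the canonical model).
#' @return integer.
#' @examples
#' countSpliceSiteBases(26)  # 104
#' @export
countSpliceSiteBases <- function(nIntrons, basesPerIntron = 4L) {
  if (is(nIntrons, "CodingTranscript")) nIntrons <- nIntrons@nIntrons
  nIntrons <- as.integer(nIntrons)
  if (length(nIntrons) != 1L || is.na(nIntrons) || nIntrons < 0L)
    stop("nIntrons must be a single non-negative integer")
  basesPerIntron * nIntrons
}

#' Summarise the mutational target space of a transcript
#'
#' Computes every class count of the target space in one pass and returns a
#' [TargetSizeSummary-class]: total / nonsense / other SNVs,
#' stop-convertible codons, hotspot missense SNVs, frameshift-capable
#' positions, canonical splice bases, the hotspot codon fraction, and the
#' ratio of enumerable loss-of-function routes (nonsense SNVs + frameshift
#' positions + splice bases) to hotspot missense routes. The ratio is a
#' documented convention: allele loss, larger deletions and rearrangements
#' are additional LOF routes that cannot be enumerated per-base and are
#' acknowledged as text in the shown report.
#'
#' @param t a [CodingTranscript-class].
#' @return a [TargetSizeSummary-class].
#' @examples
#' targetSizeReport(dicer1Transcript())
#' @export
targetSizeReport <- function(t) {
  stopifnot(is(t, "CodingTranscript"))
  snvs <- enumerateSNVs(t)
  n <- nCodons(t)
  nonsense <- sum(snvs$klass == "nonsense")
  stop_conv <- length(unique(snvs$codonIndex[snvs$klass == "nonsense"]))
  hs <- t@hotspots
  hot_mis <- if (nrow(hs)) {
    sum(snvs$klass == "missense" & snvs$codonIndex %in% hs$codon)
  } else 0L
  fs <- countFrameshiftPositions(t)
  sp <- countSpliceSiteBases(t@nIntrons)
  new("TargetSizeSummary",
      transcriptId = t@id,
      totalSNVs = nrow(snvs),
      nonsenseSNVs = as.integer(nonsense),
      nonNonsenseSNVs = as.integer(nrow(snvs) - nonsense),
      stopConvertibleCodons = as.integer(stop_conv),
      hotspotMissenseSNVs = as.integer(hot_mis),
      frameshiftPositions = as.integer(fs),
      spliceSiteBases = as.integer(sp),
      hotspotCodonFraction = nrow(hs) / n,
      lofToHotspotRatio = if (hot_mis > 0) (nonsense + fs + sp) / hot_mis
                          else NA_real_)
}
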