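#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom IRanges IRanges
NULL

#' CodingTranscript: an annotated coding sequence
#'
#' Container for the substrate of mutational target-space enumeration: the
#' coding sequence (CDS) of a transcript together with its exon structure
#' (in 1-based CDS coordinates), intron count, protein-domain spans (in codon
#' coordinates) and the set of RNase IIIb "hotspot" codons at which missense
#' changes are neomorphic.
#'
#' The CDS stored in the object contains sense codons only: a terminal stop
#' codon present in the input record is stripped at load time and recorded in
#' `hadTerminalStop`. Validity requires an ATG initiator, no internal stop
#' codon, exon spans that are disjoint, ordered and cover the CDS exactly,
#' and hotspot codons whose translation equals their declared reference
#' amino acid.
#'
#' @slot id accession string for the transcript.
#' @slot cds [Biostrings::DNAString] of length `3 * nCodons(x)`.
#' @slot exonSpans [IRanges::IRanges] of exon intervals in CDS coordinates.
#' @slot nIntrons integer; carried verbatim from the annotation input.
#' @slot domains named [IRanges::IRanges] of domain spans in codon coordinates.
#' @slot hotspots data.frame with columns `codon` (integer) and `refAA`
#'   (single-letter amino acid).
#' @slot hadTerminalStop logical; whether the input CDS ended in a stop codon.
#'
#' @seealso [loadTranscript()], [targetSizeReport()]
#' @export
setClass("CodingTranscript", slots = c(
  id             = "character",
  cds            = "DNAString",
  exonSpans      = "IRanges",
  nIntrons       = "integer",
  domains        = "IRanges",
  hotspots       = "data.frame",
  hadTerminalStop = "logical"
))

setValidity("CodingTranscript", function(object) {
  msgs <- character(0)
  len <- length(object@cds)
  if (len == 0L) msgs <- c(msgs, "CDS is empty")
  if (len %% 3L != 0L) msgs <- c(msgs, "CDS length is not a multiple of 3")
  if (length(msgs) == 0L) {
    aa <- .translateCds(as.character(object@cds))
    if (aa[1L] != "M")
      msgs <- c(msgs, "first codon does not translate to M")
    internal_stops <- which(aa == "*")
    if (length(internal_stops))
      msgs <- c(msgs, sprintf("internal stop codon at codon %d",
                              internal_stops[1L]))
    n <- length(aa)
    ex <- object@exonSpans
    if (length(ex)) {
      s <- IRanges::start(ex); e <- IRanges::end(ex)
      if (is.unsorted(s, strictly = TRUE))
        msgs <- c(msgs, "exon spans are not ordered")
      if (any(s[-1L] != e[-length(e)] + 1L) || s[1L] != 1L || e[length(e)] != len)
        msgs <- c(msgs, "exon spans do not cover 1..length(cds) without gaps/overlaps")
    } else msgs <- c(msgs, "no exon spans")
    hs <- object@hotspots
    if (nrow(hs)) {
      if (!all(c("codon", "refAA") %in% names(hs)))
        msgs <- c(msgs, "hotspots must have columns codon, refAA")
      else {
        if (anyDuplicated(hs$codon))
          msgs <- c(msgs, "duplicate hotspot codons")
        if (any(hs$codon < 1L | hs$codon > n))
          msgs <- c(msgs, "hotspot codon outside 1..n_codons")
        else {
          bad <- hs$codon[aa[hs$codon] != hs$refAA]
          if (length(bad))
            msgs <- c(msgs, sprintf(
              "hotspot codon %d translates to %s, not declared %s",
              bad[1L], aa[bad[1L]], hs$refAA[match(bad[1L], hs$codon)]))
        }
      }
    }
    if (length(object@nIntrons) != 1L || is.na(object@nIntrons) ||
        object@nIntrons < 0L)
      msgs <- c(msgs, "nIntrons must be a single non-negative integer")
  }
  if (length(msgs)) msgs else TRUE
})

#' CodingVariant: a parsed cDNA-level variant
#'
#' Structured form of a c.-notation variant string: kind (substitution,
#' deletion, duplication, insertion, delins), start/end positions given as a
#' 1-based CDS base plus a signed intronic offset (0 for exonic positions),
#' and reference/alternate allele strings (possibly empty).
#'
#' @slot raw the input c. string.
#' @slot kind one of `"substitution"`, `"deletion"`, `"duplication"`,
#'   `"insertion"`, `"delins"`.
#' @slot startBase,endBase integer CDS coordinates (1-based, inclusive).
#' @slot startOffset,endOffset signed intronic offsets (0 when exonic).
#' @slot refAllele,altAllele nucleotide strings; empty when not stated.
#' @seealso [parseCdna()], [formatCdna()], [proteinConsequence()]
#' @export
setClass("CodingVariant", slots = c(
  raw         = "character",
  kind        = "character",
  startBase   = "integer",
  startOffset = "integer",
  endBase     = "integer",
  endOffset   = "integer",
  refAllele   = "character",
  altAllele   = "character"
))

setValidity("CodingVariant", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("substitution", "deletion", "duplication",
                          "insertion", "delins"))
    msgs <- c(msgs, sprintf("unknown variant kind '%s'", object@kind))
  if (object@startBase < 1L || object@endBase < 1L)
    msgs <- c(msgs, "CDS coordinates must be >= 1")
  if (object@startBase > object@endBase ||
      (object@startBase == object@endBase &&
       object@startOffset > object@endOffset))
    msgs <- c(msgs, "start position is after end position")
  if (object@kind == "substitution" &&
      (nchar(object@refAllele) != 1L || nchar(object@altAllele) != 1L))
    msgs <- c(msgs, "substitution requires length-1 ref and alt alleles")
  if (length(msgs)) msgs else TRUE
})

#' ProteinConsequence: predicted protein-level effect of a coding variant
#'
#' @slot kind one of `"missense"`, `"nonsense"`, `"frameshift"`,
#'   `"inframe_deletion"`, `"synonymous"`, `"splice_effect"`.
#' @slot codonIndex first affected codon (NA for splice effects of unknown
#'   outcome).
#' @slot notation p.-style string in one-letter code (`"p.?"` for splice).
#' @slot truncating logical; TRUE iff the consequence truncates the open
#'   reading frame (nonsense, frameshift, or frame-disrupting exon skip).
#' @slot detail list of extra fields (refAA, altAA, skipped exon, warnings).
#' @export
setClass("ProteinConsequence", slots = c(
  kind       = "character",
  codonIndex = "integer",
  notation   = "character",
  truncating = "logical",
  detail     = "list"
))

setValidity("ProteinConsequence", function(object) {
  kinds <- c("missense", "nonsense", "frameshift", "inframe_deletion",
             "synonymous", "splice_effect")
  msgs <- character(0)
  if (!object@kind %in% kinds)
    msgs <- c(msgs, sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  if (object@kind %in% c("nonsense", "frameshift") && !object@truncating)
    msgs <- c(msgs, "nonsense/frameshift consequences must be truncating")
  if (object@kind %in% c("missense", "synonymous", "inframe_deletion") &&
      object@truncating)
    msgs <- c(msgs, sprintf("%s consequence cannot be truncating", object@kind))
  if (length(msgs)) msgs else TRUE
})

#' TargetSizeSummary: counts of possible mutations per consequence class
#'
#' Summary of the mutational target space of one transcript: every possible
#' single-nucleotide variant partitioned into synonymous / missense /
#' nonsense, the number of codons convertible to a stop by one substitution,
#' the hotspot missense target, frameshift-capable point locations, and
#' canonical splice-site bases. `lofToHotspotRatio` is the documented
#' convention (nonsense SNVs + frameshift positions + splice bases) /
#' hotspot missense SNVs; allele loss and large deletions are additional
#' unenumerable loss-of-function routes and are acknowledged in shown
#' reports as text, never as a number.
#'
#' @slot transcriptId accession of the summarised transcript.
#' @slot totalSNVs,nonsenseSNVs,nonNonsenseSNVs,stopConvertibleCodons,hotspotMissenseSNVs,frameshiftPositions,spliceSiteBases integer counts.
#' @slot hotspotCodonFraction numeric fraction of codons that are hotspots.
#' @slot lofToHotspotRatio numeric ratio of enumerable LOF routes to hotspot
#'   missense routes.
#' @seealso [targetSizeReport()]
#' @export
setClass("TargetSizeSummary", slots = c(
  transcriptId          = "character",
  totalSNVs             = "integer",
  nonsenseSNVs          = "integer",
  nonNonsenseSNVs       = "integer",
  stopConvertibleCodons = "integer",
  hotspotMissenseSNVs   = "integer",
  frameshiftPositions   = "integer",
  spliceSiteBases       = "integer",
  hotspotCodonFraction  = "numeric",
  lofToHotspotRatio     = "numeric"
))

setValidity("TargetSizeSummary", function(object) {
  msgs <- character(0)
  if (object@nonsenseSNVs + object@nonNonsenseSNVs != object@totalSNVs)
    msgs <- c(msgs, "nonsense + non-nonsense must equal total SNVs")
  if (object@stopConvertibleCodons > object@nonsenseSNVs)
    msgs <- c(msgs, "stop-convertible codons cannot exceed nonsense SNV count")
  if (length(msgs)) msgs else TRUE
})

#' PatientRecord: all evidence for one proband
#'
#' @slot patientId character identifier.
#' @slot specimens data.frame of per-specimen variant observations (see
#'   [validateSpecimens()] for the column contract).
#' @slot parents list with optional elements `mother` and `father`, each a
#'   specimen data.frame.
#' @slot lesions data.frame of clinical lesions (see [countDiseaseFoci()]).
#' @slot ageFirstDxMonths numeric age at first syndromic diagnosis, months.
#' @export
setClass("PatientRecord", slots = c(
  patientId        = "character",
  specimens        = "data.frame",
  parents          = "list",
  lesions          = "data.frame",
  ageFirstDxMonths = "numeric"
))

setValidity("PatientRecord", function(object) {
  msgs <- character(0)
  if (nrow(object@specimens) < 1L)
    msgs <- c(msgs, "a patient record needs at least one specimen observation")
  if (length(object@ageFirstDxMonths) == 1L &&
      !is.na(object@ageFirstDxMonths) && object@ageFirstDxMonths < 0)
    msgs <- c(msgs, "ageFirstDxMonths must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' ClassificationReport: category assignment with its evidence trail
#'
#' Result of applying the multi-tissue decision procedure to one proband.
#' Every category assignment lists at least one fired rule; given identical
#' inputs and policies the report is reproducible byte for byte.
#'
#' @slot patientId character.
#' @slot category one of `"germline"`, `"mosaic_lof"`, `"mosaic_hotspot"`,
#'   `"tumor_specific"`, `"unresolved"`.
#' @slot evidence data.frame of fired rules with the variant and VAFs behind
#'   each.
#' @slot warnings character vector (conflicts, hotspot-in-blood caution).
#' @slot nearBoundary logical; TRUE when the category flips if the
#'   sub-heterozygous upper bound moves by +/- 5 percentage points.
#' @slot inheritance `"inherited"`, `"de_novo"`,
#'   `"possible_parental_mosaicism"`, `"indeterminate"`, or NA when no trio.
#' @export
setClass("ClassificationReport", slots = c(
  patientId    = "character",
  category     = "character",
  evidence     = "data.frame",
  warnings     = "character",
  nearBoundary = "logical",
  inheritance  = "character"
))

setValidity("ClassificationReport", function(object) {
  cats <- c("germline", "mosaic_lof", "mosaic_hotspot", "tumor_specific",
            "unresolved")
  msgs <- character(0)
  if (!object@category %in% cats)
    msgs <- c(msgs, "unknown mutation category")
  if (nrow(object@evidence) < 1L)
    msgs <- c(msgs, "a classification must list at least one fired rule")
  if (length(msgs)) msgs else TRUE
})

#' Mutation category labels
#'
#' The five categories assigned by the decision procedure, in rule-precedence
#' order.
#' @return character vector of category labels.
#' @export
mutationCategories <- function() {
  c("germline", "mosaic_lof", "mosaic_hotspot", "tumor_specific", "unresolved")
}
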