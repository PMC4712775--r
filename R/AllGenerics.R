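#' @include AllClasses.R
NULL

#' Accessors for CodingTranscript and report objects
#'
#' `transcriptId()`, `cds()`, `nCodons()`, `exonSpans()`, `nIntrons()`,
#' `domains()` and `hotspots()` extract the corresponding parts of a
#' [CodingTranscript-class]; `category()` and `evidence()` extract the
#' assigned category and evidence trail of a [ClassificationReport-class].
#'
#' @param x a `CodingTranscript` or `ClassificationReport` object.
#' @return the slot contents; `nCodons()` returns the number of sense codons
#'   (terminal stop excluded).
#' @name transcript-accessors
#' @aliases transcriptId cds nCodons exonSpans nIntrons domains hotspots
#'   category evidence
NULL

#' @rdname transcript-accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname transcript-accessors
#' @export
setGeneric("cds", function(x) standardGeneric("cds"))
#' @rdname transcript-accessors
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))
#' @rdname transcript-accessors
#' @export
setGeneric("exonSpans", function(x) standardGeneric("exonSpans"))
#' @rdname transcript-accessors
#' @export
setGeneric("nIntrons", function(x) standardGeneric("nIntrons"))
#' @rdname transcript-accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname transcript-accessors
#' @export
setGeneric("hotspots", function(x) standardGeneric("hotspots"))
#' @rdname transcript-accessors
#' @export
setGeneric("category", function(x) standardGeneric("category"))
#' @rdname transcript-accessors
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @rdname transcript-accessors
setMethod("transcriptId", "CodingTranscript", function(x) x@id)
#' @rdname transcript-accessors
setMethod("cds", "CodingTranscript", function(x) x@cds)
#' @rdname transcript-accessors
setMethod("nCodons", "CodingTranscript", function(x) length(x@cds) %/% 3L)
#' @rdname transcript-accessors
setMethod("exonSpans", "CodingTranscript", function(x) x@exonSpans)
#' @rdname transcript-accessors
setMethod("nIntrons", "CodingTranscript", function(x) x@nIntrons)
#' @rdname transcript-accessors
setMethod("domains", "CodingTranscript", function(x) x@domains)
#' @rdname transcript-accessors
setMethod("hotspots", "CodingTranscript", function(x) x@hotspots)
#' @rdname transcript-accessors
setMethod("category", "ClassificationReport", function(x) x@category)
#' @rdname transcript-accessors
setMethod("evidence", "ClassificationReport", function(x) x@evidence)

setMethod("show", "CodingTranscript", function(object) {
  n <- nCodons(object)
  cat("CodingTranscript:", object@id, "\n")
  cat(sprintf("  %d sense codons (%d nt CDS%s), %d exon span(s), %d intron(s)\n",
              n, length(object@cds),
              if (object@hadTerminalStop) " + stripped terminal stop" else "",
              length(object@exonSpans), object@nIntrons))
  if (length(object@domains))
    cat("  domains:", paste(names(object@domains), collapse = ", "), "\n")
  if (nrow(object@hotspots))
    cat("  hotspot codons:",
        paste0(object@hotspots$refAA, object@hotspots$codon, collapse = ", "),
        "\n")
  invisible(object)
})

setMethod("show", "CodingVariant", function(object) {
  cat("CodingVariant:", formatCdna(object), sprintf("[%s]\n", object@kind))
  invisible(object)
})

setMethod("show", "ProteinConsequence", function(object) {
  cat(sprintf("ProteinConsequence: %s (%s%s)\n", object@notation, object@kind,
              if (object@truncating) ", truncating" else ""))
  invisible(object)
})

setMethod("show", "TargetSizeSummary", function(object) {
  cat("Mutational target space of", object@transcriptId, "\n")
  cat(sprintf("  total SNVs:                %d\n", object@totalSNVs))
  cat(sprintf("  nonsense SNVs:             %d (over %d stop-convertible codons)\n",
              object@nonsenseSNVs, object@stopConvertibleCodons))
  cat(sprintf("  other SNVs:                %d\n", object@nonNonsenseSNVs))
  cat(sprintf("  hotspot missense SNVs:     %d\n", object@hotspotMissenseSNVs))
  cat(sprintf("  frameshift positions:      %d\n", object@frameshiftPositions))
  cat(sprintf("  canonical splice bases:    %d\n", object@spliceSiteBases))
  cat(sprintf("  hotspot codon fraction:    %.2f%%\n",
              100 * object@hotspotCodonFraction))
  cat(sprintf("  LOF : hotspot ratio:       %.1f\n", object@lofToHotspotRatio))
  cat("  (larger deletions, rearrangements and allele loss are additional\n",
      "  unenumerable LOF routes not included in these counts)\n", sep = "")
  invisible(object)
})

setMethod("show", "PatientRecord", function(object) {
  cat("PatientRecord:", object@patientId, "-", nrow(object@specimens),
      "specimen observation(s)\n")
  invisible(object)
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: patient %s -> %s\n",
              object@patientId, object@category))
  for (i in seq_len(nrow(object@evidence)))
    cat("  rule:", object@evidence$rule[i], "|", object@evidence$detail[i], "\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  if (isTRUE(object@nearBoundary))
    cat("  note: near-boundary call (sensitive to the sub-heterozygous cutoff)\n")
  invisible(object)
})
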