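#' Load and validate a coding transcript
#'
#' Reads a CDS from a single-record FASTA file and its structural annotation
#' from a JSON document, and returns a validated [CodingTranscript-class].
#' The annotation document has fields `exons` (list of `[start, end]`
#' 1-based inclusive CDS-coordinate pairs), `n_introns`, `domains` (map from
#' domain name to `[start_codon, end_codon]`) and `hotspots` (list of
#' `[codon, ref_aa]` pairs); an optional `id` overrides the FASTA header.
#'
#' A terminal stop codon in the FASTA record is stripped (the enumerated
#' codon set covers sense codons only; stop-loss changes are outside the
#' consequence taxonomy). An internal stop codon, a CDS length that is not a
#' multiple of 3, characters outside `{A,C,G,T}`, or a hotspot whose codon
#' does not translate to its declared reference amino acid are hard errors.
#'
#' @param cdsSource path to a single-record FASTA file, or a
#'   [Biostrings::DNAStringSet] of length 1.
#' @param annotation path to the annotation JSON document, or an equivalent
#'   named list.
#' @return a validated [CodingTranscript-class].
#' @examples
#' tx <- dicer1Transcript()
#' nCodons(tx)
#' @export
loadTranscript <- function(cdsSource, annotation) {
  if (is.character(cdsSource)) {
    set <- Biostrings::readDNAStringSet(cdsSource)
  } else set <- cdsSource
  if (length(set) != 1L)
    stop("cdsSource must contain exactly one FASTA record, found ", length(set))
  seq <- toupper(as.character(set[[1L]]))
  if (nchar(seq) == 0L) stop("CDS sequence is empty")
  if (grepl("[^ACGT]", seq))
    stop("CDS contains characters outside {A,C,G,T}")
  if (nchar(seq) %% 3L != 0L)
    stop("CDS length (", nchar(seq), ") is not divisible by 3")

  had_stop <- FALSE
  last_codon <- substr(seq, nchar(seq) - 2L, nchar(seq))
  if (last_codon %in% .stopCodons) {
    seq <- substr(seq, 1L, nchar(seq) - 3L)
    had_stop <- TRUE
    if (nchar(seq) == 0L) stop("CDS contains only a stop codon")
  }
  aa <- .translateCds(seq)
  internal <- which(aa == "*")
  if (length(internal))
    stop("internal stop codon at codon ", internal[1L])

  if (is.character(annotation)) {
    ann <- jsonlite::read_json(annotation, simplifyVector = FALSE)
  } else ann <- annotation

  id <- if (!is.null(ann$id)) as.character(ann$id) else
    sub("\\s.*$", "", names(set)[1L])

  ex_list <- ann$exons
  if (is.null(ex_list) || !length(ex_list)) {
    ex <- IRanges::IRanges(start = 1L, end = nchar(seq))
  } else {
    st <- vapply(ex_list, function(p) as.integer(p[[1L]]), 1L)
    en <- vapply(ex_list, function(p) as.integer(p[[2L]]), 1L)
    ex <- IRanges::IRanges(start = st, end = en)
  }

  dom_list <- ann$domains
  if (is.null(dom_list) || !length(dom_list)) {
    dom <- IRanges::IRanges()
  } else {
    dom <- IRanges::IRanges(
      start = vapply(dom_list, function(p) as.integer(p[[1L]]), 1L),
      end   = vapply(dom_list, function(p) as.integer(p[[2L]]), 1L))
    names(dom) <- names(dom_list)
  }

  hs_list <- ann$hotspots
  if (is.null(hs_list) || !length(hs_list)) {
    hs <- data.frame(codon = integer(0), refAA = character(0))
  } else {
    hs <- data.frame(
      codon = vapply(hs_list, function(p) as.integer(p[[1L]]), 1L),
      refAA = vapply(hs_list, function(p) as.character(p[[2L]]), ""))
  }

  n_introns <- if (is.null(ann$n_introns)) 0L else as.integer(ann$n_introns)

  new("CodingTranscript",
      id = id,
      cds = Biostrings::DNAString(seq),
      exonSpans = ex,
      nIntrons = n_introns,
      domains = dom,
      hotspots = hs,
      hadTerminalStop = had_stop)
}

#' The packaged DICER1-like reference transcript (synthetic surrogate)
#'
#' Returns the transcript fixture shipped with the package. The coding
#' sequence is a **synthetic surrogate**, not the RefSeq NM_177438.2 record:
#' it is a constructed 1922-codon open reading frame whose published
#' structural properties match those reported for the DICER1 CDS -- the
#' identity of every codon anchored by a published c./p. variant pair
#' (including the five RNase IIIb hotspot codons E1705, D1709, G1809, D1810
#' and E1813), the number of codons convertible to a stop by a single
#' substitution (675), the total nonsense SNV count (736) and hence the
#' 16,562 remaining substitutions, and the 26-exon / 26-intron structure
#' with the exon-10 (243 nt) and exon-24 (269 nt) boundaries implied by the
#' published splice and deletion variants. Domain spans (including RNase
#' IIIb ending at codon 1824) are part of the synthetic annotation input.
#'
#' Counts computed from this fixture therefore exercise the full enumeration
#' pipeline on a transcript with the documented target-space composition;
#' they are not a substitute for running the pipeline on the RefSeq record,
#' which users with access to it can load with [loadTranscript()].
#'
#' @return a validated [CodingTranscript-class].
#' @examples
#' targetSizeReport(dicer1Transcript())
#' @export
dicer1Transcript <- function() {
  loadTranscript(
    system.file("extdata", "DICER1_CDS_synthetic.fa", package = "DicerMosaic",
                mustWork = TRUE),
    system.file("extdata", "DICER1_annotation_synthetic.json",
                package = "DicerMosaic", mustWork = TRUE))
}
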