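#' Predict the protein-level consequence of a coding variant
#'
#' For exonic substitutions the affected codon is re-translated; for exonic
#' small indels the rule is frameshift iff the net inserted-minus-deleted
#' length is not a multiple of 3, with the frameshifted protein obtained by
#' re-translating the mutated CDS (yielding HGVS-style `fs*N` notation); for
#' canonical splice-site variants (intronic offsets +/-1, +/-2) the adjacent
#' exon is predicted to be skipped and the effect classified by the skipped
#' length mod 3; deletions that span a whole exon are classified by the
#' deleted coding length mod 3. Variants deeper in an intron yield a
#' `splice_effect` of unknown outcome with a warning.
#'
#' A mismatch between a stated reference allele and the transcript sequence
#' is a warning recorded in the consequence's `detail`, not an error.
#'
#' @param v a [CodingVariant-class] (or a c. string, parsed on the fly).
#' @param t a [CodingTranscript-class].
#' @return a [ProteinConsequence-class].
#' @examples
#' tx <- dicer1Transcript()
#' proteinConsequence("c.5126A>G", tx)  # p.D1709G
#' proteinConsequence("c.1200G>A", tx)  # p.W400*
#' @export
proteinConsequence <- function(v, t) {
  if (is.character(v)) v <- parseCdna(v)
  stopifnot(is(v, "CodingVariant"), is(t, "CodingTranscript"))
  seq <- as.character(t@cds)
  len <- nchar(seq)
  aa <- .translateCds(seq)
  detail <- list()

  exonic <- v@startOffset == 0L && v@endOffset == 0L

  if (exonic && v@endBase > len)
    stop("variant end ", v@endBase, " beyond CDS length ", len)

  if (exonic && v@kind == "substitution") {
    pos <- v@startBase
    codon_idx <- (pos - 1L) %/% 3L + 1L
    ref_here <- substr(seq, pos, pos)
    if (ref_here != v@refAllele) {
      warning("stated reference base ", v@refAllele, " at c.", pos,
              " disagrees with transcript base ", ref_here)
      detail$refMismatch <- TRUE
    }
    codon <- substr(seq, 3L * codon_idx - 2L, 3L * codon_idx)
    mut_codon <- codon
    substr(mut_codon, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- v@altAllele
    alt_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
    ref_aa <- aa[codon_idx]
    detail$refAA <- ref_aa; detail$altAA <- alt_aa
    if (alt_aa == "*") {
      return(new("ProteinConsequence", kind = "nonsense",
                 codonIndex = codon_idx,
                 notation = sprintf("p.%s%d*", ref_aa, codon_idx),
                 truncating = TRUE, detail = detail))
    } else if (alt_aa == ref_aa) {
      return(new("ProteinConsequence", kind = "synonymous",
                 codonIndex = codon_idx,
                 notation = sprintf("p.%s%d=", ref_aa, codon_idx),
                 truncating = FALSE, detail = detail))
    } else {
      return(new("ProteinConsequence", kind = "missense",
                 codonIndex = codon_idx,
                 notation = sprintf("p.%s%d%s", ref_aa, codon_idx, alt_aa),
                 truncating = FALSE, detail = detail))
    }
  }

  if (exonic) {                               # exonic small indel
    return(.indelConsequence(v@kind, v@startBase, v@endBase,
                             v@refAllele, v@altAllele, seq, aa, detail))
  }

  # intron-involving variants ------------------------------------------------
  ex <- t@exonSpans
  ex_start <- IRanges::start(ex); ex_end <- IRanges::end(ex)

  if (v@kind == "deletion" && (v@startBase < v@endBase ||
                               (v@startOffset < 0L && v@endOffset > 0L))) {
    # a deletion whose intronic endpoints bracket coding sequence: classify
    # by the deleted coding length (whole-exon deletions land here)
    coding_start <- if (v@startOffset <= 0L) v@startBase else v@startBase + 1L
    coding_end <- if (v@endOffset >= 0L) v@endBase else v@endBase - 1L
    if (coding_end >= coding_start) {
      detail$deletedCodingLength <- coding_end - coding_start + 1L
      return(.indelConsequence("deletion", coding_start, coding_end,
                               "", "", seq, aa, detail))
    }
  }

  canonical <- abs(v@startOffset) %in% 1:2 || abs(v@endOffset) %in% 1:2
  if (canonical) {
    if (v@startOffset > 0L) {
      exon_i <- which(ex_end == v@startBase)      # donor: exon just ended
    } else if (v@startOffset < 0L) {
      exon_i <- which(ex_start == v@startBase)    # acceptor: exon starts here
    } else if (v@endOffset < 0L) {
      exon_i <- which(ex_start == v@endBase)
    } else exon_i <- which(ex_end == v@endBase)
    if (length(exon_i) == 1L) {
      skip_len <- ex_end[exon_i] - ex_start[exon_i] + 1L
      first_codon <- (ex_start[exon_i] - 1L) %/% 3L + 1L
      detail$skippedExon <- exon_i
      detail$skippedLength <- skip_len
      trunc <- skip_len %% 3L != 0L
      detail$outcome <- if (trunc) "exon_skip_frameshift" else "exon_skip_inframe"
      if (!trunc) detail$deletedAA <- skip_len %/% 3L
      return(new("ProteinConsequence", kind = "splice_effect",
                 codonIndex = first_codon,
                 notation = "p.?", truncating = trunc, detail = detail))
    }
    warning("canonical splice offset in '", v@raw,
            "' does not sit at an annotated exon boundary")
    detail$outcome <- "none/unknown"
    return(new("ProteinConsequence", kind = "splice_effect",
               codonIndex = NA_integer_, notation = "p.?",
               truncating = FALSE, detail = detail))
  }

  warning("variant '", v@raw, "' is intronic and not splice-adjacent; ",
          "protein consequence unknown")
  detail$outcome <- "none/unknown"
  new("ProteinConsequence", kind = "splice_effect",
      codonIndex = NA_integer_, notation = "p.?",
      truncating = FALSE, detail = detail)
}

# Apply an exonic indel to the CDS, re-translate, and classify. Frameshift
# iff net length change is not 0 mod 3.
.indelConsequence <- function(kind, start, end, ref, alt, seq, aa, detail) {
  len <- nchar(seq)
  mut <- switch(kind,
    deletion = {
      if (nzchar(ref) && substr(seq, start, end) != ref) {
        warning("stated deleted sequence ", ref,
                " disagrees with transcript at c.", start)
        detail$refMismatch <- TRUE
      }
      paste0(substr(seq, 1L, start - 1L), substr(seq, end + 1L, len))
    },
    duplication = paste0(substr(seq, 1L, end),
                         substr(seq, start, end),
                         substr(seq, end + 1L, len)),
    insertion = paste0(substr(seq, 1L, start),
                       alt,
                       substr(seq, start + 1L, len)),
    delins = paste0(substr(seq, 1L, start - 1L), alt,
                    substr(seq, end + 1L, len)),
    stop("unhandled indel kind ", kind))
  net <- nchar(mut) - len
  first_codon <- (start - 1L) %/% 3L + 1L

  if (net %% 3L == 0L) {
    detail$netLength <- net
    last_codon <- (end - 1L) %/% 3L + 1L
    notation <- if (kind == "deletion") {
      if (first_codon == last_codon)
        sprintf("p.%s%ddel", aa[first_codon], first_codon)
      else sprintf("p.%s%d_%s%ddel", aa[first_codon], first_codon,
                   aa[last_codon], last_codon)
    } else sprintf("p.(%d_%d)", first_codon, last_codon)
    return(new("ProteinConsequence", kind = "inframe_deletion",
               codonIndex = first_codon, notation = notation,
               truncating = FALSE, detail = detail))
  }

  mut_aa <- .translateCds(substr(mut, 1L, 3L * (nchar(mut) %/% 3L)))
  k <- min(length(aa), length(mut_aa))
  diff_i <- which(aa[seq_len(k)] != mut_aa[seq_len(k)])
  i <- if (length(diff_i)) diff_i[1L] else k + 1L
  if (i > length(mut_aa)) {
    # mutation removed the tail entirely; truncation at the end
    notation <- sprintf("p.%s%dfs*?", aa[min(i, length(aa))], i)
    return(new("ProteinConsequence", kind = "frameshift",
               codonIndex = as.integer(min(i, length(aa))),
               notation = notation, truncating = TRUE, detail = detail))
  }
  new_aa <- mut_aa[i]
  stops <- which(mut_aa[seq.int(i, length(mut_aa))] == "*")
  detail$newAA <- new_aa
  if (new_aa == "*") {
    notation <- sprintf("p.%s%d*", aa[i], i)
  } else if (length(stops)) {
    notation <- sprintf("p.%s%d%sfs*%d", aa[i], i, new_aa, stops[1L])
  } else {
    notation <- sprintf("p.%s%d%sfs*?", aa[i], i, new_aa)
  }
  new("ProteinConsequence", kind = "frameshift",
      codonIndex = as.integer(i), notation = notation,
      truncating = TRUE, detail = detail)
}

#' Assign a functional class to a protein consequence
#'
#' Deterministic mapping: truncating consequences (nonsense, frameshift,
#' frame-disrupting exon skip) are `lof_truncating`; missense at an
#' annotated hotspot codon is `hotspot_missense`; other missense is
#' `other_missense` (external pathogenicity verdicts such as SIFT/PROVEAN
#' may be attached as annotations but never change the class); in-frame
#' indels and in-frame exon skips are `inframe`; synonymous is
#' `synonymous`; splice effects of unknown outcome are `vus`.
#'
#' @param pc a [ProteinConsequence-class].
#' @param hotspots a hotspot data.frame (columns `codon`, `refAA`) or a
#'   [CodingTranscript-class] from which the hotspot set is taken.
#' @param domains unused placeholder for domain-aware extensions; the class
#'   never depends on domain location.
#' @return one of `"lof_truncating"`, `"hotspot_missense"`,
#'   `"other_missense"`, `"inframe"`, `"synonymous"`, `"vus"`.
#' @export
classifyFunctional <- function(pc, hotspots, domains = NULL) {
  stopifnot(is(pc, "ProteinConsequence"))
  if (is(hotspots, "CodingTranscript")) hotspots <- hotspots@hotspots
  if (pc@truncating) return("lof_truncating")
  switch(pc@kind,
    missense = if (nrow(hotspots) && pc@codonIndex %in% hotspots$codon)
                 "hotspot_missense" else "other_missense",
    synonymous = "synonymous",
    inframe_deletion = "inframe",
    splice_effect = if (identical(pc@detail$outcome, "exon_skip_inframe"))
                      "inframe" else "vus",
    "vus")
}

#' Does a truncating consequence interrupt the ORF before the end of the
#' RNase IIIb domain?
#'
#' Truncating mutations upstream of the end of the catalytic RNase IIIb
#' domain are predicted to abolish protein function even if the message
#' escapes nonsense-mediated decay.
#'
#' @param pc a truncating [ProteinConsequence-class]; a non-truncating
#'   consequence is a precondition error.
#' @param domains a named [IRanges::IRanges] of domain spans in codon
#'   coordinates containing `"RNase IIIb"`, or a [CodingTranscript-class].
#' @return logical.
#' @export
truncatesBeforeRNaseIIIb <- function(pc, domains) {
  stopifnot(is(pc, "ProteinConsequence"))
  if (!pc@truncating)
    stop("consequence ", pc@notation, " is not truncating")
  if (is(domains, "CodingTranscript")) domains <- domains@domains
  idx <- match("RNase IIIb", names(domains))
  if (is.na(idx))
    stop("domain annotation lacks an 'RNase IIIb' span")
  pc@codonIndex <= IRanges::end(domains)[idx]
}
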