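# cDNA-level variant notation: a purpose-built parser for the c.-string
# subset used in DICER1 mutation reports (substitution, deletion,
# duplication, insertion, delins; exonic positions and intron-offset
# positions such as 5096-498 or 1752+1). Genomic (g.) and non-coding (n.)
# notation, and multi-transcript mapping, are out of scope.

.posRe <- "(\\d+)([+-]\\d+)?"

.parsePos <- function(txt, raw) {
  m <- regmatches(txt, regexec(paste0("^", .posRe, "$"), txt))[[1L]]
  if (length(m) == 0L)
    stop("malformed coordinate '", txt, "' in '", raw, "'")
  base <- suppressWarnings(as.integer(m[2L]))
  if (is.na(base) || base < 1L)
    stop("CDS coordinate must be >= 1 in '", raw, "'")
  offset <- if (m[3L] == "") 0L else as.integer(m[3L])
  list(base = base, offset = offset)
}

#' Parse a cDNA-level (c.) variant string
#'
#' Parses the c.-notation subset used in coding-variant reports into a
#' structured [CodingVariant-class]. Supported kinds: substitution
#' (`c.5126A>G`), deletion (`c.1711delT`, `c.5096-498_5364+356del`),
#' duplication, insertion (`c.10_11insACT`) and deletion-insertion
#' (`c.10_12delinsG`). Positions are 1-based CDS coordinates with optional
#' signed intronic offsets. Unparseable input is rejected with an error that
#' names the offending part; it is never silently coerced.
#'
#' @param raw a variant string beginning `"c."`.
#' @return a validated [CodingVariant-class].
#' @examples
#' parseCdna("c.5126A>G")
#' parseCdna("c.5096-498_5364+356del")
#' @export
parseCdna <- function(raw) {
  if (!.isSingleString(raw) || !startsWith(raw, "c."))
    stop("variant string must begin with 'c.': got '", raw, "'")
  body <- substring(raw, 3L)

  mk <- function(kind, start, end, ref = "", alt = "") {
    new("CodingVariant", raw = raw, kind = kind,
        startBase = start$base, startOffset = start$offset,
        endBase = end$base, endOffset = end$offset,
        refAllele = ref, altAllele = alt)
  }

  # substitution: <pos><ref>><alt>
  m <- regmatches(body, regexec(paste0("^", .posRe, "([ACGT])>([ACGT])$"), body))[[1L]]
  if (length(m)) {
    p <- .parsePos(paste0(m[2L], m[3L]), raw)
    if (m[4L] == m[5L])
      stop("reference and alternate base are identical in '", raw, "'")
    return(mk("substitution", p, p, ref = m[4L], alt = m[5L]))
  }

  # del / dup with optional range and optional stated sequence
  m <- regmatches(body, regexec(
    paste0("^", .posRe, "(?:_", .posRe, ")?(del|dup)([ACGT]*)$"), body))[[1L]]
  if (length(m)) {
    p1 <- .parsePos(paste0(m[2L], m[3L]), raw)
    p2 <- if (m[4L] == "") p1 else .parsePos(paste0(m[4L], m[5L]), raw)
    kind <- if (m[6L] == "del") "deletion" else "duplication"
    seqs <- m[7L]
    if (nzchar(seqs) && p1$offset == 0L && p2$offset == 0L &&
        nchar(seqs) != p2$base - p1$base + 1L)
      stop("stated ", m[6L], " sequence length (", nchar(seqs),
           ") disagrees with coordinates in '", raw, "'")
    return(mk(kind, p1, p2, ref = if (kind == "deletion") seqs else "",
              alt = if (kind == "duplication") seqs else ""))
  }

  # insertion: <pos>_<pos>ins<seq>
  m <- regmatches(body, regexec(
    paste0("^", .posRe, "_", .posRe, "ins([ACGT]+)$"), body))[[1L]]
  if (length(m)) {
    p1 <- .parsePos(paste0(m[2L], m[3L]), raw)
    p2 <- .parsePos(paste0(m[4L], m[5L]), raw)
    if (!(p1$offset == 0L && p2$offset == 0L && p2$base == p1$base + 1L) &&
        !(p1$base == p2$base))
      if (p2$base != p1$base + 1L)
        stop("insertion coordinates must flank adjacent bases in '", raw, "'")
    return(mk("insertion", p1, p2, alt = m[6L]))
  }

  # delins: <pos>[_<pos>]delins<seq>
  m <- regmatches(body, regexec(
    paste0("^", .posRe, "(?:_", .posRe, ")?delins([ACGT]+)$"), body))[[1L]]
  if (length(m)) {
    p1 <- .parsePos(paste0(m[2L], m[3L]), raw)
    p2 <- if (m[4L] == "") p1 else .parsePos(paste0(m[4L], m[5L]), raw)
    return(mk("delins", p1, p2, alt = m[6L]))
  }

  stop("unsupported or malformed variant notation: '", raw, "'")
}

#' Format a CodingVariant back to its canonical c. string
#'
#' Inverse of [parseCdna()]: `parseCdna(formatCdna(v))` reproduces `v` for
#' every supported variant.
#'
#' @param v a [CodingVariant-class].
#' @return a c.-notation string.
#' @export
formatCdna <- function(v) {
  stopifnot(is(v, "CodingVariant"))
  fmt_pos <- function(base, offset) {
    if (offset == 0L) as.character(base)
    else paste0(base, ifelse(offset > 0L, "+", ""), offset)
  }
  p1 <- fmt_pos(v@startBase, v@startOffset)
  p2 <- fmt_pos(v@endBase, v@endOffset)
  single <- v@startBase == v@endBase && v@startOffset == v@endOffset
  body <- switch(v@kind,
    substitution = paste0(p1, v@refAllele, ">", v@altAllele),
    deletion     = paste0(if (single) p1 else paste0(p1, "_", p2), "del",
                          v@refAllele),
    duplication  = paste0(if (single) p1 else paste0(p1, "_", p2), "dup",
                          v@altAllele),
    insertion    = paste0(p1, "_", p2, "ins", v@altAllele),
    delins       = paste0(if (single) p1 else paste0(p1, "_", p2), "delins",
                          v@altAllele))
  paste0("c.", body)
}
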