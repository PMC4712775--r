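# Internal helpers shared across modules.

# Translate a CDS string to a character vector of one-letter amino acids
# under the standard genetic code (codon table 1; the package supports no
# other table). Length must be a multiple of 3.
.translateCds <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  unname(Biostrings::GENETIC_CODE[codons])
}

.splitCodons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq.int(1L, n, by = 3L), seq.int(3L, n, by = 3L))
}

.stopCodons <- c("TAA", "TAG", "TGA")
.bases <- c("A", "C", "G", "T")

.isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
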