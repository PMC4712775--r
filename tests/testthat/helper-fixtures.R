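# Small transcript builders used across test files.

# Build a transcript from a codon vector; single exon, optional hotspots
# given as list(list(codon, aa), ...).
tinyTx <- function(codons, hotspots = NULL, n_introns = 0L, id = "tiny",
                   domains = NULL) {
  seq <- paste(codons, collapse = "")
  ann <- list(id = id,
              exons = list(c(1L, nchar(seq))),
              n_introns = n_introns,
              domains = domains,
              hotspots = hotspots)
  loadTranscript(Biostrings::DNAStringSet(stats::setNames(seq, id)), ann)
}

# One synthetic specimen observation row (all columns the validator wants).
obsRow <- function(patient_id, specimen_id, tissue, role, organ,
                   chgvs, var_reads, total_reads, purity = NA,
                   assay = "ngs", allele_loss = 0L, vaf_pct = NA,
                   detected = NA, phgvs = NA) {
  data.frame(patient_id = patient_id, specimen_id = specimen_id,
             tissue = tissue, role = role, organ = organ, purity = purity,
             assay = assay, chgvs = chgvs, phgvs = phgvs,
             var_reads = var_reads, total_reads = total_reads,
             vaf_pct = vaf_pct, detected = detected,
             allele_loss = allele_loss, cnv = NA, source = "test",
             stringsAsFactors = FALSE)
}

patientRec <- function(specimens, parents = list()) {
  new("PatientRecord", patientId = as.character(specimens$patient_id[1L]),
      specimens = specimens, parents = parents, lesions = data.frame(),
      ageFirstDxMonths = NA_real_)
}
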