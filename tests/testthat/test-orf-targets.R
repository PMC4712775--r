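test_that("transcript loading enforces the ORF invariants", {
  tx <- tinyTx(c("ATG", "GGG"))
  expect_equal(nCodons(tx), 2L)

  expect_error(tinyTx(c("ATG", "TAG", "GGG")), "codon 2")
  expect_error(
    loadTranscript(Biostrings::DNAStringSet(c(x = "ATGGG")),
                   list(exons = list(c(1, 5)), n_introns = 0)),
    "divisible by 3")
  expect_error(
    loadTranscript(Biostrings::DNAStringSet(c(x = "ATGNNN")),
                   list(exons = list(c(1, 6)), n_introns = 0)),
    "outside")
  # hotspot reference amino acid must match the translation
  expect_error(tinyTx(c("ATG", "GAT"), hotspots = list(list(2L, "E"))),
               "hotspot")
  # a terminal stop codon is stripped, not counted
  tx2 <- loadTranscript(Biostrings::DNAStringSet(c(x = "ATGGGGTGA")),
                        list(exons = list(c(1, 6)), n_introns = 0))
  expect_equal(nCodons(tx2), 2L)
  expect_true(tx2@hadTerminalStop)
})

test_that("per-codon SNV consequences match hand-enumerated codons", {
  # GAG: of the 9 substitutions, 7 missense, 1 nonsense (TAG), 1 synonymous
  tx <- tinyTx(c("ATG", "GAG"))
  snv <- enumerateSNVs(tx)
  g <- snv[snv$codonIndex == 2L, ]
  expect_equal(sum(g$klass == "missense"), 7L)
  expect_equal(sum(g$klass == "nonsense"), 1L)
  expect_equal(sum(g$klass == "synonymous"), 1L)
  expect_equal(g$altCodon[g$klass == "nonsense"], "TAG")

  # TGG reaches two stops (TAG, TGA)
  tx <- tinyTx(c("ATG", "TGG"))
  snv <- enumerateSNVs(tx)
  expect_equal(sum(snv$codonIndex == 2L & snv$klass == "nonsense"), 2L)
  expect_setequal(snv$altCodon[snv$codonIndex == 2L & snv$klass == "nonsense"],
                  c("TAG", "TGA"))

  # neither ATG nor GGG reaches a stop in one change
  tx <- tinyTx(c("ATG", "GGG", "GGG"))
  expect_equal(countNonsenseSNVs(tx), 0L)
  expect_equal(countStopConvertibleCodons(tx), 0L)

  # GAT hotspot: only T>C at position 3 is synonymous, no stop reachable
  tx <- tinyTx(c("ATG", "GAT"), hotspots = list(list(2L, "D")))
  expect_equal(countHotspotMissenseSNVs(tx), 8L)
})

test_that("enumeration is deterministic, complete and ordered", {
  tx <- tinyTx(c("ATG", "GAT", "TGG", "CGA"))
  snv <- enumerateSNVs(tx)
  expect_equal(nrow(snv), 9L * nCodons(tx))
  expect_true(!is.unsorted(snv$cdsPos))
  by_pos <- split(snv$altBase, snv$cdsPos)
  expect_true(all(vapply(by_pos, function(a) !is.unsorted(a), TRUE)))
  expect_identical(enumerateSNVs(tx), snv)
})

test_that("class counts partition the SNV space on random ORFs", {
  for (seed in 1:10) {
    orf <- makeRandomORF(sample(5:80, 1L), seed = seed)
    snv <- enumerateSNVs(orf$transcript)
    expect_equal(sum(table(snv$klass)), 9L * nCodons(orf$transcript))
  }
})

test_that("enumeration agrees with the brute-force retranslation oracle", {
  set.seed(42)
  for (i in 1:25) {
    orf <- makeRandomORF(sample(10:120, 1L), seed = 1000L + i)
    rep <- targetSizeReport(orf$transcript)
    truth <- orf$truth
    expect_equal(rep@totalSNVs, truth$totalSNVs)
    expect_equal(rep@nonsenseSNVs, truth$nonsenseSNVs)
    expect_equal(rep@nonNonsenseSNVs, truth$nonNonsenseSNVs)
    expect_equal(rep@stopConvertibleCodons, truth$stopConvertibleCodons)
    expect_equal(rep@hotspotMissenseSNVs, truth$hotspotMissenseSNVs)
    expect_equal(rep@frameshiftPositions, truth$frameshiftPositions)
    expect_equal(rep@spliceSiteBases, truth$spliceSiteBases)
  }
})

test_that("appending a codon never decreases target-space counts", {
  base <- c("ATG", "GAT", "TGG")
  tx1 <- tinyTx(base)
  for (extra in c("GGG", "TAT", "CGA")) {
    tx2 <- tinyTx(c(base, extra))
    expect_gte(targetSizeReport(tx2)@totalSNVs,
               targetSizeReport(tx1)@totalSNVs)
    expect_gte(countFrameshiftPositions(tx2), countFrameshiftPositions(tx1))
    expect_gte(countNonsenseSNVs(tx2), countNonsenseSNVs(tx1))
  }
})

test_that("enumeration is anchored to the coding strand", {
  # double reverse-complement is the identity on the coding strand, so all
  # counts must be unchanged
  tx <- tinyTx(c("ATG", "GAT", "TGG", "TAT", "CAA"))
  seq2 <- as.character(Biostrings::reverseComplement(
    Biostrings::reverseComplement(cds(tx))))
  tx2 <- loadTranscript(Biostrings::DNAStringSet(c(tiny = seq2)),
                        list(exons = list(c(1L, nchar(seq2))), n_introns = 0))
  expect_equal(countNonsenseSNVs(tx2), countNonsenseSNVs(tx))
  expect_equal(countStopConvertibleCodons(tx2), countStopConvertibleCodons(tx))
})

test_that("splice-site base counting follows the canonical 2+2 model", {
  expect_equal(countSpliceSiteBases(26), 104L)
  expect_equal(countSpliceSiteBases(0), 0L)
  expect_equal(countSpliceSiteBases(10), 40L)
  expect_error(countSpliceSiteBases(-1), "non-negative")
})

test_that("frameshift positions equal three per codon", {
  expect_equal(countFrameshiftPositions(tinyTx(c("ATG", "GGG"))), 6L)
  orf <- makeRandomORF(100, seed = 9)
  expect_equal(countFrameshiftPositions(orf$transcript), 300L)
})

test_that("an empty hotspot set yields zero with a warning", {
  tx <- tinyTx(c("ATG", "GAT"))
  expect_warning(n <- countHotspotMissenseSNVs(tx), "empty hotspot")
  expect_equal(n, 0L)
})

test_that("the target-size report is internally consistent", {
  tx <- dicer1Transcript()
  rep <- targetSizeReport(tx)
  expect_equal(rep@nonsenseSNVs + rep@nonNonsenseSNVs, rep@totalSNVs)
  expect_equal(rep@totalSNVs, 9L * nCodons(tx))
  expect_equal(rep@hotspotCodonFraction, nrow(hotspots(tx)) / nCodons(tx))
  expect_equal(rep@lofToHotspotRatio,
               (rep@nonsenseSNVs + rep@frameshiftPositions +
                rep@spliceSiteBases) / rep@hotspotMissenseSNVs)
})
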