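test_that("c. substitution and range notation parse into structured form", {
  v <- parseCdna("c.5126A>G")
  expect_equal(v@kind, "substitution")
  expect_equal(v@startBase, 5126L)
  expect_equal(v@startOffset, 0L)
  expect_equal(v@refAllele, "A")
  expect_equal(v@altAllele, "G")

  v <- parseCdna("c.5096-498_5364+356del")
  expect_equal(v@kind, "deletion")
  expect_equal(c(v@startBase, v@startOffset), c(5096L, -498L))
  expect_equal(c(v@endBase, v@endOffset), c(5364L, 356L))

  v <- parseCdna("c.1752+1delG")
  expect_equal(v@kind, "deletion")
  expect_equal(c(v@startBase, v@startOffset), c(1752L, 1L))
  expect_equal(v@refAllele, "G")

  expect_error(parseCdna("c.0A>G"), ">= 1")
  expect_error(parseCdna("c.100A>A"), "identical")
  expect_error(parseCdna("g.100A>G"), "c\\.")
  expect_error(parseCdna("c.12inv"), "unsupported|malformed")
  expect_error(parseCdna("c.10_12delAC"), "disagrees")
})

test_that("parse -> format -> parse is the identity on the published variants", {
  published <- c("c.5126A>G", "c.5125G>A", "c.1129G>A", "c.1200G>A",
                 "c.96G>A", "c.5428G>T", "c.1711delT", "c.1775delA",
                 "c.5437G>C", "c.4626delC", "c.5425G>A", "c.1966C>T",
                 "c.5113G>A", "c.5138A>T", "c.1304C>T", "c.5125G>T",
                 "c.5125G>C", "c.5096-498_5364+356del", "c.1752+1delG")
  extra <- c("c.10_12dup", "c.10_11insACT", "c.10_12delinsG", "c.33+2T>C",
             "c.34-1G>T")
  for (s in c(published, extra)) {
    v <- parseCdna(s)
    expect_identical(formatCdna(v), s)
    expect_identical(formatCdna(parseCdna(formatCdna(v))), s)
  }
})

test_that("substitution consequences match the published c./p. pairs", {
  tx <- dicer1Transcript()
  cases <- list(
    c("c.1200G>A", "p.W400*",   "nonsense"),
    c("c.5126A>G", "p.D1709G",  "missense"),
    c("c.5125G>A", "p.D1709N",  "missense"),
    c("c.5125G>T", "p.D1709Y",  "missense"),
    c("c.5125G>C", "p.D1709H",  "missense"),
    c("c.96G>A",   "p.W32*",    "nonsense"),
    c("c.1129G>A", "p.V377I",   "missense"),
    c("c.5113G>A", "p.E1705K",  "missense"),
    c("c.5425G>A", "p.G1809R",  "missense"),
    c("c.5428G>T", "p.D1810Y",  "missense"),
    c("c.5437G>C", "p.E1813Q",  "missense"),
    c("c.1966C>T", "p.R656*",   "nonsense"),
    c("c.5138A>T", "p.D1713V",  "missense"))
  for (cs in cases) {
    pc <- proteinConsequence(cs[1L], tx)
    expect_identical(pc@notation, cs[2L])
    expect_identical(pc@kind, cs[3L])
  }
})

test_that("exonic indels truncate iff the net length change breaks frame", {
  orf <- makeRandomORF(60, seed = 7)
  tx <- orf$transcript
  chars <- strsplit(as.character(cds(tx)), "")[[1L]]
  set.seed(99)
  for (i in 1:40) {
    if (runif(1) < 0.5) {
      len <- sample(1:6, 1L)
      start <- sample.int(length(chars) - len - 3L, 1L) + 1L
      v <- sprintf("c.%d_%ddel", start, start + len - 1L)
      net <- -len
    } else {
      len <- sample(1:6, 1L)
      start <- sample.int(length(chars) - 4L, 1L)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      v <- sprintf("c.%d_%dins%s", start, start + 1L, ins)
      net <- len
    }
    pc <- proteinConsequence(v, tx)
    expect_identical(pc@truncating, net %% 3L != 0L,
                     label = paste("truncating flag for", v))
    expect_identical(pc@kind,
                     if (net %% 3L != 0L) "frameshift" else "inframe_deletion")
  }
})

test_that("substitution consequences agree with whole-ORF retranslation", {
  set.seed(11)
  for (i in 1:8) {
    orf <- makeRandomORF(sample(10:60, 1L), seed = 300L + i)
    tx <- orf$transcript
    seq <- as.character(cds(tx))
    prot <- strsplit(as.character(Biostrings::translate(cds(tx))), "")[[1L]]
    for (j in 1:15) {
      pos <- sample.int(nchar(seq), 1L)
      ref <- substr(seq, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      pc <- proteinConsequence(sprintf("c.%d%s>%s", pos, ref, alt), tx)
      mut <- seq
      substr(mut, pos, pos) <- alt
      mprot <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(mut), no.init.codon = TRUE)), "")[[1L]]
      diffs <- which(mprot != prot)
      if (length(diffs) == 0L) {
        expect_identical(pc@kind, "synonymous")
      } else if (mprot[diffs[1L]] == "*") {
        expect_identical(pc@kind, "nonsense")
        expect_equal(pc@codonIndex, diffs[1L])
      } else {
        expect_identical(pc@kind, "missense")
        expect_equal(pc@codonIndex, diffs[1L])
        expect_identical(pc@detail$altAA, mprot[diffs[1L]])
      }
    }
  }
})

test_that("canonical splice variants are classified by skipped-exon frame", {
  tx <- dicer1Transcript()
  # intron-10 donor: exon 10 is 243 nt, skip is in-frame (81 aa) and
  # therefore not truncating
  pc <- proteinConsequence("c.1752+1delG", tx)
  expect_identical(pc@kind, "splice_effect")
  expect_false(pc@truncating)
  expect_equal(pc@detail$skippedExon, 10L)
  expect_equal(pc@detail$deletedAA, 81L)
  expect_identical(classifyFunctional(pc, tx), "inframe")

  # exon 2 is 130 nt: skipping it breaks frame
  e2_end <- IRanges::end(exonSpans(tx))[2L]
  pc2 <- proteinConsequence(sprintf("c.%d+1G>A", e2_end), tx)
  expect_true(pc2@truncating)
  expect_identical(classifyFunctional(pc2, tx), "lof_truncating")

  # deep intronic: unknown outcome, warned
  expect_warning(pc3 <- proteinConsequence("c.1752+40G>A", tx),
                 "not splice-adjacent")
  expect_identical(pc3@kind, "splice_effect")
  expect_identical(classifyFunctional(pc3, tx), "vus")
})

test_that("a whole-exon deletion is classified by deleted coding length", {
  tx <- dicer1Transcript()
  # exon 24 spans c.5096..5364: 269 deleted coding bases -> frameshift
  pc <- proteinConsequence("c.5096-498_5364+356del", tx)
  expect_identical(pc@kind, "frameshift")
  expect_true(pc@truncating)
  expect_equal(pc@detail$deletedCodingLength, 269L)
  expect_identical(classifyFunctional(pc, tx), "lof_truncating")
})

test_that("functional classification follows the hotspot and truncation rules", {
  tx <- dicer1Transcript()
  expect_identical(
    classifyFunctional(proteinConsequence("c.5125G>A", tx), tx),
    "hotspot_missense")
  expect_identical(
    classifyFunctional(proteinConsequence("c.1711delT", tx), tx),
    "lof_truncating")
  # D1822V and G1708E lie in the RNase IIIb domain but are not hotspot codons
  expect_identical(
    classifyFunctional(proteinConsequence("c.5465A>T", tx), tx),  # p.D1822V
    "other_missense")
  expect_identical(
    classifyFunctional(proteinConsequence("c.5123G>A", tx), tx),  # p.G1708E
    "other_missense")
  # synonymous change
  syn <- proteinConsequence("c.5127T>C", tx)   # GAT -> GAC, still D1709
  expect_identical(syn@kind, "synonymous")
  expect_identical(classifyFunctional(syn, tx), "synonymous")
})

test_that("truncation before the end of RNase IIIb is assessed from domains", {
  tx <- dicer1Transcript()
  pc <- proteinConsequence("c.1200G>A", tx)   # p.W400*
  expect_true(truncatesBeforeRNaseIIIb(pc, tx))
  # a stop at the final codon falls after the domain
  late <- new("ProteinConsequence", kind = "nonsense",
              codonIndex = nCodons(tx), notation = "p.X1922*",
              truncating = TRUE, detail = list())
  expect_false(truncatesBeforeRNaseIIIb(late, tx))
  expect_error(truncatesBeforeRNaseIIIb(proteinConsequence("c.5126A>G", tx), tx),
               "not truncating")
  expect_error(truncatesBeforeRNaseIIIb(pc, IRanges::IRanges()), "RNase IIIb")
})

test_that("a stated reference allele that contradicts the CDS is warned", {
  tx <- dicer1Transcript()
  ref <- substr(as.character(cds(tx)), 100, 100)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  alt <- setdiff(c("A", "C", "G", "T"), c(ref, wrong))[1L]
  expect_warning(proteinConsequence(sprintf("c.100%s>%s", wrong, alt), tx),
                 "disagrees")
})
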