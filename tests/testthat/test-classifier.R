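tx <- dicer1Transcript()

test_that("each of the seven mosaic hotspot study patients classifies mosaic_hotspot", {
  recs <- hotspotEvidenceFixture()
  expect_length(recs, 7L)
  for (r in recs) {
    rep <- suppressWarnings(classifyPatient(r, tx))
    expect_identical(category(rep), "mosaic_hotspot",
                     label = paste("category of patient", r@patientId))
    expect_gte(nrow(evidence(rep)), 1L)
  }
})

test_that("a heterozygous-band LOF variant in blood is germline", {
  sp <- obsRow("g1", "g1-b", "Blood", "blood", "blood", "c.1200G>A",
               1440, 3000)  # VAF 48%
  rep <- classifyPatient(patientRec(sp), tx)
  expect_identical(category(rep), "germline")
})

test_that("biallelic hits confined to one tumor are tumor-specific", {
  sp <- rbind(
    obsRow("t1", "t1-b", "Blood", "blood", "blood", "c.5126A>G", 1, 3000),
    obsRow("t1", "t1-t", "Lung, PPB", "tumor", "lung", "c.5126A>G", 800, 2000,
           purity = 0.8),
    obsRow("t1", "t1-t", "Lung, PPB", "tumor", "lung", "c.1200G>A", 750, 2000,
           purity = 0.8))
  rep <- classifyPatient(patientRec(sp), tx)
  expect_identical(category(rep), "tumor_specific")

  # the LOF arm can also be an allele-loss flag
  sp2 <- rbind(
    obsRow("t2", "t2-b", "Blood", "blood", "blood", "c.5126A>G", 0, 3000),
    obsRow("t2", "t2-t", "Lung, PPB", "tumor", "lung", "c.5126A>G", 1500, 2000,
           purity = 0.9, allele_loss = 1L))
  expect_identical(category(classifyPatient(patientRec(sp2), tx)),
                   "tumor_specific")
})

test_that("a shared hotspot across tumors of different organs is mosaic even with negative blood", {
  sp <- rbind(
    obsRow("m1", "m1-b", "Blood", "blood", "blood", "c.5437G>C", 1, 2450),
    obsRow("m1", "m1-t1", "Thyroid Ca", "tumor", "thyroid", "c.5437G>C",
           289, 434, purity = 0.6, allele_loss = 1L),
    obsRow("m1", "m1-t2", "SLCT", "tumor", "ovary_right", "c.5437G>C",
           750, 976, purity = 0.75, allele_loss = 1L))
  rep <- classifyPatient(patientRec(sp), tx)
  expect_identical(category(rep), "mosaic_hotspot")

  # bilateral ovaries alone are one organ: the rule must not fire
  sp2 <- rbind(
    obsRow("m2", "m2-b", "Blood", "blood", "blood", "c.5437G>C", 0, 2450),
    obsRow("m2", "m2-t1", "SLCT", "tumor", "ovary_left", "c.5437G>C",
           600, 1900, purity = 0.4),
    obsRow("m2", "m2-t2", "SLCT", "tumor", "ovary_right", "c.5437G>C",
           700, 1900, purity = 0.4))
  expect_identical(category(classifyPatient(patientRec(sp2), tx)),
                   "unresolved")
})

test_that("a sub-heterozygous truncating variant in a normal tissue is mosaic LOF", {
  sp <- rbind(
    obsRow("m3", "m3-b", "Blood", "blood", "blood", "c.1711delT", 90, 3000),
    obsRow("m3", "m3-t", "Lung, PPB", "tumor", "lung", "c.1711delT", 700, 2000,
           purity = 0.7))
  rep <- suppressWarnings(classifyPatient(patientRec(sp), tx))
  expect_identical(category(rep), "mosaic_lof")
})

test_that("a hotspot at heterozygous frequency in blood is germline with a caution", {
  sp <- obsRow("h1", "h1-b", "Blood", "blood", "blood", "c.5126A>G",
               1500, 3000)
  rep <- classifyPatient(patientRec(sp), tx)
  expect_identical(category(rep), "germline")
  expect_true(any(grepl("hotspot", rep@warnings)))
})

test_that("blood takes precedence when blood and normal tissue disagree", {
  # normal kidney in the heterozygous band but blood clearly sub-het:
  # not called germline
  sp <- rbind(
    obsRow("k1", "k1-b", "Blood", "blood", "blood", "c.5125G>T", 630, 3000),
    obsRow("k1", "k1-n", "Normal kidney", "normal_tissue", "kidney",
           "c.5125G>T", 1050, 3000))
  rep <- classifyPatient(patientRec(sp), tx)
  expect_identical(category(rep), "mosaic_hotspot")
  expect_true(any(grepl("disagree", rep@warnings)))
})

test_that("classification is invariant to specimen order", {
  recs <- hotspotEvidenceFixture()
  sp <- recs[["104"]]@specimens
  ref_cat <- category(suppressWarnings(classifyPatient(patientRec(sp), tx)))
  set.seed(21)
  for (i in 1:5) {
    perm <- sp[sample.int(nrow(sp)), , drop = FALSE]
    expect_identical(
      category(suppressWarnings(classifyPatient(patientRec(perm), tx))),
      ref_cat)
  }
})

test_that("every record receives exactly one category", {
  recs <- c(hotspotEvidenceFixture(includeLiterature = TRUE),
            list(patientRec(obsRow("x", "x-b", "Blood", "blood", "blood",
                                   NA, 0, 3000))))
  for (r in recs) {
    rep <- suppressWarnings(classifyPatient(r, tx))
    expect_true(category(rep) %in% mutationCategories())
  }
})

test_that("calls that flip with the sub-heterozygous bound are flagged", {
  # VAF ~33%: sub-het at the 35% default, heterozygous if the bound drops
  sp <- obsRow("nb1", "nb1-b", "Blood", "blood", "blood", "c.1200G>A",
               990, 3000)
  rep <- classifyPatient(patientRec(sp), tx)
  expect_identical(category(rep), "mosaic_lof")
  expect_true(rep@nearBoundary)
  # a mid-band germline call is not boundary-sensitive
  sp2 <- obsRow("nb2", "nb2-b", "Blood", "blood", "blood", "c.1200G>A",
                1500, 3000)
  expect_false(classifyPatient(patientRec(sp2), tx)@nearBoundary)
})

test_that("trio evidence resolves inherited, de novo and parental mosaicism", {
  expect_identical(inheritanceStatus(
    "c.1200G>A",
    list(mother = data.frame(chgvs = "c.1200G>A", var_reads = 1500,
                             total_reads = 3000),
         father = data.frame(chgvs = "c.1200G>A", var_reads = 0,
                             total_reads = 3000))),
    "inherited")
  expect_identical(inheritanceStatus(
    "c.1200G>A",
    list(mother = data.frame(chgvs = "c.1200G>A", var_reads = 0,
                             total_reads = 3000),
         father = data.frame(chgvs = "c.1200G>A", var_reads = 0,
                             total_reads = 3000))),
    "de_novo")
  # reads slightly above the error rate in a parent: marginal mosaicism
  expect_identical(inheritanceStatus(
    "c.1200G>A",
    list(mother = data.frame(chgvs = "c.1200G>A", var_reads = 9,
                             total_reads = 3000),
         father = data.frame(chgvs = "c.1200G>A", var_reads = 0,
                             total_reads = 3000))),
    "possible_parental_mosaicism")
  expect_identical(inheritanceStatus("c.1200G>A", list()), "indeterminate")
})

test_that("cohort classification tabulates all categories including zeros", {
  empty <- classifyCohort(list(), tx)
  expect_equal(sum(empty$counts), 0L)
  expect_setequal(names(empty$counts), mutationCategories())

  cc <- suppressWarnings(classifyCohort(hotspotEvidenceFixture(), tx))
  expect_equal(unname(cc$counts["mosaic_hotspot"]), 7L)
  expect_equal(sum(cc$counts), 7L)
})

test_that("a supplied p. string that disagrees with the computed one is logged", {
  sp <- obsRow("w1", "w1-b", "Blood", "blood", "blood", "c.1200G>A",
               1500, 3000, phgvs = "p.W400L")
  rep <- classifyPatient(patientRec(sp), tx)
  expect_true(any(grepl("differs from computed", rep@warnings)))
  expect_identical(category(rep), "germline")
})
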