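test_that("disease foci follow the lung-lobe and kidney-side merging rules", {
  lesions <- data.frame(
    organ = c("lung", "lung", "kidney"),
    lesion_type = c("lung cyst", "lung cyst", "kidney cyst"),
    laterality = c("n/a", "n/a", "bilateral"),
    lung_lobe = c("RUL", "LLL", NA),
    anatomically_separate = FALSE)
  expect_equal(countDiseaseFoci(lesions), 4L)

  single <- data.frame(organ = "lung", lesion_type = "PPB",
                       laterality = "n/a", lung_lobe = NA,
                       anatomically_separate = FALSE)
  expect_equal(countDiseaseFoci(single), 1L)

  same_lobe <- data.frame(organ = "lung",
                          lesion_type = c("lung cyst", "lung cyst"),
                          laterality = "n/a", lung_lobe = "RUL",
                          anatomically_separate = FALSE)
  expect_equal(countDiseaseFoci(same_lobe), 1L)
  # anatomical separation within a lobe splits the focus
  same_lobe$anatomically_separate <- c(TRUE, FALSE)
  expect_equal(countDiseaseFoci(same_lobe), 2L)

  contralateral <- data.frame(organ = "kidney",
                              lesion_type = c("kidney cyst", "kidney cyst"),
                              laterality = c("left", "right"),
                              lung_lobe = NA, anatomically_separate = FALSE)
  expect_equal(countDiseaseFoci(contralateral), 2L)
  # same-side renal cysts merge
  contralateral$laterality <- "left"
  expect_equal(countDiseaseFoci(contralateral), 1L)

  expect_error(countDiseaseFoci(data.frame(
    organ = "liver", lesion_type = "hepatic cyst", laterality = "n/a",
    lung_lobe = NA, anatomically_separate = FALSE)), "vocabulary")
})

test_that("focus counting is permutation-invariant and additive over organs", {
  set.seed(8)
  lesions <- data.frame(
    organ = c("lung", "lung", "lung", "kidney", "ovary", "thyroid"),
    lesion_type = c("lung cyst", "lung cyst", "PPB", "cystic nephroma",
                    "SLCT", "thyroid nodule"),
    laterality = c("n/a", "n/a", "n/a", "n/a", "left", "n/a"),
    lung_lobe = c("RUL", "RML", NA, NA, NA, NA),
    anatomically_separate = FALSE)
  ref <- countDiseaseFoci(lesions)
  for (i in 1:5)
    expect_equal(countDiseaseFoci(lesions[sample.int(nrow(lesions)), ]), ref)
  parts <- split(lesions, lesions$organ)
  expect_equal(sum(vapply(parts, countDiseaseFoci, 1L)), ref)
})

test_that("summary statistics use the sample definition", {
  s <- summarizeValues(c(1, 1, 2, 3))
  expect_equal(s$median, 1.5)
  expect_equal(s$range, c(1, 3))
  expect_equal(s$mean, 1.75)
  expect_equal(s$sd, sd(c(1, 1, 2, 3)))
  expect_false(s$sdUndefined)

  one <- summarizeValues(5)
  expect_equal(one$sd, 0)
  expect_true(one$sdUndefined)
  expect_error(summarizeValues(numeric(0)), "no values")
})

test_that("the Sidak adjustment is closed-form and monotone", {
  expect_equal(sidakAdjust(0.01, 3), 1 - 0.99^3)
  expect_equal(round(sidakAdjust(0.01, 3), 4), 0.0297)
  p <- seq(0.001, 0.9, length.out = 50)
  for (m in 1:5) expect_true(all(sidakAdjust(p, m) >= p))
  expect_equal(sidakAdjust(p, 1), p)
})

test_that("identical groups give a null Kruskal-Wallis result", {
  values <- rep(c(1, 2, 3), 4)
  categories <- rep(c("germline", "mosaic_lof", "mosaic_hotspot",
                      "tumor_specific"), each = 3)
  gc <- groupCompare(values, categories)
  expect_equal(gc$H, 0)
  expect_equal(gc$p, 1)
  expect_null(gc$pairwise)
})

test_that("post-hoc tests fire below alpha and carry the Sidak correction", {
  set.seed(31)
  values <- c(rnorm(90, 1.8, 1), rnorm(5, 1.6, 0.5), rnorm(7, 15, 6.4),
              rep(1, 12))
  categories <- rep(c("germline", "mosaic_lof", "mosaic_hotspot",
                      "tumor_specific"), c(90, 5, 7, 12))
  gc <- groupCompare(values, categories)
  expect_lt(gc$p, 0.05)
  expect_equal(nrow(gc$pairwise), 3L)
  expect_equal(unique(gc$pairwise$m), 3L)
  expect_true(all(gc$pairwise$p_sidak >= gc$pairwise$p_raw))
  expect_lt(gc$pairwise$p_sidak[gc$pairwise$group == "mosaic_hotspot"], 0.05)
})

test_that("the hotspot-vs-germline focus excess is detected reliably", {
  # draws follow the generator's shifted count model at the published
  # group means/sds; 200 replicate cohorts
  set.seed(77)
  hits <- 0L
  for (i in 1:200) {
    foci <- c(1 + rnbinom(90, size = 3.2, mu = 0.8),
              1 + rpois(5, 0.6),
              1 + rnbinom(7, size = 14^2 / (6.4^2 - 14), mu = 14),
              rep(1, 12))
    categories <- rep(c("germline", "mosaic_lof", "mosaic_hotspot",
                        "tumor_specific"), c(90, 5, 7, 12))
    gc <- groupCompare(foci, categories)
    if (!is.null(gc$pairwise) &&
        gc$pairwise$p_sidak[gc$pairwise$group == "mosaic_hotspot"] < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("empty groups are dropped with a warning and small inputs error", {
  expect_warning(
    gc <- groupCompare(c(1, 2, 3, 4), factor(c("a", "a", "b", "b"),
                                             levels = c("a", "b", "c"))),
    NA)  # factors with unused levels are fine: only present groups count
  expect_error(groupCompare(c(1, 2), c("a", "a")), "two non-empty")
})

test_that("cohort summaries reproduce per-category statistics on synthetic truth", {
  cohort <- makeCohort(cohortGenConfig(nPatients = 124, seed = 5))$truth
  cs <- cohortSummary(cohort)
  hs <- cs$perCategory$foci$mosaic_hotspot
  expect_equal(hs$n, 7L)
  expect_true(hs$median >= hs$range[1] && hs$median <= hs$range[2])
  expect_true(all(vapply(cs$perCategory$age, function(s) s$sd >= 0, TRUE)))
  expect_true(is.numeric(cs$tests$foci$all_categories$p))
})
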