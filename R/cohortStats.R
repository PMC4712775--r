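#' Controlled vocabulary of syndromic lesions
#'
#' The lesion types scored as evidence of syndromic disease.
#' @return character vector of lesion-type labels.
#' @export
lesionVocabulary <- function() {
  c("lung cyst", "PPB", "kidney cyst", "cystic nephroma", "Wilms tumor",
    "thyroid nodule", "thyroid carcinoma", "SLCT", "NCMH", "ERMS cervix",
    "ERMS bladder", "CBME", "pineoblastoma", "pituitary blastoma",
    "small-intestine juvenile polyp", "pelvic sarcoma")
}

#' Count discrete disease foci for one patient
#'
#' Each lesion from the controlled vocabulary contributes one focus, with
#' two merging rules: lung cysts merge unless they lie in different lobes or
#' are marked anatomically separate within a lobe; kidney cysts merge per
#' side, with a lesion recorded as bilateral contributing a focus on each
#' side. The count is invariant to the order of the lesion rows and
#' additive over organs.
#'
#' @param lesions data.frame with columns `organ`, `lesion_type`,
#'   `laterality` (`left`, `right`, `bilateral`, `n/a`), optional
#'   `lung_lobe`, and logical `anatomically_separate`.
#' @return integer number of discrete disease foci.
#' @examples
#' lesions <- data.frame(
#'   organ = c("lung", "lung", "kidney"),
#'   lesion_type = c("lung cyst", "lung cyst", "kidney cyst"),
#'   laterality = c("n/a", "n/a", "bilateral"),
#'   lung_lobe = c("RUL", "LLL", NA),
#'   anatomically_separate = FALSE)
#' countDiseaseFoci(lesions)  # 4
#' @export
countDiseaseFoci <- function(lesions) {
  if (nrow(lesions) == 0L) return(0L)
  if (!"anatomically_separate" %in% names(lesions))
    lesions$anatomically_separate <- FALSE
  if (!"lung_lobe" %in% names(lesions)) lesions$lung_lobe <- NA_character_
  if (!"laterality" %in% names(lesions)) lesions$laterality <- "n/a"
  unknown <- setdiff(unique(lesions$lesion_type), lesionVocabulary())
  if (length(unknown))
    stop("unknown lesion type(s): ", paste(unknown, collapse = ", "),
         "; vocabulary: ", paste(lesionVocabulary(), collapse = ", "))
  if (any(!is.na(lesions$lung_lobe) & lesions$organ != "lung"))
    stop("lung_lobe given for a non-lung lesion")

  foci <- 0L

  lc <- lesions[lesions$lesion_type == "lung cyst", , drop = FALSE]
  if (nrow(lc)) {
    lobe <- ifelse(is.na(lc$lung_lobe), "(unspecified)", lc$lung_lobe)
    for (lb in unique(lobe)) {
      grp <- lc[lobe == lb, , drop = FALSE]
      n_sep <- sum(grp$anatomically_separate, na.rm = TRUE)
      foci <- foci + n_sep + as.integer(n_sep < nrow(grp))
    }
  }

  kc <- lesions[lesions$lesion_type == "kidney cyst", , drop = FALSE]
  if (nrow(kc)) {
    sides <- unlist(lapply(kc$laterality, function(l)
      if (identical(l, "bilateral")) c("left", "right") else l))
    sides[is.na(sides) | sides == "n/a"] <- "(unspecified)"
    foci <- foci + length(unique(sides))
  }

  other <- lesions[!lesions$lesion_type %in% c("lung cyst", "kidney cyst"), ,
                   drop = FALSE]
  foci <- foci + nrow(other)
  as.integer(foci)
}

#' Summary statistics for a clinical feature
#'
#' Median, range, mean and sample standard deviation (n - 1 denominator). A
#' single value yields sd 0 with a flag rather than NA.
#'
#' @param values numeric vector; empty input is an error.
#' @return list with `n`, `median`, `range`, `mean`, `sd`, `sdUndefined`.
#' @export
summarizeValues <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarise")
  sd_undef <- length(values) < 2L
  list(n = length(values),
       median = stats::median(values),
       range = range(values),
       mean = mean(values),
       sd = if (sd_undef) 0 else stats::sd(values),
       sdUndefined = sd_undef)
}

#' Sidak adjustment for multiple comparisons
#'
#' `p' = 1 - (1 - p)^m`. The adjusted value is never below the raw value
#' and equals it when `m = 1`.
#'
#' @param p raw p-value(s).
#' @param m number of comparisons.
#' @return adjusted p-value(s).
#' @examples
#' sidakAdjust(0.01, 3)  # 0.0297
#' @export
sidakAdjust <- function(p, m) {
  stopifnot(m >= 1)
  if (m == 1) return(p)
  # -expm1(m * log1p(-p)) is 1 - (1-p)^m without cancellation for small p
  ifelse(p >= 1, 1, -expm1(m * log1p(-p)))
}

#' Nonparametric comparison of a clinical feature across mutation categories
#'
#' Kruskal-Wallis test across the groups; when the overall p-value is below
#' `alpha`, pairwise Wilcoxon rank-sum tests of each other category against
#' the reference group (germline), with Sidak adjustment using `m` = number
#' of pairwise tests. Ties are handled by the normal approximation with tie
#' correction (the default of [stats::wilcox.test()] in the presence of
#' ties); `exact = TRUE` switches to the exact distribution for small,
#' tie-free groups. Empty groups are dropped with a warning.
#'
#' @param values per-patient numeric feature (age in months, foci count).
#' @param categories group label per patient.
#' @param reference the reference group for pairwise tests.
#' @param alpha gate for the post-hoc tests.
#' @param exact passed to [stats::wilcox.test()].
#' @return list with `n` per group, `H` and `p` of the Kruskal-Wallis test,
#'   and `pairwise` (data.frame with group, raw and Sidak-adjusted p, m).
#' @export
groupCompare <- function(values, categories, reference = "germline",
                         alpha = 0.05, exact = FALSE) {
  keep <- !is.na(values) & !is.na(categories)
  values <- values[keep]; categories <- as.character(categories[keep])
  tab <- table(categories)
  empty <- setdiff(unique(categories), names(tab)[tab > 0])
  if (length(empty))
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
  groups <- names(tab)[tab > 0]
  if (length(groups) < 2L)
    stop("need at least two non-empty groups")

  kw <- stats::kruskal.test(values, factor(categories, levels = groups))
  out <- list(n = stats::setNames(as.integer(tab[groups]), groups),
              H = unname(kw$statistic), p = kw$p.value,
              pairwise = NULL)

  others <- setdiff(groups, reference)
  if (kw$p.value < alpha && reference %in% groups && length(others)) {
    m <- length(others)
    raw <- vapply(others, function(g) {
      suppressWarnings(stats::wilcox.test(
        values[categories == g], values[categories == reference],
        exact = exact)$p.value)
    }, 1)
    out$pairwise <- data.frame(
      group = others,
      p_raw = unname(raw),
      p_sidak = sidakAdjust(unname(raw), m),
      m = m,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Summarise a cohort table by mutation category
#'
#' Per-category summary statistics of age at first diagnosis and disease
#' foci, plus the Kruskal-Wallis group comparison for each feature. Because
#' the category set used for the overall test can be read in two ways, the
#' comparison is computed both over all categories present and over the
#' mutation-positive categories only (excluding `unresolved` and, for age,
#' optionally `tumor_specific`), and both results are labelled.
#'
#' @param cohort data.frame with columns `patient_id`, `category`,
#'   `age_first_dx_months`, and either `foci_count` or `lesions`
#'   (JSON-encoded lesion lists, scored via [countDiseaseFoci()]).
#' @param ... passed to [groupCompare()].
#' @return nested list: `perCategory` (summaries per feature), `tests`
#'   (group comparisons per feature, all-categories and
#'   mutation-positive-only).
#' @export
cohortSummary <- function(cohort, ...) {
  if (!"foci_count" %in% names(cohort)) {
    if (!"lesions" %in% names(cohort))
      stop("cohort needs foci_count or lesions")
    cohort$foci_count <- vapply(cohort$lesions, function(js)
      countDiseaseFoci(as.data.frame(jsonlite::fromJSON(js))), 1L)
  }
  feats <- c(age = "age_first_dx_months", foci = "foci_count")
  per_cat <- lapply(feats, function(col) {
    lapply(split(cohort[[col]], cohort$category), summarizeValues)
  })
  mut_pos <- cohort$category %in% c("germline", "mosaic_lof",
                                    "mosaic_hotspot", "tumor_specific")
  tests <- lapply(feats, function(col) {
    list(
      all_categories = groupCompare(cohort[[col]], cohort$category, ...),
      mutation_positive = groupCompare(cohort[[col]][mut_pos],
                                       cohort$category[mut_pos], ...))
  })
  list(perCategory = per_cat, tests = tests)
}

#' Load a deposited per-patient clinical dataset
#'
#' Reads a CSV export of a per-patient clinical table (columns
#' `patient_id`, `category`, `age_first_dx_months`, `foci_count`) for use
#' with [cohortSummary()]. The deposited study dataset itself is an
#' external download; this loader takes a local CSV export of it.
#'
#' @param path path to the CSV file.
#' @return validated data.frame.
#' @export
loadPatientDataset <- function(path) {
  if (!file.exists(path))
    stop("patient dataset not found at '", path,
         "'; supply a local CSV export (patient_id, category, ",
         "age_first_dx_months, foci_count)")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "category", "age_first_dx_months", "foci_count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}
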