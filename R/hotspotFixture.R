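#' Per-tissue sequencing evidence for the mosaic hotspot patients
#'
#' Returns the packaged specimen observations for the children with mosaic
#' RNase IIIb hotspot mutations: the seven study patients (IDs 101, 102,
#' 103, 104, 105, 120, 123) with every reported tissue, c./p. variant
#' pair, variant/total read count, tumor purity and allele-loss flag
#' transcribed from the published table, and -- when
#' `includeLiterature = TRUE` -- three comparable literature cases (two
#' bilateral-Wilms infants and one pituitary blastoma infant) carried with
#' a `source` tag and excluded from cohort counts by default.
#'
#' @param includeLiterature include the three literature cases.
#' @return named list of [PatientRecord-class] objects.
#' @examples
#' recs <- hotspotEvidenceFixture()
#' names(recs)
#' @export
hotspotEvidenceFixture <- function(includeLiterature = FALSE) {
  path <- system.file("extdata", "mosaic_hotspot_specimens.tsv",
                      package = "DicerMosaic", mustWork = TRUE)
  df <- readSpecimenTable(path)
  if (!includeLiterature) df <- df[df$source == "this_study", , drop = FALSE]
  recs <- lapply(split(df, df$patient_id), function(sp) {
    new("PatientRecord", patientId = as.character(sp$patient_id[1L]),
        specimens = sp, parents = list(), lesions = data.frame(),
        ageFirstDxMonths = NA_real_)
  })
  # keep study-id order, literature cases after
  ord <- c("101", "102", "103", "104", "105", "120", "123",
           "klein_1", "klein_2", "dekock_12")
  recs[intersect(ord, names(recs))]
}
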