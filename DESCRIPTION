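Package: DicerMosaic
Title: Mutational Target Space and Mosaicism Classification for DICER1 Syndrome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain underlying multi-tissue
    DICER1 syndrome cohort analysis: exhaustive enumeration of the mutational
    target space of a coding transcript by consequence class (nonsense,
    missense, synonymous; frameshift positions; canonical splice bases),
    parsing of cDNA-level (c.) variant notation with protein consequence
    calling and functional classification (loss-of-function truncating vs
    RNase IIIb hotspot missense), variant-allele-frequency evidence scoring
    from deep-sequencing read counts, a multi-tissue decision procedure that
    assigns each proband a mutation category (germline, mosaic loss of
    function, mosaic hotspot, tumor-specific, unresolved), disease-foci
    scoring with nonparametric group comparison, and a stochastic two-hit
    simulator of the temporal-order model in which the rare RNase IIIb
    hotspot mutation is the rate-limiting hit. Synthetic-data generators
    with known ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DicerMosaic-package.R'
    'classifier.R'
    'cohortStats.R'
    'consequence.R'
    'hgvsParse.R'
    'hotspotFixture.R'
    'loadTranscript.R'
    'reportIO.R'
    'synthetic.R'
    'targetSpace.R'
    'twoHitSim.R'
    'utils.R'
    'vafEvidence.R'
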