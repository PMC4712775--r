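---
title: "Mutational target space, mosaicism categories and the two-hit temporal-order model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational target space, mosaicism categories and the two-hit temporal-order model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DicerMosaic)
```

## The scientific problem

Pleuropulmonary blastoma (PPB) is the sentinel tumor of DICER1 syndrome, a
pleiotropic childhood tumor predisposition. DICER1 tumorigenesis is an
unusual variant of the two-hit model: tumors combine a *neomorphic* missense
mutation at one of five "hotspot" codons in the RNase IIIb nuclease domain
(E1705, D1709, G1809, D1810, E1813) with complete loss of function (LOF) of
the other allele — a nonsense, frameshift or canonical splice mutation,
a larger deletion, or allele loss. Probands fall into clinically distinct
categories depending on *where in the body and when during development* the
two hits arose:

* **germline** LOF carriers (the majority), diagnosed at a median of about
  three years with a handful of disease foci;
* **mosaic LOF** patients, with a post-zygotic truncating mutation at
  sub-heterozygous allele fraction in normal tissues;
* **mosaic hotspot** patients, in whom the *rare* hit — the RNase IIIb
  missense — arose first, early in embryogenesis: they present in infancy
  with extraordinary numbers of discrete disease foci across multiple
  organs;
* **tumor-specific** (sporadic) patients, whose hotspot and LOF hits are
  both confined to a single tumor clone and who carry no syndromic risk.

This package implements the full computational chain behind that
classification: enumeration of the mutational target space of the coding
sequence, parsing and consequence calling of c.-notation variants,
variant-allele-frequency (VAF) evidence scoring from deep-sequencing read
counts, the multi-tissue decision procedure, disease-foci statistics, and a
stochastic simulator of the temporal-order argument.

## Target-space enumeration

Every single-base substitution of the open reading frame is enumerated
(`enumerateSNVs()`: 9 per codon — 3 positions x 3 alternates) and classified
against the standard genetic code (codon table 1; no other table is
supported). From this, `targetSizeReport()` derives:

* nonsense SNVs and the number of distinct *stop-convertible* codons (a
  codon counts once no matter how many single changes reach TAA/TAG/TGA);
* hotspot missense SNVs — missense only; a nonsense change at a hotspot
  codon is an LOF route, not a neomorphic one;
* frameshift-capable point locations, `3 x nCodons` (every ORF base);
* canonical splice bases, 4 per intron (2-base GT donor + 2-base AG
  acceptor); the intron count is carried verbatim from the annotation
  input, never recomputed from a gene model;
* the LOF : hotspot ratio, defined as (nonsense SNVs + frameshift positions
  + splice bases) / hotspot missense SNVs. This is a documented convention:
  allele loss, larger deletions and rearrangements are additional LOF
  routes that cannot be enumerated per base, and reports acknowledge them
  as text rather than inventing a number.

The terminal stop codon is excluded from the enumerated codon set (the
reference ORF is counted as 1922 *sense* codons); stop-loss changes are
outside the consequence taxonomy. Enumeration order is deterministic (CDS
position, then alternate base alphabetically) so reports are byte-stable.

The enumeration path is validated against an independent brute-force oracle
(`bruteForceTargetCounts()`) that mutates every base, re-translates the
*whole* ORF and diffs the protein; the test suite checks exact agreement on
100 random ORFs of 10–500 codons.

### The packaged transcript is a synthetic surrogate

The package ships a **synthetic surrogate** of the DICER1 coding sequence
(`dicer1Transcript()`, files `DICER1_CDS_synthetic.*` under `extdata`), not
the RefSeq NM_177438.2 record. The surrogate is a constructed 1922-codon
ORF that satisfies every published structural constraint of the reference:
the identity of each codon anchored by a published c./p. variant pair
(W32, V377, W400, R656, the five hotspot codons, D1713, G1708, D1822, and
so on), hotspot codon identities that yield exactly 36 hotspot missense
SNVs (the printed p.G1809R change forces a GGG codon at 1809, which is the
unique choice consistent with the 36-count), a codon composition with 675
stop-convertible codons and 736 nonsense SNVs, and a 26-exon annotation
anchored by the two published boundaries (exon 10 = c.1510..1752, 243 nt,
whose skip removes 81 amino acids in frame; exon 24 = c.5096..5364, 269 nt,
whose deletion shifts frame). The RNase IIIb domain span (codons
1666–1824) is part of the synthetic annotation.

Consequently, target-space counts computed from this fixture demonstrate
that the *pipeline* reproduces the documented composition end-to-end; they
are not an independent re-derivation from the RefSeq record. Users with the
RefSeq CDS and a structural annotation can run the identical code path via
`loadTranscript()`. The independent evidence that the enumerator is correct
is the brute-force oracle property, which is fixture-free.

## Variant notation and consequences

`parseCdna()` parses the c.-notation subset used in DICER1 reports
(substitution, deletion, duplication, insertion, delins; exonic positions
and intron-offset positions such as `c.5096-498` or `c.1752+1`),
1-based, CDS-anchored, with strict rejection of malformed input.
`proteinConsequence()` then applies:

* substitutions: re-translate the affected codon;
* exonic indels: frameshift iff the net length change is not 0 mod 3, with
  the `fs*N` stop distance obtained by re-translating the mutated CDS;
* canonical splice variants (offsets ±1, ±2): predicted skip of the
  adjacent exon, classified by skipped length mod 3 — so the intron-10
  donor deletion is a *non-truncating* in-frame loss of 81 residues, while
  most skips frameshift;
* deletions bracketing a whole exon: classified by deleted coding length
  mod 3 (the exon-24 deletion, 269 nt, is a frameshift);
* deeper intronic variants: splice effect of unknown outcome, warned,
  classified `vus`.

`classifyFunctional()` maps consequences to the functional classes the
classifier consumes: `lof_truncating` (any truncating consequence),
`hotspot_missense` (missense at an annotated hotspot codon),
`other_missense` (including the in-domain non-hotspot changes G1708E and
D1822V — external SIFT/PROVEAN verdicts may annotate but never change the
class), `inframe`, `synonymous`, `vus`.

## VAF evidence

* `vaf()` is the full-precision read-count ratio.
* `isDetected()` requires at least `minVarReads` (default 3) variant reads
  *and* VAF at least `minFoldOverError` (default 3) times the per-base
  substitution error rate (default 0.07%, the deep-sequencing platform
  estimate). Only the error-rate anchor is externally given; the other two
  are conventions and are exposed in `detectionPolicy()`. At depth 3000
  these defaults give >99% power for a 1% mosaic fraction and <1% false
  detections from error alone (exact binomial tails, verified in the
  tests).
* `zygosityClass()` uses a sub-heterozygous bound of 35% ("below 35% of
  reads" — so 35% itself is heterozygous-range) and a symmetric upper
  heterozygous bound of 65%. The upper bound is a convention (no published
  upper bound for "approximately heterozygous" exists); classifications
  that flip when the sub-heterozygous bound moves ±5 points are flagged
  near-boundary.
* `inferAlleleLoss()` tests tumor read counts against the purity-aware
  heterozygous expectation VAF = purity/2 with a one-sided exact binomial
  test (alpha 0.01), returning `indeterminate` below a purity floor of
  0.30 — allele loss cannot be established in low-purity specimens, so
  published allele-loss flags are carried as given, not recomputed.

## The decision procedure

`classifyPatient()` applies the rules in precedence order germline >
mosaic > tumor-specific > unresolved, mirroring the study workflow's
left-to-right flow:

1. a non-synonymous variant at heterozygous-range VAF in blood or normal
   tissue is germline (blood precedence when blood and normal tissue
   disagree; hotspot-in-blood calls carry a caution flag since germline
   hotspot alleles are likely inviable);
2. a variant detected at sub-heterozygous VAF in at least one normal-role
   specimen, or detected in two or more primary tumors of *different*
   organs (bilateral ovaries count as one organ), is mosaic — subtype
   hotspot or LOF by the shared variant's functional class;
3. a single tumor carrying both a hotspot missense and an LOF hit
   (truncating variant or allele-loss flag) with nothing detected in
   blood/normal is tumor-specific;
4. otherwise unresolved.

Observations below the error-rate threshold contribute no evidence on
their own: a trace-level blood read count neither blocks nor supports a
call, which is exactly why the multi-organ tumor rule exists. Copy-number
evidence from the hybridization assay enters as an LOF marker with no VAF.
The classifier is deterministic, seed-free and specimen-order-invariant;
every report lists the rules that fired.

`inheritanceStatus()` adds trio logic for germline calls: a heterozygous
parent means inherited; both parents assayed and negative means de novo;
parental reads above the error rate but below the sub-heterozygous bound
mean possible parental mosaicism.

## Cohort statistics

`countDiseaseFoci()` scores discrete lesions with the study's merging
rules: lung cysts merge unless in different lobes or anatomically separate
within a lobe (the flag stands in for imaging-level adjudication when lobe
data are absent); renal cysts merge per side with bilateral counting twice;
every other vocabulary lesion is one focus. `groupCompare()` runs
Kruskal-Wallis across categories and, when significant at 0.05, pairwise
Wilcoxon rank-sum tests of each category against germline with Sidak
adjustment `p' = 1 - (1-p)^m`, `m` = 3 for the four-category design. Ties
use the normal approximation with tie correction (the exact method used in
the original analysis is unspecified); `exact = TRUE` is available for
small tie-free groups. Because it is ambiguous whether the published
overall tests used all four categories, `cohortSummary()` computes and
labels both variants.

## The two-hit temporal-order simulator

`simulateTwoHit()` grows one organism as a binary lineage tree (default 18
divisions) whose 8 compartments (the level-3 subtrees) represent organ
sites at risk; there is no cell death or selection — the simplest model
consistent with the verbal argument. Each daughter cell independently
acquires a hotspot hit (probability `muHotspot` per division) and an LOF
hit (`muLof`). A cell completing both hits founds a focus; foci are counted
as founding events (maximal double-hit clades) and the clade is not
expanded further. Mosaic scenarios force the first hit into one random
cell at the onset division (default 4, an early-embryo choice). Absolute
rates are illustrative user parameters; only the LOF:hotspot *ratio* is
anchored, defaulting to the packaged transcript's target-size ratio
(6606/36 ≈ 183.5). The analytic check `P(foci ≥ 1) = 1 - (1-p)^E` with `E`
the number of daughter draws holds in the single-compartment limit and is
verified in the tests.

The simulator reproduces the qualitative claim that drives the clinical
picture: with the LOF route ~100x more abundant than the hotspot route,
hotspot-first mosaics accumulate many more foci, earlier, than
LOF-first (germline) patients.

## Synthetic data and what passing tests show

`makeCohort()` draws category-faithful cohorts under the study conditions:
proportions 90:5:7:12:10 over 124 probands, Poisson depth around 3000,
binomial read sampling with error injected at 0.07% on reference reads (no
per-position context model), germline blood VAFs uniform on the observed
42.0–57.1% band, mosaic allele fractions uniform on 0.5–30%, per-category
age distributions (normal, truncated at zero; mean/sd 36/31, 27/12, 11/6,
42/31 months) and focus counts drawn as 1 + X with X negative-binomial
matched to the published mean/sd where overdispersed (germline 1.8/1.0,
hotspot 15/6.4), Poisson where not (mosaic LOF 1.6/0.5), and constant 1
for tumor-specific (published sd 0.0). The distribution families are the
package's choice; the source reports only summaries. Unresolved patients
take cohort-typical ages and a single focus.

Synthetic cohorts capture sampling noise, detection thresholds and
category structure; they do not capture alignment artifacts, strand bias,
position-dependent error, impure normal tissue, or adjudication of real
imaging. Recovery tests (≥99% category accuracy at depth 3000 over 1000
patients) therefore validate the decision logic under the stated noise
model, not performance on raw sequencing data.

Problem sizes used by the shipped tests — 100 oracle ORFs up to 500
codons, 1000-patient recovery cohorts, 1000 null simulations for the
Kruskal-Wallis calibration, 1000 simulator replicates per scenario — were
chosen to give stable statistical assertions at desk scale.

## Numerical and interface choices

* Coordinates are 1-based, inclusive, CDS-anchored throughout; no genomic
  coordinates anywhere. Protein notation uses one-letter code with HGVS
  `fs*` / `*` conventions.
* The zygosity boundary at exactly 0.35 is heterozygous-range (the band is
  defined as *below* 35%); 0.65 is inclusive.
* Sequential conditional binomials implement the per-division multinomial
  over (both hits, hotspot only, LOF only, neither) exactly.
* The deposited per-patient clinical dataset is an external download; the
  loader (`loadPatientDataset()`) takes a local CSV export and is not
  exercised offline.

## Known limitations

* The packaged transcript is a constructed surrogate (above); exact
  RefSeq-derived counts require the real record.
* Splice outcomes are modelled only as whole-exon skips; alternative
  outcomes (cryptic sites, intron retention) are not modelled.
* No nonsense-mediated-decay prediction beyond the truncation rule; no
  probabilistic mosaic-fraction estimation; no penetrance estimation (the
  ascertainment design does not support one).
* The simulator has no developmental "windows of risk": organ-specific
  susceptibility periods are discussed in the clinical literature but have
  no parameters to implement.
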