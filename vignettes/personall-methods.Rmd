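---
title: "Methods: purity-aware CNA calling and cumulative genetic risk scores in pediatric B-ALL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purity-aware CNA calling and cumulative genetic risk scores in pediatric B-ALL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(personALL)
```

This vignette is the package's account of its science: the dosage-quotient
model behind the copy-number caller, the Cox-derived cumulative scoring
system, the classifiers built on top of them, the synthetic-cohort
generator used for validation, and the numerical and design choices made
where the underlying methodology leaves room.

## 1. The dosage-quotient model

A digitalMLPA-style assay counts sequencing reads per ligated probe. Read
depth varies per sample and per probe, so raw counts are normalized in two
steps (medians at both steps, for robustness to outlier probes and outlier
reference samples):

1. each probe count is divided by the median count of the
   digital-karyotyping *reference probes* of the same sample, and
2. that relative count is divided by the median relative count of the same
   probe across the copy-number-neutral *reference samples*.

The result, the dosage quotient (DQ), is ~1.0 at an unaffected locus. The
specimen is a mixture of leukemic blasts (fraction *p*, the purity measured
by flow cytometry) and normal cells, so a lesion present in all blasts is
diluted toward 1:

| state | blast copies | expected DQ |
|---|---|---|
| biallelic loss | 0 | 1 − *p* |
| monoallelic loss | 1 | 1 − *p*/2 |
| normal | 2 | 1 |
| one-copy gain | 3 | 1 + *p*/2 |
| multiple gain | ≥4 | ≥ 1 + *p* |

A lesion confined to a fraction *f* of the blasts (subclonal) lands between
the normal band and the clonal level, e.g. 1 − *f p*/2 for a loss.

### Caller decision rules

The methodology we implement states the purity-mixture interpretation and
the subclonal criterion qualitatively; the numeric bands are this package's
own calibration, chosen once to mirror common MLPA practice and exposed in
`caller_config()`:

* **Normal band.** A probe is aberrant when |DQ − 1| reaches
  `max(0.15, 3 × robust SD)` of that probe across reference samples. The
  0.15 floor is *closed* (a deviation of exactly 0.15 counts as aberrant):
  with the conventional expected levels, a borderline subclonal loss sits
  exactly on the floor, and treating the boundary as inside the normal
  range would silently absorb it.
* **Consecutive-probe support.** A locus with ≥2 probes needs at least 2
  consecutive aberrant probes in the same direction
  (`min_consecutive = 2`); a single-probe locus needs |DQ − 1| > 0.3.
  This extends the "multiple consecutive probes" idea from subclonal calls
  to all calls, suppressing single-probe noise.
* **Level matching.** The mean DQ of the supporting run is matched to the
  purity-expected levels with tolerance 0.10 (`level_tolerance`). A loss
  whose mean lies more than 0.10 above the monoallelic expectation is
  *subclonal*; symmetrically, a gain more than 0.10 below the one-copy
  expectation. Between two clonal levels the nearer wins; ties resolve to
  the less extreme state.
* **Discordance.** Aberrant probes pointing in opposite directions within
  one locus produce a `normal` call flagged `"discordant"`.
* **Control probes** never enter normalization; they gate samples via a
  coefficient-of-variation QC (≤ 0.25).
* Whether a biallelic call requires every probe below the biallelic band
  or only the mean was left open by the source methodology; the mean is
  used here.

### IKZF1 at exon resolution

The panel covers IKZF1 with two upstream probes (≈4 kb and ≈2 kb before
the coding sequence) and exons 1–8. Per-unit calls are merged into maximal
contiguous deleted intervals and labelled (`"ex4-7"`, `"ex1-7"`,
`"upstream+ex1-8"`, ...), the patterns recurrently seen in B-ALL.

### Digital karyotyping

Arm-level DQs are purity-corrected to integer copy numbers,
`cn = round(2 (DQ − (1 − p)) / p)`, and summed over the 23 chromosome
slots (sex chromosomes occupy one diploid slot), so an unaffected genome
has modal number 46. Chromosomes whose arms disagree are flagged
structural, counted as two copies and logged. Ploidy classes: 51–67
high-hyperdiploid (the classical nonrandom-gain karyotype), ≥68
near-triploid, 46–50 non-hyperdiploid, <46 "other" (hypodiploid range).

**Known limitation.** The DQ is a ratio to the sample's median reference
level. In a near-triploid genome the median itself is elevated, so every
quotient rescales: trisomic chromosomes read as neutral and disomic ones
as losses — the familiar ambiguity between near-triploidy and a doubled
hypodiploid genome in ratio-based copy-number data. The round-trip
recovery statistics therefore exclude near-triploid genomes; resolving
them requires an external ploidy anchor (DNA index, karyotype).

## 2. Profiles and composite genotypes

Per patient, gene CNAs, whole-chromosome gains (`"+4"`, `"+21"`, ...),
fusion markers and composite flags are merged into one lesion set:

* **IKZF1^plus^**: IKZF1 deletion co-occurring with CDKN2A/B, PAX5 or
  PAR1 deletion in the absence of ERG deletion; IKZF1 deletion without
  those partners is IKZF1^del^.
* **DT4/6**: double trisomy of chromosomes 4 and 6 (≥3 copies each), the
  marker of superior outcome within high-hyperdiploidy.
* **HHD**: modal number 51–67.

Subclonal lesions count toward profiles by default (they are reported in
cohort summaries without being excluded downstream); `min_clonality`
switches to clonal-only mode. The cytogenetic subtype is one of BCR-ABL1,
KMT2A-r, Ph-like, TCF3-PBX1, iAMP21, ETV6-RUNX1, HHD, B-other. Where
several subgroup-defining markers co-occur, precedence follows clinical
adversity — BCR-ABL1 > KMT2A-r > Ph-like > TCF3-PBX1 > iAMP21 >
ETV6-RUNX1 > HHD — because adverse fusion genotypes dominate clinical
assignment; the conflict is logged.

## 3. Score derivation

For each recurrent lesion (gene CNAs, chromosome gains, fusions, and the
composite genotypes as first-class predicates) a univariate Cox
proportional-hazards model is fit on event-free survival. EFS is
truncated at 60 months (events beyond the horizon are censored there),
matching a 5-year endpoint. Ties are handled by the Efron approximation
(Breslow via config); fits are checked in the test suite against a
brute-force grid-search maximizer of the partial likelihood. Monotone
likelihoods (complete separation) are capped at |log HR| = 10 and
flagged rather than scored blindly.

Selection keeps lesions with frequency > 1.5% of the full cohort
(denominator: all patients, not the per-lesion evaluable subset) and
HR > 1.5 or HR ≤ 0.66 — each comparison exactly as strict as printed
(the protective boundary is inclusive, the adverse one strict).

The default weight is
`score = sign × clamp(round(|ln HR| / ln 1.5), 1, 4)`, positive for
protective lesions. The banding base 1.5 makes one band per 1.5-fold
hazard change, consistent with the selection thresholds, and the clamp at
4 aligns the strongest single marker with the excellent-group threshold
(one strong favorable marker, or two moderate ones, suffices). Published
hand-set weights can replace the derived ones entirely via
`read_score_table()` — the weighting scheme is a policy, not a constant
of the method.

## 4. Classification

The cumulative score S sums the weights of a patient's matched lesions;
within an exclusion group (e.g. IKZF1^plus^ ⊃ IKZF1 deletion) only the
most specific lesion present contributes. Thresholds: excellent S ≥ 4,
good 0–3, high −1…−3, ultra-poor S ≤ −4. The printed ranges "high: −1 to
−4" and "ultra-poor: ≤ −4" overlap at −4; the boundary is assigned to
ultra-poor, reading "≤ −4" as inclusive and keeping the partition
disjoint. Adding a positively weighted lesion can never worsen the group
(monotonicity in S), and every integer maps to exactly one group — both
are property-tested.

The IKAROS classifier is a pure table lookup
(cytogenetic risk class × IKZF1 status → low/medium/high). The detailed
combination table of the original work is not reproduced in its main
text, so the shipped default is this package's reconstruction: risk
classes good = {ETV6-RUNX1, HHD}, poor = {BCR-ABL1, Ph-like, KMT2A-r,
iAMP21}, intermediate = rest; IKZF1-normal → low everywhere; del → low
in good-risk cytogenetics, medium elsewhere; plus → medium in good-risk
cytogenetics, high elsewhere. It reproduces the intended ordering (the
large majority in IKAROS-low, a small high group) and is fully
overridable via `read_ikaros_matrix()`.

## 5. Survival and co-segregation statistics

Kaplan–Meier estimation (events-first at tied times, Greenwood standard
errors), k-group log-rank tests, and Benjamini–Hochberg or Bonferroni
correction are delegated to `survival` and `stats::p.adjust` behind the
package's interfaces; the test suite verifies them against literal
product-limit, term-by-term log-rank and hypergeometric-enumeration
oracles. The 5-year EFS is the last product-limit estimate at or before
60 months. Pairwise Fisher co-segregation uses the standard two-sided
convention (sum of all table probabilities at or below the observed
table's — stated explicitly because two-sided conventions differ); the
direction label (co-occurring / mutually exclusive) is applied only to
pairs significant after BH correction, with raw-α significance reported
alongside. The Haldane–Anscombe 0.5 correction is applied to the
*displayed* odds ratio only when a cell is zero, never to the p value.

## 6. The synthetic cohort generator

`sim_config()` defaults describe the study conditions the package is
validated under — a 260-patient pediatric B-ALL cohort:

* **Subtypes** ETV6-RUNX1 25%, HHD 30%, BCR-ABL1 3%, Ph-like 5%,
  KMT2A-r 2%, TCF3-PBX1 4%, iAMP21 2%, B-other 29%.
* **Lesions** are Bernoulli draws conditional on subtype, encoding the
  field's co-segregation structure: ETV6 loss (70%) and VPREB1 loss in
  ETV6-RUNX1; IKZF1 (60%), MLLT3 and PAR1 losses with BCR-ABL1; RB1 and
  CDKN2A/B losses with iAMP21; few subchromosomal lesions in HHD.
  About 8% of planted gene lesions are subclonal (blast cell fraction
  0.3–0.6); 20% of VPREB1/CDKN2A/B losses are biallelic.
* **Karyotypes**: HHD genomes gain 5–16 extra copies from the
  recurrently gained chromosomes (21, 6, X, 14, 18, 17, 4, 10, ...),
  median modal number ≈55, with a rare (1/260) near-triploid genome of
  72 chromosomes; other subtypes are diploid.
* **Purity** is Beta(5, 2) rescaled to [0.29, 0.99] (mean 0.79), the
  blast-fraction range of a realistic diagnostic series.
* **Survival**: exponential event times — the minimal hazard model, and
  the one that makes planted hazard ratios exact. In the default
  `"group"` mode the hazard is set by the patient's planted risk group,
  with rates chosen so 5-year EFS is 96.3 / 87.2 / 67.4 / 39.0% for
  excellent / good / high / ultra-poor; in `"lesion_hr"` mode the hazard
  is baseline × Π HR(ℓ) over planted lesions. The planted group comes
  from a generator-internal score table (ETV6-RUNX1 +4, HHD +2, DT4/6
  +2, BCR-ABL1 −4, IKZF1^plus^ −3, ...). Censoring is independent
  exponential (rate 0.004/month, ≈20% non-administrative censoring)
  plus administrative censoring at 60 months.
* **Counts**: expected count = depth × (purity-mixed copy level)/2 with
  negative-binomial noise (default depth 1000, dispersion 0.02;
  dispersion 0 gives exact expectations). Reference samples are pure
  diploid.

What the generator does *not* emulate: real genome coordinates, germline
variants, probe-specific efficiency biases, GC effects, batch structure,
non-proportional hazards, or informative censoring. Passing tests
therefore demonstrate the correctness of the algorithms under the stated
generative model, not clinical performance on real data — the cohort EFS
rates printed by real-data studies require the original patient data and
are outside desk-scale reproduction.

## 7. Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class single
core: Cox-vs-grid equivalence on 200 random cohorts of n ≤ 30;
noiseless caller round-trips at n = 80 patients × 13 genes (recovery
≥99% of clonal gene states); planted-HR selection across 50 seeds at
n = 800; log-HR bias over 50 seeds at n = 1000 (|bias| < 0.1); Fisher
type-I calibration over 200 cohorts of n = 500; group-separation checks
over 20 seeds at n = 800. Newton convergence uses the `survival`
tolerance 1e-10; grid oracles use a two-stage grid (0.01 coarse, 1e-4
fine). Seeds are fixed throughout; the acceptance script derives all its
seeds from the single `--seed` argument.

## 8. Known limitations

* Near-triploid genomes rescale all dosage quotients (Section 1).
* Single-probe loci cannot be assessed for subclonality and need a
  stronger deviation to be called at all.
* The scoring system is univariate by construction: correlated lesions
  each carry their marginal hazard ratio, so stacked co-segregating
  lesions can overstate joint effects; exclusion groups mitigate only
  the explicitly declared nestings. Multivariable or MRD-adjusted models
  are out of scope.
* The IKAROS matrix and any published per-lesion weights are config
  payloads, not package constants; the shipped defaults are documented
  reconstructions.
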