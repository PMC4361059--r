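---
title: "Calling and comparing somatic mutations across synchronous lesions"
author: "mutmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing somatic mutations across synchronous lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmosaic)
```

## Overview

`mutmosaic` analyses somatic single-nucleotide variants in multiple lesions
sampled simultaneously from one patient against a shared normal sample. It
implements two callers with different sensitivity/specificity trade-offs, a
deep-amplicon validation rule, per-lesion burden and spectrum metrics, and
cross-lesion heterogeneity reports. A synthetic cohort generator stands in
for real sequencing data so that every stage is testable end to end with
known ground truth.

All user-facing functions take and return tibbles: a *pileup* table (one
row per genomic site, paired tumor/normal strand-aware allele counts,
optional per-read evidence in list-columns, mask flags) and a *call* table
(one row per candidate variant with VAFs, tags and a consequence label).

## The primary caller

Genotypes are assigned per sample from the allele fraction of the
highest-count non-reference base: `hom_ref` below 0.10, `hom_alt` above
0.85, `het` between (both thresholds configurable through
`pipeline_config()`). A deliberately simple threshold model replaces a
likelihood-based genotyper here: it is deterministic, transparent, and its
behaviour at boundaries is directly testable. A somatic candidate is a site
where the tumor genotype differs from a homozygous-reference normal; the
reverse direction (variant private to the normal) is not a somatic event
and is used only by the inverse analysis below.

Every candidate is annotated with a two-sided Fisher exact probability of
the 2×2 table (ref reads, alt reads) × (tumor, normal), computed by
summation of hypergeometric probabilities no larger than that of the
observed table. The probability is annotated, not thresholded: no cutoff is
applied by default. The filter cascade then adds tags:

* `LOW_DEPTH` — tumor **or** normal depth below 10;
* `STRAND_BIAS` — two-sided Fisher p of the (ref, alt) × (forward,
  reverse) table below 0.001;
* `LOW_MAPABILITY` — site inside the low-mapability mask;
* `TAIL_BIAS` — one-sided Wilcoxon rank-sum p below 0.005 for alt reads
  sitting nearer the read ends than ref reads. This tag annotates but does
  not disqualify; the three tags above do.

The strand-bias and tail-bias tests are stated here exactly because only
their thresholds, not their constructions, are conventional; both
constructions are pinned by tests against enumeration and permutation
oracles.

## The subclonal caller

Clonal heterozygous mutations sit near 50% VAF; subclonal events can sit
far below the het genotype threshold and are invisible to the primary
caller. The subclonal caller therefore works on read-level evidence: a
site is called when at least `min_evidence = 2` *qualified* mutant reads
support the change in the tumor — base quality at least 20, independently
confirmed (the per-read `confirmed` flag, a stand-in for secondary-aligner
agreement; alignment itself is out of scope), and at least 5 bp from the
nearer read end — while the matched normal shows **zero** reads with the
same change at any quality. Calls at sites flagged near a DNA repeat
(repeat BED applied with a 10 bp flank), at known germline variant sites,
or whose quality-qualified evidence lies entirely inside the end-exclusion
zone are removed.

The "minimum value of 2" is read as two qualified reads; "high quality" is
fixed at base quality 20 and "near the end" at 5 bp — explicit, adjustable
defaults for values that are conventionally left unstated. Detection power
is closed-form binomial, `subclonal_sensitivity(vaf, depth, min_reads)
= P(X >= min_reads), X ~ Binomial(depth, vaf)`; at depth 100 a 5% VAF
variant is detected with probability
`1 - 0.95^100 - 100*0.05*0.95^99 = 0.963`, which the test suite verifies
empirically by running the caller over 10,000 simulated sites.

## Validation and concordance

The deep-amplicon rule mirrors targeted resequencing practice: a variant is
evaluable only when both samples reach coverage 20; it is validated iff the
tumor shows at least 5 mutant reads making up at least 1% of its reads with
no mutant read in the normal. `concordance_rate()` reports the validated
fraction among primary calls whose tumor VAF ("mutational percentage")
exceeds a threshold, default 0.15. Mutant reads are taken as raw counts —
amplicon duplicate structure is assumed resolved upstream. Concordance is
per variant; a per-gene roll-up can be derived from the gene column.

## Burden metrics and the spectrum

The mutational index is `round_half_up(n / target_mb, 2)` over unique
(chrom, pos, ref, alt) passed amino-acid-changing calls. The default
`target_mb = 30` is the effective exome target consistent with published
per-Mb indices for 50 Mb-capture designs after coverage filtering; it is a
plain ratio denominator and is echoed in the run manifest. Rounding is
half-up (0.125 → 0.13), not banker's, matching how such indices are
printed.

The *inverse analysis* swaps the tumor and normal roles and re-runs the
full primary pipeline: any "somatic" call made with the lesion as the
reference sample estimates the pipeline's artifact floor. On error-free
synthetic data it is exactly zero; swapping twice is the identity.

Substitutions are collapsed onto the six pyrimidine-reference classes
(G>A → C>T, etc.). `spectrum_summary()` reports class fractions and, among
C>T/G>A transitions, the fraction at CpG dimers (C followed by G, or G
preceded by C, in the trinucleotide context) — the signature of methyl-C
deamination that dominates colorectal lesions. `compare_spectra()` tests
two call sets' CpG composition with the same two-sided Fisher construction
as the caller. The summary is invariant under reverse complement of the
entire input, which the suite checks property-style.

## Heterogeneity across lesions

"Same mutation" means identical (chrom, pos, ref, alt); gene-level
recurrence (different variants hitting one gene in several lesions) is
reported separately, since the two patterns support opposite conclusions
about lesion origin. `overlap_report()` gives pairwise shared counts,
union sizes and Jaccard indices; `classify_clonality()` labels calls
subclonal below a VAF threshold whose default, 0.25, is half the diploid
heterozygous expectation (the boundary itself is clonal);
`estimate_shared_fraction()` inverts the generator's sharing model — each
mutation copied into one sibling lesion with probability *s* — via the
consistent estimator `shared / (|A| + |B| - shared)`.

## The synthetic cohort generator

`simulate_patient()` builds one synthetic chromosome per patient: uniform
random reference bases (so trinucleotide contexts are internally
consistent), toy one- or two-exon CDS models with forced ATG/stop codons on
either strand, random low-mapability and repeat masks, germline SNPs (VAF
0.5 or 1.0, present in every sample and flagged as known variants), and
per-lesion somatic mutation sets.

Key emulated features and their defaults:

* **Depths**: negative binomial, mean 99, overdispersion φ = 0.04
  (variance = μ + φμ²), giving a central spread of roughly 78–141 reads —
  the coverage profile of a mid-coverage exome. Means within 2% of target
  at 10,000 sites are asserted in tests.
* **Clonality**: clonal mutations at VAF 0.5; a subclonal compartment
  (default 60% of mutations) uniform on VAF 0.05–0.25, reflecting the
  observation that most mutations in benign lesions are subclonal.
* **Spectrum**: class weights 60% C>T with 75% of C>T at CpG, the
  transition-dominated pattern of colorectal lesions, so spectrum code has
  real signal to summarise.
* **Independence**: somatic positions are drawn without replacement across
  sibling lesions, so with `shared_fraction = 0` truth sets are disjoint by
  construction; `shared_fraction > 0` copies mutations into one random
  sibling.
* **Artifacts**: strand-bias artifact sites carry alt reads on one strand
  only at VAF 0.5, emulating a mismapped paralog with a heterozygous
  variant — strong, unambiguous true positives for the 0.001 strand
  filter. Read-end artifact sites carry low-VAF alt reads confined to
  within 3 bp of a read end, which the subclonal end-exclusion removes and
  the primary genotype threshold never sees.
* **Error**: per-read error rate 10⁻³; error reads get mid-range qualities
  and a coin-flip `confirmed` flag, true-mutation reads high qualities and
  `confirmed = TRUE`.

Read-evidence lists are complete (ref and alt reads) at mutation and
artifact sites, where the tail-bias test needs reference end distances, and
alt-only elsewhere; the pileup validator requires read-derived counts never
to exceed the count matrix, with exact agreement when a list is complete.
Determinism is strict: one global seed spawns per-patient seeds by fixed
integer arithmetic, the same seed reproduces a cohort bit for bit, and
`run_all()` output files are byte-identical across reruns.

What the generator does **not** emulate: alignment itself (FASTQ/BAM are
out of scope; evidence flags abstract it), copy-number variation, tumor
purity (true VAF is specified directly and stands for the observed
expectation), PCR duplicates, multi-allelic sites, and INDELs. Passing
recovery tests on this generator therefore demonstrates the decision rules
and their arithmetic, not robustness to real alignment pathology.

## Numerical and design choices

* Coordinates: variants are 1-based (VCF convention); interval masks are
  0-based half-open (BED convention); a variant at position *p* lies inside
  BED region `[p-1, p)`. Both conventions are checked by round-trip tests.
* Fisher probabilities use exact hypergeometric summation with a
  `1 + 1e-7` relative slack when comparing table probabilities, the
  standard guard against ties lost to floating point; all-zero margins
  give p = 1 by convention.
* Genotype boundaries: fractions exactly at 0.10 are het, above 0.85
  hom_alt; clonality exactly at the threshold is clonal. Boundary rules are
  closed and pinned by tests.
* When a variant hits several transcripts the most severe consequence is
  reported (truncating > missense > synonymous > non_coding); start-codon
  loss counts as truncating. Standard genetic code only.
* The depth < 10 rule both tags (`LOW_DEPTH`) and filters — the tag is
  visible in the VCF FILTER column even though it also disqualifies.
* An emitted subclonal call necessarily has ≥ 2 reads passing the
  end-distance gate, so the `READ_END_ONLY` rejection can only fire on
  calls constructed outside the normal path; it is retained as a defensive
  filter and exercised directly in tests.
* Parameter-recovery analyses in the test suite run the error-free,
  clonal-only condition (`fraction_subclonal = 0`) when asserting perfect
  primary-caller recovery, because subclonal truth below the het threshold
  is invisible to a genotype-difference caller by design; subclonal
  recovery is asserted separately against the binomial sensitivity curve.
* Problem sizes used by the suite: single patients at 20,000 sites for
  recovery and artifact checks, 10,000 sites for the empirical sensitivity
  check, 200 patients at 4,000 sites for shared-fraction recovery, and a
  4-patient default-scale cohort for the overlap property — small enough to
  run everywhere, large enough that every statistical assertion has its
  stated power.

## Limitations

The subclonal caller has no strand-bias exclusion (mirroring its
minimum-evidence design), so one-strand artifacts whose reads pass the
confirmation coin-flip can survive it; on real data the confirmation flag
carries that burden. The toy consequence classifier handles CDS point
changes only — no splice sites, UTRs or regulatory annotation. The
mutational index depends linearly on the assumed effective target size;
comparisons across datasets require the same `target_mb`. Germline
contamination of the normal, sample swaps and purity shifts are not
modelled and must be caught upstream.
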