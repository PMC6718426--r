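---
title: "Methods: genomic progression analysis of mucinous ovarian carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic progression analysis of mucinous ovarian carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocprog)
```

## The scientific problem

Mucinous ovarian carcinoma (MOC) is a rare ovarian cancer subtype whose
origin has long been disputed: is it a genuine ovarian tumor arising
from benign cystadenoma (BEN) and borderline (MBT) precursors, or occult
metastasis from the gastrointestinal tract? Resolving this requires
cohort-scale genomics: somatic mutation profiles and burdens, mutational
signatures, copy-number aberration (CNA) load, structural variant (SV)
spectra, and comparison of event frequencies against other tumor types.
`mocprog` implements that analysis stack as a tested, reusable pipeline.
Patient-level data of this kind are access-restricted, so the package
pairs every analysis stage with a synthetic cohort generator that
emulates the statistical structure of such a cohort — benign through
grade 1–3 progression — with full ground-truth labels, making each stage
falsifiable.

## The filtering cascade

Multi-caller variant lists (UnifiedGenotyper, Platypus, VarScan,
VarDict, MuTect2) are reduced to high-confidence somatic calls by a
conjunctive cascade (`classify_variant()`, `filter_cohort()`):

1. population allele frequency above $10^{-4}$ in any reference
   resource excludes the variant, unless ClinVar classifies it
   pathogenic (the annotation travels as the *maximum* AF over the
   resources, so the disjunctive exclusion reduces to one comparison);
2. QUAL $\ge$ 30, depth $\ge$ 10, variant reads $\ge$ 2, tumor VAF
   $> 0.05$; the targeted panel tightens depth to $\ge$ 20 and variant
   reads to $\ge$ 10;
3. with a matched normal: normal VAF $\le 0.05$;
4. gene blacklist, panel-of-normals (reject when seen in more than one
   germline exome), cohort recurrence (reject above 20% of cases,
   hotspots such as KRAS codon 12 exempt);
5. caller concordance: VarScan-only calls are rejected everywhere;
   UnifiedGenotyper-only calls are rejected when no matched normal
   exists; calls must pass the callers' own filters; panel calls must be
   absent from the three batch normals.

Rules are conjunctive, so their order affects only the order of
reported reasons. Absent quality fields *fail* their rule — "high
confidence" semantics — rather than passing silently. Whole-genome
calls run through the paired-exome rule set. Mutation burden divides
kept coding/splice calls in panel genes by the 2.07 Mb capture
footprint, putting all platforms on a common scale.

One deliberate reading: the population-frequency rule as usually
printed ("excluded if present at an allele frequency of $\le$ 0.0001")
would exclude only ultra-rare variants, the opposite of its intent; the
cascade excludes variants *above* the cutoff, which is the direction
under which a ClinVar rescue is meaningful. The cutoff is configurable
in `moc_thresholds()`.

## Mutational signatures

`build_catalog()` tabulates SNVs into the 96 trinucleotide channels
(pyrimidine-strand convention; purine-reference variants are folded by
reverse complement). Two estimation routes are provided:

* `refit_signatures()` — greedy forward selection against a reference
  signature matrix: at each step the signature whose admission most
  reduces the squared reconstruction error (weights by non-negative
  least squares) is added, stopping below a $10^{-3}$ relative
  improvement; weights under the sparsity cutoff (0.06, the
  conventional default for signature refitting) are zeroed and the
  survivors refitted. Deterministic.
* `discover_signatures_nmf()` — de novo discovery with multiplicative
  -update NMF minimizing Frobenius error, default $k = 3$ and 50 seeded
  restarts. The multiplicative update guarantees a non-increasing
  error, which the implementation records per iteration and the tests
  assert.

Because no published reference signature table ships with the package,
`synthetic_signature_set()` provides a clearly-labelled synthetic
stand-in whose columns have the qualitative character relevant here: an
age-related C>T-at-CpG process, the two APOBEC processes (C>T and C>G
at TpC), a broad C>A signature and a flat background. Tests and the
acceptance script plant and recover these; analyses of real data should
substitute the published catalog via `signature_set()`. Exome-vs-genome
trinucleotide renormalization is not applied (no flag is set by
default); catalogs are compared on raw channel counts.

## Copy number

Segment log2 ratios are discretized at $\pm 0.2$ (gain/loss), $> 0.6$
(high-level amplification) and $< -1$ (homozygous deletion); boundary
values go to gain/loss, with strict inequalities reserved for the
extreme classes. The fraction of genome altered (FGA) is the mean over
build chromosomes of the per-chromosome fraction of bases under a
non-neutral call; copy-neutral LOH is excluded because the statistic
counts bases *changed in copy number*. The default build is hg19
autosomes + X — 23 denominators, matching the chromosome count used to
derive the per-region significance bound $0.05 / 23 \approx 0.002$
(reported rounded to three decimals, the precision at which it is
applied). Whether to include X is configurable through the build; Y is
excluded in this female-cancer setting.

Profile types are named in the field (simple, simple with one
amplification, complex, complex whole-chromosome, complex with multiple
amplifications) but nowhere operationalized; `classify_profile()`
therefore documents explicit rules: adjacent equal-call segments are
coalesced into events (making classification invariant to how a run was
split); amplifications on $\ge 2$ chromosomes give
`complex_multi_amp` (taking precedence over the whole-chromosome
pattern); otherwise fewer than 10 altered autosomal events is the
simple family (with `simple_one_amp` when exactly one chromosome bears
an amplification); at 10+ events a profile is complex, and
`complex_whole_chr` when $\ge$ 80% of altered bases come from events
covering $\ge$ 95% of their chromosome. All cutoffs sit in
`moc_thresholds()`.

Group comparison (`compare_group_frequencies()`) partitions the genome
at every observed breakpoint and tests each minimal interval and
direction (gain-family vs loss-family) with a two-sided Fisher exact
test — exact at the small group sizes typical here, where the vendor
tool's test is unspecified. Significance requires $p < 0.002$, an
absolute frequency difference $\ge$ 15%, no platform-artifact overlap
and at most 90% copy-number-polymorphism coverage.
`minimal_overlap_region()` intersects per-case unions of amplified
segments to report an amplicon's common core (e.g. a 9p13 amplicon at
33.785–35.159 Mb).

## Structural variants

Breakend pairs on different chromosomes are inter-chromosomal
translocations. Intra-chromosomal deletions, duplications and
inversions are small below 1 Mb (strict), and inversions under 30 kb
are fold-back inversions — the size regime of breakage–fusion–bridge
amplification. Orientation is not part of the call (breakend strand
conventions differ across callers); size alone decides, and
classification is invariant to breakend order. Summaries report
proportions of small-intra, large-intra and inter-chromosomal events,
with the fold-back share given both of all pairs and of inversions.

## Cross-tumor-type taxonomy

`build_event_matrix()` scores binary gene events under per-gene rules —
all non-synonymous mutations for most genes, missense-only for
KRAS/BRAF, inactivating-only for CDKN2A; copy number contributes only
high-level amplifications (ERBB2, MYC) and homozygous deletions
(CDKN2A, SMAD4). The per-grade variant `effect` annotation (missense,
nonsense, frameshift, splice, synonymous) exists precisely to support
these rules; the coarser `consequence` field cannot express them.
`cluster_tumor_types()` clusters frequency columns with Euclidean
distance and complete linkage and reorders the dendrogram by mean
frequency — the default behavior of the standard R heatmap stack —
so another implementation can reproduce the leaf order exactly.

## Cohort statistics

Prevalence of initiating events (KRAS/BRAF/CDKN2A) is reported as
count, fraction and one-decimal percent. Fisher co-occurrence tests
return the conditional-MLE odds ratio with exact CI; the orientation of
the table is part of the output because an OR of 0.12 and its
reciprocal describe the same enrichment. FGA and burden are compared by
two-factor ANOVA (group + platform) with Tukey HSD post-tests. Survival
uses the product-limit estimator and the logrank test; FGA is
dichotomized at the cohort median by default (`median_split()` returns
the cut so it can be logged), and disease-specific survival censors
deaths from other causes. Profile-by-grade tables use Pearson's
chi-square without continuity correction, warning when expected counts
drop below 5. No multiplicity correction is applied across the targeted
co-occurrence tests, mirroring single-hypothesis reporting; users can
apply `p.adjust` downstream.

## The synthetic cohort generator

`cohort_spec()` encodes the study conditions: group sizes (BEN 22,
MBT 39, G1 87, G2 79, G3 24, EOM 23), driver frequencies in carcinoma
(CDKN2A 0.76, KRAS 0.64, TP53 0.64, ERBB2-amp 0.26, RNF43/BRAF/PIK3CA/
ARID1A 0.08–0.12) and TP53 at 0.18 in MBT. Where no value is
established — benign-group driver rates, the passenger Poisson mean
(12 per case), platform mix, FGA noise — the defaults are plausible
choices a cohort of this kind could show, fixed once and documented
here. Per-case FGA is Gamma-distributed around the group mean
(CV 0.35), so configured means are recovered in expectation, and the
gradient BEN < MBT < G1 < G2 < G3 is enforced at spec validation.
Observed VAFs follow binomial read sampling at the drawn depth — the
standard sequencing noise model. Survival is exponential with hazard
$h_0 \exp(\beta \cdot \mathrm{FGA})$ ($\beta = 5$ by default, 0 for
null calibration), administrative censoring at 120 months and a small
other-cause hazard whose deaths are censored.

Artifact classes each violate exactly one cascade rule, and
identity-keyed classes (panel-of-normals, batch-normal,
cohort-recurrent) are placed in reserved position bands of the toy
reference so their variant identities cannot collide with other
simulated variants. That makes "every artifact rejected with its
designated reason, every true somatic kept" an exact, not approximate,
expectation — and the tests assert it with equality.

What the generator does *not* emulate: clonal substructure and
subclonal VAF mixtures, indels and doublet substitutions, read-level
error profiles, segmentation noise, ploidy shifts, and real linkage
between driver genotype and copy-number phenotype beyond the encoded
frequencies. Passing tests therefore demonstrate correctness of the
pipeline's logic under its stated model, not robustness to every
pathology of real sequencing data.

## Numerical and design choices

* Coordinates: variants are 1-based (VCF), segments half-open 0-based
  (BED); conversions happen only at I/O boundaries.
* Degenerate inputs: empty variant tables filter to empty; an empty SV
  set reports absent (NA) proportions rather than zeros; a constant
  frequency matrix clusters into a degenerate tree with a warning;
  zero-count catalogs refuse to refit.
* NMF determinism comes from seeded restarts (`seed + restart index`);
  ties in forward selection resolve to the first minimizer, making
  refitting deterministic.
* Problem sizes in tests and the acceptance script (600-case cohorts,
  1000 FGA oracle profiles, 500 enumerated Fisher tables, 60-catalog
  NMF, 100 survival replicates at n = 200) were chosen to give the
  oracles real discriminating power at desk-scale runtimes.

## Known limitations

Real cohort results that depend on restricted patient data (the
specific ANOVA F, logrank and odds-ratio values of any given cohort)
are reproducible with this package only given that data; the package
validates the *machinery* against oracles and planted truths. The
event-rule table beyond KRAS/BRAF/CDKN2A restrictions is a documented
default, editable per analysis. Fold-back calls use size only;
orientation-aware calling would need caller-specific strand
conventions.
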