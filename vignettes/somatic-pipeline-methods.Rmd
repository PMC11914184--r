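---
title: "Methods: somatic filtering, signature refitting and clonal metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtering, signature refitting and clonal metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpgsomatics)
```

## What this package computes

Multi-sample tumour whole-genome studies of rare cancers — the motivating
case is SDHB-mutant pheochromocytoma/paraganglioma, where patients
contribute a primary tumour, metastases and a matched blood normal — rely
on a set of bespoke computational steps layered on top of standard callers:
consensus acceptance of somatic variants across three callers, cohort-level
artifact blacklists, structural-variant recurrence filtering, mutational
signature refitting, telomere content and telomere-variant-repeat (TVR)
statistics, copy-number summary metrics, and copy-number-aware variant read
probabilities feeding clonal deconvolution. This package implements those
steps as tested, seedable functions, together with a synthetic-cohort
generator that provides ground-truthed inputs for every stage. Raw data for
such cohorts are access-controlled, so the generator — not patient data —
is what the test suite and the demo pipeline run on.

## Consensus and blacklists

A candidate variant is accepted as somatic when at least two of the three
configured callers (vardict, Strelka2, Mutect2 by convention) flag it
`pass`. Two cohort-level blacklists then remove recurrent technical
artifacts:

* **Panel of normals**: every detected somatic variant is pile-up counted
  across all normal samples; a variant supported by at least 3 reads in
  strictly more than 2 normals is removed. The boundary matters: exactly
  two supporting normals keeps the variant.
* **Reject:pass ratio**: all observations of a variant across samples and
  callers — including caller-rejected ones — are pooled; the variant is
  removed when rejects strictly outnumber passes. A variant with passes
  equal to rejects is kept (the rule reads "greater than one"); a variant
  rejected somewhere but passed nowhere has an infinite ratio and is
  removed.

Variant identity is the trimmed, left-shifted `(chrom, pos, ref, alt)` key
after decomposition of multi-allelic records; full reference-guided
left-alignment of indels is out of scope because the consensus module does
not require a reference genome as input. Tumour mutation burden divides the
filtered count by an effective genome size whose default is 3,100 Mb — the
source cohort reports mut/Mb without printing its denominator, so the value
is configurable and only comparable within a fixed choice.

Structural variants get the analogous treatment: an SV key (both breakends,
exact coordinates and orientations, lower coordinate first) observed in
strictly more than two distinct patients — rejected or passed — is removed,
with multiple samples of one patient counted once; surviving calls need 3
split reads, or 3 paired reads, or at least one of each. Orientation is
part of the key: the recurrence filter targets artifacts that reproduce
byte-identical calls, and collapsing orientations would merge genuinely
different junctions.

## Signature refitting

SBS-96 catalogs are built with the pyrimidine-centric convention
(purine-centred substitutions are mapped through the reverse complement)
from a variant list plus reference sequence. Exposures are the non-negative
least-squares solution of `min ||S e − m||₂, e ≥ 0`, computed by a
Lawson–Hanson active-set solver (gradient tolerance `1e-10`); this is the
"optimal linear combination" refit and is deterministic. The solver is
validated against an exact subset-enumeration oracle in the tests. ID-83
catalogs are accepted precomputed — the fit is scheme-agnostic — and the
repeat/microhomology classifier behind them is intentionally not
implemented here.

Cohort reporting applies the display thresholds used for such cohorts: a
signature is reported when in at least one sample it reaches 15% of the
sample's fitted total *and* an absolute minimum of 500 (SBS), 50 (ID) or 10
(DBS) mutations; ranking is by mean proportional contribution with ties
broken by signature id. The 15% threshold is applied to the *fitted*
exposure total, not the raw mutation count — the source text does not
distinguish the two, and the fitted total is what the exposures partition.

A bundled 96-class, 5-column signature matrix (`load_synthetic_signatures()`)
is generated from a fixed seed and labelled synthetic; it stands in for a
reference signature database so no download is needed. It carries no
biological meaning, which is irrelevant to the refit mathematics being
exercised.

## Telomere content and TVR statistics

Telomere content is `intratelomeric reads × 1e6 / GC-matched reads`; the
same formula serves genome (telomere content) and transcriptome (TERRA)
counts. The `1e6` scaling cancels in the tumour:blood ratio but is applied
uniformly so absolute contents are comparable across assays. Enrichment is
a log2 tumour:blood ratio strictly greater than 0.5.

TVR differential usage compares C-circle positive against negative tumours:
per-sample TVR counts normalized by intratelomeric or total reads, the
tumour/blood ratio per pair, and a two-tailed two-sample t-test per TVR
with Benjamini–Hochberg adjustment (raw flag at p < 0.05, adjusted at
p\_BH < 0.1; candidate TVRs are selected on the total-read normalization).
Welch's form is the default — the source names a "Student's t-test" without
specifying pooling, and unequal variances between a dozen positive and many
dozens of negative tumours are the realistic case — with the pooled test
available via `var_equal = TRUE`. C-circle status is a wet-lab annotation
and is never inferred.

## Copy-number metrics and MSI

The GISTIC input transform is the printed formula `log2(CN + 0.01) − 1`.
Note a documentation quirk inherited from the source material: the worked
constant for CN = 2 is sometimes quoted as 0.0072106, but direct evaluation
of the formula gives 0.0071955014 (the CN = 4 and CN = 0 worked constants
do match the formula). This package implements the formula; the tests
freeze the directly evaluated value.

Segments with fewer than 50 markers are joined before export. The join rule
is this package's own choice (the source states only the threshold): the
smallest under-threshold segment merges into the flanking neighbour with
the nearer total copy number (ties to the left), summing markers and
marker-weighting the allele-specific copy numbers, which conserves marker
count and marker-weighted mean copy number per chromosome.

Percent genome altered is judged against sample ploidy, not the diploid
state: a segment is altered when its total copy number deviates from the
rounded ploidy by more than 0.5 (nearest-integer banding; the deviation
rule is this package's convention since only the reference point is
stated). Sex chromosomes are excluded by default. MSI is microsatellite
indels per callable megabase with a strict threshold at 4.

## Variant read probabilities and clone frequencies

For clonal reconstruction, variants detected in any sample of a patient are
recalled in all samples of that patient, and a variant whose alt-read
support falls in the ambiguous band 1..3 in *any* sample is excluded from
*all* samples — zero reads is clean absence, more than three is confident
presence, the band between cannot be told apart from artifacts. "Between
zero and three" is read as inclusive of three and exclusive of zero; the
band edge is a flag (`min_reads`).

The variant read probability ω — the expected VAF of a fully clonal variant
given local copy number and purity — follows the rule table: diploid
segments (major = minor = 1) give 0.5; single copy loss with VAF > purity/2
gives 1; copy-neutral LOH gives 1 when VAF > purity/2 and 1/major below;
every other region gives 1/total. A VAF exactly at purity/2 takes the
1/major branch — the rules only state "greater"/"less", and the lower ω is
the conservative resolution.

Clone frequencies are estimated by expectation–maximization over the
binomial mixture `alt ~ Binomial(total, ω · φ)` with per-cluster,
per-sample frequencies φ. This is an explicit simplified stand-in for full
clone-tree inference (tree search and manual cluster refinement are not
reproduced); it is validated purely by parameter recovery on simulated
data. The M-step is a one-dimensional weighted binomial MLE per
(cluster, sample) solved by golden-section search with the interval
endpoints kept in contention; the observed-data log-likelihood is
non-decreasing per iteration, and a fixed multi-start schedule derived from
the seed makes results deterministic.

## The synthetic cohort: what it emulates, and what a green test proves

The generator expands one root seed into fixed per-stream substreams
(calls, reads, telomere, catalog, sv, cn, msi) so adding a generator never
shifts another's draws; identical seed and configuration give byte-identical
fixtures. Its stated world:

* **Calls**: true variants are private to one patient, detected by each
  caller independently at sensitivity 0.95, and always `pass`; artifacts
  recur across samples (rate 0.5 per sample), are rejected with
  probability 0.6, and 60% of them receive ≥3 reads in more than two panel
  normals. Artifacts are the *only* source of panel support and reject
  labels, which makes blacklist precision and recall exactly computable.
* **Reads**: depth is Poisson(60) truncated at 1 — no overdispersion model
  is claimed by the source, so the simplest one is the default — and alt
  reads are Binomial(depth, ω·φ) on a linear clone chain with child ≤
  parent fractions per sample. The generator evaluates the ω rule at
  VAF = purity (a fully clonal variant on the retained allele), breaking
  the circularity that the rule's CN-LOH branches condition on the VAF the
  read counts will later produce.
* **Telomere**: blood intratelomeric counts at 300 per million GC-matched
  reads (2×10⁶ GC-matched reads per sample); `enriched`/`alt_like` tumours
  scale the rate by 2¹·⁰, and `alt_like` additionally multiplies the
  canonical TTAGGG share (baseline 0.90 over a 10-pattern NNNGGG panel) by
  0.7. `alt_like` samples are C-circle positive.
* **Catalogs**: multinomial draws from a signature mixture with exact
  ground-truth exposures `n · mix`.
* **MSI**: uniform indel rates over 0.1–1.5 indels/Mb across 2,800
  callable Mb.

These values were chosen once as a realistic desk-scale world and are not
tuned against test outcomes. The generator deliberately omits much of real
data: no read-level error model, no mapping artifacts with positional
structure, no subclonal copy number, no overdispersion, no contamination
between the artifact and true-variant populations. A green recovery test
therefore establishes that the rules and estimators are implemented
correctly and behave as designed under their own model — not that they
would achieve the same operating characteristics on real WGS data, and not
any cohort-level biological claim of the motivating study.

## Numerical choices and degenerate inputs

* NNLS: active-set gradient tolerance `1e-10`; all-zero signature columns
  and scheme mismatches are errors; the zero catalog returns zero
  exposures with zero residual.
* EM: probabilities clamped to `[1e-12, 1 − 1e-12]`; five restarts by
  default; `k` larger than the variant count is an error; all-zero alt
  reads give φ = 0.
* t-tests on constant groups are reported as `NA` rather than raised;
  t = 0 yields p = 1.
* Enrichment, MSI and reject:pass comparisons are strict inequalities at
  their thresholds, matching the quoted wording.
* `round()` (banker's rounding) is used for the PGA ploidy reference;
  half-integer ploidies are ties and effectively do not occur.
* Zero denominators (GC-matched totals, callable megabases, total copy
  number 0, blood content 0) are errors, not NA propagation.

## Known limitations

* The ID-83 and DBS-78 classifiers are not implemented; those catalogs
  must be supplied precomputed.
* The clonal module estimates cluster frequencies only; no tree topology,
  no clonal-diversity statistic (the source never defines one).
* The recurrence filters match exact coordinates; fuzzy-window matching of
  near-identical artifacts is out of scope.
* The minimal VCF reader/writer round-trips this package's own output; it
  is not a general-purpose VCF parser.
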