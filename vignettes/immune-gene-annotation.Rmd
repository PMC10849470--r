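---
title: "Annotating and typing polymorphic immune genes on assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and typing polymorphic immune genes on assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlakir)
```

This vignette explains the models and procedures implemented in
`hlakir`, the assumptions behind them, the choices we made where the
design was genuinely open, and what the synthetic-fixture validation
does and does not demonstrate about real data.

## The annotation model

The package assumes the input is an *assembled contig*, i.e. each gene
of interest is present as a contiguous, essentially error-free sequence.
Under that assumption allele typing reduces to sequence comparison
against a reference allele database, and the hard part is locating genes
and reconstructing their structure.

Detection aligns every full-length reference allele to the contigs.
Only full-length (intron-containing) records are used here, because exon
structure can only be projected from an alignment that covers introns;
CDS-only records participate later, in typing. Each alignment is scored
by gap-compressed identity `m/(m + d)`, where `d` counts mismatching
bases plus gaps — each gap once, regardless of length. The
gap-compressed convention matters for these loci: alleles frequently
differ by multi-base intronic indels, and counting a 10-bp indel as ten
differences would push a same-allele alignment below any sensible
identity threshold.

Greedy clustering (best alignment first; join on any overlap; skip
alignments bridging two clusters) assumes genes are well separated on
the genome. For HLA- and KIR-class clusters this holds; the procedure
would merge genes that overlap on the contig.

### Thresholds

* `min_query_cov = 0.90` — a gene is only considered detected when at
  least 90% of the reference gene sequence is mapped. Genes cut by
  contig ends fall below this and are reported as detected-but-untypable
  rather than silently dropped or half-typed.
* `min_gci = 0.97` — alignments below 97% gap-compressed identity never
  define gene structure. Both thresholds are configurable in
  `run_config()`.
* `c4_long_threshold = 5000` bases of intron 9 separate the C4 long and
  short forms; the comparison is strict (`> 5000`), so exactly 5 kb is
  short-form.

### Template selection and liftover

Within a cluster, candidates are classified into four priority tiers:
perfect alignment; CDS fully aligned and gapless; CDS fully aligned but
frameshifted; CDS partly unaligned. Two reading decisions were open
here:

* *Frameshift detection is per indel*: an indel inside the CDS whose
  length is not divisible by three makes the candidate tier (c). A
  candidate whose CDS indels are all in-frame is neither "without gaps"
  nor "with frameshifts", and lands in tier (d).
* *"Alignment length" is counted in aligned query bases* (gaps
  excluded), both for ranking alignments and for ranking CDS matches.
  Query basis keeps the ranking consistent with query coverage, which
  uses the same denominator.

Liftover projects each template exon boundary through the alignment.  A
boundary whose query base has no aligned target base (inside a deletion
from the target) snaps to the nearest aligned base on the exon-interior
side, keeping lifted exons maximal within their aligned portion; the
annotation is flagged `partial` and excluded from typing when any CDS
base is unaligned. Internally all coordinates are 0-based half-open;
conversion to 1-based inclusive happens only in the GTF writer.

### Typing and novel-allele naming

Typing compares the extracted CDS against every CDS record of the gene:
full-length records by unit-cost Levenshtein edit distance (the
reference notion of "edit distance" with no stated weights), partial
records only when contained in the target CDS without mismatch. A
contained partial scores distance 0 over its own length, so an
equally-distant full-length record always outranks it — a partial can
only win when no full record explains the CDS as well.

Novelty is resolved layer by layer: translate the CDS (standard code,
frame 0) and compare proteins — a difference is a field-2 novelty; else
a CDS difference is field-3; else (CDS identical, full gene imperfect)
field-4. Decisions taken where the naming rules are underdetermined:

* Pseudogenes have no protein layer; their deepest distinction is
  field 3 versus field 4. An untranslatable CDS of a coding gene
  (internal stop, broken frame) is named at the CDS layer and flagged
  `incomplete_orf`.
* When the best matches' common name prefix is shorter than the affected
  field, `new` goes to the field after the deepest shared field, capped
  at field 4 (e.g. best match `*01:01`, non-coding difference →
  `*01:01:new`). The reported `novelty` enum always reflects the
  affected *layer*.
* Ties are joined with `/` in the call string when the call is exact;
  novel calls always produce a single consensus string.
* KIR-style names are parsed as fixed-width 3/2/2 digit fields; this is
  configurable per gene family (`nomenclature`), since the dialect is a
  property of the database, not of the algorithm.

## Alignment engines

The pipeline only requires an engine that returns base-level alignment
operations. The default internal engine seeds exact 21-mers, groups
seed hits by diagonal, and resolves each locus either gaplessly (single
consistent diagonal — a byte-wise comparison) or, when diagonals
disagree, by affine-gap dynamic programming (match 1, mismatch −2, gap
open −4, gap extend −1) on a padded window, for sequences up to 50 kb.
A minimap2-based engine and a PAF reader (`read_paf()`, cs/cg tags) are
provided for production-scale contigs; the test suite cross-checks that
both engines report identical perfect loci on planted fixtures.

The internal engine's seed-and-diagonal design deliberately trades
sensitivity for speed and determinism: it will miss a locus whose every
21-mer is mutated (irrelevant at ≥97% identity) and hands loci with
large structural differences to the DP fallback.

## C4

C4 typing uses a different route because the A/B distinction is carried
by a handful of residues, not by overall similarity. The reference
transcript's exons are placed individually (allowing a small mismatch
budget, 6% of exon length) and chained colinearly; multiple gene copies
per contig emerge as multiple chains. The four diagnostic exon-26
residues and the A/B motifs are *configuration data*
(`c4_config()`), not hard-coded: the mechanism is fixed, the residues
travel with the reference release. Exon-28 SNPs, which separate most
but not all C4A/C4B genes, are deliberately not used for the primary
call. Only an exact match to one motif types a gene; chimeric motifs
and broken frames are `ambiguous` with a reason.

## Companion statistics

**CDS diversity** is the mean pairwise Hamming fraction over aligned
CDSs (per sample: mean distance to the other samples of its population;
per gene: mean over all within-population pairs). The package consumes
a pre-computed alignment; computing MSAs is out of scope.

**The permutation test** uses the statistic mean(between-group
distance) − mean(within-group distance), permutes labels (default
`n_perm = 10000`, seeded), and applies add-one smoothing
`p = (1 + k)/(1 + n_perm)`, so p is never exactly zero and the test is
exact-level under exchangeability. Gene-wise p-values are Bonferroni
adjusted.

**Deletion genotyping** normalizes depth twice: by half the
within-sample control median (making a two-copy gene ≈ 2 regardless of
sequencing depth — the genotypes are exactly invariant to scaling one
sample's depths), then by the cross-sample median rescaled to 2
(assuming most samples carry two copies — the procedure would mis-center
if more than half the cohort carried a deletion). Copy-number calls use
midpoint thresholds (deleted < 1.5, amplified ≥ 2.5), configurable; the
reference material shows clusters but prescribes no cutoffs.

**Copy-number inference** square-root-transforms abundances, calibrates
a single-copy component on the smallest 30% of values pooled with
optional anchor genes (HLA-A/B/C, or the KIR framework genes
3DL3/2DL4/3DP1/3DL2, expected to contribute one copy per heterozygous
allele), and assigns each allele the `c` (1..`c_max`, default 6)
maximizing the scaled-normal likelihood with mean `c*mu` and sd
`c*sigma`. Two implementation decisions:

* The smallest-30% subset is a *lower tail*, so its naive mean and
  standard deviation are biased low. The fit therefore maximizes a
  truncated-normal likelihood (truncation at the calibration cut-off)
  for tail points, with anchor points entering untruncated. On
  simulated data this recovers `mu` and `sigma` essentially unbiased,
  where the naive moments underestimate both.
* When anchors are provided they are pooled with the 30% subset rather
  than replacing it.

## The synthetic-fixture generator

The generator defines the package's validation conditions. Defaults:
five genes, four alleles each, gene lengths 3–15 kb with 3–8 exons and
CDS lengths 300–1500 bp — inside the range spanned by real immune genes,
whose CDSs run from 161 bp (single-exon pseudogene-class genes) to a
5.4-kb transcript (C4). Each gene's allele set spans the nomenclature
hierarchy by construction: an intronic sibling (identical CDS), a
synonymous sibling, and a second allele group two nonsynonymous changes
away. Planted mutations draw from site pools reserved at generation
time, so the expected call for every placement is derived from the
naming rules, not hand-typed: exact plants must return their own name,
intronic SNPs a field-4 `new`, synonymous SNPs field-3, nonsynonymous
field-2, and a SNP at one of the group-diagnostic sites makes the CDS
equidistant from both groups, forcing `<gene>*new`. The depth simulator
reports the *median* per-base Poisson depth over a region, because that
median is exactly the statistic the genotyper consumes; single-draw
Poisson noise would overstate the noise of a regional median.

What the fixtures do **not** emulate: repeats and segmental
duplications (alignment confusability), assembly base errors,
recombination or gene conversion between alleles, realistic haplotype
structure, and GC/coverage biases in sequencing depth. Passing the
fixture suite therefore demonstrates the correctness of the algorithmic
pipeline — clustering, liftover, typing, naming, and the statistical
estimators — under clean inputs, not robustness to messy assemblies.
Production contigs should use the minimap2 engine.

## Validation scales

The test suite runs entirely on generated fixtures: 210 planted
placements across 10 randomized databases (expecting 100% call
recovery, including multi-copy loci and truncated genes), 100 planted
C4 isotype motifs, a 300-allele copy-number simulation
(`sigma = 0.1 mu`, copies 1–3, ≥95% recovery), a 100-sample depth cohort
with 20% hemizygous deletions at 30× (≥95% genotype recovery), and 1000
null replicates × 1000 permutations for the type-I error of the
permutation test (within two binomial standard deviations of
`alpha = 0.05`). `scripts/acceptance.R` recomputes the same quantities
at slightly reduced replicate counts from a single `--seed`.

## Known limitations

* Incomplete genes (contig breaks, < 90% mapped) are surfaced as
  untypable loci but never typed; a cohort with many fragmented
  assemblies will undercount alleles.
* A very large novel indel can fragment the seed diagonals beyond the
  DP window and lose the locus; the engine warns when it skips one.
* Greedy clustering assumes well-separated genes; overlapping or fused
  genes produce a single cluster and at most one call.
* The copy-number model assumes abundances scale additively with copy
  number and that the calibration subset is dominated by single-copy
  alleles; it mis-calibrates if most alleles are multi-copy.
* G-group/P-group reduction, expression suffixes, UTR inference beyond
  template projection, and MSA/tree construction are out of scope.
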