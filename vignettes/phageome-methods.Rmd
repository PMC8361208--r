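---
title: "Quantifying and comparing gut phageomes from read recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing gut phageomes from read recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageome)
```

## The analysis this package implements

Virus-like-particle (VLP) metagenomes of the human gut are dominated by
bacteriophages, and their community structure shifts with host conditions
such as childhood obesity (O) and obesity with metabolic syndrome (OMS).
Because most gut phages have no reference genome, the analysis is built on a
*de novo* contig catalog rather than taxonomic profiles: per-sample reads are
recruited back to the contigs, the contig set is cleaned of assembly
artifacts, and all downstream community statistics operate on the resulting
contig-by-sample matrix. This package implements that quantification and the
comparative statistics, with a synthetic-data generator that plants known
truth for every analysis.

The stages, each exposed as a function and orchestrated by `run_pipeline()`:

1. **Read recruitment** (`parse_alignments()`, `filter_alignments()`).
   Mapped primary SAM records are reduced to alignment statistics; a read
   counts only if its NM-based identity is at least 90% and at least 80% of
   its bases are aligned. Identity is `(span - NM)/span` where the span
   counts aligned columns including indels — the standard convention when an
   aligner reports only the edit distance. The "80% length" rule is read as
   aligned query bases over read length (soft clips excluded, insertions
   included), the only read-intrinsic length available after mapping. Only
   primary alignments are counted so a read contributes at most once per
   sample; a multi-mapping mode is deliberately not offered because the
   recruitment matrix would otherwise double-count.
2. **Contig filters** (`coverage_profiles()`, `chimera_filter()`,
   `length_filter()`, `dereplicate_contigs()`). A contig is kept only if, in
   at least one sample, recruited reads cover at least 80% of its length at
   1x or better (contigs never attaining that anywhere are treated as likely
   chimeric), and if it is at least 4 kb long — a threshold that removes
   fragmented genomes and most small eukaryotic viruses while retaining the
   shortest complete phage genomes. Both bounds are inclusive, and the two
   filters commute. Redundant contigs are collapsed at 95% identity keeping
   the longest representative.
3. **Abundance** (`build_abundance()`). Counts are normalized to RPKM —
   reads per kilobase of contig per million *sequenced* (not mapped) reads
   in the sample — so that values are comparable across contig lengths and
   library sizes. Raw counts are retained alongside: differential abundance
   and rarefaction need them.
4. **Taxonomy** (`filter_hits()`, `assign_lca()`, `classify_contigs()`).
   Homology hit tables (nucleotide first, protein for contigs the nucleotide
   search could not classify) are filtered MEGAN-style — minimum bitscore
   40, maximum e-value 0.01, then a 10% top-percent band per query — and the
   query is assigned the lowest common ancestor of the surviving hits
   (minimum support 1). The prokaryotic/eukaryotic virus split is a curated
   node attribute of the taxonomy file, not inferred from names; a contig
   whose retained hits span both categories is `ambiguous`, one with no
   surviving hits `unknown`. The named MEGAN complexity filter has no
   published definition at contig level and is omitted rather than
   approximated.
5. **Diversity** (`rarefy_counts()`, `shannon_index()`, `alpha_diversity()`,
   `bray_curtis()`, `pcoa_ordination()`, `clr_transform()`,
   `permutation_group_test()`, `group_compare()`). Alpha diversity is the
   per-sample median of observed contigs and Shannon diversity (base 2) over
   repeated rarefactions at the depth of the smallest sample. Rarefaction
   is ill-posed on RPKM (it is not integer), so it operates on the raw count
   matrix; this is the one place the package knowingly deviates from a
   literal reading of its sources, for the stated reason that sampling
   without replacement requires counts. Beta diversity is offered both as
   Bray-Curtis and as Aitchison distance (Euclidean on the centered
   log-ratio transform with a 1e-7 offset); group structure is tested with
   ANOSIM and PERMANOVA (vegan) using add-one permutation p-values, and
   univariate contrasts use Shapiro-Wilk reporting followed by pairwise
   Mann-Whitney tests (exact when both groups have at most 8 tie-free
   values, tie-corrected normal approximation without continuity correction
   otherwise — so fully tied data give p = 1).
6. **Prevalence structure** (`presence_matrix()`, `classify_prevalence()`,
   `unique_sweep()`, `prevalence_shift()`, `dominant_set()`). Detection is
   either coverage-based (80% of the contig at 1x in that sample) or
   nonzero-count. Contigs are classed core (prevalence > 80%), common
   ((50%, 80%]) or individual (at most 50%); the half-open boundaries are a
   choice this package makes so the classes partition every cohort size —
   for 28 samples the 80% boundary falls between integers and the choice is
   immaterial. The unique-contig sweep asks, at each cutoff, which contigs
   are present in at least that fraction of one group and absent from all
   others; since these sets shrink as the cutoff grows, the "recommended"
   cutoff is defined as the most stringent one that still attains the
   maximal total — ties between 20% and 30% resolve to 30%, matching how
   such a sweep is reported in practice.
7. **Differential abundance** (`size_factors()`, `nb_differential()`).
   Median-of-ratios size factors (reference contigs = those with positive
   counts in every sample; sparse virome matrices often have none, in which
   case geometric means over positive counts only are used — a documented
   fallback), a per-contig gamma-Poisson dispersion estimated by moments and
   floored at 1e-8, a two-group log-link negative-binomial mean fit by IRLS
   (for this saturated design the iterations converge to the group means),
   and a Wald test on the log2 fold change with Benjamini-Hochberg
   adjustment. A contig is flagged over-abundant when its estimated log2
   fold change is at least 2, its adjusted p at most 0.05, and it is
   detected in at least 30% of the target group (removing
   individual-specific contigs). This is a re-implementation, not a
   bit-compatible copy of DESeq2; the test suite cross-checks size factors
   and fold-change estimates against DESeq2 on dense fixtures and validates
   the screen by planted-truth recovery and FDR behavior.
8. **Correlation screens** (`correlation_screen()`). Spearman correlations
   (average ranks; exact p below n = 10 without ties, t-approximation with
   n - 2 degrees of freedom otherwise) between contig RPKM and bacterial
   taxa or clinical covariates. A pair is *selected* when rho^2 > 0.3 and
   the unadjusted p is at most 0.05; BH-adjusted values are reported
   alongside because at cohort sizes near 28 no pair survives FDR control
   and the screen is explicitly a tendency-finding device.

## Sequence clustering and read-level richness

`greedy_cluster()` implements greedy incremental clustering in the CD-HIT
style: sequences sorted by decreasing length (ties by id so results are
deterministic), each joining the first representative it matches at the
identity threshold, else founding a new cluster. Identity is the number of
identical bases in the optimal fit alignment of the shorter sequence against
the longer, divided by the shorter length (match +1, mismatch -1, gap -2,
free end gaps on the longer sequence). Among co-optimal alignments the
match-richest is used, which makes the value well defined; for equal-length
pairs both role assignments are evaluated and the better kept, which makes it
symmetric. A shared-k-mer prescreen (k = 8) skips pairs that provably cannot
reach the threshold — the bound assumes each of the at most `(1-t)*L` edits
destroys at most k k-mers — and the test suite asserts prescreened and
non-prescreened runs are identical, and that the whole procedure matches a
brute-force reference built on an independent aligner.

`subsampled_richness()` repeatedly subsamples each sample's reads without
replacement at a common depth, clusters each subsample at 95% identity, and
reports the per-sample median cluster count: a taxonomy-free richness
measure at even sequencing depth. Mates of a pair are treated as independent
reads. The original design used 1,000 subsamples of 149,000 reads; this
package's tests run the same estimator at desk scale (tens of subsamples,
depths up to a few thousand), which exercises every property of the
estimator except wall-clock endurance.

## What the synthetic generator emulates — and what it does not

`synth_community()` produces a cohort of 10 NW / 10 O / 8 OMS samples over a
catalog of 400 contigs with log-uniform lengths between 4 kb and 176,210 nt
(the span observed in real gut virome assemblies), plus 15% extra
low-abundance contigs present only in the disease groups (the planted
richness inflation). Counts are negative-binomial (dispersion 0.1) around
means that scale with contig length and a log-normal abundance profile
(sigma 1.2), with per-sample library-size jitter. Background presence is a
mixture — roughly a quarter of contigs common (55-95% prevalence), the rest
individual-specific (5-50%) — mirroring the prevalence structure reported
for real gut phageomes, where three quarters of contigs appear in fewer than
half the subjects.

Planted features use *balanced* presence (exactly the target number of
positive samples per group) so the planted truth is exact rather than
in expectation: a 16-contig core present everywhere; group-unique contigs at
50% within-group prevalence; 24 differential contigs at 90% within-group
prevalence with log2 fold changes uniform in [2, 3], split 34% / 19% / 47%
between O-only, OMS-only and shared (the proportions seen in the real
cohort); and the richness block at 70% prevalence in O and OMS. Differential
contigs are planted at 90% — prevalent, but with at least one zero per group
— so they never enter the all-positive reference set of the size-factor
estimator; an early version of the generator planted them at 100% and the
resulting reference-set contamination biased every fold-change estimate
downward, which is exactly the failure mode median-of-ratios is known for
when a large share of reference features is differential. Core and
differential contigs are floored at a planted mean of 100 reads per present
sample, so the differential screen is limited by biological dispersion
rather than counting noise. Covariates come from a Gaussian copula: the
covariate's normal score is correlated with the contig's normal score at
`2*sin(pi*rho/6)`, which targets the Spearman correlation `rho` exactly in
rank space; taxa tables are closed to sum 1.

What the generator does *not* emulate: real phage genome composition (reads
are uniform random DNA with substitution-only errors), indel or quality
errors, shared k-mer content between unrelated contigs (so ambiguous
mappings never occur), compositional coupling between phage and bacterial
abundances beyond the planted pairs, and confounding between library size
and group. Tests passing on this generator therefore demonstrate that the
statistics recover structure *of the planted kind* at the planted effect
sizes — not that the pipeline is robust to mapping artifacts or
batch structure in real data.

`synth_alignments()` realizes the planted counts as SAM records. Every
planted count becomes a read passing the filters (edits
Binomial(length, 0.02), capped at 10% of the read); decoys are planted to
fail exactly one filter each (15% edits, or 25% soft-clipped). Reads of
chimera-like contigs are confined to the first half of the contig, so those
contigs can never reach 80% coverage; for every other contig-sample pair
with enough planted reads, a deterministic tile covers the full contig so
that chimera-filter outcomes are a function of the planted structure rather
than of placement luck (remaining reads are uniform). This is the one place
read placement departs from uniform, traded deliberately for construction
guarantees.

## Numerical choices and degenerate inputs

* Rarefaction uses an exact multivariate-hypergeometric draw
  (`sample.int` over pooled reads, then interval lookup); it errors when the
  requested depth exceeds the sample sum and returns the input unchanged at
  equality.
* Permutation p-values use the add-one estimator `(1 + hits)/(1 + n_perm)`,
  so p = 0 is impossible.
* The CLR offset (1e-7) guarantees positivity; per-sample CLR coordinates
  sum to zero by construction and doubling a sample leaves them unchanged.
* PCoA reports all eigenvalues including negative ones and restricts
  coordinates to non-negative-eigenvalue axes.
* `family_profile()` treats numerically constant profiles (a single family)
  as untestable (NA) rather than significant, and the Kruskal-Wallis
  p-values are corrected with step-down Sidak at alpha = 0.01.
* `nb_differential()` refuses non-integer matrices: differential abundance
  operates on raw counts, never RPKM. All-zero contigs get NA p-values and
  are excluded from the BH adjustment.
* Contigs with zero coverage everywhere simply never appear in coverage
  profiles; the chimera filter treats them as removed.
* In `read_taxonomy()`, cycles and multiple roots are hard errors; category
  labels are restricted to the three known values.

Default problem sizes in the tests and the acceptance script — 400-contig
cohorts, 20-200 rarefactions, 199-999 permutations, 20-seed replication —
were chosen as the smallest sizes at which the planted effects are
comfortably identifiable; all estimators accept the original study's scales
unchanged.

## Known limitations

The NB screen estimates dispersion by moments per contig, with no shrinkage
across contigs; at n = 10 per group its Wald p-values are approximate and
the package relies on the fold-change and prevalence gates (as the original
design does) rather than on exact error control. The ambiguity category
requires retained hits in both virus categories; hits confined to one
category keep that category even when the LCA sits above the curated clade.
The greedy clusterer is quadratic in the number of sequences aside from the
k-mer prescreen and is intended for desk-scale validation, not for
clustering hundreds of millions of reads. Rarefaction on counts (rather
than RPKM) means long contigs weigh more in observed-contig richness than a
length-normalized resampling would allow; the two agree when length and
abundance are independent, which the generator plants but real data may
violate.
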