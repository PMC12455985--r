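---
title: "Assessing genomic stability across cell-culture passages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing genomic stability across cell-culture passages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passageStability)
```

## The problem

Cultured fibroblast lines are an attractive way to bank and amplify genomic
material from wild vertebrates, but every passage — detaching the cells and
reseeding them — gives somatic mutations and culture artifacts a chance to
accumulate. When a single diploid individual is sequenced at passage 0
(primary tissue), again after 5 passages (several replicate flasks), and
again after 10, the question "is the culture still the animal?" becomes a
question about a jointly genotyped multi-sample SNP callset: how many sites
are identical across all samples, how many vary, which variants are unique
to one replicate, and do those unique calls look like real mutations or
like sequencing/calling artifacts?

`passageStability` implements that analysis end to end: reading and
filtering the callset, partitioning and per-sample statistics, a rank-sum
test on the quality of private calls, a handful of assembly/annotation
summary metrics used around such a study, and a seeded simulator that
generates callsets with known truth so every step can be validated without
any external data.

## The callset model

A `callset` is an ordered sample list plus one record per variant site with
per-sample genotype calls (`GT`), depths (`DP`) and genotype qualities
(`GQ`), and seven site-level annotations (`QD`, `FS`, `MQ`, `SOR`,
`MQRankSum`, `ReadPosRankSum`, `DP`) plus `QUAL`. Coordinates are 1-based
throughout, as in VCF and GFF3 — there is no internal 0-based layer to
translate in and out of. Genotypes are stored as ordered allele pairs with
a phased flag, but **all** comparisons use the unordered pair: `0|1` and
`1|0` are the same genotype everywhere in the package. Multi-allelic SNP
records are kept as-is, because genotypes involving a second and third
alternate allele carry real signal in this design. FORMAT fields other than
GT/DP/GQ are ignored on read and not re-emitted; an absent INFO annotation
is stored as absent (`NA`), never as 0.

## Filtering

Site selection and filtering mirror a standard short-read joint-calling
pipeline:

1. `select_snps()` keeps records whose REF and every ALT are single
   nucleotides.
2. `apply_hard_filters()` applies the classical hard thresholds
   (`QD < 2.0`, `FS > 60.0`, `MQ < 40.0`, `SOR > 3.0`,
   `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`, `QUAL < 30.0`). A
   condition on an *absent* annotation never triggers: the rank-sum
   annotations are undefined at sites without heterozygous calls, and
   treating absence as failure would mass-drop hom-alt sites. Failed sites
   are labeled, not deleted, unless `drop_failed = TRUE`.
3. `cohort_depth_filter()` removes sites with total depth outside
   `[min_depth, max_depth]`, and `cohort_maf_missing_filter()` keeps sites
   with `MAF > maf_min` and `F_MISSING <= miss_max`.

The four cohort values are deliberately analyst-visible. Where a study does
not state them, `default_cohort_params()` derives documented stand-ins from
the callset itself: `min_depth = ceiling(mean site DP / 3)`,
`max_depth = 2 * mean site DP`, `maf_min = 0.05` and `miss_max = 0.125`
(at most one missing sample out of eight); all four are echoed into the
callset provenance. MAF is allele-based (the convention of cohort filtering
tools): the frequency of the least frequent *called* allele, minimum over
alleles at multi-allelic sites. A site where only one allele is called has
no minor allele and gets MAF 0 — defining it as the sole allele's frequency
(1) would keep monomorphic sites at any threshold, which cannot be the
intent of a MAF floor. Comparison strictness follows the filter expressions
exactly: strict `<`/`>` for the bounds, `<=` for missingness.

## Passage analysis

`classify_sites()` partitions retained sites into **fixed** (every sample
carries the same non-missing unordered genotype — in a single-individual
design these are dominated by true heterozygous sites of the founder that
the reference represents with one allele) and **variable** (everything
else). Any missing call makes a site variable: missingness has already been
bounded by the cohort filter, and treating it as agreement would hide
exactly the calls one should look at.

Per sample:

* `private_sites()` — sites where the sample's genotype is non-missing and
  found in no other sample. These are the candidate replicate-specific
  mutations, or artifacts.
* `deviant_sites()` — variable sites where the sample departs from the
  cohort consensus. The consensus (modal) genotype at a site is the most
  frequent non-missing genotype *provided at least two samples share it*;
  ties among equally frequent shared genotypes are broken by the smallest
  recode value (below), then lexicographically. If no genotype is shared
  by two samples there is no consensus and every sample is deviant there.
  The count >= 2 requirement is what makes the natural containment
  `private` &sube; `deviant` &sube; `variable` hold: a unique (private)
  genotype can never *be* the consensus. A missing call is deviant.
* `diff_vs_reference()` — the number of sites at which two samples'
  unordered genotypes differ; a one-sided missing call counts as a
  difference, a site missing in both does not. The count is symmetric and
  zero on the diagonal.

`recode_genotype()` maps unordered genotypes onto small integers
(`0/0 = 0`, `0/1 = 1`, `1/1 = 2`, `0/2 = 3`, `1/2 = 4`, `2/2 = 5`,
`0/3 = 6`) for compact matrix display (`recode_matrix()`,
`plot_recode_matrix()`). Pairs outside that domain — and missing calls —
map to a sentinel `NA`; a fully called out-of-domain pair additionally
warns, because it usually signals an unexpectedly allele-rich site.

`passage_table()` assembles the per-sample report: median DP and GQ over
the sample's called sites, deviant (`nonfixed_count`) and private counts,
the deviant count as a percentage of the genome (4 decimal places), how
many deviant genotypes are `0/1` and how many are neither `0/1` nor `1/1`
(`other_count`, with its share of all retained sites), and the count and
percentage (2 decimal places) of sites differing from the reference sample.
Percentages round half-to-even at the stated precision, matching how such
tables are conventionally printed. Medians over an even number of values
are the midpoint of the two central values. The `pct_nonfixed` column is
flagged in the table's metadata attribute: published analogues of this
column are not internally consistent about scale, so this package commits
to the percent definition (100 · other_count / retained sites) and says so
rather than reproducing a mixed-scale column. The deviant-site definition
itself is one of several defensible readings of "sites other than the
shared heterozygous background"; the modal-consensus reading implemented
here is recorded in provenance wherever the table is produced.

### Private-site quality

If a replicate's private calls are genuine mutations, their depth and
genotype quality should look like everyone else's; if they are artifacts,
both tend to be depressed. `compare_private_quality()` runs a two-sided
two-sample Mann-Whitney rank-sum test of the sample's per-site DP (or GQ)
at private sites against all its other retained sites. The choice of a
two-sample test (rather than a one-sample test against a grand mean)
follows from the question actually asked — are private sites *different
from the other sites* of the same sample?

`rank_sum_test()` is exact by full enumeration of all
`choose(n1 + n2, n1)` group assignments when `n1 + n2 <= 12` — unlike the
classical exact distribution, enumeration remains correct under ties,
which are the norm for integer depths — and otherwise uses the normal
approximation with tie correction and continuity correction. The exact
two-sided p-value is the probability of a U at least as far from its null
mean `n1·n2/2` as observed. The crossover at 12 keeps the enumeration
below a thousand assignments (`choose(12, 6) = 924`); the test suite
checks that both branches agree on pools of exactly 12.

## Genome and annotation metrics

Small, self-contained computations that accompany such a study:
`qv_to_error()` / `error_to_qv()` (Phred: `err = 10^(-QV/10)`),
`het_per_kb()` (a 0.2% heterozygosity is 2 het sites per kb),
`assembly_stats()` (N50/L50/N90/L90 by the cumulative-sum definition, GC
and N density from residues), `classify_chromosomes()` (avian macro- vs
microchromosomes at a 30 Mb cutoff; the boundary length itself is assigned
to the macro class, and both the cutoff and thus the boundary side are
configurable), and `gene_class_summary()` (per-class gene counts, genes
per Mb of summed class length, mean gene length from the gene feature
span, mean intron length and exon count of the retained transcript). One
transcript is retained per gene — largest summed exon length, ties by
lexicographically smallest transcript ID — mirroring a longest-isoform
reduction. Exons are sorted by start before introns are computed (GFF3
files legitimately list minus-strand exons in transcription order);
overlapping exons within a transcript are a fatal annotation error.

## The simulator

`sim_config()` / `scenario_study()` describe the study design the package
defaults to: one diploid founder with heterozygosity 0.002 per bp, samples
= one passage-0 primary-tissue lineage, an optional HiFi-like second
reference sample (included by default, giving the 9-sample layout), three
independent replicate lineages at passage 5 and four at passage 10; read
depth Poisson with mean 27; GQ saturating at 99; missing calls at 0.002
per genotype; artifact calls at 0.001 of retained sites per sample with
depth shifted by −10 and reduced GQ.

Two defaults deserve justification, because nothing in the study system
pins them down:

* **Mutation rate** `mu = 1e-6` per bp per passage. Real per-passage
  somatic rates for avian fibroblast culture are unknown; this value is an
  order-of-magnitude placeholder chosen so that a 1 Mb simulated genome
  accumulates ~5–10 detectable mutations per passage-10 replicate — enough
  to exercise every code path without swamping the founder signal. Treat
  absolute simulated mutation counts as arbitrary; ratios and detection
  properties are what the simulator is for.
* **Genome length** defaults to 1 Mb (the test suite uses 1–5 Mb
  depending on how many sites a property needs, e.g. ~10,000 sites for the
  filter-oracle and round-trip checks, 4 Mb for the artifact-power runs).
  The simulated genome is a scaled-down stand-in: every rate is per-bp, so
  the statistical structure (site density, replicate design, artifact
  behaviour) is preserved while simulation stays fast.

`simulate_truth()` draws founder het sites Bernoulli per bp, then lets
each replicate lineage independently accumulate
`Poisson(mu · L · passage)` mutations at uniform positions: a hom-ref
position becomes a heterozygote with a new allele; a founder het site
moves, with equal probability, to `0/0`, `1/1`, or a heterozygote
involving a new allele. Novel allele indices are assigned per site in
order of appearance and capped at 3, so the recode domain — and its
sentinel overflow — are both exercised. Replicates are modeled as fully
independent lineages from passage 0; the real split schedule of replicate
flasks is rarely known, and independence is the conservative choice for
concordance analyses. Artifact positions are drawn at positions hom-ref in
every sample (count Binomial(retained sites, `artifact_rate`)), so the
three per-sample truth classes — founder het, lineage mutation, artifact —
are disjoint by construction and every emitted record is explained by
exactly one class per sample. `simulate_callset()` turns the truth into a
`callset` (and optionally a VCF); site annotations come from configurable
truncated normals whose defaults pass the hard filters — they exist to
exercise filter logic, not to model a variant caller faithfully.
Everything is byte-for-byte deterministic under `seed` (the callset's
random stream is seeded from `seed` with a fixed offset so truth and
callset draws do not interleave).

`simulate_annotation()` builds a toy macro/micro genome (two chromosomes
above the 30 Mb cutoff, four below) with a requested micro/macro gene
density ratio and intron-length ratio, places genes non-overlapping, and
records the *realised* ratios so recovery tests compare against what was
actually generated.

### What the simulator does not capture

No read-level errors, no mapping, no indels or structural variants (the
karyotype-stability motivation for this kind of study argues large events
are better assessed cytogenetically), no selection within the culture, no
faithful GATK annotation distributions, and no site-to-site depth
correlation. Passing tests therefore demonstrate that the *analysis logic*
is correct and that effect signatures (private-site depth/quality deficits,
density/intron contrasts) are recovered when present — not that any
particular real dataset will show them.

## Numerical choices, in one place

* Rounding of report percentages: `round()` (half-to-even) at 4 dp for
  genome fractions, 2 dp for difference percentages, 3 dp for the
  `pct_nonfixed` column.
* Median of an even count: midpoint of the central pair.
* Exact rank-sum enumeration up to pooled size 12; tie + continuity
  corrected normal approximation beyond; enumeration comparisons use a
  1e-9 slack so floating-point midrank sums never flip an inequality.
* Modal-genotype ties: smallest recode value, then lexicographic allele
  pair; consensus requires the mode be shared by >= 2 samples.
* 30 Mb boundary length classifies as macro.
* Degenerate inputs: empty callsets round-trip as header-only VCFs;
  all-missing sites have undefined MAF and are removed (and counted);
  a sample with no private site is a hard error in
  `compare_private_quality()` rather than a silent p = 1.

## Known limitations

Filter provenance is carried as free-text header lines rather than a
structured log; `gene_class_summary()` resolves no overlapping-gene
double-counting (density denominators are whole-class lengths); and the
deviant-site definition, while documented and deterministic, is an
interpretation — when comparing against other implementations of this
analysis, check which definition their "non-fixed" column uses before
comparing counts.
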