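---
title: "Methods: allelic epigenome analysis in uniparental embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic epigenome analysis in uniparental embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelomap)
```

## The measurement model

Parthenogenetic (PG) and androgenetic (AG) embryos are haploid-origin
proxies for the maternal and paternal alleles of ordinary bi-parental
embryos. Any assay run on both — DNase hypersensitivity, H3K27me3
ChIP, bisulfite methylation, RNA-seq — becomes an allele-resolved
measurement without SNP phasing. The package's job starts *after*
alignment, peak calling and quantification: its inputs are per-CpG count
tables, peak BED files, binned signal, and RPKM matrices, and its outputs
are allelic state calls and the derived biology (germline DMRs, imprinting
control regions, imprinted genes, dual-repressed promoters, cross-species
conservation accounting).

The central assumption is that a PG-vs-AG difference reflects parental
origin rather than embryo-to-embryo variability. The package therefore
treats replicates conservatively (peak intersection across replicates;
replicate means for expression; pooled counts for methylomes via
`pool_methylomes()`) and gates every directional call behind both a
presence/absence difference and a magnitude threshold.

## Quantification layer

**Methylation level.** For a region, ML = Σmethylated / Σtotal over CpGs
with depth ≥ `min_depth`; the level is *undefined* (NA, never 0) when
fewer than `min_cpgs` CpGs qualify. Defaults `min_cpgs = 3`,
`min_depth = 3` reflect the noise floor of low-input post-bisulfite
library construction; an undefined level propagates as "unavailable",
mirroring how such bins are greyed out rather than imputed in embryo
methylome studies.

**Binned signal.** Fixed-width bins tile each chromosome
(`bin_genome()`); fragments are assigned to the single bin containing
their midpoint (half-open convention, so a midpoint on a boundary belongs
to the bin that starts there) and scaled to fragments per million. The
midpoint rule avoids double counting; defaults are 2 kb bins for
DHS/H3K27me3 analyses and 1 kb bins for methylation, typical resolutions
for these assays in low-input material.

**Differential fraction.** The accounting statistic m/n (parent-specific
regions over regions marked in either parent) is kept as an exact integer
pair; `percent_of()` renders it at one decimal when n ≥ 10 000 and as an
integer percentage otherwise, with an explicit mode override. Keeping the
pair exact means every printed-style percentage in a report is
recomputable, never a stored float. Differential fractions are computed
over merged peak loci by default; the same statistic over raw bins is
available by feeding `partition_groups()` bins instead.

## Allelic state calls

A candidate locus set is the union of PG and AG peaks, overlap-merged so
each genomic locus is judged once. A locus is AG-specific iff (i) a peak
is present in AG and absent in PG and (ii) mean AG bin signal ≥
`fold_min × max(PG signal, pseudocount)`; symmetric for PG; loci with
peaks in both parents are bi-allelic, and presence/absence differences
that fail the fold gate fall back to bi-allelic. Defaults `fold_min = 4`,
`pseudocount = 0.5` suppress threshold-straddling peaks — a peak caller
finding a peak in one parent only is weak evidence when the signals are
comparable. H3K27me3 is domain-forming, so its peaks are first merged
across gaps ≤ 3 kb per parent.

The design makes the call antisymmetric by construction: swapping the PG
and AG inputs maps AG-specific ↔ PG-specific and fixes bi-allelic, a
property the tests assert on simulated data.

## Germline DMRs and putative ICRs

DMR calling scans 1 kb bins where both parental MLs are defined and flags
|ML(PG) − ML(AG)| ≥ `delta_min` (0.5); touching bins of equal direction
merge. Candidate regions are then classified by `gdmr_rule()` on levels
measured over the *same interval* at every stage — no per-stage
re-segmentation, because germline-DMR identity is positional and
re-segmentation would break cross-stage matching:

- gDMR: hyper allele ≥ `hyper_min` (0.75) and hypo allele ≤ `hypo_max`
  (0.25) at gametes (oocyte vs sperm), morula (PG vs AG) *and* blastocyst,
  with a consistent hyper allele.
- pICR: a gDMR whose methylation in bi-parental somatic tissue sits in the
  intermediate band [`inter_lo`, `inter_hi`] = [0.30, 0.70] — in both
  placenta and six-week embryo (non-specific), only placenta
  (placenta-specific) or only embryo (embryo-specific).

The numeric cutoffs are the package's own: hypo/hyper/intermediate are
qualitative notions in the embryo literature, and 0.25/0.75 with a
0.30–0.70 band are mutually consistent with `delta_min = 0.5` and with the
expectation that a mono-allelically methylated locus reads near 0.5 in
bi-parental tissue. Any NA stage level makes the classification NA
(flagged), never a silent pass. Tightening `hyper_min`/`hypo_max` can only
shrink the gDMR set (a tested monotonicity property).

## Imprinted genes

Expression states use replicate means per parent: silent when both <
`expressed_min` (1 RPKM, the conventional expression floor); AG-specific
when AG ≥ 1 and AG/(PG + 0.1) ≥ 4; symmetric for PG; else bi-allelic. The
4-fold rule with a 0.1 pseudocount is deliberately conservative for
two-replicate designs. A gene is imprinted iff its expression is
parent-specific *and* a pICR lies within `link_max_distance` (100 kb;
distance 0 when the pICR touches the gene body or promoter, ties broken
by smaller pICR start). The 100 kb default is a stated guess — no
linkage-distance rule is established for this analysis. Links whose pICR
is hypermethylated on the *expressed* allele are retained and flagged
discordant rather than dropped: paternal-methylated gDMRs with paternal
expression exist (repressor-silencing architectures), and silent dropping
would hide them. Catalogue genes that are expressed but bi-allelic are
reported as "not allelic" (evidence against imprinting at this stage);
silent catalogue genes are listed separately as undecidable.

## Coordinated repression screen

The screen intersects two independently computed promoter sets: promoters
(TSS ± 2 kb) overlapping an AG-specific H3K27me3 call, and promoters
overlapping a PG-hyper DMR. Requiring the methylation hit *within the
promoter window* (rather than anywhere near the gene) is the stricter of
the two readings of this analysis and is the implemented one; the window
is configurable via `flank`. "Low expression" is operationalised as both
parental means < 1 RPKM for consistency with the pipeline-wide floor, and
sperm promoter methylation is classed low/mid/high at the module-wide
0.25/0.75 cutoffs.

## Cross-species accounting

Orthology is interval-to-interval through a precomputed liftover-style
map; no alignment happens in-package. A region is orthologous iff it
intersects a source interval (largest-overlap pair wins, ties to the
smaller target start); "marked in target" is ≥ 1 bp overlap with the
target peak set; SNP-trackability is an input mask, since it depends on a
specific strain pair. The chain counts are monotone by construction.
`conservation_contrast()` scores regions by the coverage-weighted mean of
a per-base conservation track and compares groups with a Wilcoxon
rank-sum test — mid-ranks for ties, exact null for small untied samples,
normal approximation with continuity correction otherwise; the U
statistic itself is computed directly and is checked against an all-pairs
counting oracle in the tests.

## The synthetic study

`simulate_study()` generates the complete input set with planted truth on
a 2 × 5 Mb two-species genome organised as 500 gene cells of 20 kb
(250 per chromosome). Defaults echo the asymmetries this kind of study
reports: 40 gDMRs (80% maternally methylated), 80 AG / 50 PG / 200 shared
DHSs, 60 AG / 20 PG / 100 shared H3K27me3 domains, 25 imprinted genes (18
paternally expressed), 15 coordinated promoters, 15% orthologue coverage.
CpGs arise at 0.01/bp (5× in island promoters); counts follow
total ~ max(1, Poisson(10)) and methylated ~ Binomial(total, p) with
p ~ Beta concentrated (c = 20) on the locus's true level — 0.9/0.05 at
planted hyper/hypo alleles, 0.5 at somatic-intermediate pICRs, and stage
backgrounds descending from 0.8 in gametes to 0.45 (PG) / 0.40 (AG) at
blastocyst, the AG methylome running globally 0.05 below PG. Signal fold
for planted-specific peaks is 10 versus a ~0.1 background; expression is
log-normal (σ = 0.3) around per-gene baselines with the silenced allele of
imprinted genes at 0.05 RPKM.

One seed determines everything; each artifact draws from its own named
RNG substream, so adding an output never perturbs existing ones. These
problem sizes run the full simulate-plus-pipeline cycle in well under a
minute, which is what lets the test suite re-simulate under many
configurations.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: read-level artefacts (mapping bias,
bisulfite conversion failure), copy-number and repeat structure,
cell-type mixtures within an embryo, partially overlapping or
fuzzy-boundary peaks, distance-decaying orthology quality, and genuine
biological variability between embryos. Planted effects are strong and
clean by design, so the recovery criteria validate the *logic* of the
callers, not their power on marginal real-world signal.

## Numerical and degenerate-input choices

- Coordinates are 1-based closed in memory (the GenomicRanges
  convention); BED-style inputs convert at the file boundary, and the
  methylation position dialect (0- or 1-based) is an explicit reader
  switch. Unknown chromosomes are hard errors — silent coordinate
  mismatch is the classic cross-species bug.
- Readers never drop records: any malformed or invariant-violating line
  aborts with its line number.
- n = 0 denominators give undefined (NA) fractions, flagged rather than
  0; empty allelic classes in summaries carry an explicit `defined`
  flag.
- `percent_of()` rounds with R's `round()` (banker's rounding at exact
  halves) — the count pairs it renders are also reported raw.
- CpGs are keyed by the plus-strand C position; strand merging is assumed
  upstream.

## Known limitations

Thresholds (0.75/0.25, the 0.30–0.70 band, 4-fold gates, 100 kb linkage)
are field-plausible defaults, not fitted quantities; real-data headline
counts depend on them and on upstream peak calling, so exact reproduction
of any particular study's totals is out of scope. The DMR caller is
bin-based with no HMM smoothing, so DMR boundaries inherit bin
resolution. H3K27me3 domain merging at 3 kb is a single global constant.
The maintenance analysis between developmental stages uses plain ≥ 1 bp
overlap; no reciprocal-overlap criterion is offered. No motif, GO or
hydroxymethylation analysis is included.
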