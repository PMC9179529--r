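---
title: "Methods: methylation levels, promoter classes and sliding-window DMRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation levels, promoter classes and sliding-window DMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscan)
```

`methylscan` implements the downstream stages of a whole-genome bisulfite
sequencing (WGBS) analysis: it starts from per-cytosine methylation call
files (the CGmap dialect emitted by BS-Seeker-family callers) and produces
context-stratified methylation statistics, metagene and repeat/genic
profiles, promoter CG-density classes, and sliding-window differentially
methylated regions (DMRs) with gene annotation. Alignment and methylation
calling are upstream of this package; a deterministic synthetic-study
generator stands in for sequencing data so every stage is testable.

## The data model

A methylation call is one cytosine's observation: chromosome, 1-based
position, strand (a `C` in the CGmap nucleotide column is a plus-strand
cytosine, a `G` a minus-strand one), sequence context (CG, CHG or CHH with
H ∈ {A, C, T}), the methylation level `m/t` with `m` methylated of `t` total
reads, and the two counts themselves. All internal coordinates are 1-based
and inclusive on both ends; BED output converts to 0-based half-open at the
boundary, and nowhere else. Chromosome names are matched by exact string
equality — an explicit reader option strips a `"chr"` prefix, but nothing is
renamed silently, because silent renaming hides annotation/genome
mismatches.

## Level definitions

Every aggregate in the package reduces to one rule: the level of a region is
the **unweighted arithmetic mean** of the levels of the qualifying sites it
contains. Qualifying means covered by at least 3 reads (the conventional
floor below which a per-site level estimate is mostly sampling noise; it is
the `min_coverage` argument everywhere). A site covered 30× counts exactly
as much as one covered 3×; a read-weighted variant exists behind a flag for
comparison but is never the default. From this rule:

* **site level** — `m/t` at one cytosine, kept only at ≥ 3×;
* **region level** — mean site level inside an interval; when no qualifying
  site falls inside, the level is *undefined* and propagates as `NA`, never
  as 0 (0 is a legitimate methylation level; conflating the two corrupts
  every downstream mean);
* **gene level** — region level over the gene body extended by 15 kb on both
  sides, taken as one joint superinterval (whether body and flank should be
  averaged jointly or separately is genuinely open; the joint mean is the
  simpler reading and is what this package computes);
* **sample level** — mean over genes with a defined level, empty genes
  excluded;
* **group level** — mean over the biological replicates of a group.

Symmetric CpG strand calls (the plus-strand C and the minus-strand C of one
CpG dinucleotide) are *not* merged by default; each strand call is an
independent site. `merge_cpg_calls()` sums the dinucleotide's counts before
filtering when strand-combined levels are wanted.

Level-distribution summaries use left-closed, right-open bins with the last
bin closed, so a split at 0.1 reproduces the "< 0.1 vs ≥ 0.1" convention
for non-CG contexts exactly; for the CG split at 0.5, a site at exactly 0.5
falls in the upper bin (levels are ratios of small integers, so exact ties
do occur, and the convention is stated rather than left to chance).

## Metagene and feature profiles

The metagene axis is: 15 kb upstream flank in 200 bp bins (75 bins), the
gene body rescaled into 100 proportional bins, and a matching downstream
flank. "Upstream" is always 5′ of the TSS: minus-strand genes are mirrored
by negating coordinates, which makes strand symmetry exact rather than
approximate. Per-gene per-bin means are computed first and then averaged
across genes with data, so a CG-rich gene cannot dominate a bin. A site
exactly on a proportional-bin boundary goes to the lower bin; genes shorter
than the bin count simply leave some body bins empty for that gene. Flanks
running off a chromosome end are truncated, and truncated bins without data
stay missing. Overlapping genes each receive a site independently — the
per-gene averaging makes deduplication unnecessary.

Feature levels pool all qualifying CG sites falling in any interval of a
class: the four repeat families (LINE, SINE, LTR, Simple), intragenic (gene
bodies), intergenic (the complement of gene bodies within the union of the
±15 kb gene neighbourhoods), exons, and introns (gene bodies minus exons).
Whether the source analysis pooled sites or averaged per element first is
not decidable from its description; pooling is the default and a
per-element mode is provided.

## Promoter CG density and classes

For each gene the TSS ± 10 kb neighbourhood is tiled into 100 strand-oriented
200 bp subregions and the CG dinucleotides in each are counted from the
genome sequence (a CG straddling a bin boundary belongs to the bin holding
its C; CG is its own reverse complement, so counting on the plus strand is
strand-safe). The promoter proper is TSS ± 2 kb in 20 bins named by signed
index, bin −10 … bin −1 upstream and bin 1 … bin 10 downstream of the TSS in
the direction of transcription; on the plus strand bin 1 starts at the TSS,
on the minus strand it ends there.

Promoters are classified by the mean CG count per 200 bp bin over the 20
bins (the simplest statistic consistent with a "per 200 bp" threshold on a
20-bin grid): **HCG** strictly above 8, **LCG** strictly below 4, **ICG**
the inclusive 4–8 band. Reading the intermediate range as inclusive makes
the three classes disjoint and exhaustive, so they partition any gene set.
Grids truncated at a chromosome edge are classified on their available bins
and flagged.

## Sliding-window DMR screening

The genome is tiled with 600 bp windows stepping by 300 bp, starting at
position 1 of every chromosome (the phase is not derivable from the
procedure's description; fixing it at 1 makes runs reproducible, and it is
exposed as an argument). Windows that would run past the chromosome end are
dropped — every scanned window is exactly 600 bp.

Replicates of a group are combined by **read pooling**: per site, methylated
and total counts are summed across replicates and the ≥ 3× filter is applied
to the pooled coverage. This yields one level per site per group, matching a
pairwise two-sample comparison; a replicate-mean mode (per-replicate window
levels, then averaged) is available as an alternative. A window enters the
comparison only if *both* groups have ≥ 3 qualifying CGs in it — a
difference against an undefined level is meaningless. The window level is
the unweighted mean of its CG site levels, and a window is a DMR when
`|level_A − level_B| ≥ 0.15`, the threshold inclusive. Overlapping flagged
windows are reported separately and never merged: reported DMRs span exactly
600 bp, which is also what published single-window coordinates imply. No
significance test is attached — the fixed-difference rule *is* the criterion
in the procedure this package implements.

DMRs are annotated to genes by positional intersection under three
relations: gene contained in the DMR (`gene_in_dmr`), DMR contained in the
gene (`dmr_in_gene`), or partial `overlap`. The most specific relation is
recorded (containment beats overlap); identical intervals resolve to
`dmr_in_gene` as a deterministic tie-break. DMRs hitting no gene are kept
with an empty gene field.

## The synthetic-study generator

`sim_config()` + `simulate_study()` produce a complete toy study: genome
FASTA, gene models (GFF3), repeat annotations (BED), one CGmap file per
replicate, and a ground-truth JSON. It emulates the downstream *structure*
of a two-breed sheep WGBS design — two tissues, groups of 3–4 biological
replicates, ~20.8× mean coverage — at desk scale (default: 2 chromosomes ×
2 Mb, 40 genes, 200 repeats).

What the generator plants, and why:

* **Genome.** Random sequence with 40% GC in which most background CpGs are
  disrupted (`cg_deplete_prob = 0.7`), leaving ~2.4 CG dinucleotides per
  200 bp — the CG-poor background typical of mammalian DNA. Each gene's
  promoter bins are rewritten to carry *exactly* the CG density of a
  designated class (defaults 12/6/3 CGs per 200 bp bin for HCG/ICG/LCG), as
  real CG dinucleotides in the FASTA, so sequence-based counting, call
  positions and the classifier agree by construction.
* **CG methylation.** A bimodal Beta mixture: fraction `p_high = 0.68` of
  sites in a high mode near saturation (mode 0.99), the rest in a low mode
  around a third (mode 0.33). The pair is chosen so that two constraints
  hold at once: about 68% of CG sites lie above 0.5, and gene-centric sample
  levels land near 0.70 after the TSS dip — with a low mode near zero the
  second constraint is unreachable, because a third of the sites would pin
  the global mean near 0.6.
* **TSS dip.** Within ±2 kb of each TSS, latent CG levels are multiplied by
  a factor that falls linearly to `1 − depth` at the TSS. The depth grows
  with the promoter's designated CG class (defaults 0.9/0.65/0.3 for
  HCG/ICG/LCG), planting the negative relationship between promoter CG
  density and methylation: class profiles order LCG > ICG > HCG and the
  metagene minimum sits at the TSS.
* **Repeats.** Family-specific additive shifts to the latent level
  (defaults: SINE 0, LINE −0.04, LTR −0.05, Simple −0.18) anchored to the
  ~0.75 non-promoter base level, reproducing the familiar ordering with
  SINE highest and Simple lowest.
* **Non-CG methylation.** A two-component mixture — 92% of CHG/CHH sites
  essentially unmethylated, 8% around 0.45 — parameterized so the overall
  mean equals `chg_chh_level = 0.05`. CHG and CHH means are equal across
  tissues by default. A single Beta at mean 0.05 is too dispersed: it puts
  only ~81% of observed site levels below 0.1 at 20× coverage, while the
  small-subpopulation mixture reaches ~88%.
* **Replicates and DMRs.** Replicates of a group share the latent site
  levels and differ only in read sampling (coverage ~ Poisson, methylated
  reads ~ Binomial), so planted effect sizes are exactly interpretable; an
  optional Beta jitter adds per-replicate biological noise but is off by
  default. A planted DMR shifts the second group's latent level by `delta`
  (clipped to [0, 1]) inside its interval. Everything is deterministic under
  a fixed seed, to the byte.

What the generator does **not** emulate: read-level artifacts (bisulfite
conversion failure, mapping bias, SNP-induced miscalls), realistic
chromosome counts and repeat landscapes, per-replicate biological
variability (off by default), and tissue differences (all groups share one
latent field unless DMRs are planted). Passing tests therefore demonstrate
that the *procedures* are implemented correctly and recover planted
structure — not that the pipeline is robust to the failure modes of real
libraries.

## Numerical and degenerate-input choices

* Undefined levels are `NA` everywhere, never 0, and are excluded from
  higher-level means rather than zero-filled.
* Interval membership is closed on both ends; the DMR threshold and the
  coverage/count floors are all inclusive (≥ 0.15, ≥ 3 CGs, ≥ 3×).
* Promoter classification cuts are strict on both sides (HCG > 8, LCG < 4).
* Proportional-bin ties go to the lower bin; CG dinucleotides straddling a
  bin boundary belong to the bin holding the C.
* Empty inputs degrade softly: a fully filtered call set warns, an empty
  DMR list writes a header-only table, an empty promoter class is omitted
  with a warning; structural errors (start > end, unknown context, exon
  outside its gene, unknown repeat family, missing chromosome in the FASTA)
  fail loudly with the offending item named.

## Problem sizes

The test suite and the acceptance script run everything on synthetic
studies sized for a desk: a shared 600 kb chromosome with 24 genes for
profile and oracle checks, 60 kb single-gene-pair studies across 25–50 seeds
for DMR recovery, a gene-free 2 × 1.7 Mb genome (> 10⁴ compared windows) for
false-positive rates, and the default 2 × 2 Mb / 40-gene study for the
headline statistics. These sizes were chosen so that per-bin and per-class
averages are stable enough to assert orderings while whole runs complete in
seconds to a few minutes.

## Known limitations

* The fraction of non-CG sites observed below 0.1 tops out near ~88–89% at
  20× coverage under this model, somewhat below values reported from real
  data: with ~20 reads, a single methylated read at a site with latent level
  ~0.02 already reaches 0.05–0.1, and two reach 0.1. Matching reported
  fractions exactly would require modelling the real, overdispersed
  coverage distribution.
* At toy scale, promoters hold ~10% of all CG sites (real genomes are
  similar in order of magnitude, but the toy gene density is higher), so
  the TSS dip depresses genome-wide CG summaries a few points below the
  non-promoter base level.
* The intragenic > intergenic ordering seen in real data is not planted:
  gene bodies at toy scale are short relative to the ±2 kb dip, so the dip
  depresses intragenic means instead.
* Published absolute results that depend on a specific reference genome and
  deposited libraries — genome-wide DMR counts per comparison, or the mean
  CG count of the first downstream promoter bin — are properties of those
  data and are not reproduced by synthetic runs; the package asserts the
  procedures and the planted structure instead.
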