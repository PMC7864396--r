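---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lentinema)
```

## Scope

`lentinema` reimplements, as tested and reusable components, the three
bespoke computational procedures needed to analyse lentiviral
transduction experiments in a parasitic nematode:

1. **Split-read detection of provirus integration** in whole-genome
   sequencing reads, with a downsampling resampling test for viral-read
   enrichment between exposed and control libraries.
2. **Secondary-siRNA quantification** from small-RNA sequencing:
   adapter removal, length filtering, selection of 23-nt 5'-G reads
   mapping to a target transcript, and reads-per-million normalisation.
3. **Comparative-Ct RT-qPCR quantification** with geometric-mean
   multi-reference normalisation, calibration to an untreated control
   group, and Kruskal-Wallis / Dunn group statistics.

No public data accompany the original experiments, so every stage is
driven by a synthetic-data generator that emits standard formats
(FASTA/FASTQ/TSV) together with machine-readable truth sets, and the
test suite validates each stage closed-loop against that truth.

## The aligner and its oracle

All alignment decisions route through one deliberately small contract: a
deterministic, **ungapped**, seed-and-extend local aligner over a k-mer
index. A hit is the *full overlap* of the (possibly reverse-complemented)
read with the reference on one diagonal, kept iff

* span `>= min_span` (default 15 nt), and
* mismatches `<= max_mismatch_rate * span` (default 0.05).

This definition makes an exhaustive per-diagonal scan an *exact* oracle:
the test suite re-derives hit sets by FFT cross-correlation of per-base
indicator vectors, with no seeding and no shared code, and asserts
set-equality against the package aligner.

**Seed length.** The seeded search provably finds every qualifying
diagonal when each such diagonal contains an exact k-mer. A placement of
span $s$ with $m$ mismatches contains an exact run of at least
$\lceil (s - m) / (m + 1) \rceil$ bases; minimising over all spans at a
5% mismatch rate gives 10 (attained at $s = 20\ldots23$, $m = 1$). The
default seed is therefore **k = 10**, which makes seeded search and
exhaustive scan *identical* at the default thresholds. A k of 12 --
otherwise a reasonable default -- can miss 1-mismatch placements of span
20-23 and would break the oracle-equivalence guarantee.

Ungapped alignment suffices because junction detection needs position
and identity, not indel modelling, and the read simulator emits
substitution errors only; this keeps the oracle exact and the whole
stack desk-scale. Gapped or quality-aware alignment is out of scope, as
is any ambition to scale beyond synthetic references of tens of
megabases (the hot loops are C++, so a 100 kb genome against $10^5$
reads screens in under half a minute on one core).

Coordinates are 0-based half-open throughout; exported junction tables
state this in a header line. Minus-strand hits report read coordinates
on the reverse-complemented read.

## Split-read integration calling

The detection pipeline mirrors the original screen:

1. **Candidate selection**: reads mapping end-to-end (a hit covering at
   least 95% of the read) to *either* host or virus are discarded;
   survivors are candidate chimeras.
2. **Sub-read enumeration**: "sub-reads of varying lengths" is realised
   as *every* prefix/suffix bipartition with both flanks at least
   `min_subread` (default 15 nt, matching the aligner's minimum span).
   A single breakpoint per read is assumed.
3. **Assignment**: a sub-read is attributed to one reference only when
   its best hit there beats its best hit to the other reference by at
   least 2 mismatch-equivalents (unaligned bases of the shorter hit
   count as mismatches). This margin prevents cross-assignment in
   homologous stretches; the original description gives no
   disambiguation rule, so the margin is a package design choice,
   config-exposed.
4. **Split choice**: among qualifying split points, the one maximising
   the summed segment identity wins; ties go to the longer host
   segment, then the smaller split position. The junction coordinate is
   the reference position adjacent to each segment's inner end.

Events are reported per read (rates are events per million reads
screened, over *all* screened reads); optional clustering into loci
uses a +/- 5 bp merge window.

**Detection gap, by construction.** The simulator labels as "junction
read" any read overlapping a truth junction by at least 1 nt per side,
while calling requires both flanks to reach `min_subread` and, before
that, the read must *fail* the end-to-end screen (overlap greater than
about 5% of the read length). Labelled reads inside that gap are
expected, quantifiable misses; recall assertions therefore target reads
with guaranteed flanks.

**Microhomology.** When the host base adjacent to an insertion equals
the terminal virus base, several split points produce identical
alignments and the junction coordinate is inherently ambiguous (the
tie-break would shift it into the homology tract). The generator
therefore draws insertion sites without single-base boundary
microhomology, so each truth junction has a unique expected coordinate.
Real integrations can carry microhomology; calls there are exact only up
to the homology interval.

## Downsampling enrichment test

The exposed (larger) library is repeatedly downsampled without
replacement to the control library's size (default 100 resamples); each
resample's virus-aligned read count forms the null distribution to which
the control count is compared. The empirical p-value uses the add-one
estimator $(1 + \#\{\text{count} \le \text{control}\}) / (n + 1)$, so it
is never exactly zero. On a constructed case the resampling distribution
is hypergeometric, which the test suite uses as an independent oracle.

## Small-RNA classification

Defaults encode the secondary-siRNA signature of this nematode: length
exactly **23 nt** and first base **G** (the "22G-RNA" class of
*C. elegans*, one nucleotide longer here), plus an end-to-end hit on the
target transcript. Strand is not restricted by default -- the original
description says only "mapping to" the target -- but biological
secondary siRNAs are antisense, so an `antisense_only` switch is
provided rather than hard-coded.

Adapter trimming cuts at the leftmost position where a prefix of the 3'
adapter matches with at most 1 mismatch per 10 nt of overlap
(minimum confirmed overlap 5 nt); the published pipeline's clipper
policy is version-dependent and unstated, so this conservative rule is
the package's own. The adapter sequence is always user-supplied (the
library kit, not the sequence, is named in the original methods); the
simulator embeds a configurable TruSeq-style adapter so tests are
closed. The rpm denominator is the number of reads surviving trimming
and the >= 15 nt filter -- "total small RNAs" -- a convention recorded in
the output metadata, since pre- versus post-filter totals are not
distinguishable from the original description.

## Comparative-Ct quantification

Per sample, $\Delta C_t = C_t^{target} - \mathrm{geomean}(C_t^{refs})$;
$\Delta\Delta C_t$ subtracts the arithmetic mean $\Delta C_t$ of the
calibrator (wild-type) samples; relative expression is
$E^{-\Delta\Delta C_t}$ with per-primer efficiency $E$ (default 2;
values outside (1, 2.2] are rejected, values outside the empirically
observed 1.9-2.1 window warn).

**Geometric mean over raw Ct.** Normalisation takes the geometric mean
of the raw Ct values, following the source description literally. Note
a mathematical consequence: a constant shift $c$ applied to every Ct of
a sample (equal loading change) cancels *exactly* in $\Delta C_t$ only
when the reference Cts are equal within the sample, because
$\mathrm{geomean}(x + c) \ne \mathrm{geomean}(x) + c$ in general. With
realistic reference spreads (Ct 18-22.5) the residual is on the order
of $10^{-3}$ cycles per unit shift -- negligible but not zero. The exact
invariance test therefore uses equal reference Cts; an
efficiency-weighted normalisation that restores exact invariance is out
of scope.

**Percent knockdown** is derived from the *group-mean* log2 fold change
as $100 (1 - 2^{\bar{x}})$ by default (so a mean log2 of -0.72 gives
39.3%, conventionally reported as ~40%); averaging per-sample
percentages is available behind a flag.

**Statistics.** The global test is tie-corrected Kruskal-Wallis; with
10 or fewer observations the p-value is computed from the *exhaustive*
permutation distribution (all distinct relabellings) rather than the
chi-square approximation, and the test suite checks it against an
independent Monte-Carlo oracle. Dunn's pairwise z statistics are
computed for each treatment against each control group with Bonferroni
adjustment over the pairs actually tested (the family-wise scheme of the
original analysis software is unstated; the choice is config-exposed).
Stars follow the 0.05 / 0.01 / 0.001 / 0.0001 convention.

**Error of the recovered knockdown.** Calibration subtracts the mean
calibrator $\Delta C_t$, so the sampling error of a recovered group mean
combines that group's SEM with the calibrator-mean uncertainty:
$\mathrm{SE} = \sqrt{\mathrm{SEM}_{trt}^2 + \mathrm{SEM}_{cal}^2}$.
Closed-loop recovery tests use this combined SE; the group SEM alone
would understate the estimator's error by up to $\sqrt{2}$.

## The synthetic-data generator

The generator states a world and stays there; its defaults are the
conditions of the emulated experiments where those are stated, and a
single realistic choice elsewhere:

| Parameter | Default | Why |
|---|---|---|
| WGS read length | 150 nt | paired-end 150 bp libraries were sequenced; pairs carry no extra information for the described procedure, so reads are simulated single-end |
| virus length | 8 kb | typical lentiviral transfer-vector scale; the real vector sequence is not public, a random stand-in is used and LTR structure is not modelled |
| host GC | 0.4 | nematode-like base composition |
| small-RNA read length | 50 nt | 50 bp single-end small-RNA sequencing |
| secondary-siRNA length / first base | 23 / G | the documented signature in this species |
| length filter | >= 15 nt | stated discard rule, boundary retained |
| enrichment resamples | 100 | the stated number of downsampling rounds |
| qPCR efficiencies | 2.0, accepted 1.9-2.1 | stated empirical range |
| reference genes | *eif-3C*, *idhg-1*, *rbd-1* | the stated reference panel |
| Ct noise sd | 0.2 | typical replicate-level qPCR noise |

Decoy small-RNA classes (wrong length 18-28, wrong first base,
off-target source, adapter-only) exercise every classifier gate; truth
tables record each read's emitted class. What the generator does *not*
emulate -- indels, quality-dependent errors, PCR duplicates, coverage
bias, insert-size variation, real genome repeat structure -- bounds what
a green test establishes: correctness of the implemented procedures on
their stated input model, not robustness to every artefact of real
libraries.

## Numerical and degenerate-input choices

* Mismatch comparisons use `mm <= rate * span + 1e-9` in both the
  aligner and its oracle, so floating-point rounding cannot split them.
* `N` (or any non-ACGT base) never matches, including `N` vs `N`;
  k-mers containing such bases are not indexed and not seeded.
* All-identical values in the group comparison give H = 0 (the tie
  correction would divide by zero) and permutation p = 1.
* A single-sample group reports SEM as `NA` rather than 0.
* Empty FASTA/FASTQ files yield empty record sets with a warning;
  malformed records are reported with line number or read id.
* RNA input (`U`) is converted to `T` on ingest and flagged; the
  internal alphabet is DNA because all alignment targets are DNA.
* All generators are bit-reproducible per seed, and seeds never leak
  into the caller's RNG state.

## Known limitations

* The aligner is ungapped by design; an integration junction flanked by
  an indel-containing read segment will lose identity rather than gap.
* Read pairing is ignored (pairs are treated as independent reads), as
  in the described procedure.
* The enrichment test conditions on library sizes; it does not model
  batch effects between exposed and control libraries.
* Reference-gene stability ranking and standard-curve efficiency
  estimation are out of scope; efficiencies are inputs.
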