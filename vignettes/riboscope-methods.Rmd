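---
title: "Codon-level ribosome profiling analysis with riboscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level ribosome profiling analysis with riboscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscope)
```

## The measurement and its coordinate system

Ribosome profiling sequences the ~18-35 nt mRNA fragments ("footprints")
that a translating ribosome protects from nuclease digestion. Footprint
libraries have two dominant size classes - short (21-22 nt) and long
(29-31 nt in human; 28-32 nt when a wider gel cut is used) - attributed
to distinct ribosome conformations, and when digestion is stringent the
5' ends of footprints show strong 3-nt periodicity relative to the
reading frame.

riboscope works entirely in transcript coordinates: a transcriptome is a
set of sequences with a CDS interval each, all coordinates are 0-based
and half-open (BED convention), and codon index 0 is the start codon.
Codon indices may be negative (5' UTR) because reference ORFs are
treated as extended 18 nt into the UTRs for mapping and assignment, so
initiating and terminating ribosomes are representable.

## A-, P- and E-site assignment

The A-site of a ribosome sits at a fixed distance from the footprint's
5' end, but that distance depends on the frame of the 5' end:

* 5' end in frame 0 (codon-aligned): the A-site codon occupies footprint
  positions 16-18 (1-based), i.e. a 15-nt offset;
* 5' end in frame -1: positions 17-19, a 16-nt offset;
* 5' end in frame +1: no A-site is defined and the footprint is
  discarded (it still appears in frame QC tallies).

Both offsets land exactly on the codon grid, so A-site indices are
always integers; the P and E sites trail by one and two codons. Two
documented choices here were genuinely open:

* **Short footprints use the same 5'-anchored offsets as long ones.**
  Short-footprint occupancy is routinely reported, but no separate
  offset rule for 21-22 nt fragments is established; a single anchored
  rule keeps the assignment simple and testable. Users who prefer a
  different convention can re-run `assign_sites()` on a filtered
  alignment set.
* **Assignments beyond 6 codons outside the CDS are dropped**, matching
  the 18-nt UTR extension: anything further cannot arise from a mapped
  footprint and indicates a coordinate error.

`assign_sites()` is verified against an independent per-read oracle that
locates the A-site nucleotides inside each footprint sequence and maps
them through the transcript's codon grid.

## Per-gene density and the metagene ramp

Within one footprint class, let $F_{ij}$ be the number of A-site
footprints at codon $j$ of gene $i$ and $L_i$ the ORF length in codons.
The normalized density

$$D_{ij} = \frac{F_{ij}}{\left(\sum_{j=1}^{L_i} F_{ij}\right) / L_i}$$

has mean exactly 1 over each covered gene, which removes expression
differences and makes positions comparable across genes. The metagene
profile averages these densities at aligned offsets over the $N$
well-expressed genes,

$$A_j = \frac{\sum_{i=1}^{N} D_{ij}}{N},$$

anchored either at the start (the 5' "translation ramp": elevated
density over roughly the first 150-200 codons) or at the stop codon
(termination accumulation). Two filters define "well-expressed": more
than 64 A-site-assigned footprints in the CDS, and an ORF of at least
200 codons so every gene contributes to every offset of a 200-codon
window. The read filter is interpreted on A-site-assigned counts of the
analyzed footprint class, since the profile itself is built from
A-site coverage. The 95% confidence band is a normal approximation
across genes ($A_j \pm 1.96\,\mathrm{SE}$), appropriate for the dozens
to hundreds of genes that pass the filters.

## Codon occupancy and cross-condition comparison

Codon occupancy estimates relative dwell time: the average normalized
density observed when codon $c$ occupies a ribosomal site. Per passing
gene, densities are renormalized over the *retained* positions - codons
15 to $L_i - 5$ by default, shielding the statistic from initiation and
termination accumulation - and the occupancy of $c$ is the mean density
over all retained positions whose site codon is $c$. For the P and E
sites the codon identity is looked up one and two codons upstream of
the recorded A-site position. The position-weighted mean occupancy is 1
by construction. This positional-averaging formulation is a
reconstruction of common practice rather than a single canonical
formula; it is the package's largest methodological reconstruction and
is therefore pinned down by generative-model tests (log-normal dwell
weights are recovered with $r > 0.99$ at library scale).

Cross-condition agreement is summarized by a signed coefficient of
determination, $\mathrm{sign}(r)\,r^2$ for Pearson $r$ on untransformed
occupancy values. The sign is kept because anti-correlated occupancy
profiles occur in practice (e.g. between orthogonal methods) and plain
$r^2$ cannot express them. Comparisons with $p > 0.05$ are flagged
("crossed out"). Stop codons are tabulated - termination occupancy is
biologically real - but excluded from comparisons by default; with the
default 5-codon terminal exclusion they carry no positions at all and
report `NA`.

## Wave profiles

A "wave" is excess ribosome density downstream of a specific codon,
the signature reported for CGA/CGG in CHX-pretreated budding yeast:
ribosomes keep elongating in the lysate until they stack behind a
slowly decoded codon. For every occurrence of the query codon in a
passing gene (at least 20 codons away from either ORF end), the
normalized density is collected at each relative offset
$d \in [-20, +100]$ codons and averaged over occurrences. Under no
wave, enrichment is 1 at all offsets; a wave appears as enrichment
rising just downstream ($d$ of a few codons) and decaying with
distance. Overlapping occurrences are used independently - deduplication
would bias the average toward isolated occurrences. The window and edge
exclusion are package choices: the window covers the reported extent of
waves with upstream context as a built-in negative control, and the
edge exclusion keeps start/stop accumulation out of the average.

## Count matrices

`gene_counts()` counts footprints of one class whose A-site codon lies
in $[15, L_i)$; excluding the first 15 codons keeps CHX-induced
initiation accumulation from skewing gene-level measurements toward
initiation rates. The conventional long class for count matrices is the
wider 28-32 nt cut (`assign_sites(long_range = c(28, 32))`). The output
is a plain genes x samples integer matrix, i.e. direct input for
DESeq2/edgeR; the differential model itself is out of scope. 5'-UTR
counts use the A-site codon index ($< 0$) rather than the 5' end, for
consistency with every other site-level analysis.

## The synthetic footprint generator

The generator exists so that every stage has a ground truth. Its model:
per gene $i$ and codon $j$ a dwell intensity

$$\lambda_{ij} = w_{c(i,j)} \; r(j) \; s_\text{start}(j) \; s_\text{stop}(j)
  \prod_{\text{upstream hits } k} \left(1 + \alpha e^{-d_{jk}/\tau_w}\right),$$

with codon dwell weights $w_c$ (flat, log-normal, or explicit), a ramp
$r(j) = 1 + a e^{-j/\tau_r}$, start/stop multipliers, and a
multiplicative wave kernel applied $1 \le d \le D$ codons downstream of
each target-codon occurrence. Gene totals are proportional to
expression times $\sum_j \lambda_{ij}$; A-site positions are drawn
multinomially; each read then receives a class (long with probability
0.8), a length (29-31 or 21-22 nt), and a 5'-end frame
(0.87 / 0.10 / 0.03 for frames 0 / -1 / +1, the in-frame fraction
typical of stringently digested libraries), with the 5' coordinate
computed by inverting the assignment offsets. A small dwell mass
(1%) on A-site positions -6..-1 exercises the 5'-UTR path, and FASTQ
emission appends a randomized 4-nt linker plus a constant adapter so
the clipping/mapping front end is testable end to end.

Default study conditions: 500 genes of 200-600 codons (uniform), 60-nt
UTRs, 2.5M reads (~2M long footprints), log-normal expression with
sdlog 0.5. Null and calibration runs in the test-suite set expression
sdlog to 0 so that deviations measure estimator error at the binomial
floor rather than expression dispersion; these sizes keep the whole
validation suite to a few minutes on one CPU.

What the generator deliberately does **not** emulate: sequencing
errors and quality scores, transcript isoforms and multi-mapping
structure of real genomes, rRNA/contaminant reads, non-uniform codon
usage, kinetic ribosome movement (waves are a static density kernel,
not a traffic simulation), and nuclease sequence bias. Tests passing
on synthetic data therefore validate the estimators against their
generative model - they do not certify behavior on real libraries with
those additional artifacts.

## Numerical and degenerate-input conventions

* Adapter clipping takes the left-most exact adapter occurrence
  (synthetic reads are error-free); inserts outside 15-35 nt are
  dropped and counted. The 15-nt floor is a configurable package
  choice - below it, exact mapping is not reliably unique.
* The exact mapper reports a read only at a unique match location
  across all transcripts; multi-mappers and no-hits are counted
  separately.
* Zero-read genes yield all-zero densities and a `zero_read` flag;
  empty QC input warns and returns zeros; "no genes pass" and "no
  usable occurrences" are hard errors naming the filters.
* Frame fractions are reported over footprints whose 5' end lies in
  `[cds_start - 18, cds_end)`; outside that corridor the frame is not
  meaningful.
* All generator randomness derives from the configuration seed, so a
  configuration determines its outputs byte for byte.

## Limitations

Offsets are fixed, not calibrated from periodicity; species with other
dominant lengths need their ranges passed explicitly. Occupancy and
wave definitions are reconstructions of field practice (see above) and
alternative normalizations (expected-frequency, log-scale correlation)
are not implemented. The exact mapper is for synthetic or pre-cleaned
transcript-space reads; real genome alignment, mismatch tolerance and
contaminant depletion belong to upstream tools.
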