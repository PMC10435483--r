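---
title: "Models and methods: from nascent reads to enhancer biology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from nascent reads to enhancer biology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catnet)
```

## The measurement and the problem

High-sensitivity NET-seq-style protocols sequence the 3' ends of nascent
RNA, placing transcriptionally engaged RNA polymerase II on the genome at
single-nucleotide, strand-resolved precision. Because enhancer RNAs are
short-lived and lowly transcribed, this kind of data is one of the few
ways to see enhancer transcription directly. The package implements the
downstream analysis that turns aligned nascent reads into biology:

1. artifact-filtered single-nucleotide occupancy tracks,
2. de novo transcription units,
3. classification of antisense transcription into convergent (CAT) and
   divergent (DAT) classes,
4. intragenic and extragenic putative-enhancer calls supported by
   H3K27ac and H3K4me1,
5. spike-in-normalized differential occupancy with pausing matrices, and
6. enhancer-to-target-gene assignment through 3D contacts.

A first-class synthetic-data module generates all inputs with a
machine-readable truth table, so every stage is testable end to end
without external downloads.

## Occupancy extraction and artifact filtering

Reads are collapsed to one per (position, UMI) key — exact-match
collapse, no edit-distance clustering, mirroring `starcode -d 0`
behaviour. Three artifact classes are then handled:

* **RT mispriming.** If the reverse-transcription primer anneals to
  genomic sequence instead of the ligated adapter, the apparent UMI is
  genomic sequence. A read is removed iff its UMI equals
  (case-insensitively) the genomic k-mer immediately adjacent to its 3'
  end *in read orientation*: the k bases following `end` for plus-strand
  reads, the reverse complement of the k bases preceding `start` for
  minus-strand reads. The adjacency side is a design choice (the
  mechanism acts at the primer side); exact matching is the default
  because tolerating mismatches would remove ~3 extra reads per million
  by chance at k = 10 while genuine artifacts match exactly.
* **RNA-processing intermediates.** Splicing and 3'-end cleavage leave
  RNA 3' ends precisely at the 3'-most nucleotide of exons and introns
  and at polyA sites. Those positions (on the annotation's strand) are
  deleted from the track and recorded in a mask set, so metaprofiles can
  *skip* rather than zero them and avoid artificial signal drops.
* **Region masks.** ncRNA loci (sn/snoRNA and the like, transcribed by
  other polymerases or heavily structured) and blacklist intervals are
  deleted outright.

Occupancy itself is the read's 5'-most aligned base in read orientation
— the nascent-RNA 3' end — assigned, under the default `flip = TRUE`
convention that matches the library chemistry, to the strand opposite
the alignment strand. Each processing step conserves or reduces counts;
on artifact-free input the chain is the identity on the source track.

Spike-in material (an exogenous species mixed in at a fixed cell ratio,
1:8 by default) lives on reference names with the reserved prefix
`spike_`; the species split keys on that prefix rather than carrying two
genome builds.

## Transcription units

The paper-grade toolchain calls nascent transcription units with HOMER's
groseq mode; its exact semantics (two-valued body-size parameter, seeded
background model) are not fully specified, so this package deliberately
replaces it with a transparent gap-merge caller whose behaviour is
checkable against a brute-force oracle: per chromosome and strand,
covered positions (count >= 1 by default) are merged while consecutive
covered positions are at most `max_gap = 250` bp apart; runs spanning
under `min_body = 150` bp or holding under `min_count = 10` reads are
dropped; long runs are never split at internal dips. The origin is the
5'-most covered position in unit orientation. The defaults were fixed on
synthetic data before any downstream evaluation and are deliberately
permissive: downstream rules, not the caller, carry the classification
burden.

## Active genes and isoforms

A gene is *active* iff its expression (the sum of its isoform TPMs — a
deliberate internal-consistency choice over a separate gene-level
estimate) is at least 1 **and** at least one called transcription unit
on the gene strand overlaps it; expression without nascent transcription
does not count. Active isoforms contribute at least 10% of the gene's
summed expression; their TSS and polyA sites form the active sets, and
the *effective span* — first active TSS to last active polyA in gene
orientation — is the gene interval every downstream rule uses.

## CAT / DAT classification and enhancer calling

Antisense transcription units (ATUs) are units opposite-strand to an
active gene. Candidacy is decided against the gene's effective span
*extended 1 kb upstream*: a divergent antisense unit originates upstream
of the TSS and transcribes away from the gene, so it can never overlap
the gene body; without the upstream window the DAT class would be
unreachable. This is the one place where the package had to interpolate
a geometric convention; everything downstream follows the published
rules exactly:

* **Spill-over removal.** An ATU is discarded if it overlaps a
  same-strand gene by at least 50% of the unit or at least 90% of the
  gene, or if it covers the entire host gene region (frequent over very
  short genes).
* **DAT**: the origin lies strictly within 1000 bp upstream of *any*
  active TSS of the host, in host orientation. Including downstream
  alternative TSSs here is what re-assigns apparent CATs that are really
  divergent transcription from alternative promoters.
* **CAT**: otherwise, the origin lies strictly downstream of the first
  active TSS and inside the effective span. Units fitting neither window
  are discarded as ambiguous.
* **Intragenic enhancers** are CATs whose unit span overlaps (>= 1 bp)
  both an H3K27ac and an H3K4me1 peak; the call center is the CAT
  origin.
* **Extragenic enhancers** are units distal to active genes (zero
  overlap with any active effective span, either strand) whose origin is
  neither inside a promoter region (any annotated isoform TSS +/- 500
  bp, active or not) nor inside a termination zone (polyA to polyA +
  2 kb, gene orientation — engaged polymerase past the polyA site is
  terminating, not initiating). Opposite-strand eligible units with
  origins strictly closer than 500 bp merge into one bidirectional call
  (greedy nearest-origin pairing, deterministic after a
  distance-then-coordinate sort, each unit used once; center = origin
  midpoint); the rest become unidirectional calls. Both kinds require
  both marks.

Boundary conventions chosen here (and frozen before evaluation): the
promoter window is closed (`|origin - TSS| <= 500` excludes), the
termination zone is half-open (`0 <= d < 2000` excludes), the DAT window
is strict (`0 < d < 1000`), and bidirectional pairing is strict
(`d < 500`). Mark support is tested against the unit span rather than a
fixed window around the origin; both geometries are defensible, the span
test is the more permissive and is configurable.

## Quantification, normalization and the differential test

Regions (whole genes, promoter-proximal `[TSS, TSS + 500)`, gene body
`[TSS + 500, polyA)`, enhancer span, enhancer-proximal center +/- 250
bp, enhancer-distal remainder) are counted sense-strand for genes and
both-strands for enhancers. The proximal/distal boundaries are
configuration, not biology: 500 bp covers the promoter-proximal pausing
region in human cells, and the conclusions the tests check are
insensitive to +/- a factor of two on these widths.

Normalization offers RPM, TPM and RLE. The scientifically load-bearing
variant is **spike-in RLE**: median-of-ratios size factors computed on
the spike-in regions only and applied to all regions. Because the
spike-in was added at a fixed cell ratio before library preparation, a
global loss of primary signal leaves spike counts untouched, so the
factors carry the global change. Plain library-size normalization
renormalizes it away — the package's tests demonstrate exactly this
failure (a simulated uniform 4-fold loss reads as log2FC ~ 0 under
library-size factors and ~ -2 under spike-in factors).

Differential testing deliberately does **not** re-implement DESeq2.
Regions with fewer than 6 raw reads summed over all samples are excluded
up front. For each region the log2 fold change uses mean normalized
counts with a 0.5 pseudocount. The Wald statistic divides the
natural-log difference of means by a standard error from the NB variance
function `v(mu) = mu + alpha mu^2`, with `alpha` from pooled
within-group method of moments, truncated at zero, with no shrinkage;
p-values use a Student-t reference with the pooled within-group degrees
of freedom. The t reference is the package's small-sample correction:
with three replicates per group a normal reference is visibly
anticonservative, while the t reference keeps the empirical type-I error
at the nominal 5% level (the test suite checks 3-8% on 1000 null NB
regions) without sacrificing power on four-fold changes. With a single
replicate per condition the test falls back to Poisson (`alpha = 0`)
with a warning. Multiple testing is Benjamini-Hochberg; significance
means padj < 0.05. An adapter (`export_deseq2_inputs()`) writes counts,
design and spike factors for an external DESeq2 run when the full
dispersion machinery is wanted.

Pausing matrices pair each gene's promoter-proximal and gene-body
(distal) log2 fold changes and assign a sign quadrant; a zero fold
change maps to "unchanged" and the cell gets no quadrant rather than
being forced into one.

Quantile stratification (e.g. by promoter BRD4 signal) ranks regions and
cuts them into k near-equal groups, ties broken by stable region-id
order, extra members to the lower quantiles — fully deterministic.

## Target-gene assignment from contacts

An enhancer is assigned to a gene iff at least one contact with padj <
0.01 has one anchor overlapping the enhancer interval and the *other*
anchor overlapping the gene's effective span extended by the promoter
window (contact bins cannot separate a promoter from its proximal
region). The cross-anchor requirement matters: an anchor overlapping
both an enhancer and a gene does not pair them with itself. No distance
cap is applied by default. A *responsive* enhancer shows padj < 0.05
with negative log2 fold change; genes are reported in strata of 0, 1 and
>= 2 responsive enhancers.

## What the synthetic-data generator emulates — and what it does not

`simulate_genome()` lays out non-overlapping genes (round-robin across
chromosomes, 2-5 kb long, 6-12 kb apart), each with a promoter-proximal
peak (geometric decay over the first 500 bp, mean density =
`pausing_index` x body density; default pausing index 4), a uniform
body, 1-3 exons, optionally a second isoform with a downstream
alternative TSS (15%), and a divergent antisense unit upstream of the
TSS (60% of active genes). Intragenic enhancers are convergent antisense
units planted in single-isoform host bodies; extragenic enhancers sit in
intergenic slots cleared of promoter windows and termination zones; 70%
of enhancers are bidirectional with origins < 500 bp apart. Decoy
transcribed loci receive no histone marks; sn/snoRNA-like loci receive
high signal and an ncRNA mask. Spike-in units live on a `spike_`
chromosome at 1/8 of primary depth. Counts are Poisson draws around the
expected intensity (a gamma-mixing knob adds NB overdispersion for the
differential tests); reads invert the extraction convention exactly, and
UMIs are drawn distinct within each position (each nascent molecule is
its own molecule; UMI-space collisions are not modeled, which is what
makes duplicate-collapse bookkeeping exact). Mispriming and intermediate
rates default to 1% each — arbitrary but harmless knobs, since no
published estimate exists. A perturbation scales proximal and
body/distal compartments independently (spike intensity never moves),
generates one true contact per enhancer (to the host gene, or the
nearest transcribed gene) plus decoy and sub-threshold contacts, and can
couple a gene's body fold change to its number of connected enhancers
(`perturbation_enhancer_coupling`), emulating additive enhancer
contributions.

The generator does *not* emulate sequence composition bias, mappability,
alignment errors, overlapping gene dense regions (an option exists but
is off by default), chromatin-state heterogeneity of marks, or
distance-dependent contact background. Passing tests therefore certify
the *rules* — geometry, bookkeeping, normalization algebra, test
calibration — on clean signal; they do not certify robustness to
mapping artifacts or annotation errors in real data.

Test problem sizes are the package's own choices: the recovery checks
run on the default 200-gene genome at 2 x 10^6 reads; normalization and
pausing checks on 100-gene genomes with three replicates per condition;
calibration on 1000 directly simulated NB regions. Determinism is
absolute: one seed fixes every draw, and the generator consumes
randomness in a documented fixed order (genome, expression, elements,
sequence; then occupancy; then reads; then perturbation), so any stage
can be re-run bit-identically.

## Known limitations

* The transcription-unit caller is intentionally simpler than
  fold-over-background callers; on very noisy real data the per-base
  coverage threshold knob (`min_signal`) matters.
* Method-of-moments dispersion without shrinkage is noisier than
  DESeq2's shrunken estimates at low counts; the <6-read filter and the
  t reference compensate at the scale tested, but for deeply replicated
  real data the DESeq2 export adapter is the better route.
* CAT calls require the origin inside the host's effective span; a
  convergent unit originating just past the polyA site is not a CAT
  here.
* Enhancer centers are origin-derived, not signal-weighted; a
  bidirectional call's center is the origin midpoint even if the two
  units differ greatly in strength.
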