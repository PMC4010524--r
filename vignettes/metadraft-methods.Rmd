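---
title: "Methods: models, thresholds and design choices in metadraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in metadraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metadraft` reassembles the standard analysis chain for enrichment
metagenomes — composition-based binning, ANI-based species delineation,
fragment-recruitment island detection, codon-usage deviation, GC-skew
profiling, and 16S read classification — around a synthetic community
generator with complete ground truth. This vignette records the models,
the tunable parameters and why their defaults are what they are, and the
design decisions taken where the methodology is genuinely open.

## The synthetic community model

Each taxon is an order-*m* Markov chain over `{A,C,G,T}` (default
*m* = 2). Rather than drawing transition rows freely, every row is
*GC-pinned*: the conditional probability of emitting G or C equals the
taxon's GC target in every context, while log-normal multiplicative
biases (`signature_sd`, default 0.35) perturb the split *within* the
AT and GC base groups per context. The pinning decouples the two signals
a binner uses: realized genome GC is a binomial proportion around the
target (standard error ≈ 0.15 percentage points at 100 kb, so the ±2
point tolerance always holds), while the context biases create the
taxon-specific tetranucleotide signature. Order 2 is the smallest order
that yields distinct tetranucleotide spectra; the signature strength is a
free parameter in reality, and the default is chosen so that
three-taxon separation is comfortable rather than marginal — the
stress case can be produced by lowering `signature_sd`.

The default community emulates a three-member enrichment: an archaeal
host at 34% GC, an epsilonproteobacterium at 43% and a
gammaproteobacterium at 53%, at abundances 0.5/0.3/0.2. Strain pairs are
generated by independent per-site substitution at probability *d*
(uniform over the three alternative bases, no transition bias — only the
mean identity matters for ANI recovery), so a pair's expected ANI is
100·(1−*d*)%. The orchestrated run plants *d* = 0.15, which puts the
pair at ≈ 85% ANI, squarely on the "separate species" side of the 94%
boundary, matching the inter-species distances typical of confamilial
archaea; `d` < 0.3 is enforced because beyond that the seeded aligner's
premise (a dominant shared diagonal) starts to erode.

Contig lengths are log-normal with a 20 kb median truncated to
[1 kb, 200 kb] — scaled down from the tens-to-hundreds-of-kb contigs of
real 454 enrichment assemblies so that a 300-contig community fits in a
couple of megabases. Gene calls are synthetic non-overlapping intervals
(~800 bp, 50–150 bp spacers) carrying the contig's true taxon, with an
optional label-noise rate; they stand in for an external gene predictor,
which is out of scope. Read pools have normal lengths around 270 bp
(between the two platforms' empirical means), and the "water-column"
pool samples uniformly from the genome *excluding* island intervals —
the construction that makes planted islands recruitment-free by
definition. The generator does not model sequencing error, paired ends,
chimeras or assembly artifacts; a green test suite therefore
demonstrates correctness of the analysis logic under clean composition
signals, not robustness to platform noise.

## Composition profiles and projection

Oligonucleotide frequencies use word size *k* = 4 (tetranucleotides, the
field standard; `k` is configurable since word size is rarely reported).
Counting is single-strand with overlapping windows; words containing N
are skipped, and GC likewise excludes N from numerator and denominator.
A reverse-complement-collapsing flag exists but is off by default,
mirroring classic word-frequency tools.

The projection is an SVD of the column-centered frequency matrix —
centering only, no variance scaling, because the 256 frequency columns
already share a scale. Component signs are fixed by making each
component's largest-magnitude loading positive, so projections are
reproducible across BLAS implementations. Reference genomes are
projected *post hoc* into the fitted space (`project_profiles()`)
rather than co-fitted; co-fitting would let a large reference drag the
components of the contig cloud it is supposed to contextualize.

## Binning

Filtering keeps contigs with length ≥ 5,000 bp (the boundary itself is
retained) and ≥ 3 genes. Taxonomic uniformity is strict by default: all
informative (non-"unknown") gene labels must agree; a tolerant
majority-fraction mode exists for noisy-label benchmarks. Clustering
runs k-means (fixed seed, 25 restarts) on the first two principal
components plus standardized GC; k-means is a deliberate choice for
determinism, since in practice clusters of this kind are read off a
plot. A cluster inherits the majority uniformity label of its members,
and members whose own label disagrees are *flagged, never reassigned* —
the disagreement is the interesting signal. Bin statistics use
length-weighted means for GC and coverage; coding percentage is total
gene length over total contig length.

## Alignment and ANI

The local aligner is an affine-gap Smith–Waterman with match +1,
mismatch −1, gap open −2, gap extend −1 (a gap of length L costs
open + L·ext). The exhaustive dynamic program defines correctness; the
fast path seeds candidate diagonals with shared 13-mers, votes them into
band-width buckets, and runs the same recursion restricted to a ±48
diagonal band around the winners. For substitution-divergent sequences
the optimal path lies on the seeded diagonal, so the banded score equals
the exhaustive one; the test suite asserts this equality directly, both
with a full-width band (which must reduce the banded recursion to the
exhaustive one) and with seeded narrow bands on divergent copies. Score
ties break toward the smallest (query start, subject start). Identity is
matches over alignment columns.

ANI fragments the query into 1,020-bp non-overlapping windows (the
classical fragment length; terminal remainders shorter than half a
fragment are dropped, longer ones kept). Fragments are kept at ≥ 50%
identity over ≥ 70% of their length — the thresholds used for the
package's nucleotide comparisons generally; the older 30%/70% preset can
be set via the arguments. ANI is the *unweighted* mean identity of kept
fragments, and zero kept fragments yields an explicit undefined (`NA`)
rather than 0, which `species_call()` refuses to interpret. The
species boundary is inclusive: ANI ≥ 94.0 means same species. Both
one-directional and symmetric (two-direction average) modes are
reported because conventions differ between tools. Ortholog pairing is
reciprocal-best-hit with the same 50%/70% rule applied query-side, on
nucleotide CDS sequence — translated comparison is out of scope, and on
synthetic nucleotide CDS it would add nothing.

## Recruitment, islands, codon usage

Reads recruit at their best locus when they reach 50% identity over 70%
of their length. Windows tile the genome at 1 kb / 500 bp (artifact
choices — fine enough to resolve 15 kb islands, coarse enough to keep
profiles small); each recruited read increments *every* overlapping
window, so overlapping tilings intentionally multi-count boundary
reads, and window counts are a coverage proxy, not a partition of the
read set. Density is count per actual window length.

"Under-recruited" has no canonical numeric definition, so the island
caller uses density < 0.2× the genome-wide median: fully read-excluded
islands sit orders of magnitude below it (their only signal is flank
reads bleeding into boundary windows), while Poisson dips at ≥ 10×
coverage stay far above it (a window at 20× sees ~90 overlapping reads;
a 5-fold dip has vanishing probability). Runs closer than 2 kb merge,
and only runs strictly longer than 15 kb are reported. Boundaries snap
to window edges, so coordinates carry about one step of uncertainty and
recovery is evaluated by reciprocal overlap, not exact endpoints. A
zero-median profile (no recruitment at all) refuses to normalize and
calls nothing, with a warning.

Codon usage is counted in-frame from position 0 of each CDS, pooled
over the gene set, as fractions over the 64 codons; deviation between
two tables is the sum of squared fraction differences — symmetric, zero
iff identical. Island significance is assessed against a permutation
null: 200 random core-gene subsets of the same size as the island gene
set, scored against the core table. Recruitment defines island
coordinates; codon deviation only annotates them.

GC skew is (G−C)/(G+C) per 25 kb window stepped every 1 kb; windows
with no G or C report 0 with an explicit flag.

## 16S classification

A read needs > 100 aligned bases and ≥ 80% identity for any assignment;
≥ 95% identity earns the reference's genus, below that the read gets
the reference's high-level taxon. The 80% floor replaces the e-value
cutoff used with large databases: an e-value needs a database-size
model, and for a fixed labelled reference set an identity floor plus
the alignment-length rule provides the equivalent specificity control.
Taxonomy is deliberately flat — two fields, high-level and genus,
carried by the reference set — because rank sets "at or above class"
vary by nomenclature. Best-hit ties break by longer alignment, then
lexicographic reference id. The genus thresholds are asserted on every
output table.

## Problem sizes and determinism

Every stochastic function takes an integer seed and evaluates under a
temporary RNG state, so identical inputs and seeds give byte-identical
outputs (including FASTA artifacts); the orchestrated pipeline derives
per-stage seeds from one master seed and records a manifest (config
echo, versions, artifact checksums) sufficient for bit-identical
re-runs. The test and acceptance fixtures use 200 kb genomes, ~300
contigs, 20× read pools, 1,000-read 16S pools and 200-resample nulls —
sizes chosen so the full suite exercises every recovery guarantee at
comfortable statistical margins while a complete run stays in the
minutes range on a single core.

## Known limitations

* The generator's clean composition signal means binning results here
  are an upper bound on real-data performance; no sequencing error or
  chimera model is included.
* The seeded banded aligner can miss optima for alignments dominated by
  long indels; its guarantees are stated (and tested) for
  substitution-divergent sequences, which is what the divergence model
  produces. The exhaustive path remains available everywhere.
* Island coordinates are window-quantized; sub-window boundary accuracy
  is out of scope.
* rRNA gene *detection* (finding 16S genes inside contigs) and rRNA
  operon counting are not implemented; classification starts from reads
  already known to be 16S-like.
* `NA`-heavy inputs are tolerated in GC and k-mer counting (N-windows
  are skipped) but the generator itself never emits N.
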