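---
title: "Models and methods behind magqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magqc)
```

`magqc` evaluates the two lossy steps of genome reconstruction from
metagenomes — assembly and binning — using biologically interpretable
statistics rather than tool-internal diagnostics. This vignette documents
each model, the tunable parameters and their defaults, the numerical
choices, what the community simulator does and does not emulate, and the
design decisions that were genuinely open.

## Assembly continuity

`contig_stats()` reports the standard continuity statistics. N50 is the
length of the contig at which the cumulative length of contigs, sorted in
descending order, first reaches **at least** half the total assembly
length; L50 is the number of contigs in that prefix. The "at least" matters
only at ties: when the cumulative sum lands exactly on the half-total, the
prefix closes there, resolving toward the shorter N50-defining contig.
This is the convention of the mainstream assembly-evaluation tools, and it
is what the exhaustive prefix-scan oracle in the test suite asserts.
Alternative readings of L50 ("number of contigs longer than N50") are
ambiguous whenever several contigs tie at the N50 length, which is why the
prefix definition is used throughout.

No minimum-contig-length filter is applied by default; `min_contig` (and
the CLI's `--min-contig`) filters before the statistics when an analysis
wants parity with tools that default to, e.g., 500 bp.

The proportion of reads assembled is `100 × distinct mapped read ids /
total reads`. Multi-mapped reads count once — the quantity is "what
fraction of my sequencing effort made it into contigs", not an alignment
count. SAM ingestion honours exactly the flag bits this contract needs:
unmapped (0x4), secondary (0x100) and supplementary (0x800) records are
excluded, and duplicate (read, contig) pairs collapse to one. How the
upstream mapper treats mismatches or multi-mapping is outside the package:
the mapping file is taken as given.

## Composition profiling

All composition work uses canonical (strand-merged) kmers: every window is
counted once under the lexicographically smaller of the kmer and its
reverse complement, because contig orientation is arbitrary. Windows
containing `N` are skipped. Two kmer sizes serve two jobs:

* **k = 6** (`kmer_size_profile`) for mixture estimation, the range used
  by published composition-based profilers;
* **k = 4** (`kmer_size_assign`) for per-contig assignment, the
  tetranucleotide convention of the binning literature.

Mixture estimation solves non-negative least squares
`min ||A x − q||², x ≥ 0`, with reference frequency vectors as the columns
of `A`, then renormalises `x` to the simplex and drops taxa below `1e-4`
(numerical dust from the active-set solver, far below any meaningful
abundance). Per-contig assignment computes the Pearson correlation between
the contig's tetranucleotide profile and each reference; the best match is
assigned iff its correlation reaches `tau` (default 0.8), with ties broken
toward the lexicographically smaller taxon id for determinism. A contig
shorter than k is reported `UNASSIGNED` with no similarity.

The threshold-correlation design is deliberately transparent rather than a
reimplementation of any specific profiler's contig mechanism. It preserves
the one property the chimerism analysis needs: a 50/50 chimera's profile
is a blend of two genomes, correlates well with neither, and stays
`UNASSIGNED`, while genuine fragments ≥ ~5 kb correlate above 0.9 with
their source. For chimera screening specifically, a stricter `tau = 0.9`
is recommended (and used in the package's own checks): on simulated
communities the 90th percentile of chimera best-correlations sits near
0.85, while pure-fragment self-correlations stay above 0.95.

## Diversity and the chimerism contrast

For an abundance table with `S` taxa and `N` counts, `diversity_indices()`
returns Margalef richness `d = (S − 1)/ln N` (0 when `N = 1`), Shannon
entropy `H′ = −Σ pᵢ ln pᵢ`, Pielou evenness `J′ = H′/ln S` (undefined, and
reported `NA`, when `S = 1`) and the Simpson complement `1 − D = 1 − Σ pᵢ²`.
Natural logarithms are the default; `log_base` rescales `d` and `H′`
consistently (`J′` is base-invariant). The Simpson index is reported in
complement form so that larger always means more diverse, matching the
orientation of the other indices.

`assess_chimerism()` contrasts a read-level and a contig-level taxon table
of the same sample. The point contrast is Δ = contigs − reads in Margalef
richness and Pielou evenness. Uncertainty comes from a seeded bootstrap:
each table's `N` classified items are resampled with replacement
(multinomially) `B` times (default 1000, minimum 100 — percentile
intervals are unstable below), Δ-richness is recomputed per replicate, and
the 2.5/97.5 percentiles form the interval. Chimerism is flagged iff the
whole interval lies below zero: richness significantly lost in assembly.
A bootstrap contrast is used instead of an ANOVA across projects because a
single read/contig file pair carries no replicate structure; project-level
hypothesis testing on the emitted tables is left to downstream statistics
tools. Abundance tables are presence counts (one per classified item) by
default; length weighting is available where contigs should count by bp.

Calibration, verified in the test suite at `N = 10⁴` over 100 seeded
replicates: when the contig table is itself a resample of the read table
the flag fires ≤ 5% of the time, and when 30% of taxa are removed it fires
≥ 95% of the time.

## Bin quality and classification

Per bin, `bin_quality()` reports contig count and total bp; unweighted
mean and sample standard deviation (`n − 1`) of per-contig GC (GC excludes
`N` from the denominator; a single-contig bin has `gc_sd = 0`); genus
composition from the per-contig assignments — dominant genus and its
**length-weighted** share (unassigned bp stays in the denominator), the
count-based unassigned fraction, and genus richness as both the Margalef
index and the raw genus count (the two readings of "species richness" in
use for bins; both columns are emitted so either can be consumed);
and marker completeness `100·m/M` / contamination `100·excess/M` against a
universal single-copy marker set of `M = 104` opaque identifiers. Marker
*detection* is deliberately external: any annotator's hits can be supplied
as a TSV, and the simulator fabricates hits with known content for
testing. Lineage-specific marker refinement is a documented
simplification left to dedicated completeness tools.

Classification applies two rules in order, then a residual:

1. **MAG** — `dominant_share ≥ mag_dominance` (default 0.8). "One genus"
   is operationalised as a dominance threshold rather than literal 100%
   purity because real bins almost always carry a few contigs from
   distant taxa (horizontal transfer, binning noise); the threshold is a
   declared free parameter, not an inferred constant.
2. **POTENTIALLY_NOVEL** — dominance failed but completeness ≥
   `novel_min_completeness` (default 50%): substantially complete genetic
   material that composition profiling cannot place, covering both
   high-unassigned bins and many-low-abundance-genera bins.
3. **MIXED** — everything else.

Labels partition the bin set; raising either threshold can only shrink its
rule's class (monotonicity, property-tested). Project summaries report
percentages rounded to two decimals and a genus table restricted to genera
above a 20% within-bin display share.

## Genome relatedness

`anib()` follows the fragment convention of the standard ANI tools: the
query is cut into 1020 bp windows (a terminal remainder is kept iff
≥ 200 bp), each fragment is aligned to the subject on both strands, and a
fragment contributes iff identity ≥ 30% over ≥ 70% of its length; ANI is
the mean identity of contributing fragments, and `same_species` is
strictly `ANI > 95`. Alignment is exact 15-mer seeding followed by
gap-free extension along the best-supported diagonal: fragments vote over
all seed hits, the modal diagonal wins, and identity is the base-match
fraction over the overlap. This is exact for substitution divergence (the
simulator's mutation model) and appropriate for the ≤ 5–10% divergence
range where ANI is informative; at 5% divergence a fragment still carries
~68 seeds with a ~46% per-seed exact-match probability, so fragments
essentially never go unseeded. Indel-rich comparisons would need a gapped
extender and are outside the intended range. ANI is computed on nucleotide
fragments (the procedure of the tools the convention comes from), not on
extracted protein-coding genes.

`tetra_zscores()` compares strand-merged observed tetranucleotide counts
with the maximal-order Markov expectation
`exp(w₁w₂w₃w₄) = n(w₁w₂w₃)·n(w₂w₃w₄)/n(w₂w₃)` and variance
`exp·(1 − n(w₁w₂w₃)/n(w₂w₃))·(1 − n(w₂w₃w₄)/n(w₂w₃))`; entries with zero
expectation or variance get `z = 0`. Several variance approximations exist
in the literature; this one is the common choice, and TCS values
(`tcs()` = Pearson correlation of two z-vectors) are therefore comparable
only within this implementation. Sequences shorter than 5 kb are rejected
(z-scores are unstable below; configurable).

## The community simulator

The simulator emulates the axes along which real projects differ:
taxonomic diversity (number of genomes), GC content (default spread
0.35–0.65 across the community), abundance skew, pairwise divergence, and
sequencing platform — Illumina-like (250 bp reads, 0.1% substitution
error) versus IonTorrent-like (200 bp reads, 1% error with substitutions,
insertions and deletions at 2:1:1 odds, flat along the read; no
homopolymer-length modelling).

Genomes are either i.i.d. base sequences (`bias_beta = NULL`) or carry a
per-genome **composition-neutral word bias**: for each of the 16
dinucleotide contexts, the fixed GC probability mass is split between G
and C — and the AT mass between A and T — by Beta(`bias_beta`,
`bias_beta`) draws made once per genome (default `bias_beta = 1`, uniform
splits). Because every context keeps `P(G) + P(C)` exactly at the genome's
GC, local GC cannot drift along the genome, so the signature is
homogeneous — the property that makes tetranucleotide binning work on
2–5 kb fragments of real genomes — while the context-specific preferences
give each genome a strong fingerprint. (An earlier design that perturbed
whole transition rows was rejected: unconstrained rows can create
compositional attractor regions, i.e. genomes whose windows drift away
from their own genome-wide profile, which real genomes do not show at
this scale.) Under the defaults, 5 kb fragments correlate ≥ 0.95 with
their source genome, distinct genomes' profiles correlate ≤ ~0.7, and
50/50 chimeras' best correlations concentrate near 0.8 — verified across
independent community seeds.

Chimeric contigs concatenate two half-slices from two different genomes.
By default the parents are drawn from compositionally distant pairs
(profile correlation at or below the median over all pairs), matching the
divergent-parent character of the chimeras that random sequence overlap
produces; `distant_pairs = FALSE` draws any distinct pair. The chimera
count is exactly `round(chimera_fraction × n_contigs)`, and every contig's
source genome(s) and chimera flag are returned as ground truth.

What the simulator does **not** emulate: gene structure and coding bias,
repeat content, realistic error profiles (homopolymer effects, quality
decay), actual assembly (contigs are slices, not assembled reads), and
coverage-dependent binning signals. Passing tests on simulated data
therefore demonstrate the *metrics* behave correctly against known truth —
they do not certify any particular assembler or binner on real data, where
those unmodelled features matter.

`mutate_genome()` substitutes each site independently with probability
`sub_rate` to a uniformly chosen different base and returns the exact edit
list, so identity-based metrics can be checked against construction.

## Determinism and numerical conventions

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state (`withr::with_seed`), so identical seed + inputs give
bit-identical outputs — including the end-to-end workflow, whose stage
TSVs and JSON manifest are byte-reproducible (the manifest records input
digests, config and seed, never timestamps). Coordinates in fragment
tables are 1-based inclusive, the native R convention. Sequences are
uppercased on ingest and restricted to `A/C/G/T/N`; anything else is
rejected with the offending position named, on the principle that corrupt
input should fail at the boundary, not as a strange result later.

## Problem sizes in the package's own checks

The test suite exercises the statistics at sizes chosen to make the
guarantees meaningful while staying comfortable on a laptop: 10-genome
communities of 100 kb genomes for classification and mixture recovery
(100 contigs of 5 kb; 100k reads for the sampled-mixture check), 100
seeded replicates at N = 10⁴ for the chimerism calibration, and 20
replicates per divergence level on 0.5 Mb genomes for ANI. The acceptance
script (`scripts/acceptance.R`) re-runs the same computations at
comparable sizes from a single command-line seed.
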