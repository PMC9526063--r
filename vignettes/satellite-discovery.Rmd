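---
title: "Satellite family discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellite family discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(satfam)
```

This vignette documents the models behind each pipeline stage, the tunable
parameters with their defaults and rationale, the numerical conventions,
and the limits of what the synthetic-genome tests demonstrate.

## The problem

Satellite DNA consists of tandem arrays of a short monomer (here ~20–400
bp) that can occupy several percent of a genome. Two questions drive the
pipeline: *which* satellite families dominate an assembly (by total covered
bases), and *how* each family is distributed along chromosomes — many small
arrays scattered everywhere (the pattern expected around holocentric
chromosomes) versus one dominant cluster per chromosome (the classical
monocentric pattern). The package answers both from a FASTA assembly alone
and reports distribution statistics only; it makes no claim about
centromere identity, which would require CenH3 ChIP evidence.

## Tandem repeat detection

**Candidates.** An exact k-mer (default `k = 13`) recurring at distance
`d` is evidence of periodicity `d` at that locus. Candidates are
deduplicated to one per period per monomer-length window. A 13-mer is long
enough that random recurrences within the 2 kb period window are rare
(expected ≪ 1 per 10 kb of random sequence) and short enough that arrays
diverged by several percent still seed reliably.

**Wraparound alignment.** The core scoring aligns a genomic segment
globally against unlimited tandem copies of a monomer: dynamic programming
over one column per monomer position, with the column index wrapping
modulo the period. Start and end phase are free. Scoring is additive —
`+match` per match, `−mismatch` per mismatch, `−indel` per indel column —
with defaults 2/7/7, `min_score = 50`, `min_copies = 2`, periods 1–2000
bp: the canonical parameterisation used for tandem-repeat scanning, stated
explicitly so that full-scale runs are reproducible. The wrapped
horizontal dependency is resolved with two sweeps per row; a deletion
chain never benefits from wrapping more than once, so two sweeps are
exact.

**Extension and reporting.** Each candidate is extended left and right
while the row-maximum score improves, terminating after an X-drop of 30
points (standard drop-off behaviour; bounds runtime). The segment is first
aligned against the raw monomer to derive a per-column majority consensus,
then re-aligned against that consensus; the reported score, copy number
(monomer columns consumed divided by the period) and percent identity
(matches over aligned columns) all refer to this final alignment, and the
consensus — not the first copy — is the reported `base_seq`. This makes
every reported hit exactly reproducible by a single direct alignment of
its interval against its reported monomer, which is how the test suite's
brute-force oracle checks it.

**Redundant period variants.** A tandem array with period `p` also
produces k-mer recurrences at `2p, 3p, …`, and (via indels) at near
multiples such as `2p − 1`. Re-evaluating a multi-kilobase array at every
multiple is both wasteful and confusing for downstream period statistics,
so a longer-period variant of an already-explained locus is kept only when
it *improves* percent identity by more than `ident_delta` (default 0.5
points), up to `max_multiple` (default 8) times the covering period.
Genuine higher-order structure shows up exactly this way: an array built
from alternating monomer variants aligns imperfectly at the monomer period
but (near-)perfectly at the block period, so both hits are reported — the
behaviour the consensus stage relies on for HOR detection. Pure arrays, in
contrast, report only their fundamental period. Equally-scoring competing
periods at one locus are all retained; the interval merge downstream is
explicitly designed to absorb such redundancy.

**Degenerate inputs.** Homopolymers and dinucleotide microsatellites are
detected (period ≥ 1) but excluded from family clustering by the
clustering stage's `min_period = 10`, since satellite families of interest
here are tens of bases and longer and microsatellites would otherwise
dominate the census.

## Family clustering

**Rotation tolerance.** Tandem-repeat detectors report monomers at an
arbitrary rotation (and strand) of the underlying circular sequence.
Clustering therefore (i) reduces every monomer to a canonical form — the
lexicographically smallest rotation over both strands — and joins
identical canonical forms by definition, and (ii) aligns each
representative monomer against the *triple self-concatenation* of every
other, so that any rotation of a homologous monomer can align full-length.
Both query orientations are searched. Each unordered pair is evaluated in
both directions (A against B's triple and B against A's triple): the
directions are not symmetric when periods differ, and the longer-into-
shorter direction is what links a base monomer's family to its
higher-order multiples.

**E-values.** Alignment scores convert to E-values by the Karlin–Altschul
formula `E = K·m·n·exp(−λS)`, with `λ` the positive root of
`Σ p_s exp(λ s) = 1` and `K` computed by the classical convergent series
over partial-sum distributions on the score lattice, both at uniform base
frequencies. For the default match/mismatch of +2/−3 this yields
λ = 0.634, K = 0.408 — matching the published constants for this scoring —
and the gapped alignments reuse the ungapped constants, the standard
practical approximation. The search space is `m` = query monomer length
and `n` = summed tripled subject lengths, mimicking a database search.
Edges require `E ≤ 1e−20`.

A consequence worth stating: a perfect full-length self-match of a 31-bp
monomer scores 62, and no 31-bp alignment can reach `E ≤ 1e−20` in any
realistic search space. Short-monomer families therefore cohere through
exact canonical-form identity (which, after consensus building, covers
nearly all members), while monomers of roughly 80 bp and longer also link
through alignment — including across HOR multiples. This is inherent to
the cutoff, not an implementation artifact, and it is why the canonical
dedup step is part of the clustering definition rather than a mere
optimisation.

**Period selection.** "Highly represented" period sizes are those whose
census total copy number reaches `max(100, 1% of the grand total)` —
an absolute floor so that desk-scale runs behave, and a relative floor so
that the rule is scale-free on full assemblies. Both knobs are exposed in
`cluster_params()`.

## Metrics and ranking

Member-hit intervals are merged per family with bookended semantics
(touching intervals unite — the default of the standard interval-merge
tooling), implemented over `GenomicRanges::reduce()`. Metrics are computed
for the 20 largest groups by instance count (configurable), then families
are ranked by total covered bases, ties broken by instance count and then
label; this honours both selection rules that are natural here — groups
prominent by instance count, final ranking by footprint. Combined genome
fraction uses the interval *union* across the selected families, so
co-located families are not double-counted. Fractions are reported to
three decimals.

## Consensus and higher-order periods

The base period is the modal member period, ties broken toward the smaller
period (the monomer is the smallest repeating unit; an HOR family whose
block period ties with its monomer period should report the monomer).
Members at the modal period are canonically rotated, re-phased against the
most frequent canonical sequence by minimum Hamming distance over all
rotations and strands (star alignment), and voted column-by-column; ties
break by base precedence A < C < G < T. Members at HOR multiples
contribute to HOR detection but not to the vote, avoiding phase ambiguity.
The final consensus is reported in canonical rotation so it is stable
under growth of the member set and member rotation. HOR detection reports
every distinct member period within ±2 bp of an integer multiple (≥2) of
the base period; the 2-bp tolerance accommodates single-indel variants
such as a `2p − 1` block period.

## Distribution profiling

Merged intervals on each chromosome are chained into positional clusters
by single linkage with maximum gap `cluster_gap`. The default is adaptive:
2% of the chromosome length, capped at 500 kb. On multi-megabase
chromosomes this is effectively the fixed large-scale gap appropriate to
genome-browser-scale clustering; on short chromosomes it scales down so
the dispersed/localized contrast remains meaningful rather than collapsing
every chromosome into one cluster. A family is `localized` when its
largest cluster holds ≥ 50% of its bases on ≥ 75% of occupied chromosomes,
`dispersed` when the largest-cluster fraction stays below 50% on the same
majority, and `mixed` otherwise — the qualitative contrast made
reproducible, with all three thresholds exposed in `profile_params()` and
the underlying largest-cluster fractions reported alongside the label.
Co-localization tiles chromosomes into 200-kb bins (1 bp of overlap
occupies a bin); the GC track uses non-overlapping 200-kb windows, final
partial window kept, ambiguous bases excluded from the denominator and
all-ambiguous windows reported as missing.

## The synthetic-genome simulator

The simulator emulates the statistical structure the analysis assumes:
uniform background at a chosen GC (default 0.37, a typical plant
background), families planted either as many small arrays per chromosome
(dispersed) or as one dominant array plus sporadic small arrays per
chromosome (localized), per-copy substitution and single-base indel
divergence, optional HOR block structure via cycled monomer variants,
arrays on either strand, and interspersed *identical, non-tandem* copies
of a decoy sequence as a transposon-like negative control. Placement is
rejection sampling with a 1000-retry cap; arrays never overlap and never
span chromosome ends, so truth intervals are well defined. Coordinates are
0-based half-open internally; exported GFF3 is 1-based inclusive. One seed
fully determines the genome and manifest.

Default study conditions used in the recovery tests: dispersed families of
period ~29–31 bp with 20–60 copies per array and 2% substitution
divergence, 30 arrays per chromosome on 4 × 500 kb chromosomes; localized
families of period 155 bp with a ~50-kb dominant array and three ~2-kb
sporadic arrays per chromosome on 2 × 150 kb chromosomes, evaluated across
20 seeds. These sizes exercise every stage (seeding, extension across
multi-kilobase arrays, rotation-tolerant clustering, ranking,
classification) at desk scale; they are the package's chosen test
conditions, not tuning targets.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: realistic transposon landscapes (only identical
decoys), assembly gaps and collapsed arrays, multi-base indels and
segmental rearrangements within arrays, library-of-variants monomer
evolution (divergence is i.i.d. per copy from one master), and GC
heterogeneity of real chromosomes. Full-scale behaviour on real
assemblies additionally depends on the detector scoring thresholds;
treat `min_score` and the scoring triple as a sensitivity axis there.

## Numerical conventions and determinism

Alignment tie-breaks prefer the diagonal move, then the segment-insertion
move, then the monomer-deletion move; consensus ties prefer A < C < G < T;
the canonical-rotation order treats N after T. The Karlin–Altschul λ is
solved to 1e−12 by root bracketing; the K series is truncated when a term
falls below 1e−12 (well inside double precision for all sane scorings),
and scorings with non-negative expected score are rejected as degenerate.
All randomness flows through explicit integer seeds; `build_genome()`
restores the caller's RNG state, and `run_pipeline()` seeds once from its
configuration so identical input plus configuration reproduces identical
output byte-for-byte.

## Known limitations

- Greedy X-drop extension can leave or take a few bases at array edges;
  interval boundaries are reproducible but not guaranteed to mirror
  exactly under reverse complementation (periods and footprints do).
- The E-value cutoff of 1e−20 makes alignment-based linking impossible for
  monomers shorter than ~80 bp (see above); families of short monomers
  rely on exact canonical identity of their consensus monomers.
- HOR reporting depends on the longer period improving identity by more
  than `ident_delta`; HOR blocks whose variants differ by much less than
  one substitution per monomer copy can fall below this margin.
- Distribution labels on chromosomes carrying very few arrays are noisy by
  construction; the per-chromosome largest-cluster fractions should be
  consulted alongside the label, and are always reported.
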