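# satfam

Satellite repeat family discovery and chromosomal distribution profiling for
genome assemblies.

Satellite DNA — long tandem arrays of a short repeated unit (the *monomer*)
— is a major component of plant and animal genomes and is frequently
associated with centromeres. How satellite arrays are arranged along
chromosomes is informative about centromere organisation: monocentric
chromosomes typically carry one dominant satellite cluster per chromosome,
while holocentric chromosomes show many small arrays scattered along their
length. `satfam` implements the full computational path from an assembly
FASTA to that comparison:

1. **Tandem repeat detection.** Exact k-mer recurrences seed candidate
   periods; each candidate array is extended by *wraparound dynamic
   programming* — global alignment of the genomic segment against unlimited
   tandem copies of the monomer, with the DP column index wrapping modulo
   the monomer length — under additive scoring (+2 match, −7 mismatch,
   −7 indel by default) with X-drop termination. Each hit reports period,
   copy number, percent identity, score, and the array consensus.
2. **Rotation-tolerant family clustering.** Monomers of highly represented
   period sizes are self-concatenated into triples, so any circular
   permutation of a homologous monomer aligns full-length. Pairwise
   word-seeded gapped local alignments are converted to E-values via
   Karlin–Altschul statistics, `E = K·m·n·exp(−λS)`, with `(K, λ)` solved
   from the ungapped theory for the chosen scoring (for the default
   +2/−3 scoring: λ = 0.634, K = 0.408). Families are the connected
   components of the similarity graph at `E ≤ 1e−20`.
3. **Family metrics.** Per-family intervals are sorted and merged
   (bookended intervals unite), families are ranked by total covered bases,
   and genome fractions are computed from interval unions.
4. **Consensus and higher-order repeats (HORs).** A canonical-rotation,
   star-alignment majority vote builds each family's consensus monomer;
   member periods near integer multiples of the base period (±2 bp) are
   reported as HOR periods with their multipliers.
5. **Distribution profiling.** Merged intervals are chained into positional
   clusters per chromosome; each family is labelled `localized` (one
   dominant cluster per chromosome), `dispersed` (scattered), or `mixed`,
   alongside per-window family co-localization counts and a windowed GC
   track.

A deterministic synthetic-genome simulator plants satellite families with a
ground-truth manifest (dispersed or localized spatial modes, divergence,
HOR block structure, reverse-strand arrays, interspersed non-tandem decoys),
so every stage of the pipeline is testable without external data.

## Worked example

```r
library(satfam)

set.seed(7)
rand <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
fams <- list(
  family_spec("SAT31",  rand(31),  "dispersed", n_arrays_per_chromosome = 12,
              copies_min = 20, copies_max = 60, substitution_rate = 0.02),
  family_spec("SAT155", rand(155), "localized", n_arrays_per_chromosome = 2,
              copies_min = 12, copies_max = 14, substitution_rate = 0.02,
              dominant_copies = 200))
spec   <- sim_spec(n_chromosomes = 2, chromosome_length = 2e5,
                   background_gc = 0.37, families = fams, seed = 42)
genome <- build_genome(spec)
res    <- run_pipeline(genome$assembly, satfam_config(seed = 1, top_n = 2))
print(res)
```

```
satfam pipeline result
  hits: 30  | represented periods: 31, 155
  top families (combined genome fraction 24.6%):
 family_id base_period n_instances total_bases genome_fraction     label
        F2         155           6       70376          17.594 localized
        F1          31          24       28026           7.006 dispersed
```

Both planted families are recovered: the 155-bp family planted as one
dominant array per chromosome is labelled `localized`, the scattered 31-bp
family `dispersed`; the reported genome fractions (17.6% and 7.0%) reflect
the planted footprints. `run_pipeline(..., out_dir = "out")` additionally
writes hit GFF3/TSV, family assignments, merged-interval BED, consensus
FASTA, the HOR table, the distribution report, a GC bedGraph and a JSON run
manifest. `plot(res)` draws family locations over a windowed GC strip, one
row per chromosome.

A thin command-line front end over the same functions is installed at
`inst/scripts/satfam.R`:

```sh
Rscript inst/scripts/satfam.R simulate --config spec.yaml --out-prefix sim
Rscript inst/scripts/satfam.R detect   --fasta sim.fa --out hits.gff3
Rscript inst/scripts/satfam.R run      --fasta sim.fa --out-dir out
```

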