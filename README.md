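# mmejscan

Alignment-free detection of microhomology-mediated end-joining (MMEJ)
deletions in short-read sequencing data.

## The problem

MMEJ repairs a DNA double-strand break by annealing two short identical
sequences ("homologies", ≥ 5 bp) that lie close together (≤ 100 bp
apart), deleting one homolog copy plus the intervening bases. The
outcome is deterministic: given a reference genome, *every possible*
MMEJ deletion can be enumerated in advance. These medium-sized (6–100
bp) deletions are exactly the ones alignment-based variant callers
handle worst — reads spanning the junction get soft-clipped or
misplaced, and callers disagree with each other.

`mmejscan` inverts the problem. Instead of interpreting alignments it:

1. **indexes** all homolog pairs — maximal exact repeats of length
   *L* ≥ 5 whose copies start *D* ∈ [6, 100] bases apart — by diagonal
   scanning of 240 bp windows (step 100 bp), with full-contig
   maximality checks and window deduplication;
2. **precompiles** each pair's junction *search sequence*: 15 bp of
   upstream context + the retained homolog + 15 bp of downstream
   context in the post-deletion product, for the perfect-match deletion
   and for the one-base imperfect variants (type A: one extra base
   deleted left of the junction, type B: right). Candidates whose
   search sequence occurs verbatim in the reference (either strand) or
   whose deleted segment is > 80 % microsatellite are filtered out;
3. **scans** reads for exact occurrences of each search sequence —
   the full read sequence, soft-clipped bases included, so the
   aligner's representation is irrelevant — and reports supporting
   reads, local depth, and VAF = support / junction-spanning effective
   depth;
4. **classifies** matched tumor/normal calls (somatic: tumor VAF > 0.1,
   normal support = 0, depth > 30 both; germline: both VAFs in
   [0.1, 0.86], depth ≥ 30 both), observed deletions by junction
   homology (MMEJ ≥ 5, short-homology < 3) and flank signature
   (e.g. `GT_CG`), and sequence context (minisatellites, G-quadruplex
   motifs, extended-homolog mispairing potential) with two-proportion
   z-tests and Bonferroni correction;
5. **simulates** its own benchmark: a synthetic reference with planted
   homolog pairs on a repeat-free background, spiked deletions at
   chosen VAFs, error-configurable paired-end reads written as
   BAM (+FASTQ) with D-op or soft-clip junction CIGARs, and
   sensitivity/specificity scoring against the known truth.

## Worked example

```r
library(mmejscan)

## synthetic experiment: 30 kb contig, 25 planted homolog pairs,
## 10 deletions spiked at VAF 0.5, 60x error-free 2x150 bp reads
sim   <- makeReference(seed = 11, contigLen = 30000, nPairs = 25)
truth <- chooseTruth(sim$manifest, 10, vafs = 0.5, seed = 3)
reads <- simulateReads(sim$reference, truth, coverage = 60, seed = 5,
                       outPrefix = tempfile("demo"))

index <- buildHomologIndex(sim$reference)
index
#> HomologIndex with 25 homolog pairs
#>   contigs: sim1
#>   homolog length: 5 - 12 bp; deletion span: 24 - 79 bp
#>   overlapping (tandem-periodic) pairs: 0
#>   config: window=240, step=100, kMin=5, dMin=6, dMax=100, allowOverlap=1

cand  <- generateCandidates(index, sim$reference)
calls <- callCandidates(reads$bam, cand)
benchmarkCalls(calls, truth, vafThreshold = 0.05)
#> BenchmarkResult
#>   TP=10 FN=0 FP=0 TN=65
#>   sensitivity = 1.0000, specificity = 1.0000
```

All 10 spiked deletions are recovered (TP), none of the 65 other
candidate loci (the remaining perfect candidates plus all imperfect
A/B variants) attract a single supporting read (TN) — with exact
35-mer matching on error-free reads there is nothing for a false
positive to come from. Per-call evidence is in
`deletionCalls(calls)`: supporting reads, flanking depth, effective
depth and VAF per candidate. `exportVCF(calls, sim$reference,
"calls.vcf")` writes the supported calls as VCF 4.2 with `HOMLEN`,
`HOMSEQ` and `MATCHTYPE` tags.

A command-line wrapper with the same workflow
(`index / candidates / scan / call / region / context / simulate /
benchmark` subcommands) is installed at
`system.file("scripts", "mmejscan.R", package = "mmejscan")`.

## Scope and limitations

Only exact homologies and one-base imperfect variants are modelled;
templated-insertion junctions are out of scope. The tandem-repeat
detector finds perfect repeats only (no mismatch-tolerant alignment
scoring), and the G-quadruplex detector is a motif grammar, not a
thermodynamic model. Exact-substring matching loses sensitivity on
high-error reads. See the methods vignette
(`vignettes/mmejscan-methods.Rmd`) for the model, parameter
definitions, estimator details and design rationale.
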