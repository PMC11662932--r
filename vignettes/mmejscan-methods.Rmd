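---
title: "Detecting MMEJ deletions without alignment: methods and design"
author: "mmejscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting MMEJ deletions without alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmejscan)
```

## The problem and the model

Microhomology-mediated end joining (MMEJ) repairs a double-strand break
by annealing two short identical sequences — homologies — that flank the
break, then trimming the unpaired flaps. The repaired chromosome retains
exactly one homolog copy; the other copy and the bases between the two
copies are deleted. Because the outcome is determined by the sequence
alone, the complete set of possible MMEJ deletions of a genome can be
written down in advance: one candidate deletion per *homolog pair*, a
maximal exact repeat of length $L \ge 5$ whose two copies start
$D$ bases apart with $6 \le D \le 100$.

Short-read aligners handle these medium-sized deletions poorly: a read
spanning the junction is soft-clipped, split, or placed with a shifted
gap, so alignment-based callers disagree with each other and miss real
events. `mmejscan` therefore never asks the aligner where the deletion
is. For each homolog pair it precomputes the *junction search sequence*
— the post-deletion product restricted to `flank` bases of upstream
context, the retained homolog, and `flank` bases of downstream context —
and counts the reads whose raw sequence contains that string exactly.
With the default `flank = 15` the search sequence is a $(30 + L)$-mer;
for a random genome the expected number of chance occurrences of a
35-mer is negligible, which is what makes the exact-substring criterion
specific.

Three variants are generated per pair. The perfect-match deletion
removes $[\mathrm{start}_1, \mathrm{start}_2)$. The imperfect variants
remove one extra base immediately left (type A) or right (type B) of the
perfect junction; they are the sequence-level signature of the repair
machinery extending the paired homology by one base at the cost of a
mispair, and occur at roughly a tenth of the frequency of perfect
matches. Type B's deleted bases are the downstream homolog copy plus
one base, which is equivalent to the contiguous interval
$[\mathrm{start}_1 + L, \mathrm{start}_2 + L + 1)$; records store that
contiguous form so all downstream interval logic is uniform.

## Homolog discovery

`findHomologsWindow()` finds maximal exact repeats by scanning the
diagonals of the implicit self-comparison matrix: for each offset $d \in
[d_\min, d_\max]$ the positions with `seq[i] == seq[i + d]` form runs,
and each maximal run of length $\ge k_\min$ is one pair. This
reproduces the "dot-plot" contract (nested and consecutive homologies
collapse into the longest run) in $O(n \cdot d_\max)$ without building
the matrix. `N` never matches, so assembly gaps cannot create pairs.

`buildHomologIndex()` slides 240 bp windows in steps of 100 bp,
translates window-local hits to contig coordinates, re-extends each hit
to maximality against the *full contig* (so a window edge can never
truncate a pair), and deduplicates hits found in overlapping windows.
Sliding-window completeness requires
`step <= window - dMax - kMin + 1`; with the defaults (100 vs 136) every
pair in range is fully visible, with at least `kMin` matching positions,
in at least one window — the constructor enforces this inequality rather
than the weaker `step <= window - dMax`, which would still allow a run
to straddle a boundary in fragments shorter than `kMin`. Pairs whose
copies overlap (`start2 < start1 + length`, i.e. tandem periodicity) are
kept and flagged; genuinely low-complexity candidates are removed later
by the microsatellite filter.

## Artifact filters

Two filters remove candidates whose junction string cannot be trusted:

* **Reference self-match**: a search sequence that occurs verbatim
  anywhere in the unedited reference (either strand) is uninformative,
  since a normal read can contain it. The filter is an exact substring
  scan of both strands. The same intent is often implemented by mapping
  the search sequences back to the genome and discarding complete
  matches; the direct scan is deterministic and needs no aligner.
* **Microsatellite content**: candidates whose deleted segment is more
  than 80% covered by perfect tandem repeats of unit 1–4 are removed, as
  deletions in such low-complexity runs are indistinguishable from
  replication slippage artifacts. Coverage is computed from the perfect
  tandem-repeat detector with one refinement: a homopolymer must run at
  least 3 bases to count. A merely doubled base (e.g. `CC`) satisfies
  the letter of "two full copies of a unit-1 repeat" but is not a
  microsatellite by any practical definition, and counting it would put
  ~19% of random bases inside "repeats".

## Scanning and VAF

For each candidate the scanner fetches reads overlapping the pair padded
by 100 bp, and counts reads whose sequence contains the search sequence.
By default the *full* read sequence is searched, including soft-clipped
bases (`searchSpace = "full_read"`): junction-spanning reads are exactly
the reads aligners tend to clip, and the whole point of the method is to
be independent of how the aligner represented them. `aligned_only` is
available to quantify that effect. BAM stores sequences on the forward
reference strand, so only the forward search sequence is needed; FASTQ
mode (amplicon data) searches both orientations. Mates are distinct
reads; duplicate-flagged reads are excluded.

Local depth is the mean per-base coverage over the 5 positions
immediately upstream of the first copy and the 5 immediately downstream
of the second copy — just outside the deletion, so both haplotypes
contribute.

A read can only evidence the junction if it spans the entire search
sequence: of the `readLen` placements that cover a given base, only
`readLen - k + 1` contain a given $k$-mer. Dividing the supporting-read
count by the raw flanking coverage therefore underestimates the allele
fraction by the factor $(readLen - k + 1)/readLen$ (about 0.77 for
150 bp reads and $k = 35$). `mmejscan` reports
`vaf = support / eff_depth`, with `eff_depth` the flanking coverage
scaled by that factor (read length taken as the modal length of the
fetched reads). This estimator is unbiased — the spike-in recovery
checks in the test suite confirm it across VAFs 0.05–0.5 — and is the
default (`vafDenominator = "junction"`); the unscaled ratio is available
as `vafDenominator = "raw"`. Raw depth, effective depth, support and VAF
are all reported per call. VAF is clamped at 1 with a warning counter,
because the support window and the depth windows are different pieces of
sequence and can disagree slightly in either direction.

## Somatic/germline classification

`classifyPaired()` applies fixed thresholds to a matched tumor/normal
pair of calls: somatic requires tumor VAF > 0.1, **zero** supporting
reads in the normal, and depth > 30 in both samples (strict); germline
requires both VAFs within [0.1, 0.86] and depth ≥ 30 in both
(inclusive). The asymmetry between the strict somatic and inclusive
germline depth bounds follows the rule set as stated; the normal-VAF
"= 0" clause is deliberately tested as zero supporting reads rather than
a small threshold. Cross-cohort exclusion ("not seen in other datasets")
is generalised to a user-supplied blacklist of loci, since the original
cohorts are not reproducible inputs. The two rules cannot both fire
(somatic needs normal VAF 0, germline needs ≥ 0.1), so the verdict is
total and unambiguous; every `NONE` carries the failed clauses.

## Hotspot mode and repair-mechanism classes

`enumerateRegionDeletions()` bypasses the homolog index and builds the
junction string of *every* deletion of length 6–100 starting in a small
region — the right tool for CRISPR cut sites and known hotspots.
Distinct (start, length) pairs that produce the same search sequence
(deletions shifted within a repeat) are collapsed to the leftmost
representative with a multiplicity count, since reads cannot distinguish
them. The cap (10 kb) exists because the candidate count grows as
region width × 95.

`classifyDeletionMechanism()` assigns an observed deletion to a repair
class from its junction homology — the longest exact match between the
sequence entering and leaving the junction, measured by both the right-
and left-slide comparison: ≥ 5 is MMEJ, < 3 is short-homology
(NHEJ/POLQ-compatible), and 3–4 is labelled INTERMEDIATE (the band is
real but has no established name; thresholds are parameters). The
flank signature — two bases either side of the junction in the repaired
sequence, e.g. `"GT_CG"` — distinguishes perfect repair from the
one-base mispair outcomes, whose signatures differ in exactly one
position. `extensionPotential()` tests the sequence configuration that
enables the mispair: skipping one mismatched base beyond the homolog
lets pairing continue if `a2 == b1` or `a1 == b2`; under uniform random
flanks conditioned on the junction mismatch the rate of this
configuration is exactly $7/16 = 0.4375$ (exhaustive enumeration of the
$4^4$ assignments), which the test suite verifies by simulation.

## Sequence context

`findTandemRepeats()` reports every maximal *perfect* tandem array with
at least two (possibly fractionally trailing) copies, nested
periodicities collapsed to the smallest unit. This replaces
alignment-scoring repeat finders: it cannot see degenerate (mismatched)
repeats, which is an accepted limitation noted here and in the README —
for the enrichment questions asked of it (is there a minisatellite near
the deletion?) perfect arrays are the conservative choice. Units ≥ 5
within ±50 bp of a deletion are minisatellites, annotated as
overlapping the deletion or flanking it with a signed distance.

`findG4()` scans both strands of the ±20 bp window with an explicit
G-quadruplex grammar: four guanine tracts of ≥ 2 G's, at most one tract
carrying a single non-G interruption, loops of 1–7 bases with at most
one extreme loop up to 30. Tracts are maximal G-runs (an imperfect
tract is two runs joined by a one-base gap); candidate parses are
resolved deterministically — leftmost first, perfect tracts preferred,
standard loops before extreme. Because upstream G4 tools differ in
their defaults, every grammar constant is a parameter. Enrichment of
minisatellites and G4 motifs in deletion categories versus
length-matched random controls is tested with the pooled two-proportion
z-test, Bonferroni-corrected over the number of emitted tests.

## The simulator

The simulator provides ground truth the real data cannot: a reference
whose homolog-pair content is known *exactly*. `makeReference()` plants
`nPairs` pairs (homolog length 5–12, span 20–80 by default) on a random
background that is rejection-sampled until it contains no unintended
repeat of length ≥ 5 within 100 bp — the scan-and-mutate loop also
enforces that the bases just outside each planted copy differ, so every
planted pair is maximal and the homolog index must recover the manifest
exactly (a property the tests assert). Pairs sit in separate blocks
≥ ~1 kb apart so spiked deletions never interact.

`simulateReads()` draws paired-end fragments (Normal fragment length,
default 350 ± 50; 2 × 150 bp reads; default 100×) uniformly along the
contig. A fragment overlapping a spiked deletion comes from the deleted
haplotype with probability `target_vaf` and keeps its length by reading
through the junction, so junction-spanning read counts are binomial at
the target VAF. Junction reads are written either with the correct
D-op CIGAR (we know the truth, no re-alignment is needed) or, as an
option, in a soft-clip representation — used by the tests to show that
support counting is invariant to the alignment representation. Errors
are i.i.d. substitutions; there is no quality-decay model, no indel
error, and no GC bias, so passing benchmarks here demonstrate
correctness of the machinery, not robustness to every real-data
pathology. Against real data the main differences are non-uniform
coverage, correlated errors, and reference repeats denser than the
rejection-sampled background.

`benchmarkCalls()` scores a callset at `vafThreshold = 0.05` with
support ≥ 1: true positives are truth loci whose perfect-match candidate
is called; negatives are all other scanned candidate loci (including
imperfect variants of spiked pairs, which error-free reads must not
support). The benchmark configuration used by `scripts/acceptance.R`
and the test suite — one 200 kb contig, 200 planted pairs, 100 spiked
deletions at VAF 0.5, 100× error-free reads, simulation seed 7 — is a
desk-scale experiment chosen so the full pipeline completes in about a
minute; under these conditions the expected outcome is sensitivity and
specificity of 100%.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at BAM (1-based) and VCF (1-based, anchored) boundaries.
* Case-insensitive matching; soft-masked references are treated as
  plain sequence. `N` never matches anything, including itself.
* Candidates whose flanks would cross a contig edge, or whose window
  contains `N`, are skipped with a classed warning (`mmejSkip`) and
  counted, never fatal — genome edges are normal inputs.
* Depth windows truncated at a contig edge are averaged over the
  remaining positions, with a warning.
* Empty inputs (no pairs, empty index, zero-support candidates) flow
  through as empty objects, not errors; an empty FASTQ is an error
  because depth would be undefined.
* `chooseTruth()` rejects requests for more non-overlapping deletions
  than exist; `makeReference()` rejects pair counts that cannot be
  packed at the required separation.

## Known limitations

* Only exact (mismatch-free) homology is indexed, and only one-base
  imperfect variants are generated; junctions with templated insertions
  or multi-base mispairs are out of scope.
* Exact-substring support counting loses sensitivity with read error
  rate roughly as $(1 - e)^{k}$; at 0.1% error and $k = 35$ this is a
  ~3.4% loss, at 1% it is ~30%.
* The tandem-repeat detector is perfect-repeat only; the G4 detector is
  a motif grammar, not a thermodynamic model.
* Multi-sample joint calling, CRAM input and population-frequency
  annotation are not provided.
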