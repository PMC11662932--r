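## Shared fixtures, built once per test run and cached. All fixtures are
## generated in code; nothing binary is stored in the repository.

.fixtures <- new.env(parent = emptyenv())

## small end-to-end simulation used by scanner/simulate/cli tests:
## 30 kb contig, 25 planted pairs, 10 spiked deletions at VAF 0.5, 60x
smallSim <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  sim <- makeReference(seed = 11L, contigLen = 30000L, nPairs = 25L)
  idx <- buildHomologIndex(sim$reference)
  truth <- chooseTruth(sim$manifest, 10L, vafs = 0.5, seed = 3L)
  reads <- simulateReads(sim$reference, truth, coverage = 60,
                         seed = 5L, outPrefix = tempfile("smallsim"))
  cand <- generateCandidates(idx, sim$reference)
  .fixtures$small <- list(sim = sim, index = idx, truth = truth,
                          reads = reads, cand = cand)
  .fixtures$small
}

## the spike-in benchmark conditions: 1 x 200 kb contig, 200 planted
## pairs, error-free 2x150 bp reads at 100x; reference/index/candidates
## are shared by the VAF-recovery run which spikes different VAFs
accReference <- function() {
  if (!is.null(.fixtures$accRef)) return(.fixtures$accRef)
  sim <- makeReference(seed = 7L, contigLen = 200000L, nPairs = 200L)
  idx <- buildHomologIndex(sim$reference)
  cand <- generateCandidates(idx, sim$reference)
  .fixtures$accRef <- list(sim = sim, index = idx, cand = cand)
  .fixtures$accRef
}

accBenchmarkRun <- function() {
  if (!is.null(.fixtures$accRun)) return(.fixtures$accRun)
  ref <- accReference()
  truth <- chooseTruth(ref$sim$manifest, 100L, vafs = 0.5, seed = 7L)
  reads <- simulateReads(ref$sim$reference, truth, coverage = 100,
                         readLen = 150L, errorRate = 0, seed = 7L,
                         outPrefix = tempfile("accbam"))
  calls <- callCandidates(reads$bam, ref$cand)
  .fixtures$accRun <- list(ref = ref, truth = truth, reads = reads,
                           calls = calls)
  .fixtures$accRun
}
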