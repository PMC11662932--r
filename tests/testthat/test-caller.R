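mkCall <- function(vaf, depth, support = NULL, ds = 100L) {
  if (is.null(support)) support <- as.integer(round(vaf * depth))
  data.frame(chrom = "chr", del_start = ds, del_len = 20L,
             match_type = "perfect", vaf = vaf, depth = depth,
             support = support, stringsAsFactors = FALSE)
}

test_that("paired classification reproduces the decision rules", {
  expect_equal(classifyPaired(mkCall(0.30, 50), mkCall(0, 50, 0L))$verdict,
               "SOMATIC")
  expect_equal(classifyPaired(mkCall(0.45, 40), mkCall(0.52, 45))$verdict,
               "GERMLINE")
  ## above the germline band on both sides
  r <- classifyPaired(mkCall(0.95, 100), mkCall(0.93, 100))
  expect_equal(r$verdict, "NONE")
  expect_match(r$reason, "VAF")
  ## blacklisted locus cannot be somatic
  bl <- data.frame(chrom = "chr", del_start = 100L, del_len = 20L)
  r <- classifyPaired(mkCall(0.30, 50), mkCall(0, 50, 0L), blacklist = bl)
  expect_equal(r$verdict, "NONE")
  expect_match(r$reason, "blacklist")
  ## mismatched candidates are a hard error
  expect_error(classifyPaired(mkCall(0.3, 50), mkCall(0, 50, 0L, ds = 101L)),
               "different candidates")
})

test_that("classification truth table is total over the boundary grid", {
  vafs <- c(0, 0.05, 0.1, 0.1 + 1e-9, 0.3, 0.5, 0.86, 0.86 + 1e-9, 1)
  depths <- c(0, 29, 30, 30 + 1e-9, 31, 100)
  ## independent restatement of the printed rules
  oracle <- function(vt, vn, dt, dn, sn) {
    if (vt > 0.1 && sn == 0L && dt > 30 && dn > 30) "SOMATIC"
    else if (vt >= 0.1 && vt <= 0.86 && vn >= 0.1 && vn <= 0.86 &&
             dt >= 30 && dn >= 30) "GERMLINE"
    else "NONE"
  }
  grid <- expand.grid(vt = vafs, vn = vafs, dt = depths, dn = depths)
  verdicts <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sn <- if (g$vn == 0) 0L else max(1L, as.integer(round(g$vn * g$dn)))
    r <- classifyPaired(mkCall(g$vt, g$dt),
                        mkCall(g$vn, g$dn, support = sn))
    verdicts[i] <- r$verdict
    expect_equal(r$verdict, oracle(g$vt, g$vn, g$dt, g$dn, sn))
    expect_true(r$verdict %in% c("SOMATIC", "GERMLINE", "NONE"))
  }
  ## every verdict class is reachable on the grid
  expect_setequal(unique(verdicts), c("SOMATIC", "GERMLINE", "NONE"))
})

test_that("paired call sets join on the candidate key", {
  t1 <- rbind(mkCall(0.4, 60, ds = 100L), mkCall(0.3, 80, ds = 300L))
  n1 <- rbind(mkCall(0.45, 55, ds = 100L), mkCall(0, 70, 0L, ds = 300L))
  out <- classifyPairedCalls(t1, n1)
  expect_equal(out$verdict[out$del_start == 100L], "GERMLINE")
  expect_equal(out$verdict[out$del_start == 300L], "SOMATIC")
})

test_that("region enumeration has the right cardinality and collapses", {
  set.seed(55)
  s <- randomDNA(400)
  ref <- Biostrings::DNAStringSet(c(chr = s))
  ## width w, full range: sum of multiplicities = w * (dMax - dMin + 1)
  out <- enumerateRegionDeletions(ref, "chr", 100L, 140L,
                                  dMin = 6L, dMax = 30L)
  expect_equal(sum(out$multiplicity), 40L * (30L - 6L + 1L))
  ## dMin = dMax = 6 on a 10 bp region: 10 records
  out6 <- enumerateRegionDeletions(ref, "chr", 100L, 110L,
                                   dMin = 6L, dMax = 6L)
  expect_equal(nrow(out6), 10L)
  expect_equal(out6$multiplicity, rep(1L, 10L))
  ## a deletion inside a long exact repeat collapses with its shifted
  ## twin once the whole junction window lies inside the periodic array
  unit <- "GATCCTGA"
  rep8 <- paste0(randomDNA(180), strrep(unit, 8), randomDNA(156))
  refR <- Biostrings::DNAStringSet(c(chr = rep8))
  outR <- enumerateRegionDeletions(refR, "chr", 196L, 216L,
                                   dMin = 8L, dMax = 8L)
  coll <- outR[outR$multiplicity > 1L, ]
  expect_gt(nrow(coll), 0L)
  ## verify the collapse via the independent edit oracle
  expect_true(applyDeletion(rep8, 200L, 8L) == applyDeletion(rep8, 208L, 8L))
  ## collapsed representative is the leftmost start
  expect_true(all(coll$del_start <= 216L - coll$multiplicity))
  ## region too large
  expect_error(enumerateRegionDeletions(ref, "chr", 0L, 200L, cap = 100L),
               "cap")
})

test_that("mechanism classification follows junction homology", {
  ref <- Biostrings::DNAStringSet(c(chr = "GGGTACGAAACGTCCA"))
  r <- classifyDeletionMechanism(ref, "chr", 4L, 5L)
  expect_equal(r$junction_homology, 3L)
  expect_equal(r$category, "INTERMEDIATE")
  ## a perfect candidate of an L >= 5 pair is MMEJ
  set.seed(12)
  s <- plantPair(300, start1 = 100L, D = 40L, L = 7L)
  refP <- Biostrings::DNAStringSet(c(chr = s))
  r <- classifyDeletionMechanism(refP, "chr", 100L, 40L)
  expect_gte(r$junction_homology, 7L)
  expect_equal(r$category, "MMEJ")
  ## no repeated base at the junction -> SHORT_HOMOLOGY
  refS <- Biostrings::DNAStringSet(c(chr = "TTTTTACGTGGGGGCATTTTT"))
  r <- classifyDeletionMechanism(refS, "chr", 8L, 4L)
  expect_equal(r$category, "SHORT_HOMOLOGY")
  ## flank signature is the post-deletion junction context
  sig <- classifyDeletionMechanism(refP, "chr", 100L, 40L)$flank_signature
  expect_match(sig, "^[ACGT]{2}_[ACGT]{2}$")
  expect_equal(sig, paste0(substring(s, 99, 100), "_",
                           substring(s, 141, 142)))
})

test_that("observed deletions match back to the index", {
  set.seed(13)
  s <- plantPair(500, start1 = 150L, D = 45L, L = 9L)
  ref <- Biostrings::DNAStringSet(c(chr = s))
  idx <- buildHomologIndex(ref)
  p <- homologPairs(idx)
  p <- p[p$start1 == 150L, ]
  ## perfect product
  m <- matchToIndex(ref, "chr", 150L, 45L, idx)
  expect_equal(m$match_type, "perfect")
  expect_equal(m$pair$start1, 150L)
  ## the A variant's contiguous interval
  m <- matchToIndex(ref, "chr", 149L, 46L, idx)
  expect_equal(m$match_type, "imperfect_A")
  ## the B variant's contiguous interval
  m <- matchToIndex(ref, "chr", 150L + 9L, 46L, idx)
  expect_equal(m$match_type, "imperfect_B")
  ## an unrelated deletion has no MMEJ interpretation
  expect_null(matchToIndex(ref, "chr", 30L, 20L, idx))
  ## a deletion shifted within the homology is product-identical
  m <- matchToIndex(ref, "chr", 151L, 45L, idx)
  expect_equal(m$match_type, "perfect")
})

test_that("region enumeration recovers index candidates as MMEJ", {
  fix <- smallSim()
  p <- homologPairs(fix$index)
  p <- p[p$start1 >= 2000L & p$start1 <= 6000L, ]
  for (i in seq_len(min(5L, nrow(p)))) {
    r <- classifyDeletionMechanism(fix$sim$reference, p$chrom[i],
                                   p$start1[i], p$start2[i] - p$start1[i])
    expect_gte(r$junction_homology, p$length[i])
    expect_equal(r$category, "MMEJ")
  }
})
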