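ref16 <- Biostrings::DNAStringSet(c(chr = "GGGTACGAAACGTCCA"))

test_that("search sequences match the worked examples (flank 3)", {
  p <- makeSearchSeq(ref16, "chr", 4L, 9L, 3L, "perfect", flank = 3L)
  expect_equal(p$search_seq, "GGTACGTCC")
  expect_equal(p$del_start, 4L)
  expect_equal(p$del_len, 5L)
  a <- makeSearchSeq(ref16, "chr", 4L, 9L, 3L, "imperfect_A", flank = 3L)
  expect_equal(a$search_seq, "GGGACGTCC")
  expect_equal(c(a$del_start, a$del_len), c(3L, 6L))
  b <- makeSearchSeq(ref16, "chr", 4L, 9L, 3L, "imperfect_B", flank = 3L)
  expect_equal(b$search_seq, "GGTACGCCA")
  expect_equal(b$del_len, 6L)
})

test_that("search_seq equals the string-edit oracle for planted pairs", {
  set.seed(314)
  flank <- 15L
  for (rep in 1:200) {
    L <- sample(5:12, 1)
    D <- sample((L + 2L):80L, 1)
    start1 <- sample(200:700, 1)
    s <- plantPair(1000, start1, D, L)
    ref <- Biostrings::DNAStringSet(c(chr = s))
    start2 <- start1 + D
    for (tt in c("perfect", "imperfect_A", "imperfect_B")) {
      rec <- makeSearchSeq(ref, "chr", start1, start2, L, tt, flank)
      ## independent oracle: actually apply the deletion, then cut the
      ## junction window out of the edited genome
      edited <- applyDeletion(s, rec$del_start, rec$del_len)
      junction <- substring(edited, rec$del_start - flank -
                              (if (tt == "imperfect_B") L else 0L) + 1L,
                            rec$del_start +
                              (if (tt == "imperfect_B") 0L else L) + flank)
      expect_identical(rec$search_seq, junction)
      ## length law
      expect_equal(nchar(rec$search_seq), 2L * flank + L)
    }
  }
})

test_that("imperfect variants differ from perfect by a one-base shift", {
  set.seed(11)
  s <- plantPair(400, 100L, 40L, 8L)
  ref <- Biostrings::DNAStringSet(c(chr = s))
  p <- makeSearchSeq(ref, "chr", 100L, 140L, 8L, "perfect")
  a <- makeSearchSeq(ref, "chr", 100L, 140L, 8L, "imperfect_A")
  b <- makeSearchSeq(ref, "chr", 100L, 140L, 8L, "imperfect_B")
  ## A shifts the left flank one base left; right flank identical
  expect_identical(substring(a$search_seq, 16), substring(p$search_seq, 16))
  expect_identical(substring(a$search_seq, 1, 14),
                   substring(s, 100L - 15L, 100L - 2L))
  ## B shifts the right flank one base right; left part identical
  expect_identical(substring(b$search_seq, 1, 23),
                   substring(p$search_seq, 1, 23))
})

test_that("contig edges and N windows are skipped, not fatal", {
  s <- plantPair(60, 5L, 20L, 6L)
  ref <- Biostrings::DNAStringSet(c(chr = s))
  expect_warning(r <- makeSearchSeq(ref, "chr", 5L, 25L, 6L, "perfect"),
                 class = "mmejSkip")
  expect_null(r)
  sN <- plantPair(200, 50L, 30L, 6L)
  substr(sN, 60, 60) <- "N"
  refN <- Biostrings::DNAStringSet(c(chr = sN))
  expect_warning(r <- makeSearchSeq(refN, "chr", 50L, 80L, 6L, "perfect"),
                 class = "mmejSkip")
  expect_null(r)
})

test_that("reference self-match filter flags planted duplications", {
  set.seed(21)
  L <- 8L; D <- 40L; start1 <- 100L
  s <- plantPair(600, start1, D, L)
  rec <- makeSearchSeq(Biostrings::DNAStringSet(c(chr = s)),
                       "chr", start1, start1 + D, L, "perfect")
  ## clean pair: junction absent from reference (exhaustive scan oracle)
  occurs <- gregexpr(rec$search_seq, s, fixed = TRUE)[[1]][1] != -1
  expect_false(occurs)
  expect_false(referenceMatchFilter(rec$search_seq,
                                    Biostrings::DNAStringSet(c(chr = s))))
  ## plant the junction product verbatim elsewhere -> filtered
  s2 <- paste0(s, "TTTT", rec$search_seq, "TTTT")
  expect_true(referenceMatchFilter(rec$search_seq,
                                   Biostrings::DNAStringSet(c(chr = s2))))
  ## minus-strand plant -> filtered via reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rec$search_seq)))
  s3 <- paste0(s, "TTTT", rc, "TTTT")
  expect_true(referenceMatchFilter(rec$search_seq,
                                   Biostrings::DNAStringSet(c(chr = s3))))
})

test_that("microsatellite fraction follows the coverage definition", {
  mkref <- function(seg) {
    pad1 <- "GTCAGTCCAGTTGACCATGG"; pad2 <- "CCATTGGACAGATCAGGACT"
    Biostrings::DNAStringSet(c(chr = paste0(pad1, seg, pad2)))
  }
  expect_equal(microsatelliteFraction(mkref("ACACACACAC"), "chr", 20L, 10L),
               1.0)
  expect_equal(microsatelliteFraction(mkref("ACGTGCTAGT"), "chr", 20L, 10L),
               0.0)
  ## 6 poly-A bases of 19 deleted bases
  expect_equal(microsatelliteFraction(mkref("AAAAAACGTGCTAGTCCGA"),
                                      "chr", 20L, 19L), 6 / 19)
})

test_that("candidate generation applies both filters and keeps order", {
  set.seed(33)
  ## one clean pair, one poly-AC pair (microsatellite), background
  pad <- function() randomDNA(150)
  H <- "GTCAGGTC"
  acac <- strrep("AC", 20)                      # 40 bp of dinucleotide
  s <- paste0(pad(), H, "TGACCTAGGACTTGACCATGGACTT", H, pad(),
              acac, pad())
  ref <- Biostrings::DNAStringSet(c(chr = s))
  idx <- buildHomologIndex(ref)
  p <- homologPairs(idx)
  cand <- generateCandidates(idx, ref)
  df <- candidateTable(cand)
  ## the poly-AC region yields pairs whose deleted segment is pure
  ## microsatellite; none survive
  expect_true(all(df$microsat_frac <= 0.8))
  expect_true(all(!df$ref_self_match))
  ## the clean planted pair yields its three records
  keep <- df$start1 == p$start1[which(p$seq == H)[1]]
  expect_setequal(df$match_type[keep],
                  c("perfect", "imperfect_A", "imperfect_B"))
  ## deterministic order: grouped by pair, perfect/A/B
  expect_equal(df, df[order(match(paste(df$chrom, df$start1, df$start2),
                                  unique(paste(df$chrom, df$start1,
                                               df$start2)))), ],
               ignore_attr = TRUE)
})

test_that("candidate TSV round-trips", {
  fix <- smallSim()
  tsv <- tempfile(fileext = ".tsv")
  writeCandidates(fix$cand, tsv)
  back <- readCandidates(tsv)
  expect_equal(candidateTable(back)$search_seq,
               candidateTable(fix$cand)$search_seq)
  expect_equal(candidateTable(back)$del_start,
               candidateTable(fix$cand)$del_start)
})
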