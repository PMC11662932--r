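test_that("tandem-repeat detector matches its worked examples", {
  r <- findTandemRepeats("ACACACAC")
  expect_equal(r, data.frame(start = 0L, end = 8L, unit_len = 2L,
                             copies = 4), ignore_attr = TRUE)
  ## 18-mer repeated 4.5 times inside a longer sequence
  set.seed(61)
  unit <- "GATCCTGGAAGTCCTAGA"
  arr <- paste0(strrep(unit, 4), substring(unit, 1, 9))
  s <- paste0("TTGTACGTCC", arr, "TGCATGCGAA")
  r <- findTandemRepeats(s)
  big <- r[r$unit_len == 18L, ]
  expect_equal(nrow(big), 1L)
  expect_equal(big$start, 10L)
  expect_equal(big$copies, 4.5)
})

test_that("tandem-repeat detector equals brute-force period scan", {
  set.seed(1234)
  for (rep in 1:60) {
    s <- randomDNA(60, alphabet = c("A", "C", "G", "T"))
    expect_equal(findTandemRepeats(s), bruteTandemRepeats(s),
                 ignore_attr = TRUE)
  }
  for (rep in 1:40) {            # repeat-dense alphabet
    s <- randomDNA(60, alphabet = c("A", "C"))
    expect_equal(findTandemRepeats(s), bruteTandemRepeats(s),
                 ignore_attr = TRUE)
  }
})

test_that("minisatellite search keeps unit >= 5 and classifies position", {
  unit <- "GATCCTGGAAGTCCTAGA"                 # 18-mer
  arr <- strrep(unit, 3)
  pad <- function(n) strrep("GTCA", n / 4)
  ## array overlapping the deletion
  s <- paste0(pad(100), arr, pad(100))
  ref <- Biostrings::DNAStringSet(c(chr = s))
  ms <- findMinisatellites(ref, "chr", 120L, 30L)
  expect_true(any(ms$unit_len == 18L & ms$position == "OVERLAP"))
  ## strictly upstream array
  ms <- findMinisatellites(ref, "chr", 156L, 20L)
  expect_true(any(ms$unit_len == 18L & ms$position == "LEFT_FLANK" &
                  ms$distance <= 0))
  ## unit-3 arrays are excluded
  s3 <- paste0(pad(100), strrep("GAT", 8), pad(100))
  ms3 <- findMinisatellites(Biostrings::DNAStringSet(c(chr = s3)),
                            "chr", 110L, 10L)
  expect_false(any(ms3$unit_len < 5L))
})

test_that("G4 scanner detects canonical and extreme-loop motifs", {
  telo <- "GGGTTAGGGTTAGGGTTAGGG"
  ref <- Biostrings::DNAStringSet(
    c(chr = paste0("ACATCATACT", telo, "ACTATCATCA")))
  g4 <- findG4(ref, "chr", 15L, 5L, flank = 20L)
  fwd <- g4[g4$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(unlist(fwd[, c("tract1", "tract2", "tract3", "tract4")],
                      use.names = FALSE), rep(3L, 4))
  expect_equal(unlist(fwd[, c("loop1", "loop2", "loop3")],
                      use.names = FALSE), rep(3L, 4 - 1))
  expect_equal(fwd$imperfect_tract, 0L)
  ## no motif in AT-only sequence
  at <- Biostrings::DNAStringSet(c(chr = strrep("AT", 30)))
  expect_equal(nrow(findG4(at, "chr", 20L, 10L)), 0L)
  ## one extreme loop up to 30 is allowed
  x <- paste0("GGTTGG", "ACTACTTCATCATCATACTA", "GGTTGG")
  refx <- Biostrings::DNAStringSet(c(chr = paste0("ACTAT", x, "TCATC")))
  g4x <- findG4(refx, "chr", 10L, 12L, flank = 20L)
  plus <- g4x[g4x$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(sort(unlist(plus[, c("loop1", "loop2", "loop3")],
                           use.names = FALSE)), c(2L, 2L, 20L))
})

test_that("G4 motifs revalidate against the grammar; revcomp swaps strands", {
  set.seed(404)
  validate <- function(m, s) {
    body <- substring(s, m$start + 1L, m$end)
    tracts <- c(m$tract1, m$tract2, m$tract3, m$tract4)
    loops <- c(m$loop1, m$loop2, m$loop3)
    expect_equal(sum(tracts) + sum(loops), nchar(body))
    expect_true(all(loops >= 1))
    expect_lte(sum(loops > 7), 1L)
    expect_true(all(loops <= 30))
    off <- 0L
    for (i in 1:4) {
      tr <- substring(body, off + 1L, off + tracts[i])
      nonG <- nchar(gsub("G", "", tr))
      expect_lte(nonG, 1L)                      # at most one interruption
      expect_gte(nchar(tr) - nonG, 2L)          # >= 2 guanines
      expect_true(startsWith(tr, "G") && endsWith(tr, "G"))
      off <- off + tracts[i] + (if (i < 4L) loops[i] else 0L)
    }
    expect_lte(m$imperfect_tract, 1L)
  }
  nMotif <- 0L
  for (rep in 1:40) {
    s <- randomDNA(70, alphabet = c("G", "T", "A"))
    ref <- Biostrings::DNAStringSet(c(chr = s))
    g4 <- findG4(ref, "chr", 25L, 20L, flank = 25L)
    for (i in seq_len(nrow(g4))) {
      m <- g4[i, ]
      seqStrand <- if (m$strand == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      mm <- m
      if (m$strand == "-") {
        mm$start <- nchar(s) - m$end
        mm$end <- nchar(s) - m$start
      }
      validate(mm, seqStrand)
      nMotif <- nMotif + 1L
    }
    ## strand swap under reverse complement
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    g4rc <- findG4(Biostrings::DNAStringSet(c(chr = rc)), "chr", 25L, 20L,
                   flank = 25L)
    expect_equal(sum(g4$strand == "+"), sum(g4rc$strand == "-"))
    expect_equal(sum(g4$strand == "-"), sum(g4rc$strand == "+"))
  }
  expect_gt(nMotif, 10L)        # the property actually exercised motifs
})

test_that("gc fraction and the two-proportion z-test match closed forms", {
  expect_equal(gcFraction("GGCC"), 1.0)
  expect_equal(gcFraction("AATT"), 0.0)
  expect_equal(gcFraction("ACGT"), 0.5)

  zt <- twoProportionZTest(20, 100, 10, 100)
  phat <- 30 / 200
  zExp <- 0.1 / sqrt(phat * (1 - phat) * (1 / 100 + 1 / 100))
  expect_equal(zt$z, zExp, tolerance = 1e-12)
  expect_equal(zt$p, 2 * pnorm(-abs(zExp)), tolerance = 1e-12)
  ## equal proportions -> z = 0, p = 1
  expect_equal(twoProportionZTest(5, 50, 10, 100), list(z = 0, p = 1))
  ## antisymmetry
  expect_equal(twoProportionZTest(10, 100, 20, 100)$z, -zt$z)
  ## random rational inputs against the closed form
  set.seed(50)
  for (rep in 1:50) {
    n1 <- sample(5:500, 1); n2 <- sample(5:500, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    zt <- twoProportionZTest(x1, n1, x2, n2)
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    zc <- if (se == 0) 0 else (x1 / n1 - x2 / n2) / se
    expect_equal(zt$z, zc, tolerance = 1e-12)
  }
  expect_error(twoProportionZTest(1, 0, 1, 10), "positive")
  expect_equal(bonferroniAdjust(c(0.01, 0.4)), c(0.02, 0.8))
})

test_that("extension potential follows its definition", {
  ## a1='A', b1='C', a2='C', b2='T': a2 == b1 -> TRUE
  mk <- function(a1, a2, b1, b2) {
    H <- "GGGGG"
    s <- paste0("TTTTT", H, a1, a2, "TTTTTTTTTTTTT", H, b1, b2, "TTTTT")
    Biostrings::DNAStringSet(c(chr = s))
  }
  expect_true(extensionPotential(mk("A", "C", "C", "T"), "chr",
                                 5L, 25L, 5L, side = "RIGHT"))
  expect_false(extensionPotential(mk("A", "G", "C", "G"), "chr",
                                  5L, 25L, 5L, side = "RIGHT"))
  ## exhaustive 4^4 enumeration: conditioned on a1 != b1, 84/192 TRUE
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(a1 = b, a2 = b, b1 = b, b2 = b,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$a1 != grid$b1, ]
  expect_equal(nrow(grid), 192L)
  got <- vapply(seq_len(nrow(grid)), function(i)
    extensionPotential(mk(grid$a1[i], grid$a2[i], grid$b1[i], grid$b2[i]),
                       "chr", 5L, 25L, 5L, side = "RIGHT"), logical(1))
  expect_equal(sum(got), 84L)
  ## LEFT side mirrors: context before the copies
  mkL <- function(a2, a1, b2, b1) {
    H <- "GGGGG"
    s <- paste0("TTT", a2, a1, H, "TTTTTTTTTTTTTT", b2, b1, H, "TTTTT")
    Biostrings::DNAStringSet(c(chr = s))
  }
  expect_true(extensionPotential(mkL("T", "A", "A", "C"), "chr",
                                 5L, 26L, 5L, side = "LEFT"))
  ## missing context -> NA with skip warning
  tiny <- Biostrings::DNAStringSet(c(chr = "GGGGGTTTTTTTGGGGGAA"))
  expect_warning(r <- extensionPotential(tiny, "chr", 0L, 12L, 5L,
                                         side = "LEFT"),
                 class = "mmejSkip")
  expect_true(is.na(r))
})

test_that("enrichment report detects planted enrichment", {
  set.seed(71)
  unit <- "GATCCTGGAAGTCCTAGA"
  n <- 200L
  ## genome of 200 blocks of 200 bp; minisatellite planted in the first
  ## 80% of "case" blocks and 10% of "control" blocks
  blocks <- character(2L * n)
  caseHas <- rep(c(TRUE, FALSE), times = c(160L, 40L))
  ctrlHas <- rep(c(TRUE, FALSE), times = c(20L, 180L))
  has <- c(caseHas, ctrlHas)
  for (i in seq_along(blocks)) {
    bg <- randomDNA(200)
    if (has[i]) {
      arr <- strrep(unit, 3)
      substring(bg, 81, 80 + nchar(arr)) <- arr
    }
    blocks[i] <- bg
  }
  s <- paste(blocks, collapse = "")
  ref <- Biostrings::DNAStringSet(c(chr = s))
  mkdel <- function(i) (i - 1L) * 200L + 90L    # overlaps planted array
  calls <- data.frame(chrom = "chr", del_start = mkdel(seq_len(n)),
                      del_len = 30L, match_type = "perfect")
  ctrl <- data.frame(chrom = "chr", del_start = mkdel(n + seq_len(n)),
                     del_len = 30L, match_type = "random")
  rep <- enrichmentReport(calls, ctrl, ref)
  summ <- attr(rep, "summary")
  expect_equal(summ$n[summ$category == "perfect"], n)
  row <- rep[rep$feature == "minisat" & rep$group1 == "perfect" &
             rep$group2 == "random", ]
  expect_lt(row$p_adj, 0.001)
  expect_gt(row$z, 0)
  ## identical sets -> p = 1
  rep2 <- enrichmentReport(calls, transform(calls, match_type = "random"),
                           ref)
  expect_true(all(rep2$p_raw[rep2$group1 == "perfect" &
                             rep2$group2 == "random"] == 1))
  ## empty imperfect category -> NA rows, no error
  expect_true(any(is.na(rep$p_raw[rep$group1 == "imperfect" |
                                  rep$group2 == "imperfect"])))
})
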