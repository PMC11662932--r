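## Self-contained spike-in simulator: a synthetic reference with planted
## homolog pairs on a repeat-free background, a non-overlapping truth set
## of deletions with target VAFs, paired-end reads (BAM + FASTQ) mixing
## reference and deleted haplotypes, and sensitivity/specificity scoring.

#' Build a synthetic reference with planted homolog pairs
#'
#' Generates random background sequence, rejection-sampled so it contains
#' no unintended exact repeat of length >= \code{kMin} within
#' \code{dMax}, then plants \code{nPairs} homolog pairs (two identical
#' copies of a random homolog) at well-separated positions. Every
#' planted pair is maximal (the bases just outside the two copies
#' differ), so the homolog index recovers exactly the manifest.
#'
#' @param seed RNG seed (determines the reference byte-for-byte).
#' @param nContigs number of contigs (default 1).
#' @param contigLen contig length in bp (default 200000).
#' @param nPairs homolog pairs planted per contig (default 200).
#' @param homologLenRange homolog length range (default c(5, 12)).
#' @param delSpanRange deletion span (start2 - start1) range
#'   (default c(20, 80)).
#' @param kMin,dMin,dMax repeat-freedom / pair constraints matching the
#'   index defaults (5, 6, 100).
#' @param margin bases left unplanted at contig ends (default 800).
#' @param maxIter rejection-sampling iteration cap (default 200).
#' @param fasta optional path; when given the reference is written there
#'   (with a .fai index via Rsamtools).
#' @return list with \code{reference} (DNAStringSet) and \code{manifest}
#'   (data.frame chrom, start1, start2, length, seq).
#' @export
makeReference <- function(seed = 7L, nContigs = 1L, contigLen = 200000L,
                          nPairs = 200L, homologLenRange = c(5L, 12L),
                          delSpanRange = c(20L, 80L), kMin = 5L,
                          dMin = 6L, dMax = 100L, margin = 800L,
                          maxIter = 200L, fasta = NULL) {
  stopifnot(homologLenRange[1] >= kMin,
            delSpanRange[1] >= dMin, delSpanRange[2] <= dMax,
            delSpanRange[1] >= homologLenRange[2] + 2L)
  block <- (contigLen - 2L * margin) %/% nPairs
  if (block < dMax + 2L * homologLenRange[2] + 60L)
    stop("infeasible parameters: ", nPairs, " pairs do not fit in a ",
         contigLen, " bp contig with the required separation")
  BASES <- c("A", "C", "G", "T")
  .withSeed(seed, {
    contigs <- character(nContigs)
    manifest <- vector("list", nContigs)
    for (ci in seq_len(nContigs)) {
      chrom <- paste0("sim", ci)
      bases <- sample(BASES, contigLen, replace = TRUE)
      ## plant one pair per block, jittered
      drawFrom <- function(range, n) {   # safe for degenerate ranges
        v <- seq.int(range[1], range[2])
        if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
      }
      L <- drawFrom(homologLenRange, nPairs)
      D <- drawFrom(delSpanRange, nPairs)
      D <- pmax(D, L + 2L)           # copies must not overlap or abut
      jitterMax <- pmax(1L, block - D - L - 4L)
      s1 <- margin + (seq_len(nPairs) - 1L) * block +
        vapply(jitterMax, function(m) sample.int(m, 1L), integer(1))
      s2 <- s1 + D
      for (i in seq_len(nPairs))
        bases[(s2[i] + 1L):(s2[i] + L[i])] <-
          bases[(s1[i] + 1L):(s1[i] + L[i])]
      ## enforce maximality guards (the bases just outside the two
      ## copies must differ) and freeze copies + guards against the
      ## background fix-up below
      protected <- logical(contigLen)
      for (i in seq_len(nPairs)) {
        protected[(s1[i] + 1L):(s1[i] + L[i])] <- TRUE
        protected[(s2[i] + 1L):(s2[i] + L[i])] <- TRUE
        gl1 <- s1[i]; gl2 <- s2[i]                     # 1-based guards
        gr1 <- s1[i] + L[i] + 1L; gr2 <- s2[i] + L[i] + 1L
        if (bases[gl2] == bases[gl1])
          bases[gl2] <- sample(setdiff(BASES, bases[gl1]), 1L)
        if (bases[gr2] == bases[gr1])
          bases[gr2] <- sample(setdiff(BASES, bases[gr1]), 1L)
        protected[c(gl1, gl2, gr1, gr2)] <- TRUE
      }
      man <- data.frame(chrom = chrom, start1 = s1, start2 = s2,
                        length = L, stringsAsFactors = FALSE)
      manKey <- paste(man$start1, man$start2, man$length)

      ## rejection loop: rescan, mutate a background base inside every
      ## repeat that is not exactly a manifest pair
      iter <- 0L
      repeat {
        iter <- iter + 1L
        if (iter > maxIter)
          stop("reference rejection sampling did not converge after ",
               maxIter, " iterations")
        found <- .scanDiagonals(charToRaw(paste(bases, collapse = "")),
                                kMin, dMin, dMax)
        bad <- found[!(paste(found$offset1, found$offset2, found$length)
                       %in% manKey), , drop = FALSE]
        if (nrow(bad) == 0L &&
            nrow(found) == nrow(man)) break
        for (b in seq_len(nrow(bad))) {
          o1 <- bad$offset1[b]; o2 <- bad$offset2[b]; Lb <- bad$length[b]
          d <- o2 - o1
          cand1 <- (o1 + 1L):(o1 + Lb)      # 1-based copy positions
          cand2 <- (o2 + 1L):(o2 + Lb)
          free <- c(cand1[!protected[cand1]], cand2[!protected[cand2]])
          if (length(free) == 0L) {
            ## repeat entirely inside planted copies: redraw the homolog
            ## content of an involved pair
            hit <- which(vapply(seq_len(nPairs), function(i) {
              any(cand1 %in% c((s1[i] + 1L):(s1[i] + L[i]),
                               (s2[i] + 1L):(s2[i] + L[i])))
            }, logical(1)))[1L]
            fresh <- sample(BASES, L[hit], replace = TRUE)
            bases[(s1[hit] + 1L):(s1[hit] + L[hit])] <- fresh
            bases[(s2[hit] + 1L):(s2[hit] + L[hit])] <- fresh
            next
          }
          p <- if (length(free) == 1L) free else sample(free, 1L)
          partner <- if (p <= o1 + Lb) p + d else p - d
          bases[p] <- sample(setdiff(BASES, c(bases[p], bases[partner])),
                             1L)
        }
      }
      contigs[ci] <- paste(bases, collapse = "")
      man$seq <- substring(contigs[ci], man$start2 + 1L,
                           man$start2 + man$length)
      manifest[[ci]] <- man
      names(contigs)[ci] <- chrom
    }
    reference <- Biostrings::DNAStringSet(contigs)
    manifest <- do.call(rbind, manifest)
    if (!is.null(fasta)) {
      Biostrings::writeXStringSet(reference, fasta)
      Rsamtools::indexFa(fasta)
    }
    list(reference = reference, manifest = manifest)
  })
}

#' Choose a non-overlapping truth set of deletions to spike in
#'
#' Draws a uniform random subset of the planted pairs and assigns target
#' VAFs (recycled over the sorted loci). The perfect-match deletion
#' intervals of the chosen pairs must be pairwise non-overlapping.
#'
#' @param pairs planted-pair manifest (data.frame from [makeReference()])
#'   or a \linkS4class{HomologIndex}.
#' @param nSpike number of deletions to spike.
#' @param vafs vector of target VAFs, recycled across loci.
#' @param seed RNG seed.
#' @return a \linkS4class{SimTruth}
#' @export
chooseTruth <- function(pairs, nSpike, vafs = 0.5, seed = 1L) {
  man <- if (methods::is(pairs, "HomologIndex")) pairs@pairs else pairs
  stopifnot(is.data.frame(man), nSpike >= 1L,
            all(vafs > 0), all(vafs <= 1))
  .withSeed(seed, {
    ord <- man[order(man$chrom, man$start1), , drop = FALSE]
    ## greedy non-overlap filter on the deletion intervals
    keep <- rep(TRUE, nrow(ord))
    lastEnd <- -1L; lastChrom <- ""
    for (i in seq_len(nrow(ord))) {
      dEnd <- ord$start2[i] + ord$length[i]
      if (ord$chrom[i] == lastChrom && ord$start1[i] < lastEnd) {
        keep[i] <- FALSE
      } else {
        lastEnd <- dEnd; lastChrom <- ord$chrom[i]
      }
    }
    avail <- ord[keep, , drop = FALSE]
    if (nSpike > nrow(avail))
      stop("nSpike = ", nSpike, " exceeds the ", nrow(avail),
           " available non-overlapping pairs")
    sel <- sort(sample.int(nrow(avail), nSpike))
    del <- avail[sel, , drop = FALSE]
    del$del_start <- del$start1
    del$del_len <- del$start2 - del$start1
    del$target_vaf <- rep_len(vafs, nSpike)
    rownames(del) <- NULL
    methods::new("SimTruth",
                 deletions = del[, c("chrom", "start1", "start2", "length",
                                     "del_start", "del_len", "target_vaf")],
                 params = list(), seed = as.integer(seed))
  })
}

#' Simulate paired-end reads over a reference with spiked deletions
#'
#' Draws paired-end fragments uniformly along each contig at the stated
#' coverage. Fragments overlapping a truth deletion come from the deleted
#' haplotype with probability equal to that deletion's target VAF;
#' deleted-haplotype fragments keep their length by reading through the
#' junction. Per-base substitution errors are applied i.i.d. at
#' \code{errorRate}. Reads are written as a coordinate-sorted, indexed
#' BAM (junction-spanning reads carry either a D-op CIGAR or a soft-clip
#' representation) and as a FASTQ pair.
#'
#' @param reference DNAStringSet or FASTA path.
#' @param truth a \linkS4class{SimTruth} (or NULL for no spikes).
#' @param coverage mean read coverage (default 100).
#' @param readLen read length in bp (default 150).
#' @param fragMean,fragSd fragment-length normal model (defaults 350, 50).
#' @param errorRate i.i.d. per-base substitution rate (default 0).
#' @param seed RNG seed.
#' @param deletionCigar \code{"dop"} (default) writes junction reads with
#'   a D CIGAR op; \code{"softclip"} aligns only the leftmost segment and
#'   soft-clips the rest.
#' @param outPrefix file prefix for outputs; \code{<prefix>.bam(.bai)},
#'   \code{<prefix>_R1.fastq}, \code{<prefix>_R2.fastq}.
#' @param writeFastq also write the FASTQ pair (default TRUE).
#' @return list with \code{bam}, \code{fastq1}, \code{fastq2},
#'   \code{nFragments}.
#' @export
simulateReads <- function(reference, truth = NULL, coverage = 100,
                          readLen = 150L, fragMean = 350, fragSd = 50,
                          errorRate = 0, seed = 1L,
                          deletionCigar = c("dop", "softclip"),
                          outPrefix = tempfile("sim"), writeFastq = TRUE) {
  deletionCigar <- match.arg(deletionCigar)
  if (coverage <= 0) stop("coverage must be positive")
  refstr <- .refStrings(reference)
  dels <- if (is.null(truth)) NULL else truthTable(truth)
  BASES <- c("A", "C", "G", "T")
  sam <- character(0)
  fq1 <- character(0); fq2 <- character(0)
  totFrag <- 0L

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(refstr), "\tLN:", nchar(refstr)))

  .withSeed(seed, {
    for (chrom in names(refstr)) {
      s <- refstr[[chrom]]
      clen <- nchar(s)
      nFrag <- max(1L, as.integer(round(coverage * clen / (2 * readLen))))
      totFrag <- totFrag + nFrag
      fragLen <- pmax(readLen, as.integer(round(
        stats::rnorm(nFrag, fragMean, fragSd))))
      fragLen <- pmin(fragLen, clen)
      fragStart <- as.integer(floor(stats::runif(nFrag, 0,
                                                 clen - fragLen + 1)))
      ## which fragments carry which deletions
      carried <- vector("list", nFrag)
      dc <- dels[dels$chrom == chrom, , drop = FALSE]
      if (!is.null(dc) && nrow(dc)) {
        dc <- dc[order(dc$del_start), , drop = FALSE]
        for (j in seq_len(nrow(dc))) {
          ds <- dc$del_start[j]; de <- ds + dc$del_len[j]
          ## fragments overlapping the deletion and starting before it
          idx <- which(fragStart < ds & fragStart + fragLen > ds)
          if (!length(idx)) next
          hap <- stats::rbinom(length(idx), 1L, dc$target_vaf[j]) == 1L
          for (ii in idx[hap])
            carried[[ii]] <- c(carried[[ii]], j)
        }
      }
      plain <- vapply(carried, is.null, logical(1))

      seqs <- character(nFrag)
      segs <- vector("list", nFrag)   # ref intervals (0-based) per fragment
      seqs[plain] <- substring(s, fragStart[plain] + 1L,
                               fragStart[plain] + fragLen[plain])
      for (i in which(!plain)) {
        res <- .fragmentThroughDeletions(s, clen, fragStart[i], fragLen[i],
                                         dc[carried[[i]], , drop = FALSE])
        seqs[i] <- res$seq
        segs[[i]] <- res$segs
        fragLen[i] <- nchar(res$seq)
      }

      r1 <- substr(seqs, 1L, readLen)
      r2 <- substr(seqs, fragLen - readLen + 1L, fragLen)
      if (errorRate > 0) {
        r1 <- .addErrors(r1, errorRate, BASES)
        r2 <- .addErrors(r2, errorRate, BASES)
      }

      ## alignment representation
      pos1 <- fragStart + 1L            # 1-based, plain fragments
      cig1 <- rep(paste0(readLen, "M"), nFrag)
      pos2 <- fragStart + fragLen - readLen + 1L
      cig2 <- cig1
      tlen <- fragLen
      for (i in which(!plain)) {
        a1 <- .readAlignment(segs[[i]], 0L, readLen, deletionCigar)
        a2 <- .readAlignment(segs[[i]], fragLen[i] - readLen, readLen,
                             deletionCigar)
        pos1[i] <- a1$pos; cig1[i] <- a1$cigar
        pos2[i] <- a2$pos; cig2[i] <- a2$cigar
        tlen[i] <- (segs[[i]][[length(segs[[i]])]][2L]) -
          (segs[[i]][[1L]][1L])
      }

      qn <- sprintf("%s_frag%07d", chrom, seq_len(nFrag))
      qual <- strrep("I", readLen)
      sam <- c(sam,
        paste(qn, 99L, chrom, pos1, 60L, cig1, "=", pos2, tlen,
              r1, qual, sep = "\t"),
        paste(qn, 147L, chrom, pos2, 60L, cig2, "=", pos1, -tlen,
              r2, qual, sep = "\t"))
      if (writeFastq) {
        fq1 <- c(fq1, paste0("@", qn, "/1\n", r1, "\n+\n", qual))
        fq2 <- c(fq2, paste0("@", qn, "/2\n",
                             .revcomp(r2), "\n+\n", qual))
      }
    }
  })

  samPath <- paste0(outPrefix, ".sam")
  writeLines(c(header, sam), samPath)
  bam0 <- Rsamtools::asBam(samPath, paste0(outPrefix, "_unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, outPrefix)
  Rsamtools::indexBam(bam)
  unlink(c(samPath, bam0))
  out <- list(bam = bam, nFragments = totFrag)
  if (writeFastq) {
    out$fastq1 <- paste0(outPrefix, "_R1.fastq")
    out$fastq2 <- paste0(outPrefix, "_R2.fastq")
    writeLines(fq1, out$fastq1)
    writeLines(fq2, out$fastq2)
  }
  out
}

## fragment sequence and kept ref segments (0-based half-open) for a
## deleted-haplotype fragment starting at fs with target length fl
.fragmentThroughDeletions <- function(s, clen, fs, fl, dc) {
  dc <- dc[order(dc$del_start), , drop = FALSE]
  segs <- list()
  cur <- fs
  remaining <- fl
  j <- 1L
  while (remaining > 0L && cur < clen) {
    nextDel <- NA_integer_
    while (j <= nrow(dc)) {
      if (dc$del_start[j] + dc$del_len[j] <= cur) { j <- j + 1L; next }
      nextDel <- j; break
    }
    segEnd <- if (!is.na(nextDel) && dc$del_start[nextDel] < cur + remaining)
      max(cur, dc$del_start[nextDel]) else cur + remaining
    segEnd <- min(segEnd, clen)
    if (segEnd > cur) {
      segs[[length(segs) + 1L]] <- c(cur, segEnd)
      remaining <- remaining - (segEnd - cur)
    }
    cur <- if (!is.na(nextDel) && segEnd == dc$del_start[nextDel])
      dc$del_start[nextDel] + dc$del_len[nextDel] else segEnd
    if (!is.na(nextDel) && segEnd == dc$del_start[nextDel]) j <- j + 1L
  }
  seq <- paste(vapply(segs, function(iv) substring(s, iv[1L] + 1L, iv[2L]),
                      character(1)), collapse = "")
  list(seq = seq, segs = segs)
}

## pos (1-based) and CIGAR for the read covering fragment offsets
## [off, off + rl) of a segmented fragment
.readAlignment <- function(segs, off, rl, mode) {
  ivs <- list()
  haploPos <- 0L
  need0 <- off; need1 <- off + rl
  for (iv in segs) {
    w <- iv[2L] - iv[1L]
    a <- max(need0, haploPos); b <- min(need1, haploPos + w)
    if (b > a)
      ivs[[length(ivs) + 1L]] <- c(iv[1L] + (a - haploPos),
                                   iv[1L] + (b - haploPos))
    haploPos <- haploPos + w
  }
  pos <- ivs[[1L]][1L] + 1L
  if (length(ivs) == 1L) return(list(pos = pos, cigar = paste0(rl, "M")))
  if (mode == "dop") {
    parts <- character(0)
    for (k in seq_along(ivs)) {
      if (k > 1L)
        parts <- c(parts, paste0(ivs[[k]][1L] - ivs[[k - 1L]][2L], "D"))
      parts <- c(parts, paste0(ivs[[k]][2L] - ivs[[k]][1L], "M"))
    }
    list(pos = pos, cigar = paste(parts, collapse = ""))
  } else {
    m <- ivs[[1L]][2L] - ivs[[1L]][1L]
    list(pos = pos, cigar = paste0(m, "M", rl - m, "S"))
  }
}

.addErrors <- function(reads, rate, BASES) {
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(nchar(reads[i]), nerr[i])
    ch <- strsplit(reads[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Score a callset against the simulation truth
#'
#' A candidate locus is called positive when its VAF is at least
#' \code{vafThreshold} with at least one supporting read. True positives
#' are truth deletions whose perfect-match candidate is called positive;
#' negatives are all scanned candidate loci not in the truth set.
#'
#' @param calls a \linkS4class{DeletionCallSet} over the candidate set.
#' @param truth a \linkS4class{SimTruth}.
#' @param vafThreshold minimum VAF to call a locus (default 0.05).
#' @return a \linkS4class{BenchmarkResult}
#' @export
benchmarkCalls <- function(calls, truth, vafThreshold = 0.05) {
  df <- if (methods::is(calls, "DeletionCallSet")) calls@calls else calls
  tt <- truthTable(truth)
  key <- function(x) paste(x$chrom, x$del_start, x$del_len)
  callKey <- key(df)
  truthKey <- unique(key(tt))
  positive <- df$vaf >= vafThreshold & df$support >= 1L
  isTruth <- callKey %in% truthKey
  tp <- length(intersect(truthKey, callKey[positive]))
  fn <- length(truthKey) - tp
  fp <- sum(positive & !isTruth)
  tn <- sum(!positive & !isTruth)
  methods::new("BenchmarkResult",
               tp = as.integer(tp), fn = as.integer(fn),
               fp = as.integer(fp), tn = as.integer(tn),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NaN)
}

#' Write / read a truth table as TSV
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path TSV path.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(methods::is(truth, "SimTruth"))
  .writeTSV(truthTable(truth), path, command = "writeTruth",
            config = c(truth@params, list(seed = truth@seed)))
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- .readTSV(path, required = c("chrom", "start1", "start2", "length",
                                    "del_start", "del_len", "target_vaf"))
  methods::new("SimTruth", deletions = df, params = list(), seed = NA_integer_)
}
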