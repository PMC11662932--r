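## Sequence-context analysis around deletions: perfect tandem repeats
## (micro- and minisatellites), G-quadruplex motifs, GC content,
## extended-homolog mispairing potential, and enrichment statistics.

#' Find maximal perfect tandem repeats
#'
#' Detects every maximal perfect tandem array in \code{seq} with unit
#' length in \code{[unitMin, unitMax]} and at least two full copies. An
#' array \code{[start, end)} with unit \code{u} satisfies
#' \code{seq[i] == seq[i + u]} for all \code{i} in \code{[start, end -
#' u)}; a fractional trailing copy is allowed, so copy number is
#' \code{(end - start) / u}. Arrays whose span is contained in an array
#' of smaller unit are suppressed (nested periodicities are reported at
#' the smallest unit only: a poly-A run is unit 1, not unit 2).
#' \code{N} never matches itself.
#'
#' @param seq nucleotide string.
#' @param unitMin,unitMax repeat-unit length range in bp (defaults 1, 30).
#' @return data.frame with 0-based \code{start}, \code{end},
#'   \code{unit_len}, \code{copies}, sorted by \code{(start, unit_len)}.
#' @examples
#' findTandemRepeats("ACACACAC")      # unit 2, 4 copies
#' @export
findTandemRepeats <- function(seq, unitMin = 1L, unitMax = 30L) {
  stopifnot(length(seq) == 1L, unitMin >= 1L, unitMax >= unitMin)
  .checkNucleotides(seq, "sequence")
  r <- charToRaw(toupper(seq))
  n <- length(r)
  isN <- r == as.raw(0x4e)
  st <- integer(0); en <- integer(0); un <- integer(0)
  uHi <- min(unitMax, n %/% 2L)
  u <- unitMin
  while (u <= uHi) {
    m <- (r[seq_len(n - u)] == r[(u + 1L):n]) & !isN[seq_len(n - u)]
    rl <- rle(m)
    ends <- cumsum(rl$lengths)
    keep <- rl$values & rl$lengths >= u     # run of l matches = array l+u
    if (any(keep)) {
      s0 <- ends[keep] - rl$lengths[keep]   # 0-based array start
      st <- c(st, s0); en <- c(en, ends[keep] + u); un <- c(un, rep(u, sum(keep)))
    }
    u <- u + 1L
  }
  out <- data.frame(start = st, end = en, unit_len = un)
  if (nrow(out) > 1L) {
    ## suppress arrays nested inside a smaller-unit array
    o <- order(out$unit_len, out$start)
    out <- out[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      smaller <- which(out$unit_len < out$unit_len[i] & keep)
      if (any(out$start[smaller] <= out$start[i] &
              out$end[smaller] >= out$end[i]))
        keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out$copies <- (out$end - out$start) / out$unit_len
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find minisatellites around a deletion
#'
#' Extracts the reference window from \code{flank} bases upstream of the
#' deletion to \code{flank} bases downstream, detects perfect tandem
#' arrays, keeps those with unit length >= \code{unitMin} (minisatellites;
#' unit <= 4 is microsatellite territory) and annotates each with its
#' position relative to the deletion span: \code{OVERLAP},
#' \code{LEFT_FLANK} or \code{RIGHT_FLANK}, plus a signed distance
#' (0 when overlapping, negative upstream, positive downstream).
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param chrom contig name.
#' @param delStart 0-based deletion start.
#' @param delLen deletion length (bp).
#' @param flank window half-width beyond the deletion (default 50).
#' @param unitMin minimum repeat-unit length kept (default 5).
#' @param unitMax maximum repeat-unit length scanned (default 30).
#' @return data.frame with genomic \code{start}, \code{end} (0-based),
#'   \code{unit_len}, \code{copies}, \code{position}, \code{distance}.
#' @export
findMinisatellites <- function(reference, chrom, delStart, delLen,
                               flank = 50L, unitMin = 5L, unitMax = 30L) {
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  n <- nchar(s)
  ws <- delStart - flank; we <- delStart + delLen + flank
  if (ws < 0L || we > n) {
    warning("context window truncated at contig edge for deletion ",
            chrom, ":", delStart)
    ws <- max(0L, ws); we <- min(n, we)
  }
  reps <- findTandemRepeats(.sub0(s, ws, we), unitMin = 1L,
                            unitMax = unitMax)
  reps <- reps[reps$unit_len >= unitMin, , drop = FALSE]
  if (nrow(reps) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      unit_len = integer(0), copies = numeric(0),
                      position = character(0), distance = integer(0)))
  reps$start <- reps$start + ws
  reps$end <- reps$end + ws
  delEnd <- delStart + delLen
  reps$position <- ifelse(reps$start < delEnd & reps$end > delStart,
                          "OVERLAP",
                   ifelse(reps$end <= delStart, "LEFT_FLANK", "RIGHT_FLANK"))
  reps$distance <- ifelse(reps$position == "OVERLAP", 0L,
                   ifelse(reps$position == "LEFT_FLANK",
                          reps$end - delStart, reps$start - delEnd))
  rownames(reps) <- NULL
  reps
}

## ---- G-quadruplex motif scanner ---------------------------------------

## Scan one strand (character string, forward orientation) for G4 motifs.
## Grammar: 4 G-tracts; a perfect tract is one maximal G-run of >= tractMin
## guanines; at most one imperfect tract = two G-runs joined by a single
## non-G base (>= 1 G each side, >= tractMin Gs total); loops between
## tracts have length 1..loopMax, except at most one extreme loop of
## length up to extremeLoopMax. Overlapping candidates are resolved
## greedily left-to-right; tract options are tried perfect-first and
## loops standard-first, so the reported parse is deterministic.
.scanG4Strand <- function(s, tractMin = 2L, loopMax = 7L,
                          extremeLoopMax = 30L, allowImperfect = TRUE) {
  n <- nchar(s)
  r <- strsplit(s, "")[[1]]
  isG <- r == "G"
  if (!any(isG)) return(NULL)
  rl <- rle(isG)
  ends <- cumsum(rl$lengths)
  gi <- which(rl$values)
  runs <- data.frame(start = ends[gi] - rl$lengths[gi],  # 0-based
                     len = rl$lengths[gi])
  nr <- nrow(runs)
  runEnd <- runs$start + runs$len

  ## a tract starting at run j: list of (endRun, span, glen, imperfect)
  tractOptions <- function(j) {
    opts <- list()
    if (runs$len[j] >= tractMin)
      opts[[length(opts) + 1L]] <- list(jEnd = j, from = runs$start[j],
                                        to = runEnd[j], imperfect = 0L)
    if (allowImperfect && j < nr &&
        runs$start[j + 1L] - runEnd[j] == 1L &&
        runs$len[j] + runs$len[j + 1L] >= tractMin)
      opts[[length(opts) + 1L]] <- list(jEnd = j + 1L, from = runs$start[j],
                                        to = runEnd[j + 1L], imperfect = 1L)
    opts
  }

  ## depth-first assembly of 4 tracts from run j1; returns first parse
  build <- function(j, tractsLeft, impUsed, extUsed, acc) {
    for (opt in tractOptions(j)) {
      if (opt$imperfect && impUsed) next
      acc2 <- c(acc, list(opt))
      if (tractsLeft == 1L) return(acc2)
      jn <- opt$jEnd + 1L
      while (jn <= nr) {
        loop <- runs$start[jn] - opt$to
        if (loop > extremeLoopMax || (extUsed && loop > loopMax)) break
        res <- build(jn, tractsLeft - 1L,
                     impUsed || opt$imperfect == 1L,
                     extUsed || loop > loopMax, acc2)
        if (!is.null(res)) return(res)
        jn <- jn + 1L
      }
    }
    NULL
  }

  hits <- NULL
  j <- 1L
  while (j <= nr) {
    parse <- build(j, 4L, FALSE, FALSE, list())
    if (!is.null(parse)) {
      froms <- vapply(parse, `[[`, numeric(1), "from")
      tos <- vapply(parse, `[[`, numeric(1), "to")
      hit <- data.frame(start = froms[1L], end = tos[4L],
                        tract1 = tos[1L] - froms[1L],
                        tract2 = tos[2L] - froms[2L],
                        tract3 = tos[3L] - froms[3L],
                        tract4 = tos[4L] - froms[4L],
                        loop1 = froms[2L] - tos[1L],
                        loop2 = froms[3L] - tos[2L],
                        loop3 = froms[4L] - tos[3L],
                        imperfect_tract = sum(vapply(parse, `[[`,
                                                     numeric(1), "imperfect")))
      hits <- rbind(hits, hit)
      ## greedy: resume after this motif
      j <- which(runs$start >= hit$end)
      j <- if (length(j)) j[1L] else nr + 1L
    } else j <- j + 1L
  }
  hits
}

#' Find G-quadruplex motifs around a deletion
#'
#' Scans both strands of the reference window from \code{flank} bases
#' upstream to \code{flank} bases downstream of the deletion for
#' G-quadruplex-forming motifs: four guanine tracts of at least
#' \code{tractMin} G's (optionally one imperfect tract carrying a single
#' non-G interruption) separated by loops of 1-\code{loopMax} bases, with
#' at most one extreme loop of up to \code{extremeLoopMax} bases.
#'
#' @inheritParams findMinisatellites
#' @param flank window half-width beyond the deletion (default 20).
#' @param tractMin minimum guanines per tract (default 2).
#' @param loopMax standard loop maximum (default 7).
#' @param extremeLoopMax length cap for the single allowed extreme loop
#'   (default 30).
#' @param allowImperfect allow one interrupted tract (default TRUE).
#' @return data.frame with genomic \code{start}, \code{end} (0-based,
#'   forward-strand coordinates), tract and loop lengths,
#'   \code{imperfect_tract} (0/1) and \code{strand}.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr = "TTGGGTTAGGGTTAGGGTTAGGGTT"))
#' findG4(ref, "chr", delStart = 10, delLen = 5)
#' @export
findG4 <- function(reference, chrom, delStart, delLen, flank = 20L,
                   tractMin = 2L, loopMax = 7L, extremeLoopMax = 30L,
                   allowImperfect = TRUE) {
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  n <- nchar(s)
  ws <- max(0L, delStart - flank)
  we <- min(n, delStart + delLen + flank)
  w <- .sub0(s, ws, we)
  wl <- nchar(w)
  fwd <- .scanG4Strand(w, tractMin, loopMax, extremeLoopMax, allowImperfect)
  rev <- .scanG4Strand(.revcomp(w), tractMin, loopMax, extremeLoopMax,
                       allowImperfect)
  out <- NULL
  if (!is.null(fwd)) { fwd$strand <- "+"; out <- rbind(out, fwd) }
  if (!is.null(rev)) {
    tmp <- rev
    tmp$start <- wl - rev$end
    tmp$end <- wl - rev$start
    tmp$strand <- "-"
    out <- rbind(out, tmp)
  }
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      tract1 = integer(0), tract2 = integer(0),
                      tract3 = integer(0), tract4 = integer(0),
                      loop1 = integer(0), loop2 = integer(0),
                      loop3 = integer(0), imperfect_tract = integer(0),
                      strand = character(0)))
  out$start <- out$start + ws
  out$end <- out$end + ws
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GC fraction of a sequence
#'
#' @param seq nucleotide string.
#' @return fraction of G and C bases (NaN for the empty string).
#' @examples
#' gcFraction("ACGT")  # 0.5
#' @export
gcFraction <- function(seq) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n == 0L) return(NaN)
  sum(Biostrings::letterFrequency(Biostrings::DNAString(toupper(seq)),
                                  c("G", "C"))) / n
}

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic for comparing \code{x1/n1} with
#' \code{x2/n2}, with a two-sided normal p-value:
#' \deqn{z = (p1 - p2) / \sqrt{\hat p (1-\hat p)(1/n1 + 1/n2)}}
#' where \eqn{\hat p = (x1+x2)/(n1+n2)}. When the pooled proportion is 0
#' or 1 the two sample proportions are equal and \code{z = 0}.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with elements \code{z} and \code{p} (two-sided).
#' @seealso [bonferroniAdjust()]
#' @export
twoProportionZTest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1
#' (\code{stats::p.adjust} with method \code{"bonferroni"}).
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p) stats::p.adjust(p, method = "bonferroni")

#' Extended-homolog mispairing potential
#'
#' Tests whether the bases just beyond a homolog pair allow the repair
#' machinery to extend the paired homology by skipping one mismatched
#' base, the configuration proposed to produce one-base imperfect-match
#' deletions. On the RIGHT side, with \code{a1, a2} the two bases after
#' the upstream copy and \code{b1, b2} the two bases after the downstream
#' copy, the extension is possible when \code{a2 == b1} or \code{a1 ==
#' b2}; the LEFT side is the mirrored comparison on the two bases before
#' each copy. For uniform random flanks conditioned on the junction
#' mismatch \code{a1 != b1}, the expected true-rate is 7/16 = 0.4375.
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param chrom contig name.
#' @param start1,start2 0-based starts of the two homolog copies.
#' @param length homolog length in bp.
#' @param side \code{"LEFT"} or \code{"RIGHT"}.
#' @return logical, or \code{NA} (with a skip warning) when fewer than
#'   two bases of context exist on the requested side.
#' @export
extensionPotential <- function(reference, chrom, start1, start2, length,
                               side = c("RIGHT", "LEFT")) {
  side <- match.arg(side)
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  n <- nchar(s)
  ch <- function(p) substring(s, p + 1L, p + 1L)
  if (side == "RIGHT") {
    if (start2 + length + 2L > n) {
      .skip(paste0("no right context for pair ", chrom, ":", start1),
            "no_context")
      return(NA)
    }
    a1 <- ch(start1 + length); a2 <- ch(start1 + length + 1L)
    b1 <- ch(start2 + length); b2 <- ch(start2 + length + 1L)
  } else {
    if (start1 - 2L < 0L) {
      .skip(paste0("no left context for pair ", chrom, ":", start1),
            "no_context")
      return(NA)
    }
    a1 <- ch(start1 - 1L); a2 <- ch(start1 - 2L)
    b1 <- ch(start2 - 1L); b2 <- ch(start2 - 2L)
  }
  (a2 == b1) || (a1 == b2)
}

#' Context features for a set of deletions
#'
#' Per deletion: number of minisatellites in the +/-50 bp window (and how
#' many overlap the deletion), number of G-quadruplex motifs in the
#' +/-20 bp window, and GC fraction of the deleted segment.
#'
#' @param deletions data.frame with \code{chrom}, \code{del_start},
#'   \code{del_len} (e.g. from [candidateTable()] or [deletionCalls()]).
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param minisatFlank,g4Flank window half-widths (defaults 50 and 20).
#' @return the input with columns \code{minisat_count},
#'   \code{minisat_overlap}, \code{g4_count}, \code{gc_del} appended.
#' @export
contextFeatures <- function(deletions, reference, minisatFlank = 50L,
                            g4Flank = 20L) {
  deletions <- .asDeletionDF(deletions)
  refstr <- .refStrings(reference)
  nms <- integer(nrow(deletions)); ovl <- integer(nrow(deletions))
  ng4 <- integer(nrow(deletions)); gc <- numeric(nrow(deletions))
  for (i in seq_len(nrow(deletions))) {
    ms <- findMinisatellites(refstr, deletions$chrom[i],
                             deletions$del_start[i], deletions$del_len[i],
                             flank = minisatFlank)
    nms[i] <- nrow(ms)
    ovl[i] <- sum(ms$position == "OVERLAP")
    g4 <- findG4(refstr, deletions$chrom[i], deletions$del_start[i],
                 deletions$del_len[i], flank = g4Flank)
    ng4[i] <- nrow(g4)
    s <- .getContig(refstr, deletions$chrom[i])
    gc[i] <- gcFraction(.sub0(s, deletions$del_start[i],
                              deletions$del_start[i] + deletions$del_len[i]))
  }
  deletions$minisat_count <- nms
  deletions$minisat_overlap <- ovl
  deletions$g4_count <- ng4
  deletions$gc_del <- gc
  deletions
}

#' Enrichment of context features across deletion categories
#'
#' Compares the fraction of deletions carrying at least one minisatellite
#' and at least one G-quadruplex motif between perfect-match deletions,
#' imperfect-match deletions and random length-matched control deletions,
#' using pairwise two-proportion z-tests with Bonferroni correction over
#' all emitted tests.
#'
#' @param callset data.frame (or \linkS4class{CandidateSet} /
#'   \linkS4class{DeletionCallSet}) with \code{chrom}, \code{del_start},
#'   \code{del_len} and \code{match_type}.
#' @param randomControls data.frame of control deletions with
#'   \code{chrom}, \code{del_start}, \code{del_len} (see
#'   [sampleRandomDeletions()]).
#' @param reference FASTA path or \code{DNAStringSet}.
#' @return data.frame: one row per (feature, category pair) with counts,
#'   fractions, \code{z}, \code{p_raw} and \code{p_adj}; the per-category
#'   summary is attached as attribute \code{"summary"}.
#' @export
enrichmentReport <- function(callset, randomControls, reference) {
  calls <- .asDeletionDF(callset)
  ctrl <- .asDeletionDF(randomControls)
  calls$category <- ifelse(grepl("^imperfect", calls$match_type),
                           "imperfect", "perfect")
  ctrl$category <- "random"
  keep <- c("chrom", "del_start", "del_len", "category")
  all <- rbind(calls[, keep], ctrl[, keep])
  feats <- contextFeatures(all, reference)
  cats <- c("perfect", "imperfect", "random")
  summ <- do.call(rbind, lapply(cats, function(cc) {
    f <- feats[feats$category == cc, , drop = FALSE]
    data.frame(category = cc, n = nrow(f),
               with_minisat = sum(f$minisat_count >= 1L),
               with_g4 = sum(f$g4_count >= 1L),
               frac_minisat = if (nrow(f)) mean(f$minisat_count >= 1L) else NA,
               frac_g4 = if (nrow(f)) mean(f$g4_count >= 1L) else NA)
  }))
  pairsOf <- utils::combn(cats, 2L)
  rows <- list()
  for (feature in c("minisat", "g4")) {
    xcol <- paste0("with_", feature)
    for (k in seq_len(ncol(pairsOf))) {
      c1 <- pairsOf[1L, k]; c2 <- pairsOf[2L, k]
      n1 <- summ$n[summ$category == c1]; n2 <- summ$n[summ$category == c2]
      if (n1 == 0L || n2 == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feature, group1 = c1, group2 = c2, x1 = NA, n1 = n1,
          x2 = NA, n2 = n2, z = NA, p_raw = NA)
        next
      }
      x1 <- summ[[xcol]][summ$category == c1]
      x2 <- summ[[xcol]][summ$category == c2]
      zt <- twoProportionZTest(x1, n1, x2, n2)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feature, group1 = c1, group2 = c2, x1 = x1, n1 = n1,
        x2 = x2, n2 = n2, z = zt$z, p_raw = zt$p)
    }
  }
  report <- do.call(rbind, rows)
  ok <- !is.na(report$p_raw)
  report$p_adj <- NA_real_
  report$p_adj[ok] <- bonferroniAdjust(report$p_raw[ok])
  attr(report, "summary") <- summ
  report
}

#' Draw random length-matched control deletions
#'
#' Samples deletions at uniform positions on the reference whose lengths
#' are drawn (with replacement) from \code{lengths}, for use as the
#' random category in [enrichmentReport()].
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param n number of control deletions.
#' @param lengths vector of deletion lengths to match.
#' @param seed RNG seed.
#' @param margin distance kept from contig ends (default 100).
#' @return data.frame with \code{chrom}, \code{del_start}, \code{del_len}.
#' @export
sampleRandomDeletions <- function(reference, n, lengths, seed = 1L,
                                  margin = 100L) {
  refstr <- .refStrings(reference)
  clen <- nchar(refstr)
  .withSeed(seed, {
    chrom <- sample(names(refstr), n, replace = TRUE,
                    prob = clen / sum(clen))
    len <- sample(rep(lengths, length.out = max(n, length(lengths))), n,
                  replace = TRUE)
    start <- vapply(seq_len(n), function(i) {
      hi <- clen[[chrom[i]]] - len[i] - margin
      sample.int(max(1L, hi - margin), 1L) + margin
    }, numeric(1))
    data.frame(chrom = chrom, del_start = as.integer(start),
               del_len = as.integer(len), match_type = "random",
               stringsAsFactors = FALSE)
  })
}

## coerce the various containers to a deletion data.frame
.asDeletionDF <- function(x) {
  if (methods::is(x, "CandidateSet")) x <- x@candidates
  if (methods::is(x, "DeletionCallSet")) x <- x@calls
  stopifnot(is.data.frame(x),
            all(c("chrom", "del_start", "del_len") %in% names(x)))
  if (!"match_type" %in% names(x)) x$match_type <- "perfect"
  x
}
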