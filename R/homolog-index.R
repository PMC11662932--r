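## Homolog-pair discovery: maximal exact repeats within deletion range.
##
## A homolog pair (start1, start2, L) is two identical L-mers on the same
## contig with spacing D = start2 - start1 inside [dMin, dMax]. Each pair
## is the substrate of one candidate MMEJ deletion. Discovery is
## equivalent to finding diagonal match runs in the self-comparison
## dot-plot of the sequence: for each diagonal offset d the positions
## where seq[i] == seq[i + d] form runs, and every maximal run of length
## >= kMin is one pair. Nested/consecutive homologies collapse into the
## longest run automatically.

#' Find maximal homolog pairs within one sequence window
#'
#' Enumerates every maximal exact repeat pair \code{(offset1, offset2,
#' length)} in \code{seq} with \code{length >= kMin} and spacing
#' \code{offset2 - offset1} in \code{[dMin, dMax]}. A pair is maximal when
#' it cannot be extended by one base on either side while both copies
#' still match (sequence ends count as non-extendable). Positions holding
#' \code{N} never match. Offsets are 0-based.
#'
#' @param seq nucleotide string (A/C/G/T/N, case-insensitive).
#' @param kMin minimum homolog length in bp (default 5).
#' @param dMin,dMax deletion-span range in bp (defaults 6 and 100):
#'   only pairs whose spacing lies in this range are reported.
#' @return data.frame with columns \code{offset1}, \code{offset2},
#'   \code{length}, sorted by \code{(offset1, offset2)}.
#' @examples
#' findHomologsWindow("AAGCTGATTTCGCATAAGCTGC")   # AAGCTG at 0 and 15
#' @export
findHomologsWindow <- function(seq, kMin = 5L, dMin = 6L, dMax = 100L) {
  stopifnot(length(seq) == 1L, kMin >= 1L, dMin >= 1L, dMax >= dMin)
  .checkNucleotides(seq, "window sequence")
  s <- toupper(seq)
  n <- nchar(s)
  out <- .scanDiagonals(charToRaw(s), kMin, dMin, dMax)
  out[order(out$offset1, out$offset2), , drop = FALSE]
}

## core diagonal run-length scan over a raw byte vector; returns 0-based
## offsets. N (0x4e) never matches.
.scanDiagonals <- function(r, kMin, dMin, dMax) {
  n <- length(r)
  isN <- r == as.raw(0x4e)
  res1 <- integer(0); res2 <- integer(0); resL <- integer(0)
  dHi <- min(dMax, n - 1L)
  d <- dMin
  while (d <= dHi) {
    m <- (r[seq_len(n - d)] == r[(d + 1L):n]) & !isN[seq_len(n - d)]
    rl <- rle(m)
    len <- rl$lengths
    ends <- cumsum(len)
    keep <- rl$values & len >= kMin
    if (any(keep)) {
      st <- ends[keep] - len[keep]          # 0-based run start
      res1 <- c(res1, st)
      res2 <- c(res2, st + d)
      resL <- c(resL, len[keep])
    }
    d <- d + 1L
  }
  data.frame(offset1 = res1, offset2 = res2, length = resL)
}

#' Build a homolog-pair index over a reference
#'
#' Slides fixed-size windows along each contig (or along supplied target
#' regions), finds window-local homolog pairs with
#' \code{\link{findHomologsWindow}}, re-checks maximality against the
#' full contig so window edges cannot truncate a pair, and deduplicates
#' pairs discovered in overlapping windows.
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param regions optional target regions: a BED file path or a
#'   \code{GRanges}. Windows are restricted to these regions; maximality
#'   is still assessed in full-contig context.
#' @param window window size in bp (default 240).
#' @param step window step in bp (default 100). Must satisfy
#'   \code{step <= window - dMax - kMin + 1} so no pair can be missed
#'   between windows.
#' @param kMin minimum homolog length (default 5).
#' @param dMin,dMax deletion-span range (defaults 6, 100).
#' @param allowOverlap keep pairs whose two copies overlap
#'   (tandem-periodic homologies, \code{start2 < start1 + length});
#'   default TRUE. They are flagged in the output either way.
#' @return a \linkS4class{HomologIndex}
#' @seealso [findHomologsWindow()], [writeHomologIndex()]
#' @export
buildHomologIndex <- function(reference, regions = NULL, window = 240L,
                              step = 100L, kMin = 5L, dMin = 6L,
                              dMax = 100L, allowOverlap = TRUE) {
  refstr <- .refStrings(reference)
  if (step > window - dMax - kMin + 1L)
    stop("step must be <= window - dMax - kMin + 1 (", window - dMax - kMin + 1L,
         ") or homolog pairs spanning window boundaries could be missed")
  regs <- .resolveRegions(regions, refstr)

  acc <- vector("list", nrow(regs))
  for (i in seq_len(nrow(regs))) {
    chrom <- regs$chrom[i]
    s <- refstr[[chrom]]
    rstart <- regs$start[i]; rend <- regs$end[i]
    wlen <- rend - rstart
    if (wlen <= window) {
      starts <- rstart
      wsize <- wlen
    } else {
      starts <- seq.int(rstart, rend - window, by = step)
      if (starts[length(starts)] + window < rend)
        starts <- c(starts, rend - window)
      wsize <- window
    }
    hits <- lapply(starts, function(ws) {
      h <- findHomologsWindow(.sub0(s, ws, min(ws + wsize, rend)),
                              kMin = kMin, dMin = dMin, dMax = dMax)
      if (nrow(h)) { h$offset1 <- h$offset1 + ws; h$offset2 <- h$offset2 + ws }
      h
    })
    h <- do.call(rbind, hits)
    if (!nrow(h)) { acc[[i]] <- NULL; next }
    h <- .extendToContigMaximal(s, h)
    h <- h[h$length >= kMin, , drop = FALSE]
    h <- unique(h)
    h$chrom <- chrom
    acc[[i]] <- h
  }
  pairs <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(chrom = character(0), start1 = integer(0),
                        start2 = integer(0), length = integer(0),
                        seq = character(0), overlapping = logical(0))
  } else {
    names(pairs)[names(pairs) == "offset1"] <- "start1"
    names(pairs)[names(pairs) == "offset2"] <- "start2"
    pairs <- unique(pairs)   # same pair can enter via two regions
    pairs$seq <- .sub0(refstr[pairs$chrom], pairs$start2,
                       pairs$start2 + pairs$length)
    pairs$overlapping <- pairs$start2 < pairs$start1 + pairs$length
    if (!allowOverlap)
      pairs <- pairs[!pairs$overlapping, , drop = FALSE]
    pairs <- pairs[order(pairs$chrom, pairs$start1, pairs$start2), ,
                   drop = FALSE]
    pairs <- pairs[, c("chrom", "start1", "start2", "length", "seq",
                       "overlapping")]
    rownames(pairs) <- NULL
  }
  methods::new("HomologIndex", pairs = pairs,
               config = list(window = window, step = step, kMin = kMin,
                             dMin = dMin, dMax = dMax,
                             allowOverlap = allowOverlap),
               reference = if (is.character(reference)) reference
                           else "DNAStringSet")
}

## extend window-local pairs to full-contig maximality (same diagonal);
## N never matches so extension stops at N
.extendToContigMaximal <- function(s, h) {
  n <- nchar(s)
  ch <- function(p) substring(s, p + 1L, p + 1L)   # 0-based single base
  for (k in seq_len(nrow(h))) {
    a <- h$offset1[k]; b <- h$offset2[k]; L <- h$length[k]
    while (a > 0L) {
      x <- ch(a - 1L); y <- ch(b - 1L)
      if (x != y || x == "N") break
      a <- a - 1L; b <- b - 1L; L <- L + 1L
    }
    while (b + L < n) {
      x <- ch(a + L); y <- ch(b + L)
      if (x != y || x == "N") break
      L <- L + 1L
    }
    h$offset1[k] <- a; h$offset2[k] <- b; h$length[k] <- L
  }
  h
}

## normalise `regions` to a data.frame(chrom, start, end), 0-based
.resolveRegions <- function(regions, refstr) {
  clen <- nchar(refstr)
  if (is.null(regions)) {
    return(data.frame(chrom = names(refstr), start = 0L, end = unname(clen),
                      stringsAsFactors = FALSE))
  }
  if (is.character(regions) && length(regions) == 1L) {
    gr <- rtracklayer::import(regions, format = "BED")
  } else if (methods::is(regions, "GRanges")) {
    gr <- regions
  } else stop("regions must be a BED path or a GRanges")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    if (!df$chrom[i] %in% names(refstr))
      stop("region ", df$chrom[i], ":", df$start[i], "-", df$end[i],
           " references an unknown contig")
    if (df$start[i] < 0L || df$end[i] > clen[[df$chrom[i]]] ||
        df$start[i] >= df$end[i])
      stop("region ", df$chrom[i], ":", df$start[i], "-", df$end[i],
           " lies outside contig bounds (length ",
           clen[[df$chrom[i]]], ")")
  }
  df
}

#' Write / read a homolog index as TSV
#'
#' The on-disk format is a tab-separated table with a comment header and
#' columns \code{chrom}, \code{start1}, \code{start2}, \code{length},
#' \code{homolog_seq}. \code{readHomologIndex(writeHomologIndex(x)) == x}.
#'
#' @param index a \linkS4class{HomologIndex}
#' @param path output TSV path
#' @return \code{writeHomologIndex}: the path, invisibly.
#' @export
writeHomologIndex <- function(index, path) {
  stopifnot(methods::is(index, "HomologIndex"))
  p <- index@pairs
  df <- data.frame(chrom = p$chrom, start1 = p$start1, start2 = p$start2,
                   length = p$length, homolog_seq = p$seq)
  .writeTSV(df, path, command = "writeHomologIndex", config = index@config)
  invisible(path)
}

#' @rdname writeHomologIndex
#' @param reference optional reference; when given, each row's
#'   \code{homolog_seq} is validated against both homolog copies.
#' @return \code{readHomologIndex}: a \linkS4class{HomologIndex}.
#' @export
readHomologIndex <- function(path, reference = NULL) {
  df <- .readTSV(path, required = c("chrom", "start1", "start2", "length",
                                    "homolog_seq"))
  bad <- which(is.na(df$start1) | is.na(df$start2) | is.na(df$length) |
               !nzchar(df$chrom) | nchar(df$homolog_seq) != df$length)
  if (length(bad))
    stop("malformed index row(s) in ", path, ": data line ",
         paste(bad, collapse = ", "))
  pairs <- data.frame(chrom = as.character(df$chrom),
                      start1 = as.integer(df$start1),
                      start2 = as.integer(df$start2),
                      length = as.integer(df$length),
                      seq = toupper(as.character(df$homolog_seq)),
                      stringsAsFactors = FALSE)
  pairs$overlapping <- pairs$start2 < pairs$start1 + pairs$length
  if (!is.null(reference)) {
    refstr <- .refStrings(reference)
    for (i in seq_len(nrow(pairs))) {
      s <- .getContig(refstr, pairs$chrom[i])
      h1 <- .sub0(s, pairs$start1[i], pairs$start1[i] + pairs$length[i])
      h2 <- .sub0(s, pairs$start2[i], pairs$start2[i] + pairs$length[i])
      if (h1 != pairs$seq[i] || h2 != pairs$seq[i])
        stop("homolog_seq mismatch against reference at data line ", i,
             " (", pairs$chrom[i], ":", pairs$start1[i], ")")
    }
  }
  methods::new("HomologIndex", pairs = pairs, config = list(),
               reference = if (is.null(reference)) "unspecified"
                           else if (is.character(reference)) reference
                           else "DNAStringSet")
}
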