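## Read scanning: count reads whose sequence contains a candidate's
## junction search sequence, measure local depth next to the homolog
## pair, and derive the variant allele frequency.
##
## The search is alignment-free on purpose: a read whose aligner chose a
## soft-clip or a shifted gap still contains the junction string, so by
## default the full read sequence (including clipped bases) is searched.
## BAM stores read sequences on the forward reference strand, so BAM mode
## searches the forward search sequence only; FASTQ mode searches both
## orientations.

#' Scan configuration
#'
#' @param fetchPad bases added on both sides of the homolog pair when
#'   fetching reads (default 100).
#' @param depthFlank width of the depth windows immediately outside the
#'   homolog pair (default 5): depth is the mean per-base coverage over
#'   \code{[start1 - depthFlank, start1)} and
#'   \code{[start2 + L, start2 + L + depthFlank)}.
#' @param dedup ignore duplicate-flagged reads for support counting
#'   (default TRUE; depth always excludes duplicates).
#' @param minMapq minimum mapping quality (default 0: no filter).
#' @param searchSpace \code{"full_read"} (default: whole read sequence,
#'   soft-clipped bases included) or \code{"aligned_only"} (soft-clipped
#'   bases removed before the search).
#' @param vafDenominator \code{"junction"} (default) divides support by
#'   the junction-spanning effective depth -- the flanking coverage scaled
#'   by \code{(readLen - k + 1) / readLen} with \code{k} the search-seq
#'   length, i.e. the expected number of read placements that fully span
#'   the junction -- giving an unbiased VAF. \code{"raw"} divides by the
#'   unscaled flanking coverage.
#' @return validated list of class \code{ScanConfig}
#' @export
scanConfig <- function(fetchPad = 100L, depthFlank = 5L, dedup = TRUE,
                       minMapq = 0L,
                       searchSpace = c("full_read", "aligned_only"),
                       vafDenominator = c("junction", "raw")) {
  stopifnot(fetchPad >= 0L, depthFlank >= 1L, minMapq >= 0L)
  cfg <- list(fetchPad = as.integer(fetchPad),
              depthFlank = as.integer(depthFlank),
              dedup = isTRUE(dedup), minMapq = as.integer(minMapq),
              searchSpace = match.arg(searchSpace),
              vafDenominator = match.arg(vafDenominator))
  class(cfg) <- "ScanConfig"
  cfg
}

## fetch reads overlapping `which` (GRanges); returns list per range with
## qname, flag, pos (1-based), cigar, seq (character), mapq
.fetchReads <- function(bam, which) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index not found for ", bam,
         " -- create it with Rsamtools::indexBam() or samtools index")
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(which))),
                     names(hdr))
  if (length(missing))
    stop("contig(s) ", paste(missing, collapse = ", "),
         " absent from BAM header (BAM contigs: ",
         paste(names(hdr), collapse = ", "), ")")
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "pos", "cigar", "seq", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)
  lapply(res, function(x) {
    x$seq <- as.character(x$seq)
    x
  })
}

## drop soft-clipped prefix/suffix from read sequences (aligned_only)
.clipSoft <- function(seqs, cigars) {
  lead <- as.integer(sub("^([0-9]+)S.*$", "\\1",
                         ifelse(grepl("^[0-9]+S", cigars), cigars, "0S")))
  trail <- as.integer(sub("^.*[A-Z=]([0-9]+)S$", "\\1",
                          ifelse(grepl("[A-Z=][0-9]+S$", cigars), cigars,
                                 "M0S")))
  substr(seqs, lead + 1L, nchar(seqs) - trail)
}

## per-read support decision for one candidate given fetched reads
.supportFromReads <- function(reads, searchSeq, config) {
  if (length(reads$qname) == 0L) return(0L)
  keep <- reads$mapq >= config$minMapq | is.na(reads$mapq)
  if (config$dedup) keep <- keep & !bitwAnd(reads$flag, 1024L)
  if (!any(keep)) return(0L)
  key <- paste(reads$qname[keep], reads$flag[keep], reads$pos[keep])
  first <- !duplicated(key)
  seqs <- reads$seq[keep][first]
  if (config$searchSpace == "aligned_only")
    seqs <- .clipSoft(seqs, reads$cigar[keep][first])
  hits <- Biostrings::vcountPattern(Biostrings::DNAString(searchSeq),
                                    Biostrings::DNAStringSet(seqs),
                                    fixed = TRUE)
  sum(hits > 0L)
}

## ref-space coverage intervals of a read: list of (start0, end0) from
## cigar ops that consume reference AND align bases (M, =, X)
.coverIntervals <- function(pos1, cigar) {
  ## fast path: plain full-length match
  if (grepl("^[0-9]+M$", cigar)) {
    n <- as.integer(sub("M", "", cigar))
    return(list(c(pos1 - 1L, pos1 - 1L + n)))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  p <- pos1 - 1L   # 0-based
  out <- list()
  for (t in toks) {
    n <- as.integer(sub("[A-Z=]", "", t))
    op <- sub("[0-9]+", "", t)
    if (op %in% c("M", "=", "X")) {
      out[[length(out) + 1L]] <- c(p, p + n); p <- p + n
    } else if (op %in% c("D", "N")) {
      p <- p + n
    }
    ## I, S, H, P consume no reference
  }
  out
}

## mean coverage over 0-based positions `positions` from fetched reads
.depthFromReads <- function(reads, positions, config) {
  if (length(positions) == 0L) return(0)
  if (length(reads$qname) == 0L) return(0)
  keep <- !bitwAnd(reads$flag, 1024L)           # never count duplicates
  keep <- keep & (reads$mapq >= config$minMapq | is.na(reads$mapq))
  if (!any(keep)) return(0)
  key <- paste(reads$qname[keep], reads$flag[keep], reads$pos[keep])
  first <- !duplicated(key)
  pos1 <- reads$pos[keep][first]
  cigs <- reads$cigar[keep][first]
  cov <- numeric(length(positions))
  for (i in seq_along(pos1)) {
    for (iv in .coverIntervals(pos1[i], cigs[i])) {
      hit <- positions >= iv[1L] & positions < iv[2L]
      cov[hit] <- cov[hit] + 1
    }
  }
  mean(cov)
}

## depth window positions for a candidate (0-based), truncated to contig
.depthPositions <- function(cand, config, contigLen = NA) {
  df <- config$depthFlank
  left <- seq.int(cand$start1 - df, cand$start1 - 1L)
  right <- seq.int(cand$start2 + cand$length,
                   cand$start2 + cand$length + df - 1L)
  pos <- c(left, right)
  ok <- pos >= 0L & (is.na(contigLen) | pos < contigLen)
  if (!all(ok))
    warning("depth window truncated at contig edge near ",
            cand$chrom, ":", cand$start1)
  pos[ok]
}

#' Count reads supporting one candidate deletion
#'
#' Fetches reads overlapping the homolog pair padded by
#' \code{config$fetchPad} and counts those whose sequence contains the
#' candidate's search sequence as an exact substring. Each read is
#' counted at most once; mates are distinct reads.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param candidate one-row data.frame (a row of [candidateTable()]).
#' @param config a [scanConfig()].
#' @return integer supporting-read count.
#' @export
countSupportingReads <- function(bam, candidate, config = scanConfig()) {
  which <- .fetchRange(candidate, config)
  reads <- .fetchReads(bam, which)[[1L]]
  .supportFromReads(reads, candidate$search_seq, config)
}

.fetchRange <- function(cand, config) {
  lo <- max(0L, cand$start1 - config$fetchPad)
  hi <- cand$start2 + cand$length + config$fetchPad
  GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(lo + 1L, hi))
}

#' Mean local depth next to a candidate's homolog pair
#'
#' Mean per-base coverage (duplicate-flagged reads excluded) over the
#' \code{depthFlank} positions immediately upstream of the first homolog
#' copy and immediately downstream of the second.
#'
#' @inheritParams countSupportingReads
#' @return numeric mean coverage.
#' @export
localDepth <- function(bam, candidate, config = scanConfig()) {
  which <- .fetchRange(candidate, config)
  reads <- .fetchReads(bam, which)[[1L]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  pos <- .depthPositions(candidate, config,
                         contigLen = unname(hdr[[candidate$chrom]]))
  .depthFromReads(reads, pos, config)
}

#' Scan a BAM for all candidate deletions
#'
#' For every candidate, counts supporting reads and computes local depth
#' and VAF in a single pass over the BAM (one fetch per candidate
#' window). VAF is \code{support / eff_depth} (see
#' \code{vafDenominator} in [scanConfig()]), clamped to 1 with a warning
#' counter, and 0 when depth is 0.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param candidates a \linkS4class{CandidateSet} (or data.frame).
#' @param config a [scanConfig()].
#' @param sample sample label (default: BAM basename).
#' @return a \linkS4class{DeletionCallSet}
#' @export
callCandidates <- function(bam, candidates, config = scanConfig(),
                           sample = NULL) {
  cand <- if (methods::is(candidates, "CandidateSet"))
    candidates@candidates else candidates
  stopifnot(is.data.frame(cand))
  if (is.null(sample)) sample <- sub("\\.bam$", "", basename(bam))
  n <- nrow(cand)
  support <- integer(n); depth <- numeric(n); effDepth <- numeric(n)
  if (n > 0L) {
    which <- GenomicRanges::GRanges(
      cand$chrom,
      IRanges::IRanges(pmax(0L, cand$start1 - config$fetchPad) + 1L,
                       cand$start2 + cand$length + config$fetchPad))
    allReads <- .fetchReads(bam, which)
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    for (i in seq_len(n)) {
      reads <- allReads[[i]]
      support[i] <- .supportFromReads(reads, cand$search_seq[i], config)
      pos <- .depthPositions(cand[i, ], config,
                             contigLen = unname(hdr[[cand$chrom[i]]]))
      depth[i] <- .depthFromReads(reads, pos, config)
      effDepth[i] <- .effectiveDepth(depth[i], reads,
                                     nchar(cand$search_seq[i]), config)
    }
  }
  vaf <- ifelse(effDepth > 0, support / effDepth, 0)
  over <- sum(vaf > 1)
  if (over > 0L)
    warning(over, " candidate(s) had support exceeding effective depth; ",
            "VAF clamped to 1")
  vaf <- pmin(vaf, 1)
  calls <- cand
  calls$support <- support
  calls$depth <- depth
  calls$eff_depth <- effDepth
  calls$vaf <- vaf
  methods::new("DeletionCallSet", calls = calls, sample = sample,
               config = unclass(config))
}

## junction-spanning effective depth: a read of length rl has rl - k + 1
## placements containing a k-mer vs rl placements covering a base, so the
## flanking coverage is scaled by (rl - k + 1)/rl. Read length is taken
## as the modal length of the fetched reads.
.effectiveDepth <- function(depth, reads, k, config) {
  if (config$vafDenominator == "raw" || depth == 0) return(depth)
  lens <- nchar(reads$seq)
  if (length(lens) == 0L) return(depth)
  rl <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  if (rl <= k) return(0)
  depth * (rl - k + 1) / rl
}

#' Scan a FASTQ for candidate deletions (amplicon mode)
#'
#' For amplicon or hotspot sequencing without alignment: support is the
#' number of reads containing the search sequence in either orientation,
#' depth is the total number of reads scanned, and VAF = support/depth.
#'
#' @param fastq path to a FASTQ file (optionally gzipped).
#' @param candidates a \linkS4class{CandidateSet} or data.frame
#'   (single-locus candidate sets are the intended use).
#' @param sample sample label (default: file basename).
#' @return a \linkS4class{DeletionCallSet}
#' @export
scanFastq <- function(fastq, candidates, sample = NULL) {
  cand <- if (methods::is(candidates, "CandidateSet"))
    candidates@candidates else candidates
  if (!file.exists(fastq)) stop("FASTQ file not found: ", fastq)
  reads <- tryCatch(Biostrings::readDNAStringSet(fastq, format = "fastq"),
                    error = function(e)
                      stop("malformed FASTQ ", fastq, ": ",
                           conditionMessage(e)))
  if (length(reads) == 0L) stop("FASTQ file ", fastq, " contains no reads")
  if (is.null(sample)) sample <- sub("\\.f(ast)?q(\\.gz)?$", "",
                                     basename(fastq))
  n <- nrow(cand)
  support <- integer(n)
  for (i in seq_len(n)) {
    pat <- Biostrings::DNAString(cand$search_seq[i])
    fwd <- Biostrings::vcountPattern(pat, reads, fixed = TRUE)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                     reads, fixed = TRUE)
    support[i] <- sum(fwd > 0L | rev > 0L)
  }
  calls <- cand
  calls$support <- support
  calls$depth <- length(reads)
  calls$eff_depth <- as.numeric(length(reads))
  calls$vaf <- support / length(reads)
  methods::new("DeletionCallSet", calls = calls, sample = sample,
               config = list(mode = "fastq"))
}

#' Write / read a call table as TSV
#'
#' @param calls a \linkS4class{DeletionCallSet}.
#' @param path TSV path.
#' @export
writeCalls <- function(calls, path) {
  stopifnot(methods::is(calls, "DeletionCallSet"))
  df <- calls@calls
  df$sample <- calls@sample
  .writeTSV(df, path, command = "writeCalls", config = calls@config)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  df <- .readTSV(path, required = c("chrom", "del_start", "del_len",
                                    "match_type", "search_seq", "support",
                                    "depth", "vaf"))
  sample <- if ("sample" %in% names(df)) df$sample[1L] else "unknown"
  df$sample <- NULL
  if (!"eff_depth" %in% names(df)) df$eff_depth <- df$depth
  methods::new("DeletionCallSet", calls = df,
               sample = if (is.na(sample)) "unknown" else sample,
               config = list())
}
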