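## Candidate construction: each homolog pair is turned into up to three
## candidate deletion variants, each carrying the exact post-deletion
## junction sequence ("search sequence") whose presence in a read is the
## detection signal.
##
## With H the homolog sequence (ref[start2, start2+L)), D = start2-start1:
##   perfect      removes [start1, start2): product keeps one homolog copy
##   imperfect A  removes [start1-1, start2): one extra base lost on the
##                left of the perfect junction
##   imperfect B  additionally loses the base just right of the retained
##                homolog; its contiguous equivalent removes
##                [start1+L, start2+L+1)
## The search sequence is always flank + H + flank in the post-deletion
## product, so length = 2*flank + L.

.MATCH_TYPES <- c("perfect", "imperfect_A", "imperfect_B")

#' Build the junction search sequence for one homolog pair
#'
#' Constructs the predicted post-deletion junction sequence for a homolog
#' pair and match type: \code{flank} bases of upstream context, the
#' retained homolog, and \code{flank} bases of downstream context, taken
#' from the appropriate coordinates of the unedited reference. The
#' returned record also carries the deletion interval (0-based,
#' contiguous equivalent) in reference coordinates.
#'
#' Candidates too close to a contig edge for their flanks, or whose
#' window contains \code{N}, are skipped with a warning of class
#' \code{mmejSkip} and return \code{NULL} (recoverable; not an error).
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param chrom contig name.
#' @param start1,start2 0-based starts of the homolog copies.
#' @param length homolog length L.
#' @param matchType \code{"perfect"}, \code{"imperfect_A"} or
#'   \code{"imperfect_B"}.
#' @param flank flank size in bp (default 15).
#' @return one-row data.frame with \code{chrom}, \code{del_start},
#'   \code{del_len}, \code{match_type}, \code{start1}, \code{start2},
#'   \code{length}, \code{search_seq}; or \code{NULL} when skipped.
#' @export
makeSearchSeq <- function(reference, chrom, start1, start2, length,
                          matchType = "perfect", flank = 15L) {
  matchType <- match.arg(matchType, .MATCH_TYPES)
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  n <- nchar(s)
  L <- length; D <- start2 - start1
  stopifnot(D >= 1L, L >= 1L, flank >= 1L)
  H <- .sub0(s, start2, start2 + L)

  lo <- start1 - flank - (matchType == "imperfect_A")
  hi <- start2 + L + flank + (matchType == "imperfect_B")
  if (lo < 0L || hi > n)
    return(.skip(paste0("insufficient flank for pair ", chrom, ":", start1,
                        "/", start2, " (", matchType, ")"), "edge"))

  ss <- switch(matchType,
    perfect = paste0(.sub0(s, start1 - flank, start1), H,
                     .sub0(s, start2 + L, start2 + L + flank)),
    imperfect_A = paste0(.sub0(s, start1 - flank - 1L, start1 - 1L), H,
                         .sub0(s, start2 + L, start2 + L + flank)),
    imperfect_B = paste0(.sub0(s, start1 - flank, start1), H,
                         .sub0(s, start2 + L + 1L, start2 + L + flank + 1L)))
  if (grepl("N", .sub0(s, lo, hi), fixed = TRUE))
    return(.skip(paste0("N in search window for pair ", chrom, ":", start1,
                        "/", start2), "N"))
  ds <- switch(matchType, perfect = start1, imperfect_A = start1 - 1L,
               imperfect_B = start1 + L)
  data.frame(chrom = chrom, del_start = ds,
             del_len = D + (matchType != "perfect"),
             match_type = matchType, start1 = start1, start2 = start2,
             length = L, search_seq = ss, stringsAsFactors = FALSE)
}

#' Reference self-match filter
#'
#' A search sequence that occurs verbatim anywhere in the unedited
#' reference (forward strand or reverse complement) cannot distinguish a
#' deletion-carrying read from a normal read and must be discarded.
#'
#' @param searchSeq junction search sequence (character).
#' @param reference FASTA path or \code{DNAStringSet}.
#' @return TRUE when the candidate must be discarded.
#' @export
referenceMatchFilter <- function(searchSeq, reference) {
  ref <- loadReference(reference)
  pat <- Biostrings::DNAString(toupper(searchSeq))
  fwd <- sum(Biostrings::vcountPattern(pat, ref, fixed = TRUE))
  if (fwd > 0L) return(TRUE)
  rev <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                       ref, fixed = TRUE))
  rev > 0L
}

#' Microsatellite coverage of a deleted segment
#'
#' Fraction of the deleted bases covered by perfect tandem repeats with
#' unit length 1..\code{unitMax} and at least two full copies. A
#' homopolymer must run at least \code{minSpan} bases to count (a merely
#' doubled base is not a microsatellite). Candidates whose deleted
#' segment exceeds 80 percent microsatellite coverage are low-complexity
#' artifact territory and are filtered in [generateCandidates()].
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param chrom contig name.
#' @param delStart 0-based deletion start.
#' @param delLen deletion length.
#' @param unitMax maximum microsatellite unit (default 4; unit >= 5 is a
#'   minisatellite and is handled by [findMinisatellites()]).
#' @param minSpan minimum tandem-array span in bases (default 3).
#' @return fraction in [0, 1].
#' @export
microsatelliteFraction <- function(reference, chrom, delStart, delLen,
                                   unitMax = 4L, minSpan = 3L) {
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  seg <- .sub0(s, delStart, delStart + delLen)
  .microsatFractionSeq(seg, unitMax = unitMax, minSpan = minSpan)
}

.microsatFractionSeq <- function(seg, unitMax = 4L, minSpan = 3L) {
  n <- nchar(seg)
  if (n == 0L) return(0)
  reps <- findTandemRepeats(seg, unitMin = 1L, unitMax = unitMax)
  reps <- reps[reps$end - reps$start >= minSpan, , drop = FALSE]
  if (nrow(reps) == 0L) return(0)
  covered <- logical(n)
  for (i in seq_len(nrow(reps)))
    covered[(reps$start[i] + 1L):reps$end[i]] <- TRUE
  sum(covered) / n
}

#' Generate filtered candidate deletion variants from a homolog index
#'
#' For every homolog pair, emits the perfect-match candidate and (when
#' \code{imperfect = TRUE}) the two one-base imperfect variants, then
#' applies the two artifact filters: candidates whose search sequence has
#' a complete match in the reference (either strand) are dropped, as are
#' candidates whose deleted segment is more than \code{microsatMax}
#' covered by microsatellites. Skipped pairs (contig edge, N) are counted
#' in the returned object.
#'
#' @param index a \linkS4class{HomologIndex} (or its pairs data.frame).
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param flank flank size in bp (default 15).
#' @param imperfect also emit imperfect type A/B candidates (default
#'   TRUE).
#' @param microsatMax microsatellite-coverage threshold above which the
#'   candidate is removed (default 0.8).
#' @param keepFiltered keep filtered rows (flagged, not removed); default
#'   FALSE.
#' @return a \linkS4class{CandidateSet}
#' @export
generateCandidates <- function(index, reference, flank = 15L,
                               imperfect = TRUE, microsatMax = 0.8,
                               keepFiltered = FALSE) {
  pairs <- if (methods::is(index, "HomologIndex")) index@pairs else index
  stopifnot(is.data.frame(pairs))
  refstr <- .refStrings(reference)
  ref <- loadReference(reference)
  types <- if (imperfect) .MATCH_TYPES else "perfect"

  res <- .collectSkips({
    rows <- vector("list", nrow(pairs) * length(types))
    k <- 0L
    for (i in seq_len(nrow(pairs))) {
      for (tt in types) {
        k <- k + 1L
        rows[[k]] <- makeSearchSeq(refstr, pairs$chrom[i], pairs$start1[i],
                                   pairs$start2[i], pairs$length[i],
                                   matchType = tt, flank = flank)
      }
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
  cand <- res$value
  skipped <- res$skipped
  if (is.null(cand) || nrow(cand) == 0L) {
    cand <- data.frame(chrom = character(0), del_start = integer(0),
                       del_len = integer(0), match_type = character(0),
                       start1 = integer(0), start2 = integer(0),
                       length = integer(0), search_seq = character(0),
                       ref_self_match = logical(0),
                       microsat_frac = numeric(0))
  } else {
    cand$ref_self_match <- vapply(cand$search_seq, referenceMatchFilter,
                                  logical(1), reference = ref,
                                  USE.NAMES = FALSE)
    cand$microsat_frac <- vapply(seq_len(nrow(cand)), function(i) {
      s <- .getContig(refstr, cand$chrom[i])
      .microsatFractionSeq(.sub0(s, cand$del_start[i],
                                 cand$del_start[i] + cand$del_len[i]))
    }, numeric(1))
    if (!keepFiltered)
      cand <- cand[!cand$ref_self_match & cand$microsat_frac <= microsatMax,
                   , drop = FALSE]
    rownames(cand) <- NULL
  }
  methods::new("CandidateSet", candidates = cand, flank = as.integer(flank),
               skipped = if (length(skipped)) skipped else
                 stats::setNames(integer(0), character(0)),
               config = list(flank = flank, imperfect = imperfect,
                             microsatMax = microsatMax))
}

#' Write / read a candidate table as TSV
#'
#' @param candidates a \linkS4class{CandidateSet}.
#' @param path TSV path.
#' @return \code{writeCandidates}: the path invisibly;
#'   \code{readCandidates}: a \linkS4class{CandidateSet}.
#' @export
writeCandidates <- function(candidates, path) {
  stopifnot(methods::is(candidates, "CandidateSet"))
  .writeTSV(candidates@candidates, path, command = "writeCandidates",
            config = candidates@config)
  invisible(path)
}

#' @rdname writeCandidates
#' @param flank flank size recorded with the set (default 15).
#' @export
readCandidates <- function(path, flank = 15L) {
  df <- .readTSV(path, required = c("chrom", "del_start", "del_len",
                                    "match_type", "start1", "start2",
                                    "length", "search_seq"))
  if (!"ref_self_match" %in% names(df)) df$ref_self_match <- FALSE
  if (!"microsat_frac" %in% names(df)) df$microsat_frac <- 0
  methods::new("CandidateSet", candidates = df, flank = as.integer(flank),
               skipped = stats::setNames(integer(0), character(0)),
               config = list(flank = flank))
}
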