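## Tumor/normal classification, hotspot-region enumeration of all
## possible deletions, and repair-mechanism classification.

#' Classify one tumor/normal candidate pair as somatic or germline
#'
#' Decision rules applied to a matched tumor and normal call for the same
#' candidate:
#' \itemize{
#'   \item SOMATIC: tumor VAF > 0.1, normal has zero supporting reads,
#'     both depths > 30, and the locus is not blacklisted;
#'   \item GERMLINE: both VAFs within [0.1, 0.86] and both depths >= 30;
#'   \item otherwise NONE, with a reason naming the failed clause.
#' }
#' The somatic depth bound is strict (> 30) and the germline bound
#' inclusive (>= 30); the normal-VAF requirement for somatic status is
#' tested as exactly zero supporting reads.
#'
#' @param tumor,normal one-row data.frames (rows of [deletionCalls()])
#'   for the same candidate, carrying \code{vaf}, \code{depth},
#'   \code{support} and the deletion coordinates.
#' @param blacklist optional data.frame of excluded loci with
#'   \code{chrom}, \code{del_start}, \code{del_len}.
#' @return list with \code{verdict} (\code{"SOMATIC"}, \code{"GERMLINE"}
#'   or \code{"NONE"}) and \code{reason}.
#' @export
classifyPaired <- function(tumor, normal, blacklist = NULL) {
  key <- c("chrom", "del_start", "del_len")
  if (!all(unlist(tumor[key]) == unlist(normal[key])))
    stop("tumor and normal calls refer to different candidates")
  blacklisted <- FALSE
  if (!is.null(blacklist) && nrow(blacklist) > 0L)
    blacklisted <- any(blacklist$chrom == tumor$chrom &
                       blacklist$del_start == tumor$del_start &
                       blacklist$del_len == tumor$del_len)
  vt <- tumor$vaf; vn <- normal$vaf
  dt <- tumor$depth; dn <- normal$depth
  sn <- normal$support

  if (vt > 0.1 && sn == 0L && dt > 30 && dn > 30 && !blacklisted)
    return(list(verdict = "SOMATIC",
                reason = "tumor VAF > 0.1, normal support 0, depths > 30"))
  if (vt >= 0.1 && vt <= 0.86 && vn >= 0.1 && vn <= 0.86 &&
      dt >= 30 && dn >= 30)
    return(list(verdict = "GERMLINE",
                reason = "both VAFs in [0.1, 0.86], depths >= 30"))

  somFail <- c(
    if (vt <= 0.1) "tumor VAF <= 0.1",
    if (sn != 0L) "normal support > 0",
    if (dt <= 30) "tumor depth <= 30",
    if (dn <= 30) "normal depth <= 30",
    if (blacklisted) "locus blacklisted")
  germFail <- c(
    if (vt < 0.1 || vt > 0.86) "tumor VAF outside [0.1, 0.86]",
    if (vn < 0.1 || vn > 0.86) "normal VAF outside [0.1, 0.86]",
    if (dt < 30) "tumor depth < 30",
    if (dn < 30) "normal depth < 30")
  list(verdict = "NONE",
       reason = paste0("somatic: ", paste(somFail, collapse = ", "),
                       "; germline: ", paste(germFail, collapse = ", ")))
}

#' Classify all shared candidates of a tumor/normal pair
#'
#' Joins the two call sets on the candidate key (chrom, del_start,
#' del_len, match_type) and applies [classifyPaired()] to each shared
#' candidate.
#'
#' @param tumorCalls,normalCalls \linkS4class{DeletionCallSet}s scanned
#'   against the same candidate set.
#' @param blacklist optional excluded-locus data.frame (or TSV path) with
#'   \code{chrom}, \code{del_start}, \code{del_len}.
#' @return data.frame with candidate columns, tumor/normal evidence and
#'   \code{verdict}, \code{reason}.
#' @export
classifyPairedCalls <- function(tumorCalls, normalCalls, blacklist = NULL) {
  tc <- if (methods::is(tumorCalls, "DeletionCallSet")) tumorCalls@calls
        else tumorCalls
  nc <- if (methods::is(normalCalls, "DeletionCallSet")) normalCalls@calls
        else normalCalls
  if (is.character(blacklist))
    blacklist <- .readTSV(blacklist,
                          required = c("chrom", "del_start", "del_len"))
  key <- function(df) paste(df$chrom, df$del_start, df$del_len,
                            df$match_type)
  tk <- key(tc); nk <- key(nc)
  shared <- intersect(tk, nk)
  out <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    t1 <- tc[match(shared[i], tk), , drop = FALSE]
    n1 <- nc[match(shared[i], nk), , drop = FALSE]
    cls <- classifyPaired(t1, n1, blacklist)
    out[[i]] <- data.frame(
      chrom = t1$chrom, del_start = t1$del_start, del_len = t1$del_len,
      match_type = t1$match_type,
      vaf_tumor = t1$vaf, vaf_normal = n1$vaf,
      depth_tumor = t1$depth, depth_normal = n1$depth,
      support_tumor = t1$support, support_normal = n1$support,
      verdict = cls$verdict, reason = cls$reason,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), del_start = integer(0),
                      del_len = integer(0), match_type = character(0),
                      vaf_tumor = numeric(0), vaf_normal = numeric(0),
                      depth_tumor = numeric(0), depth_normal = numeric(0),
                      support_tumor = integer(0),
                      support_normal = integer(0),
                      verdict = character(0), reason = character(0))
  res[order(res$chrom, res$del_start, res$del_len), , drop = FALSE]
}

#' Enumerate all possible deletions in a hotspot region
#'
#' Builds the junction search sequence of every deletion with start
#' inside the region and length in \code{[dMin, dMax]}:
#' \code{ref[start-flank, start) + ref[start+len, start+len+flank)}.
#' Distinct (start, length) pairs that yield the same search sequence
#' (deletions shifted within a repeat) are collapsed to the leftmost
#' representative with a \code{multiplicity} count.
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param chrom contig name.
#' @param regionStart,regionEnd 0-based half-open region of deletion
#'   start positions. Region plus flanks must lie inside the contig.
#' @param dMin,dMax deletion-length range (defaults 6, 100).
#' @param flank flank size (default 15).
#' @param cap maximum region width (default 10000); larger regions
#'   should use the homolog-index workflow instead.
#' @return data.frame with \code{chrom}, \code{del_start},
#'   \code{del_len}, \code{search_seq}, \code{multiplicity}.
#' @export
enumerateRegionDeletions <- function(reference, chrom, regionStart,
                                     regionEnd, dMin = 6L, dMax = 100L,
                                     flank = 15L, cap = 10000L) {
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  n <- nchar(s)
  w <- regionEnd - regionStart
  if (w <= 0L) stop("empty region")
  if (w > cap)
    stop("region width ", w, " exceeds cap ", cap,
         "; use buildHomologIndex() for large targets")
  if (regionStart - flank < 0L || regionEnd - 1L + dMax + flank > n)
    stop("region plus flanks extends outside contig ", chrom,
         " (length ", n, ")")
  grid <- expand.grid(del_start = seq.int(regionStart, regionEnd - 1L),
                      del_len = seq.int(dMin, dMax))
  left <- .sub0(s, grid$del_start - flank, grid$del_start)
  right <- .sub0(s, grid$del_start + grid$del_len,
                 grid$del_start + grid$del_len + flank)
  grid$search_seq <- paste0(left, right)
  grid <- grid[order(grid$del_start, grid$del_len), , drop = FALSE]
  mult <- table(grid$search_seq)
  first <- !duplicated(grid$search_seq)
  out <- grid[first, , drop = FALSE]
  out$multiplicity <- as.integer(mult[out$search_seq])
  out <- data.frame(chrom = chrom, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify the repair mechanism of a deletion from junction homology
#'
#' Junction homology is the longest exact match between the sequence
#' entering the junction and the sequence leaving it, measured in both
#' directions: the right-slide compares \code{ref[del_start + i]} with
#' \code{ref[del_start + del_len + i]} and the left-slide mirrors it on
#' the other side. Categories: homology >= \code{thresholds[2]} is MMEJ;
#' homology < \code{thresholds[1]} is SHORT_HOMOLOGY (NHEJ/POLQ
#' plausible); in between is INTERMEDIATE. The flank signature is the two
#' bases on each side of the junction in the post-deletion sequence,
#' e.g. \code{"GT_CG"}.
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param chrom contig name.
#' @param delStart 0-based deletion start.
#' @param delLen deletion length.
#' @param thresholds length-2 vector: (short-homology bound, MMEJ bound);
#'   default \code{c(3, 5)}.
#' @return list with \code{junction_homology}, \code{category},
#'   \code{flank_signature}.
#' @export
classifyDeletionMechanism <- function(reference, chrom, delStart, delLen,
                                      thresholds = c(3L, 5L)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  n <- nchar(s)
  ch <- function(p) substring(s, p + 1L, p + 1L)
  delEnd <- delStart + delLen
  ## right-slide: deleted prefix vs retained suffix
  mR <- 0L
  while (delStart + mR < n && delEnd + mR < n) {
    a <- ch(delStart + mR); b <- ch(delEnd + mR)
    if (a != b || a == "N") break
    mR <- mR + 1L
  }
  ## left-slide: retained prefix vs deleted suffix
  mL <- 0L
  while (delStart - 1L - mL >= 0L && delEnd - 1L - mL >= 0L) {
    a <- ch(delStart - 1L - mL); b <- ch(delEnd - 1L - mL)
    if (a != b || a == "N") break
    mL <- mL + 1L
  }
  h <- max(mR, mL)
  category <- if (h >= thresholds[2]) "MMEJ"
              else if (h < thresholds[1]) "SHORT_HOMOLOGY"
              else "INTERMEDIATE"
  sig <- if (delStart >= 2L && delEnd + 2L <= n)
    paste0(.sub0(s, delStart - 2L, delStart), "_",
           .sub0(s, delEnd, delEnd + 2L))
  else NA_character_
  list(junction_homology = h, category = category, flank_signature = sig)
}

#' Match an observed deletion to the homolog index
#'
#' Finds the homolog pair and match type whose candidate deletion yields
#' the identical post-deletion sequence as the observed deletion (two
#' deletions of equal length are product-identical when the reference
#' between their start points repeats with the deletion length as
#' period). Returns \code{NULL} when no MMEJ interpretation exists.
#'
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param chrom contig name.
#' @param delStart 0-based deletion start.
#' @param delLen deletion length.
#' @param index a \linkS4class{HomologIndex} built over the same
#'   reference.
#' @return list with \code{pair} (one-row data.frame) and
#'   \code{match_type}, or \code{NULL}.
#' @export
matchToIndex <- function(reference, chrom, delStart, delLen, index) {
  pairs <- if (methods::is(index, "HomologIndex")) index@pairs else index
  refstr <- .refStrings(reference)
  s <- .getContig(refstr, chrom)
  near <- pairs[pairs$chrom == chrom &
                abs(pairs$start1 - delStart) <= delLen + pairs$length + 2L, ,
                drop = FALSE]
  for (i in seq_len(nrow(near))) {
    p <- near[i, ]
    D <- p$start2 - p$start1
    variants <- list(perfect = c(p$start1, D),
                     imperfect_A = c(p$start1 - 1L, D + 1L),
                     imperfect_B = c(p$start1 + p$length, D + 1L))
    for (tt in names(variants)) {
      v <- variants[[tt]]
      if (.sameDeletionProduct(s, delStart, delLen, v[1L], v[2L]))
        return(list(pair = p, match_type = tt))
    }
  }
  NULL
}

## two same-length deletions give an identical edited sequence iff the
## reference between their start points is periodic with period = length
.sameDeletionProduct <- function(s, s1, l1, s2, l2) {
  if (l1 != l2) return(FALSE)
  if (s1 == s2) return(TRUE)
  lo <- min(s1, s2); hi <- max(s1, s2)
  n <- nchar(s)
  if (hi + l1 > n) return(FALSE)
  a <- .sub0(s, lo, hi)
  b <- .sub0(s, lo + l1, hi + l1)
  identical(a, b) && !grepl("N", a, fixed = TRUE)
}
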