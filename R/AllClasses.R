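#' @import methods
NULL

#' HomologIndex: homolog pairs discovered in a reference
#'
#' Container for the homolog-pair index: every maximal exact repeat pair
#' (two identical sequences of length \code{length} starting at 0-based
#' positions \code{start1} and \code{start2} on the same contig) whose
#' spacing \code{start2 - start1} lies inside the configured deletion-size
#' range. Each pair defines one candidate MMEJ deletion.
#'
#' @slot pairs data.frame with columns \code{chrom}, \code{start1},
#'   \code{start2}, \code{length}, \code{seq}, \code{overlapping}.
#'   Coordinates are 0-based; \code{seq} is the homolog sequence;
#'   \code{overlapping} flags tandem-periodic pairs whose two copies
#'   overlap (\code{start2 < start1 + length}).
#' @slot config list of the discovery parameters (window, step, kMin,
#'   dMin, dMax, allowOverlap).
#' @slot reference character description of the reference scanned.
#'
#' @seealso [buildHomologIndex()], [homologPairs()]
#' @export
setClass("HomologIndex",
  representation(pairs = "data.frame", config = "list",
                 reference = "character"))

setValidity("HomologIndex", function(object) {
  p <- object@pairs
  need <- c("chrom", "start1", "start2", "length", "seq", "overlapping")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  if (any(p$start2 <= p$start1)) return("start2 must exceed start1")
  if (any(p$length < 1L)) return("homolog length must be >= 1")
  if (any(nchar(p$seq) != p$length)) return("seq length must equal 'length'")
  TRUE
})

#' CandidateSet: junction search sequences for candidate deletions
#'
#' One row per candidate deletion variant derived from a homolog pair:
#' the perfect-match deletion and, optionally, the two one-base imperfect
#' variants (type A: one extra base removed left of the junction; type B:
#' one extra base removed right). \code{search_seq} is the predicted
#' post-deletion junction sequence (flank + retained homolog + flank)
#' whose exact occurrence in a read evidences the deletion.
#'
#' @slot candidates data.frame with columns \code{chrom}, \code{del_start},
#'   \code{del_len}, \code{match_type} (\code{"perfect"},
#'   \code{"imperfect_A"}, \code{"imperfect_B"}), \code{start1},
#'   \code{start2}, \code{length}, \code{search_seq},
#'   \code{ref_self_match}, \code{microsat_frac}.
#' @slot flank integer flank size used on each side of the retained
#'   homolog (bases).
#' @slot skipped named integer vector of skip-with-warning counts
#'   (contig-edge or N-containing windows).
#' @slot config list of generation parameters.
#'
#' @seealso [generateCandidates()], [candidateTable()]
#' @export
setClass("CandidateSet",
  representation(candidates = "data.frame", flank = "integer",
                 skipped = "integer", config = "list"))

setValidity("CandidateSet", function(object) {
  p <- object@candidates
  need <- c("chrom", "del_start", "del_len", "match_type", "start1",
            "start2", "length", "search_seq", "ref_self_match",
            "microsat_frac")
  if (!all(need %in% names(p)))
    return(paste("candidates must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) > 0L &&
      !all(p$match_type %in% c("perfect", "imperfect_A", "imperfect_B")))
    return("invalid match_type value")
  if (length(object@flank) != 1L || object@flank < 1L)
    return("flank must be a single positive integer")
  TRUE
})

#' DeletionCallSet: per-sample supporting-read evidence
#'
#' Scan results for one sample: per candidate, the number of reads whose
#' sequence contains the junction search sequence (\code{support}), the
#' mean read coverage in small windows flanking the homolog pair
#' (\code{depth}), the junction-spanning effective depth
#' (\code{eff_depth}) and the variant allele frequency (\code{vaf}).
#'
#' @slot calls data.frame: candidate columns plus \code{support},
#'   \code{depth}, \code{eff_depth}, \code{vaf}.
#' @slot sample character sample label.
#' @slot config list: the scan configuration used.
#' @seealso [callCandidates()], [deletionCalls()]
#' @export
setClass("DeletionCallSet",
  representation(calls = "data.frame", sample = "character",
                 config = "list"))

setValidity("DeletionCallSet", function(object) {
  p <- object@calls
  need <- c("chrom", "del_start", "del_len", "match_type", "search_seq",
            "support", "depth", "vaf")
  if (!all(need %in% names(p)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) > 0L) {
    if (any(p$support < 0)) return("support must be >= 0")
    if (any(p$vaf < 0 | p$vaf > 1)) return("vaf must lie in [0, 1]")
  }
  TRUE
})

#' SimTruth: ground truth for a spike-in simulation
#'
#' @slot deletions data.frame of spiked deletions: homolog-pair columns,
#'   the perfect-match deletion interval (\code{del_start},
#'   \code{del_len}) and \code{target_vaf}.
#' @slot params list of simulation parameters (coverage, read length,
#'   fragment size model, error rate, ...).
#' @slot seed integer seed the truth set was drawn with.
#' @seealso [chooseTruth()], [simulateReads()], [benchmarkCalls()]
#' @export
setClass("SimTruth",
  representation(deletions = "data.frame", params = "list",
                 seed = "integer"))

setValidity("SimTruth", function(object) {
  d <- object@deletions
  need <- c("chrom", "start1", "start2", "length", "del_start", "del_len",
            "target_vaf")
  if (!all(need %in% names(d)))
    return(paste("deletions must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) > 1L) {
    # spiked deletions must not overlap each other
    bychrom <- split(d, d$chrom)
    for (dd in bychrom) {
      o <- order(dd$del_start)
      s <- dd$del_start[o]; e <- dd$del_start[o] + dd$del_len[o]
      if (any(s[-1L] < e[-length(e)]))
        return("spiked deletions overlap in reference coordinates")
    }
  }
  if (nrow(d) > 0L && any(d$target_vaf < 0 | d$target_vaf > 1))
    return("target_vaf must lie in [0, 1]")
  TRUE
})

#' BenchmarkResult: sensitivity/specificity of a callset against truth
#'
#' @slot tp,fn,fp,tn integer confusion-matrix counts over candidate loci.
#' @slot sensitivity,specificity numeric fractions: tp/(tp+fn) and
#'   tn/(tn+fp).
#' @seealso [benchmarkCalls()]
#' @export
setClass("BenchmarkResult",
  representation(tp = "integer", fn = "integer", fp = "integer",
                 tn = "integer", sensitivity = "numeric",
                 specificity = "numeric"))

## ---- generics ----------------------------------------------------------

#' Extract the homolog-pair table from a HomologIndex
#' @param x a \linkS4class{HomologIndex}
#' @return data.frame of homolog pairs (0-based coordinates)
#' @export
setGeneric("homologPairs", function(x) standardGeneric("homologPairs"))

#' @rdname homologPairs
#' @export
setMethod("homologPairs", "HomologIndex", function(x) x@pairs)

#' Extract the candidate table from a CandidateSet
#' @param x a \linkS4class{CandidateSet}
#' @return data.frame of candidate deletion variants
#' @export
setGeneric("candidateTable", function(x) standardGeneric("candidateTable"))

#' @rdname candidateTable
#' @export
setMethod("candidateTable", "CandidateSet", function(x) x@candidates)

#' Extract the call table from a DeletionCallSet
#' @param x a \linkS4class{DeletionCallSet}
#' @return data.frame of per-candidate calls
#' @export
setGeneric("deletionCalls", function(x) standardGeneric("deletionCalls"))

#' @rdname deletionCalls
#' @export
setMethod("deletionCalls", "DeletionCallSet", function(x) x@calls)

#' Extract the truth table from a SimTruth
#' @param x a \linkS4class{SimTruth}
#' @return data.frame of spiked deletions with target VAFs
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname truthTable
#' @export
setMethod("truthTable", "SimTruth", function(x) x@deletions)

#' @describeIn HomologIndex number of homolog pairs
#' @param x a HomologIndex
#' @export
setMethod("length", "HomologIndex", function(x) nrow(x@pairs))

#' @describeIn CandidateSet number of candidate records
#' @param x a CandidateSet
#' @export
setMethod("length", "CandidateSet", function(x) nrow(x@candidates))

#' @describeIn DeletionCallSet number of calls
#' @param x a DeletionCallSet
#' @export
setMethod("length", "DeletionCallSet", function(x) nrow(x@calls))

#' @export
setMethod("show", "HomologIndex", function(object) {
  p <- object@pairs
  cat("HomologIndex with", nrow(p), "homolog pairs\n")
  if (nrow(p) > 0L) {
    cat("  contigs:", paste(unique(p$chrom), collapse = ", "), "\n")
    cat("  homolog length:", min(p$length), "-", max(p$length), "bp;",
        "deletion span:", min(p$start2 - p$start1), "-",
        max(p$start2 - p$start1), "bp\n")
    cat("  overlapping (tandem-periodic) pairs:", sum(p$overlapping), "\n")
  }
  cfg <- object@config
  if (length(cfg))
    cat("  config: ", paste(names(cfg), unlist(cfg), sep = "=",
                            collapse = ", "), "\n", sep = "")
})

#' @export
setMethod("show", "CandidateSet", function(object) {
  p <- object@candidates
  cat("CandidateSet with", nrow(p), "candidate deletion variants",
      sprintf("(flank %d bp)\n", object@flank))
  if (nrow(p) > 0L)
    print(table(match_type = p$match_type))
  if (length(object@skipped) && sum(object@skipped) > 0L)
    cat("  skipped: ", paste(names(object@skipped), object@skipped,
                             sep = "=", collapse = ", "), "\n", sep = "")
})

#' @export
setMethod("show", "DeletionCallSet", function(object) {
  p <- object@calls
  cat("DeletionCallSet for sample", sQuote(object@sample), "with",
      nrow(p), "candidates\n")
  if (nrow(p) > 0L) {
    pos <- sum(p$support > 0)
    cat("  candidates with >= 1 supporting read:", pos, "\n")
    cat("  mean depth:", round(mean(p$depth), 1), "\n")
  }
})

#' @export
setMethod("show", "SimTruth", function(object) {
  d <- object@deletions
  cat("SimTruth with", nrow(d), "spiked deletions (seed", object@seed, ")\n")
  if (nrow(d) > 0L)
    cat("  target VAFs:", paste(sort(unique(d$target_vaf)), collapse = ", "),
        "\n")
})

#' @export
setMethod("show", "BenchmarkResult", function(object) {
  cat("BenchmarkResult\n")
  cat(sprintf("  TP=%d FN=%d FP=%d TN=%d\n", object@tp, object@fn,
              object@fp, object@tn))
  cat(sprintf("  sensitivity = %.4f, specificity = %.4f\n",
              object@sensitivity, object@specificity))
})
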