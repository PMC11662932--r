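## VCF 4.2 export of deletion calls. Internal coordinates are 0-based
## half-open; VCF wants the 1-based anchor base before the deleted run,
## so POS equals the internal del_start, REF is anchor + deleted bases
## and ALT is the anchor alone.

#' Export deletion calls to VCF 4.2
#'
#' Writes one record per call (optionally only those with supporting
#' reads): \code{POS} is the base before the deletion, \code{REF} the
#' anchor plus deleted bases, \code{ALT} the anchor. INFO carries the
#' homolog length (\code{HOMLEN}), homolog sequence (\code{HOMSEQ}),
#' match type (\code{MATCHTYPE}), deletion length (\code{SVLEN},
#' negative), supporting reads (\code{SUPPORT}), local depth (\code{DP})
#' and VAF (\code{VAF}).
#'
#' @param calls a \linkS4class{DeletionCallSet}.
#' @param reference FASTA path or \code{DNAStringSet} (for the anchor
#'   base and contig lengths).
#' @param path output VCF path.
#' @param onlySupported drop calls without supporting reads (default
#'   TRUE).
#' @return the path, invisibly.
#' @export
exportVCF <- function(calls, reference, path, onlySupported = TRUE) {
  stopifnot(methods::is(calls, "DeletionCallSet"))
  df <- calls@calls
  if (onlySupported) df <- df[df$support > 0L, , drop = FALSE]
  refstr <- .refStrings(reference)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=mmejscan-",
           tryCatch(as.character(utils::packageVersion("mmejscan")),
                    error = function(e) "dev")),
    paste0("##contig=<ID=", names(refstr), ",length=", nchar(refstr), ">"),
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Homolog length\">",
    "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Homolog sequence\">",
    paste0("##INFO=<ID=MATCHTYPE,Number=1,Type=String,",
           "Description=\"perfect, imperfect_A or imperfect_B\">"),
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Local mean depth\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  rows <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    s <- .getContig(refstr, df$chrom[i])
    ds <- df$del_start[i]; dl <- df$del_len[i]
    if (ds < 1L) stop("deletion at contig start cannot be anchored: ",
                      df$chrom[i], ":", ds)
    anchor <- .sub0(s, ds - 1L, ds)
    refAllele <- .sub0(s, ds - 1L, ds + dl)
    info <- paste0("HOMLEN=", df$length[i], ";HOMSEQ=",
                   .sub0(s, df$start2[i], df$start2[i] + df$length[i]),
                   ";MATCHTYPE=", df$match_type[i], ";SVLEN=", -dl,
                   ";SUPPORT=", df$support[i],
                   ";DP=", sprintf("%.2f", df$depth[i]),
                   ";VAF=", sprintf("%.4f", df$vaf[i]))
    rows[i] <- paste(df$chrom[i], ds, ".", refAllele, anchor, ".", "PASS",
                     info, sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
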