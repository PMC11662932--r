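## Internal helpers shared across modules. Coordinates are 0-based
## half-open everywhere inside the package; conversion to 1-based happens
## only at VCF/BAM boundaries.

#' Load a reference genome
#'
#' Accepts a FASTA path or an existing \code{DNAStringSet} and returns a
#' \code{DNAStringSet} whose names are the first whitespace-delimited
#' token of each FASTA header.
#'
#' @param reference FASTA file path or \code{Biostrings::DNAStringSet}.
#' @return named \code{DNAStringSet}
#' @export
loadReference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    ref <- reference
  } else if (is.character(reference) && !is.null(names(reference))) {
    ## already-prepared named contig strings
    ref <- Biostrings::DNAStringSet(reference)
  } else if (is.character(reference) && length(reference) == 1L) {
    if (!file.exists(reference))
      stop("reference FASTA not found: ", reference,
           " (create it, e.g. with makeReference(), before indexing)")
    ref <- Biostrings::readDNAStringSet(reference)
  } else {
    stop("reference must be a FASTA path or a DNAStringSet")
  }
  if (is.null(names(ref)) || anyNA(names(ref)))
    stop("reference contigs must be named")
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

## reference as named character vector of uppercase contig strings; a
## named character vector passes through unchanged (already prepared)
.refStrings <- function(reference) {
  if (is.character(reference) && !is.null(names(reference)))
    return(reference)
  ref <- loadReference(reference)
  out <- toupper(as.character(ref))
  names(out) <- names(ref)
  out
}

## 0-based half-open substring
.sub0 <- function(s, start, end) substring(s, start + 1L, end)

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

## validate a nucleotide string (A/C/G/T/N, case-insensitive)
.checkNucleotides <- function(seq, what = "sequence") {
  bad <- gsub("[ACGTNacgtn]", "", seq)
  if (any(nzchar(bad)))
    stop(what, " contains non-nucleotide characters: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ""))
  invisible(TRUE)
}

## skip-with-warning signal: recoverable per-record conditions (contig
## edge, N in window), distinct from hard errors
.skip <- function(msg, reason = "skip") {
  warning(warningCondition(msg, class = c("mmejSkip", reason)))
  invisible(NULL)
}

## run fn, counting mmejSkip warnings by their reason class
.collectSkips <- function(expr) {
  counts <- integer(0)
  val <- withCallingHandlers(expr, mmejSkip = function(w) {
    reason <- setdiff(class(w), c("mmejSkip", "warning", "condition",
                                  "simpleWarning"))
    reason <- if (length(reason)) reason[1L] else "skip"
    counts[reason] <<- (if (reason %in% names(counts))
      counts[[reason]] else 0L) + 1L
    invokeRestart("muffleWarning")
  })
  list(value = val, skipped = counts)
}

## resolve chrom -> contig string, with a helpful error
.getContig <- function(refstr, chrom) {
  if (!chrom %in% names(refstr))
    stop("contig ", sQuote(chrom), " not found in reference (contigs: ",
         paste(names(refstr), collapse = ", "), ")")
  refstr[[chrom]]
}

## evaluate expr with a locally-seeded RNG, restoring global state after
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## provenance header written at the top of every output file
.fileHeader <- function(command = "", config = list()) {
  cfgtxt <- paste(names(config), unlist(lapply(config, paste, collapse = ",")),
                  sep = "=", collapse = ";")
  tf <- tempfile(); writeLines(cfgtxt, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  ver <- tryCatch(as.character(utils::packageVersion("mmejscan")),
                  error = function(e) "dev")
  c(paste0("## mmejscan v", ver),
    paste0("## command: ", command),
    paste0("## config: ", cfgtxt),
    paste0("## config_md5: ", hash))
}

## write a data.frame as TSV with provenance header
.writeTSV <- function(df, path, command = "", config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.fileHeader(command, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## read a TSV written by .writeTSV (comment lines stripped)
.readTSV <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("malformed table ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  df
}
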