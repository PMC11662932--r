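## Independent oracles: deliberately naive re-derivations of the
## contracts, sharing no code with the implementation.

randomDNA <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## brute-force enumeration of maximal exact repeat pairs: every (i, j)
## start pair is extended greedily and kept when long enough, in range,
## and not left-extendable
bruteMaximalRepeats <- function(seq, kMin = 5L, dMin = 6L, dMax = 100L) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  out <- list()
  for (i in 0:(n - 2L)) {
    jmax <- min(i + dMax, n - 1L)
    j <- i + dMin
    while (j <= jmax) {
      ## left-maximality
      if (!(i > 0L && s[i] == s[j] && s[i] != "N")) {
        L <- 0L
        while (i + L < n && j + L < n && s[i + L + 1L] == s[j + L + 1L] &&
               s[i + L + 1L] != "N")
          L <- L + 1L
        if (L >= kMin)
          out[[length(out) + 1L]] <- c(i, j, L)
      }
      j <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(offset1 = integer(0), offset2 = integer(0),
                      length = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(offset1 = m[, 1L], offset2 = m[, 2L], length = m[, 3L])
  df[order(df$offset1, df$offset2), , drop = FALSE]
}

## brute-force maximal perfect tandem arrays, smallest-unit suppression
bruteTandemRepeats <- function(seq, unitMin = 1L, unitMax = 30L) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  rows <- list()
  for (u in unitMin:min(unitMax, n %/% 2L)) {
    a <- 0L
    while (a + 2L * u <= n) {
      ## left-maximal array start?
      if (a > 0L && s[a] == s[a + u] && s[a] != "N") { a <- a + 1L; next }
      b <- a + u
      while (b < n && s[b + 1L] == s[b + 1L - u] && s[b + 1L] != "N")
        b <- b + 1L
      if (b - a >= 2L * u)
        rows[[length(rows) + 1L]] <- c(a, b, u)
      a <- a + 1L
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      unit_len = integer(0), copies = numeric(0)))
  m <- do.call(rbind, rows)
  df <- data.frame(start = m[, 1L], end = m[, 2L], unit_len = m[, 3L])
  df <- df[!duplicated(df), , drop = FALSE]
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(df$unit_len < df$unit_len[i] & df$start <= df$start[i] &
         df$end >= df$end[i])
  }, logical(1))
  df <- df[keep, , drop = FALSE]
  df$copies <- (df$end - df$start) / df$unit_len
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## string-edit oracle: apply a deletion and return the edited genome
applyDeletion <- function(refSeq, delStart, delLen) {
  paste0(substring(refSeq, 1L, delStart),
         substring(refSeq, delStart + delLen + 1L, nchar(refSeq)))
}

## plant an exact repeat pair into a random background string
plantPair <- function(n, start1, D, L) {
  s <- strsplit(randomDNA(n), "")[[1]]
  s[(start1 + D + 1L):(start1 + D + L)] <- s[(start1 + 1L):(start1 + L)]
  paste(s, collapse = "")
}

## hand-built BAM with perfectly tiled error-free reads: read length rl,
## one read starting at every `step` positions on each strand-free tile;
## gives exactly rl/step coverage everywhere in the interior
tiledBam <- function(refSeq, chrom = "chr", rl = 50L, step = 5L,
                     prefix = tempfile("tiled")) {
  n <- nchar(refSeq)
  starts <- seq.int(1L, n - rl + 1L, by = step)
  sam <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", chrom, "\tLN:", n),
           paste(sprintf("r%05d", seq_along(starts)), 0L, chrom, starts,
                 60L, paste0(rl, "M"), "*", 0L, 0L,
                 substring(refSeq, starts, starts + rl - 1L),
                 strrep("I", rl), sep = "\t"))
  samPath <- paste0(prefix, ".sam")
  writeLines(sam, samPath)
  bam0 <- Rsamtools::asBam(samPath, paste0(prefix, "_u"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, prefix)
  Rsamtools::indexBam(bam)
  unlink(c(samPath, bam0))
  bam
}
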