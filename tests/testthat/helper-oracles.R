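# Independent brute-force oracles used to validate the package's scanners and
# tests. These deliberately share no code with the implementation: plain
# character walks and exhaustive enumeration.

# Enumerate every ATG-initiated ORF with its first in-frame terminator by
# walking codons one at a time. Codons containing N terminate extension
# without yielding an ORF. Returns 0-based half-open coordinates.
bruteForceOrfs <- function(seq, minLenAa, requireStop = TRUE,
                           nestedStarts = FALSE) {
  n <- nchar(seq)
  rows <- list()
  for (p0 in 0:(max(n - 3L, 0L))) {
    if (substr(seq, p0 + 1L, p0 + 3L) != "ATG") next
    q <- p0 + 3L
    hit <- NULL
    while (q + 3L <= n) {
      cod <- substr(seq, q + 1L, q + 3L)
      if (grepl("N", cod, fixed = TRUE)) { hit <- "N"; break }
      if (cod %in% c("TAA", "TAG", "TGA")) { hit <- "stop"; break }
      q <- q + 3L
    }
    if (identical(hit, "N")) next
    if (identical(hit, "stop")) {
      len_aa <- (q - p0) %/% 3L
      if (len_aa >= minLenAa)
        rows[[length(rows) + 1L]] <-
          data.frame(start = p0, end = q + 3L, frame = p0 %% 3L,
                     length_aa = len_aa)
    } else if (!requireStop) {
      q <- p0 + 3L * ((n - p0) %/% 3L)   # last complete codon boundary
      len_aa <- (q - p0) %/% 3L
      if (len_aa >= minLenAa)
        rows[[length(rows) + 1L]] <-
          data.frame(start = p0, end = q, frame = p0 %% 3L,
                     length_aa = len_aa)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      frame = integer(), length_aa = integer()))
  df <- do.call(rbind, rows)
  if (!nestedStarts) {
    # keep the 5'-most start per (frame, end)
    df <- df[order(df$start, df$end), , drop = FALSE]
    df <- df[!duplicated(paste(df$frame, df$end)), , drop = FALSE]
  }
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exhaustive tryptic peptide enumeration: find cleavage sites by direct
# character inspection, then take all runs of <= maxMissed + 1 consecutive
# fragments and length-filter.
bruteForceDigest <- function(seq, maxMissed = 2, minLen = 7, maxLen = 50) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  cuts <- integer()
  for (i in seq_len(n - 1L))
    if (aa[i] %in% c("K", "R") && aa[i + 1L] != "P") cuts <- c(cuts, i)
  bounds <- c(0L, cuts, n)
  frag <- mapply(function(a, b) substr(seq, a + 1L, b),
                 bounds[-length(bounds)], bounds[-1])
  peps <- character()
  for (i in seq_along(frag))
    for (m in 0:maxMissed) {
      if (i + m > length(frag)) break
      p <- paste(frag[i:(i + m)], collapse = "")
      if (nchar(p) >= minLen && nchar(p) <= maxLen) peps <- c(peps, p)
    }
  peps
}

# Two-sided Fisher p for a 2x2 table by direct hypergeometric summation over
# all tables with the observed margins (minimum-likelihood convention).
bruteForceFisher2x2 <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row 1 total
  n2 <- sum(tab[2, ])         # row 2 total
  k <- sum(tab[, 1])          # column 1 total
  support <- max(0, k - n2):min(k, m)
  d <- stats::dhyper(support, m, n2, k)
  sum(d[d <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

randProtein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
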