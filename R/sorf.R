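## Small-ORF discovery on lncRNA transcripts.
## Coordinates are 0-based half-open internally; 1-based closed in written
## reports. All scanning is transcript-strand only.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Normalize a nucleotide sequence
#'
#' Uppercases and converts U to T. Any residual character outside ACGTN is an
#' input error reported with its (1-based) position.
#'
#' @param seq Character scalar nucleotide sequence.
#' @param id Identifier used in error messages.
#' @return Normalized sequence string.
#' @export
normalizeTranscript <- function(seq, id = "transcript") {
  seq <- chartr("u", "t", toupper(as.character(seq)))
  seq <- chartr("U", "T", seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L)
    stop(sprintf("%s: non-nucleotide character '%s' at position %d",
                 id, substr(seq, bad, bad), bad))
  if (!nzchar(seq)) stop(sprintf("%s: empty sequence", id))
  seq
}

#' Read transcripts from FASTA
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA of transcript sequences
#' and normalizes them (U to T, uppercase). Record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file path.
#' @return A named character vector of normalized sequences.
#' @export
readTranscripts <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(x)
  names(seqs) <- ids
  mapply(normalizeTranscript, seqs, ids, USE.NAMES = TRUE)
}

## Scan one normalized sequence. Returns the ORF table for one transcript.
.findOrfsOne <- function(seq, id, params) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L)          # 0-based codon starts
    codons <- substring(seq, starts + 1L, starts + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% .STOP_CODONS
    # codons containing N are untranslatable and terminate ORF extension
    has_n <- grepl("N", codons, fixed = TRUE)
    if (!any(is_atg)) next
    term <- which(is_stop | has_n)
    atg_idx <- which(is_atg)
    # first terminator strictly after each ATG codon
    nxt <- findInterval(atg_idx, term) + 1L
    term_idx <- ifelse(nxt <= length(term), term[nxt], NA_integer_)
    for (k in seq_along(atg_idx)) {
      i <- atg_idx[k]; j <- term_idx[k]
      if (!is.na(j) && has_n[j]) next           # runs into an N codon: no ORF
      if (is.na(j)) {
        if (params@requireStop) next
        len_aa <- ncod - i + 1L
        end <- starts[i] + 3L * len_aa
        stopped <- FALSE
      } else {
        len_aa <- j - i
        end <- starts[j] + 3L
        stopped <- TRUE
      }
      if (len_aa < params@minLenAa) next
      out[[length(out) + 1L]] <- list(start = starts[i], end = end,
                                      frame = frame, length_aa = len_aa,
                                      stop_idx = if (stopped) j else NA_integer_)
    }
  }
  if (!length(out))
    return(.emptyOrfTable())
  df <- do.call(rbind, lapply(out, as.data.frame))
  if (!params@reportNestedStarts) {
    # one ORF per (frame, stop codon): keep the 5'-most ATG
    key <- paste(df$frame, ifelse(is.na(df$stop_idx), "open", df$stop_idx))
    ord <- order(df$start, df$end)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
  }
  df <- df[order(df$start, df$end), , drop = FALSE]
  cod_end <- ifelse(is.na(df$stop_idx), df$end, df$end - 3L)
  prot <- vapply(seq_len(nrow(df)), function(r) {
    cds <- substr(seq, df$start[r] + 1L, cod_end[r])
    as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  }, character(1))
  data.frame(transcript_id = id, start = df$start, end = df$end,
             frame = df$frame, length_aa = df$length_aa,
             protein_seq = prot, stringsAsFactors = FALSE)
}

.emptyOrfTable <- function() {
  data.frame(transcript_id = character(), start = integer(), end = integer(),
             frame = integer(), length_aa = integer(),
             protein_seq = character(), stringsAsFactors = FALSE)
}

#' Scan transcripts for ATG-initiated small ORFs
#'
#' Enumerates open reading frames starting at ATG in all three frames of the
#' given strand, requiring (by default) an in-frame stop codon within the
#' transcript. With \code{reportNestedStarts = FALSE} (default), each stop
#' codon in each frame yields at most one ORF, anchored at its 5'-most ATG.
#' Codons containing N are untranslatable and terminate ORF extension without
#' providing a stop.
#'
#' @param x A named character vector of normalized transcript sequences (as
#'   from \code{\link{readTranscripts}}), or a single unnamed sequence.
#' @param params An \code{\link{OrfParams}} object.
#' @return A \code{data.frame} with columns \code{transcript_id},
#'   \code{start}, \code{end} (0-based half-open, stop codon included),
#'   \code{frame}, \code{length_aa} (residues, stop excluded),
#'   \code{protein_seq}; sorted by transcript, start, end.
#' @examples
#' findOrfs(c(tx = "ATGAAATAA"), OrfParams(minLenAa = 1))
#' @export
findOrfs <- function(x, params = OrfParams()) {
  stopifnot(is(params, "OrfParams"))
  nm <- names(x)
  x <- as.character(x)
  names(x) <- if (is.null(nm)) sprintf("tx%d", seq_along(x)) else nm
  res <- lapply(names(x), function(id)
    .findOrfsOne(normalizeTranscript(x[[id]], id), id, params))
  do.call(rbind, c(res, list(.emptyOrfTable())))
}

#' Select the canonical ORF per transcript
#'
#' The canonical ORF of a transcript is the longest one; ties are broken by
#' the smallest start coordinate (5'-most). The convention reflects standard
#' longest-ORF selection for candidate microprotein databases.
#'
#' @param orfs ORF table from \code{\link{findOrfs}}.
#' @return One row per transcript, same columns as the input.
#' @export
selectCanonicalOrf <- function(orfs) {
  if (nrow(orfs) == 0L) stop("no ORF")
  orfs <- orfs[order(orfs$transcript_id, -orfs$length_aa, orfs$start), ,
               drop = FALSE]
  out <- orfs[!duplicated(orfs$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the candidate microprotein database
#'
#' Emits one FASTA record per ORF with header
#' \code{LEP|<transcript_id>|<start>-<end>} (1-based closed coordinates).
#'
#' @param orfs ORF table from \code{\link{findOrfs}}.
#' @param path Output FASTA path.
#' @return Invisibly, the number of records written.
#' @export
writeCandidateDb <- function(orfs, path) {
  headers <- sprintf("LEP|%s|%d-%d", orfs$transcript_id,
                     orfs$start + 1L, orfs$end)
  if (anyDuplicated(headers))
    stop("duplicate header(s): ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  aa <- Biostrings::AAStringSet(setNames(as.character(orfs$protein_seq),
                                         headers))
  Biostrings::writeXStringSet(aa, path)
  invisible(nrow(orfs))
}

#' Write a human-readable ORF table
#'
#' TSV report with 1-based closed coordinates.
#'
#' @param orfs ORF table from \code{\link{findOrfs}}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeOrfTable <- function(orfs, path) {
  out <- data.frame(transcript_id = orfs$transcript_id,
                    start_1based = orfs$start + 1L,
                    end_1based = orfs$end,
                    frame = orfs$frame,
                    length_aa = orfs$length_aa,
                    protein_seq = orfs$protein_seq)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
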