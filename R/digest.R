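## In-silico tryptic digestion and peptide-uniqueness classification.
##
## Uniqueness semantics: a peptide is compared against the set of tryptic
## peptides of every database protein ("tryptic" mode, the default, mirroring
## how search engines assign peptides to proteins), or against protein
## sequences as plain substrings ("substring" mode, stricter).

#' Read a protein database from FASTA
#'
#' Accepts UniProt-style headers (\code{>sp|ACC|NAME ...}), in which case the
#' accession is the second pipe-delimited field, or plain headers, in which
#' case the accession is the first whitespace-delimited token.
#'
#' @param path FASTA file path.
#' @param origin Either \code{"reference"} (Swiss-Prot-style reference
#'   proteome) or \code{"lep"} (candidate microprotein database).
#' @return A \code{data.frame} with columns \code{accession},
#'   \code{sequence}, \code{origin}.
#' @export
readProteome <- function(path, origin = c("reference", "lep")) {
  origin <- match.arg(origin)
  x <- Biostrings::readAAStringSet(path)
  headers <- names(x)
  acc <- vapply(headers, function(h) {
    if (grepl("^(sp|tr)\\|", h)) strsplit(h, "|", fixed = TRUE)[[1]][2]
    else sub("\\s.*$", "", h)
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  data.frame(accession = acc, sequence = toupper(as.character(x)),
             origin = origin, stringsAsFactors = FALSE)
}

.checkPeptideChars <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seq)
  if (bad != -1L)
    stop(sprintf("%s: non-amino-acid character '%s' at position %d",
                 what, substr(seq, bad, bad), bad))
  invisible(seq)
}

## 0-based cleavage points of the trypsin rule (after K/R not before P),
## including both sequence ends. Fragment i spans [pts[i], pts[i+1]).
.cleavagePoints <- function(seq) {
  n <- nchar(seq)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  c(0L, cut_after, n)
}

#' Digest a protein with trypsin in silico
#'
#' Cleaves C-terminal to K or R except before proline, then enumerates all
#' peptides carrying at most \code{maxMissedCleavages} internal uncleaved
#' sites, filtered to \code{[minLen, maxLen]} residues.
#'
#' @param sequence Amino-acid sequence (20 standard letters plus X).
#' @param params A \code{\link{DigestParams}} object.
#' @param accession Parent accession recorded in the output.
#' @return A \code{data.frame} with columns \code{sequence},
#'   \code{parent_accession}, \code{start} (1-based within parent),
#'   \code{missed_cleavages}, ordered by start then length.
#' @examples
#' digestProtein("MKRGGK", DigestParams(minLen = 1, maxMissedCleavages = 1))
#' @export
digestProtein <- function(sequence, params = DigestParams(),
                          accession = NA_character_) {
  sequence <- toupper(as.character(sequence))
  .checkPeptideChars(sequence, accession %||% "protein")
  pts <- .cleavagePoints(sequence)
  nfrag <- length(pts) - 1L
  out <- vector("list", nfrag * (params@maxMissedCleavages + 1L))
  k <- 0L
  for (i in seq_len(nfrag)) {
    for (m in 0:params@maxMissedCleavages) {
      j <- i + m
      if (j > nfrag) break
      len <- pts[j + 1L] - pts[i]
      if (len < params@minLen || len > params@maxLen) next
      k <- k + 1L
      out[[k]] <- list(sequence = substr(sequence, pts[i] + 1L, pts[j + 1L]),
                       start = pts[i] + 1L, missed_cleavages = m)
    }
  }
  if (k == 0L)
    return(data.frame(sequence = character(), parent_accession = character(),
                      start = integer(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(out[seq_len(k)], as.data.frame))
  df$parent_accession <- accession
  df <- df[order(df$start, nchar(df$sequence)),
           c("sequence", "parent_accession", "start", "missed_cleavages")]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Digest every protein in a database
#'
#' @param proteins \code{data.frame} with \code{accession} and
#'   \code{sequence} columns (as from \code{\link{readProteome}}).
#' @param params A \code{\link{DigestParams}}.
#' @return Row-bound \code{\link{digestProtein}} results.
#' @export
digestProteins <- function(proteins, params = DigestParams()) {
  do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    digestProtein(proteins$sequence[i], params, proteins$accession[i])))
}

.collapseIL <- function(x) chartr("I", "L", x)

#' Build a tryptic-peptide membership index
#'
#' Digests every protein of the combined reference-plus-candidate database and
#' indexes peptide sequences in a hash environment, so that membership queries
#' run in expected constant time. With \code{ilEquivalent} (default), I and L
#' are collapsed before indexing and lookup.
#'
#' @param proteins \code{data.frame} with columns \code{accession},
#'   \code{sequence}, \code{origin} (\code{"reference"} or \code{"lep"});
#'   typically \code{rbind} of the two databases.
#' @param params A \code{\link{DigestParams}}.
#' @return A \linkS4class{PeptideIndex}.
#' @export
buildPeptideIndex <- function(proteins, params = DigestParams()) {
  if (nrow(proteins) == 0L) stop("empty protein database")
  if (anyDuplicated(proteins$accession))
    stop("duplicate accession(s): ",
         paste(unique(proteins$accession[duplicated(proteins$accession)]),
               collapse = ", "))
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(proteins))) {
    pep <- unique(digestProtein(proteins$sequence[i], params,
                                proteins$accession[i])$sequence)
    if (params@ilEquivalent) pep <- unique(.collapseIL(pep))
    for (p in pep) {
      env[[p]] <- c(env[[p]], proteins$accession[i])
    }
  }
  origins <- setNames(proteins$origin, proteins$accession)
  seqs <- setNames(if (params@ilEquivalent) .collapseIL(proteins$sequence)
                   else proteins$sequence,
                   proteins$accession)
  new("PeptideIndex", env = env, origins = origins, sequences = seqs,
      params = params)
}

#' Query a peptide against the index
#'
#' @param index A \linkS4class{PeptideIndex}.
#' @param peptide Peptide sequence.
#' @param mode \code{"tryptic"} (membership in the indexed tryptic-peptide
#'   sets) or \code{"substring"} (plain substring of any protein sequence).
#' @return Character vector of matching accessions (possibly empty).
#' @export
queryPeptide <- function(index, peptide, mode = c("tryptic", "substring")) {
  mode <- match.arg(mode)
  peptide <- toupper(as.character(peptide))
  .checkPeptideChars(peptide, "peptide")
  if (index@params@ilEquivalent) peptide <- .collapseIL(peptide)
  if (mode == "tryptic") {
    hits <- index@env[[peptide]]
    if (is.null(hits)) character() else hits
  } else {
    names(index@sequences)[grepl(peptide, index@sequences, fixed = TRUE)]
  }
}

#' Classify peptides against reference and candidate databases
#'
#' Each peptide is classified as \code{reference} (matches at least one
#' reference protein), \code{unique_lep} (matches exactly one candidate
#' microprotein and no reference protein), \code{shared_lep} (matches several
#' candidates but no reference protein), or \code{unmatched} (absent from the
#' indexed database). Classification is a pure function of sequence content.
#'
#' @param peptides Character vector of peptide sequences.
#' @param index A \linkS4class{PeptideIndex} built over reference plus
#'   candidate proteins.
#' @param mode See \code{\link{queryPeptide}}.
#' @return \code{data.frame} with columns \code{peptide}, \code{status},
#'   \code{matched_accessions} (semicolon-joined).
#' @export
classifyPeptides <- function(peptides, index,
                             mode = c("tryptic", "substring")) {
  mode <- match.arg(mode)
  rows <- lapply(peptides, function(p) {
    hits <- queryPeptide(index, p, mode)
    orig <- index@origins[hits]
    status <- if (any(orig == "reference")) "reference"
      else if (sum(orig == "lep") == 1L) "unique_lep"
      else if (sum(orig == "lep") > 1L) "shared_lep"
      else "unmatched"
    data.frame(peptide = p, status = status,
               matched_accessions = paste(hits, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(peptide = character(),
                                         status = character(),
                                         matched_accessions = character(),
                                         stringsAsFactors = FALSE))))
}

#' @rdname classifyPeptides
#' @param peptide A single peptide sequence.
#' @export
classifyPeptide <- function(peptide, index, mode = c("tryptic", "substring")) {
  classifyPeptides(peptide, index, mode)
}

#' Count unique peptides per candidate microprotein
#'
#' Digests each candidate, classifies its length-valid tryptic peptides, and
#' counts those unique to it. A candidate is "peptide-supported" when at least
#' one of its peptides is unique: this is the in-silico analogue of detecting
#' a microprotein by a peptide found in no reference protein.
#'
#' @param leps Candidate database \code{data.frame} (\code{accession},
#'   \code{sequence}).
#' @param index A \linkS4class{PeptideIndex} over reference plus candidates.
#' @param mode See \code{\link{queryPeptide}}.
#' @return \code{data.frame} with \code{accession}, \code{n_peptides},
#'   \code{n_unique}, \code{peptide_supported}.
#' @export
lepUniquePeptideCounts <- function(leps, index,
                                   mode = c("tryptic", "substring")) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(nrow(leps)), function(i) {
    pep <- unique(digestProtein(leps$sequence[i], index@params,
                                leps$accession[i])$sequence)
    calls <- classifyPeptides(pep, index, mode)
    uniq <- calls$status == "unique_lep" &
      calls$matched_accessions == leps$accession[i]
    data.frame(accession = leps$accession[i], n_peptides = length(pep),
               n_unique = sum(uniq), peptide_supported = sum(uniq) >= 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write peptide classification results
#'
#' @param calls Output of \code{\link{classifyPeptides}}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeUniquenessCalls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
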