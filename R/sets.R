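## Set algebra over replicate protein-identification lists: the Venn logic of
## probe-vs-control pulldowns, replicate-consistent interactor lists, and
## cross-experiment overlaps.

#' @importFrom BiocGenerics setdiff intersect
NULL

#' Normalize accessions for comparison
#'
#' Optionally strips isoform suffixes (\code{"-2"}) and version numbers
#' (\code{".3"}) and upper-cases, so that supplementary tables mixing
#' notations compare on a common key. All transformations are off by default
#' except case folding.
#'
#' @param x Character vector of accessions.
#' @param stripIsoform Drop a trailing \code{-<digits>} suffix.
#' @param stripVersion Drop a trailing \code{.<digits>} suffix.
#' @param caseFold Upper-case (default \code{TRUE}).
#' @return Normalized character vector.
#' @export
normalizeAccessions <- function(x, stripIsoform = FALSE,
                                stripVersion = FALSE, caseFold = TRUE) {
  x <- as.character(x)
  if (stripVersion) x <- sub("\\.\\d+$", "", x)
  if (stripIsoform) x <- sub("-\\d+$", "", x)
  if (caseFold) x <- toupper(x)
  x
}

#' Proteins consistently identified across replicates
#'
#' Returns the accessions appearing in at least \code{rMin} of the replicate
#' lists. The default \code{rMin} (all replicates) encodes the
#' present-in-every-replicate reading of "identified across N independent
#' biological replicates"; lower values relax it down to the union at
#' \code{rMin = 1}.
#'
#' @param lists A \code{\link{ReplicateLists}}.
#' @param rMin Minimum number of replicates (1..number of replicates).
#' @return A \code{\link{ProteinSet}} named
#'   \code{"<experiment>_r<rMin>of<n>"}.
#' @export
replicateConsistentSet <- function(lists, rMin = length(lists)) {
  n <- length(lists)
  if (rMin < 1L || rMin > n)
    stop(sprintf("rMin must be in 1..%d, got %s", n, rMin))
  tab <- table(unlist(replicates(lists), use.names = FALSE))
  keep <- names(tab)[tab >= rMin]
  ProteinSet(sprintf("%s_r%dof%d", lists@experiment, rMin, n), sort(keep))
}

#' @describeIn setOps members of \code{x} not in \code{y}; the probe-specific
#'   set when \code{x} is a probe pulldown and \code{y} its control. The
#'   result is named \code{"<x>_minus_<y>"}.
#' @export
setMethod("setdiff", signature("ProteinSet", "ProteinSet"), function(x, y) {
  ProteinSet(sprintf("%s_minus_%s", x@name, y@name),
             sort(base::setdiff(x@members, y@members)))
})

#' Set operations on ProteinSet objects
#'
#' \code{setdiff} and \code{intersect} follow the generics from
#' \pkg{BiocGenerics}; \code{intersectSets} intersects any number of sets and
#' is invariant to their order.
#'
#' @param x,y \code{\link{ProteinSet}} objects.
#' @name setOps
NULL

#' @describeIn setOps members common to \code{x} and \code{y}, named
#'   \code{"<x>_and_<y>"}.
#' @export
setMethod("intersect", signature("ProteinSet", "ProteinSet"), function(x, y) {
  ProteinSet(sprintf("%s_and_%s", x@name, y@name),
             sort(base::intersect(x@members, y@members)))
})

#' @describeIn setOps intersection of two or more sets.
#' @param sets A list of at least two \code{\link{ProteinSet}} objects.
#' @param name Optional name for the result.
#' @export
intersectSets <- function(sets, name = NULL) {
  if (length(sets) < 2L) stop("at least two sets are required")
  mem <- Reduce(base::intersect, lapply(sets, members))
  if (is.null(name))
    name <- paste(vapply(sets, setName, character(1)), collapse = "_and_")
  ProteinSet(name, sort(mem))
}

#' Two-set Venn region counts
#'
#' @param a,b \code{\link{ProteinSet}} objects.
#' @return Named list: \code{a_only}, \code{b_only}, \code{both} counts plus
#'   the set names.
#' @export
vennSummary <- function(a, b) {
  both <- base::intersect(a@members, b@members)
  list(a = a@name, b = b@name,
       a_only = length(base::setdiff(a@members, b@members)),
       b_only = length(base::setdiff(b@members, a@members)),
       both = length(both))
}

#' Read replicate identification lists from TSV files
#'
#' Each file holds one replicate: the first column is the accession (a header
#' line named \code{accession} is recognized and skipped); further columns
#' (e.g. abundance) are ignored.
#'
#' @param paths Character vector of per-replicate TSV paths.
#' @param experiment Experiment label.
#' @param ... Passed to \code{\link{normalizeAccessions}}.
#' @return A \code{\link{ReplicateLists}}.
#' @export
readReplicateLists <- function(paths, experiment, ...) {
  reps <- lapply(paths, function(p) {
    tab <- read.delim(p, header = FALSE, stringsAsFactors = FALSE)
    acc <- as.character(tab[[1]])
    if (length(acc) && tolower(acc[1]) == "accession") acc <- acc[-1]
    unique(normalizeAccessions(acc, ...))
  })
  ReplicateLists(experiment, reps)
}

#' Write a ProteinSet membership table
#'
#' @param x A \code{\link{ProteinSet}}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeProteinSet <- function(x, path) {
  write.table(data.frame(accession = members(x)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
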