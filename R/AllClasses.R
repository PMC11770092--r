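#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats p.adjust quantile rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Parameters for small-ORF scanning
#'
#' Controls how ATG-initiated open reading frames are called on a transcript.
#'
#' @slot minLenAa Minimum protein length in residues (stop codon excluded).
#' @slot requireStop If \code{TRUE} (default), an ORF must end at an in-frame
#'   stop codon within the transcript; open-ended runs are discarded.
#' @slot reportNestedStarts If \code{TRUE}, every in-frame ATG sharing a stop
#'   codon yields its own ORF; by default only the 5'-most ATG per stop and
#'   frame is reported.
#'
#' @param minLenAa,requireStop,reportNestedStarts See slot descriptions.
#' @return An \code{OrfParams} object.
#' @examples
#' OrfParams(minLenAa = 50)
#' @export OrfParams
#' @exportClass OrfParams
OrfParams <- setClass("OrfParams",
  representation(minLenAa = "integer", requireStop = "logical",
                 reportNestedStarts = "logical"),
  prototype(minLenAa = 20L, requireStop = TRUE, reportNestedStarts = FALSE),
  validity = function(object) {
    if (length(object@minLenAa) != 1L || is.na(object@minLenAa) ||
        object@minLenAa < 1L)
      return("minLenAa must be a single integer >= 1")
    TRUE
  })

setMethod("initialize", "OrfParams", function(.Object, ...,
    minLenAa = 20L, requireStop = TRUE, reportNestedStarts = FALSE) {
  callNextMethod(.Object, minLenAa = as.integer(minLenAa),
                 requireStop = isTRUE(requireStop),
                 reportNestedStarts = isTRUE(reportNestedStarts), ...)
})

#' Parameters for in-silico tryptic digestion
#'
#' Trypsin cleaves C-terminal to lysine (K) or arginine (R), except when the
#' next residue is proline. Peptides are enumerated up to a maximum number of
#' missed cleavage sites and filtered by length, mirroring common search-engine
#' defaults.
#'
#' @slot maxMissedCleavages Maximum number of internal uncleaved K/R sites
#'   (0--5, default 2).
#' @slot minLen,maxLen Peptide length bounds in residues (defaults 7 and 50).
#' @slot ilEquivalent If \code{TRUE} (default), isoleucine and leucine are
#'   treated as indistinguishable when peptides are compared, as they are
#'   isobaric in mass spectrometry.
#'
#' @param maxMissedCleavages,minLen,maxLen,ilEquivalent See slot descriptions.
#' @return A \code{DigestParams} object.
#' @examples
#' DigestParams(maxMissedCleavages = 1)
#' @export DigestParams
#' @exportClass DigestParams
DigestParams <- setClass("DigestParams",
  representation(maxMissedCleavages = "integer", minLen = "integer",
                 maxLen = "integer", ilEquivalent = "logical"),
  prototype(maxMissedCleavages = 2L, minLen = 7L, maxLen = 50L,
            ilEquivalent = TRUE),
  validity = function(object) {
    if (object@maxMissedCleavages < 0L || object@maxMissedCleavages > 5L)
      return("maxMissedCleavages must be in 0..5")
    if (object@minLen > object@maxLen)
      return("minLen must be <= maxLen")
    if (object@minLen < 1L) return("minLen must be >= 1")
    TRUE
  })

setMethod("initialize", "DigestParams", function(.Object, ...,
    maxMissedCleavages = 2L, minLen = 7L, maxLen = 50L, ilEquivalent = TRUE) {
  callNextMethod(.Object,
                 maxMissedCleavages = as.integer(maxMissedCleavages),
                 minLen = as.integer(minLen), maxLen = as.integer(maxLen),
                 ilEquivalent = isTRUE(ilEquivalent), ...)
})

#' Parameters for cohort presence and differential-expression screening
#'
#' Encodes the screening thresholds: a protein counts as identified in a
#' cohort when it is quantified in strictly more than \code{presenceFrac} of
#' the tumor samples or of the non-tumor samples; differential testing is
#' restricted to proteins quantified in strictly more than
#' \code{dePresenceFrac} of the samples in \emph{both} groups; significance
#' requires \code{p < alpha} and a linear fold change of at least
#' \code{fcCut} in either direction.
#'
#' @slot presenceFrac Presence threshold, strict \code{>} (default 0.30).
#' @slot dePresenceFrac Per-group presence threshold for differential testing,
#'   strict \code{>}, required in both groups (default 0.50).
#' @slot fcCut Linear fold-change cut-off (default 1.5).
#' @slot alpha Significance level for the two-sided test (default 0.05).
#' @slot normalityAlpha Level of the per-group Shapiro-Wilk pre-test that
#'   routes a protein to Student's t (both groups normal) or Mann-Whitney U
#'   (default 0.05).
#' @slot paired If \code{TRUE}, tumor/non-tumor samples are matched by
#'   \code{pair_id} and paired tests are used.
#' @slot pooledVariance If \code{TRUE} (default) the t test uses a pooled
#'   variance estimate; otherwise Welch.
#' @slot pAdjust Multiple-testing adjustment passed to
#'   \code{\link[stats]{p.adjust}}; default \code{"none"} (raw p screening).
#'
#' @param presenceFrac,dePresenceFrac,fcCut,alpha,normalityAlpha,paired,pooledVariance,pAdjust
#'   See slot descriptions.
#' @return A \code{ScreenParams} object.
#' @examples
#' ScreenParams(fcCut = 2)
#' @export ScreenParams
#' @exportClass ScreenParams
ScreenParams <- setClass("ScreenParams",
  representation(presenceFrac = "numeric", dePresenceFrac = "numeric",
                 fcCut = "numeric", alpha = "numeric",
                 normalityAlpha = "numeric", paired = "logical",
                 pooledVariance = "logical", pAdjust = "character"),
  prototype(presenceFrac = 0.30, dePresenceFrac = 0.50, fcCut = 1.5,
            alpha = 0.05, normalityAlpha = 0.05, paired = FALSE,
            pooledVariance = TRUE, pAdjust = "none"),
  validity = function(object) {
    if (object@presenceFrac <= 0 || object@presenceFrac >= 1)
      return("presenceFrac must be in (0, 1)")
    if (object@dePresenceFrac <= 0 || object@dePresenceFrac >= 1)
      return("dePresenceFrac must be in (0, 1)")
    if (object@fcCut <= 1) return("fcCut must be > 1")
    if (object@alpha <= 0 || object@alpha >= 1)
      return("alpha must be in (0, 1)")
    if (!object@pAdjust %in% stats::p.adjust.methods)
      return("pAdjust must be a stats::p.adjust method")
    TRUE
  })

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Protein abundance matrix with cohort/group metadata
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one assay,
#' \code{"intensity"}: linear-scale positive protein intensities
#' (proteins x samples) with \code{NA} for missing quantifications. Column
#' metadata must provide \code{cohort} (cancer-type label), \code{group}
#' (\code{"tumor"} or \code{"nontumor"}), and optionally \code{pair_id} for
#' paired designs.
#'
#' @param values Numeric matrix, proteins x samples; rownames are protein
#'   accessions, colnames sample ids; missing entries \code{NA}.
#' @param sampleInfo \code{data.frame} with one row per sample (matched to
#'   \code{colnames(values)} by its \code{sample_id} column or by rownames),
#'   containing \code{cohort}, \code{group}, optional \code{pair_id}.
#' @return A \code{LEPAbundance} object.
#' @seealso \code{\link{callPresence}}, \code{\link{differentialExpression}}
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' info <- data.frame(sample_id = colnames(m), cohort = "kidney",
#'                    group = rep(c("tumor", "nontumor"), each = 2))
#' LEPAbundance(m, info)
#' @aliases LEPAbundance-class
#' @export LEPAbundance
#' @exportClass LEPAbundance
setClass("LEPAbundance", contains = "SummarizedExperiment")

.validLEPAbundance <- function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(!is.na(a) & a <= 0))
      msg <- c(msg, "all present intensities must be > 0")
  }
  cd <- SummarizedExperiment::colData(object)
  for (col in c("cohort", "group"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", col))
  if ("group" %in% colnames(cd) &&
      !all(cd$group %in% c("tumor", "nontumor")))
    msg <- c(msg, "group must be 'tumor' or 'nontumor'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "protein accessions (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (length(msg)) msg else TRUE
}
setValidity("LEPAbundance", .validLEPAbundance)

LEPAbundance <- function(values, sampleInfo) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have protein rownames and sample colnames")
  sampleInfo <- as.data.frame(sampleInfo)
  if ("sample_id" %in% colnames(sampleInfo))
    rownames(sampleInfo) <- sampleInfo$sample_id
  missing_samples <- setdiff(colnames(values), rownames(sampleInfo))
  if (length(missing_samples))
    stop("no metadata for sample(s): ", paste(missing_samples, collapse = ", "))
  sampleInfo <- sampleInfo[colnames(values), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = values),
    colData = S4Vectors::DataFrame(sampleInfo))
  new("LEPAbundance", se)
}

#' @describeIn LEPAbundance linear-scale intensity matrix (with \code{NA}s).
#' @param x,object A \code{LEPAbundance}.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn LEPAbundance per-sample tumor/non-tumor labels.
#' @export
sampleGroup <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn LEPAbundance per-sample cohort (cancer-type) labels.
#' @export
sampleCohort <- function(x) SummarizedExperiment::colData(x)$cohort

setMethod("show", "LEPAbundance", function(object) {
  a <- intensities(object)
  cat(sprintf("LEPAbundance: %d proteins x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  cohorts: %s\n",
              paste(unique(sampleCohort(object)), collapse = ", ")))
  tab <- table(sampleGroup(object))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(a))))
})

#' Named set of protein accessions
#'
#' A labelled, deduplicated set of protein accessions, the unit of the
#' interactome set algebra (replicate consistency, probe-minus-control
#' differences, cross-experiment intersections).
#'
#' @param name Non-empty label; operations record provenance here
#'   (e.g. \code{"probe_minus_control"}).
#' @param members Character vector of accessions; duplicates are removed.
#' @return A \code{ProteinSet}.
#' @examples
#' ProteinSet("demo", c("P1", "P2", "P2"))
#' @aliases ProteinSet-class
#' @exportClass ProteinSet
#' @export
setClass("ProteinSet",
  representation(name = "character", members = "character"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("name must be a single non-empty string")
    if (anyDuplicated(object@members))
      return("members must be deduplicated")
    TRUE
  })

#' @rdname ProteinSet-class
#' @export
ProteinSet <- function(name, members = character()) {
  new("ProteinSet", name = as.character(name),
      members = unique(as.character(members)))
}

#' @describeIn ProteinSet-class the accessions in the set.
#' @param x,object A \code{ProteinSet}.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname ProteinSet-class
#' @export
setMethod("members", "ProteinSet", function(x) x@members)

#' @describeIn ProteinSet-class the set's label.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname ProteinSet-class
#' @export
setMethod("setName", "ProteinSet", function(x) x@name)

#' @rdname ProteinSet-class
#' @export
setMethod("length", "ProteinSet", function(x) length(x@members))

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet '%s': %d accessions\n", object@name,
              length(object@members)))
  if (length(object@members)) {
    shown <- utils::head(object@members, 5L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(object@members) > 5L) ", ..." else "", "\n", sep = "")
  }
})

#' Replicate protein-identification lists from one experiment
#'
#' An ordered collection of per-replicate accession sets from a single pulldown
#' or immunoprecipitation mass-spectrometry experiment.
#'
#' @param experiment Experiment label.
#' @param replicates List of character vectors, one per biological replicate;
#'   each is deduplicated.
#' @return A \code{ReplicateLists}.
#' @seealso \code{\link{replicateConsistentSet}}
#' @examples
#' ReplicateLists("ipms", list(c("A", "B"), c("B", "C")))
#' @aliases ReplicateLists-class
#' @exportClass ReplicateLists
#' @export
setClass("ReplicateLists",
  representation(experiment = "character", replicates = "list"),
  validity = function(object) {
    if (length(object@experiment) != 1L || !nzchar(object@experiment))
      return("experiment must be a single non-empty label")
    if (length(object@replicates) < 1L)
      return("at least one replicate is required")
    if (!all(vapply(object@replicates, is.character, logical(1))))
      return("replicates must be character vectors")
    if (any(vapply(object@replicates, anyDuplicated, integer(1)) > 0L))
      return("each replicate must be deduplicated")
    TRUE
  })

#' @rdname ReplicateLists-class
#' @export
ReplicateLists <- function(experiment, replicates) {
  new("ReplicateLists", experiment = as.character(experiment),
      replicates = lapply(replicates, function(r) unique(as.character(r))))
}

#' @describeIn ReplicateLists-class number of replicates.
#' @param x,object A \code{ReplicateLists}.
#' @export
setMethod("length", "ReplicateLists", function(x) length(x@replicates))

#' @describeIn ReplicateLists-class the per-replicate accession lists.
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname ReplicateLists-class
#' @export
setMethod("replicates", "ReplicateLists", function(x) x@replicates)

setMethod("show", "ReplicateLists", function(object) {
  cat(sprintf("ReplicateLists '%s': %d replicates (sizes %s)\n",
              object@experiment, length(object@replicates),
              paste(lengths(object@replicates), collapse = ", ")))
})

#' Tryptic-peptide membership index
#'
#' Hash-backed index answering, in expected constant time, which database
#' proteins contain a given tryptic peptide. Built over the union of the
#' reference proteome and the candidate microprotein database so that one
#' lookup classifies a peptide as reference-matching, shared among candidates,
#' or unique to a single candidate.
#'
#' @seealso \code{\link{buildPeptideIndex}}, \code{\link{classifyPeptide}}
#' @aliases PeptideIndex-class
#' @exportClass PeptideIndex
setClass("PeptideIndex",
  representation(env = "environment", origins = "character",
                 sequences = "character", params = "DigestParams"))

setMethod("show", "PeptideIndex", function(object) {
  cat(sprintf("PeptideIndex: %d peptides over %d proteins (%d reference, %d candidate)\n",
              length(ls(object@env)), length(object@origins),
              sum(object@origins == "reference"),
              sum(object@origins == "lep")))
})
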