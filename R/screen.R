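## Presence calling, pan-cancer set analysis, and differential expression on
## protein abundance matrices with missing values.
##
## Presence rule: a protein is identified in a cohort when it is quantified in
## strictly more than presenceFrac of the tumor samples OR of the non-tumor
## samples. Differential testing requires quantification in strictly more than
## dePresenceFrac of the samples in BOTH groups; fold changes are ratios of
## linear-scale group means over observed values (no imputation); tests run on
## log2 intensities with a Shapiro-Wilk pre-test routing each protein to
## Student's t (both groups normal) or Mann-Whitney U.

#' Read an abundance matrix and its sample metadata
#'
#' The abundance TSV has protein accessions in the first column and sample ids
#' as the remaining column headers; empty cells or \code{NA} are missing. The
#' metadata TSV has columns \code{sample_id}, \code{cohort}, \code{group}
#' (\code{tumor}/\code{nontumor}) and optional \code{pair_id}.
#'
#' @param valuesPath Abundance TSV path.
#' @param metaPath Sample metadata TSV path.
#' @return A \code{\link{LEPAbundance}}.
#' @export
readAbundance <- function(valuesPath, metaPath) {
  tab <- read.delim(valuesPath, check.names = FALSE, na.strings = c("", "NA"))
  prot <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- prot
  meta <- read.delim(metaPath, check.names = FALSE)
  LEPAbundance(m, meta)
}

#' Write an abundance matrix and metadata to TSV
#'
#' @param x A \code{\link{LEPAbundance}}.
#' @param valuesPath,metaPath Output paths.
#' @return Invisibly, \code{valuesPath}.
#' @export
writeAbundance <- function(x, valuesPath, metaPath) {
  m <- intensities(x)
  out <- data.frame(protein = rownames(m), m, check.names = FALSE)
  write.table(out, valuesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- as.data.frame(SummarizedExperiment::colData(x))
  meta <- cbind(sample_id = colnames(x),
                meta[, setdiff(colnames(meta), "sample_id"), drop = FALSE])
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(valuesPath)
}

#' Call per-cohort presence of each protein
#'
#' Applies the presence rule within each cohort: fraction of tumor samples and
#' of non-tumor samples with a quantified (non-missing) value, identified when
#' either fraction strictly exceeds \code{presenceFrac}. With
#' \code{pooled = TRUE} all samples are treated as a single cohort
#' (\code{"pooled"}).
#'
#' @param x A \code{\link{LEPAbundance}}.
#' @param params A \code{\link{ScreenParams}}.
#' @param pooled Evaluate over all samples jointly instead of per cohort.
#' @return \code{data.frame} with columns \code{protein}, \code{cohort},
#'   \code{frac_tumor}, \code{frac_nontumor}, \code{identified}.
#' @export
callPresence <- function(x, params = ScreenParams(), pooled = FALSE) {
  m <- intensities(x)
  cohort <- if (pooled) rep("pooled", ncol(m)) else sampleCohort(x)
  group <- sampleGroup(x)
  rows <- lapply(unique(cohort), function(co) {
    tu <- cohort == co & group == "tumor"
    nt <- cohort == co & group == "nontumor"
    if (!any(tu) && !any(nt))
      stop(sprintf("cohort '%s' has no samples in either group", co))
    ft <- if (any(tu)) rowMeans(!is.na(m[, tu, drop = FALSE])) else
      rep(0, nrow(m))
    fn <- if (any(nt)) rowMeans(!is.na(m[, nt, drop = FALSE])) else
      rep(0, nrow(m))
    data.frame(protein = rownames(m), cohort = co, frac_tumor = ft,
               frac_nontumor = fn,
               identified = ft > params@presenceFrac |
                 fn > params@presenceFrac,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Pan-cancer core and cohort-unique protein sets
#'
#' From per-cohort identification, computes the core (proteins identified in
#' every cohort -- the centre of the flower plot) and, per cohort, the unique
#' set (identified in that cohort and no other -- the petals).
#'
#' @param identified Either the \code{data.frame} returned by
#'   \code{\link{callPresence}} or a named list mapping cohort to a character
#'   vector of identified proteins.
#' @return A list with \code{core} (character), \code{unique} (named list),
#'   \code{counts} (\code{data.frame} of per-cohort identified/unique counts),
#'   and \code{n_cohorts}.
#' @export
panCancerSets <- function(identified) {
  if (is.data.frame(identified)) {
    identified <- split(identified$protein[identified$identified],
                        identified$cohort[identified$identified])
  }
  if (length(identified) < 1L) stop("at least one cohort is required")
  identified <- lapply(identified, unique)
  core <- Reduce(intersect, identified)
  uniq <- lapply(seq_along(identified), function(i) {
    others <- unlist(identified[-i], use.names = FALSE)
    setdiff(identified[[i]], others)
  })
  names(uniq) <- names(identified)
  counts <- data.frame(cohort = names(identified),
                       n_identified = lengths(identified),
                       n_unique = lengths(uniq), row.names = NULL)
  list(core = sort(core), unique = lapply(uniq, sort), counts = counts,
       n_cohorts = length(identified))
}

## Shapiro-Wilk normality check; degenerate groups (constant, or n outside
## shapiro.test's 3..5000 support) are routed to the rank test.
.groupNormal <- function(v, alpha) {
  if (length(v) < 3L || length(v) > 5000L || sd(v) == 0) return(FALSE)
  stats::shapiro.test(v)$p.value >= alpha
}

.testOne <- function(tu, nt, params) {
  lt <- log2(tu); ln <- log2(nt)
  normal <- .groupNormal(lt, params@normalityAlpha) &&
    .groupNormal(ln, params@normalityAlpha)
  if (normal) {
    p <- stats::t.test(lt, ln, paired = params@paired,
                       var.equal = params@pooledVariance)$p.value
    list(p = p, test = "student_t")
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(lt, ln, paired = params@paired)$p.value)
    list(p = p, test = "mann_whitney")
  }
}

#' Differential expression screen between tumor and non-tumor samples
#'
#' For each protein passing the per-group presence rule
#' (\code{> dePresenceFrac} quantified in both groups) and having at least 3
#' observed values per group, computes the linear-scale fold change of group
#' means over observed values and a two-sided p-value on log2 intensities:
#' Student's t when both groups pass the Shapiro-Wilk normality pre-test,
#' Mann-Whitney U otherwise. A protein is significant when
#' \code{p < alpha} and \code{|log2fc| >= log2(fcCut)}. Excluded proteins are
#' reported with a \code{skip_reason} rather than dropped.
#'
#' @param x A \code{\link{LEPAbundance}}.
#' @param params A \code{\link{ScreenParams}}.
#' @param cohort Optional cohort label; if given, only that cohort's samples
#'   are used.
#' @return \code{data.frame} with columns \code{protein}, \code{log2fc},
#'   \code{p_value}, \code{test_used}, \code{significant},
#'   \code{skip_reason} (\code{NA} for tested proteins).
#' @export
differentialExpression <- function(x, params = ScreenParams(),
                                   cohort = NULL) {
  m <- intensities(x)
  keep <- if (is.null(cohort)) rep(TRUE, ncol(m)) else
    sampleCohort(x) == cohort
  if (!any(keep)) stop(sprintf("no samples in cohort '%s'", cohort))
  m <- m[, keep, drop = FALSE]
  group <- sampleGroup(x)[keep]
  if (params@paired) {
    pid <- SummarizedExperiment::colData(x)$pair_id[keep]
    if (is.null(pid)) stop("paired = TRUE requires a pair_id column")
    common <- intersect(pid[group == "tumor"], pid[group == "nontumor"])
    tu_idx <- match(common, ifelse(group == "tumor", pid, NA))
    nt_idx <- match(common, ifelse(group == "nontumor", pid, NA))
  } else {
    tu_idx <- which(group == "tumor")
    nt_idx <- which(group == "nontumor")
  }
  n_tu <- length(tu_idx); n_nt <- length(nt_idx)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    tu <- m[i, tu_idx]; nt <- m[i, nt_idx]
    if (params@paired) {
      ok <- !is.na(tu) & !is.na(nt)
      tu_obs <- tu[ok]; nt_obs <- nt[ok]
      frac_tu <- frac_nt <- mean(ok)
    } else {
      tu_obs <- tu[!is.na(tu)]; nt_obs <- nt[!is.na(nt)]
      frac_tu <- length(tu_obs) / max(n_tu, 1L)
      frac_nt <- length(nt_obs) / max(n_nt, 1L)
    }
    skip <- if (length(tu_obs) == 0L && length(nt_obs) == 0L) "all_missing"
      else if (!(frac_tu > params@dePresenceFrac &&
                 frac_nt > params@dePresenceFrac)) "presence_filter"
      else if (length(tu_obs) < 3L || length(nt_obs) < 3L)
        "too_few_observations"
      else NA_character_
    if (!is.na(skip))
      return(data.frame(protein = rownames(m)[i], log2fc = NA_real_,
                        p_value = NA_real_, test_used = NA_character_,
                        significant = NA, skip_reason = skip,
                        stringsAsFactors = FALSE))
    lfc <- log2(mean(tu_obs) / mean(nt_obs))
    tst <- .testOne(tu_obs, nt_obs, params)
    data.frame(protein = rownames(m)[i], log2fc = lfc, p_value = tst$p,
               test_used = tst$test, significant = NA,
               skip_reason = NA_character_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  tested <- is.na(res$skip_reason)
  p_eff <- res$p_value
  if (params@pAdjust != "none")
    p_eff[tested] <- p.adjust(res$p_value[tested], method = params@pAdjust)
  res$significant[tested] <- p_eff[tested] < params@alpha &
    abs(res$log2fc[tested]) >= log2(params@fcCut)
  res
}

#' Histogram of microprotein lengths
#'
#' Bins are left-closed, right-open \code{[e_i, e_{i+1})}.
#'
#' @param lengths Positive integer lengths (residues).
#' @param binEdges Strictly increasing numeric bin edges.
#' @return \code{data.frame} with \code{bin}, \code{count}, \code{fraction}
#'   (fractions are \code{NaN}-free: all zero for empty input).
#' @export
lengthHistogram <- function(lengths, binEdges) {
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("binEdges must be strictly increasing")
  if (length(lengths) && any(lengths <= 0))
    stop("lengths must be positive")
  nb <- length(binEdges) - 1L
  labs <- sprintf("[%g,%g)", binEdges[-length(binEdges)], binEdges[-1])
  if (!length(lengths)) {
    return(data.frame(bin = labs, count = rep(0L, nb),
                      fraction = rep(0, nb)))
  }
  idx <- findInterval(lengths, binEdges, rightmost.closed = FALSE)
  if (any(idx == 0L | idx > nb))
    stop("length(s) outside the bin range")
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin = labs, count = counts,
             fraction = counts / length(lengths))
}

#' Write presence calls or DE results to TSV
#'
#' @param df A result \code{data.frame}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeScreenTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pan-cancer core/unique summary as JSON
#'
#' @param sets Output of \code{\link{panCancerSets}}.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
writePanCancerSummary <- function(sets, path) {
  jsonlite::write_json(
    list(core = sets$core, core_size = length(sets$core),
         unique = sets$unique,
         unique_sizes = lapply(sets$unique, length),
         n_cohorts = sets$n_cohorts),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
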