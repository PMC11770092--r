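## Percent-spliced-in (PSI) quantification of alternative-splicing events from
## junction counts, condition testing, event-type summaries, and long/short
## isoform ratios.
##
## For skipped-exon (SE) events the inclusion count is the sum of the upstream
## and downstream inclusion junctions; with length normalization it is halved
## so that one included transcript contributes the same effective weight as
## one skipping transcript. Replicates are pooled within condition before
## testing; the condition test is a two-sided Fisher exact test on the 2x2
## table of effective inclusion/exclusion counts (minimum-likelihood
## summation convention, as implemented by stats::fisher.test).

.EVENT_TYPES <- c("SE", "RI", "A5SS", "A3SS", "MXE")

#' Read a splice-event junction-count table
#'
#' TSV with columns \code{event_id}, \code{gene}, \code{event_type} (one of
#' SE, RI, A5SS, A3SS, MXE), \code{sample_id}, \code{condition},
#' \code{inclusion_count}, \code{exclusion_count}; one row per event and
#' sample, mirroring an rMATS-style junction-count export.
#'
#' @param path TSV path.
#' @return Validated \code{data.frame}.
#' @export
readSpliceEvents <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  validateSpliceEvents(ev)
}

#' Validate a splice-event table
#'
#' @param ev \code{data.frame} in the schema of
#'   \code{\link{readSpliceEvents}}.
#' @return The validated table (invisibly modified: counts as integers).
#' @export
validateSpliceEvents <- function(ev) {
  need <- c("event_id", "gene", "event_type", "sample_id", "condition",
            "inclusion_count", "exclusion_count")
  miss <- base::setdiff(need, colnames(ev))
  if (length(miss))
    stop("splice-event table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(ev$event_type %in% .EVENT_TYPES))
    stop("event_type must be one of ", paste(.EVENT_TYPES, collapse = ", "))
  if (any(ev$inclusion_count < 0 | ev$exclusion_count < 0))
    stop("junction counts must be >= 0")
  ev$inclusion_count <- as.integer(ev$inclusion_count)
  ev$exclusion_count <- as.integer(ev$exclusion_count)
  ev
}

## Pool counts within condition for one event; returns per-condition raw and
## effective (length-normalized) counts.
.poolEvent <- function(evOne, lengthNormalize) {
  se <- evOne$event_type[1] == "SE"
  agg <- lapply(split(evOne, evOne$condition), function(d) {
    I <- sum(d$inclusion_count); E <- sum(d$exclusion_count)
    I_eff <- if (se && lengthNormalize) I / 2 else I
    list(I = I, E = E, I_eff = I_eff, E_eff = E)
  })
  agg
}

#' Compute percent spliced in per condition
#'
#' Pools junction counts over the samples of each condition and computes
#' \code{PSI = I_eff / (I_eff + E_eff)}; for SE events with
#' \code{lengthNormalize} (default), \code{I_eff = inclusion / 2}, reflecting
#' the two inclusion junctions supporting each included transcript versus one
#' skipping junction. Events whose pooled raw coverage
#' (inclusion + exclusion) falls below \code{minCoverage} in any condition
#' are skipped with a reason.
#'
#' @param events Splice-event table (\code{\link{readSpliceEvents}} schema).
#' @param lengthNormalize Halve SE inclusion counts (default \code{TRUE}).
#' @param minCoverage Minimum pooled raw coverage per condition (default 10).
#' @return \code{data.frame} with one row per event and condition:
#'   \code{event_id}, \code{gene}, \code{event_type}, \code{condition},
#'   \code{inclusion}, \code{exclusion}, \code{psi}, \code{skip_reason}.
#' @examples
#' ev <- data.frame(event_id = "e1", gene = "g", event_type = "SE",
#'                  sample_id = "s1", condition = "ctrl",
#'                  inclusion_count = 100L, exclusion_count = 50L)
#' computePsi(ev)  # PSI = 50 / (50 + 50) = 0.5
#' @export
computePsi <- function(events, lengthNormalize = TRUE, minCoverage = 10) {
  events <- validateSpliceEvents(events)
  rows <- lapply(split(events, events$event_id), function(d) {
    agg <- .poolEvent(d, lengthNormalize)
    low <- vapply(agg, function(a) a$I + a$E < minCoverage, logical(1))
    skip <- if (any(low))
      sprintf("coverage_below_%g_in_%s", minCoverage,
              paste(names(agg)[low], collapse = ","))
      else NA_character_
    do.call(rbind, lapply(names(agg), function(co) {
      a <- agg[[co]]
      psi <- if (!is.na(skip) || a$I_eff + a$E_eff == 0) NA_real_
        else a$I_eff / (a$I_eff + a$E_eff)
      data.frame(event_id = d$event_id[1], gene = d$gene[1],
                 event_type = d$event_type[1], condition = co,
                 inclusion = a$I, exclusion = a$E, psi = psi,
                 skip_reason = skip, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test a PSI difference between two conditions
#'
#' Pools replicates within condition, computes PSI per condition and
#' \code{delta_psi = PSI(test) - PSI(control)}, and tests the 2x2 table of
#' effective inclusion/exclusion counts (rounded to integers) with a
#' two-sided Fisher exact test. Significance requires \code{p < alpha} and
#' \code{|delta_psi| >= minDelta}.
#'
#' @param events Splice-event table.
#' @param testCondition,controlCondition Condition labels.
#' @param alpha Significance level (default 0.05).
#' @param minDelta Minimum absolute PSI difference (default 0.1).
#' @param lengthNormalize,minCoverage See \code{\link{computePsi}}.
#' @return \code{data.frame} with one row per event: \code{event_id},
#'   \code{gene}, \code{event_type}, \code{psi_test}, \code{psi_control},
#'   \code{delta_psi}, \code{p_value}, \code{significant},
#'   \code{skip_reason}.
#' @export
deltaPsiTest <- function(events, testCondition, controlCondition,
                         alpha = 0.05, minDelta = 0.1,
                         lengthNormalize = TRUE, minCoverage = 10) {
  events <- validateSpliceEvents(events)
  conds <- unique(events$condition)
  for (co in c(testCondition, controlCondition))
    if (!co %in% conds) stop(sprintf("condition '%s' not present", co))
  rows <- lapply(split(events, events$event_id), function(d) {
    agg <- .poolEvent(d, lengthNormalize)
    base <- data.frame(event_id = d$event_id[1], gene = d$gene[1],
                       event_type = d$event_type[1], stringsAsFactors = FALSE)
    if (!all(c(testCondition, controlCondition) %in% names(agg)))
      return(cbind(base, psi_test = NA_real_, psi_control = NA_real_,
                   delta_psi = NA_real_, p_value = NA_real_,
                   significant = NA, skip_reason = "condition_missing"))
    at <- agg[[testCondition]]; ac <- agg[[controlCondition]]
    if (at$I + at$E < minCoverage || ac$I + ac$E < minCoverage)
      return(cbind(base, psi_test = NA_real_, psi_control = NA_real_,
                   delta_psi = NA_real_, p_value = NA_real_,
                   significant = NA,
                   skip_reason = sprintf("coverage_below_%g", minCoverage)))
    psi_t <- at$I_eff / (at$I_eff + at$E_eff)
    psi_c <- ac$I_eff / (ac$I_eff + ac$E_eff)
    tab <- matrix(round(c(at$I_eff, at$E_eff, ac$I_eff, ac$E_eff)),
                  nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    delta <- psi_t - psi_c
    cbind(base, psi_test = psi_t, psi_control = psi_c, delta_psi = delta,
          p_value = p,
          significant = p < alpha & abs(delta) >= minDelta,
          skip_reason = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of event types among significant splicing changes
#'
#' @param results Output of \code{\link{deltaPsiTest}}.
#' @return \code{data.frame} with \code{event_type}, \code{count},
#'   \code{proportion} among significant events (proportions sum to 1);
#'   zero rows, with a warning, when nothing is significant.
#' @export
eventTypeDistribution <- function(results) {
  sig <- results[!is.na(results$significant) & results$significant, ,
                 drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no significant events")
    return(data.frame(event_type = character(), count = integer(),
                      proportion = numeric()))
  }
  tab <- table(sig$event_type)
  data.frame(event_type = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab), row.names = NULL)
}

#' Long/short isoform ratio
#'
#' Ratio of the exon-including (long) to the exon-skipping (short) isoform
#' abundance; with inclusion level \code{p} and total abundance \code{T},
#' \code{long = p*T} and \code{short = (1-p)*T} give ratio
#' \code{p / (1 - p)}.
#'
#' @param longAbundance,shortAbundance Non-negative abundances.
#' @return A list with \code{long}, \code{short}, \code{ratio}.
#' @export
isoformRatio <- function(longAbundance, shortAbundance) {
  if (longAbundance < 0 || shortAbundance < 0)
    stop("abundances must be >= 0")
  if (shortAbundance == 0)
    stop("short-isoform abundance is zero: ratio undefined")
  list(long = longAbundance, short = shortAbundance,
       ratio = longAbundance / shortAbundance)
}

#' Relative isoform ratio between two samples
#'
#' @param testRatio,controlRatio Outputs of \code{\link{isoformRatio}}.
#' @return \code{ratio_test / ratio_control}.
#' @export
relativeIsoformRatio <- function(testRatio, controlRatio) {
  testRatio$ratio / controlRatio$ratio
}

#' Write PSI test results and the event-type distribution
#'
#' @param results Output of \code{\link{deltaPsiTest}}.
#' @param tsvPath Output TSV for per-event results.
#' @param distJsonPath Optional JSON path for the event-type distribution.
#' @return Invisibly, \code{tsvPath}.
#' @export
writePsiResults <- function(results, tsvPath, distJsonPath = NULL) {
  write.table(results, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(distJsonPath)) {
    dist <- tryCatch(eventTypeDistribution(results),
                     warning = function(w) data.frame(
                       event_type = character(), count = integer(),
                       proportion = numeric()))
    jsonlite::write_json(dist, distJsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsvPath)
}
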