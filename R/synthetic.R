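## Seeded synthetic-data generator. Every generator returns its data together
## with a truth record so that each pipeline stage can be validated by
## parameter recovery. All randomness flows from the seed argument via R's
## default RNG; identical seeds give identical outputs.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

.randCodon <- function(exclude = character()) {
  pool <- base::setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")), 1, paste,
                        collapse = ""), exclude)
  sample(pool, 1)
}

## Inner ORF codons: not a stop, not ATG, and no ATG spanning the junction
## with the previous two bases.
.sampleInnerCodons <- function(nAa, prevTail) {
  codons <- character(nAa)
  tail2 <- prevTail
  for (i in seq_len(nAa)) {
    repeat {
      cod <- .randCodon(exclude = c(.STOP_CODONS, "ATG"))
      if (!grepl("ATG", paste0(tail2, cod), fixed = TRUE)) break
    }
    codons[i] <- cod
    tail2 <- substr(cod, 2, 3)
  }
  codons
}

.randBackground <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Mutate initiators of ORFs >= minAa that are not the planted one, until the
## scan is clean. Mutations ('A'->'C' or 'G'->'C') can never create an ATG.
.scrubSpurious <- function(seq, plantedStart, plantedEnd, minAa) {
  params <- OrfParams(minLenAa = minAa, requireStop = TRUE,
                      reportNestedStarts = TRUE)
  for (iter in 1:50) {
    orfs <- .findOrfsOne(seq, "tmp", params)
    bad <- orfs[is.na(plantedStart) | orfs$start != plantedStart |
                  orfs$end != plantedEnd, , drop = FALSE]
    if (nrow(bad) == 0L) return(seq)
    for (p0 in bad$start) {
      # mutate the G of the initiator ATG; fall back to the A if that base
      # sits inside the planted span
      pos <- p0 + 2L
      if (!is.na(plantedStart) && pos >= plantedStart && pos < plantedEnd)
        pos <- p0
      substr(seq, pos + 1L, pos + 1L) <- "C"
    }
  }
  stop("could not scrub spurious ORFs")   # nocov
}

#' Generate a synthetic lncRNA transcriptome with planted small ORFs
#'
#' Each transcript carries at most one planted ATG-initiated ORF at recorded
#' coordinates, flanked by random UTRs. Planted ORF lengths default to the
#' 50--200 residue range typical of lncRNA-encoded microproteins. Background
#' sequence is scrubbed of spurious ATG-initiated ORFs of at least
#' \code{min(50, planted lengths)} residues (shorter chance ORFs are left in
#' place), so the planted ORF is exactly recoverable by
#' \code{\link{findOrfs}} at that minimum length.
#'
#' @param seed Integer seed.
#' @param nTranscripts Number of transcripts.
#' @param orfLengths Integer vector of planted ORF lengths in residues,
#'   recycled across transcripts; \code{NA} entries plant no ORF. Default:
#'   uniform draws in \code{lenRange}.
#' @param lenRange Range for default ORF lengths (residues).
#' @param utrRange Range of flanking UTR lengths (nucleotides).
#' @return List with \code{sequences} (named character vector) and
#'   \code{truth} (\code{data.frame}: \code{transcript_id}, \code{start},
#'   \code{end}, \code{length_aa}, \code{protein_seq}; planted ORFs only)
#'   plus the \code{seed}.
#' @export
genTranscriptome <- function(seed, nTranscripts, orfLengths = NULL,
                             lenRange = c(50L, 200L),
                             utrRange = c(60L, 300L)) {
  stopifnot(nTranscripts >= 1)
  .withSeed(seed, {
    if (is.null(orfLengths))
      orfLengths <- sample(lenRange[1]:lenRange[2], nTranscripts,
                           replace = TRUE)
    orfLengths <- rep_len(orfLengths, nTranscripts)
    seqs <- character(nTranscripts)
    truth <- vector("list", nTranscripts)
    scrubMin <- min(c(50L, orfLengths[!is.na(orfLengths)]))
    for (t in seq_len(nTranscripts)) {
      id <- sprintf("SYNTX%04d", t)
      utr5 <- .randBackground(sample(utrRange[1]:utrRange[2], 1))
      utr3 <- .randBackground(sample(utrRange[1]:utrRange[2], 1))
      len <- orfLengths[t]
      if (is.na(len)) {
        seq <- paste0(utr5, utr3)
        seq <- .scrubSpurious(seq, NA_integer_, NA_integer_, scrubMin)
        seqs[t] <- seq
        truth[t] <- list(NULL)
        next
      }
      if (len < 2L) stop("planted ORF length must be >= 2 residues")
      tail2 <- substr(utr5, max(1L, nchar(utr5) - 1L), nchar(utr5))
      inner <- .sampleInnerCodons(len - 1L, "TG")  # ATG ends in "TG"
      stopPool <- .STOP_CODONS
      lastTail <- if (length(inner)) substr(inner[length(inner)], 2, 3)
                  else "TG"
      stopCod <- NULL
      for (sc in sample(stopPool)) {
        if (!grepl("ATG", paste0(lastTail, sc), fixed = TRUE)) {
          stopCod <- sc; break
        }
      }
      orfSeq <- paste0("ATG", paste(inner, collapse = ""), stopCod)
      start <- nchar(utr5)
      end <- start + nchar(orfSeq)
      seq <- paste0(utr5, orfSeq, utr3)
      seq <- .scrubSpurious(seq, start, end, scrubMin)
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(seq, start + 1L, end - 3L))))
      seqs[t] <- seq
      truth[[t]] <- data.frame(transcript_id = id, start = start, end = end,
                               length_aa = len, protein_seq = prot,
                               stringsAsFactors = FALSE)
      names(seqs)[t] <- id
    }
    names(seqs) <- sprintf("SYNTX%04d", seq_len(nTranscripts))
    list(sequences = seqs, truth = do.call(rbind, truth), seed = seed)
  })
}

#' Write a synthetic transcriptome to FASTA
#'
#' The seed is recorded in each header after the transcript id.
#'
#' @param transcriptome Output of \code{\link{genTranscriptome}}.
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
writeTranscriptome <- function(transcriptome, path) {
  x <- Biostrings::DNAStringSet(transcriptome$sequences)
  names(x) <- sprintf("%s seed=%d", names(transcriptome$sequences),
                      transcriptome$seed)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Generate a synthetic multi-cohort protein abundance matrix
#'
#' Emulates processed tumor-proteomics cohorts: per-protein baseline log2
#' intensities, Gaussian sample noise, planted tumor-vs-nontumor effects, and
#' intensity-dependent (MNAR) plus completely-random (MCAR) missingness.
#' Planted structure with recorded truth: \code{nCore} proteins expressed at
#' high level in every cohort, \code{nUniquePerCohort} proteins expressed in
#' exactly one cohort, and background proteins expressed in random cohort
#' subsets of size 2..(k-1) (with k >= 3 cohorts) so that the pan-cancer core
#' and unique sets are exactly the planted ones.
#'
#' @param seed Integer seed.
#' @param design \code{data.frame} with columns \code{cohort},
#'   \code{n_tumor}, \code{n_nontumor} (each >= 3).
#' @param nProteins Total number of proteins (>= planted).
#' @param deFraction Fraction of proteins given a planted tumor effect.
#' @param effectLog2fc Absolute planted effect on log2 scale; signs alternate.
#' @param sigma Within-group standard deviation of log2 intensities.
#' @param nCore,nUniquePerCohort Planted universal / cohort-unique proteins.
#' @param missingModel \code{NULL} for complete data, or a list with
#'   \code{midQuantile} (MNAR logistic midpoint as an intensity quantile,
#'   default 0.2), \code{slope} (logistic slope per log2 unit, default 1),
#'   \code{mcarRate} (floor missingness, default 0.02).
#' @param baseMean,baseSd Distribution of per-protein baseline log2
#'   intensities.
#' @return List with \code{abundance} (a \code{\link{LEPAbundance}}) and
#'   \code{truth} (planted DE table, core / unique sets, expression design),
#'   plus the \code{seed}.
#' @export
genAbundanceCohort <- function(seed, design, nProteins = 1000,
                               deFraction = 0.1, effectLog2fc = 1,
                               sigma = 0.5, nCore = 3, nUniquePerCohort = 5,
                               missingModel = list(midQuantile = 0.2,
                                                   slope = 1,
                                                   mcarRate = 0.02),
                               baseMean = 25, baseSd = 2) {
  design <- as.data.frame(design)
  stopifnot(all(c("cohort", "n_tumor", "n_nontumor") %in% colnames(design)),
            all(design$n_tumor >= 3), all(design$n_nontumor >= 3))
  if (deFraction < 0 || deFraction > 1)
    stop("deFraction must be in [0, 1]")
  k <- nrow(design)
  nPlanted <- nCore + k * nUniquePerCohort
  if (nProteins < nPlanted)
    stop("nProteins smaller than the planted structure")
  .withSeed(seed, {
    prot <- sprintf("LEP%04d", seq_len(nProteins))
    role <- rep("background", nProteins)
    role[seq_len(nCore)] <- "core"
    uniqueOf <- rep(NA_character_, nProteins)
    if (nUniquePerCohort > 0)
      for (c_i in seq_len(k)) {
        idx <- nCore + (c_i - 1L) * nUniquePerCohort +
          seq_len(nUniquePerCohort)
        role[idx] <- "unique"
        uniqueOf[idx] <- design$cohort[c_i]
      }
    # expression design: which cohorts each protein is expressed in
    exprIn <- matrix(FALSE, nProteins, k,
                     dimnames = list(prot, design$cohort))
    exprIn[role == "core", ] <- TRUE
    for (i in which(role == "unique"))
      exprIn[i, uniqueOf[i]] <- TRUE
    for (i in which(role == "background")) {
      if (k >= 3) {
        sz <- sample(2:(k - 1L), 1)
        exprIn[i, sample(k, sz)] <- TRUE
      } else exprIn[i, ] <- TRUE
    }
    mu <- rnorm(nProteins, baseMean, baseSd)
    mu[role != "background"] <- baseMean + 2 * baseSd   # planted: well above
                                                        # the MNAR midpoint
    nDe <- floor(deFraction * nProteins)
    deIdx <- if (nDe > 0) sample(nProteins, nDe) else integer()
    lfc <- rep(0, nProteins)
    if (nDe > 0)
      lfc[deIdx] <- effectLog2fc * rep_len(c(1, -1), nDe)
    samples <- do.call(rbind, lapply(seq_len(k), function(c_i) {
      co <- design$cohort[c_i]
      data.frame(
        sample_id = c(sprintf("%s_T%02d", co, seq_len(design$n_tumor[c_i])),
                      sprintf("%s_N%02d", co,
                              seq_len(design$n_nontumor[c_i]))),
        cohort = co,
        group = c(rep("tumor", design$n_tumor[c_i]),
                  rep("nontumor", design$n_nontumor[c_i])),
        stringsAsFactors = FALSE)
    }))
    nS <- nrow(samples)
    X <- matrix(rnorm(nProteins * nS, 0, sigma), nProteins, nS,
                dimnames = list(prot, samples$sample_id))
    X <- X + mu
    tumorCols <- samples$group == "tumor"
    X[, tumorCols] <- X[, tumorCols] + lfc
    # mask cohorts where a protein is not expressed
    for (c_i in seq_len(k)) {
      cols <- samples$cohort == design$cohort[c_i]
      X[!exprIn[, c_i], cols] <- NA
    }
    if (!is.null(missingModel)) {
      mid <- quantile(X, missingModel$midQuantile %||% 0.2, na.rm = TRUE)
      slope <- missingModel$slope %||% 1
      mcar <- missingModel$mcarRate %||% 0.02
      pMiss <- stats::plogis(-(X - mid) * slope)
      pMiss <- pmin(1, pMiss + mcar)
      drop <- matrix(runif(length(X)) < pMiss, nrow(X), ncol(X))
      X[drop & !is.na(X)] <- NA
    }
    ab <- LEPAbundance(2^X, samples)
    truth <- list(
      planted_de = data.frame(protein = prot[deIdx],
                              true_log2fc = lfc[deIdx],
                              stringsAsFactors = FALSE),
      core = prot[role == "core"],
      unique = lapply(setNames(design$cohort, design$cohort), function(co)
        prot[!is.na(uniqueOf) & uniqueOf == co]),
      expressed_in = exprIn,
      baseline_log2 = mu, seed = seed)
    list(abundance = ab, truth = truth, seed = seed)
  })
}

#' Generate synthetic interactome replicate lists
#'
#' Plants a core of accessions present in every replicate plus per-replicate
#' noise accessions, each appearing in exactly one replicate -- the structure
#' of replicate IP-MS identification lists.
#'
#' @param seed Integer seed.
#' @param nCore Number of always-present accessions.
#' @param nNoisePerReplicate Noise accessions per replicate.
#' @param nReplicates Number of replicates.
#' @param experiment Experiment label.
#' @return List with \code{lists} (a \code{\link{ReplicateLists}}) and
#'   \code{truth} (\code{core}, per-replicate noise), plus the \code{seed}.
#' @export
genInteractomeReplicates <- function(seed, nCore, nNoisePerReplicate,
                                     nReplicates, experiment = "ipms") {
  stopifnot(nCore >= 0, nNoisePerReplicate >= 0, nReplicates >= 1)
  .withSeed(seed, {
    core <- sprintf("%s_CORE%04d", toupper(experiment), seq_len(nCore))
    reps <- lapply(seq_len(nReplicates), function(r) {
      noise <- if (nNoisePerReplicate > 0)
        sprintf("%s_R%d_NOISE%04d", toupper(experiment), r,
                seq_len(nNoisePerReplicate)) else character()
      sample(c(core, noise))          # shuffled, as real exports are unordered
    })
    list(lists = ReplicateLists(experiment, reps),
         truth = list(core = core, seed = seed), seed = seed)
  })
}

#' Generate a pair of protein sets with a planted overlap
#'
#' Emulates two independent experiments (for example an RNA-pulldown
#' probe-specific set and a replicate-consistent IP-MS set) sharing exactly
#' \code{nOverlap} accessions.
#'
#' @param seed Integer seed.
#' @param nA,nB Set sizes (each >= \code{nOverlap}).
#' @param nOverlap Planted overlap size.
#' @param nameA,nameB Set labels.
#' @return List with \code{a}, \code{b} (\code{\link{ProteinSet}}s) and
#'   \code{truth} (the shared accessions), plus the \code{seed}.
#' @export
genProteinSetPair <- function(seed, nA, nB, nOverlap,
                              nameA = "setA", nameB = "setB") {
  stopifnot(nOverlap >= 0, nA >= nOverlap, nB >= nOverlap)
  .withSeed(seed, {
    shared <- sprintf("SHARED%04d", seq_len(nOverlap))
    onlyA <- sprintf("ONLYA%04d", seq_len(nA - nOverlap))
    onlyB <- sprintf("ONLYB%04d", seq_len(nB - nOverlap))
    list(a = ProteinSet(nameA, sample(c(shared, onlyA))),
         b = ProteinSet(nameB, sample(c(shared, onlyB))),
         truth = list(overlap = shared, seed = seed), seed = seed)
  })
}

#' Generate synthetic junction counts from true PSI values
#'
#' For each event, sample and condition, draws the inclusion junction count
#' from a binomial over \code{depth} junction reads. SE events honor the
#' two-junction convention: an included transcript contributes two inclusion
#' junctions, so the per-read inclusion probability is
#' \code{2*psi / (1 + psi)} and \code{\link{computePsi}} with length
#' normalization recovers \code{psi}. Other event types use probability
#' \code{psi} directly.
#'
#' @param seed Integer seed.
#' @param eventsSpec \code{data.frame} with columns \code{event_id},
#'   \code{gene}, \code{event_type}, and one column of true PSI per
#'   condition named \code{psi.<condition>} (values in [0, 1]).
#' @param depth Junction reads per sample (>= 1).
#' @param nReps Samples per condition.
#' @return List with \code{events} (the junction-count table) and
#'   \code{truth} (true PSI per event and condition), plus the \code{seed}.
#' @export
genJunctionCounts <- function(seed, eventsSpec, depth = 100, nReps = 3) {
  stopifnot(depth >= 1, nReps >= 1)
  psiCols <- grep("^psi\\.", colnames(eventsSpec), value = TRUE)
  if (!length(psiCols)) stop("eventsSpec needs psi.<condition> columns")
  conds <- sub("^psi\\.", "", psiCols)
  psiVals <- as.matrix(eventsSpec[, psiCols, drop = FALSE])
  if (any(psiVals < 0 | psiVals > 1)) stop("true PSI must be in [0, 1]")
  .withSeed(seed, {
    rows <- list()
    for (e in seq_len(nrow(eventsSpec))) {
      se <- eventsSpec$event_type[e] == "SE"
      for (ci in seq_along(conds)) {
        psi <- psiVals[e, ci]
        pInc <- if (se) 2 * psi / (1 + psi) else psi
        for (r in seq_len(nReps)) {
          inc <- rbinom(1, depth, pInc)
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = eventsSpec$event_id[e], gene = eventsSpec$gene[e],
            event_type = eventsSpec$event_type[e],
            sample_id = sprintf("%s_rep%d", conds[ci], r),
            condition = conds[ci], inclusion_count = inc,
            exclusion_count = depth - inc, stringsAsFactors = FALSE)
        }
      }
    }
    events <- do.call(rbind, rows)
    truth <- eventsSpec[, c("event_id", "event_type", psiCols)]
    list(events = events, truth = list(psi = truth, seed = seed),
         seed = seed)
  })
}

#' Write a synthetic truth record as JSON
#'
#' @param truth A truth list from any generator.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
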