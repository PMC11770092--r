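## End-to-end orchestration: a YAML run configuration, stages in dependency
## order (generate -> sorfs -> digest -> screen -> sets -> splice), one
## structured log line per stage to stderr, and a machine-readable JSON
## report. Reruns with the same configuration and seed reproduce identical
## outputs.

#' Default run configuration
#'
#' Returns the full configuration list with every stage enabled, synthetic
#' inputs, and the screening defaults (30\% presence, 50\% DE presence,
#' fold-change 1.5, alpha 0.05).
#'
#' @param outDir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it by fixed
#'   small offsets.
#' @return A nested configuration list.
#' @export
defaultRunConfig <- function(outDir = "lepscreen_out", seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = outDir,
    stages = list(generate = TRUE, sorfs = TRUE, digest = TRUE,
                  screen = TRUE, sets = TRUE, splice = TRUE),
    generate = list(n_transcripts = 20L, n_proteins = 400L,
                    n_cohorts = 4L, n_tumor = 10L, n_nontumor = 10L,
                    de_fraction = 0.1, effect_log2fc = 1, sigma = 0.5,
                    missingness = TRUE,
                    n_core = 3L, n_unique_per_cohort = 5L,
                    interactome_core = 25L, interactome_noise = 10L,
                    interactome_replicates = 4L,
                    n_events = 12L, junction_depth = 200L),
    orf = list(min_len_aa = 50L, require_stop = TRUE),
    digest = list(max_missed_cleavages = 2L, min_len = 7L, max_len = 50L,
                  il_equivalent = TRUE),
    screen = list(presence_frac = 0.30, de_presence_frac = 0.50,
                  fc_cut = 1.5, alpha = 0.05, normality_alpha = 0.05),
    splice = list(min_delta = 0.1, min_coverage = 10L, alpha = 0.05,
                  test_condition = "test", control_condition = "control"),
    inputs = list(transcripts_fasta = NULL, reference_fasta = NULL,
                  abundance_tsv = NULL, sample_meta_tsv = NULL,
                  replicate_tsvs = NULL, events_tsv = NULL))
}

#' Read / write a run configuration (YAML)
#'
#' The on-disk form round-trips losslessly through
#' \code{\link[yaml]{read_yaml}} / \code{\link[yaml]{write_yaml}}.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  utils::modifyList(base, cfg, keep.null = TRUE)
}

#' @rdname readRunConfig
#' @param config A configuration list.
#' @return \code{writeRunConfig}: invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.logStage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " ")
  message(sprintf("[lepscreen] stage=%s %s", stage, msg))
}

#' Run the full screening pipeline
#'
#' Executes the enabled stages in dependency order. With no external inputs
#' configured, the synthetic generator produces every input with recorded
#' ground truth, making the run an end-to-end self-check. Outputs are written
#' under \code{config$out_dir}; the report is returned and written to
#' \code{report.json}.
#'
#' @param config A configuration list (see \code{\link{defaultRunConfig}}),
#'   or the path to a YAML configuration.
#' @return The run report: per-stage counts, thresholds used, output paths,
#'   elapsed seconds.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- as.integer(config$seed)
  report <- list(seed = seed, out_dir = config$out_dir, stages = list())
  gen <- config$generate
  truthAll <- list()

  ## ---- generate --------------------------------------------------------
  if (isTRUE(config$stages$generate)) {
    tg <- genTranscriptome(seed + 11L, gen$n_transcripts)
    writeTranscriptome(tg, out("transcripts.fasta"))
    design <- data.frame(cohort = sprintf("cohort%02d",
                                          seq_len(gen$n_cohorts)),
                         n_tumor = gen$n_tumor, n_nontumor = gen$n_nontumor)
    mm <- if (isTRUE(gen$missingness))
      list(midQuantile = 0.2, slope = 1, mcarRate = 0.02) else NULL
    ga <- genAbundanceCohort(seed + 12L, design, gen$n_proteins,
                             deFraction = gen$de_fraction,
                             effectLog2fc = gen$effect_log2fc,
                             sigma = gen$sigma, nCore = gen$n_core,
                             nUniquePerCohort = gen$n_unique_per_cohort,
                             missingModel = mm)
    writeAbundance(ga$abundance, out("abundance.tsv"),
                   out("sample_meta.tsv"))
    gi <- genInteractomeReplicates(seed + 13L, gen$interactome_core,
                                   gen$interactome_noise,
                                   gen$interactome_replicates)
    for (r in seq_along(replicates(gi$lists)))
      write.table(data.frame(accession = replicates(gi$lists)[[r]]),
                  out(sprintf("replicate_%d.tsv", r)), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    nEv <- gen$n_events
    spec <- data.frame(event_id = sprintf("EV%03d", seq_len(nEv)),
                       gene = sprintf("GENE%03d", seq_len(nEv)),
                       event_type = rep_len(c("SE", "SE", "SE", "RI", "A5SS"),
                                            nEv),
                       stringsAsFactors = FALSE)
    set.seed(seed + 14L)
    spec$psi.control <- round(runif(nEv, 0.2, 0.6), 2)
    shift <- rep_len(c(0.3, 0, 0.25, 0, 0.2), nEv)
    spec$psi.test <- pmin(0.95, spec$psi.control + shift)
    gj <- genJunctionCounts(seed + 15L, spec, depth = gen$junction_depth)
    write.table(gj$events, out("splice_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truthAll <- list(transcriptome = tg$truth, abundance = ga$truth,
                     interactome = gi$truth, splice = gj$truth,
                     splice_shifted = spec$event_id[shift > 0])
    writeTruth(truthAll, out("truth.json"))
    config$inputs$transcripts_fasta <- out("transcripts.fasta")
    config$inputs$abundance_tsv <- out("abundance.tsv")
    config$inputs$sample_meta_tsv <- out("sample_meta.tsv")
    config$inputs$replicate_tsvs <-
      out(sprintf("replicate_%d.tsv", seq_len(gen$interactome_replicates)))
    config$inputs$events_tsv <- out("splice_events.tsv")
    report$stages$generate <- list(
      n_transcripts = length(tg$sequences),
      n_proteins = nrow(ga$abundance),
      n_replicates = length(gi$lists), n_events = nEv)
    .logStage("generate", transcripts = length(tg$sequences),
              proteins = nrow(ga$abundance))
  }

  ## ---- sorfs -----------------------------------------------------------
  orfs <- NULL
  if (isTRUE(config$stages$sorfs)) {
    if (is.null(config$inputs$transcripts_fasta))
      stop("sorfs stage: no transcript FASTA configured")
    tx <- readTranscripts(config$inputs$transcripts_fasta)
    op <- OrfParams(minLenAa = config$orf$min_len_aa,
                    requireStop = config$orf$require_stop)
    orfs <- findOrfs(tx, op)
    canon <- if (nrow(orfs)) selectCanonicalOrf(orfs) else orfs
    writeOrfTable(orfs, out("orfs.tsv"))
    if (nrow(canon)) writeCandidateDb(canon, out("candidate_leps.fasta"))
    report$stages$sorfs <- list(n_orfs = nrow(orfs),
                                n_canonical = nrow(canon),
                                min_len_aa = config$orf$min_len_aa)
    .logStage("sorfs", in_transcripts = length(tx), out_orfs = nrow(orfs))
    orfs <- canon
  }

  ## ---- digest ----------------------------------------------------------
  if (isTRUE(config$stages$digest)) {
    dp <- DigestParams(maxMissedCleavages = config$digest$max_missed_cleavages,
                       minLen = config$digest$min_len,
                       maxLen = config$digest$max_len,
                       ilEquivalent = config$digest$il_equivalent)
    leps <- if (!is.null(orfs) && nrow(orfs))
      data.frame(accession = sprintf("LEP|%s|%d-%d", orfs$transcript_id,
                                     orfs$start + 1L, orfs$end),
                 sequence = orfs$protein_seq, origin = "lep",
                 stringsAsFactors = FALSE)
    else data.frame(accession = character(), sequence = character(),
                    origin = character())
    ref <- if (!is.null(config$inputs$reference_fasta))
      readProteome(config$inputs$reference_fasta, "reference")
    else data.frame(accession = character(), sequence = character(),
                    origin = character())
    if (nrow(leps) + nrow(ref) > 0) {
      idx <- buildPeptideIndex(rbind(ref, leps), dp)
      counts <- if (nrow(leps)) lepUniquePeptideCounts(leps, idx) else
        data.frame(accession = character(), n_peptides = integer(),
                   n_unique = integer(), peptide_supported = logical())
      writeScreenTable(counts, out("lep_peptide_support.tsv"))
      nSupported <- sum(counts$peptide_supported)
    } else nSupported <- 0L
    report$stages$digest <- list(n_leps = nrow(leps),
                                 n_reference = nrow(ref),
                                 n_peptide_supported = nSupported)
    .logStage("digest", leps = nrow(leps), supported = nSupported)
  }

  ## ---- screen ----------------------------------------------------------
  if (isTRUE(config$stages$screen)) {
    if (is.null(config$inputs$abundance_tsv))
      stop("screen stage: no abundance matrix configured")
    ab <- readAbundance(config$inputs$abundance_tsv,
                        config$inputs$sample_meta_tsv)
    sp <- ScreenParams(presenceFrac = config$screen$presence_frac,
                       dePresenceFrac = config$screen$de_presence_frac,
                       fcCut = config$screen$fc_cut,
                       alpha = config$screen$alpha,
                       normalityAlpha = config$screen$normality_alpha)
    pres <- callPresence(ab, sp)
    writeScreenTable(pres, out("presence.tsv"))
    sets <- panCancerSets(pres)
    writePanCancerSummary(sets, out("pan_cancer.json"))
    de <- do.call(rbind, lapply(unique(sampleCohort(ab)), function(co) {
      d <- differentialExpression(ab, sp, cohort = co)
      cbind(cohort = co, d)
    }))
    writeScreenTable(de, out("de.tsv"))
    report$stages$screen <- list(
      n_identified_calls = sum(pres$identified),
      core_size = length(sets$core),
      unique_sizes = lapply(sets$unique, length),
      n_de_significant = sum(de$significant, na.rm = TRUE),
      thresholds = config$screen)
    .logStage("screen", core = length(sets$core),
              de_sig = sum(de$significant, na.rm = TRUE))
  }

  ## ---- sets ------------------------------------------------------------
  if (isTRUE(config$stages$sets)) {
    if (is.null(config$inputs$replicate_tsvs))
      stop("sets stage: no replicate lists configured")
    rl <- readReplicateLists(config$inputs$replicate_tsvs, "ipms")
    consistent <- replicateConsistentSet(rl)
    writeProteinSet(consistent, out("replicate_consistent.tsv"))
    report$stages$sets <- list(n_replicates = length(rl),
                               consistent_size = length(consistent))
    .logStage("sets", replicates = length(rl),
              consistent = length(consistent))
  }

  ## ---- splice ----------------------------------------------------------
  if (isTRUE(config$stages$splice)) {
    if (is.null(config$inputs$events_tsv))
      stop("splice stage: no event table configured")
    ev <- readSpliceEvents(config$inputs$events_tsv)
    res <- deltaPsiTest(ev, config$splice$test_condition,
                        config$splice$control_condition,
                        alpha = config$splice$alpha,
                        minDelta = config$splice$min_delta,
                        minCoverage = config$splice$min_coverage)
    writePsiResults(res, out("psi.tsv"), out("event_type_distribution.json"))
    report$stages$splice <- list(
      n_events = length(unique(ev$event_id)),
      n_significant = sum(res$significant, na.rm = TRUE))
    .logStage("splice", events = length(unique(ev$event_id)),
              significant = sum(res$significant, na.rm = TRUE))
  }

  report$elapsed_sec <- round(proc.time()[["elapsed"]] - t0, 2)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(report)
}
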