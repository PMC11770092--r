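---
title: "lepscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lepscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepscreen)
```

# Scope

`lepscreen` implements the computational core of a proteogenomic screen for
microproteins encoded by transcripts annotated as long noncoding RNAs
(lncRNA-encoded proteins, LEPs): small-ORF discovery and candidate database
construction, tryptic peptide-uniqueness validation against a reference
proteome, missing-value-aware presence and differential screening of tumor
proteomics cohorts, interactome set algebra over replicate identification
lists, and percent-spliced-in (PSI) quantification of exon-skipping events.
A seeded synthetic-data generator produces every input with recorded ground
truth, so the whole pipeline is testable by parameter recovery without any
external download.

This vignette records the models, the tunable parameters and their
rationale, the numerical conventions, and the design decisions taken where
the underlying procedures are conventionally underspecified.

# Small-ORF discovery

An ORF is an ATG-initiated codon run ending at the first in-frame stop codon
(`TAA`/`TAG`/`TGA`), scanned on the given strand in all three frames;
translation uses the standard genetic code via `Biostrings::translate()`.
Key conventions:

* **Start codon.** Only ATG. Near-cognate starts are deliberately excluded:
  the screen targets products whose translation is abolished by mutating the
  ATG, so ATG initiation is the operational definition of a candidate.
* **Stop required.** `requireStop = TRUE` by default; a run reaching the
  transcript end without a stop is not a candidate (configurable).
* **Nested starts.** With `reportNestedStarts = FALSE` (default) each
  (frame, stop) pair yields one ORF anchored at its 5'-most ATG, the usual
  search-database convention.
* **Canonical ORF.** Per transcript, the longest ORF wins; ties break to the
  5'-most start. Longest-ORF is the field convention for naming the product
  of a transcript; nothing else in the pipeline depends on this choice.
* **Ambiguity codes.** Sequences are normalized (U→T, uppercase); `N` is
  accepted but any codon containing `N` is untranslatable and terminates ORF
  extension without providing a stop.
* **Coordinates.** 0-based half-open internally (stop codon included in
  `end`); 1-based closed in every written table and FASTA header.
* **Minimum length.** `minLenAa = 20` by default. Observed LEP lengths
  concentrate in the 50–200-residue range, but that is a description of
  detected products, not a discovery filter, so the default is deliberately
  permissive and exposed in `OrfParams`.

The scanner is validated against an independent brute-force enumeration
(all ATG positions, codon-by-codon walk) on hundreds of random transcripts.

# Peptide uniqueness

Candidate microproteins are only credible if shotgun MS could in principle
distinguish them from the reference proteome, i.e. if they yield at least
one tryptic peptide found in no reference protein.

* **Digestion.** Trypsin rule: cleave C-terminal to K or R, not before P
  (the common search-engine default; the protease itself does cleave some
  K/R-P bonds, but uniqueness should mirror what a search engine would
  report). Peptides with up to `maxMissedCleavages = 2` internal sites and
  lengths in 7–50 residues are enumerated — typical engine defaults, all
  exposed in `DigestParams`.
* **Uniqueness semantics.** Default comparison is at the tryptic-peptide
  level: a peptide matches a protein when it is a member of that protein's
  tryptic peptide set. This mirrors peptide-to-protein assignment in search
  engines. A stricter plain-substring mode is available
  (`mode = "substring"`), since a peptide that occurs inside a reference
  protein in a non-tryptic context could still be misassigned in unusual
  workflows.
* **I/L equivalence.** Isoleucine and leucine are isobaric and
  indistinguishable by standard MS, so both are collapsed before comparison
  by default (`ilEquivalent = TRUE`). Collapsing can only shrink the unique
  set; the property is tested.
* **Classification.** `reference` (matches any reference protein) takes
  precedence over `shared_lep` (matches several candidates) over
  `unique_lep` (exactly one candidate, no reference). Modified and
  semi-tryptic peptides are out of scope.

The index is a hash environment keyed by (collapsed) peptide sequence,
giving expected constant-time membership queries; classification is a pure
function of sequence content.

# Cohort presence and differential screening

Inputs are proteins × samples matrices of positive linear-scale intensities
with explicit missing values, plus per-sample cohort and tumor/non-tumor
labels, wrapped in a `SummarizedExperiment` subclass (`LEPAbundance`).
Intensities are assumed pre-normalized, as processed consortium matrices
are; no imputation is performed anywhere.

* **Presence rule.** A protein is identified in a cohort when it is
  quantified in *strictly more than* 30% of the tumor samples or of the
  non-tumor samples (`presenceFrac = 0.30`). The strict inequality is a
  deliberate reading of the ">30%" wording; the boundary case (exactly 30%)
  is excluded and pinned by tests. Per-cohort evaluation is the default; a
  pooled mode treats all samples as one cohort.
* **Core and unique sets.** Core = identified in every cohort (the centre
  of a flower plot); unique = identified in exactly one cohort (the
  petals). Together with the shared-but-not-core remainder these partition
  the union of identified sets, a property the tests check exhaustively.
* **Differential screen.** Only proteins quantified in strictly more than
  50% of the samples in *both* groups are tested (`dePresenceFrac = 0.50`,
  AND across groups), with at least 3 observed values per group. Fold
  change is the ratio of linear-scale group means over observed values —
  the scale of the underlying quantities, not of the test. The test runs on
  log2 intensities: a Shapiro–Wilk pre-test per group at
  `normalityAlpha = 0.05` routes the protein to a pooled-variance Student's
  t test when both groups look normal, otherwise to the Mann–Whitney U
  test. Degenerate groups (constant values, or sizes outside Shapiro–Wilk's
  support) are routed to the rank test. Significance requires `p < 0.05`
  and linear fold change ≥ 1.5 in either direction. No multiple-testing
  correction is applied by default — this is a raw-p screening rule —
  but Benjamini–Hochberg is one `ScreenParams(pAdjust = "BH")` away.
  Welch's t and a paired mode (matching by `pair_id`) are likewise
  config-exposed.
* **Skip records.** Excluded proteins are reported with a reason
  (`presence_filter`, `too_few_observations`, `all_missing`) rather than
  dropped, so screen outputs always have one row per protein.

The screen's operating characteristics are validated by simulation: under a
Gaussian null (2000 proteins, 20 vs 20) the fraction of raw p-values below
0.05 must fall in [0.03, 0.07], and planted 2-fold effects (σ = 0.5,
20 vs 20) must be flagged at ≥ 90%.

# Interactome set algebra

Replicate identification lists are deduplicated accession sets.
`replicateConsistentSet()` keeps accessions present in ≥ `rMin` replicates;
the default `rMin =` (number of replicates) encodes the
present-in-all-replicates reading of "identified across N independent
replicates", which is the stringent choice — `rMin` is exposed because
union-with-filters readings exist. `setdiff`/`intersect` methods implement
probe-minus-control and cross-experiment overlap logic, recording
provenance in the result's name. Control subtraction is performed on pooled
per-experiment sets (not per-replicate), matching how Venn counts are
usually computed from supplementary tables. Accession normalization
(case folding; optional isoform/version stripping) is available because
supplementary MS tables mix notations; no remote ID-mapping is ever called.

# Splicing quantification

The splicing caller consumes an rMATS-like per-sample junction-count table;
read alignment and event discovery are out of scope.

* **PSI.** Replicate counts are pooled within condition;
  `PSI = I_eff / (I_eff + E_eff)`. For skipped-exon (SE) events with
  `lengthNormalize = TRUE` (default), `I_eff = inclusion / 2`: each
  included transcript contributes two inclusion junctions (upstream and
  downstream of the cassette exon) but each skipping transcript only one
  junction, and halving restores a per-transcript scale. Other event types
  are used as-is.
* **Coverage.** Events with pooled raw coverage below `minCoverage = 10` in
  any condition are skipped with a reason — junction-level PSI at lower
  depth is noise.
* **Condition test.** Two-sided Fisher exact test on the 2×2 table of
  rounded effective counts × condition, via `stats::fisher.test` — the
  minimum-likelihood summation convention; two-sided conventions differ
  between implementations, so tests pin ours to a brute-force
  hypergeometric summation for all margins ≤ 30. Pooling replicates before
  testing means no replicate-variance model: p-values are calibrated for
  the pooled counts, which is the deterministic desk-scale stand-in for a
  full replicate-aware caller. Significance requires `p < alpha` and
  `|ΔPSI| ≥ minDelta = 0.1`.
* **Isoform ratio.** `long/short`, with the algebraic identity
  `ratio = p/(1-p)` under inclusion level `p`; a zero short-isoform
  abundance is an error, not infinity.

# Synthetic data: what it emulates, and what it does not

Each generator takes a seed and returns data plus a truth record; identical
seeds reproduce byte-identical outputs (R's default RNG, one stream per
invocation, no reliance on hash ordering).

* **Transcriptome.** Random-nucleotide transcripts with one planted ORF at
  recorded coordinates (default lengths uniform in 50–200 residues, the
  observed microprotein range; UTRs 60–300 nt). Background is scrubbed of
  chance ATG-initiated ORFs of ≥ min(50, planted length) residues by
  mutating their initiators (a `G`→`C` or `A`→`C` edit can never create a
  new ATG); shorter chance ORFs are left for realism. Planted ORF interiors
  are sampled codon-wise to exclude internal ATG and stop codons, including
  across codon junctions, so the planted start is the 5'-most for its stop.
* **Abundance cohorts.** Per-protein baselines `N(25, 2)` on the log2
  scale, within-group noise `N(0, σ = 0.5)`, planted effects added to the
  tumor group with alternating signs. Missingness is
  missing-not-at-random — logistic in intensity with midpoint at the 20th
  intensity percentile and slope 1 per log2 unit — plus a 2% floor of
  completely-random missingness. These rates are invented but fixed and
  stated, since processed proteomics matrices do not document their
  missingness mechanisms. Planted structure: `nCore` proteins expressed in
  every cohort and `nUniquePerCohort` in exactly one; background proteins
  are expressed in random cohort subsets of size 2..k−1 (k ≥ 3 cohorts), so
  the planted core and unique sets are exactly recoverable. With fewer than
  3 cohorts this guarantee lapses (background is then expressed
  everywhere) — a documented limitation.
* **Interactome lists.** A core present in every replicate plus
  per-replicate noise, each noise accession in exactly one replicate; and
  set pairs with an exactly planted overlap.
* **Junction counts.** Per sample, inclusion ~ Binomial(depth, p) with
  `p = 2ψ/(1+ψ)` for SE events (so the two-junction convention and its
  normalization cancel exactly in expectation) and `p = ψ` otherwise.

What the generator does **not** emulate: batch effects, TMT ratio
compression, shared-peptide quantification ambiguity, correlated proteins,
isoform-level splicing complexity, or any raw-spectrum property. Passing
recovery tests therefore demonstrates the correctness of the screening
logic under its stated model, not robustness to those real-data artifacts.

# Pipeline, problem sizes and reproducibility

`runPipeline()` executes the stages in dependency order from a single
configuration (YAML round-trip; every threshold surfaced with its default),
logs one structured line per stage to stderr, and writes a JSON report. A
rerun with the same configuration and seed reproduces byte-identical
tables. The thin CLI in `inst/scripts/lepscreen.R` exposes subcommands
(`generate`, `sorfs`, `digest`, `screen`, `sets`, `splice`, `run-all`) with
exit codes 0/1/2 for ok / input error / stage failure.

Default simulation sizes — 20 transcripts, 400 proteins over 4 cohorts of
10 + 10 samples, 4 interactome replicates, 12 splice events at depth 200,
and the 2000-protein null / 200-run PSI calibrations — were chosen so that
the complete validation suite exercises every recovery property in well
under a minute on a single CPU while keeping Monte-Carlo standard errors
small relative to the tolerances tested. Scaling the generators up is a
matter of configuration, not code.

# Known limitations

* Uniqueness is sequence-level only; spectral evidence, modifications and
  FDR control belong to the (external) search engine.
* The splicing test has no replicate-variance model; with many replicates
  and high depth its pooled Fisher p-values overstate certainty relative
  to a hierarchical caller.
* Fold changes with no observed values in one group are undefined and the
  protein is skipped, rather than imputed.
* Genomic (multi-exon) coordinates are not modeled; all ORF coordinates
  are transcript-space.

# A worked micro-example

```{r example}
tg <- genTranscriptome(seed = 92, nTranscripts = 1, orfLengths = 92L)
orfs <- findOrfs(tg$sequences, OrfParams(minLenAa = 20))
selectCanonicalOrf(orfs)[, c("transcript_id", "start", "end", "length_aa")]
```

The planted 92-residue ORF is recovered at its exact coordinates; the same
recovery logic, at scale, is what the test suite and the acceptance script
assert.
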