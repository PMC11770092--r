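# lepscreen

Discovery and pan-cancer screening of lncRNA-encoded microproteins (LEPs).

Many transcripts annotated as long noncoding RNAs carry small open reading
frames (sORFs) that are actively translated into microproteins, some with
oncogenic activity. Establishing that such a protein exists — and that it
matters across tumors — takes a chain of computational steps between the
transcript catalogue and the biology: find candidate sORFs, prove the
products are distinguishable from the reference proteome at the peptide
level, screen their abundance across tumor proteomics cohorts riddled with
missing values, intersect interactome lists from replicate pulldowns, and
quantify the splicing changes they drive. `lepscreen` implements that chain
as a tested, reusable R/Bioconductor-style package, with a seeded
synthetic-data generator so every stage is verifiable by parameter recovery
without downloading anything.

## What it computes

* **sORF discovery** — ATG-initiated ORFs with an in-frame stop, scanned in
  three frames (`findOrfs`); longest-ORF canonical selection
  (`selectCanonicalOrf`); candidate FASTA database emission.
* **Peptide uniqueness** — in-silico tryptic digestion (cleave after K/R,
  not before P, ≤ 2 missed cleavages, 7–50 aa) and classification of each
  peptide as `reference`, `shared_lep` or `unique_lep` against a hash index
  of the combined databases, with I/L treated as indistinguishable
  (`digestProtein`, `buildPeptideIndex`, `classifyPeptides`). A candidate is
  *peptide-supported* when it has ≥ 1 unique peptide.
* **Cohort screening** — the presence rule (identified in a cohort when
  quantified in > 30% of tumor *or* non-tumor samples), pan-cancer
  core/unique set analysis (flower-plot logic), and a differential screen:
  proteins quantified in > 50% of *both* groups, linear fold change of group
  means, Shapiro–Wilk-routed Student's *t* / Mann–Whitney U on log2
  intensities, significant when *p* < 0.05 and |FC| ≥ 1.5
  (`callPresence`, `panCancerSets`, `differentialExpression`).
* **Interactome sets** — replicate-consistent interactor lists
  (`replicateConsistentSet`), probe-minus-control differences and
  cross-experiment overlaps (`setdiff`/`intersect` on `ProteinSet`).
* **Splicing** — percent spliced in from junction counts with the SE
  two-junction normalization, PSI = (I/2) / (I/2 + E); two-sided Fisher
  exact tests for ΔPSI; event-type distributions; long/short isoform ratios
  (`computePsi`, `deltaPsiTest`, `isoformRatio`).
* **Synthetic data** — generators for every input with recorded ground
  truth (`genTranscriptome`, `genAbundanceCohort`,
  `genInteractomeReplicates`, `genJunctionCounts`).
* **Pipeline** — `runPipeline()` orchestrates all stages from one YAML
  config; `inst/scripts/lepscreen.R` is a thin CLI
  (`generate | sorfs | digest | screen | sets | splice | run-all`).

## Worked example

Plant a 92-residue ORF in a synthetic lncRNA and recover it:

```r
library(lepscreen)
tg   <- genTranscriptome(seed = 92, nTranscripts = 1, orfLengths = 92L)
orfs <- findOrfs(tg$sequences, OrfParams(minLenAa = 20))
selectCanonicalOrf(orfs)[, c("transcript_id", "start", "end", "frame", "length_aa")]
#>   transcript_id start end frame length_aa
#> 1     SYNTX0001   269 548     2        92
```

The canonical ORF is found at exactly the planted coordinates (0-based
half-open, stop codon included: 279 nt = 92 codons + stop) and translates
to a 92-residue microprotein.

Screen a nine-cohort synthetic pan-cancer matrix with three planted
universally expressed proteins:

```r
design <- data.frame(cohort = sprintf("c%d", 1:9), n_tumor = 12, n_nontumor = 12)
ga   <- genAbundanceCohort(777, design, nProteins = 400, deFraction = 0.1,
                           nCore = 3, nUniquePerCohort = 5,
                           missingModel = list(midQuantile = 0.1, slope = 1.5,
                                               mcarRate = 0.02))
sets <- panCancerSets(callPresence(ga$abundance))
sets$core
#> [1] "LEP0001" "LEP0002" "LEP0003"
head(sets$counts, 3)
#>   cohort n_identified n_unique
#> 1     c1          202        5
#> 2     c2          188        5
#> 3     c3          195        6
```

The three planted universal proteins are exactly the recovered core; each
cohort keeps its five planted cohort-unique proteins. Differential
screening in one cohort then flags planted effects with the test chosen by
the normality pre-test:

```r
de <- differentialExpression(ga$abundance, cohort = "c1")
head(de[!is.na(de$significant) & de$significant,
        c("protein", "log2fc", "p_value", "test_used")], 3)
#>    protein     log2fc      p_value    test_used
#> 6  LEP0006 -0.9601480 1.523982e-05    student_t
#> 66 LEP0066  0.8570482 5.528527e-04 mann_whitney
#> 84 LEP0084 -0.9211488 1.529934e-03    student_t
```

`log2fc` is the log2 ratio of tumor to non-tumor mean intensity (linear
scale, observed values only); a row is significant when *p* < 0.05 and the
linear fold change exceeds 1.5 either way.

The full chain — generate, scan, digest, screen, intersect, splice-test —
runs as one call:

```r
report <- runPipeline(defaultRunConfig(outDir = "run1", seed = 1))
```

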