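test_that("cleavage rule basics: K/R cut, proline protection, no-site protein", {
  p <- DigestParams(maxMissedCleavages = 0, minLen = 1, maxLen = 50)
  expect_equal(digestProtein("MKR", p)$sequence, c("MK", "R"))
  # no K or R: the whole sequence is the only peptide
  expect_equal(digestProtein("MGGAWGG", p)$sequence, "MGGAWGG")
  # K before P is protected
  expect_equal(digestProtein("MKPGGR", p)$sequence, "MKPGGR")
})

test_that("digestion equals brute-force fragment enumeration", {
  set.seed(99)
  for (i in 1:20) {
    prot <- randProtein(sample(30:200, 1))
    for (mm in 0:2) {
      p <- DigestParams(maxMissedCleavages = mm, minLen = 4, maxLen = 30)
      got <- digestProtein(prot, p)$sequence
      want <- bruteForceDigest(prot, mm, 4, 30)
      expect_setequal(got, want)
      expect_equal(length(got), length(want))
    }
  }
})

test_that("0-missed fragments concatenate back to the protein", {
  set.seed(5)
  for (i in 1:10) {
    prot <- randProtein(sample(20:120, 1))
    frag <- digestProtein(prot, DigestParams(maxMissedCleavages = 0,
                                             minLen = 1, maxLen = 1000))
    expect_equal(paste(frag$sequence, collapse = ""), prot)
  }
})

test_that("peptide index answers membership, I/L equivalence collapses lookup", {
  p <- DigestParams(minLen = 5, maxLen = 30, maxMissedCleavages = 1)
  ref <- data.frame(accession = c("R1", "R2"),
                    sequence = c("MAAAIKGGGGWK", "MCCCCCKDDDDDR"),
                    origin = "reference")
  idx <- buildPeptideIndex(ref, p)
  # self-containment: every tryptic peptide of R1 maps back to R1
  for (pep in digestProtein(ref$sequence[1], p)$sequence)
    expect_true("R1" %in% queryPeptide(idx, pep))
  expect_equal(queryPeptide(idx, "WWWWWWW"), character())
  # I <-> L variant hits the same protein under ilEquivalent
  expect_equal(queryPeptide(idx, "MAAALK"), queryPeptide(idx, "MAAAIK"))
  # without equivalence the variant misses
  idx2 <- buildPeptideIndex(ref, DigestParams(minLen = 5, maxLen = 30,
                                              maxMissedCleavages = 1,
                                              ilEquivalent = FALSE))
  expect_equal(queryPeptide(idx2, "MAAALK"), character())
  expect_error(buildPeptideIndex(rbind(ref, ref[1, ]), p), "duplicate")
})

test_that("peptide classification honors reference > shared > unique precedence", {
  p <- DigestParams(minLen = 5, maxLen = 30, maxMissedCleavages = 0)
  ref <- data.frame(accession = "REF1", sequence = "MAAAAAKWWWWWK",
                    origin = "reference")
  leps <- data.frame(accession = c("L1", "L2"),
                     sequence = c("MAAAAAKCCCCCK", "MDDDDDKCCCCCK"),
                     origin = "lep")
  idx <- buildPeptideIndex(rbind(ref, leps), p)
  calls <- classifyPeptides(c("MAAAAAK", "CCCCCK", "MDDDDDK", "EEEEEEE"), idx)
  expect_equal(calls$status,
               c("reference", "shared_lep", "unique_lep", "unmatched"))
  expect_equal(calls$matched_accessions[3], "L2")
  expect_error(classifyPeptide("MAAA*AK", idx), "non-amino-acid")
})

test_that("a planted homolog's shared peptides are never unique", {
  # LEP shares its first half (two tryptic peptides) with a reference protein
  shared <- "MAAAAAKGGGGGGR"
  lepTail <- "WWYYWWKHHHHHHK"
  refTail <- "CCCCCCKDDDDDDK"
  p <- DigestParams(minLen = 5, maxLen = 30, maxMissedCleavages = 0)
  db <- rbind(
    data.frame(accession = "REF", sequence = paste0(shared, refTail),
               origin = "reference"),
    data.frame(accession = "LEP", sequence = paste0(shared, lepTail),
               origin = "lep"))
  idx <- buildPeptideIndex(db, p)
  peps <- digestProtein(db$sequence[2], p)
  calls <- classifyPeptides(peps$sequence, idx)
  expect_equal(sum(calls$status == "reference"), 2L)   # the shared half
  expect_equal(sum(calls$status == "unique_lep"), 2L)  # the LEP-only half
})

test_that("unique-peptide counts match construction and support calls", {
  p <- DigestParams(minLen = 5, maxLen = 30, maxMissedCleavages = 0)
  ref <- data.frame(accession = "REF", sequence = "MAAAAAKGGGGGGR",
                    origin = "reference")
  leps <- rbind(
    data.frame(accession = "SAME", sequence = "MAAAAAKGGGGGGR",
               origin = "lep"),                       # identical to reference
    data.frame(accession = "NOVEL", sequence = "MWYWYWKHFHFHFK",
               origin = "lep"))                       # fully disjoint
  idx <- buildPeptideIndex(rbind(ref, leps), p)
  counts <- lepUniquePeptideCounts(leps, idx)
  expect_equal(counts$n_unique[counts$accession == "SAME"], 0L)
  novel <- counts[counts$accession == "NOVEL", ]
  expect_equal(novel$n_unique, novel$n_peptides)
  expect_equal(counts$peptide_supported, c(FALSE, TRUE))
})

test_that("per-LEP unique counts equal generator truth on a synthetic database", {
  set.seed(31)
  p <- DigestParams(minLen = 6, maxLen = 40, maxMissedCleavages = 1)
  nRef <- 30; nLep <- 25
  ref <- data.frame(accession = sprintf("REF%02d", 1:nRef),
                    sequence = vapply(1:nRef, function(i) randProtein(120),
                                      character(1)),
                    origin = "reference")
  leps <- data.frame(accession = sprintf("LEP%02d", 1:nLep),
                     sequence = vapply(1:nLep, function(i) randProtein(70),
                                       character(1)),
                     origin = "lep")
  idx <- buildPeptideIndex(rbind(ref, leps), p)
  counts <- lepUniquePeptideCounts(leps, idx)
  refPeps <- unique(chartr("I", "L", unlist(
    lapply(ref$sequence, function(s) bruteForceDigest(s, 1, 6, 40)))))
  allLepPeps <- lapply(leps$sequence,
                       function(s) unique(chartr("I", "L",
                                                 bruteForceDigest(s, 1, 6, 40))))
  for (i in seq_len(nLep)) {
    mine <- allLepPeps[[i]]
    others <- unique(unlist(allLepPeps[-i]))
    wantUnique <- sum(!mine %in% refPeps & !mine %in% others)
    expect_equal(counts$n_unique[i], wantUnique)
  }
})

test_that("I/L collapsing can only shrink the unique set", {
  set.seed(77)
  for (i in 1:5) {
    ref <- data.frame(accession = "R", sequence = randProtein(150),
                      origin = "reference")
    lep <- data.frame(accession = "L", sequence = randProtein(60),
                      origin = "lep")
    db <- rbind(ref, lep)
    pIL <- DigestParams(minLen = 5, maxLen = 40, ilEquivalent = TRUE)
    pNo <- DigestParams(minLen = 5, maxLen = 40, ilEquivalent = FALSE)
    nIL <- lepUniquePeptideCounts(lep, buildPeptideIndex(db, pIL))$n_unique
    nNo <- lepUniquePeptideCounts(lep, buildPeptideIndex(db, pNo))$n_unique
    expect_lte(nIL, nNo)
  }
})

test_that("substring mode is at least as strict as tryptic mode", {
  p <- DigestParams(minLen = 5, maxLen = 30, maxMissedCleavages = 0)
  # peptide is an internal substring of REF but not one of its tryptic peptides
  ref <- data.frame(accession = "REF", sequence = "MAAACCCCCDDDAAAK",
                    origin = "reference")
  lep <- data.frame(accession = "LEP", sequence = "MCCCCCDDDK",
                    origin = "lep")
  idx <- buildPeptideIndex(rbind(ref, lep), p)
  expect_equal(classifyPeptides("MCCCCCDDDK", idx, "tryptic")$status,
               "unique_lep")
  expect_equal(queryPeptide(idx, "CCCCCDDD", "substring"),
               c("REF", "LEP"))
})

test_that("UniProt-style and plain FASTA headers are both parsed", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P12345|NAME_HUMAN Description", "MAAAK",
               ">PLAIN2 other words", "MCCCK"), path)
  db <- readProteome(path, "reference")
  expect_equal(db$accession, c("P12345", "PLAIN2"))
  expect_equal(db$sequence, c("MAAAK", "MCCCK"))
})
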