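# helper: build a LEPAbundance from a plain matrix of log2 values
makeAb <- function(log2mat, cohort, group, pair_id = NULL) {
  info <- data.frame(sample_id = colnames(log2mat), cohort = cohort,
                     group = group)
  if (!is.null(pair_id)) info$pair_id <- pair_id
  LEPAbundance(2^log2mat, info)
}

test_that("presence rule is strict: 40% passes, exactly 30% does not", {
  m <- matrix(NA_real_, 2, 20,
              dimnames = list(c("P40", "P30"),
                              c(sprintf("T%02d", 1:10), sprintf("N%02d", 1:10))))
  m["P40", 1:4] <- 20          # 4/10 tumor
  m["P30", 1:3] <- 20          # 3/10 tumor
  m["P30", 11:13] <- 20        # 3/10 nontumor
  ab <- LEPAbundance(2^m, data.frame(sample_id = colnames(m), cohort = "kid",
                                     group = rep(c("tumor", "nontumor"),
                                                 each = 10)))
  pres <- callPresence(ab)
  expect_true(pres$identified[pres$protein == "P40"])
  expect_false(pres$identified[pres$protein == "P30"])
  expect_equal(pres$frac_tumor[pres$protein == "P30"], 0.3)
})

test_that("identification frequency matches the binomial closed form", {
  set.seed(202)
  n <- 10; pi <- 0.35; nProt <- 1000
  present <- matrix(runif(nProt * n) < pi, nProt, n)
  m <- matrix(20, nProt, n,
              dimnames = list(sprintf("P%04d", 1:nProt), sprintf("T%02d", 1:n)))
  m[!present] <- NA
  ab <- LEPAbundance(2^m, data.frame(sample_id = colnames(m), cohort = "c",
                                     group = "tumor"))
  pres <- callPresence(ab)
  pHit <- 1 - stats::pbinom(floor(0.3 * n), n, pi)  # P(X/n > 0.3) = P(X >= 4)
  se <- sqrt(pHit * (1 - pHit) / nProt)
  expect_lt(abs(mean(pres$identified) - pHit), 3 * se)
})

test_that("raising the presence threshold never adds identified proteins", {
  set.seed(11)
  m <- matrix(ifelse(runif(600) < 0.5, 20, NA), 30, 20,
              dimnames = list(sprintf("P%02d", 1:30), sprintf("S%02d", 1:20)))
  ab <- LEPAbundance(2^m, data.frame(sample_id = colnames(m), cohort = "c",
                                     group = rep(c("tumor", "nontumor"), 10)))
  prev <- NULL
  for (f in c(0.2, 0.3, 0.5, 0.7)) {
    ids <- callPresence(ab, ScreenParams(presenceFrac = f))
    cur <- ids$protein[ids$identified]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("a cohort with no samples in either group is an error", {
  m <- matrix(20, 1, 2, dimnames = list("P", c("a", "b")))
  info <- data.frame(sample_id = c("a", "b"), cohort = "c",
                     group = c("tumor", "nontumor"))
  ab <- LEPAbundance(2^m, info)
  expect_silent(callPresence(ab))
  expect_error(differentialExpression(ab, cohort = "nope"), "nope")
})

test_that("pan-cancer sets: single cohort, disjoint cohorts, partition identity", {
  one <- panCancerSets(list(kid = c("A", "B")))
  expect_equal(one$core, c("A", "B"))
  expect_equal(one$unique$kid, c("A", "B"))

  two <- panCancerSets(list(x = c("A", "B"), y = c("C")))
  expect_equal(two$core, character())
  expect_equal(two$unique$x, c("A", "B"))
  expect_equal(two$unique$y, "C")

  set.seed(8)
  ids <- lapply(1:5, function(i) sample(LETTERS, sample(5:15, 1)))
  names(ids) <- paste0("c", 1:5)
  ps <- panCancerSets(ids)
  all_ids <- unique(unlist(ids))
  shared_not_core <- base::setdiff(all_ids,
                                   c(ps$core, unlist(ps$unique)))
  # core, the unique sets, and shared-but-not-core partition the union
  expect_setequal(c(ps$core, unlist(ps$unique), shared_not_core), all_ids)
  expect_equal(length(ps$core) + sum(lengths(ps$unique)) +
                 length(shared_not_core), length(all_ids))
  for (i in 1:5) for (j in setdiff(1:5, i))
    expect_length(base::intersect(ps$unique[[i]], ps$unique[[j]]), 0)
  expect_length(base::intersect(ps$core, unlist(ps$unique)), 0)
})

test_that("planted universal proteins are exactly the recovered core", {
  design <- data.frame(cohort = sprintf("c%d", 1:9), n_tumor = 12,
                       n_nontumor = 12)
  ga <- genAbundanceCohort(606, design, nProteins = 300, deFraction = 0,
                           nCore = 3, nUniquePerCohort = 4,
                           missingModel = list(midQuantile = 0.05,
                                               slope = 2, mcarRate = 0.01))
  sets <- panCancerSets(callPresence(ga$abundance))
  expect_equal(sets$core, ga$truth$core)
  expect_equal(length(sets$core), 3L)
})

test_that("identical groups give log2fc 0 and no significance", {
  m <- matrix(20, 2, 12, dimnames = list(c("P1", "P2"), sprintf("S%02d", 1:12)))
  m["P2", ] <- rep(c(18, 19, 20, 21, 22, 23), 2)   # same values in both groups
  ab <- makeAb(m, "c", rep(c("tumor", "nontumor"), each = 6))
  de <- differentialExpression(ab)
  expect_equal(de$log2fc, c(0, 0))
  expect_false(any(de$significant))
})

test_that("proteins below the 50% rule are excluded with a reason", {
  m <- matrix(rnorm(40, 20), 2, 20,
              dimnames = list(c("OK", "SPARSE"), sprintf("S%02d", 1:20)))
  m["SPARSE", 1:6] <- NA       # 4/10 = 40% observed in tumor
  ab <- makeAb(m, "c", rep(c("tumor", "nontumor"), each = 10))
  de <- differentialExpression(ab)
  expect_equal(de$skip_reason[de$protein == "SPARSE"], "presence_filter")
  expect_true(is.na(de$p_value[de$protein == "SPARSE"]))
  expect_true(is.na(de$skip_reason[de$protein == "OK"]))
  # an all-missing protein is a skip record, not an exception
  m2 <- m; m2["SPARSE", ] <- NA
  de2 <- differentialExpression(makeAb(m2, "c",
                                       rep(c("tumor", "nontumor"), each = 10)))
  expect_equal(de2$skip_reason[de2$protein == "SPARSE"], "all_missing")
})

test_that("swapping group labels negates log2fc and keeps p-values", {
  set.seed(99)
  m <- matrix(rnorm(30 * 24, 20, 1), 30, 24,
              dimnames = list(sprintf("P%02d", 1:30), sprintf("S%02d", 1:24)))
  g <- rep(c("tumor", "nontumor"), each = 12)
  de1 <- differentialExpression(makeAb(m, "c", g))
  de2 <- differentialExpression(makeAb(m, "c", rev(g)))
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$p_value, de2$p_value)
  expect_equal(de1$test_used, de2$test_used)
})

test_that("non-normal data are routed to the Mann-Whitney test", {
  set.seed(4)
  n <- 15
  tumor <- 2^rnorm(n, 21, 0.5)
  nont <- 2^rnorm(n, 20, 0.5)
  nont[1:4] <- nont[1:4] * 1000    # heavy outliers break normality
  m <- matrix(log2(c(tumor, nont)), 1, 2 * n,
              dimnames = list("P", sprintf("S%02d", 1:(2 * n))))
  ab <- makeAb(m, "c", rep(c("tumor", "nontumor"), each = n))
  de <- differentialExpression(ab)
  expect_equal(de$test_used, "mann_whitney")
  gm <- rnorm(n, 20, 0.3)
  m2 <- matrix(c(gm + 1, gm), 1, 2 * n,
               dimnames = list("P", sprintf("S%02d", 1:(2 * n))))
  de2 <- differentialExpression(makeAb(m2, "c",
                                       rep(c("tumor", "nontumor"), each = n)))
  expect_equal(de2$test_used, "student_t")
})

test_that("fold change is computed on linear-scale means of observed values", {
  tu <- c(4, 8, 16, 32, 64, NA)
  nt <- c(2, 4, 8, 16, 32, 64)
  m <- matrix(log2(c(tu, nt)), 1, 12,
              dimnames = list("P", sprintf("S%02d", 1:12)))
  ab <- makeAb(m, "c", rep(c("tumor", "nontumor"), each = 6))
  de <- differentialExpression(ab)
  expect_equal(de$log2fc, log2(mean(tu, na.rm = TRUE) / mean(nt)))
})

test_that("Benjamini-Hochberg option only removes significant calls", {
  set.seed(12)
  m <- matrix(rnorm(50 * 20, 20, 0.5), 50, 20,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:20)))
  m[1:5, 1:10] <- m[1:5, 1:10] + 2
  ab <- makeAb(m, "c", rep(c("tumor", "nontumor"), each = 10))
  raw <- differentialExpression(ab)
  bh <- differentialExpression(ab, ScreenParams(pAdjust = "BH"))
  expect_true(all(which(bh$significant) %in% which(raw$significant)))
  expect_true(all(bh$significant[1:5]))
})

test_that("length histogram bins are left-closed right-open", {
  h <- lengthHistogram(92, c(0, 50, 200, 1000))
  expect_equal(h$count, c(0L, 1L, 0L))
  h2 <- lengthHistogram(c(50, 199, 200), c(0, 50, 200, 1000))
  expect_equal(h2$count, c(0L, 2L, 1L))
  expect_equal(sum(h2$fraction), 1)
  empty <- lengthHistogram(integer(), c(0, 50, 200))
  expect_equal(empty$count, c(0L, 0L))
  expect_error(lengthHistogram(10, c(0, 200, 50)), "increasing")
  expect_error(lengthHistogram(-5, c(-10, 0, 10)), "positive")
})

test_that("histogram fractions recover mixture weights within 3 SE", {
  set.seed(66)
  n <- 2000; w <- 0.7    # 70% short (50-200), 30% long (200-1000)
  lens <- ifelse(runif(n) < w, sample(50:199, n, TRUE),
                 sample(200:999, n, TRUE))
  h <- lengthHistogram(lens, c(0, 50, 200, 1000))
  se <- sqrt(w * (1 - w) / n)
  expect_lt(abs(h$fraction[2] - w), 3 * se)
})

test_that("abundance matrices round-trip through TSV", {
  design <- data.frame(cohort = c("a", "b"), n_tumor = 4, n_nontumor = 4)
  ga <- genAbundanceCohort(77, design, nProteins = 40, nCore = 2,
                           nUniquePerCohort = 2)
  v <- withr::local_tempfile(fileext = ".tsv")
  s <- withr::local_tempfile(fileext = ".tsv")
  writeAbundance(ga$abundance, v, s)
  back <- readAbundance(v, s)
  expect_equal(intensities(back), intensities(ga$abundance))
  expect_equal(sampleGroup(back), sampleGroup(ga$abundance))
  expect_equal(sampleCohort(back), sampleCohort(ga$abundance))
})
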