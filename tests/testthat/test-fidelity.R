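# Alignment input, trimming, filtering, variant masking and the
# mismatch statistic, checked against naive per-base oracles.

refSeq40 <- paste(rep("ACGT", 10), collapse = "")

test_that("SAM round trip preserves reads and handles edge cases", {
  # empty SAM (header only)
  sam <- tempfile(fileext = ".sam")
  fa <- tempfile(fileext = ".fa")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:40"), sam)
  writeLines(c(">ref", refSeq40), fa)
  empty <- readAlignments(sam, fa)
  expect_equal(length(empty), 0)
  expect_equal(length(computeErrorTable(empty)@readPos), 0)

  # one read identical to its reference window: zero mismatches
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:40",
               paste("r1", 0, "ref", 5, 255, "8M", "*", 0, 0,
                     substr(refSeq40, 5, 12), "IIIIIIII", sep = "\t")),
             sam)
  one <- readAlignments(sam, fa)
  expect_equal(one@mismatches, 0L)
  expect_true(one@unique)

  # non single-M CIGAR skipped with a warning
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:40",
               paste("r1", 0, "ref", 1, 255, "4M1I3M", "*", 0, 0,
                     "ACGTAACG", "IIIIIIII", sep = "\t"),
               paste("r2", 0, "ref", 1, 255, "8M", "*", 0, 0,
                     substr(refSeq40, 1, 8), "IIIIIIII", sep = "\t")),
             sam)
  expect_warning(two <- readAlignments(sam, fa), "CIGAR")
  expect_equal(two@id, "r2")

  # secondary alignments lose the uniqueness flag
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:40",
               paste("r1", 256, "ref", 1, 255, "8M", "*", 0, 0,
                     substr(refSeq40, 1, 8), "IIIIIIII", sep = "\t")),
             sam)
  sec <- readAlignments(sam, fa)
  expect_false(sec@unique)
})

test_that("simulated SAM mismatch counts equal truth-table resolution", {
  cfg <- SimConfig(genomeLength = 4000, nReads = 800, readLength = 50,
                   errorMatrix = uniformErrorMatrix(2e-3),
                   snvFraction = 0.01, qualityMean = 25, qualitySd = 3,
                   reverseStrandFraction = 0.3, seed = 23)
  fx <- simFixture(cfg)
  expect_equal(length(fx$reads), 800)
  # reader restores sequencing orientation: sequences match the simulator
  ord <- match(fx$sim@id, fx$reads@id)
  expect_identical(fx$reads@seq[ord], fx$sim@seq)
  expect_identical(fx$reads@strand[ord], fx$sim@strand)
  expect_identical(matrix(unlist(fx$reads@qual[ord]), nrow = 800,
                          byrow = TRUE), unname(fx$sim@qual))
  expected <- truthMismatchCounts(fx$sim)
  expect_identical(unname(fx$reads@mismatches[ord]),
                   unname(as.integer(expected[fx$sim@id])))
  unlink(fx$dir, recursive = TRUE)
})

test_that("trimming is exact index arithmetic on bases and qualities", {
  cfg <- SimConfig(genomeLength = 2000, nReads = 100, readLength = 50,
                   errorMatrix = uniformErrorMatrix(5e-3),
                   reverseStrandFraction = 0.5, seed = 31)
  fx <- simFixture(cfg)
  reads <- fx$reads

  # identity trim
  same <- trimReads(reads, keepFirst = 50, dropFirst = 0)
  expect_identical(same@seq, reads@seq)
  expect_identical(same@start0, reads@start0)

  # drop 2, keep 40: base 1 of the trimmed read was original base 3
  tr <- trimReads(reads, keepFirst = 40, dropFirst = 2)
  expect_identical(substr(tr@seq, 1, 1), substr(reads@seq, 3, 3))
  expect_identical(unlist(tr@qual[[1]]), reads@qual[[1]][3:42])
  # every retained base keeps its reference position: recounted
  # mismatches never exceed the originals
  expect_true(all(tr@mismatches <= reads@mismatches))

  # the error profile shifts by exactly dropFirst positions
  full <- computeErrorTable(reads, qmin = 0)
  trimmed <- computeErrorTable(tr, qmin = 0)
  expect_identical(trimmed@N, full@N[3:42])
  expect_identical(trimmed@M, full@M[3:42])
  expect_identical(unname(trimmed@subCounts), unname(full@subCounts[3:42, ]))

  expect_error(trimReads(reads, keepFirst = 49, dropFirst = 2), "exceeds")
  expect_error(trimReads(reads, keepFirst = 0), "positive")
  unlink(fx$dir, recursive = TRUE)
})

test_that("alignment filtering matches a brute-force predicate scan", {
  cfg <- SimConfig(genomeLength = 2000, nReads = 500, readLength = 40,
                   errorMatrix = uniformErrorMatrix(0.02),
                   qualityMean = 20, qualitySd = 4, seed = 37)
  fx <- simFixture(cfg)
  reads <- fx$reads
  expect_gt(max(reads@mismatches), 3)  # fixture exercises the cut

  kept <- filterAlignments(reads, maxMismatches = 3, uniqueOnly = TRUE)
  wanted <- vapply(seq_along(reads@id), function(i)
    reads@mismatches[i] <= 3 && reads@unique[i], TRUE)
  expect_identical(sort(kept@id), sort(reads@id[wanted]))

  # identity when both predicates are disabled
  all <- filterAlignments(reads, maxMismatches = Inf, uniqueOnly = FALSE)
  expect_equal(length(all), length(reads))
  unlink(fx$dir, recursive = TRUE)
})

test_that("variant mask applies the frequency-consensus definition", {
  # all reads agree with the reference: empty mask
  ref <- refSeq40
  agree <- makeAlignedReads(rep(substr(ref, 1, 20), 12), rep(0, 12), 40, ref)
  expect_equal(length(callVariantMask(agree)), 0)

  # 10 reads all showing the same alt base at one position
  alt <- paste0(substr(ref, 1, 9), "T", substr(ref, 11, 20))  # pos0 9: G->T
  ten <- makeAlignedReads(rep(alt, 10), rep(0, 10), 40, ref)
  m <- callVariantMask(ten, minCoverage = 5, altFraction = 0.8)
  expect_identical(maskedPositions(m), 9L)
  expect_equal(as.data.frame(m@evidence)$altBase, "T")
  expect_equal(as.data.frame(m@evidence)$altFraction, 1)

  # low-quality alt calls do not count towards the mask
  lowq <- makeAlignedReads(rep(alt, 10), rep(0, 10), 20, ref)
  expect_equal(length(callVariantMask(lowq, minCoverage = 5, qmin = 30)), 0)

  # tied alternative bases mask on their combined fraction
  altA <- paste0(substr(ref, 1, 9), "A", substr(ref, 11, 20))
  tie <- makeAlignedReads(c(rep(alt, 5), rep(altA, 5)), rep(0, 10), 40, ref)
  expect_message(mTie <- callVariantMask(tie, minCoverage = 5,
                                         altFraction = 0.8), "tied")
  expect_identical(maskedPositions(mTie), 9L)

  expect_error(callVariantMask(ten, altFraction = 0.4), "altFraction")
})

test_that("variant mask recovers true variants and nothing else", {
  cfg <- SimConfig(genomeLength = 10000, nReads = 10000, readLength = 50,
                   errorMatrix = makeErrorMatrix(c("C>T" = 1e-3)),
                   snvFraction = 0.005, seed = 41)
  fx <- simFixture(cfg)
  reads <- filterAlignments(fx$reads)
  mask <- callVariantMask(reads, minCoverage = 10, altFraction = 0.8)
  truePos <- as.data.frame(variantTable(fx$sim@genome))$pos0

  cov <- tabulate(unlist(lapply(seq_along(reads@id), function(i)
    reads@start0[i] + 1:50)), nbins = 10000)
  wellCovered <- truePos[cov[truePos + 1] >= 20]
  expect_gte(mean(wellCovered %in% maskedPositions(mask)), 0.95)
  # no position without a true variant is masked at coverage >= 20
  false <- setdiff(maskedPositions(mask), truePos)
  expect_equal(false[cov[false + 1] >= 20], integer(0))
  unlink(fx$dir, recursive = TRUE)
})

test_that("VCF and TSV mask files round-trip", {
  cfg <- SimConfig(genomeLength = 1000, nReads = 50, readLength = 30,
                   snvFraction = 0.01, seed = 43)
  sim <- simulateReads(cfg)
  files <- writeSimulatedReads(sim, tempfile("mask"))
  truePos <- as.data.frame(variantTable(sim@genome))$pos0
  expect_identical(maskedPositions(readVariantMask(files[["variantsVcf"]])),
                   truePos)
  expect_identical(maskedPositions(readVariantMask(files[["variantsTsv"]])),
                   truePos)
  expect_identical(maskedPositions(variantMaskFromPositions(c(5, 2, 5))),
                   c(2L, 5L))
  unlink(dirname(files[["sam"]]), recursive = TRUE)
})

test_that("mismatch events obey the inclusion predicates", {
  ref <- refSeq40
  # read with one high-quality mismatch, one low-quality mismatch and
  # one mismatch at a masked position
  rd <- paste0("T", substr(ref, 2, 9), "A", "T", substr(ref, 12, 20))
  # pos0 0: A->T (Q40); pos0 9: G->A (Q29); pos0 10: C->T (Q40, masked)
  q <- c(40L, rep(40L, 8), 29L, rep(40L, 10))
  ar <- makeAlignedReads(rd, 0, list(q), ref)
  mask <- variantMaskFromPositions(10)
  ev <- as.data.frame(extractMismatches(ar, mask, qmin = 30))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$readPos, 1)
  expect_equal(ev$refBase, "A")
  expect_equal(ev$readBase, "T")

  # below-threshold quality boundary: Phred 30 passes, 29 does not
  q30 <- q; q30[10] <- 30L
  ev30 <- as.data.frame(extractMismatches(makeAlignedReads(rd, 0,
                                                           list(q30), ref),
                                          mask, qmin = 30))
  expect_equal(nrow(ev30), 2)

  # N in read or reference excluded from numerator and denominator
  refN <- paste0("N", substr(ref, 2, 40))
  arN <- makeAlignedReads(substr(ref, 1, 10), 0, 40, refN)
  tabN <- computeErrorTable(arN)
  expect_equal(tabN@N[1], 0L)
  expect_true(is.na(errorRate(tabN)[1]))
})

test_that("error table equals the naive double-loop recount exactly", {
  cfg <- SimConfig(genomeLength = 3000, nReads = 400, readLength = 40,
                   errorMatrix = uniformErrorMatrix(5e-3),
                   snvFraction = 0.01, qualityMean = 32, qualitySd = 4,
                   reverseStrandFraction = 0.3, seed = 47)
  fx <- simFixture(cfg)
  reads <- filterAlignments(fx$reads)
  mask <- callVariantMask(reads, minCoverage = 4, altFraction = 0.8)
  for (qmin in c(0L, 30L)) {
    tab <- computeErrorTable(reads, mask, qmin = qmin)
    oracle <- bruteForceCounts(reads, maskedPositions(mask), qmin = qmin)
    expect_identical(tab@N, oracle$N)
    expect_identical(tab@M, oracle$M)
    expect_identical(unname(tab@subCounts), unname(oracle$S))
    # decomposition: substitution counts partition the numerator
    expect_identical(rowSums(tab@subCounts), as.numeric(tab@M))
  }
  unlink(fx$dir, recursive = TRUE)
})

test_that("single-read arithmetic and rate accessors behave", {
  ref <- refSeq40
  rd <- paste0(substr(ref, 1, 2), "A", substr(ref, 4, 10))  # pos 3: G->A
  ar <- makeAlignedReads(rd, 0, 40, ref)
  tab <- computeErrorTable(ar)
  e <- errorRate(tab)
  expect_equal(e[3], 100)
  expect_equal(e[-3], rep(0, 9))
  expect_equal(as.numeric(specificErrorRate(tab, 3, "G>A")), 100)
  expect_equal(as.numeric(specificErrorRate(tab, 3, "C>T")), 0)
  expect_error(specificErrorRate(tab, 3, "G>G"), "unknown substitution")
  expect_error(specificErrorRate(tab, 99, "G>A"), "not in table")

  # comparing a table with itself gives 100 percent
  cmp <- compareSamples(tab, tab, 3, "G>A")
  expect_equal(cmp$ratioPercent, 100)

  # plain ratio arithmetic: 0.002% over 0.001% is 200%
  mk <- function(m, n) {
    sc <- matrix(0L, 1, 12, dimnames = list(NULL, substitutionTypes()))
    sc[1, "C>T"] <- m
    new("ErrorRateTable", readPos = 1L, N = n, M = m, subCounts = sc,
        qmin = 30L, nMasked = 0L)
  }
  cmp2 <- compareSamples(mk(2L, 100000L), mk(1L, 100000L), 1, "C>T")
  expect_equal(cmp2$ratioPercent, 200)
  expect_error(compareSamples(mk(1L, 100L), mk(0L, 100L), 1, "C>T"),
               "zero")
})

test_that("raising qmin or enlarging the mask never adds events", {
  cfg <- SimConfig(genomeLength = 3000, nReads = 500, readLength = 40,
                   errorMatrix = uniformErrorMatrix(5e-3),
                   snvFraction = 0.01, qualityMean = 30, qualitySd = 5,
                   seed = 53)
  fx <- simFixture(cfg)
  reads <- filterAlignments(fx$reads)
  key <- function(ev) paste(ev$id, ev$readPos)

  # threshold monotonicity: counted events at q2 > q1 are a subset
  for (pair in list(c(20, 30), c(30, 35), c(0, 38))) {
    e1 <- as.data.frame(extractMismatches(reads, qmin = pair[1]))
    e2 <- as.data.frame(extractMismatches(reads, qmin = pair[2]))
    expect_true(all(key(e2) %in% key(e1)))
  }

  # masking monotonicity: a larger mask never increases any M(p, s)
  truePos <- as.data.frame(variantTable(fx$sim@genome))$pos0
  small <- variantMaskFromPositions(truePos[1:10])
  large <- variantMaskFromPositions(c(truePos, 0:50))
  tSmall <- computeErrorTable(reads, small)
  tLarge <- computeErrorTable(reads, large)
  expect_true(all(tLarge@subCounts <= tSmall@subCounts))
  expect_true(all(tLarge@M <= tSmall@M))
  unlink(fx$dir, recursive = TRUE)
})

test_that("specific rates recover the configured transcription rate", {
  # sequencing channel off, no variants: E(p, C>T) ~ rate among C sites
  rate <- 2e-3
  cfg <- SimConfig(genomeLength = 20000, nReads = 30000, readLength = 50,
                   errorMatrix = makeErrorMatrix(c("C>T" = rate)),
                   snvFraction = 0, qualityMean = 93, qualitySd = 0,
                   qualityMax = 93, seed = 7)
  fx <- simFixture(cfg)
  reads <- filterAlignments(fx$reads)
  tab <- computeErrorTable(reads, qmin = 30)

  refc <- strsplit(as.character(referenceSeq(fx$sim@genome)), "")[[1]]
  nC <- vapply(1:50, function(p) sum(refc[reads@start0 + p] == "C"), 1)
  for (p in 1:50) {
    expM <- nC[p] * rate
    expect_lt(abs(tab@subCounts[p, "C>T"] - expM), 3 * sqrt(expM),
              label = sprintf("position %d", p))
  }
  unlink(fx$dir, recursive = TRUE)
})
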