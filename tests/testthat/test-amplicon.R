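test_that("detectPalindromes applies the identity/arm/spacer/repeat rules", {
  seg <- function(q1, q2, t1, t2, strand = "-", id = 0.985)
    alignmentSegments(GRanges("c", IRanges(q1, q2)),
                      GRanges("c", IRanges(t1, t2)), strand, id)

  # arms 10 kb, 98.5% identity, spacer 100 kb, no repeats: one palindrome
  good <- detectPalindromes(seg(1, 10000, 110001, 120000))
  expect_equal(nrow(good), 1L)
  expect_equal(good$armLength, 10000)
  expect_equal(good$spacer, 100000)

  # arm one base under 8 kb is rejected
  expect_equal(nrow(detectPalindromes(seg(1, 7999, 110001, 117999))), 0L)
  # identity below 98% is rejected
  expect_equal(nrow(detectPalindromes(seg(1, 10000, 110001, 120000,
                                          id = 0.97))), 0L)
  # spacer beyond 500 kb is rejected
  expect_equal(nrow(detectPalindromes(seg(1, 10000, 610001, 620000))), 0L)
  # plus-strand (direct) duplications are not palindromes
  expect_equal(nrow(detectPalindromes(seg(1, 10000, 110001, 120000,
                                          strand = "+"))), 0L)
  # repeat-saturated span is rejected
  reps <- GRanges("c", IRanges(1, 120000))
  expect_equal(nrow(detectPalindromes(seg(1, 10000, 110001, 120000),
                                      repeats = reps)), 0L)
})

test_that("detectPalindromes chains co-linear inverted segments", {
  # one 12-kb arm split into three pieces with small gaps
  segs <- alignmentSegments(
    GRanges("c", IRanges(c(1, 4501, 9001), c(4000, 8500, 12000))),
    GRanges("c", IRanges(c(58001, 53501, 50001), c(62000, 57500, 53000))),
    "-", c(0.99, 0.99, 0.99))
  pal <- detectPalindromes(segs)
  expect_equal(nrow(pal), 1L)
  expect_equal(pal$arm1Start, 1)
  expect_equal(pal$arm1End, 12000)
  expect_equal(pal$arm2Start, 50001)
  expect_equal(pal$arm2End, 62000)
})

test_that("planted palindrome is recovered exactly; decoys are rejected", {
  sc <- defaultScenario()
  pal <- detectPalindromes(selfSegments(sc), scenarioRepeats(sc))
  expect_equal(nrow(pal), 1L)
  truth <- truthPalindromes(sc)
  expect_equal(pal$chrom, as.character(seqnames(truth)))
  expect_lte(abs(pal$arm1Start - start(truth)), 100)
  expect_lte(abs(pal$arm2End - end(truth)), 100)
  expect_gte(pal$identity, 0.98)
})

test_that("detectArrays applies coverage, identity, and length rules", {
  # window covered 60% at 99.5% identity by a non-self-locus hit
  sizes <- c(s = 9000)
  hit <- alignmentSegments(GRanges("s", IRanges(1, 4000)),
                           GRanges("other", IRanges(1, 4000)),
                           "+", 0.995)
  got <- detectArrays(sizes, hit)
  expect_equal(length(got), 0L)  # merged run 5 kb < 10 kb

  # identity at or below 99% is not retained
  lowId <- alignmentSegments(GRanges("s", IRanges(1, 4000)),
                             GRanges("other", IRanges(1, 4000)), "+", 0.99)
  expect_equal(length(detectArrays(sizes, lowId)), 0L)

  # a hit whose target overlaps the window itself is a self-locus hit
  selfHit <- alignmentSegments(GRanges("s", IRanges(1, 4000)),
                               GRanges("s", IRanges(500, 4500)), "+", 0.995)
  expect_equal(length(detectArrays(sizes, selfHit)), 0L)

  # long coverage passes the merged-length rule
  sizes2 <- c(s = 30000)
  hits2 <- alignmentSegments(GRanges("s", IRanges(1, 15000)),
                             GRanges("other", IRanges(1, 15000)),
                             "+", 0.995)
  got2 <- detectArrays(sizes2, hits2)
  expect_equal(length(got2), 1L)
  expect_gte(width(got2), 10000)
})

test_that("the planted tandem array is recovered within one window", {
  sc <- defaultScenario()
  labels <- truthLabels(sc)
  sexScafs <- names(labels)[labels %in% c("X_div", "Y_div")]
  arr <- detectArrays(scenarioSizes(sc)[sexScafs], selfSegments(sc))
  truth <- truthArrays(sc)
  onX2 <- arr[as.character(seqnames(arr)) == "X2"]
  expect_equal(length(onX2), 1L)
  expect_lte(abs(start(onX2) - start(truth)), 3000)
  expect_lte(abs(end(onX2) - end(truth)), 3000)
  # output is invariant to window enumeration order (shuffle the sizes)
  arrRev <- detectArrays(rev(scenarioSizes(sc)[sexScafs]), selfSegments(sc))
  expect_setequal(paste(seqnames(arr), start(arr), end(arr)),
                  paste(seqnames(arrRev), start(arrRev), end(arrRev)))
  # every array call overlaps a planted amplicon (array or palindrome arm)
  planted <- suppressWarnings(
    c(granges(truth), granges(truthPalindromes(sc))))
  for (i in seq_along(arr))
    expect_gt(overlapFraction(arr[i], planted), 0)
})

test_that("gcCorrectDepth removes a planted bias and preserves the median", {
  # uniform GC: correction is the identity
  gr <- GRanges("c", IRanges(seq(1, 5000 * 100, 5000), width = 5000))
  d <- windowTrack(gr, rnorm(100, 30, 1))
  g <- windowTrack(gr, rep(0.4, 100))
  expect_equal(trackValues(gcCorrectDepth(d, g)), trackValues(d))

  # sinusoidal bias on a large synthetic track: correlation collapses
  set.seed(23)
  n <- 2000
  gr2 <- GRanges("c", IRanges(seq(1, 5000 * n, 5000), width = 5000))
  gc <- 0.42 + 0.08 * sin(seq_len(n) / 12)
  mu <- 30 * (1 + 1.5 * (gc - 0.42))
  depth <- windowTrack(gr2, rnbinom(n, mu = mu * 33, size = 200) / 33)
  gcT <- windowTrack(gr2, gc)
  corrected <- gcCorrectDepth(depth, gcT)
  expect_gt(abs(cor(trackValues(depth), gc)), 0.5)
  expect_lt(abs(cor(trackValues(corrected), gc)), 0.05)
  expect_equal(median(trackValues(corrected)), median(trackValues(depth)),
               tolerance = 0.01)
})

test_that("reference-based GC correction shrinks the bias on the scenario", {
  sc <- bigAutosomeScenario()
  autos <- c("A1", "A2", "A3")
  corr <- gcCorrectDepth(depthTrack(sc, "male"), gcTrack(sc),
                         referenceSeqs = autos)
  isA <- as.character(seqnames(trackWindows(gcTrack(sc)))) %in% autos
  rPre <- cor(trackValues(depthTrack(sc, "male"))[isA],
              trackValues(gcTrack(sc))[isA])
  rPost <- cor(trackValues(corr)[isA], trackValues(gcTrack(sc))[isA])
  expect_gt(abs(rPre), 0.5)
  expect_lt(abs(rPost), 0.05)
})

test_that("depth-excess amplicon calls obey the boundary and repeat rules", {
  gr <- GRanges("Y", IRanges(seq(1, 5000 * 10, 5000), width = 5000))
  sex <- GRanges("Y", IRanges(1, 50000))
  # window exactly at the autosomal reference is kept (>= rule)
  d <- windowTrack(gr, c(30, rep(15, 9)))
  got <- detectDepthAmplicons(d, 30, sex)
  expect_equal(c(start(got), end(got)), c(1, 5000))
  # repeat-saturated window is dropped
  reps <- GRanges("Y", IRanges(1, 4500))   # 90% of the first window
  expect_equal(length(detectDepthAmplicons(d, 30, sex, repeats = reps)), 0L)
  # window below the reference is not called
  expect_equal(length(detectDepthAmplicons(
    windowTrack(gr, rep(29.9, 10)), 30, sex)), 0L)
})

test_that("the collapsed amplicon is found by depth on the scenario", {
  sc <- defaultScenario()
  corr <- gcCorrectDepth(depthTrack(sc, "male"), gcTrack(sc),
                         referenceSeqs = c("A1", "A2", "A3"))
  ref <- autosomeDepthReference(corr, c("A1", "A2", "A3"))
  dep <- detectDepthAmplicons(corr, ref, sexDivRegions(sc),
                              scenarioRepeats(sc))
  truth <- truthCollapsed(sc)
  expect_equal(length(dep), 1L)
  expect_equal(as.character(seqnames(dep)), as.character(seqnames(truth)))
  expect_lte(abs(start(dep) - start(truth)), 5000)
  expect_lte(abs(end(dep) - end(truth)), 5000)
})

test_that("mergeEvidence unions regions and annotates channels", {
  pal <- GRanges("c", IRanges(1, 100))
  arr <- GRanges("c", IRanges(500, 600))
  dep <- GRanges("c", IRanges(90, 200))
  merged <- mergeEvidence(pal, arr, dep)
  expect_equal(length(merged), 2L)
  expect_equal(mcols(merged)$evidence, c("palindrome,depth", "array"))
  # union length equals the per-base mask union
  mask <- rep(FALSE, 600)
  mask[1:100] <- TRUE; mask[500:600] <- TRUE; mask[90:200] <- TRUE
  expect_equal(sum(width(merged)), sum(mask))
})

test_that("ampliconic gene calls use the >80% rule and exclusions", {
  regions <- GRanges("c", IRanges(1, 1000))
  genes <- GRanges("c", IRanges(c(191, 209, 101), width = 1000))
  names(genes) <- c("geneA", "geneB", "OR5K1")
  calls <- callAmpliconicGenes(genes, regions)
  expect_equal(calls$called, c(TRUE, FALSE, FALSE))   # 81%, 79.2%, excluded
  expect_gt(calls$overlapFraction[1], 0.80)
  expect_lt(calls$overlapFraction[2], 0.80)
  expect_true(calls$excludedClass[3])
})

test_that("full amplicon pipeline on the scenario: truth genes, truth copy number", {
  sc <- defaultScenario()
  corr <- gcCorrectDepth(depthTrack(sc, "male"), gcTrack(sc),
                         referenceSeqs = c("A1", "A2", "A3"))
  ref <- autosomeDepthReference(corr, c("A1", "A2", "A3"))
  pal <- detectPalindromes(selfSegments(sc), scenarioRepeats(sc))
  labels <- truthLabels(sc)
  sexScafs <- names(labels)[labels %in% c("X_div", "Y_div")]
  arr <- detectArrays(scenarioSizes(sc)[sexScafs], selfSegments(sc))
  dep <- detectDepthAmplicons(corr, ref, sexDivRegions(sc),
                              scenarioRepeats(sc))
  regions <- mergeEvidence(pal, arr, dep)
  calls <- callAmpliconicGenes(scenarioGenes(sc), regions, corr, ref)
  truthCalls <- mcols(scenarioGenes(sc))$ampliconic
  expect_identical(calls$called, truthCalls)
  # the planted 4-copy collapsed gene gets copy number 4 +/- 1
  cn <- calls$copyNumberEstimate[calls$gene == "CNVY1"]
  expect_lte(abs(cn - mcols(truthCollapsed(sc))$copyNumber), 1)
})
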