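test_that("identityWindows projects matches onto windows", {
  # fully covered window with 10 mismatches per 1000 columns
  segs <- alignmentSegments(GRanges("X", IRanges(1, 1000)),
                            GRanges("Y", IRanges(1, 1000)), "+", 0.990)
  tr <- identityWindows(segs, chromSizes = c(X = 3000))
  expect_equal(trackValues(tr), c(0.990, NA, NA))

  # a segment spanning two windows contributes by overlap
  seg2 <- alignmentSegments(GRanges("X", IRanges(501, 1500)),
                            GRanges("Y", IRanges(501, 1500)), "+", 0.95)
  tr2 <- identityWindows(seg2, chromSizes = c(X = 2000))
  expect_equal(trackValues(tr2), c(0.95, 0.95))
})

test_that("total matched bases are conserved across windows", {
  sc <- defaultScenario()
  segs <- filterYSegments(xySegments(sc), yVsOtherSegments(sc))
  tr <- identityWindows(segs, chromSizes = c(X1 = 600000))
  wins <- trackWindows(tr)
  aligned <- sapply(seq_along(wins), function(i) {
    ov <- pmax(0, pmin(end(wins[i]), end(segQuery(segs))) -
                  pmax(start(wins[i]), start(segQuery(segs))) + 1)
    sum(ov)
  })
  windowMatches <- sum(trackValues(tr) * aligned, na.rm = TRUE)
  expect_equal(windowMatches, sum(segMatches(segs)), tolerance = 1e-9)
})

test_that("per-window identity tracks the planted stratum divergences", {
  sc <- defaultScenario()
  segs <- filterYSegments(xySegments(sc), yVsOtherSegments(sc))
  tr <- identityWindows(segs, chromSizes = c(X1 = 600000))
  st <- truthStrata(sc)
  for (k in seq_along(st)) {
    inStr <- start(trackWindows(tr)) >= start(st[k]) &
      end(trackWindows(tr)) <= end(st[k])
    mid <- mean(trackValues(tr)[inStr], na.rm = TRUE)
    expected <- 1 - jc69ExpectedP(mcols(st)$divergence[k])
    expect_lt(abs(mid - expected), 0.01)
  }
})

test_that("filterYSegments drops only strictly dominated segments", {
  xy <- alignmentSegments(GRanges("X", IRanges(c(1, 2001), width = 1000)),
                          GRanges("Y", IRanges(c(1, 2001), width = 1000)),
                          "+", c(0.95, 0.95))
  # competitor strictly better on both axes for the first Y span
  comp <- alignmentSegments(GRanges("Y", IRanges(1, 1100)),
                            GRanges("A", IRanges(1, 1100)), "+", 0.99,
                            alignedLength = 2000)
  kept <- filterYSegments(xy, comp)
  expect_equal(length(kept), 1L)
  expect_equal(start(segQuery(kept)), 2001)

  # equal identity: tie keeps the segment
  tie <- alignmentSegments(GRanges("Y", IRanges(1, 1100)),
                           GRanges("A", IRanges(1, 1100)), "+", 0.95,
                           alignedLength = 2000)
  expect_equal(length(filterYSegments(xy, tie)), 2L)

  # no competitors: everything kept
  expect_equal(length(filterYSegments(xy, alignmentSegments(
    GRanges(), GRanges(), character(), numeric(),
    alignedLength = integer(), matches = numeric()))), 2L)

  # the scenario's planted spurious segment is removed, the rest kept
  sc <- defaultScenario()
  kept2 <- filterYSegments(xySegments(sc), yVsOtherSegments(sc))
  expect_equal(length(kept2), length(xySegments(sc)) - 1L)
})

test_that("jc69 matches the closed form and rejects saturation", {
  expect_equal(jc69(0), 0)
  expect_equal(jc69(0.3), -0.75 * log(0.6))
  expect_equal(jc69(0.3), 0.3831192, tolerance = 1e-6)
  expect_error(jc69(0.75), "satur")
  expect_error(jc69(0.9), "satur")
  # inverse round-trip to 1e-12
  d <- seq(0.001, 2.5, length.out = 200)
  expect_lt(max(abs(jc69(jc69ExpectedP(d)) - d)), 1e-12)
  p <- seq(0, 0.74, length.out = 200)
  expect_lt(max(abs(jc69ExpectedP(jc69(p)) - p)), 1e-12)
  expect_true(all(jc69(p) >= p))
})

test_that("bootstrapDivergence is deterministic and degenerates cleanly", {
  s <- paste(rep("ACGT", 500), collapse = "")
  aln <- pairAlignment(s, s)
  est <- bootstrapDivergence(aln, B = 100, seed = 4)
  expect_equal(est$d, 0)
  expect_equal(est$ci, c(0, 0))
  expect_equal(est$nColumns, 2000)

  mism <- c(rep(TRUE, 150), rep(FALSE, 850))
  a <- bootstrapDivergence(mism, B = 200, seed = 9)
  b <- bootstrapDivergence(mism, B = 200, seed = 9)
  expect_identical(a$ci, b$ci)
  c2 <- bootstrapDivergence(mism, B = 200, seed = 10)
  expect_false(identical(a$ci, c2$ci))
  expect_true(a$ci[1] <= a$d && a$d <= a$ci[2])

  expect_error(bootstrapDivergence(logical(), B = 10, seed = 1), "columns")
})

test_that("masked and gapped columns are excluded from divergence", {
  aln <- pairAlignment("ACGTAC-TNA", "ACGTTC-ANA",
                       mask = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)))
  # 10 columns minus one masked, one gap pair, one N pair = 7 valid
  mism <- SexChromTools:::mismatchVector(aln)
  expect_equal(length(mism), 7L)
  expect_equal(sum(mism), 1L)
})

test_that("the rate model reproduces hand-computed values", {
  m <- buildRateModel(alpha = 2.95, muAA = 7e-9)
  expect_equal(rateRatio(m), (2 + 4 * 2.95) / (3 + 3 * 2.95))
  expect_equal(signif(rateMuXY(m), 3), 8.15e-9)
  expect_equal(rateMuF(m), 2 * 7e-9 / 3.95)

  # no male bias: XY rate equals the autosomal rate
  m1 <- buildRateModel(1, 7e-9)
  expect_equal(rateRatio(m1), 1)
  expect_equal(rateMuXY(m1), 7e-9)

  m2 <- buildRateModel(2, 7e-9)
  expect_equal(rateRatio(m2), 10 / 9)
  expect_equal(rateMuXY(m2), 7e-9 * 10 / 9)

  expect_error(buildRateModel(-1, 7e-9))
})

test_that("the XY/A ratio is bounded and monotone in alpha", {
  alphas <- seq(0.1, 10, length.out = 50)
  ratios <- vapply(alphas, function(a) rateRatio(buildRateModel(a, 1e-9)),
                   numeric(1))
  expect_true(all(ratios > 2 / 3 & ratios < 4 / 3))
  expect_true(all(diff(ratios) > 0))
})

test_that("stratumAge divides divergence and CI by muXY", {
  m <- buildRateModel(2.95, 7e-9)
  est <- list(d = 0.0815, ci = c(0.08, 0.083))
  age <- stratumAge(est, m)
  expect_equal(age$T, 0.0815 / rateMuXY(m))
  expect_equal(age$ci, c(0.08, 0.083) / rateMuXY(m))

  # d = 0.0815 at muXY ~8.15e-9 dates to ~1e7 years
  expect_equal(age$T, 1.0e7, tolerance = 3e-4)
  expect_equal(stratumAge(list(d = 0, ci = c(0, 0)), m)$T, 0)
})

test_that("stratum ages are recovered end-to-end from planted divergences", {
  sc <- defaultScenario()
  model <- buildRateModel(2.95, 7e-9)
  st <- truthStrata(sc)
  for (k in seq_along(st)) {
    est <- bootstrapDivergence(stratumAlignment(sc, k), B = 500,
                               seed = 100 + k)
    d <- mcols(st)$divergence[k]
    expect_gte(d, est$ci[1] - 0.01)
    expect_lte(d, est$ci[2] + 0.01)
    age <- stratumAge(est, model)
    plantedAge <- d / rateMuXY(model)
    expect_lt(abs(age$T - plantedAge) / plantedAge, 0.05)
  }
})
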