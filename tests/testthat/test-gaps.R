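test_that("findGaps returns maximal N-runs", {
  asm <- DNAStringSet(c(s1 = "ACGTNNNNNACGT", s2 = "ACGTACGT"))
  gaps <- findGaps(asm)
  expect_equal(length(gaps), 1L)
  expect_equal(c(start(gaps), end(gaps)), c(5, 9))
  expect_equal(mcols(gaps)$size, 5L)
  expect_equal(length(findGaps(DNAStringSet(c(s = "ACGT")))), 0L)
})

test_that("findGaps matches a regex oracle on random planted runs", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 3000
    chars <- sample(c("A", "C", "G", "T"), n, TRUE)
    for (k in seq_len(sample.int(5, 1))) {
      s <- sample.int(n - 60, 1)
      chars[s:(s + sample.int(50, 1))] <- "N"
    }
    seqStr <- paste(chars, collapse = "")
    gaps <- findGaps(DNAStringSet(c(s = seqStr)))
    m <- gregexpr("N+", seqStr)[[1]]
    expect_equal(start(gaps), as.integer(m))
    expect_equal(width(gaps), attr(m, "match.length"))
  }
})

test_that("extractFlanks applies the exclusion rules and truncation", {
  set.seed(2)
  chars <- sample(c("A", "C", "G", "T"), 30000, TRUE)
  chars[10001:10100] <- "N"
  asm <- DNAStringSet(c(s = paste(chars, collapse = "")))
  gap <- GRanges("s", IRanges(10001, 10100))
  fl <- extractFlanks(asm, gap)
  expect_false(fl$excluded)
  expect_equal(as.character(fl$upstream),
               paste(chars[9501:10000], collapse = ""))
  expect_equal(as.character(fl$downstream),
               paste(chars[10101:10600], collapse = ""))

  # gap 150 bp from the scaffold start is excluded
  near <- c(sample(c("A", "C", "G", "T"), 150, TRUE), rep("N", 100),
            sample(c("A", "C", "G", "T"), 1000, TRUE))
  asm2 <- DNAStringSet(c(s = paste(near, collapse = "")))
  expect_true(extractFlanks(asm2, GRanges("s", IRanges(151, 250)))$excluded)

  # gap under 5 bp is excluded
  chars4 <- chars
  chars4[10001:10100] <- sample(c("A", "C", "G", "T"), 100, TRUE)
  chars4[20001:20004] <- "N"
  asm3 <- DNAStringSet(c(s = paste(chars4, collapse = "")))
  expect_true(extractFlanks(asm3, GRanges("s", IRanges(20001, 20004)))$excluded)
})

test_that("mapFlank finds verbatim and mutated copies, misses absences", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  flank <- paste(sample(bases, 500, TRUE), collapse = "")
  context1 <- paste(sample(bases, 2000, TRUE), collapse = "")
  context2 <- paste(sample(bases, 2000, TRUE), collapse = "")
  asm <- DNAStringSet(c(t1 = paste0(context1, flank, context2)))

  hit <- mapFlank(flank, asm)
  expect_equal(hit$scaffold, "t1")
  expect_equal(hit$rate, 1.0)
  expect_equal(c(hit$start, hit$end), c(2001, 2500))
  expect_equal(hit$strand, "+")

  # reverse-complement copy found on the minus strand
  rcAsm <- DNAStringSet(c(t1 = paste0(
    context1, as.character(reverseComplement(DNAString(flank))), context2)))
  rcHit <- mapFlank(flank, rcAsm)
  expect_equal(rcHit$strand, "-")
  expect_equal(c(rcHit$start, rcHit$end), c(2001, 2500))

  # absent flank yields no hit
  expect_null(mapFlank(paste(sample(bases, 500, TRUE), collapse = ""), asm))
})

test_that("mapFlank tolerates 10% substitutions in nearly all trials", {
  set.seed(19)
  bases <- c("A", "C", "G", "T")
  found <- replicate(100, {
    flank <- sample(bases, 500, TRUE)
    noisy <- flank
    idx <- sample.int(500, 50)
    noisy[idx] <- sample(bases, 50, TRUE)
    asm <- DNAStringSet(c(t = paste(
      c(sample(bases, 1500, TRUE), noisy, sample(bases, 1500, TRUE)),
      collapse = "")))
    hit <- mapFlank(paste(flank, collapse = ""), asm)
    !is.null(hit) && hit$rate >= 0.7
  })
  expect_gte(sum(found), 95)
})

test_that("classifyGap matches an independently enumerated rule oracle", {
  # brute-force oracle over the rule combinations, written directly from
  # the closure rules rather than the implementation
  oracle <- function(up, down, sameScaffold, sameStrand, rightOrder, hasN) {
    if (!up || !down) return("open")
    if (!sameScaffold) return("trans_scaffold_break")
    if (!sameStrand || !rightOrder) return("open")
    if (hasN) return("open")
    "closed"
  }
  seqN <- paste(c(rep("A", 100), rep("N", 10), rep("C", 890)), collapse = "")
  seqClean <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")
  gap <- GRanges("old", IRanges(1001, 1100))
  mkHit <- function(scaffold, start, end, strand)
    list(scaffold = scaffold, start = start, end = end, strand = strand,
         rate = 1, identity = 1, matches = end - start + 1)
  for (up in c(TRUE, FALSE)) for (down in c(TRUE, FALSE))
    for (sameScaffold in c(TRUE, FALSE)) for (sameStrand in c(TRUE, FALSE))
      for (rightOrder in c(TRUE, FALSE)) for (hasN in c(TRUE, FALSE)) {
        asm <- DNAStringSet(c(n1 = if (hasN) seqN else seqClean,
                              n2 = seqClean))
        upHit <- if (up) mkHit("n1", 1, 50, "+") else NULL
        downHit <- if (!down) NULL else mkHit(
          if (sameScaffold) "n1" else "n2",
          if (rightOrder) 201 else ifelse(sameScaffold, 1, 201),
          if (rightOrder) 250 else ifelse(sameScaffold, 40, 250),
          if (sameStrand) "+" else "-")
        got <- classifyGap(gap, upHit, downHit, asm)$status
        want <- oracle(up, down, sameScaffold, sameStrand, rightOrder, hasN)
        expect_equal(got, want,
                     info = paste(up, down, sameScaffold, sameStrand,
                                  rightOrder, hasN))
      }
})

test_that("audit recovers the planted gap outcomes exactly", {
  sc <- defaultScenario()
  aud <- auditGaps(oldAssembly(sc), newAssembly(sc))
  truth <- table(truthGaps(sc)$outcome)
  expect_equal(aud$summary$counts[["closed"]], unname(truth[["closed"]]))
  expect_equal(aud$summary$counts[["open"]], unname(truth[["open"]]))
  expect_equal(aud$summary$counts[["trans_scaffold_break"]],
               unname(truth[["trans_scaffold_break"]]))
  expect_equal(aud$summary$counts[["excluded"]], unname(truth[["excluded"]]))
  expect_equal(sum(aud$summary$counts), nrow(truthGaps(sc)))
  expect_equal(aud$summary$closedFraction, 10 / 20)
  expect_equal(aud$summary$closedLength,
               sum(truthGaps(sc)$size[truthGaps(sc)$outcome == "closed"]))
})

test_that("auditing against the old assembly itself closes nothing", {
  sc <- defaultScenario()
  old <- oldAssembly(sc)
  aud <- auditGaps(old, old)
  expect_equal(aud$summary$counts[["closed"]], 0)
})

test_that("status counts are invariant under reverse-complementing the new assembly", {
  sc <- defaultScenario()
  # a subset keeps this quick; covers closed, open and trans cases
  keep <- grep("closed_[123]$|open_[12]$|trans_[12]", names(oldAssembly(sc)))
  old <- oldAssembly(sc)[keep]
  new <- newAssembly(sc)
  rc <- reverseComplement(new)
  names(rc) <- names(new)
  a <- auditGaps(old, new)
  b <- auditGaps(old, rc)
  expect_equal(a$summary$counts, b$summary$counts)
})
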