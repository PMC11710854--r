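suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# The default scenario (seed 1) is expensive enough to share across files;
# testthat sources helpers once per run, so the memo persists.
.scenarioMemo <- new.env(parent = emptyenv())

defaultScenario <- function() {
  if (is.null(.scenarioMemo$default))
    .scenarioMemo$default <- simulateScenario(scenarioConfig(seed = 1))
  .scenarioMemo$default
}

# Larger autosomes for law-of-large-numbers checks on depth and GC
bigAutosomeScenario <- function() {
  if (is.null(.scenarioMemo$big))
    .scenarioMemo$big <- simulateScenario(scenarioConfig(
      seed = 7, autosomeLengths = c(A1 = 2e6, A2 = 2e6, A3 = 2e6)))
  .scenarioMemo$big
}

# truth label -> expected depth-classifier call
expectedCallFor <- function(labels) {
  map <- c(autosome = "unclassified", X_div = "X_linked",
           Y_div = "Y_linked", PAR = "unclassified")
  unname(map[labels])
}

# per-base boolean-mask oracles for the interval algebra
maskMerge <- function(starts, ends, maxGap, n) {
  mask <- rep(FALSE, n)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  if (maxGap > 0) {
    r <- rle(mask)
    cum <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (!r$values[j] && j > 1 && j < length(r$values) &&
          r$lengths[j] <= maxGap) {
        mask[(cum[j] - r$lengths[j] + 1):cum[j]] <- TRUE
      }
    }
  }
  r <- rle(mask)
  ends2 <- cumsum(r$lengths)
  starts2 <- ends2 - r$lengths + 1
  cbind(starts2[r$values], ends2[r$values])
}

maskOverlapFraction <- function(aStart, aEnd, bStarts, bEnds) {
  n <- aEnd
  mask <- rep(FALSE, n)
  for (i in seq_along(bStarts)) {
    s <- max(1, bStarts[i]); e <- min(n, bEnds[i])
    if (s <= e) mask[s:e] <- TRUE
  }
  mean(mask[aStart:aEnd])
}

# exact one-sided rank-sum p-value by enumeration of all splits
enumWilcoxonGreater <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  obs <- sum(rank(pooled)[seq_len(n)])
  splits <- combn(length(pooled), n)
  stats <- apply(splits, 2, function(idx) sum(rank(pooled)[idx]))
  mean(stats >= obs)
}
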