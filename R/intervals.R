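#' Merge genomic intervals, bridging gaps up to a maximum
#'
#' Union-preserving merge: any two intervals on the same sequence separated
#' by at most `maxGap` bases are fused. `maxGap = 0` fuses only overlapping
#' or bookended intervals. The operation is idempotent and independent of
#' input order.
#'
#' @param intervals A `GRanges`.
#' @param maxGap Maximum intervening gap in bp (>= 0) to bridge.
#'
#' @return A sorted `GRanges` whose union of bases covers exactly the input
#'   plus bridged gaps.
#' @examples
#' gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 6), c(10, 20)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(intervals, maxGap = 0) {
  stopifnot(maxGap >= 0)
  reduce(sort(intervals), min.gapwidth = maxGap + 1)
}

#' Fraction of one interval covered by a set of intervals
#'
#' Computes the fraction of bases of `a` covered by the (merged) union of
#' `b`, counting each base once. Used for gene-vs-ampliconic-region overlap
#' calls at the >80% rule.
#'
#' @param a A length-one `GRanges`.
#' @param b A `GRanges` of covering intervals.
#'
#' @return A number in \[0, 1\].
#' @examples
#' a <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 41), c(50, 81)))
#' overlapFraction(a, b)  # 0.81
#' @export
overlapFraction <- function(a, b) {
  stopifnot(length(a) == 1L)
  if (length(b) == 0L) return(0)
  m <- mergeIntervals(b)
  m <- m[as.character(seqnames(m)) == as.character(seqnames(a))]
  if (length(m) == 0L) return(0)
  w <- pmax(0, pmin(end(a), end(m)) - pmax(start(a), start(m)) + 1)
  sum(w) / width(a)
}

#' Tile a genome into (possibly sliding) windows
#'
#' Windows start at the beginning of each sequence and advance by `step`;
#' the final window is truncated at the sequence end. A sequence shorter
#' than `window` yields a single full-length window. With `step < window`
#' the windows overlap (e.g. 5-kb windows with 2-kb overlap use
#' `step = 3000`).
#'
#' @param chromSizes Named numeric vector of sequence lengths in bp.
#' @param window Window size in bp (>= 1).
#' @param step Step between window starts in bp (1 <= step <= window).
#'
#' @return A `GRanges` of windows, ordered by sequence then start.
#' @examples
#' binGenome(c(chr1 = 12000), window = 5000, step = 3000)
#' @export
binGenome <- function(chromSizes, window, step = window) {
  stopifnot(window >= 1, step >= 1)
  if (step > window)
    stop("step must not exceed window")
  parts <- lapply(names(chromSizes), function(chr) {
    len <- chromSizes[[chr]]
    if (len < window) {
      starts <- 0
    } else {
      n <- ceiling((len - window) / step) + 1
      starts <- step * (seq_len(n) - 1)
    }
    ends <- pmin(starts + window, len)
    list(chrom = rep(chr, length(starts)), start = starts + 1, end = ends)
  })
  GRanges(unlist(lapply(parts, `[[`, "chrom")),
          IRanges(unlist(lapply(parts, `[[`, "start")),
                  unlist(lapply(parts, `[[`, "end"))))
}
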