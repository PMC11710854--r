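#' Detect palindromes from inverted self-alignment segments
#'
#' Keeps inverted-orientation self-alignment segments (query and target on
#' the same sequence, strand "-", query left of target), chains segments
#' whose arm projections are co-linear with gaps at most `chainGap` on both
#' arms, and emits chains that satisfy the palindrome thresholds: arm
#' identity >= `minIdentity` (0.98), both arms >= `minArm` (8 kb), spacer
#' <= `maxSpacer` (500 kb), and repeat content of the palindrome span
#' < `maxRepeat` (0.80). Overlapping candidates are deduplicated keeping
#' the longer arm.
#'
#' @param selfSegments An [AlignmentSegments-class] of self-alignments
#'   (trivial diagonal removed).
#' @param repeats A `GRanges` repeat annotation.
#' @param minIdentity,minArm,maxSpacer,maxRepeat,chainGap Thresholds (see
#'   description).
#'
#' @return A `data.frame`: chrom, arm1Start, arm1End, arm2Start, arm2End
#'   (1-based closed), spacer, armLength, identity, repeatFraction.
#' @export
detectPalindromes <- function(selfSegments, repeats = GRanges(),
                              minIdentity = 0.98, minArm = 8000,
                              maxSpacer = 500000, maxRepeat = 0.80,
                              chainGap = 2000) {
  q <- segQuery(selfSegments)
  t <- segTarget(selfSegments)
  sameChrom <- as.character(seqnames(q)) == as.character(seqnames(t))
  if (any(!sameChrom))
    warning(sum(!sameChrom), " self-segment(s) mix sequences; skipped")
  keep <- sameChrom & segStrand(selfSegments) == "-" & start(q) < start(t) &
    !(start(q) == start(t) & end(q) == end(t))
  segs <- selfSegments[keep]
  if (!length(segs)) return(.emptyPalindromes())
  q <- segQuery(segs)
  t <- segTarget(segs)
  o <- order(as.character(seqnames(q)), start(q))
  segs <- segs[o]
  q <- segQuery(segs)
  t <- segTarget(segs)
  chroms <- as.character(seqnames(q))
  # greedy co-linear chaining: for an inverted repeat, arm-1 coordinates
  # ascend while arm-2 forward coordinates descend
  chains <- list()
  cur <- NULL
  flush <- function(cur, chains) {
    if (!is.null(cur)) chains[[length(chains) + 1L]] <- cur
    chains
  }
  for (i in seq_along(segs)) {
    si <- list(chrom = chroms[i], q1 = start(q)[i], q2 = end(q)[i],
               t1 = start(t)[i], t2 = end(t)[i],
               id = segIdentity(segs)[i] * segAlignedLength(segs)[i],
               len = segAlignedLength(segs)[i])
    if (!is.null(cur) && cur$chrom == si$chrom &&
        si$q1 - cur$q2 >= -100 && si$q1 - cur$q2 <= chainGap &&
        cur$t1 - si$t2 >= -100 && cur$t1 - si$t2 <= chainGap) {
      cur$q2 <- max(cur$q2, si$q2)
      cur$t1 <- min(cur$t1, si$t1)
      cur$t2 <- max(cur$t2, si$t2)
      cur$id <- cur$id + si$id
      cur$len <- cur$len + si$len
    } else {
      chains <- flush(cur, chains)
      cur <- si
    }
  }
  chains <- flush(cur, chains)
  rows <- lapply(chains, function(ch) {
    armLen <- min(ch$q2 - ch$q1 + 1, ch$t2 - ch$t1 + 1)
    spacer <- ch$t1 - ch$q2 - 1
    identity <- ch$id / ch$len
    if (ch$q2 > ch$t1) return(NULL)            # arms must not overlap
    if (armLen < minArm || spacer > maxSpacer || identity < minIdentity)
      return(NULL)
    span <- GRanges(ch$chrom, IRanges(ch$q1, ch$t2))
    repFrac <- overlapFraction(span, repeats)
    if (repFrac >= maxRepeat) return(NULL)
    data.frame(chrom = ch$chrom, arm1Start = ch$q1, arm1End = ch$q2,
               arm2Start = ch$t1, arm2End = ch$t2, spacer = spacer,
               armLength = armLen, identity = identity,
               repeatFraction = repFrac, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyPalindromes())
  out <- do.call(rbind, rows)
  # dedupe overlapping palindromes, keeping the longer arm
  out <- out[order(-out$armLength), , drop = FALSE]
  spans <- GRanges(out$chrom, IRanges(out$arm1Start, out$arm2End))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prior <- spans[which(keep[seq_len(i - 1L)])]
    if (length(prior) && overlapFraction(spans[i], prior) > 0)
      keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$chrom, out$arm1Start), , drop = FALSE]
}

.emptyPalindromes <- function() {
  data.frame(chrom = character(), arm1Start = numeric(),
             arm1End = numeric(), arm2Start = numeric(),
             arm2End = numeric(), spacer = numeric(),
             armLength = numeric(), identity = numeric(),
             repeatFraction = numeric(), stringsAsFactors = FALSE)
}

#' Detect tandem-array ampliconic regions from self-hits
#'
#' The sex-linked sequence is scanned in 5-kb windows with 2-kb overlap
#' (step 3 kb). A window is a candidate when at least one retained self-hit
#' -- identity > `minIdentity` (0.99), not a self-locus hit (target
#' overlapping the window itself) -- covers more than `minRate` (0.5) of
#' the window. Candidate windows are merged and merged runs shorter than
#' `minMerged` (10 kb) are dropped.
#'
#' @param chromSizes Named lengths (bp) of the sequences to scan.
#' @param hits An [AlignmentSegments-class] of self-hits on repeat-masked
#'   sequence.
#' @param window,step Window geometry in bp.
#' @param minRate Minimum fraction of a window covered by one hit.
#' @param minIdentity Minimum hit identity (exclusive).
#' @param minMerged Minimum merged region length in bp.
#'
#' @return A `GRanges` of array regions.
#' @export
detectArrays <- function(chromSizes, hits, window = 5000, step = 3000,
                         minRate = 0.5, minIdentity = 0.99,
                         minMerged = 10000) {
  wins <- binGenome(chromSizes, window = window, step = step)
  hq <- segQuery(hits)
  ht <- segTarget(hits)
  good <- segIdentity(hits) > minIdentity
  hq <- hq[good]
  ht <- ht[good]
  if (!length(hq) || !length(wins)) return(GRanges())
  ovq <- suppressWarnings(findOverlaps(wins, hq))
  cand <- rep(FALSE, length(wins))
  if (length(ovq)) {
    wI <- queryHits(ovq)
    hI <- subjectHits(ovq)
    ovWidth <- width(suppressWarnings(pintersect(wins[wI], hq[hI])))
    # self-locus: the hit's own target overlaps this window
    selfLocus <- as.character(seqnames(ht[hI])) ==
      as.character(seqnames(wins[wI])) &
      start(ht[hI]) <= end(wins[wI]) & end(ht[hI]) >= start(wins[wI])
    ok <- !selfLocus & ovWidth > minRate * width(wins[wI])
    cand[unique(wI[ok])] <- TRUE
  }
  if (!any(cand)) return(GRanges())
  merged <- mergeIntervals(wins[cand])
  merged[width(merged) >= minMerged]
}

#' GC-correct a depth track by binned-median scaling
#'
#' Windows are grouped into GC bins of width `binWidth`; each window's
#' depth is scaled by `globalMedian / binMedian` for its bin. Bins with
#' fewer than `minBin` windows inherit the factor of the nearest populated
#' bin. When `referenceSeqs` is given (typically the autosomes), bin
#' medians and the global median are estimated from those sequences only
#' and the factors applied genome-wide -- on a mixed diploid/hemizygous
#' genome this keeps the copy-number signal out of the bias estimate.
#' The reference median is preserved by construction.
#'
#' @param depth,gc [WindowTrack-class] objects on an identical grid.
#' @param binWidth GC bin width (fraction).
#' @param minBin Minimum windows per bin to estimate its own factor.
#' @param referenceSeqs Optional sequence ids used to estimate the bias.
#'
#' @return A corrected [WindowTrack-class].
#' @export
gcCorrectDepth <- function(depth, gc, binWidth = 0.01, minBin = 20,
                           referenceSeqs = NULL) {
  d <- trackValues(depth)
  g <- trackValues(gc)
  if (length(d) != length(g))
    stop("depth and gc tracks must share a window grid")
  bin <- floor(g / binWidth)
  ok <- !is.na(d) & !is.na(g)
  if (!is.null(referenceSeqs))
    ok <- ok & as.character(seqnames(trackWindows(depth))) %in% referenceSeqs
  if (!any(ok))
    stop("no usable reference windows for GC correction")
  globalMed <- median(d[ok])
  binIds <- sort(unique(bin[ok]))
  med <- vapply(binIds, function(b) median(d[ok & bin == b]), numeric(1))
  n <- vapply(binIds, function(b) sum(ok & bin == b), numeric(1))
  factor <- globalMed / med
  # sparsely populated bins borrow the nearest populated bin's factor
  pop <- n >= minBin
  if (any(pop) && any(!pop)) {
    for (i in which(!pop)) {
      j <- which(pop)[which.min(abs(binIds[pop] - binIds[i]))]
      factor[i] <- factor[j]
    }
  }
  nearest <- vapply(bin, function(b) {
    if (is.na(b)) return(NA_integer_)
    which.min(abs(binIds - b))
  }, integer(1))
  f <- factor[nearest]
  windowTrack(trackWindows(depth), d * f, sort = FALSE)
}

#' Detect ampliconic regions from depth excess
#'
#' A non-PAR sex-linked window whose GC-corrected male depth is at least
#' the autosomal reference and whose repeat content is below `maxRepeat`
#' is a candidate; candidates are merged. Amplicon copies collapsed during
#' assembly pile up male reads, so a hemizygous window reaching diploid
#' autosomal depth implies amplification.
#'
#' @param correctedDepth GC-corrected male [WindowTrack-class].
#' @param autosomeReference Reference corrected autosomal depth (a mean;
#'   see [autosomeDepthReference()]).
#' @param sexRegions `GRanges` of non-PAR X/Y intervals to scan.
#' @param repeats `GRanges` repeat annotation.
#' @param maxRepeat Maximum window repeat fraction.
#'
#' @return A `GRanges` of depth-evidence regions.
#' @export
detectDepthAmplicons <- function(correctedDepth, autosomeReference,
                                 sexRegions, repeats = GRanges(),
                                 maxRepeat = 0.80) {
  wins <- trackWindows(correctedDepth)
  v <- trackValues(correctedDepth)
  inSex <- rep(FALSE, length(wins))
  if (length(sexRegions)) {
    ov <- suppressWarnings(findOverlaps(wins, sexRegions))
    if (length(ov)) {
      covered <- width(suppressWarnings(pintersect(
        wins[queryHits(ov)], sexRegions[subjectHits(ov)])))
      frac <- covered / width(wins[queryHits(ov)])
      inSex[unique(queryHits(ov)[frac >= 0.5])] <- TRUE
    }
  }
  cand <- which(inSex & !is.na(v) & v >= autosomeReference)
  if (!length(cand)) return(GRanges())
  if (length(repeats)) {
    repFrac <- vapply(cand, function(i)
      overlapFraction(wins[i], repeats), numeric(1))
    cand <- cand[repFrac < maxRepeat]
  }
  if (!length(cand)) return(GRanges())
  mergeIntervals(wins[cand])
}

#' Mean corrected depth over autosomal windows
#'
#' @param correctedDepth GC-corrected [WindowTrack-class].
#' @param autosomes Character vector of autosomal sequence ids.
#' @param stat "mean" (default) or "median".
#' @return The reference depth.
#' @export
autosomeDepthReference <- function(correctedDepth, autosomes,
                                   stat = c("mean", "median")) {
  stat <- match.arg(stat)
  v <- trackValues(trackOnSeq(correctedDepth, autosomes))
  if (stat == "mean") mean(v, na.rm = TRUE) else median(v, na.rm = TRUE)
}

#' Merge the three amplicon evidence channels
#'
#' Takes the palindrome, array, and depth region sets, merges their union,
#' and annotates each merged region with the channels contributing at
#' least one base.
#'
#' @param palindromes Output of [detectPalindromes()] (its spans are
#'   used), or a `GRanges`.
#' @param arrays,depthRegions `GRanges` region sets.
#'
#' @return A `GRanges` with an `evidence` metadata column
#'   (comma-separated channel names).
#' @export
mergeEvidence <- function(palindromes, arrays = GRanges(),
                          depthRegions = GRanges()) {
  pal <- if (is.data.frame(palindromes)) {
    if (nrow(palindromes))
      GRanges(palindromes$chrom,
              IRanges(palindromes$arm1Start, palindromes$arm2End))
    else GRanges()
  } else palindromes
  channels <- list(palindrome = pal, array = arrays, depth = depthRegions)
  all <- suppressWarnings(do.call(c, unname(lapply(channels, granges))))
  if (!length(all)) return(GRanges())
  merged <- mergeIntervals(all)
  ev <- vapply(seq_along(merged), function(i) {
    has <- vapply(channels, function(ch)
      length(ch) > 0 && overlapFraction(merged[i], ch) > 0, logical(1))
    paste(names(channels)[has], collapse = ",")
  }, character(1))
  mcols(merged)$evidence <- ev
  merged
}

#' Call ampliconic genes
#'
#' A gene is ampliconic when more than `minOverlap` (0.80) of its length
#' overlaps the merged ampliconic regions and its name does not match an
#' exclusion pattern (olfactory / vomeronasal receptor families, which are
#' amplified genome-wide). For hemizygous non-PAR sex-linked genes a copy
#' number is estimated as the rounded ratio of the gene's median corrected
#' depth to half the autosomal reference.
#'
#' @param genes A named `GRanges` (names = gene ids) of gene models.
#' @param regions Merged ampliconic regions (`GRanges`).
#' @param correctedDepth GC-corrected male [WindowTrack-class].
#' @param autosomeReference Reference corrected autosomal depth.
#' @param exclusionPatterns Regexes applied to gene names; matches are
#'   excluded.
#' @param minOverlap Minimum overlap fraction (exclusive).
#'
#' @return A `data.frame`: gene, chrom, start, end, overlapFraction,
#'   excludedClass, called, copyNumberEstimate.
#' @export
callAmpliconicGenes <- function(genes, regions, correctedDepth = NULL,
                                autosomeReference = NULL,
                                exclusionPatterns = c(
                                  "olfactory", "vomeronasal",
                                  "^OR[0-9]", "^V[12]R"),
                                minOverlap = 0.80) {
  ids <- names(genes)
  if (is.null(ids)) ids <- as.character(seq_along(genes))
  rows <- lapply(seq_along(genes), function(i) {
    ovf <- overlapFraction(genes[i], regions)
    excl <- any(vapply(exclusionPatterns, function(p)
      grepl(p, ids[i], ignore.case = TRUE), logical(1)))
    called <- ovf > minOverlap && !excl
    cn <- NA_real_
    if (called && !is.null(correctedDepth) && !is.null(autosomeReference)) {
      ov <- suppressWarnings(
        findOverlaps(trackWindows(correctedDepth), genes[i]))
      dv <- trackValues(correctedDepth)[queryHits(ov)]
      if (length(dv))
        cn <- round(median(dv, na.rm = TRUE) / (autosomeReference / 2))
    }
    data.frame(gene = ids[i], chrom = as.character(seqnames(genes[i])),
               start = start(genes[i]), end = end(genes[i]),
               overlapFraction = ovf, excludedClass = excl,
               called = called, copyNumberEstimate = cn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
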