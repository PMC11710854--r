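#' Find assembly gaps (maximal N-runs)
#'
#' @param assembly A named `DNAStringSet`.
#' @return A `GRanges` of maximal N-runs with a `size` metadata column.
#' @export
findGaps <- function(assembly) {
  parts <- lapply(names(assembly), function(nm) {
    m <- Biostrings::matchPattern("N", assembly[[nm]])
    r <- reduce(IRanges(start(m), end(m)))
    list(chrom = rep(nm, length(r)), start = start(r), end = end(r))
  })
  gr <- GRanges(unlist(lapply(parts, `[[`, "chrom")),
                IRanges(unlist(lapply(parts, `[[`, "start")),
                        unlist(lapply(parts, `[[`, "end"))))
  if (length(gr)) mcols(gr)$size <- width(gr)
  gr
}

#' Extract the 500-bp flanks of a gap, or mark it excluded
#'
#' A gap is excluded when it is smaller than 5 bp or lies within 200 bp of
#' a scaffold end. Otherwise the upstream flank is the (up to) `flank`
#' bases ending at the gap start and the downstream flank the (up to)
#' `flank` bases starting at the gap end; flanks are truncated near
#' scaffold ends but, by the exclusion rule, are always at least 200 bp.
#'
#' @param assembly A named `DNAStringSet` (the gapped assembly).
#' @param gap A length-one `GRanges` over the N-run.
#' @param flank Flank length in bp.
#' @param minEndDistance Exclusion distance from scaffold ends in bp.
#' @param minSize Exclusion threshold on gap size in bp.
#'
#' @return A list with `excluded` (logical) and, when not excluded,
#'   `upstream`/`downstream` `DNAString` flanks.
#' @export
extractFlanks <- function(assembly, gap, flank = 500,
                          minEndDistance = 200, minSize = 5) {
  stopifnot(length(gap) == 1L)
  chr <- as.character(seqnames(gap))
  len <- length(assembly[[chr]])
  gstart <- start(gap)
  gend <- end(gap)
  if (width(gap) < minSize ||
      (gstart - 1) < minEndDistance || (len - gend) < minEndDistance)
    return(list(excluded = TRUE))
  upStart <- max(1L, gstart - flank)
  downEnd <- min(len, gend + flank)
  list(excluded = FALSE,
       upstream = subseq(assembly[[chr]], upStart, gstart - 1L),
       downstream = subseq(assembly[[chr]], gend + 1L, downEnd))
}

# Seed-and-extend mapping of one flank onto an assembly: exact k-mer
# seeding, co-diagonal chaining, then local alignment of the flank against
# the chained window.
#' Map a flank sequence onto a new assembly
#'
#' Built-in mapper for gap auditing: exact 31-mer seeds of the flank are
#' located in each scaffold ([Biostrings::matchPDict()]), co-diagonal seeds
#' are chained, and the flank is aligned to the best chained window with
#' [Biostrings::pairwiseAlignment()] (local). The aligning rate is the
#' fraction of flank bases inside the aligned block; a hit is reported only
#' when it exceeds `minRate`. Ties between equally good hits are broken by
#' match count, then identity, then leftmost coordinate.
#'
#' @param flankSeq A `DNAString` (or character) flank, >= 200 bp.
#' @param assembly A named `DNAStringSet` to map against.
#' @param k Seed length.
#' @param seedStep Spacing of seed starts along the flank.
#' @param minRate Minimum aligning rate to report a hit.
#'
#' @return `NULL`, or a list `scaffold`, `start`, `end` (1-based closed,
#'   forward strand), `strand`, `rate`, `identity`, `matches`.
#' @export
mapFlank <- function(flankSeq, assembly, k = 31, seedStep = 8,
                     minRate = 0.7) {
  if (!length(assembly))
    stop("empty assembly index")
  flankSeq <- DNAString(as.character(flankSeq))
  flankLen <- length(flankSeq)
  if (flankLen < k) return(NULL)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  best <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") flankSeq else reverseComplement(flankSeq)
    offs <- seq(1L, flankLen - k + 1L, by = seedStep)
    kmers <- DNAStringSet(pat, start = offs, width = k)
    clean <- !grepl("N", as.character(kmers), fixed = TRUE)
    if (!any(clean)) next
    kmers <- kmers[clean]
    offs <- offs[clean]
    pd <- PDict(kmers)
    for (nm in names(assembly)) {
      subject <- assembly[[nm]]
      hits <- matchPDict(pd, subject)
      starts <- unlist(lapply(seq_along(hits), function(i)
        start(hits[[i]]) - offs[i]))
      if (!length(starts)) next
      # cluster seed diagonals; take the best-supported cluster
      diag_bin <- round(starts / 32)
      tab <- table(diag_bin)
      top <- as.numeric(names(tab)[which.max(tab)])
      anchor <- median(starts[diag_bin == top])
      wStart <- max(1L, floor(anchor) - 100L)
      wEnd <- min(length(subject), floor(anchor) + flankLen + 100L)
      aln <- pairwiseAlignment(pat, subseq(subject, wStart, wEnd),
                               type = "local",
                               substitutionMatrix = submat,
                               gapOpening = 5, gapExtension = 2)
      patRange <- pattern(aln)
      rate <- (end(patRange) - start(patRange) + 1L) / flankLen
      nm_match <- nmatch(aln)
      id <- nm_match / nchar(aln)
      alnSubject <- Biostrings::subject(aln)
      sStart <- wStart + start(alnSubject) - 1L
      sEnd <- wStart + end(alnSubject) - 1L
      cand <- list(scaffold = nm, start = sStart, end = sEnd,
                   strand = strand, rate = rate, identity = id,
                   matches = nm_match)
      if (is.null(best) ||
          cand$matches > best$matches ||
          (cand$matches == best$matches && cand$identity > best$identity) ||
          (cand$matches == best$matches && cand$identity == best$identity &&
           cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best) || best$rate <= minRate) return(NULL)
  best
}

#' Classify one gap from its two flank hits
#'
#' Rules, in order: both flanks mapped to the same scaffold with
#' consistent orientation and order and no ambiguous base (N) in the
#' intervening sequence -> `closed`; flanks on different scaffolds ->
#' `trans_scaffold_break`; otherwise (a flank unmapped, inconsistent
#' geometry, an oversized intervening span, or an N in between) -> `open`.
#'
#' @param gap Length-one `GRanges` of the gap (used for bookkeeping).
#' @param upHit,downHit Hits from [mapFlank()], or `NULL`.
#' @param newAssembly The named `DNAStringSet` the flanks were mapped to.
#' @param maxSpan Cap on the intervening span in bp (guards against
#'   spurious distant hits).
#'
#' @return A list `status` plus `interveningHasN` (or `NA`).
#' @export
classifyGap <- function(gap, upHit, downHit, newAssembly, maxSpan = 1e6) {
  if (is.null(upHit) || is.null(downHit))
    return(list(status = "open", interveningHasN = NA))
  if (upHit$scaffold != downHit$scaffold)
    return(list(status = "trans_scaffold_break", interveningHasN = NA))
  if (upHit$strand != downHit$strand)
    return(list(status = "open", interveningHasN = NA))
  if (upHit$strand == "+") {
    if (downHit$start <= upHit$start || downHit$end <= upHit$end)
      return(list(status = "open", interveningHasN = NA))
    innerStart <- upHit$end + 1L
    innerEnd <- downHit$start - 1L
  } else {
    if (upHit$start <= downHit$start || upHit$end <= downHit$end)
      return(list(status = "open", interveningHasN = NA))
    innerStart <- downHit$end + 1L
    innerEnd <- upHit$start - 1L
  }
  if (innerEnd - innerStart + 1L > maxSpan)
    return(list(status = "open", interveningHasN = NA))
  hasN <- FALSE
  if (innerStart <= innerEnd) {
    seg <- subseq(newAssembly[[upHit$scaffold]], innerStart, innerEnd)
    hasN <- letterFrequency(seg, "N")[1L] > 0
  }
  if (hasN)
    return(list(status = "open", interveningHasN = TRUE))
  list(status = "closed", interveningHasN = FALSE)
}

#' Audit gap closure between two assemblies
#'
#' Finds every gap (N-run) of `oldAssembly`, extracts its flanks, maps
#' them onto `newAssembly` with the built-in mapper (or uses supplied
#' hits), classifies each gap, and summarizes: counts per status, the
#' closed fraction among non-excluded gaps, and the total length of closed
#' gaps.
#'
#' @param oldAssembly,newAssembly Named `DNAStringSet` objects.
#' @param flank Flank length in bp.
#' @param minRate Minimum aligning rate (see [mapFlank()]).
#' @param maxSpan See [classifyGap()].
#' @param flankHits Optional externally computed hits: a list with one
#'   element per gap, each a list with `up` and `down` entries in
#'   [mapFlank()] format (or `NULL`).
#'
#' @return A list with `table` (one row per gap: scaffold, start, end,
#'   size, status) and `summary` (named counts, `closedFraction`,
#'   `closedLength`).
#' @export
auditGaps <- function(oldAssembly, newAssembly, flank = 500,
                      minRate = 0.7, maxSpan = 1e6, flankHits = NULL) {
  gaps <- findGaps(oldAssembly)
  rows <- lapply(seq_along(gaps), function(i) {
    g <- gaps[i]
    fl <- extractFlanks(oldAssembly, g, flank = flank)
    if (fl$excluded) {
      status <- "excluded"
    } else {
      if (is.null(flankHits)) {
        up <- mapFlank(fl$upstream, newAssembly, minRate = minRate)
        down <- mapFlank(fl$downstream, newAssembly, minRate = minRate)
      } else {
        up <- flankHits[[i]]$up
        down <- flankHits[[i]]$down
      }
      status <- classifyGap(g, up, down, newAssembly,
                            maxSpan = maxSpan)$status
    }
    data.frame(scaffold = as.character(seqnames(g)), start = start(g),
               end = end(g), size = width(g), status = status,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               size = integer(), status = character())
  statuses <- c("closed", "trans_scaffold_break", "open", "excluded")
  counts <- vapply(statuses, function(s) sum(tab$status == s), numeric(1))
  nonExcluded <- sum(counts) - counts[["excluded"]]
  list(table = tab,
       summary = list(
         counts = counts,
         closedFraction = if (nonExcluded > 0)
           counts[["closed"]] / nonExcluded else NA_real_,
         closedLength = sum(tab$size[tab$status == "closed"])))
}
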