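#' Construct an AlignmentSegments object
#'
#' Segments map query intervals to target intervals. Minus-strand target
#' coordinates are stored on the forward strand (lastZ "+ columns"), with
#' the orientation carried by `segStrand`.
#'
#' @param query,target `GRanges` of query/target intervals (equal length).
#' @param segStrand Character "+"/"-" per segment.
#' @param identity Fractional identity in \[0, 1\].
#' @param alignedLength Aligned columns per segment; defaults to the query
#'   width (gapless convention).
#' @param matches Matched-base count per segment; defaults to
#'   `round(identity * alignedLength)`.
#'
#' @return An [AlignmentSegments-class] object.
#' @export
alignmentSegments <- function(query, target, segStrand, identity,
                              alignedLength = width(query),
                              matches = round(identity * alignedLength)) {
  n <- length(query)
  new("AlignmentSegments",
      query = query, target = target,
      segStrand = rep_len(as.character(segStrand), n),
      identity = rep_len(as.numeric(identity), n),
      alignedLength = as.integer(rep_len(alignedLength, n)),
      matches = as.numeric(rep_len(matches, n)))
}

#' @describeIn alignmentSegments Query intervals.
#' @param x An `AlignmentSegments` object.
#' @export
segQuery <- function(x) x@query

#' @describeIn alignmentSegments Target intervals (forward-strand coords).
#' @export
segTarget <- function(x) x@target

#' @describeIn alignmentSegments Per-segment strand.
#' @export
segStrand <- function(x) x@segStrand

#' @describeIn alignmentSegments Per-segment fractional identity.
#' @export
segIdentity <- function(x) x@identity

#' @describeIn alignmentSegments Per-segment aligned length (columns).
#' @export
segAlignedLength <- function(x) x@alignedLength

#' @describeIn alignmentSegments Per-segment matched-base count.
#' @export
segMatches <- function(x) x@matches

#' @export
setMethod("length", "AlignmentSegments", function(x) length(x@query))

#' @export
setMethod("[", "AlignmentSegments", function(x, i, j, ..., drop = TRUE) {
  new("AlignmentSegments", query = x@query[i], target = x@target[i],
      segStrand = x@segStrand[i], identity = x@identity[i],
      alignedLength = x@alignedLength[i], matches = x@matches[i])
})

setMethod("show", "AlignmentSegments", function(object) {
  cat("AlignmentSegments with", length(object), "segments\n")
  if (length(object)) {
    cat(sprintf("  identity: %.4f-%.4f; aligned length: %d-%d; %d on '-'\n",
                min(object@identity), max(object@identity),
                min(object@alignedLength), max(object@alignedLength),
                sum(object@segStrand == "-")))
  }
})

#' @describeIn alignmentSegments Coerce to a data.frame in the TSV dialect
#'   (0-based half-open coordinates).
#' @export
segAsDataFrame <- function(x) {
  data.frame(
    q_name = as.character(seqnames(x@query)),
    q_start = start(x@query) - 1L,
    q_end = end(x@query),
    t_name = as.character(seqnames(x@target)),
    t_strand = x@segStrand,
    t_start = start(x@target) - 1L,
    t_end = end(x@target),
    identity_pct = 100 * x@identity,
    aligned_len = x@alignedLength,
    stringsAsFactors = FALSE)
}

# rbind-like combination of two AlignmentSegments objects
combineSegments <- function(a, b) {
  new("AlignmentSegments",
      query = c(a@query, b@query), target = c(a@target, b@target),
      segStrand = c(a@segStrand, b@segStrand),
      identity = c(a@identity, b@identity),
      alignedLength = c(a@alignedLength, b@alignedLength),
      matches = c(a@matches, b@matches))
}

emptySegments <- function() {
  new("AlignmentSegments", query = GRanges(), target = GRanges(),
      segStrand = character(), identity = numeric(),
      alignedLength = integer(), matches = numeric())
}
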