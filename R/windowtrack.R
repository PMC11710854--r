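#' Construct a WindowTrack
#'
#' @param windows A `GRanges` of windows.
#' @param values Numeric vector of per-window values (`NA` = missing).
#' @param sort Sort windows (and values) by sequence then start first?
#'
#' @return A [WindowTrack-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5001), width = 5000))
#' windowTrack(gr, c(30.2, 29.8))
#' @export
windowTrack <- function(windows, values, sort = TRUE) {
  if (sort && length(windows) > 1L) {
    # radix keeps the ordering locale-independent
    o <- order(as.character(seqnames(windows)), start(windows),
               method = "radix")
    windows <- windows[o]
    values <- values[o]
  }
  new("WindowTrack", windows = windows, values = as.numeric(values))
}

#' @describeIn windowTrack Windows of a track, as a `GRanges`.
#' @param x A `WindowTrack`.
#' @export
trackWindows <- function(x) x@windows

#' @describeIn windowTrack Per-window values of a track.
#' @export
trackValues <- function(x) x@values

#' @describeIn windowTrack Does any pair of windows overlap on one sequence?
#' @export
isOverlapping <- function(x) {
  gr <- x@windows
  if (length(gr) < 2L) return(FALSE)
  sq <- as.character(seqnames(gr))
  same <- sq[-1L] == sq[-length(sq)]
  any(same & start(gr)[-1L] <= end(gr)[-length(gr)])
}

#' @export
setMethod("length", "WindowTrack", function(x) length(x@windows))

setMethod("show", "WindowTrack", function(object) {
  v <- object@values
  cat("WindowTrack with", length(object), "windows on",
      length(unique(as.character(seqnames(object@windows)))), "sequence(s)\n")
  if (length(v)) {
    cat(sprintf("  values: median %.4g [%.4g, %.4g], %d missing\n",
                median(v, na.rm = TRUE), suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  }
})

#' @export
setMethod("[", "WindowTrack", function(x, i, j, ..., drop = TRUE) {
  new("WindowTrack", windows = x@windows[i], values = x@values[i])
})

# Restrict a track to given seqnames.
trackOnSeq <- function(x, seqs) {
  keep <- as.character(seqnames(x@windows)) %in% seqs
  x[keep]
}
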