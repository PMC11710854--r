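#' Normalize a depth track by its peak coverage
#'
#' The peak is the mode of the window-depth histogram (bin width 1x),
#' restricted to bins above 0.25 x the maximum depth so zero-inflated and
#' hemizygous windows do not pull the mode down; the reported peak is the
#' median depth within the modal bin, so a constant track normalizes to
#' exactly 1. On whole-genome data the peak sits at the diploid coverage
#' (sex-linked sequence skews the mean, not the mode).
#'
#' @param track A [WindowTrack-class] of raw depths.
#'
#' @return A list with `track` (values divided by the peak) and `peak` (x
#'   coverage).
#' @export
normalizeDepth <- function(track) {
  v <- trackValues(track)
  ok <- !is.na(v)
  if (!any(ok) || all(v[ok] == 0))
    stop("cannot normalize an all-zero depth track")
  vv <- v[ok]
  bins <- floor(vv)
  keep <- bins > 0.25 * max(vv)
  if (!any(keep)) keep <- rep(TRUE, length(bins))
  tab <- table(bins[keep])
  modal <- as.numeric(names(tab)[which.max(tab)])
  peak <- median(vv[keep][bins[keep] == modal])
  list(track = windowTrack(trackWindows(track), v / peak, sort = FALSE),
       peak = peak)
}

#' Female/male normalized depth ratio per window
#'
#' Computes `(f + pseudocount) / (m + pseudocount)` on normalized depths
#' over an identical window grid. The pseudocount keeps denominators finite
#' on windows where the male has no coverage; the ratio is capped.
#'
#' @param female,male Normalized [WindowTrack-class] objects on identical
#'   grids (diploid windows ~1).
#' @param pseudocount Added to both numerator and denominator (default
#'   0.05 in normalized-depth units).
#' @param cap Upper bound on the ratio (default 10).
#'
#' @return A [WindowTrack-class] of F/M ratios (~2 over X-differentiated
#'   sequence, ~0 over Y, ~1 over autosomes and PARs).
#' @export
fmRatio <- function(female, male, pseudocount = 0.05, cap = 10) {
  fw <- trackWindows(female)
  mw <- trackWindows(male)
  if (length(fw) != length(mw) ||
      !all(as.character(seqnames(fw)) == as.character(seqnames(mw))) ||
      !all(start(fw) == start(mw)) || !all(end(fw) == end(mw)))
    stop("female and male tracks must share an identical window grid")
  r <- (trackValues(female) + pseudocount) /
       (trackValues(male) + pseudocount)
  windowTrack(fw, pmin(r, cap), sort = FALSE)
}

#' Classify scaffolds as X-linked / Y-linked / unclassified
#'
#' A scaffold longer than `minLen` is called X-linked when more than
#' `minFrac` of its usable windows have an F/M ratio inside `xBand`
#' \[1.5, 2.5\], and Y-linked when more than `minFrac` fall inside `yBand`
#' \[0, 0.3\]; otherwise it is unclassified. Band endpoints are inclusive.
#' Missing windows are excluded from denominators. With `minFrac > 0.5`
#' and disjoint bands the two calls are mutually exclusive.
#'
#' @param ratios A [WindowTrack-class] of F/M ratios.
#' @param scaffoldLengths Named vector of scaffold lengths in bp; defaults
#'   to the last window end per scaffold.
#' @param minLen Minimum scaffold length (bp, exclusive) for a call.
#' @param minFrac Minimum fraction of windows in a band (exclusive).
#' @param xBand,yBand Closed ratio intervals for the X and Y calls.
#'
#' @return A `data.frame` with one row per scaffold: `scaffold`, `length`,
#'   `nWindows` (usable), `fractionXBand`, `fractionYBand`, `label`.
#' @export
classifyScaffolds <- function(ratios, scaffoldLengths = NULL,
                              minLen = 10000, minFrac = 0.60,
                              xBand = c(1.5, 2.5), yBand = c(0.0, 0.3)) {
  gr <- trackWindows(ratios)
  v <- trackValues(ratios)
  sq <- as.character(seqnames(gr))
  scaffolds <- unique(sq)
  if (is.null(scaffoldLengths))
    scaffoldLengths <- vapply(split(end(gr), sq), max, numeric(1))[scaffolds]
  res <- lapply(scaffolds, function(s) {
    vs <- v[sq == s]
    usable <- vs[!is.na(vs)]
    n <- length(usable)
    fx <- if (n) mean(usable >= xBand[1] & usable <= xBand[2]) else NA_real_
    fy <- if (n) mean(usable >= yBand[1] & usable <= yBand[2]) else NA_real_
    len <- unname(scaffoldLengths[[s]])
    label <- "unclassified"
    if (n == 0L) {
      warning("scaffold ", s, " has no usable windows")
    } else if (len > minLen) {
      if (fx > minFrac) label <- "X_linked"
      else if (fy > minFrac) label <- "Y_linked"
    }
    data.frame(scaffold = s, length = len, nWindows = n,
               fractionXBand = fx, fractionYBand = fy, label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Delineate pseudoautosomal regions within a scaffold
#'
#' Windows with an F/M ratio inside `parBand` (~1, diploid in both sexes)
#' are labelled PAR; labels are smoothed by majority vote over `smoothK`
#' consecutive windows, and maximal PAR runs of at least `minRun` windows
#' are reported, snapped to window boundaries. This automates what is
#' usually done by eye on depth plots; all knobs are exposed.
#'
#' @param ratios A [WindowTrack-class] of F/M ratios.
#' @param scaffold Scaffold id to scan.
#' @param minRun Minimum run length in windows.
#' @param parBand Closed ratio interval treated as pseudoautosomal.
#' @param smoothK Width (windows) of the majority-vote smoother (odd).
#'
#' @return A `GRanges` of PAR intervals (possibly empty).
#' @export
delineatePar <- function(ratios, scaffold, minRun = 10,
                         parBand = c(0.75, 1.25), smoothK = 5) {
  gr <- trackWindows(ratios)
  keep <- as.character(seqnames(gr)) == scaffold
  if (!any(keep))
    stop("scaffold ", scaffold, " not present in ratio track")
  gr <- gr[keep]
  v <- trackValues(ratios)[keep]
  inBand <- !is.na(v) & v >= parBand[1] & v <= parBand[2]
  n <- length(inBand)
  half <- floor(smoothK / 2)
  smoothed <- vapply(seq_len(n), function(i) {
    w <- inBand[max(1L, i - half):min(n, i + half)]
    mean(w) > 0.5
  }, logical(1))
  r <- rle(smoothed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= minRun)
  if (!length(sel)) return(GRanges())
  GRanges(scaffold,
          IRanges(start(gr)[starts[sel]], end(gr)[ends[sel]]))
}
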