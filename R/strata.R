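#' X/Y identity in fixed windows along the X
#'
#' Projects X-vs-Y alignment segments onto fixed windows of the X (1 kb by
#' default) and reports, per window, matched bases / aligned columns for
#' the columns intersecting the window. When only segment-level identities
#' are available, matched bases over a partial overlap are apportioned
#' uniformly (overlap width x segment identity), which conserves the total
#' match count. Windows with no aligned columns are missing.
#'
#' @param segments An [AlignmentSegments-class]; query = X, target = Y.
#' @param chromSizes Named lengths (bp) of the X sequences; defaults to the
#'   largest query end per sequence.
#' @param window Window size in bp.
#'
#' @return A [WindowTrack-class] of per-window identity fractions.
#' @export
identityWindows <- function(segments, chromSizes = NULL, window = 1000) {
  q <- segQuery(segments)
  if (is.null(chromSizes)) {
    sq <- as.character(seqnames(q))
    chromSizes <- vapply(split(end(q), sq), max, numeric(1))
  }
  wins <- binGenome(chromSizes, window = window)
  aligned <- rep(0, length(wins))
  matched <- rep(0, length(wins))
  if (length(q)) {
    ov <- suppressWarnings(findOverlaps(wins, q))
    if (length(ov)) {
      wI <- queryHits(ov)
      sI <- subjectHits(ov)
      w <- width(pintersect(wins[wI], q[sI]))
      m <- w * segIdentity(segments)[sI]
      aligned <- aligned + as.numeric(tapply(w, factor(wI, seq_along(wins)),
                                             sum, default = 0))
      matched <- matched + as.numeric(tapply(m, factor(wI, seq_along(wins)),
                                             sum, default = 0))
    }
  }
  vals <- ifelse(aligned > 0, matched / aligned, NA_real_)
  windowTrack(wins, vals, sort = FALSE)
}

#' Filter X/Y segments whose Y side aligns better elsewhere
#'
#' An X/Y alignment segment is dropped when its Y span has a competing hit
#' to autosome or PAR sequence with *strictly* higher identity and
#' *strictly* longer aligned length (ties keep the segment). Competing
#' hits are matched on >= 50% reciprocal overlap of the Y spans.
#'
#' @param xySegments X-vs-Y [AlignmentSegments-class] (target = Y spans).
#' @param yVsOtherSegments Y-vs-autosome/PAR [AlignmentSegments-class]
#'   (query = Y spans).
#'
#' @return The retained subset of `xySegments`.
#' @export
filterYSegments <- function(xySegments, yVsOtherSegments) {
  if (!length(xySegments) || !length(yVsOtherSegments))
    return(xySegments)
  ySpans <- segTarget(xySegments)
  comp <- segQuery(yVsOtherSegments)
  ov <- suppressWarnings(findOverlaps(ySpans, comp))
  drop <- rep(FALSE, length(xySegments))
  if (length(ov)) {
    a <- ySpans[queryHits(ov)]
    b <- comp[subjectHits(ov)]
    inter <- width(pintersect(a, b))
    recip <- inter >= 0.5 * width(a) & inter >= 0.5 * width(b)
    better <- segIdentity(yVsOtherSegments)[subjectHits(ov)] >
      segIdentity(xySegments)[queryHits(ov)] &
      segAlignedLength(yVsOtherSegments)[subjectHits(ov)] >
      segAlignedLength(xySegments)[queryHits(ov)]
    drop[unique(queryHits(ov)[recip & better])] <- TRUE
  }
  xySegments[!drop]
}

#' Jukes-Cantor (JC69) divergence from a mismatch proportion
#'
#' `d = -(3/4) ln(1 - (4/3) p)` corrects the observed mismatch proportion
#' for multiple hits; the model saturates at p = 3/4.
#'
#' @param p Mismatch proportion(s) in \[0, 0.75).
#' @return The corrected divergence d (>= p).
#' @examples
#' jc69(0.3)  # ~0.38312
#' @export
jc69 <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("JC69 saturates: p must lie in [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Expected mismatch proportion under JC69 at divergence d
#'
#' The inverse of [jc69()]: `p = (3/4)(1 - exp(-4 d / 3))`.
#'
#' @param d Divergence(s) >= 0.
#' @return Expected mismatch proportion.
#' @export
jc69ExpectedP <- function(d) {
  stopifnot(all(d >= 0))
  0.75 * (1 - exp(-4 * d / 3))
}

#' Build a pairwise alignment with a column mask
#'
#' @param seqX,seqY Gapped sequences (character scalars, "-" = gap).
#' @param mask Logical per column (`TRUE` = excluded, e.g. coding or
#'   repetitive); defaults to all `FALSE`.
#' @return A [PairwiseAlignment-class].
#' @export
pairAlignment <- function(seqX, seqY, mask = NULL) {
  seqX <- toupper(as.character(seqX))
  seqY <- toupper(as.character(seqY))
  if (is.null(mask)) mask <- rep(FALSE, nchar(seqX))
  new("PairwiseAlignment", seqX = seqX, seqY = seqY, mask = mask)
}

# Mismatch indicator over valid (non-gap, non-N, unmasked) columns.
mismatchVector <- function(aln) {
  x <- strsplit(aln@seqX, "", fixed = TRUE)[[1]]
  y <- strsplit(aln@seqY, "", fixed = TRUE)[[1]]
  valid <- !(x %in% c("-", "N")) & !(y %in% c("-", "N")) & !aln@mask
  (x != y)[valid]
}

#' Bootstrap JC69 divergence of a concatenated alignment
#'
#' Computes the point JC69 divergence over the valid columns, then
#' resamples columns with replacement `B` times; the confidence interval
#' is the (2.5th, 97.5th) percentile of the replicate divergences.
#' Replicates whose resampled mismatch proportion reaches JC69 saturation
#' are discarded and counted. Deterministic under `seed`.
#'
#' @param aln A [PairwiseAlignment-class], or a logical mismatch vector
#'   over valid columns.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#'
#' @return A list: `p`, `d`, `nColumns`, `ci` (length 2), `nBootstrap`,
#'   `nDiscarded`, `seed`.
#' @export
bootstrapDivergence <- function(aln, B = 1000, seed = 1L) {
  mism <- if (is(aln, "PairwiseAlignment")) mismatchVector(aln) else
    as.logical(aln)
  L <- length(mism)
  if (L == 0L)
    stop("alignment has no valid columns")
  p <- mean(mism)
  d <- jc69(p)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b)
    mean(mism[sample.int(L, L, replace = TRUE)]), numeric(1))
  bad <- reps >= 0.75
  if (any(bad))
    warning(sum(bad), " bootstrap replicate(s) reached JC69 saturation; discarded")
  dReps <- jc69(reps[!bad])
  ci <- unname(quantile(dReps, c(0.025, 0.975)))
  list(p = p, d = d, nColumns = L, ci = ci, nBootstrap = B,
       nDiscarded = sum(bad), seed = seed)
}

#' Build the male-mutation-bias rate model
#'
#' With male-to-female mutation-rate ratio `alpha`, the per-chromosome
#' rates are A = (alpha+1)/2 mu_f, X = (2+alpha)/3 mu_f, Y = alpha mu_f,
#' so X/Y sequence divergence accumulates at
#' `ratio = (2 + 4 alpha) / (3 + 3 alpha)` times the autosomal divergence
#' rate, and `mu_XY = ratio * mu_AA`.
#'
#' @param alpha Male mutation bias (> 0).
#' @param muAA Autosomal divergence rate per site per year.
#'
#' @return A [RateModel-class].
#' @examples
#' m <- buildRateModel(alpha = 2.95, muAA = 7e-9)
#' rateMuXY(m)  # ~8.15e-9
#' @export
buildRateModel <- function(alpha, muAA) {
  stopifnot(alpha > 0, muAA > 0)
  ratio <- (2 + 4 * alpha) / (3 + 3 * alpha)
  new("RateModel", alpha = alpha, muF = 2 * muAA / (1 + alpha),
      muAA = muAA, ratio = ratio, muXY = ratio * muAA)
}

#' @describeIn buildRateModel XY-to-autosome divergence-rate ratio.
#' @param model A `RateModel`.
#' @export
rateRatio <- function(model) model@ratio

#' @describeIn buildRateModel XY divergence rate (per site per year).
#' @export
rateMuXY <- function(model) model@muXY

#' @describeIn buildRateModel Derived female rate mu_f = 2 mu_AA/(1+alpha).
#' @export
rateMuF <- function(model) model@muF

setMethod("show", "RateModel", function(object) {
  cat(sprintf(paste0("RateModel: alpha = %.4g, mu_AA = %.4g /site/yr\n",
                     "  XY/A ratio = %.6g; mu_XY = %.4g /site/yr; ",
                     "mu_f = %.4g /site/yr\n"),
              object@alpha, object@muAA, object@ratio, object@muXY,
              object@muF))
})

#' Convert a divergence estimate into a stratum age
#'
#' Under a molecular clock, `T = d / mu_XY`; confidence-interval endpoints
#' divide likewise.
#'
#' @param estimate Output of [bootstrapDivergence()] (or any list with
#'   `d` and `ci`).
#' @param model A [RateModel-class].
#'
#' @return A list: `T` (years) and `ci` (years).
#' @export
stratumAge <- function(estimate, model) {
  list(T = estimate$d / model@muXY, ci = estimate$ci / model@muXY)
}
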