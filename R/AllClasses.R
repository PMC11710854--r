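#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' WindowTrack: ordered genomic windows with one numeric value each
#'
#' A thin container pairing a set of genomic windows (a [GRanges]) with one
#' numeric value per window -- sequencing depth, a female/male depth ratio,
#' an X/Y identity fraction, or a GC fraction. Within a sequence the windows
#' are kept sorted by start; overlapping windows are permitted (sliding
#' windows with step < width). Values may be `NA` to mark windows with no
#' usable signal; arithmetic operations skip them.
#'
#' @slot windows A `GRanges` of windows.
#' @slot values Numeric vector, one value per window (`NA` = missing).
#'
#' @seealso [windowTrack()], [trackValues()], [binGenome()]
#' @export
setClass("WindowTrack",
  representation(windows = "GRanges", values = "numeric"))

setValidity("WindowTrack", function(object) {
  msg <- character()
  if (length(object@windows) != length(object@values))
    msg <- c(msg, "length(windows) must equal length(values)")
  if (length(object@windows) > 1L) {
    sq <- as.character(seqnames(object@windows))
    st <- start(object@windows)
    same <- sq[-1L] == sq[-length(sq)]
    if (any(same & st[-1L] < st[-length(st)]))
      msg <- c(msg, "windows must be sorted by start within each sequence")
  }
  if (any(is.infinite(object@values)))
    msg <- c(msg, "values must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' AlignmentSegments: pairwise local alignment blocks
#'
#' Holds a set of pairwise local alignment segments, each mapping a query
#' interval to a target interval with a strand, a fractional identity, an
#' aligned length in columns, and an optional matched-base count. Minus-strand
#' target coordinates are stored on the forward strand (as in lastZ
#' "+ columns"), so a single coordinate system serves both strands.
#'
#' @slot query `GRanges` of query intervals.
#' @slot target `GRanges` of target intervals (forward-strand coordinates).
#' @slot segStrand Character vector of "+"/"-": target orientation relative
#'   to the query.
#' @slot identity Numeric in \[0, 1\].
#' @slot alignedLength Integer, aligned columns (>= 1).
#' @slot matches Numeric matched-base count, or `NA` when unknown.
#'
#' @seealso [alignmentSegments()], [readAlignmentSegments()]
#' @export
setClass("AlignmentSegments",
  representation(query = "GRanges", target = "GRanges",
                 segStrand = "character", identity = "numeric",
                 alignedLength = "integer", matches = "numeric"))

setValidity("AlignmentSegments", function(object) {
  n <- length(object@query)
  msg <- character()
  if (length(object@target) != n || length(object@segStrand) != n ||
      length(object@identity) != n || length(object@alignedLength) != n ||
      length(object@matches) != n)
    msg <- c(msg, "all slots must have equal length")
  if (!all(object@segStrand %in% c("+", "-")))
    msg <- c(msg, "segStrand must be '+' or '-'")
  if (any(object@identity < 0 | object@identity > 1, na.rm = TRUE))
    msg <- c(msg, "identity must lie in [0, 1]")
  if (any(object@alignedLength < 1L))
    msg <- c(msg, "alignedLength must be >= 1")
  bad <- !is.na(object@matches) & object@matches > object@alignedLength
  if (any(bad))
    msg <- c(msg, "matches must not exceed alignedLength")
  if (length(msg)) msg else TRUE
})

#' RateModel: male-mutation-bias divergence-rate model
#'
#' Converts an autosomal divergence rate into an X/Y divergence rate under a
#' male mutation bias `alpha` (ratio of male to female germline mutation
#' rates). Per-chromosome rates are A = (alpha+1)/2 mu_f, X = (2+alpha)/3
#' mu_f, Y = alpha mu_f, so the XY-to-autosome divergence-rate ratio is
#' r = (2+4 alpha)/(3+3 alpha), bounded in (2/3, 4/3) and equal to 1 only at
#' alpha = 1.
#'
#' @slot alpha Male-to-female mutation rate ratio (> 0).
#' @slot muF Female per-site rate per year (derived: 2 mu_AA / (1+alpha)).
#' @slot muAA Autosomal divergence rate per site per year.
#' @slot ratio XY-to-autosome rate ratio r.
#' @slot muXY XY divergence rate, r * mu_AA.
#'
#' @seealso [buildRateModel()], [stratumAge()]
#' @export
setClass("RateModel",
  representation(alpha = "numeric", muF = "numeric", muAA = "numeric",
                 ratio = "numeric", muXY = "numeric"))

setValidity("RateModel", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@ratio <= 2 / 3 || object@ratio >= 4 / 3)
    msg <- c(msg, "ratio must lie in (2/3, 4/3)")
  if (abs(object@muXY - object@ratio * object@muAA) >
      1e-12 * abs(object@muXY))
    msg <- c(msg, "muXY must equal ratio * muAA")
  if (length(msg)) msg else TRUE
})

#' PairwiseAlignment: a gapped two-sequence alignment with a column mask
#'
#' Two equal-length gapped sequences plus a per-column exclusion mask
#' (coding or repetitive columns). Valid columns are those where both
#' sequences carry a non-gap, non-N base and the mask is `FALSE`; only
#' valid columns enter divergence estimation.
#'
#' @slot seqX,seqY Character scalars of equal length; "-" marks gaps.
#' @slot mask Logical per column; `TRUE` = excluded.
#'
#' @seealso [pairAlignment()], [bootstrapDivergence()]
#' @export
setClass("PairwiseAlignment",
  representation(seqX = "character", seqY = "character", mask = "logical"))

setValidity("PairwiseAlignment", function(object) {
  msg <- character()
  if (length(object@seqX) != 1L || length(object@seqY) != 1L)
    msg <- c(msg, "seqX and seqY must be single strings")
  else if (nchar(object@seqX) != nchar(object@seqY))
    msg <- c(msg, "seqX and seqY must have equal length")
  else if (length(object@mask) != nchar(object@seqX))
    msg <- c(msg, "mask length must equal alignment length")
  if (length(msg)) msg else TRUE
})

#' ScenarioConfig: parameters of a synthetic sex-chromosome scenario
#'
#' Collects every knob of the synthetic-data generator. The defaults define
#' the package's reference scenario: a scaled-down genome with three
#' autosomes, an X1/Y1 pair sharing an assembled PAR, an X2/Y2 pair whose
#' PAR is an unplaced scaffold, an unplaced X-Div fragment, three strata of
#' planted divergence, planted palindrome/array/collapsed-amplicon features
#' (plus negative decoys), a gap-closure assembly pair, and a tissue
#' expression matrix with planted testis-specific genes.
#'
#' @slot seed Integer seed; the same config yields byte-identical outputs.
#' @slot autosomeLengths,xSpecificLength,ySpecificLength,parLength,par2Length
#'   Geometry in bp (see [scenarioConfig()]).
#' @slot strataDivergences Planted per-stratum JC69 divergences, each in
#'   \[0, 0.75).
#' @slot stratumLength Length in bp of each stratum block.
#' @slot depthMean Diploid sequencing depth in x coverage.
#' @slot depthDispersion Negative-binomial dispersion of per-window read
#'   counts.
#' @slot readLength Read length in bp used to convert depth to read counts.
#' @slot depthWindow Depth window size in bp.
#' @slot femaleYFloor Contamination floor on female Y depth, as a fraction
#'   of `depthMean`.
#' @slot gcAmplitude,gcPeriod Sinusoidal GC content: 0.42 +/- amplitude with
#'   the given period in bp.
#' @slot gcBiasSlope Linear depth bias per unit GC deviation.
#' @slot hicResolution Hi-C bin size in bp.
#' @slot hicDecayExponent Contact strength is proportional to
#'   distance^-exponent within a chromosome.
#' @slot transRatio Inter-chromosomal baseline relative to the
#'   shortest-distance intra strength, in (0, 1).
#' @slot hicNoiseSd Log-normal multiplicative noise sd on strengths.
#' @slot gapPlan Integer vector c(closed, open, trans, excluded) gap counts.
#' @slot gapSize Size in bp of each planted (non-excluded) gap.
#' @slot nGenes Number of genes in the expression matrix.
#' @slot tissues Tissue names (must include "testis").
#' @slot testisSpecificFraction Fraction of genes planted testis-specific.
#'
#' @seealso [scenarioConfig()], [simulateScenario()]
#' @export
setClass("ScenarioConfig",
  representation(seed = "integer",
                 autosomeLengths = "numeric",
                 xSpecificLength = "numeric",
                 ySpecificLength = "numeric",
                 parLength = "numeric",
                 par2Length = "numeric",
                 strataDivergences = "numeric",
                 stratumLength = "numeric",
                 depthMean = "numeric",
                 depthDispersion = "numeric",
                 readLength = "numeric",
                 depthWindow = "numeric",
                 femaleYFloor = "numeric",
                 gcAmplitude = "numeric",
                 gcPeriod = "numeric",
                 gcBiasSlope = "numeric",
                 hicResolution = "numeric",
                 hicDecayExponent = "numeric",
                 transRatio = "numeric",
                 hicNoiseSd = "numeric",
                 gapPlan = "integer",
                 gapSize = "numeric",
                 nGenes = "integer",
                 tissues = "character",
                 testisSpecificFraction = "numeric"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (any(object@strataDivergences < 0 | object@strataDivergences >= 0.75))
    msg <- c(msg, "strataDivergences must lie in [0, 0.75)")
  if (object@transRatio <= 0 || object@transRatio >= 1)
    msg <- c(msg, "transRatio must lie in (0, 1)")
  if (length(object@gapPlan) != 4L || any(object@gapPlan < 0L))
    msg <- c(msg, "gapPlan must be 4 non-negative counts (closed, open, trans, excluded)")
  if (!"testis" %in% object@tissues)
    msg <- c(msg, "tissues must include 'testis'")
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be > 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: a generated genome with full ground truth
#'
#' The output of [simulateScenario()]: sequences, per-sex depth tracks, GC
#' track, Hi-C interaction records, X/Y and self alignment segments, an
#' assembly pair with planted gaps, an expression matrix -- and, for each,
#' the truth tables needed to score every downstream stage without
#' re-reading sequence.
#'
#' @slot config The [ScenarioConfig-class] that produced the scenario.
#' @slot genome A `DNAStringSet` of all scaffolds.
#' @slot truthScaffoldLabels Named character: scaffold ->
#'   autosome/X_div/Y_div/PAR.
#' @slot truthPars `GRanges` of planted PARs (on their carrier scaffolds).
#' @slot truthPalindromes,truthArrays,truthCollapsed `GRanges` of planted
#'   amplicon features (collapsed regions carry a `copyNumber` column).
#' @slot truthStrata `GRanges` on X with a `divergence` metadata column.
#' @slot repeats `GRanges` of the planted repeat annotation.
#' @slot genes `GRanges` of planted gene models (named); metadata column
#'   `ampliconic` marks the truth calls.
#' @slot depthMale,depthFemale,gcTrack [WindowTrack-class] objects on the
#'   depth window grid.
#' @slot hic `data.frame` of interaction records (chromA, startA, chromB,
#'   startB, strength) with a `resolution` attribute.
#' @slot xySegments,selfSegments,yVsOtherSegments
#'   [AlignmentSegments-class]: X-vs-Y alignment (query = X, target = Y),
#'   self-alignment hits feeding palindrome/array detection, and Y-vs-
#'   autosome/PAR competitor hits.
#' @slot oldAssembly,newAssembly `DNAStringSet` assembly pair for gap
#'   auditing.
#' @slot truthGaps `data.frame` of planted gaps with their true outcome.
#' @slot expression Numeric matrix gene x tissue (TPM).
#' @slot truthSpecificGenes Character vector of planted testis-specific
#'   gene ids.
#'
#' @seealso [simulateScenario()]
#' @export
setClass("SyntheticScenario",
  representation(config = "ScenarioConfig",
                 genome = "DNAStringSet",
                 truthScaffoldLabels = "character",
                 truthPars = "GRanges",
                 truthPalindromes = "GRanges",
                 truthArrays = "GRanges",
                 truthCollapsed = "GRanges",
                 truthStrata = "GRanges",
                 repeats = "GRanges",
                 genes = "GRanges",
                 depthMale = "WindowTrack",
                 depthFemale = "WindowTrack",
                 gcTrack = "WindowTrack",
                 hic = "data.frame",
                 xySegments = "AlignmentSegments",
                 selfSegments = "AlignmentSegments",
                 yVsOtherSegments = "AlignmentSegments",
                 oldAssembly = "DNAStringSet",
                 newAssembly = "DNAStringSet",
                 truthGaps = "data.frame",
                 expression = "matrix",
                 truthSpecificGenes = "character"))
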