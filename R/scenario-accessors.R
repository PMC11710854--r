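#' Accessors for SyntheticScenario components
#'
#' @param scenario A [SyntheticScenario-class].
#' @name scenario-accessors
NULL

#' @describeIn scenario-accessors The generating [ScenarioConfig-class].
#' @export
scenarioConfigOf <- function(scenario) scenario@config

#' @describeIn scenario-accessors All scaffold sequences (`DNAStringSet`).
#' @export
scenarioGenome <- function(scenario) scenario@genome

#' @describeIn scenario-accessors Named scaffold lengths in bp.
#' @export
scenarioSizes <- function(scenario)
  setNames(Biostrings::width(scenario@genome), names(scenario@genome))

#' @describeIn scenario-accessors Truth labels: scaffold ->
#'   autosome/X_div/Y_div/PAR.
#' @export
truthLabels <- function(scenario) scenario@truthScaffoldLabels

#' @describeIn scenario-accessors Planted PAR intervals (`GRanges`).
#' @export
truthPars <- function(scenario) scenario@truthPars

#' @describeIn scenario-accessors Planted palindromes (`GRanges` spans).
#' @export
truthPalindromes <- function(scenario) scenario@truthPalindromes

#' @describeIn scenario-accessors Planted tandem arrays (`GRanges`).
#' @export
truthArrays <- function(scenario) scenario@truthArrays

#' @describeIn scenario-accessors Planted collapsed amplicons (`GRanges`
#'   with `copyNumber`).
#' @export
truthCollapsed <- function(scenario) scenario@truthCollapsed

#' @describeIn scenario-accessors Planted strata (`GRanges` on X with
#'   `divergence`).
#' @export
truthStrata <- function(scenario) scenario@truthStrata

#' @describeIn scenario-accessors Planted gap table (scaffold, start, end,
#'   size, outcome).
#' @export
truthGaps <- function(scenario) scenario@truthGaps

#' @describeIn scenario-accessors Planted testis-specific gene ids.
#' @export
truthSpecificGenes <- function(scenario) scenario@truthSpecificGenes

#' @describeIn scenario-accessors Repeat annotation (`GRanges`).
#' @export
scenarioRepeats <- function(scenario) scenario@repeats

#' @describeIn scenario-accessors Gene models (named `GRanges` with an
#'   `ampliconic` truth column).
#' @export
scenarioGenes <- function(scenario) scenario@genes

#' @describeIn scenario-accessors Depth track for one sex.
#' @param sex "male" or "female".
#' @export
depthTrack <- function(scenario, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") scenario@depthMale else scenario@depthFemale
}

#' @describeIn scenario-accessors GC-content track.
#' @export
gcTrack <- function(scenario) scenario@gcTrack

#' @describeIn scenario-accessors Hi-C interaction records.
#' @export
hicRecords <- function(scenario) scenario@hic

#' @describeIn scenario-accessors X-vs-Y alignment segments.
#' @export
xySegments <- function(scenario) scenario@xySegments

#' @describeIn scenario-accessors Self-alignment segments (palindrome /
#'   array evidence).
#' @export
selfSegments <- function(scenario) scenario@selfSegments

#' @describeIn scenario-accessors Y-vs-autosome/PAR competitor segments.
#' @export
yVsOtherSegments <- function(scenario) scenario@yVsOtherSegments

#' @describeIn scenario-accessors The gapped "old" assembly.
#' @export
oldAssembly <- function(scenario) scenario@oldAssembly

#' @describeIn scenario-accessors The "new" assembly.
#' @export
newAssembly <- function(scenario) scenario@newAssembly

#' @describeIn scenario-accessors Expression matrix (genes x tissues,
#'   TPM).
#' @export
expressionMatrix <- function(scenario) scenario@expression

#' @describeIn scenario-accessors Non-PAR sex-linked intervals
#'   (`GRanges`), derived from the truth labels minus the planted PARs.
#' @export
sexDivRegions <- function(scenario) {
  labels <- scenario@truthScaffoldLabels
  sex <- names(labels)[labels %in% c("X_div", "Y_div")]
  sizes <- scenarioSizes(scenario)[sex]
  full <- GRanges(sex, IRanges(1, unname(sizes)))
  suppressWarnings(
    GenomicRanges::setdiff(full, scenario@truthPars, ignore.strand = TRUE))
}
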