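#' Configure a synthetic sex-chromosome scenario
#'
#' Returns a [ScenarioConfig-class] with the package's reference study
#' conditions (scaled-down genome, 30x depth, three strata, planted
#' amplicon features and gaps). Any parameter can be overridden.
#'
#' The reference genome comprises three 400-kb autosomes; an X1 (150-kb
#' PAR + three 100-kb strata + 150-kb X-specific tail) with its Y1
#' counterpart (same PAR and strata, 100-kb Y-specific tail carrying a
#' planted palindrome and a collapsed 4-copy amplicon); a second pair
#' X2/Y2 whose 200-kb PAR is an *unplaced* scaffold (`scaffold_par`); and
#' an unplaced 150-kb X-Div fragment (`scaffold_xdiv`) belonging at the
#' end of X1. A tandem array (6 x 5 kb at ~99.5% identity) is planted on
#' X2, plus two negative decoys: a short-arm (7 kb) inverted repeat on X1
#' and a fully repeat-annotated palindrome on A1.
#'
#' @param seed Integer seed.
#' @param ... Overrides for any [ScenarioConfig-class] slot.
#' @return A [ScenarioConfig-class].
#' @examples
#' cfg <- scenarioConfig(seed = 1)
#' @export
scenarioConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    autosomeLengths = c(A1 = 400000, A2 = 400000, A3 = 400000),
    xSpecificLength = 150000,
    ySpecificLength = 100000,
    parLength = 150000,
    par2Length = 200000,
    strataDivergences = c(0.05, 0.20, 0.652),
    stratumLength = 100000,
    depthMean = 30,
    depthDispersion = 0.005,
    readLength = 150,
    depthWindow = 5000,
    femaleYFloor = 0.02,
    gcAmplitude = 0.08,
    gcPeriod = 60000,
    gcBiasSlope = 1.5,
    hicResolution = 25000,
    hicDecayExponent = 1,
    transRatio = 0.02,
    hicNoiseSd = 0.1,
    gapPlan = c(closed = 10L, open = 5L, trans = 5L, excluded = 2L),
    gapSize = 100,
    nGenes = 60L,
    tissues = c("brain", "liver", "kidney", "heart", "lung", "testis"),
    testisSpecificFraction = 0.2)
  args <- list(...)
  if (length(args)) {
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
      stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(args)] <- args
  }
  defaults$seed <- as.integer(defaults$seed)
  defaults$gapPlan <- setNames(as.integer(defaults$gapPlan),
                               names(defaults$gapPlan))
  defaults$nGenes <- as.integer(defaults$nGenes)
  do.call(new, c(list("ScenarioConfig"), defaults))
}

# ---- low-level sequence helpers (character-vector representation) -------

# per-base GC fraction along a scaffold: sinusoid around 0.42
.gcProfile <- function(len, amplitude, period) {
  0.42 + amplitude * sin(2 * pi * seq_len(len) / period)
}

.randChars <- function(len, gcVec = rep(0.42, len)) {
  isGC <- runif(len) < gcVec
  pick <- runif(len) < 0.5
  out <- character(len)
  out[isGC & pick] <- "G"
  out[isGC & !pick] <- "C"
  out[!isGC & pick] <- "A"
  out[!isGC & !pick] <- "T"
  out
}

# JC-style substitution: each site changes with probability p to a
# uniformly random different base (the JC transition matrix at that p)
.mutateChars <- function(x, p) {
  idx <- which(runif(length(x)) < p)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(x[idx], bases)
    x[idx] <- bases[((cur - 1L + sample.int(3L, length(idx),
                                            replace = TRUE)) %% 4L) + 1L]
  }
  x
}

.revcompChars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

.collapseSeq <- function(chars) paste(chars, collapse = "")

# realized identity between two equal-length character vectors
.realizedIdentity <- function(a, b) {
  mm <- sum(a != b)
  list(identity = 1 - mm / length(a), matches = length(a) - mm)
}

# ---- scenario assembly --------------------------------------------------

#' Generate a synthetic scenario with full ground truth
#'
#' Builds the genome (PARs copied identically into their X and Y carriers;
#' strata derived from a common ancestor by JC-style substitutions at half
#' the planted divergence on each branch; palindrome/array/collapsed
#' features planted with realized identities recorded), the per-sex depth
#' tracks, the GC track, Hi-C interaction records, the X/Y and self
#' alignment segments, the gap-audit assembly pair, and the expression
#' matrix. Fully deterministic under the config seed.
#'
#' @param config A [ScenarioConfig-class].
#' @return A [SyntheticScenario-class].
#' @export
simulateScenario <- function(config) {
  set.seed(config@seed)
  parLen <- config@parLength
  nStrata <- length(config@strataDivergences)
  strataLen <- nStrata * config@stratumLength
  xSpec <- config@xSpecificLength
  ySpec <- config@ySpecificLength
  x1Len <- parLen + strataLen + xSpec
  y1Len <- parLen + strataLen + ySpec
  x2Len <- 400000
  y2Len <- 300000
  xdivFragLen <- 150000

  gc <- function(len) .gcProfile(len, config@gcAmplitude, config@gcPeriod)

  # --- sequences ---
  parChars <- .randChars(parLen, gc(parLen))
  ancestor <- .randChars(strataLen, gc(strataLen))
  xStrata <- ancestor
  yStrata <- ancestor
  for (k in seq_len(nStrata)) {
    span <- (k - 1) * config@stratumLength + seq_len(config@stratumLength)
    pBranch <- jc69ExpectedP(config@strataDivergences[k] / 2)
    xStrata[span] <- .mutateChars(xStrata[span], pBranch)
    yStrata[span] <- .mutateChars(yStrata[span], pBranch)
  }
  xSpecChars <- .randChars(xSpec, gc(xSpec))
  ySpecChars <- .randChars(ySpec, gc(ySpec))

  # planted palindrome on Y1 Y-specific tail (coordinates within Y1)
  palArm <- 12000
  palSpacer <- 10000
  palArm1Start <- parLen + strataLen + 5001          # 455001 with defaults
  arm1 <- .randChars(palArm, rep(0.42, palArm))
  arm2 <- .mutateChars(.revcompChars(arm1), 0.005)
  off <- palArm1Start - (parLen + strataLen) - 1
  ySpecChars[off + seq_len(palArm)] <- arm1
  palArm2Start <- palArm1Start + palArm + palSpacer
  ySpecChars[off + palArm + palSpacer + seq_len(palArm)] <- arm2
  palId <- .realizedIdentity(arm1, .revcompChars(arm2))

  # collapsed 4-copy amplicon on Y1 Y-specific tail
  collapseStart <- parLen + strataLen + 50001        # 500001 with defaults
  collapseEnd <- collapseStart + 20000 - 1

  # short-arm decoy inverted repeat on X1 X-specific tail
  decoyArm <- 7000
  decoyA1Start <- parLen + strataLen + 50001
  decoyA2Start <- decoyA1Start + decoyArm + 10000
  # identity ~0.985: above the palindrome cutoff (0.98) so rejection is
  # driven by the 8-kb arm rule, below the array cutoff (0.99) so the
  # array channel ignores it
  dArm1 <- .randChars(decoyArm, rep(0.42, decoyArm))
  dArm2 <- .mutateChars(.revcompChars(dArm1), 0.015)
  offX <- decoyA1Start - (parLen + strataLen) - 1
  xSpecChars[offX + seq_len(decoyArm)] <- dArm1
  xSpecChars[offX + decoyArm + 10000 + seq_len(decoyArm)] <- dArm2
  decoyId <- .realizedIdentity(dArm1, .revcompChars(dArm2))

  x1Chars <- c(parChars, xStrata, xSpecChars)
  y1Chars <- c(parChars, yStrata, ySpecChars)

  # X2 with a planted tandem array (6 x 5 kb) and an OR gene inside it
  x2Chars <- .randChars(x2Len, gc(x2Len))
  unitLen <- 5000
  nUnits <- 6
  arrayStart <- 150001
  unit <- .randChars(unitLen, rep(0.42, unitLen))
  copies <- lapply(seq_len(nUnits), function(i) .mutateChars(unit, 0.0025))
  for (i in seq_len(nUnits))
    x2Chars[arrayStart - 1 + (i - 1) * unitLen + seq_len(unitLen)] <-
      copies[[i]]
  arrayEnd <- arrayStart + nUnits * unitLen - 1

  y2Chars <- .randChars(y2Len, gc(y2Len))
  par2Chars <- .randChars(config@par2Length, gc(config@par2Length))
  xdivFragChars <- .randChars(xdivFragLen, gc(xdivFragLen))

  autosomes <- lapply(config@autosomeLengths, function(len)
    .randChars(len, gc(len)))

  # repeat-annotated decoy palindrome on A1
  repArm <- 10000
  repA1Start <- 100001
  repA2Start <- repA1Start + repArm + 20000
  rArm1 <- .randChars(repArm, rep(0.42, repArm))
  rArm2 <- .mutateChars(.revcompChars(rArm1), 0.005)
  autosomes[[1]][repA1Start - 1 + seq_len(repArm)] <- rArm1
  autosomes[[1]][repA2Start - 1 + seq_len(repArm)] <- rArm2
  repId <- .realizedIdentity(rArm1, .revcompChars(rArm2))

  seqChars <- c(autosomes,
                list(X1 = x1Chars, Y1 = y1Chars, X2 = x2Chars,
                     Y2 = y2Chars, scaffold_par = par2Chars,
                     scaffold_xdiv = xdivFragChars))
  genome <- DNAStringSet(vapply(seqChars, .collapseSeq, character(1)))

  # --- truth tables ---
  autoNames <- names(config@autosomeLengths)
  labels <- c(setNames(rep("autosome", length(autoNames)), autoNames),
              X1 = "X_div", Y1 = "Y_div", X2 = "X_div", Y2 = "Y_div",
              scaffold_par = "PAR", scaffold_xdiv = "X_div")
  truthPars <- GRanges(c("X1", "Y1", "scaffold_par"),
                       IRanges(1, c(parLen, parLen, config@par2Length)))
  truthPalindromes <- GRanges("Y1", IRanges(palArm1Start,
                                            palArm2Start + palArm - 1))
  truthArrays <- GRanges("X2", IRanges(arrayStart, arrayEnd))
  truthCollapsed <- GRanges("Y1", IRanges(collapseStart, collapseEnd))
  mcols(truthCollapsed)$copyNumber <- 4
  truthStrata <- GRanges("X1",
    IRanges(parLen + (seq_len(nStrata) - 1) * config@stratumLength + 1,
            parLen + seq_len(nStrata) * config@stratumLength))
  mcols(truthStrata)$divergence <- config@strataDivergences
  repeats <- GRanges(autoNames[1],
                     IRanges(repA1Start - 5000,
                             repA2Start + repArm - 1 + 5000))

  genes <- GRanges(c("Y1", "X2", "Y1", "X2", autoNames[1]),
                   IRanges(c(palArm1Start + 1000, arrayStart + 5000,
                             collapseStart + 5000, arrayStart + 10000,
                             200001),
                           width = c(10000, 5000, 10000, 5000, 10000)))
  names(genes) <- c("PALY1", "ARRX2", "CNVY1", "OR5X1", "HKA1")
  mcols(genes)$ampliconic <- c(TRUE, TRUE, TRUE, FALSE, FALSE)

  # --- alignment segments ---
  # X-vs-Y strata segments, 10-kb pieces with realized identities
  segLen <- 10000
  segStarts <- integer()
  ids <- numeric()
  for (k in seq_len(nStrata)) {
    s0 <- (k - 1) * config@stratumLength
    for (j in seq_len(config@stratumLength / segLen)) {
      span <- s0 + (j - 1) * segLen + seq_len(segLen)
      ri <- .realizedIdentity(xStrata[span], yStrata[span])
      segStarts <- c(segStarts, parLen + span[1])
      ids <- c(ids, ri$identity)
    }
  }
  # spurious X/Y segment whose Y span aligns better to an autosome
  xq <- c(GRanges("X1", IRanges(segStarts, width = segLen)),
          GRanges("X1", IRanges(430001, 435000)))
  yt <- c(GRanges("Y1", IRanges(segStarts, width = segLen)),
          GRanges("Y1", IRanges(530001, 535000)))
  ids <- c(ids, 0.90)
  xySegments <- alignmentSegments(xq, yt, "+", ids)
  yVsOtherSegments <- alignmentSegments(
    GRanges("Y1", IRanges(530001, 535000)),
    GRanges(autoNames[1], IRanges(50001, 56000)),
    "+", 0.95, alignedLength = 6000)

  # self-alignment segments: the palindrome, the two decoys, array hits
  selfChrom <- c("Y1", "X1", autoNames[1])
  selfQStart <- c(palArm1Start, decoyA1Start, repA1Start)
  selfTStart <- c(palArm2Start, decoyA2Start, repA2Start)
  selfWidth <- c(palArm, decoyArm, repArm)
  selfStrand <- c("-", "-", "-")
  selfId <- c(palId$identity, decoyId$identity, repId$identity)
  pairsIdx <- which(upper.tri(matrix(0, nUnits, nUnits)), arr.ind = TRUE)
  for (r in seq_len(nrow(pairsIdx))) {
    i <- pairsIdx[r, 1]; j <- pairsIdx[r, 2]
    ri <- .realizedIdentity(copies[[i]], copies[[j]])
    for (pr in list(c(i, j), c(j, i))) {
      selfChrom <- c(selfChrom, "X2")
      selfQStart <- c(selfQStart, arrayStart + (pr[1] - 1) * unitLen)
      selfTStart <- c(selfTStart, arrayStart + (pr[2] - 1) * unitLen)
      selfWidth <- c(selfWidth, unitLen)
      selfStrand <- c(selfStrand, "+")
      selfId <- c(selfId, ri$identity)
    }
  }
  selfSegments <- alignmentSegments(
    GRanges(selfChrom, IRanges(selfQStart, width = selfWidth)),
    GRanges(selfChrom, IRanges(selfTStart, width = selfWidth)),
    selfStrand, selfId)

  scenario <- new("SyntheticScenario",
    config = config, genome = genome,
    truthScaffoldLabels = labels, truthPars = truthPars,
    truthPalindromes = truthPalindromes, truthArrays = truthArrays,
    truthCollapsed = truthCollapsed, truthStrata = truthStrata,
    repeats = repeats, genes = genes,
    depthMale = windowTrack(GRanges(), numeric()),
    depthFemale = windowTrack(GRanges(), numeric()),
    gcTrack = windowTrack(GRanges(), numeric()),
    hic = data.frame(),
    xySegments = xySegments, selfSegments = selfSegments,
    yVsOtherSegments = yVsOtherSegments,
    oldAssembly = DNAStringSet(), newAssembly = DNAStringSet(),
    truthGaps = data.frame(),
    expression = matrix(numeric(), 0, 0),
    truthSpecificGenes = character())

  scenario@gcTrack <- .gcWindows(scenario)
  scenario@depthMale <- simulateDepth(scenario, "male")
  scenario@depthFemale <- simulateDepth(scenario, "female")
  scenario@hic <- simulateHic(scenario)
  ap <- simulateAssemblyPair(config)
  scenario@oldAssembly <- ap$old
  scenario@newAssembly <- ap$new
  scenario@truthGaps <- ap$truth
  ex <- .simulateExpression(config)
  scenario@expression <- ex$matrix
  scenario@truthSpecificGenes <- ex$specific
  scenario
}

# GC fraction per depth window, measured from the generated sequence
.gcWindows <- function(scenario) {
  config <- scenario@config
  sizes <- setNames(Biostrings::width(scenario@genome),
                    names(scenario@genome))
  wins <- binGenome(sizes, config@depthWindow, config@depthWindow)
  gcv <- unlist(lapply(names(scenario@genome), function(nm) {
    w <- wins[as.character(seqnames(wins)) == nm]
    v <- Biostrings::Views(scenario@genome[[nm]],
                           start(w), end(w))
    letterFrequency(v, "GC", as.prob = TRUE)[, 1]
  }))
  windowTrack(wins, gcv, sort = FALSE)
}

# per-window copy number for one sex; -1 flags the female-Y noise floor
.windowCopyNumber <- function(scenario, sex) {
  wins <- trackWindows(scenario@gcTrack)
  sq <- as.character(seqnames(wins))
  mid <- (start(wins) + end(wins)) / 2
  labels <- scenario@truthScaffoldLabels[sq]
  cn <- ifelse(labels %in% c("autosome", "PAR"), 2,
               ifelse(labels == "X_div",
                      if (sex == "male") 1 else 2,
                      if (sex == "male") 1 else -1))
  # embedded PARs are diploid in both sexes
  pars <- scenario@truthPars
  for (i in seq_along(pars)) {
    hit <- sq == as.character(seqnames(pars[i])) &
      mid >= start(pars[i]) & mid <= end(pars[i])
    cn[hit] <- 2
  }
  # collapsed amplicons multiply the male copy number
  if (sex == "male") {
    col <- scenario@truthCollapsed
    for (i in seq_along(col)) {
      hit <- sq == as.character(seqnames(col[i])) &
        mid >= start(col[i]) & mid <= end(col[i])
      cn[hit] <- cn[hit] * mcols(col)$copyNumber[i]
    }
  }
  cn
}

#' Simulate a per-window depth track for one sex
#'
#' Per-window read counts are negative binomial with mean
#' `depthMean * copyNumber / 2 * window / readLength`, modulated by the
#' planted GC bias; depth is reads x readLength / window. Copy numbers
#' follow sex and truth label (male X-Div 1, female X-Div 2, male Y-Div 1,
#' female Y-Div 0 + contamination floor, autosome/PAR 2); collapsed
#' amplicons multiply the male copy number.
#'
#' @param scenario A [SyntheticScenario-class].
#' @param sex "male" or "female".
#' @param seed Integer seed; the default reproduces the scenario slot.
#' @return A [WindowTrack-class] of depths.
#' @export
simulateDepth <- function(scenario, sex = c("male", "female"),
                          seed = NULL) {
  sex <- match.arg(sex)
  config <- scenario@config
  if (is.null(seed))
    seed <- config@seed + if (sex == "male") 104729L else 104743L
  set.seed(seed)
  wins <- trackWindows(scenario@gcTrack)
  gcv <- trackValues(scenario@gcTrack)
  cn <- .windowCopyNumber(scenario, sex)
  mu <- ifelse(cn < 0, config@depthMean * config@femaleYFloor,
               config@depthMean * cn / 2)
  mu <- mu * (1 + config@gcBiasSlope * (gcv - 0.42))
  mu <- pmax(mu, 1e-6)
  w <- width(wins)
  reads <- rnbinom(length(mu), mu = mu * w / config@readLength,
                   size = 1 / config@depthDispersion)
  windowTrack(wins, reads * config@readLength / w, sort = FALSE)
}

# truth placements of each scaffold on its chromosome(s): list of
# (chrom, offset); scaffold_par sits at the head of both X2 and Y2
.truthPlacements <- function(scenario) {
  config <- scenario@config
  parLen <- config@parLength
  nStrata <- length(config@strataDivergences)
  x1Len <- parLen + nStrata * config@stratumLength +
    config@xSpecificLength
  auto <- names(config@autosomeLengths)
  pl <- c(setNames(lapply(auto, function(a)
    list(list(chrom = a, offset = 0))), auto),
    list(X1 = list(list(chrom = "chrX1", offset = 0)),
         scaffold_xdiv = list(list(chrom = "chrX1", offset = x1Len)),
         Y1 = list(list(chrom = "chrY1", offset = 0)),
         X2 = list(list(chrom = "chrX2", offset = config@par2Length)),
         Y2 = list(list(chrom = "chrY2", offset = config@par2Length)),
         scaffold_par = list(list(chrom = "chrX2", offset = 0),
                             list(chrom = "chrY2", offset = 0))))
  pl
}

#' Simulate Hi-C interaction records
#'
#' Bin pairs on the same underlying chromosome (per the truth placement of
#' each scaffold, including unplaced ones) get strength
#' `(d / resolution)^-decay` for genomic distance d, with log-normal
#' noise; all other pairs sit at the `transRatio` baseline. The unplaced
#' PAR scaffold is placed at the head of both chromosomes of its pair, so
#' it carries intra-chromosomal profiles with both.
#'
#' @param scenario A [SyntheticScenario-class].
#' @param resolution Bin size in bp (default: config).
#' @param seed Integer seed; the default reproduces the scenario slot.
#' @return Interaction data.frame with a `resolution` attribute.
#' @export
simulateHic <- function(scenario, resolution = NULL, seed = NULL) {
  config <- scenario@config
  if (is.null(resolution)) resolution <- config@hicResolution
  if (is.null(seed)) seed <- config@seed + 104759L
  set.seed(seed)
  placements <- .truthPlacements(scenario)
  sizes <- setNames(Biostrings::width(scenario@genome),
                    names(scenario@genome))
  bins <- do.call(rbind, lapply(names(sizes), function(nm) {
    starts <- seq(0, max(sizes[[nm]] - 1, 0), by = resolution)
    data.frame(scaffold = nm, start = starts,
               center = pmin(starts + resolution / 2, sizes[[nm]]),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(bins)
  ii <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  jj <- unlist(lapply(seq_len(n), function(i) i:n))
  # minimal genomic distance over shared chromosomes; NA when none shared
  dist <- rep(NA_real_, length(ii))
  plA <- placements[bins$scaffold[ii]]
  plB <- placements[bins$scaffold[jj]]
  for (k in seq_along(ii)) {
    best <- NA_real_
    for (a in plA[[k]]) for (b in plB[[k]]) {
      if (a$chrom == b$chrom) {
        d <- abs((a$offset + bins$center[ii[k]]) -
                 (b$offset + bins$center[jj[k]]))
        if (is.na(best) || d < best) best <- d
      }
    }
    dist[k] <- best
  }
  strength <- ifelse(is.na(dist), config@transRatio,
                     pmax(dist, resolution) / resolution) ^
    ifelse(is.na(dist), 1, -config@hicDecayExponent)
  strength <- ifelse(is.na(dist), config@transRatio, strength)
  strength <- strength * exp(rnorm(length(strength), 0, config@hicNoiseSd))
  out <- data.frame(chromA = bins$scaffold[ii], startA = bins$start[ii],
                    chromB = bins$scaffold[jj], startB = bins$start[jj],
                    strength = strength, stringsAsFactors = FALSE)
  attr(out, "resolution") <- resolution
  out
}

#' Simulate an assembly pair with planted gap outcomes
#'
#' Builds an "old" (gapped) assembly with one N-run per planned gap and a
#' "new" assembly realizing each outcome: closed gaps get contiguous
#' sequence, open gaps lose one flank, trans gaps put the two flanks on
#' different scaffolds. Excluded gaps alternate the two exclusion causes
#' (size < 5 bp; gap within 200 bp of a scaffold end).
#'
#' @param config A [ScenarioConfig-class].
#' @param seed Integer seed; the default reproduces the scenario slots.
#' @return A list: `old`, `new` (`DNAStringSet`), `truth` (data.frame:
#'   scaffold, start, end, size, outcome).
#' @export
simulateAssemblyPair <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config@seed + 104773L
  set.seed(seed)
  plan <- config@gapPlan
  gapSize <- config@gapSize
  oldSeqs <- list()
  newSeqs <- list()
  truth <- list()
  addGap <- function(kind, idx) {
    nm <- sprintf("old_%s_%d", kind, idx)
    L1 <- .randChars(1000)
    L2 <- .randChars(1000)
    if (kind == "excl_size") {
      old <- c(L1, rep("N", 4), L2)
      gstart <- 1001; gend <- 1004; outcome <- "excluded"
      newSeqs[[sprintf("new_%s_%d", kind, idx)]] <<- c(.randChars(500))
    } else if (kind == "excl_end") {
      head <- .randChars(150)
      old <- c(head, rep("N", gapSize), L2)
      gstart <- 151; gend <- 150 + gapSize; outcome <- "excluded"
      newSeqs[[sprintf("new_%s_%d", kind, idx)]] <<- c(.randChars(500))
    } else {
      old <- c(L1, rep("N", gapSize), L2)
      gstart <- 1001; gend <- 1000 + gapSize
      outcome <- switch(kind, closed = "closed", open = "open",
                        trans = "trans_scaffold_break")
      ctx1 <- .randChars(400)
      ctx2 <- .randChars(400)
      if (kind == "closed") {
        fill <- .randChars(gapSize)
        newSeqs[[sprintf("new_%s_%d", kind, idx)]] <<-
          c(ctx1, L1, fill, L2, ctx2)
      } else if (kind == "open") {
        newSeqs[[sprintf("new_%s_%d", kind, idx)]] <<- c(ctx1, L1, ctx2)
      } else {
        newSeqs[[sprintf("new_%s_%da", kind, idx)]] <<- c(ctx1, L1, ctx2)
        newSeqs[[sprintf("new_%s_%db", kind, idx)]] <<-
          c(.randChars(400), L2, .randChars(400))
      }
    }
    oldSeqs[[nm]] <<- old
    truth[[length(truth) + 1L]] <<- data.frame(
      scaffold = nm, start = gstart, end = gend, size = gend - gstart + 1,
      outcome = outcome, stringsAsFactors = FALSE)
  }
  for (i in seq_len(plan[["closed"]])) addGap("closed", i)
  for (i in seq_len(plan[["open"]])) addGap("open", i)
  for (i in seq_len(plan[["trans"]])) addGap("trans", i)
  for (i in seq_len(plan[["excluded"]]))
    addGap(if (i %% 2 == 1) "excl_size" else "excl_end", i)
  list(old = DNAStringSet(vapply(oldSeqs, .collapseSeq, character(1))),
       new = DNAStringSet(vapply(newSeqs, .collapseSeq, character(1))),
       truth = do.call(rbind, truth))
}

# expression matrix with planted testis-specific genes
.simulateExpression <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config@seed + 104779L
  set.seed(seed)
  n <- config@nGenes
  tissues <- config@tissues
  nSpec <- round(n * config@testisSpecificFraction)
  genes <- sprintf("gene%03d", seq_len(n))
  specific <- genes[seq_len(nSpec)]
  mat <- matrix(0, n, length(tissues), dimnames = list(genes, tissues))
  for (i in seq_len(n)) {
    if (i <= nSpec) {
      v <- runif(length(tissues), 0, 0.5)
      v[tissues == "testis"] <- exp(rnorm(1, log(200), 0.3))
    } else {
      base <- exp(rnorm(1, log(50), 0.5))
      v <- base * exp(rnorm(length(tissues), 0, 0.3))
    }
    mat[i, ] <- v
  }
  list(matrix = mat, specific = specific)
}

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario (seed", object@config@seed, ")\n")
  cat("  scaffolds:", length(object@genome), "(",
      sum(Biostrings::width(object@genome)), "bp )\n")
  cat("  labels:", paste(sprintf("%s=%s", names(object@truthScaffoldLabels),
                                 object@truthScaffoldLabels),
                         collapse = ", "), "\n")
  cat("  strata divergences:",
      paste(mcols(object@truthStrata)$divergence, collapse = ", "), "\n")
  cat("  planted gaps:", nrow(object@truthGaps), "; expression:",
      nrow(object@expression), "genes x", ncol(object@expression),
      "tissues\n")
})

#' Extract the gapless X/Y alignment of one stratum
#'
#' Returns the planted stratum's X and Y sequences as an equal-length
#' (gapless) [PairwiseAlignment-class], ready for
#' [bootstrapDivergence()].
#'
#' @param scenario A [SyntheticScenario-class].
#' @param stratum Stratum index (1-based).
#' @return A [PairwiseAlignment-class].
#' @export
stratumAlignment <- function(scenario, stratum) {
  st <- scenario@truthStrata[stratum]
  x <- as.character(subseq(scenario@genome[["X1"]], start(st), end(st)))
  y <- as.character(subseq(scenario@genome[["Y1"]], start(st), end(st)))
  pairAlignment(x, y)
}

#' Write every scenario file to a directory
#'
#' Emits the standard-format files (FASTA genome and assembly pair,
#' bedGraph depth and GC tracks, interaction TSV, alignment TSVs,
#' repeat/gene BEDs, expression TSV) plus `truth_*.tsv` tables, all
#' re-parseable with the package readers.
#'
#' @param scenario A [SyntheticScenario-class].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeFastaFile(scenario@genome, p("genome.fa"))
  writeFastaFile(scenario@oldAssembly, p("assembly_old.fa"))
  writeFastaFile(scenario@newAssembly, p("assembly_new.fa"))
  writeBedGraph(scenario@depthMale, p("depth_male.bedgraph"))
  writeBedGraph(scenario@depthFemale, p("depth_female.bedgraph"))
  writeBedGraph(scenario@gcTrack, p("gc.bedgraph"))
  writeInteractions(scenario@hic, p("hic.tsv"))
  writeAlignmentSegments(scenario@xySegments, p("xy_segments.tsv"))
  writeAlignmentSegments(scenario@selfSegments, p("self_segments.tsv"))
  writeAlignmentSegments(scenario@yVsOtherSegments, p("y_vs_other.tsv"))
  writeBedFile(scenario@repeats, p("repeats.bed"))
  g <- scenario@genes
  mcols(g)$name <- names(g)
  writeBedFile(g, p("genes.bed"))
  writeExpressionMatrix(scenario@expression, p("expression.tsv"))
  write.table(data.frame(scaffold = names(scenario@truthScaffoldLabels),
                         label = scenario@truthScaffoldLabels),
              p("truth_scaffold_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(scenario@truthGaps, p("truth_gaps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
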