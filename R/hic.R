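#' Extract the interaction profile between a scaffold and a chromosome
#'
#' Returns one strength per (scaffold bin, chromosome bin) pair. By default
#' only pairs present in the records contribute (sparse); with
#' `dense = TRUE` absent pairs contribute 0, using bin counts inferred from
#' the records (or supplied via `binCounts`).
#'
#' @param records Interaction data.frame from [readInteractions()] (or the
#'   `hic` slot of a scenario), with a `resolution` attribute.
#' @param scaffold,chrom Sequence ids.
#' @param dense Include absent pairs as zeros?
#' @param binCounts Optional named vector of bin counts per sequence (used
#'   only when `dense = TRUE`).
#'
#' @return Numeric vector of interaction strengths.
#' @export
interactionProfile <- function(records, scaffold, chrom, dense = FALSE,
                               binCounts = NULL) {
  all_seqs <- unique(c(records$chromA, records$chromB))
  if (!scaffold %in% all_seqs)
    stop("scaffold ", scaffold, " absent from interaction records")
  sel1 <- records$chromA == scaffold & records$chromB == chrom
  sel2 <- records$chromB == scaffold & records$chromA == chrom
  s <- c(records$strength[sel1], records$strength[sel2])
  if (dense) {
    res <- attr(records, "resolution")
    if (is.null(binCounts)) {
      binCounts <- vapply(unique(c(records$chromA, records$chromB)),
        function(sq) {
          mx <- max(records$startA[records$chromA == sq],
                    records$startB[records$chromB == sq], 0)
          mx / res + 1
        }, numeric(1))
    }
    total <- binCounts[[scaffold]] * binCounts[[chrom]]
    if (length(s) < total) s <- c(s, rep(0, total - length(s)))
  }
  s
}

#' One-sided Wilcoxon rank-sum test (H1: x stochastically greater than y)
#'
#' Exact enumeration is used when `length(x) + length(y) <= 16` and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. Hi-C assignment decisions built on this test are invariant
#' under any monotone rescaling of the strengths.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) selects it automatically as described.
#' @return The one-sided p-value.
#' @examples
#' wilcoxonOneSided(c(5, 6, 7), c(1, 2, 3))  # 1/20
#' @export
wilcoxonOneSided <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y))
    stop("empty input to wilcoxonOneSided")
  if (is.null(exact)) {
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- (length(x) + length(y) <= 16L) && !ties
  }
  suppressWarnings(
    wilcox.test(x, y, alternative = "greater",
                exact = exact, correct = TRUE)$p.value)
}

#' Assign an unplaced scaffold to a single chromosome by Hi-C
#'
#' The scaffold's interaction profile with `candidate` is tested against
#' its profile with every competitor chromosome (one-sided Wilcoxon
#' rank-sum); the scaffold is assigned iff every competitor test has
#' p < `alpha`.
#'
#' @param records Interaction records (see [interactionProfile()]).
#' @param scaffold Unplaced scaffold id.
#' @param candidate Candidate chromosome id.
#' @param competitors Character vector of competing anchored chromosomes.
#' @param alpha Per-test significance level.
#' @param dense Passed to [interactionProfile()].
#'
#' @return A list: `scaffold`, `mode`, `targets`, `pValues` (named by
#'   competitor), `decision` ("assigned"/"unassigned"), `alpha`.
#' @export
assignSingle <- function(records, scaffold, candidate, competitors,
                         alpha = 0.05, dense = FALSE) {
  if (candidate %in% competitors)
    stop("candidate must not appear among competitors")
  if (alpha >= 1)
    warning("alpha >= 1 makes every scaffold assigned")
  target <- interactionProfile(records, scaffold, candidate, dense = dense)
  p <- vapply(competitors, function(comp) {
    wilcoxonOneSided(target,
                     interactionProfile(records, scaffold, comp,
                                        dense = dense))
  }, numeric(1))
  list(scaffold = scaffold, mode = "single_target", targets = candidate,
       pValues = p,
       decision = if (all(p < alpha)) "assigned" else "unassigned",
       alpha = alpha)
}

#' Assign an unplaced scaffold to a chromosome pair (PAR call) by Hi-C
#'
#' A pseudoautosomal scaffold interacts strongly with *both* chromosomes of
#' its pair. The scaffold's profiles with the two pair members are pooled
#' into one dataset and compared against its profile with each competitor
#' chromosome; the scaffold is called the pair's PAR iff every competitor
#' test has p < `alpha`. With `pooled = FALSE` each pair member is instead
#' required to beat every competitor on its own (AND rule).
#'
#' @param records,scaffold,competitors,alpha,dense See [assignSingle()].
#' @param pair Character vector of the two pair chromosomes.
#' @param pooled Pool the two pair profiles (default) or test each
#'   separately?
#'
#' @return As [assignSingle()], with `mode = "pair_target"`. For
#'   `pooled = FALSE` the p-values matrix has one row per pair member.
#' @export
assignPair <- function(records, scaffold, pair, competitors,
                       alpha = 0.05, dense = FALSE, pooled = TRUE) {
  stopifnot(length(pair) == 2L)
  if (any(pair %in% competitors))
    stop("pair chromosomes must not appear among competitors")
  if (alpha >= 1)
    warning("alpha >= 1 makes every scaffold assigned")
  profiles <- lapply(pair, function(ch)
    interactionProfile(records, scaffold, ch, dense = dense))
  if (pooled) {
    target <- unlist(profiles)
    p <- vapply(competitors, function(comp) {
      wilcoxonOneSided(target,
                       interactionProfile(records, scaffold, comp,
                                          dense = dense))
    }, numeric(1))
    decision <- if (all(p < alpha)) "assigned" else "unassigned"
  } else {
    p <- sapply(competitors, function(comp) {
      comp_prof <- interactionProfile(records, scaffold, comp, dense = dense)
      vapply(profiles, wilcoxonOneSided, numeric(1), y = comp_prof)
    })
    p <- matrix(p, nrow = 2L, dimnames = list(pair, competitors))
    decision <- if (all(p < alpha)) "assigned" else "unassigned"
  }
  list(scaffold = scaffold, mode = "pair_target", targets = pair,
       pValues = p, decision = decision, alpha = alpha)
}
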