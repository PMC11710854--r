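#' Tau tissue-specificity index
#'
#' For a profile of mean expression values x_i over n >= 2 tissues,
#' `tau = sum_i (1 - x_i / max_j x_j) / (n - 1)`: 0 for uniform
#' (ubiquitous) expression, 1 for single-tissue expression. Computed on
#' linear TPM by default; `log2(x+1)` transformation available.
#'
#' @param values Non-negative expression values, one per tissue
#'   (replicate-averaged).
#' @param log2Transform Apply `log2(x + 1)` before computing tau?
#'
#' @return Tau in \[0, 1\]; `NA` for an all-zero profile.
#' @examples
#' tauIndex(c(10, 5, 0, 5))  # 2/3
#' @export
tauIndex <- function(values, log2Transform = FALSE) {
  if (length(values) < 2L)
    stop("tau requires at least two tissues")
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  if (log2Transform) values <- log2(values + 1)
  mx <- max(values)
  if (is.na(mx) || mx == 0) return(NA_real_)
  sum(1 - values / mx) / (length(values) - 1L)
}

#' Average replicate columns of an expression matrix by tissue
#'
#' Columns named `tissue.replicate` (anything after the first `.` is the
#' replicate id) are averaged into one column per tissue.
#'
#' @param mat Numeric matrix, genes x columns.
#' @return Numeric matrix, genes x tissues.
#' @export
averageReplicates <- function(mat) {
  tissue <- sub("\\..*$", "", colnames(mat))
  out <- sapply(unique(tissue), function(t)
    rowMeans(mat[, tissue == t, drop = FALSE]))
  matrix(out, nrow = nrow(mat),
         dimnames = list(rownames(mat), unique(tissue)))
}

#' Flag tissue-specific genes by tau
#'
#' A gene is specific to `tissue` when its tau reaches `threshold`
#' (inclusive) *and* that tissue is the unique expression maximum (ties
#' break as non-specific).
#'
#' @param mat Numeric matrix, genes x tissues (replicate-averaged TPM).
#' @param tissue Target tissue name.
#' @param threshold Tau cutoff.
#' @param log2Transform Passed to [tauIndex()].
#'
#' @return A `data.frame`: gene, tau, topTissue, isSpecific.
#' @export
classifySpecific <- function(mat, tissue = "testis", threshold = 0.8,
                             log2Transform = FALSE) {
  if (!tissue %in% colnames(mat))
    stop("tissue '", tissue, "' not in matrix columns")
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    tv <- tauIndex(v, log2Transform = log2Transform)
    mx <- max(v)
    top <- if (mx > 0 && sum(v == mx) == 1L) colnames(mat)[which.max(v)]
           else NA_character_
    data.frame(gene = rownames(mat)[i], tau = tv, topTissue = top,
               isSpecific = !is.na(tv) && tv >= threshold &&
                 !is.na(top) && top == tissue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
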