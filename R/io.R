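#' Read and write the pipeline's file formats
#'
#' Thin readers/writers around the formats the pipeline touches. All
#' on-disk coordinates are 0-based half-open (BED convention); in-memory
#' objects use `GRanges` (1-based closed) -- the conversion is confined to
#' these functions. Malformed lines raise errors naming the file and line.
#'
#' * FASTA via Biostrings ([readFastaFile()] uppercases on read).
#' * BED3/BED6 via rtracklayer ([readBedFile()], [writeBedFile()]).
#' * bedGraph dialect with `NA` values ([readBedGraph()], [writeBedGraph()]).
#' * Alignment-segment TSV with columns
#'   `q_name,q_start,q_end,t_name,t_strand,t_start,t_end,identity_pct,aligned_len`
#'   (the lastZ `--format=general` field list).
#' * Interaction TSV `chrom_a,start_a,chrom_b,start_b,strength` with a
#'   `#resolution=<bp>` header line.
#' * Expression TSV: genes x tissues matrix of TPM.
#'
#' @name io
NULL

#' Read a FASTA file as an uppercased DNAStringSet
#'
#' @param path FASTA file.
#' @return A `DNAStringSet`; sequences are uppercased, names are the first
#'   whitespace-delimited token.
#' @export
readFastaFile <- function(path) {
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence names in ", path)
  # DNAStringSet reads lowercase as-is; normalise case
  DNAStringSet(toupper(x))
}

#' @rdname readFastaFile
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @export
writeFastaFile <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read/write BED3 or BED6 intervals
#'
#' @param path BED file.
#' @return `readBedFile()`: a `GRanges` (with `name`, `score` columns when
#'   BED6).
#' @export
readBedFile <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname readBedFile
#' @param gr A `GRanges`.
#' @export
writeBedFile <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph-style track with NA support
#'
#' Four tab-separated columns `chrom start end value`; `value` may be the
#' literal string `NA` for missing windows. Overlapping windows are
#' accepted and flagged via [isOverlapping()].
#'
#' @param path bedGraph file.
#' @return A [WindowTrack-class].
#' @export
readBedGraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx))
    stop("no data lines in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed bedGraph line ", idx[which(nf != 4L)[1L]], " in ", path,
         ": expected 4 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end0 <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
  if (length(bad))
    stop("malformed bedGraph line ", idx[bad[1L]], " in ", path,
         ": invalid coordinates")
  vals <- suppressWarnings(as.numeric(m[, 4L]))
  badv <- which(is.na(vals) & m[, 4L] != "NA")
  if (length(badv))
    stop("malformed bedGraph line ", idx[badv[1L]], " in ", path,
         ": non-numeric value")
  windowTrack(GRanges(m[, 1L], IRanges(start0 + 1, end0)), vals)
}

#' @rdname readBedGraph
#' @param track A [WindowTrack-class].
#' @export
writeBedGraph <- function(track, path) {
  gr <- trackWindows(track)
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   ifelse(is.na(trackValues(track)), "NA",
                          format(trackValues(track), digits = 15,
                                 scientific = FALSE, trim = TRUE)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.alnCols <- c("q_name", "q_start", "q_end", "t_name", "t_strand",
              "t_start", "t_end", "identity_pct", "aligned_len")

#' Read/write alignment segments in the general TSV dialect
#'
#' Columns `q_name,q_start,q_end,t_name,t_strand,t_start,t_end,
#' identity_pct,aligned_len`, with a header line, coordinates 0-based
#' half-open, minus-strand target coordinates already forward-strand.
#'
#' @param path TSV file.
#' @return An [AlignmentSegments-class].
#' @export
readAlignmentSegments <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(.alnCols %in% names(df)))
    stop("alignment TSV ", path, " must have columns: ",
         paste(.alnCols, collapse = ","))
  bad <- which(!df$t_strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand symbol '", df$t_strand[bad[1L]], "' at line ",
         bad[1L] + 1L, " in ", path)
  alignmentSegments(
    query = GRanges(df$q_name, IRanges(df$q_start + 1, df$q_end)),
    target = GRanges(df$t_name, IRanges(df$t_start + 1, df$t_end)),
    segStrand = df$t_strand,
    identity = df$identity_pct / 100,
    alignedLength = df$aligned_len)
}

#' @rdname readAlignmentSegments
#' @param segments An [AlignmentSegments-class].
#' @export
writeAlignmentSegments <- function(segments, path) {
  write.table(segAsDataFrame(segments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read/write Hi-C interaction records
#'
#' TSV with a `#resolution=<bp>` header line followed by a header row and
#' records `chrom_a,start_a,chrom_b,start_b,strength` (starts 0-based bin
#' starts; strength >= 0). The resolution is attached as the `resolution`
#' attribute of the returned data.frame.
#'
#' @param path TSV file.
#' @return A `data.frame` (chromA, startA, chromB, startB, strength) with a
#'   `resolution` attribute.
#' @export
readInteractions <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#resolution=", first))
    stop("interaction TSV ", path, " must start with '#resolution=<bp>'")
  res <- as.numeric(sub("^#resolution=", "", first))
  if (is.na(res) || res <= 0)
    stop("invalid resolution in header of ", path)
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1L,
                   stringsAsFactors = FALSE)
  names(df) <- c("chromA", "startA", "chromB", "startB", "strength")
  if (any(df$strength < 0))
    stop("negative interaction strength in ", path)
  attr(df, "resolution") <- res
  df
}

#' @rdname readInteractions
#' @param records Interaction data.frame with a `resolution` attribute.
#' @export
writeInteractions <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#resolution=%d", as.integer(attr(records, "resolution"))),
             con)
  out <- records
  names(out) <- c("chrom_a", "start_a", "chrom_b", "start_b", "strength")
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a gene-by-tissue expression matrix
#'
#' TSV with gene ids in the first column and one column per tissue (or
#' `tissue.replicate`); values are TPM.
#'
#' @param path TSV file.
#' @return A numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname readExpressionMatrix
#' @param mat Numeric matrix, gene rownames, tissue colnames.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
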