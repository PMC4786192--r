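## Per-column conservation statistics of a multiple sequence alignment:
## variability (VAR), Shannon entropy (ENT) and a compression-based
## Kolmogorov-complexity estimate (KOL).

#: the 20 standard amino-acid one-letter codes; everything else in a
#: column (gaps "-"/".", unknown "X", ambiguity codes) is ignored by the
#: per-column counts.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a multiple sequence alignment from aligned FASTA
#'
#' Reads an aligned FASTA file (gap "-", unknown "X") with
#' \code{Biostrings::readAAStringSet} and validates that it is a genuine
#' alignment: at least two records, all of identical length.
#'
#' @param path path to an aligned FASTA file
#' @return an [Biostrings::AAStringSet] with one record per sequence,
#'   order preserved
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACD-", ">s2", "ACEW"), f)
#' aln <- readAlignment(f)
#' @export
readAlignment <- function(path) {
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) == 0L)
    stop("empty alignment file: ", path)
  if (length(aln) < 2L)
    stop("need >=2 sequences, got ", length(aln))
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    stop("ragged alignment: record '", names(aln)[bad], "' has length ",
         w[bad], " but record '", names(aln)[1L], "' has length ", w[1L])
  }
  if (w[1L] < 1L)
    stop("alignment has zero columns")
  aln
}

## character matrix view of an alignment (rows = sequences, cols = positions)
alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  m <- as.matrix(aln)
  mode(m) <- "character"
  m
}

#' Residue counts for one alignment column
#'
#' Counts occurrences of the 20 standard residues at alignment position
#' \code{pos}.  Gaps, "X" and any other non-standard symbols are excluded
#' from the counts and from \code{nUngapped}.
#'
#' @param aln an alignment ([readAlignment()]) or a character matrix
#' @param pos 1-based column index
#' @return a list with \code{position}, \code{counts} (named integer
#'   vector over observed residues) and \code{nUngapped}
#' @export
columnProfile <- function(aln, pos) {
  m <- alignmentMatrix(aln)
  if (pos < 1L || pos > ncol(m))
    stop("position ", pos, " out of range 1..", ncol(m))
  col <- m[, pos]
  col <- col[col %in% AA_LETTERS]
  counts <- table(col)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(position = as.integer(pos), counts = counts,
       nUngapped = sum(counts))
}

#' Shannon entropy of a column profile (bits)
#'
#' H = -sum_a p_a log2 p_a with p_a = count_a / nUngapped.  An all-gap
#' column has no defined entropy and yields NA rather than 0.
#'
#' @param profile a column profile from [columnProfile()]
#' @return entropy in bits, in [0, log2(min(20, nUngapped))]; NA for an
#'   all-gap column
#' @export
shannonEntropy <- function(profile) {
  n <- profile$nUngapped
  if (n == 0L) return(NA_real_)
  p <- profile$counts / n
  -sum(p * log2(p))
}

#' Column variability: number of distinct residue types
#'
#' @param profile a column profile from [columnProfile()]
#' @param normalize divide by 20 so the score lies in (0, 1]
#' @return distinct-residue count (or fraction); NA for an all-gap column
#' @export
variability <- function(profile, normalize = FALSE) {
  if (profile$nUngapped == 0L) return(NA_real_)
  v <- length(profile$counts)
  if (normalize) v / 20 else as.numeric(v)
}

## Deterministic pseudo-random byte stream (LCG), used to build the
## incompressible reference strings for the complexity estimator.  Kept
## independent of R's RNG so scores never depend on the session seed.
referenceBytes <- function(len) {
  x <- 48271
  out <- integer(len)
  for (i in seq_len(len)) {
    x <- (x * 1103515245 + 12345) %% 2147483648
    out[i] <- (x %/% 65536) %% 256L
  }
  as.raw(out)
}

compressedSize <- function(bytes, type = "gzip") {
  length(memCompress(bytes, type = type))
}

## memoised compressed size of the reference stream per length
.refCache <- new.env(parent = emptyenv())
referenceCompressedSize <- function(len, type = "gzip") {
  key <- paste0(type, ":", len)
  if (is.null(.refCache[[key]]))
    .refCache[[key]] <- compressedSize(referenceBytes(len), type = type)
  .refCache[[key]]
}

#' Compression-based complexity score of one alignment column
#'
#' Estimates the Kolmogorov complexity of the column by lossless
#' compression: the column's non-gap residues are concatenated into a
#' string, compressed, and the compressed size is divided by the
#' compressed size of an incompressible reference byte string of equal
#' length, then clipped to [0, 1].  A fully conserved column compresses
#' far better than a maximally mixed one and so scores lower.  The score
#' is deterministic for a fixed compressor; the compressor is recorded in
#' the output of [columnScores()].
#'
#' @param aln an alignment or character matrix
#' @param pos 1-based column index
#' @param compressor compression type passed to [memCompress()]
#'   ("gzip", "bzip2" or "xz")
#' @return score in [0, 1]; NA when the column has fewer than 2 non-gap
#'   residues
#' @export
kolmogorovScore <- function(aln, pos, compressor = "gzip") {
  prof <- columnProfile(aln, pos)
  if (prof$nUngapped < 2L) return(NA_real_)
  m <- alignmentMatrix(aln)
  col <- m[, pos]
  col <- col[col %in% AA_LETTERS]
  s <- charToRaw(paste(col, collapse = ""))
  ratio <- compressedSize(s, type = compressor) /
    referenceCompressedSize(length(s), type = compressor)
  min(max(ratio, 0), 1)
}

#' Per-column conservation scores for a whole alignment
#'
#' Computes VAR, ENT and KOL for every alignment column.  Columns with
#' fewer than \code{minUngappedFrac} of their symbols among the 20
#' standard residues are flagged missing (NA scores) and should not enter
#' range selection.
#'
#' @param aln an alignment ([readAlignment()]) or character matrix
#' @param normalizeVar report VAR as a fraction of 20 instead of a count
#' @param compressor compressor for the complexity score (see
#'   [kolmogorovScore()])
#' @param minUngappedFrac minimum fraction of ungapped symbols for a
#'   column to be scored (default 0.5)
#' @return data.frame with columns position, var, ent, kol, n_ungapped;
#'   the compressor configuration is attached as attribute
#'   \code{"compressor"}
#' @examples
#' m <- matrix(c("A", "A", "A", "C"), nrow = 2)
#' columnScores(m)
#' @export
columnScores <- function(aln, normalizeVar = FALSE, compressor = "gzip",
                         minUngappedFrac = 0.5) {
  m <- alignmentMatrix(aln)
  nseq <- nrow(m)
  res <- lapply(seq_len(ncol(m)), function(pos) {
    prof <- columnProfile(m, pos)
    ok <- prof$nUngapped >= minUngappedFrac * nseq && prof$nUngapped >= 1L
    data.frame(
      position = pos,
      var = if (ok) variability(prof, normalize = normalizeVar) else NA_real_,
      ent = if (ok) shannonEntropy(prof) else NA_real_,
      kol = if (ok) kolmogorovScore(m, pos, compressor = compressor)
            else NA_real_,
      n_ungapped = prof$nUngapped)
  })
  out <- do.call(rbind, res)
  attr(out, "compressor") <- compressor
  out
}

#' Write column scores as TSV
#'
#' One row per column (position, var, ent, kol, n_ungapped) preceded by a
#' comment header recording the compressor configuration, so score files
#' are self-describing and reproducible.
#'
#' @param scores output of [columnScores()]
#' @param path output file
#' @return invisibly, the path
#' @export
writeColumnScores <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# compressor: %s",
                     attr(scores, "compressor") %||% "gzip"), con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
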