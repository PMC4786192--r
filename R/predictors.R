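## Turning conservation scores, a residue-pair likelihood matrix, or
## external server output into PredictionSets of candidate contacts.

newPredictionSet <- function(method, pairs, provenance) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) > 0L) {
    # normalize to i < j and de-duplicate, ordered by (i, j)
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                   pmax(pairs[, 1L], pairs[, 2L]))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  new("PredictionSet", method = method, pairs = pairs,
      provenance = provenance)
}

#' Select alignment positions whose score falls in a band
#'
#' Range selection: positions whose conservation score lies in the closed
#' interval [center - halfWidth, center + halfWidth] are declared
#' candidate contact participants.  Missing scores never match.
#'
#' @param scores numeric vector of per-position scores (NA = missing)
#' @param center band center, on the score's own scale
#' @param halfWidth band half-width (> 0, default 0.05)
#' @return integer vector of selected positions (possibly empty)
#' @export
selectPositions <- function(scores, center, halfWidth = 0.05) {
  if (halfWidth <= 0)
    stop("halfWidth must be positive")
  sel <- which(!is.na(scores) &
               scores >= center - halfWidth &
               scores <= center + halfWidth)
  if (length(sel) == 0L)
    message("range selection [", center - halfWidth, ", ",
            center + halfWidth, "] is empty")
  as.integer(sel)
}

#' All unordered pairs over a set of selected positions
#'
#' The pairing rule for the range-based predictors: every unordered pair
#' of in-band positions is proposed as a contact, k(k-1)/2 pairs for k
#' selected positions.
#'
#' @param selected integer vector of positions
#' @param method label for the resulting [PredictionSet-class]
#' @param provenance free-text provenance
#' @return a [PredictionSet-class]
#' @export
pairsFromSelection <- function(selected, method = "other",
                               provenance = "all pairs over selection") {
  selected <- sort(unique(as.integer(selected)))
  k <- length(selected)
  pairs <- if (k < 2L) matrix(integer(), ncol = 2L)
           else t(utils::combn(selected, 2L))
  newPredictionSet(method, pairs, provenance)
}

#' Default band half-width for each conservation score
#'
#' The three scores live on different scales, so a sensible band width
#' differs: 0.05 on the [0, 1] complexity (KOL) scale, 0.5 bits on the
#' entropy scale (0 to log2(20) ~ 4.32), and 1.5 residue types on the
#' variability count scale (1..20).  Each is roughly 1/9 of the usable
#' range, mirroring the complexity score's calibrated +/- 0.05 slice.
#'
#' @param score one of "var", "ent", "kol"
#' @return half-width on that score's scale
#' @export
defaultHalfWidth <- function(score = c("kol", "ent", "var")) {
  score <- match.arg(score)
  c(kol = 0.05, ent = 0.5, var = 1.5)[[score]]
}

#' Range-based predictor from per-column scores
#'
#' Convenience wrapper: [selectPositions()] then [pairsFromSelection()].
#'
#' @param scores per-position score vector
#' @param center,halfWidth score band (see [selectPositions()])
#' @param method label, e.g. "KOL", "VRN", "ENT"
#' @return a [PredictionSet-class]
#' @export
rangePredict <- function(scores, center, halfWidth = 0.05,
                         method = "other") {
  sel <- selectPositions(scores, center, halfWidth)
  pairsFromSelection(sel, method = method,
                     provenance = sprintf("score band %.4g +/- %.4g (%d positions)",
                                          center, halfWidth, length(sel)))
}

#' Read a 20x20 residue-pair likelihood matrix
#'
#' Reads a whitespace-delimited text table with the 20 one-letter residue
#' codes as row and column names.  The matrix must be complete and
#' symmetric.
#'
#' @param path text file
#' @return symmetric 20 x 20 numeric matrix with residue dimnames
#' @export
readSvbMatrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                   check.names = FALSE))
  validateSvbMatrix(m)
  m
}

validateSvbMatrix <- function(m) {
  if (!all(AA_LETTERS %in% rownames(m)) || !all(AA_LETTERS %in% colnames(m)))
    stop("likelihood matrix must cover all 20 residue types; missing: ",
         paste(setdiff(AA_LETTERS, intersect(rownames(m), colnames(m))),
               collapse = ", "))
  m <- m[AA_LETTERS, AA_LETTERS]
  if (any(!is.finite(m)))
    stop("likelihood matrix has non-finite entries")
  if (max(abs(m - t(m))) > 1e-8)
    stop("likelihood matrix must be symmetric")
  invisible(m)
}

#' Synthetic residue-pair likelihood matrix
#'
#' Generates a symmetric 20x20 matrix of pair likelihoods for tests and
#' examples.  This is a synthetic stand-in, not a matrix derived from any
#' structure database: values are drawn from a log-normal and
#' symmetrised, which gives the right shape (positive, skewed, complete)
#' but carries no biological signal.
#'
#' @param seed integer seed
#' @return symmetric 20 x 20 numeric matrix with residue dimnames
#' @export
syntheticSvbMatrix <- function(seed = 1L) {
  withSeed(seed, {
    m <- matrix(stats::rlnorm(400, sdlog = 0.6), 20, 20,
                dimnames = list(AA_LETTERS, AA_LETTERS))
    (m + t(m)) / 2
  })
}

#' Residue-pair likelihood predictor
#'
#' Proposes every pair (i, j), i < j, of sequence positions whose residue
#' types have pair likelihood at or above \code{threshold}.  Positions
#' carrying non-standard letters are skipped with a warning.
#'
#' @param sequence amino-acid sequence (single string or character vector)
#' @param matrix complete symmetric 20x20 likelihood matrix
#'   ([readSvbMatrix()] or [syntheticSvbMatrix()])
#' @param threshold likelihood threshold; lowering it can only add pairs
#' @return a [PredictionSet-class] with method "SVB"
#' @export
svbPredict <- function(sequence, matrix, threshold) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  matrix <- validateSvbMatrix(matrix)
  ok <- sequence %in% AA_LETTERS
  if (any(!ok))
    warning(sum(!ok), " position(s) with non-standard residue letters skipped")
  pos <- which(ok)
  pairs <- matrix(integer(), ncol = 2L)
  if (length(pos) >= 2L) {
    cand <- t(utils::combn(pos, 2L))
    lik <- matrix[cbind(sequence[cand[, 1L]], sequence[cand[, 2L]])]
    pairs <- cand[lik >= threshold, , drop = FALSE]
  }
  newPredictionSet("SVB", pairs,
                   sprintf("pair likelihood >= %.4g over %d positions",
                           threshold, length(pos)))
}

#' Read an externally produced contact-prediction pair list
#'
#' Parses plain-text pair lists as produced by coevolution or
#' substitution-matrix contact servers: one pair per line,
#' whitespace- or comma-delimited, "i j" or "i j score" with 1-based
#' residue indices.  Pairs are normalized to i < j and de-duplicated
#' (keeping the highest score).  Self-pairs (i = j) are skipped with a
#' warning; a non-integer index is a hard error naming the line.
#'
#' @param path text file of predictions
#' @param topK keep only the k highest-scoring pairs ("all" keeps
#'   everything; requires a score column); ties broken by (i, j)
#'   lexicographic order
#' @param method label for the resulting set (e.g. "CMA", "P2P")
#' @return a [PredictionSet-class]
#' @export
readExternalPredictions <- function(path, topK = "all", method = "other") {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop("no prediction lines in ", path)
  i <- j <- integer(length(lines))
  score <- rep(NA_real_, length(lines))
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "[,[:space:]]+")[[1L]]
    if (length(tok) < 2L)
      stop("line ", lineno[k], ": expected 'i j [score]', got '",
           lines[k], "'")
    ii <- suppressWarnings(as.numeric(tok[1:2]))
    if (any(is.na(ii)) || any(ii != round(ii)))
      stop("line ", lineno[k], ": non-integer residue index in '",
           lines[k], "'")
    i[k] <- as.integer(ii[1L]); j[k] <- as.integer(ii[2L])
    if (length(tok) >= 3L)
      score[k] <- suppressWarnings(as.numeric(tok[3L]))
  }
  self <- i == j
  if (any(self)) {
    warning(sum(self), " self-pair(s) (i = j) skipped")
    i <- i[!self]; j <- j[!self]; score <- score[!self]
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  df <- data.frame(i = lo, j = hi, score = score)
  # de-duplicate, keeping the highest score for a repeated pair
  df <- df[order(df$i, df$j, -xtfrm(df$score)), , drop = FALSE]
  df <- df[!duplicated(df[, c("i", "j")]), , drop = FALSE]
  if (!identical(topK, "all")) {
    topK <- as.integer(topK)
    if (all(is.na(df$score)))
      stop("topK requested but file has no score column")
    df <- df[order(-xtfrm(df$score), df$i, df$j), , drop = FALSE]
    df <- utils::head(df, topK)
  }
  newPredictionSet(method, cbind(df$i, df$j),
                   sprintf("read from %s (top_k = %s, %d pairs)",
                           basename(path), as.character(topK), nrow(df)))
}
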